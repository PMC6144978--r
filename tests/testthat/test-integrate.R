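mk_part <- function(ids, ent, method, marker) {
  structure(tibble::tibble(specimen_id = ids, entity_id = ent),
            method = method, marker = marker)
}

test_that("a split supported by two COI methods is adopted over a lumping 28S", {
  ids <- paste0("s", 1:6) # one morphospecies, 6 specimens
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "Adelencyrtus aulacaspidis")
  split2 <- c(1, 1, 1, 2, 2, 2)
  res <- integrate_delimitations(morpho, list(
    mk_part(ids, split2, "ABGD", "COI"),
    mk_part(ids, split2, "GMYC", "COI"),
    mk_part(ids, rep(1, 6), "ABGD", "28S")
  ))
  expect_equal(length(unique(res$partition$entity_id)), 2)
  rep1 <- res$report
  expect_equal(rep1$n_entities, 2)
  expect_equal(rep1$ABGD_COI, "y")
  expect_equal(rep1$GMYC_COI, "y")
  expect_equal(rep1$ABGD_28S, "n")
})

test_that("unanimous no-split keeps the morphospecies whole", {
  ids <- paste0("s", 1:4)
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "m1")
  res <- integrate_delimitations(morpho, list(
    mk_part(ids, rep(1, 4), "ABGD", "COI"),
    mk_part(ids, rep(1, 4), "GMYC", "COI")
  ))
  expect_equal(length(unique(res$partition$entity_id)), 1)
  expect_equal(res$report$ABGD_COI, "y")
})

test_that("two agreeing splitters outvote one lumper (4 entities)", {
  ids <- paste0("s", 1:8)
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "Zaomma lambinus")
  four <- rep(1:4, each = 2)
  res <- integrate_delimitations(morpho, list(
    mk_part(ids, rep(1, 8), "ABGD", "COI"),
    mk_part(ids, four, "GMYC", "COI"),
    mk_part(ids, four, "PTP", "COI")
  ))
  expect_equal(length(unique(res$partition$entity_id)), 4)
  expect_equal(res$report$ABGD_COI, "n")
  expect_equal(res$report$GMYC_COI, "y")
})

test_that("disagreeing splitters without a majority fall back to no split", {
  ids <- paste0("s", 1:6)
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "m1")
  res <- integrate_delimitations(morpho, list(
    mk_part(ids, c(1, 1, 1, 2, 2, 2), "ABGD", "COI"),
    mk_part(ids, c(1, 2, 3, 4, 5, 6), "GMYC", "COI"),
    mk_part(ids, rep(1, 6), "PTP", "COI")
  ))
  expect_equal(length(unique(res$partition$entity_id)), 1)
})

test_that("consensus refines but never lumps morphospecies", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 20
    ids <- sprintf("x%02d", 1:n)
    morpho <- tibble::tibble(specimen_id = ids,
                             morphospecies = sample(c("A", "B", "C"), n, TRUE))
    # molecular methods that freely merge across morphospecies
    p1 <- mk_part(ids, sample(1:4, n, TRUE), "ABGD", "COI")
    p2 <- mk_part(ids, sample(1:4, n, TRUE), "GMYC", "COI")
    res <- integrate_delimitations(morpho, list(p1, p2))
    part <- res$partition
    # refinement: every entity sits inside exactly one morphospecies
    cross <- part |> dplyr::distinct(.data$entity_id, .data$morphospecies) |>
      dplyr::count(.data$entity_id)
    expect_true(all(cross$n == 1))
    expect_gte(length(unique(part$entity_id)),
               length(unique(morpho$morphospecies)))
  }
})

test_that("specimens without molecular data are carried as their morphospecies", {
  ids <- paste0("s", 1:5)
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "m1")
  res <- integrate_delimitations(morpho, list(
    mk_part(ids[1:3], c(1, 1, 2), "ABGD", "COI"),
    mk_part(ids[1:3], c(1, 1, 2), "GMYC", "COI")
  ))
  expect_false(any(res$partition$molecular_data[4:5]))
  expect_equal(res$report$no_molecular_data, 2)
  # unsequenced specimens fold into an existing entity, not new singletons
  expect_lte(length(unique(res$partition$entity_id)), 2)
})

test_that("a single COI method decides alone", {
  ids <- paste0("s", 1:4)
  morpho <- tibble::tibble(specimen_id = ids, morphospecies = "m1")
  res <- integrate_delimitations(morpho, list(
    mk_part(ids, c(1, 1, 2, 2), "ABGD", "COI")
  ))
  expect_equal(length(unique(res$partition$entity_id)), 2)
})
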