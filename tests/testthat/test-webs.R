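test_that("records aggregate into the expected matrix", {
  M <- build_web(toy_records())
  expect_equal(unclass(M)[c("h1", "h2"), c("p1", "p2")],
               matrix(c(5L, 0L, 3L, 2L), 2, 2,
                      dimnames = list(c("h1", "h2"), c("p1", "p2"))),
               ignore_attr = TRUE)
  expect_equal(grand_total(M), 10)
  expect_equal(attr(M, "dropped_records"), 0)
})

test_that("marginals and availabilities are consistent on random matrices", {
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rpois(12, 2), 3, 4)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    M <- interaction_matrix(m)
    expect_equal(sum(host_totals(M)), grand_total(M))
    expect_equal(sum(parasitoid_totals(M)), grand_total(M))
    expect_equal(sum(host_availability(M)), 1)
  }
})

test_that("splitting a host by specimen province preserves row sums and m", {
  rec <- toy_records()
  rec$host_specimens <- list(c("ha1", "ha2"), c("hb1"), c("hc1"))
  host_map <- tibble::tibble(
    specimen_id = c("ha1", "ha2", "hb1", "hc1"),
    morphospecies = c("h1", "h1", "h1", "h2"),
    taxon = c("h1a", "h1a", "h1b", "h2")
  )
  M <- build_web(rec, host_map = host_map)
  expect_equal(grand_total(M), 10)
  expect_equal(nrow(M), 3)
  expect_equal(sum(unclass(M)["h1a", ]) + sum(unclass(M)["h1b", ]), 8)
})

test_that("unknown labels raise a mapping error naming the label", {
  rec <- toy_records()
  host_map <- tibble::tibble(specimen_id = "z1", morphospecies = "h1", taxon = "h1")
  expect_error(build_web(rec, host_map = host_map), "h2",
               class = "cryptwebs_mapping_error")
})

test_that("apportioning uses largest-remainder on sequenced specimens", {
  rec <- tibble::tibble(
    sample_id = "s1", site_id = "A", province = "Yunnan",
    host_mor = "h1", parasitoid_mor = "p1", count = 7L,
    host_specimens = list(character(0)),
    parasitoid_specimens = list(c("a", "b", "c"))
  )
  para_map <- tibble::tibble(
    specimen_id = c("a", "b", "c"),
    morphospecies = "p1", taxon = c("p1x", "p1x", "p1y")
  )
  M <- build_web(rec, para_map = para_map)
  # 7 * (2/3, 1/3) -> (4.67, 2.33) -> largest remainder (5, 2)
  expect_equal(unclass(M)["h1", c("p1x", "p1y")], c(p1x = 5, p1y = 2))
  # a record of a split morphospecies without specimens is dropped
  rec2 <- rec
  rec2$parasitoid_specimens <- list(character(0))
  expect_error(build_web(rec2, para_map = para_map),
               class = "cryptwebs_empty_web_error")
})

test_that("the four crossed webs share the grand total", {
  cfg <- small_sim_config(7)
  study <- simulate_study(cfg, alignments = FALSE)
  maps <- study$truth
  ws <- build_webset(study$records, maps$host, maps$parasitoid)
  ms <- vapply(ws, grand_total, numeric(1))
  expect_equal(length(unique(ms)), 1)
  # refinement: molecular webs have at least as many links
  links <- vapply(ws, function(M) sum(unclass(M) > 0), numeric(1))
  expect_gte(links[["MOL-MOL"]], links[["MOR-MOR"]])
  expect_gte(ncol(ws[["MOR-MOL"]]), ncol(ws[["MOR-MOR"]]))
  expect_gte(nrow(ws[["MOL-MOR"]]), nrow(ws[["MOR-MOR"]]))
})

test_that("identity maps reproduce the morphospecies web", {
  rec <- toy_records()
  rec$host_specimens <- list("a1", "a2", "b1")
  rec$parasitoid_specimens <- list("q1", "q2", "q3")
  host_map <- tibble::tibble(specimen_id = c("a1", "a2", "b1"),
                             morphospecies = c("h1", "h1", "h2"),
                             taxon = c("h1", "h1", "h2"))
  para_map <- tibble::tibble(specimen_id = c("q1", "q2", "q3"),
                             morphospecies = c("p1", "p2", "p2"),
                             taxon = c("p1", "p2", "p2"))
  ws <- build_webset(rec, host_map, para_map)
  for (k in names(ws)) {
    expect_equal(unclass(ws[[k]]), unclass(ws[["MOR-MOR"]]), ignore_attr = TRUE)
  }
})

test_that("province subsetting is exact, case-sensitive, and commutes with building", {
  rec <- toy_records()
  expect_equal(nrow(subset_by_province(rec, "Yunnan")), 2)
  expect_warning(sub0 <- subset_by_province(rec, "yunnan"), "yunnan")
  expect_equal(nrow(sub0), 0)
  expect_equal(nrow(subset_by_province(rec, "yunnan", normalize = TRUE)), 2)
  expect_equal(nrow(subset_by_province(rec, " Yunnan ")), 2)

  # subset-then-build equals build-then-filter to Yunnan rows/columns
  M_sub <- build_web(subset_by_province(rec, "Yunnan"))
  M_all <- build_web(rec)
  keep_h <- rownames(M_sub); keep_p <- colnames(M_sub)
  expect_equal(unclass(M_sub),
               unclass(M_all)[keep_h, keep_p, drop = FALSE],
               ignore_attr = TRUE)
})

test_that("tidying an interaction matrix lists the positive cells", {
  M <- build_web(toy_records())
  td <- tidy(M)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$count), 10)
})
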