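dm <- function(v, nr, nc) interaction_matrix(matrix(v, nr, nc))

test_that("connectance counts realized links on the binary matrix", {
  expect_equal(connectance(dm(c(1, 1, 1, 1), 2, 2)), 1)
  M <- interaction_matrix(cbind(diag(4) * 3, c(0, 0, 0, 9)))
  expect_equal(connectance(M), 5 / 20)
  expect_equal(connectance(interaction_matrix(unclass(M) * 10)), connectance(M))
})

test_that("H2' reproduces hand-computed and enumerated extremes", {
  expect_equal(h2_prime(dm(c(4, 0, 0, 4), 2, 2)), 1)
  expect_equal(h2_prime(dm(rep(2, 4), 2, 2)), 0)
  M <- dm(c(3, 1, 1, 3), 2, 2)
  H2 <- -sum(rep(c(3, 1), 2) / 8 * log(rep(c(3, 1), 2) / 8))
  expect_equal(H2, 1.2555, tolerance = 1e-4)
  # extremes with marginals (4,4)/(4,4): H2min = ln 2 (diagonal), H2max = ln 4
  expect_equal(h2_prime(M), (log(4) - H2) / (log(4) - log(2)))
  expect_equal(round(h2_prime(M), 3), 0.189)
})

test_that("H2 extremes agree with an independent exhaustive oracle", {
  set.seed(31)
  for (rep in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    repeat {
      m <- matrix(rpois(nr * nc, 1.2), nr, nc)
      if (sum(m) >= 2 && sum(m) <= 12 && all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    rs <- rowSums(m); cs <- colSums(m)
    # oracle: enumerate row-wise compositions meeting the column totals
    fills <- list()
    grow <- function(i, caps, acc) {
      if (i > nr) { fills[[length(fills) + 1L]] <<- acc; return(invisible()) }
      comps <- compositions_of(rs[i], nc)
      for (r in seq_len(nrow(comps))) {
        if (all(comps[r, ] <= caps)) grow(i + 1, caps - comps[r, ], c(acc, comps[r, ]))
      }
    }
    grow(1, cs, numeric(0))
    h2_of <- function(cells) {
      p <- cells[cells > 0] / sum(cells)
      -sum(p * log(p))
    }
    h2s <- vapply(fills, h2_of, numeric(1))
    ex <- cryptwebs:::h2_extremes(rs, cs)
    expect_equal(ex$H2min, min(h2s), tolerance = 1e-10)
    expect_equal(ex$H2max, max(h2s), tolerance = 1e-10)
  }
})

test_that("greedy H2 extremes bracket the observed entropy on larger webs", {
  set.seed(8)
  m <- matrix(rnbinom(30 * 25, mu = 4, size = 0.5), 30, 25)
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  M <- interaction_matrix(m)
  hp <- h2_prime(M)
  expect_gte(hp, 0)
  expect_lte(hp, 1)
})

test_that("generality and vulnerability are abundance-weighted effective numbers", {
  gv <- generality_vulnerability_linkage(dm(c(3, 0, 0, 3), 2, 2))
  expect_equal(gv$generality, 1)
  gv2 <- generality_vulnerability_linkage(dm(rep(2, 4), 2, 2))
  expect_equal(gv2$generality, 2)
  # columns (3,1) and (0,4), equal column totals
  M <- interaction_matrix(matrix(c(3, 1, 0, 4), 2, 2))
  gv3 <- generality_vulnerability_linkage(M)
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(gv3$generality, 0.5 * exp(H) + 0.5 * 1)
  expect_equal(round(gv3$generality, 4), 1.3774)
  expect_equal(gv3$linkage_density, (gv3$generality + gv3$vulnerability) / 2)
})

test_that("compartments are connected components of the bipartite graph", {
  blocks <- matrix(0, 4, 4)
  blocks[1:2, 1:2] <- 1; blocks[3:4, 3:4] <- 2
  expect_equal(compartments(interaction_matrix(blocks)), 2)
  expect_equal(compartments(dm(rep(1, 9), 3, 3)), 1)
  expect_equal(compartments(interaction_matrix(diag(3) * 4)), 3)
})

test_that("NODF matches the paired-overlap definition and vegan", {
  tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nestedness(interaction_matrix(tri))$NODF, 100)
  expect_equal(nestedness(interaction_matrix(diag(3) * 2))$NODF, 0)
  rows110 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(nestedness(interaction_matrix(rows110))$NODF, 0)

  skip_if_not_installed("vegan")
  set.seed(10)
  for (i in 1:10) {
    m <- matrix(rbinom(35, 1, 0.45), 5, 7)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ours <- nestedness(interaction_matrix(m))$NODF
    ref <- unname(vegan::nestednodf(m)$statistic["NODF"])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("temperature is 0 for perfectly nested fills", {
  tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nestedness(interaction_matrix(tri))$temperature, 0)
  expect_equal(nestedness(interaction_matrix(matrix(1, 1, 1)))$temperature, 0)
  anti <- interaction_matrix(diag(3) * 2)
  expect_gt(nestedness(anti)$temperature, 0)
})

test_that("specialization asymmetry is antisymmetric and zero for symmetry", {
  M <- dm(c(4, 1, 1, 4), 2, 2)
  expect_equal(specialization_asymmetry(M), 0)
  set.seed(2)
  m <- matrix(rpois(12, 3) + 1, 3, 4)
  M2 <- interaction_matrix(m)
  M2t <- interaction_matrix(t(m))
  expect_equal(specialization_asymmetry(M2), -specialization_asymmetry(M2t))
})

test_that("robustness reproduces exact small-web values", {
  one_host <- interaction_matrix(matrix(c(3, 2, 5), 1, 3))
  expect_equal(robustness(one_host, n_orders = 5, seed = 1), 0.5)
  full22 <- dm(c(2, 2, 2, 2), 2, 2)
  expect_equal(robustness(full22, n_orders = 10, seed = 1), 0.75)
  expect_equal(robustness(interaction_matrix(diag(2) + 1 * diag(2)), n_orders = 10,
                          seed = 1), 0.5)
  expect_error(robustness(full22, n_orders = 0), class = "cryptwebs_domain_error")
  # deterministic given seed
  set.seed(99)
  m <- matrix(rbinom(30, 3, 0.4), 5, 6)
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  M <- interaction_matrix(m)
  expect_equal(robustness(M, n_orders = 50, seed = 7),
               robustness(M, n_orders = 50, seed = 7))
  # degree-ordered removal is deterministic without a seed
  expect_equal(robustness(M, order = "degree"), robustness(M, order = "degree"))
})

test_that("robustness approaches one half for one-to-one matching webs", {
  for (n in c(2, 5, 10)) {
    M <- interaction_matrix(diag(n) * 3)
    expect_equal(robustness(M, n_orders = 40, seed = 3), 0.5, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under permutations and count rescaling", {
  set.seed(14)
  # small enough that the H2 extremes come from exact enumeration
  repeat {
    m <- matrix(rpois(9, 1.2), 3, 3)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) && sum(m) <= 12) break
  }
  M <- interaction_matrix(m)
  Mp <- interaction_matrix(m[sample(nrow(m)), sample(ncol(m))])
  expect_equal(connectance(M), connectance(Mp))
  expect_equal(h2_prime(M), h2_prime(Mp), tolerance = 1e-9)
  expect_equal(generality_vulnerability_linkage(M)$linkage_density,
               generality_vulnerability_linkage(Mp)$linkage_density)
  expect_equal(compartments(M), compartments(Mp))
  expect_equal(nestedness(M)$NODF, nestedness(Mp)$NODF)
  expect_equal(specialization_asymmetry(M), specialization_asymmetry(Mp),
               tolerance = 1e-9)
  # rescaling all counts by an integer leaves the standardized metrics
  # unchanged up to integer-filling granularity of the extremes (checked on a
  # web with substantive specialization, where the ratios are stable)
  ms <- matrix(c(3, 1, 0, 0, 2, 0, 0, 0, 3), 3, 3)
  Ms <- interaction_matrix(ms)
  Ms3 <- interaction_matrix(ms * 3)
  expect_equal(h2_prime(Ms3), h2_prime(Ms), tolerance = 0.05)
  expect_equal(specialization_asymmetry(Ms3), specialization_asymmetry(Ms),
               tolerance = 0.05)
})

test_that("network_metrics assembles the full metric table", {
  M <- dm(c(3, 1, 0, 4), 2, 2)
  tab <- network_metrics(M, seed = 5, n_orders = 20)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("connectance", "H2_prime", "generality", "vulnerability",
                    "linkage_density", "n_compartments", "NODF",
                    "nestedness_temperature", "specialization_asymmetry",
                    "robustness", "rng_seed") %in% names(tab)))
  expect_equal(tab$linkage_density, (tab$generality + tab$vulnerability) / 2)
})
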