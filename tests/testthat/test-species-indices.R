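test_that("resource range matches the closed form and its boundaries", {
  expect_equal(round(resource_range(8, 28), 2), 0.74)
  expect_equal(round(resource_range(10, 37), 2), 0.75)
  expect_equal(resource_range(1, 28), 1)
  expect_equal(resource_range(28, 28), 0)
  expect_equal(resource_range(1, 1), 1) # degenerate single-host web
  expect_error(resource_range(5, 4), class = "cryptwebs_domain_error")
})

test_that("paired difference index handles specialists, generalists and skew", {
  expect_equal(paired_difference_index(c(9, rep(0, 27))), 1)
  expect_equal(paired_difference_index(rep(3, 10)), 0)
  expect_equal(paired_difference_index(c(1, 0.5, 0, 0)), 0.5 / 3 + 2 / 3)
  expect_equal(round(paired_difference_index(c(1, 0.5, 0, 0)), 4), 0.8333)
  expect_error(paired_difference_index(rep(0, 4)), class = "cryptwebs_domain_error")
})

test_that("species specificity index uses the population-SD CV", {
  # single positive entry: CV = sqrt(R - 1) exactly, so SSI = 1
  expect_equal(species_specificity_index(c(42, rep(0, 27))), 1)
  # equal split over r of R hosts: sqrt((R - r)/r) / sqrt(R - 1)
  expect_equal(species_specificity_index(c(7, 7, rep(0, 26))),
               sqrt(26 / 2) / sqrt(27))
  expect_equal(round(species_specificity_index(c(7, 7, rep(0, 26))), 2), 0.69)
  expect_equal(round(species_specificity_index(c(3, 3, rep(0, 35))), 2), 0.70)
  expect_error(species_specificity_index(5), class = "cryptwebs_domain_error")
})

test_that("d' is exact against exhaustive enumeration of integer columns", {
  # d_raw example: column (6, 2) with q = (1/2, 1/2)
  M <- interaction_matrix(matrix(c(6, 2, 2, 6), 2, 2))
  d <- bluethgen_d(M, 1)
  expect_equal(d$d_raw, 0.75 * log(1.5) + 0.25 * log(0.5))
  expect_equal(round(d$d_raw, 4), 0.1308)

  # oracle: enumerate every integer column with the same total
  kl_of <- function(a, q) {
    p <- a / sum(a); pos <- p > 0
    sum(p[pos] * log(p[pos] / q[pos]))
  }
  set.seed(42)
  for (rep in 1:30) {
    R <- sample(2:3, 1)
    q <- as.numeric(rmultinom(1, sample(4:12, 1), rep(1, R)))
    if (any(q == 0)) next
    q <- q / sum(q)
    A <- sample(1:12, 1)
    comps <- compositions_of(A, R)
    comps <- comps[rowSums(comps) == A, , drop = FALSE]
    kls <- apply(comps, 1, kl_of, q = q)
    expect_equal(cryptwebs:::kl_min(A, q), min(kls), tolerance = 1e-12)
    expect_equal(-log(min(q)), max(kls), tolerance = 1e-12)
  }
})

test_that("d' endpoints behave as expected", {
  M <- interaction_matrix(matrix(c(4, 0, 0, 4), 2, 2))
  expect_equal(bluethgen_d(M, 1)$d_prime, 1)
  expect_equal(bluethgen_d(M, 2)$d_prime, 1)
  # column proportional to availability -> d_raw = 0 and d' = 0
  M2 <- interaction_matrix(matrix(c(6, 2, 3, 1), 2, 2))
  d <- bluethgen_d(M2, 2)
  expect_equal(d$d_raw, 0)
  expect_equal(d$d_prime, 0)
})

test_that("service index captures reciprocal dependence", {
  M <- interaction_matrix(matrix(c(4, 0, 0, 4), 2, 2))
  expect_equal(service_index(M, 1), 1) # exclusive reciprocal pair
  # exclusive parasitoid contributing half of its host's parasitism
  M2 <- interaction_matrix(matrix(c(5, 0, 5, 3), 2, 2,
                                  dimnames = list(c("h1", "h2"), c("pj", "po"))))
  expect_equal(service_index(M2, "pj"), 0.5)
  M3 <- interaction_matrix(matrix(2, 2, 2))
  expect_equal(service_index(M3, 1), 0.5)
})

test_that("indices are invariant to host order and column scale", {
  set.seed(9)
  col <- c(rpois(6, 3) + 1, 0, 0)
  for (f in list(paired_difference_index, species_specificity_index)) {
    expect_equal(f(col), f(sample(col)))
    expect_equal(f(col), f(col * 7))
  }
  expect_equal(resource_range(sum(col > 0), length(col)),
               resource_range(sum(col * 3 > 0), length(col)))
})

test_that("within a web RR decreases strictly with the number of hosts", {
  R <- 15
  rr <- vapply(1:R, resource_range, numeric(1), R = R)
  expect_true(all(diff(rr) < 0))
})

test_that("the species_indices table reproduces per-column computations", {
  set.seed(4)
  m <- matrix(rpois(20, 3), 4, 5)
  m[1, ] <- m[1, ] + 1
  m[, 1] <- m[, 1] + 1
  M <- interaction_matrix(m)
  idx <- species_indices(M, "parasitoid")
  expect_equal(nrow(idx), ncol(M))
  expect_true(all(idx$RR >= 0 & idx$RR <= 1))
  expect_true(all(idx$PDI >= 0 & idx$PDI <= 1 + 1e-9))
  expect_true(all(idx$SSI >= 0 & idx$SSI <= 1 + 1e-9))
  expect_true(all(idx$d_prime >= 0 & idx$d_prime <= 1 + 1e-9))
  expect_true(all(idx$PSI >= 0 & idx$PSI <= 1 + 1e-9))
  j <- colnames(M)[2]
  expect_equal(idx$PSI[idx$label == j], service_index(M, j))
  # host side = transposed computation
  idxh <- species_indices(M, "host")
  expect_equal(idxh$PSI[1], service_index(interaction_matrix(t(unclass(M))),
                                          rownames(M)[1]))
})
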