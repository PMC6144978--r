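#' Connectance
#'
#' Realized fraction of possible links, `L / (R * P)` with L the number of
#' positive cells. A binary metric: invariant to rescaling counts.
#'
#' @param M An [interaction_matrix()].
#' @return Connectance in `(0, 1]`.
#' @export
connectance <- function(M) {
  m <- unclass(M)
  if (sum(m) == 0) abort("empty web", class = "cryptwebs_domain_error")
  sum(m > 0) / (nrow(m) * ncol(m))
}

xlogx <- function(a) ifelse(a > 0, a * log(a), 0)

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon entropy of the interaction frequencies,
#' `H2 = -sum (a/m) ln(a/m)`, standardized against the least and most
#' specialized integer matrices sharing the observed marginals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, so 0 means interactions follow
#' the marginal expectation and 1 means maximal reciprocal specialization.
#' The extremes are found by exhaustive enumeration of the transportation
#' polytope when it is small enough, and by greedy integer filling
#' otherwise (marginal allocation for the entropy maximum; largest-block
#' filling for the minimum).
#'
#' @param M An [interaction_matrix()].
#' @param exact_limit Maximum enumeration size before switching to the
#'   greedy heuristics (default `2e5`).
#' @return H2' in `[0, 1]`.
#' @export
h2_prime <- function(M, exact_limit = 2e5) {
  m <- unclass(M)
  tot <- sum(m)
  if (tot == 0) abort("empty web", class = "cryptwebs_domain_error")
  H2 <- log(tot) - sum(xlogx(as.numeric(m))) / tot
  ex <- h2_extremes(rowSums(m), colSums(m), exact_limit = exact_limit)
  if (ex$H2max - ex$H2min < 1e-12) return(0)
  min(max((ex$H2max - H2) / (ex$H2max - ex$H2min), 0), 1)
}

# Extremes of H2 over integer matrices with fixed marginals. Returns the
# achievable entropy range; exact when the polytope is small.
h2_extremes <- function(rs, cs, exact_limit = 2e5) {
  stopifnot(sum(rs) == sum(cs))
  tot <- sum(rs)
  # upper bound on the number of row-composition paths
  est <- prod(pmin(choose(rs + length(cs) - 1, length(cs) - 1), Inf))
  if (is.finite(est) && est <= exact_limit) {
    s <- enumerate_s_range(as.integer(rs), as.integer(cs))
  } else {
    s <- list(min = greedy_s_min(rs, cs), max = greedy_s_max(rs, cs))
  }
  list(H2min = log(tot) - s$max / tot, H2max = log(tot) - s$min / tot)
}

# DFS over all integer matrices with the given marginals, tracking the
# range of S = sum a*log(a).
enumerate_s_range <- function(rs, cs) {
  env <- new.env()
  env$min <- Inf; env$max <- -Inf
  recurse <- function(i, caps, acc) {
    if (i > length(rs)) {
      if (acc < env$min) env$min <- acc
      if (acc > env$max) env$max <- acc
      return(invisible())
    }
    for (comp in compositions_capped(rs[i], caps)) {
      recurse(i + 1, caps - comp, acc + sum(xlogx(comp)))
    }
    invisible()
  }
  recurse(1, cs, 0)
  list(min = env$min, max = env$max)
}

# All compositions of n into length(caps) parts with part k <= caps[k].
compositions_capped <- function(n, caps) {
  k <- length(caps)
  if (k == 1) {
    if (n <= caps[1]) return(list(n)) else return(list())
  }
  out <- list()
  hi <- min(n, caps[1])
  lo <- max(0, n - sum(caps[-1]))
  for (v in lo:hi) {
    for (rest in compositions_capped(n - v, caps[-1])) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

# Greedy minimum of S (entropy maximum): place units one at a time into the
# feasible cell with the smallest marginal increase of a*log(a).
greedy_s_min <- function(rs, cs) {
  R <- length(rs); P <- length(cs)
  a <- matrix(0, R, P)
  rr <- rs; cc <- cs
  marg <- matrix(0, R, P) # increase for the next unit: (a+1)log(a+1)-a*log(a)
  for (step in seq_len(sum(rs))) {
    pen <- marg
    pen[rr == 0, ] <- Inf
    pen[, cc == 0] <- Inf
    idx <- arrayInd(which.min(pen), dim(pen))
    i <- idx[1]; j <- idx[2]
    a[i, j] <- a[i, j] + 1
    rr[i] <- rr[i] - 1; cc[j] <- cc[j] - 1
    v <- a[i, j]
    marg[i, j] <- (v + 1) * log(v + 1) - v * log(v)
  }
  sum(xlogx(a))
}

# Greedy maximum of S (entropy minimum): repeatedly place the largest block
# min(row remainder, col remainder) in the cell where that block is biggest.
greedy_s_max <- function(rs, cs) {
  rr <- rs; cc <- cs
  s <- 0
  while (sum(rr) > 0) {
    blk <- outer(rr, cc, pmin)
    idx <- arrayInd(which.max(blk), dim(blk))
    v <- blk[idx]
    s <- s + xlogx(v)
    rr[idx[1]] <- rr[idx[1]] - v
    cc[idx[2]] <- cc[idx[2]] - v
  }
  s
}

#' Generality, vulnerability and linkage density
#'
#' Abundance-weighted effective partner numbers: for each parasitoid j the
#' effective number of hosts is `exp(H_j)` with H_j the Shannon entropy of
#' column j's proportions; generality averages these with weights
#' `A_j / m`. Vulnerability is the symmetric quantity over hosts, and
#' linkage density is their mean.
#'
#' @param M An [interaction_matrix()].
#' @return Named list with `generality`, `vulnerability`,
#'   `linkage_density`.
#' @export
generality_vulnerability_linkage <- function(M) {
  m <- unclass(M)
  tot <- sum(m)
  if (tot == 0) abort("empty web", class = "cryptwebs_domain_error")
  eff <- function(v) {
    p <- v[v > 0] / sum(v)
    exp(-sum(p * log(p)))
  }
  gen <- sum(colSums(m) / tot * apply(m, 2, eff))
  vul <- sum(rowSums(m) / tot * apply(m, 1, eff))
  list(generality = gen, vulnerability = vul, linkage_density = (gen + vul) / 2)
}

#' Number of compartments
#'
#' Connected components of the bipartite graph whose edges are the positive
#' cells.
#'
#' @param M An [interaction_matrix()] (or bare matrix).
#' @return Integer component count (0 for an empty web).
#' @export
compartments <- function(M) {
  m <- unclass(M)
  pos <- which(m > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(0L)
  edges <- cbind(paste0("H:", rownames(m)[pos[, 1]]),
                 paste0("P:", colnames(m)[pos[, 2]]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  as.integer(igraph::components(g)$no)
}

#' Nestedness: NODF and a matrix-temperature approximation
#'
#' NODF follows the standard paired-overlap definition on the binary
#' matrix: for each ordered pair with strictly decreasing fill, the
#' percentage of the poorer species' links shared with the richer one,
#' averaged over all row pairs and column pairs (0-100; higher = more
#' nested). Equal-fill pairs contribute zero.
#'
#' The temperature reported here is a deterministic approximation of the
#' published matrix-temperature concept: after sorting rows and columns by
#' decreasing marginal totals (ties broken by label), presences are compared
#' with the maximally packed nested pattern of the same fills, and the
#' mismatch is scaled to 0-100 (0 = perfectly nested). It is not numerically
#' interchangeable with genetic-algorithm implementations of temperature.
#'
#' @param M An [interaction_matrix()].
#' @return Named list with `NODF` and `temperature`, both in `[0, 100]`.
#' @export
nestedness <- function(M) {
  b <- unclass(M) > 0
  if (nrow(b) == 1 && ncol(b) == 1) return(list(NODF = 0, temperature = 0))
  list(NODF = nodf(b), temperature = nested_temperature(b))
}

nodf <- function(b) {
  pair_sum <- function(mat) { # rows of mat are the compared objects
    n <- nrow(mat)
    if (n < 2) return(c(0, 0))
    fills <- rowSums(mat)
    s <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        hi <- which.max(c(fills[i], fills[j]))
        f_lo <- min(fills[i], fills[j])
        if (fills[i] == fills[j] || f_lo == 0) next
        lo_row <- if (hi == 1) mat[j, ] else mat[i, ]
        hi_row <- if (hi == 1) mat[i, ] else mat[j, ]
        s <- s + 100 * sum(lo_row & hi_row) / f_lo
      }
    }
    c(s, n * (n - 1) / 2)
  }
  r <- pair_sum(b)
  c2 <- pair_sum(t(b))
  denom <- r[2] + c2[2]
  if (denom == 0) return(0)
  (r[1] + c2[1]) / denom
}

nested_temperature <- function(b) {
  ord_r <- order(-rowSums(b), rownames(b))
  ord_c <- order(-colSums(b), colnames(b))
  s <- b[ord_r, ord_c, drop = FALSE]
  packed <- t(vapply(seq_len(nrow(s)), function(i) {
    seq_len(ncol(s)) <= sum(s[i, ])
  }, logical(ncol(s))))
  L <- sum(s)
  worst <- 2 * min(L, length(s) - L)
  if (worst == 0) return(0)
  100 * min(sum(s != packed) / worst, 1)
}

#' Specialization asymmetry
#'
#' Contrast of mean standardized specialization between the two trophic
#' levels: `SA = (D_P - D_H) / (D_P + D_H)`, with D_P and D_H the
#' abundance-weighted mean d' of parasitoids and hosts (unweighted means
#' with `weighted = FALSE`). Positive values indicate the parasitoid level
#' is the more specialized; by convention 0 when both means vanish.
#'
#' @param M An [interaction_matrix()].
#' @param weighted Weight species by their total counts (default `TRUE`).
#' @return SA in `[-1, 1]`.
#' @export
specialization_asymmetry <- function(M, weighted = TRUE) {
  dp <- species_indices(M, "parasitoid")
  dh <- species_indices(M, "host")
  wp <- if (weighted) parasitoid_totals(M) / grand_total(M) else
    rep(1 / nrow(dp), nrow(dp))
  wh <- if (weighted) host_totals(M) / grand_total(M) else
    rep(1 / nrow(dh), nrow(dh))
  D_P <- sum(wp[dp$label] * dp$d_prime)
  D_H <- sum(wh[dh$label] * dh$d_prime)
  if (D_P + D_H == 0) return(0)
  (D_P - D_H) / (D_P + D_H)
}

#' Secondary-extinction robustness
#'
#' Hosts are removed one at a time; a parasitoid goes secondarily extinct
#' once all of its hosts are gone. The curve of the fraction of parasitoid
#' species surviving against the fraction of hosts removed (anchored at
#' (0, 1) and (1, 0)) is integrated by the trapezoidal rule, and robustness
#' is the mean area across removal orders. With `order = "random"` the
#' removal order is uniform-random and `n_orders` replicates are averaged
#' (deterministic given `seed`); `order = "degree"` removes the
#' best-connected host first, a single deterministic order. Set
#' `remove = "parasitoid"` to remove the upper level instead.
#'
#' @param M An [interaction_matrix()].
#' @param n_orders Number of random removal orders (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param order `"random"` (default) or `"degree"`.
#' @param remove Which level is removed: `"host"` (default) or
#'   `"parasitoid"`.
#' @return Robustness in `[0, 1]`.
#' @export
robustness <- function(M, n_orders = 1000, seed = NULL,
                       order = c("random", "degree"),
                       remove = c("host", "parasitoid")) {
  order <- match.arg(order)
  remove <- match.arg(remove)
  if (n_orders < 1) abort("n_orders must be >= 1", class = "cryptwebs_domain_error")
  m <- unclass(M)
  if (remove == "parasitoid") m <- t(m)
  R <- nrow(m); P <- ncol(m)
  auc_for <- function(ord) {
    # a consumer survives until its last resource is removed
    pos <- m > 0
    last <- apply(pos, 2, function(col) max(match(which(col), ord)))
    surv <- vapply(0:R, function(t) sum(last > t) / P, numeric(1))
    sum((surv[-1] + surv[-length(surv)]) / 2) / R
  }
  if (order == "degree") {
    ord <- order(-rowSums(m > 0), rownames(m))
    return(auc_for(ord))
  }
  with_local_seed(seed, {
    mean(vapply(seq_len(n_orders), function(k) auc_for(sample.int(R)), numeric(1)))
  })
}

# Evaluate expr under a temporary RNG state when seed is given.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Whole-web metric set
#'
#' Computes the full network-level metric table for one web or for a set of
#' webs: connectance, H2', generality, vulnerability, linkage density,
#' compartments, NODF and temperature, specialization asymmetry and
#' robustness.
#'
#' @param x An [interaction_matrix()] or a `cw_webset`.
#' @param seed Seed for the stochastic robustness orders.
#' @param n_orders Random removal orders for robustness (default 1000).
#' @param ... Unused.
#' @return A one-row tibble per web.
#' @export
network_metrics <- function(x, seed = 1L, n_orders = 1000, ...) {
  UseMethod("network_metrics")
}

#' @export
network_metrics.interaction_matrix <- function(x, seed = 1L, n_orders = 1000, ...) {
  gvl <- generality_vulnerability_linkage(x)
  nest <- nestedness(x)
  tibble(
    n_hosts = nrow(x), n_parasitoids = ncol(x),
    n_links = sum(unclass(x) > 0), m = grand_total(x),
    connectance = connectance(x),
    H2_prime = h2_prime(x),
    generality = gvl$generality,
    vulnerability = gvl$vulnerability,
    linkage_density = gvl$linkage_density,
    n_compartments = compartments(x),
    NODF = nest$NODF,
    nestedness_temperature = nest$temperature,
    specialization_asymmetry = specialization_asymmetry(x),
    robustness = robustness(x, n_orders = n_orders, seed = seed),
    rng_seed = as.integer(seed)
  )
}

#' @export
network_metrics.cw_webset <- function(x, seed = 1L, n_orders = 1000, ...) {
  imap(x, function(M, key) {
    network_metrics(M, seed = seed, n_orders = n_orders) |>
      mutate(web = key, .before = 1)
  }) |> bind_rows()
}
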