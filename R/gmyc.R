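#' Single-threshold generalized mixed Yule-coalescent (GMYC) fit
#'
#' Fits the single-threshold GMYC model to an ultrametric tree: a time
#' threshold T separates diversification (Yule) branching among species
#' lineages (nodes older than T) from neutral coalescence within species
#' (nodes younger than T). Tips descending from each lineage crossing the
#' threshold form one delimited entity.
#'
#' For a candidate threshold, the likelihood is a product over inter-node
#' waiting intervals. During interval i the total branching rate is
#' \deqn{b_i = \lambda_{div} \, n_{div,i}^{\,p_{div}} +
#'       \lambda_{coal} \sum_k \left[n_{k,i}(n_{k,i}-1)\right]^{p_{coal}},}
#' where \eqn{n_{div,i}} counts species lineages (branches ancestral to, or
#' stems of, the clusters) and \eqn{n_{k,i}} counts lineages inside
#' coalescent cluster k. Each interval of length \eqn{x_i} ending in a
#' branching event contributes \eqn{\log b_i - b_i x_i}. Rates are fitted on
#' the log scale and the scaling exponents within `[0, 3]`, by quasi-Newton
#' maximization started from (1, 1); thresholds where the optimizer fails
#' are skipped and flagged. The null model is a single generalized Yule
#' process with rate \eqn{\lambda n_i^p} over the whole tree; it is nested
#' in the mixed model (threshold below all nodes), so the mixed maximum is
#' never below the null. Significance is assessed by a likelihood-ratio
#' test against a chi-square with `df` degrees of freedom (default 3:
#' threshold, extra rate, extra exponent).
#'
#' @param tree An ultrametric [ape::phylo] tree with at least 3 tips and
#'   positive branch lengths.
#' @param df Degrees of freedom for the likelihood-ratio test (default 3).
#' @param tol Relative ultrametricity tolerance passed to
#'   [validate_ultrametric()].
#' @return An object of class `cw_gmyc` with elements `threshold`,
#'   `lambda_div`, `p_div`, `lambda_coal`, `p_coal`, `logL_mixed`,
#'   `logL_null`, `lr_stat`, `lr_pvalue`, `n_entities`, `assignment`
#'   (a [partition()] of the tips at the best threshold) and `candidates`
#'   (per-threshold tibble). Use [gmyc_partition()] for the
#'   significance-gated partition.
#' @export
gmyc_fit <- function(tree, df = 3, tol = 1e-6) {
  if (ape::Ntip(tree) < 3) {
    abort("GMYC requires at least 3 tips", class = "cryptwebs_fit_error")
  }
  if (any(tree$edge.length < 0) ||
      any(tree$edge.length[tree$edge[, 2] > ape::Ntip(tree)] <= 0)) {
    abort("GMYC requires strictly positive internal branch lengths",
          class = "cryptwebs_fit_error")
  }
  tree <- validate_ultrametric(ape::reorder.phylo(tree, "cladewise"), tol = tol)
  geom <- gmyc_geometry(tree)
  cands <- gmyc_candidates(geom)
  null_fit <- gmyc_null_fit(geom)

  rows <- map(cands, function(T) {
    fit <- try(gmyc_fit_at(geom, T), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$logL)) {
      return(tibble(threshold = T, logL = NA_real_, n_entities = NA_integer_,
                    converged = FALSE, fit = list(NULL)))
    }
    tibble(threshold = T, logL = fit$logL, n_entities = fit$n_entities,
           converged = TRUE, fit = list(fit))
  })
  candidates <- bind_rows(rows)
  if (!any(candidates$converged)) {
    abort("GMYC optimization failed at every candidate threshold",
          class = "cryptwebs_fit_error")
  }
  ok <- which(candidates$converged)
  best <- ok[which.max(candidates$logL[ok])]
  bf <- candidates$fit[[best]]
  logL_mixed <- max(candidates$logL[ok], null_fit$logL)
  lr <- max(0, 2 * (logL_mixed - null_fit$logL))
  structure(list(
    threshold = candidates$threshold[best],
    lambda_div = bf$lambda_div, p_div = bf$p_div,
    lambda_coal = bf$lambda_coal, p_coal = bf$p_coal,
    logL_mixed = logL_mixed, logL_null = null_fit$logL,
    lr_stat = lr, df = df,
    lr_pvalue = stats::pchisq(lr, df = df, lower.tail = FALSE),
    n_entities = bf$n_entities,
    assignment = partition(geom$tip_labels, bf$tip_cluster,
                           method = "GMYC", marker = NA_character_),
    candidates = candidates |> select("threshold", "logL", "n_entities", "converged"),
    tree_height = geom$height
  ), class = "cw_gmyc")
}

#' Partition implied by a GMYC fit, gated on significance
#'
#' When the likelihood-ratio test does not reject the single-process null at
#' level `alpha`, there is no evidence for a within/between-species rate
#' shift and all specimens are reported as one entity.
#'
#' @param fit A `cw_gmyc` object from [gmyc_fit()].
#' @param alpha Significance level (default 0.05).
#' @return A [partition()].
#' @export
gmyc_partition <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cw_gmyc"))
  if (fit$lr_pvalue < alpha) {
    fit$assignment
  } else {
    partition(fit$assignment$specimen_id, rep(1L, nrow(fit$assignment)),
              method = "GMYC", marker = attr(fit$assignment, "marker"))
  }
}

#' @export
print.cw_gmyc <- function(x, ...) {
  cat(sprintf(paste0("<GMYC fit: threshold %.4g (tree height %.4g), %d entities, ",
                     "LR = %.3f (df = %d, p = %.4g)>\n"),
              x$threshold, x$tree_height, x$n_entities, x$lr_stat, x$df, x$lr_pvalue))
  invisible(x)
}

#' @rdname gmyc_fit
#' @param x A `cw_gmyc` object.
#' @param ... Unused.
#' @method tidy cw_gmyc
#' @export
tidy.cw_gmyc <- function(x, ...) x$candidates

#' @rdname gmyc_fit
#' @method glance cw_gmyc
#' @export
glance.cw_gmyc <- function(x, ...) {
  tibble(threshold = x$threshold, n_entities = x$n_entities,
         lambda_div = x$lambda_div, p_div = x$p_div,
         lambda_coal = x$lambda_coal, p_coal = x$p_coal,
         logL_mixed = x$logL_mixed, logL_null = x$logL_null,
         lr_stat = x$lr_stat, df = x$df, lr_pvalue = x$lr_pvalue)
}

# --- internal geometry -----------------------------------------------------

# Precompute node heights, edges and event ordering once per tree.
gmyc_geometry <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  h <- height - depth            # node heights above the present
  h[seq_len(ntip)] <- 0          # tips exactly at the present
  list(tree = tree, ntip = ntip, nnode = nnode, h = h, height = height,
       edge = tree$edge, tip_labels = tree$tip.label,
       node_heights = sort(h[(ntip + 1):(ntip + nnode)], decreasing = TRUE))
}

gmyc_candidates <- function(geom) {
  hs <- unique(geom$node_heights)
  cand <- if (length(hs) >= 2) (hs[-1] + hs[-length(hs)]) / 2 else numeric(0)
  sort(unique(c(cand, min(hs) / 2)), decreasing = TRUE)
}

# Classify branches for threshold T and build per-interval lineage counts.
gmyc_structure <- function(geom, T) {
  ntip <- geom$ntip
  h <- geom$h
  edge <- geom$edge
  root <- ntip + 1L
  nn <- ntip + geom$nnode
  # cluster membership: 0 = diversification zone; entity roots flagged apart
  m <- integer(nn)
  is_root_entity <- logical(nn)
  next_cl <- 0L
  if (h[root] <= T) { # degenerate: whole tree below threshold, one cluster
    next_cl <- 1L
    m[root] <- 1L
    is_root_entity[root] <- TRUE
  }
  for (e in seq_len(nrow(edge))) { # cladewise: parents precede children
    p <- edge[e, 1]; c <- edge[e, 2]
    if (m[p] > 0L) {
      m[c] <- m[p]
    } else if (c <= ntip || h[c] <= T) {
      next_cl <- next_cl + 1L
      m[c] <- next_cl
      is_root_entity[c] <- TRUE
    }
  }
  # interval bookkeeping
  ts <- geom$node_heights
  k <- length(ts)
  intervals <- list()
  if (k >= 2) {
    hp <- h[edge[, 1]]; hc <- h[edge[, 2]]
    for (i in seq_len(k - 1)) {
      tau <- (ts[i] + ts[i + 1]) / 2
      cross <- which(hc < tau & hp > tau)
      if (length(cross) == 0) next # tied heights: zero-width pseudo-interval
      cc <- edge[cross, 2]
      is_div <- m[cc] == 0L | is_root_entity[cc]
      n_div <- sum(is_div)
      cl_counts <- tabulate(m[cc][!is_div])
      cl_counts <- cl_counts[cl_counts >= 2]
      intervals[[length(intervals) + 1L]] <- list(x = ts[i] - ts[i + 1],
                                                  n_div = n_div, cl = cl_counts)
    }
  }
  tip_cluster <- m[seq_len(ntip)]
  list(intervals = intervals, n_entities = next_cl,
       tip_cluster = tip_cluster)
}

# Penalized (finite) log-likelihood so box-constrained quasi-Newton search
# never sees an infinite objective.
gmyc_loglik <- function(par, intervals) {
  lam_d <- exp(par[1]); lam_c <- exp(par[2])
  p_d <- par[3]; p_c <- par[4]
  ll <- 0
  for (iv in intervals) {
    coal <- if (length(iv$cl) > 0) sum((iv$cl * (iv$cl - 1))^p_c) else 0
    b <- lam_d * iv$n_div^p_d + lam_c * coal
    if (!is.finite(b) || b <= 0) return(-1e10)
    ll <- ll + log(b) - b * iv$x
  }
  if (!is.finite(ll)) return(-1e10)
  ll
}

gmyc_fit_at <- function(geom, T) {
  st <- gmyc_structure(geom, T)
  iv <- st$intervals
  if (length(iv) == 0) abort("too few events", class = "cryptwebs_fit_error")
  tot_lx <- sum(map_dbl(iv, ~ (.x$n_div + sum(.x$cl)) * .x$x))
  lam0 <- log(max(length(iv) / tot_lx, 1e-8))
  opt <- stats::optim(c(lam0, lam0, 1, 1),
                      fn = function(p) -gmyc_loglik(p, iv),
                      method = "L-BFGS-B",
                      lower = c(-20, -20, 0, 0), upper = c(20, 20, 3, 3))
  if (!is.finite(opt$value)) abort("non-finite likelihood", class = "cryptwebs_fit_error")
  list(logL = -opt$value,
       lambda_div = exp(opt$par[1]), lambda_coal = exp(opt$par[2]),
       p_div = opt$par[3], p_coal = opt$par[4],
       n_entities = st$n_entities, tip_cluster = st$tip_cluster)
}

# Single generalized-Yule process over all events (the null model).
gmyc_null_fit <- function(geom) {
  ts <- geom$node_heights
  k <- length(ts)
  x <- ts[-k] - ts[-1]
  n <- seq_len(k - 1) + 1 # lineages during interval i
  nll <- function(par) {
    lam <- exp(par[1]); p <- par[2]
    b <- lam * n^p
    v <- -(sum(log(b) - b * x))
    if (!is.finite(v)) 1e10 else v
  }
  lam0 <- log(max((k - 1) / sum(n * x), 1e-8))
  opt <- stats::optim(c(lam0, 1), fn = nll, method = "L-BFGS-B",
                      lower = c(-20, 0), upper = c(20, 3))
  list(logL = -opt$value, lambda = exp(opt$par[1]), p = opt$par[2])
}
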