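#' Resource range
#'
#' Qualitative host-range index: the proportion of available host species
#' *not* used, `RR = (R - r) / (R - 1)`, so that a strict specialist (r = 1)
#' scores 1 and a complete generalist (r = R) scores 0. For the degenerate
#' single-host web (R = 1) the index is defined as 1.
#'
#' @param r_j Number of host species used (positive links).
#' @param R Number of host species in the web.
#' @return RR in `[0, 1]`.
#' @examples
#' resource_range(8, 28)  # 0.7407...
#' @export
resource_range <- function(r_j, R) {
  stopifnot(r_j >= 1, R >= 1)
  if (r_j > R) abort("r_j cannot exceed R", class = "cryptwebs_domain_error")
  if (R == 1) return(1)
  (R - r_j) / (R - 1)
}

#' Paired difference index
#'
#' Contrasts the strongest link with all others: link strengths are
#' normalized so the largest equals 1, sorted decreasingly as P_1 >= ... >=
#' P_R (zeros included), and `PDI = sum_{i>=2} (P_1 - P_i) / (R - 1)`. A
#' single-host specialist scores 1; uniform use of all hosts scores 0. The
#' max-normalization makes the index invariant to rescaling the column.
#'
#' @param col Link-strength vector over all R hosts (counts or proportions).
#' @return PDI in `[0, 1]`.
#' @export
paired_difference_index <- function(col) {
  if (all(col == 0)) abort("all-zero link vector", class = "cryptwebs_domain_error")
  if (any(col < 0)) abort("negative link strength", class = "cryptwebs_domain_error")
  R <- length(col)
  if (R == 1) return(1)
  p <- sort(col / max(col), decreasing = TRUE)
  sum(p[1] - p[-1]) / (R - 1)
}

#' Species specificity index
#'
#' Coefficient of variation of the link strengths across all R hosts (zeros
#' included), using the population standard deviation, normalized by
#' `sqrt(R - 1)` so that a single-host specialist scores exactly 1:
#' `SSI = CV / sqrt(R - 1)`. For equal use of r of R hosts the closed form
#' is `sqrt((R - r) / r) / sqrt(R - 1)`.
#'
#' @param col Link-strength vector over all R hosts.
#' @return SSI in `[0, 1]`.
#' @export
species_specificity_index <- function(col) {
  R <- length(col)
  if (R < 2) abort("SSI requires R >= 2 hosts", class = "cryptwebs_domain_error")
  if (all(col == 0)) abort("all-zero link vector", class = "cryptwebs_domain_error")
  mu <- mean(col)
  sd_pop <- sqrt(mean((col - mu)^2))
  (sd_pop / mu) / sqrt(R - 1)
}

#' Bluethgen's d and standardized d'
#'
#' Kullback-Leibler specialization of parasitoid j's host-use distribution
#' p_ij against host availability q_i = A_i / m:
#' `d = sum_i p_ij * ln(p_ij / q_i)` over positive cells. The standardized
#' `d' = (d - d_min) / (d_max - d_min)` rescales against the extremes
#' achievable by an integer column with the same total A_j under the fixed
#' availabilities: `d_max` concentrates the total on the rarest host (the
#' maximum of a convex function over integer compositions is attained at a
#' point mass), and `d_min` is found by greedy marginal allocation, which is
#' exact for this separable convex minimization. If the extremes coincide,
#' `d' = 0`.
#'
#' @param M An [interaction_matrix()].
#' @param j Column index or name.
#' @return Named list with `d_raw` (nats) and `d_prime` in `[0, 1]`.
#' @export
bluethgen_d <- function(M, j) {
  a <- unclass(M)[, j]
  A <- sum(a)
  if (A == 0) abort("empty column", class = "cryptwebs_domain_error")
  q <- host_availability(M)
  p <- a / A
  pos <- p > 0
  d_raw <- sum(p[pos] * log(p[pos] / q[pos]))
  d_max <- -log(min(q))
  d_min <- kl_min(A, q)
  d_prime <- if (d_max - d_min < 1e-12) 0 else (d_raw - d_min) / (d_max - d_min)
  list(d_raw = d_raw, d_prime = min(max(d_prime, 0), 1))
}

# Exact minimum of sum p_i log(p_i/q_i) over integer vectors a with sum A:
# marginal allocation on the separable convex objective
# g(a) = sum a_i log a_i - a_i log q_i (the KL times A, up to a constant).
kl_min <- function(A, q) {
  R <- length(q)
  a <- integer(R)
  marg <- -log(q) # cost of the first unit in each cell: 1*log(1) - log(q_i)
  for (step in seq_len(A)) {
    i <- which.min(marg)
    a[i] <- a[i] + 1L
    ai <- a[i]
    marg[i] <- (ai + 1) * log(ai + 1) - ai * log(ai) - log(q[i])
  }
  p <- a / A
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Interaction service index (PSI)
#'
#' Reciprocal-dependence index: the dependence of parasitoid j on host i
#' times j's share of the total parasitism of host i, summed over hosts:
#' `PSI_j = sum_i (a_ij / A_j) * (a_ij / A_i)`. Equals 1 for an exclusive
#' reciprocal pair.
#'
#' @inheritParams bluethgen_d
#' @return PSI in `[0, 1]`.
#' @export
service_index <- function(M, j) {
  m <- unclass(M)
  a <- m[, j]
  A_col <- sum(a)
  if (A_col == 0) abort("empty column", class = "cryptwebs_domain_error")
  A_row <- rowSums(m)
  pos <- a > 0
  sum((a[pos] / A_col) * (a[pos] / A_row[pos]))
}

#' Species-level specialization indices for one web
#'
#' Computes, for every parasitoid (or, with `level = "host"`, every host via
#' the transposed matrix), the full index panel: number of
#' partners, RR, PDI, SSI, raw d and standardized d', and PSI.
#'
#' @param M An [interaction_matrix()].
#' @param level `"parasitoid"` (columns; default) or `"host"` (rows).
#' @return A tibble with one row per species, columns `label`, `n_host`,
#'   `RR`, `PDI`, `SSI`, `d_raw`, `d_prime`, `PSI`.
#' @export
species_indices <- function(M, level = c("parasitoid", "host")) {
  level <- match.arg(level)
  m <- unclass(M)
  if (level == "host") m <- t(m)
  M2 <- interaction_matrix(m)
  R <- nrow(M2)
  map(colnames(M2), function(j) {
    col <- unclass(M2)[, j]
    d <- bluethgen_d(M2, j)
    tibble(label = j,
           n_host = sum(col > 0),
           RR = resource_range(sum(col > 0), R),
           PDI = paired_difference_index(as.numeric(col)),
           SSI = if (R >= 2) species_specificity_index(as.numeric(col)) else NA_real_,
           d_raw = d$d_raw, d_prime = d$d_prime,
           PSI = service_index(M2, j))
  }) |> bind_rows()
}

#' Render a species-index table at printed precision
#'
#' Two-decimal presentation as used in published index tables, keeping full-precision
#' companions alongside.
#'
#' @param idx Tibble from [species_indices()].
#' @return Tibble with rounded display columns and `*_full` companions.
#' @export
format_species_indices <- function(idx) {
  num <- c("RR", "PDI", "SSI", "d_prime", "PSI")
  out <- idx
  for (cn in num) {
    out[[paste0(cn, "_full")]] <- idx[[cn]]
    out[[cn]] <- round(idx[[cn]], 2)
  }
  out
}
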