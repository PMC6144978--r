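#' Abundance vector from rearing records
#'
#' Collapses rearing counts into per-species individual totals, the input of
#' the coverage and rarefaction estimators. By default species are
#' parasitoid morphospecies; supply a taxonomy map to count molecular
#' entities, or `level = "host"` for the host side.
#'
#' @param records Rearing-record tibble.
#' @param level `"parasitoid"` (default) or `"host"`.
#' @param map Optional molecular taxonomy map (see [molecular_map()]); when
#'   given, records are resolved like in [build_web()] and unresolvable
#'   records are dropped.
#' @return Named integer vector of positive per-species counts.
#' @export
abundance_vector <- function(records, level = c("parasitoid", "host"), map = NULL) {
  level <- match.arg(level)
  lab_col <- if (level == "parasitoid") "parasitoid_mor" else "host_mor"
  spec_col <- if (level == "parasitoid") "parasitoid_specimens" else "host_specimens"
  out <- list()
  for (r in seq_len(nrow(records))) {
    al <- allocate_record(records[[lab_col]][r], records[[spec_col]][[r]],
                          map, records$count[r])
    if (!is.null(al)) out[[length(out) + 1L]] <- al
  }
  agg <- bind_rows(out) |> group_by(.data$taxon) |>
    summarise(n = sum(.data$n), .groups = "drop")
  setNames(as.integer(agg$n), agg$taxon)
}

#' Sample coverage estimator
#'
#' Estimates the fraction of the community's individuals belonging to
#' species already observed:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\cdot
#'   \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2},}
#' with f1 and f2 the singleton and doubleton counts. When there are no
#' singletons the sample is taken as complete (C = 1).
#'
#' @param x Vector of per-species individual counts (positive integers).
#' @return Coverage in `[0, 1]`.
#' @examples
#' sample_coverage(c(90, 10 * 0 + rep(1, 10)))
#' @export
sample_coverage <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n == 0) abort("empty abundance vector", class = "cryptwebs_domain_error")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  denom <- (n - 1) * f1 + 2 * f2
  if (denom == 0) return(1 - f1 / n)
  1 - (f1 / n) * ((n - 1) * f1 / denom)
}

#' Simpson-diversity (Hill q = 2) rarefaction and extrapolation
#'
#' Estimated effective number of dominant species at sample size m:
#' \deqn{{}^2D(m) = \left[\frac{1}{m} + \frac{m-1}{m}
#'   \sum_i \frac{x_i (x_i - 1)}{n (n - 1)}\right]^{-1},}
#' valid both below (rarefaction) and above (extrapolation) the observed
#' sample size n.
#'
#' @param x Vector of per-species individual counts.
#' @param m Target sample size(s), `>= 1`.
#' @return `2D(m)`, vectorized over `m`.
#' @export
simpson_hill_estimate <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  if (n < 2) abort("need at least 2 individuals", class = "cryptwebs_domain_error")
  if (any(m < 1)) abort("m must be >= 1", class = "cryptwebs_domain_error")
  s2 <- sum(x * (x - 1)) / (n * (n - 1))
  1 / (1 / m + (m - 1) / m * s2)
}

#' Rarefaction-extrapolation curve with coverage
#'
#' @param x Abundance vector (see [abundance_vector()]).
#' @param m_grid Sample sizes to evaluate; defaults to 40 points from 1 to
#'   twice the observed total.
#' @return A tibble of class `cw_completeness` with columns `m`, `D2`, and
#'   constant columns `n`, `coverage` (coverage at the observed size) and
#'   `flat` (whether the curve has flattened: relative slope over the last
#'   decile below 1%).
#' @export
completeness_curve <- function(x, m_grid = NULL) {
  x <- x[x > 0]
  n <- sum(x)
  if (is.null(m_grid)) {
    m_grid <- unique(round(seq(1, 2 * n, length.out = 40)))
  }
  m_grid <- sort(unique(pmax(1, m_grid)))
  d <- simpson_hill_estimate(x, m_grid)
  last <- m_grid >= quantile(m_grid, 0.9)
  flat <- if (sum(last) >= 2) {
    rng <- range(d[last])
    (rng[2] - rng[1]) / rng[2] < 0.01
  } else NA
  out <- tibble(m = m_grid, D2 = d, n = n,
                coverage = sample_coverage(x), flat = flat)
  class(out) <- c("cw_completeness", class(out))
  out
}
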