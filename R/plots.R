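#' Plot an interaction matrix as a heat map
#'
#' Hosts on the y axis, parasitoids on the x axis, tile fill proportional to
#' the log of the interaction count.
#'
#' @param object An [interaction_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$parasitoid, y = .data$host, fill = log10(.data$count))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10 count") +
    labs(x = "parasitoid", y = "host") +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Plot the four crossed webs side by side
#'
#' @param object A `cw_webset`.
#' @param ... Unused.
#' @return A ggplot object faceted by web key.
#' @method autoplot cw_webset
#' @export
autoplot.cw_webset <- function(object, ...) {
  imap(object, function(M, key) tidy(M) |> mutate(web = key)) |>
    bind_rows() |>
    mutate(web = factor(.data$web, levels = names(object))) |>
    ggplot(aes(x = .data$parasitoid, y = .data$host, fill = log10(.data$count))) +
    geom_tile() +
    facet_wrap(~web, scales = "free") +
    scale_fill_viridis_c(name = "log10 count") +
    theme_minimal(base_size = 7) +
    theme(axis.text = element_blank(), axis.ticks = element_blank())
}

#' Plot a GMYC fit profile
#'
#' Log-likelihood of each candidate threshold, with the selected threshold
#' marked.
#'
#' @param object A `cw_gmyc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cw_gmyc
#' @export
autoplot.cw_gmyc <- function(object, ...) {
  tidy(object) |>
    filter(.data$converged) |>
    ggplot(aes(x = .data$threshold, y = .data$logL)) +
    geom_line() +
    geom_point(aes(size = .data$n_entities), alpha = 0.6) +
    geom_vline(xintercept = object$threshold, linetype = 2, colour = "red") +
    scale_x_reverse() +
    labs(x = "threshold (time before present)", y = "log-likelihood",
         size = "entities") +
    theme_minimal()
}

#' Plot a rarefaction-extrapolation curve
#'
#' Hill q = 2 diversity against sample size, with the observed sample size
#' marked; extrapolated sizes are dashed.
#'
#' @param object A `cw_completeness` tibble from [completeness_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cw_completeness
#' @export
autoplot.cw_completeness <- function(object, ...) {
  n_obs <- object$n[1]
  df <- as_tibble(object) |> mutate(phase = ifelse(.data$m <= n_obs,
                                                   "rarefaction", "extrapolation"))
  ggplot(df, aes(x = .data$m, y = .data$D2, linetype = .data$phase)) +
    geom_line() +
    geom_vline(xintercept = n_obs, colour = "grey50") +
    labs(x = "sample size (individuals)", y = "Simpson diversity (q = 2)",
         linetype = NULL) +
    theme_minimal()
}
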