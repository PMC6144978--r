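#' Quantitative host-parasitoid interaction matrix
#'
#' Wraps a non-negative integer count matrix (hosts as rows, parasitoids as
#' columns) after dropping all-zero rows and columns. The cell `a[i, j]` is
#' the number of individuals of parasitoid j reared from host i.
#'
#' @param m Numeric matrix of non-negative counts with dimnames.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (any(m < 0) || any(m != floor(m))) {
    abort("interaction counts must be non-negative integers",
          class = "cryptwebs_validation_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("h", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (length(m) == 0 || sum(m) == 0) {
    abort("empty web: no positive interaction counts", class = "cryptwebs_empty_web_error")
  }
  structure(m, class = c("interaction_matrix", class(m)))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction matrix: %d hosts x %d parasitoids, %d links, m = %d>\n",
              nrow(x), ncol(x), sum(x > 0), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname interaction_matrix
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of the positive cells with columns `host`,
#'   `parasitoid`, `count`.
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x), check.names = FALSE), rownames = "host") |>
    pivot_longer(-"host", names_to = "parasitoid", values_to = "count") |>
    filter(.data$count > 0)
}

#' Marginals of an interaction matrix
#'
#' `host_totals()` and `parasitoid_totals()` return the row and column sums;
#' `grand_total()` the total number of reared individuals m; and
#' `host_availability()` the availability distribution q_i = A_i / m used by
#' the d' family of indices.
#'
#' @param M An `interaction_matrix`.
#' @export
host_totals <- function(M) rowSums(unclass(M))

#' @rdname host_totals
#' @export
parasitoid_totals <- function(M) colSums(unclass(M))

#' @rdname host_totals
#' @export
grand_total <- function(M) sum(unclass(M))

#' @rdname host_totals
#' @export
host_availability <- function(M) {
  a <- rowSums(unclass(M))
  a / sum(a)
}

#' Build a quantitative web from rearing records
#'
#' Aggregates rearing counts into an interaction matrix under a choice of
#' taxonomy for each side. A `NULL` map keeps the morphospecies labels. A
#' molecular map (see [molecular_map()]) may split a morphospecies into
#' several entities; a record of a split morphospecies is then apportioned
#' over entities in proportion to its own sequenced specimens, rounded by
#' largest remainder so counts stay integral and the grand total is
#' conserved. Records of a split morphospecies carrying no sequenced
#' specimens cannot be resolved and are dropped (their number is reported in
#' the `dropped_records` attribute).
#'
#' @param records Rearing-record tibble (see [read_rearing_table()]).
#' @param host_map,para_map `NULL` for morphospecies, or a taxonomy map
#'   tibble with columns `specimen_id`, `morphospecies`, `taxon`.
#' @return An `interaction_matrix` with attribute `dropped_records`.
#' @export
build_web <- function(records, host_map = NULL, para_map = NULL) {
  stopifnot(is.data.frame(records))
  cells <- list(); dropped <- 0L
  for (r in seq_len(nrow(records))) {
    para <- allocate_record(records$parasitoid_mor[r],
                            records$parasitoid_specimens[[r]], para_map,
                            records$count[r])
    if (is.null(para)) { dropped <- dropped + 1L; next }
    res <- list()
    for (k in seq_along(para$taxon)) {
      hs <- allocate_record(records$host_mor[r], records$host_specimens[[r]],
                            host_map, para$n[k])
      if (is.null(hs)) { res <- NULL; break }
      res[[k]] <- tibble(host = hs$taxon, parasitoid = para$taxon[k], n = hs$n)
    }
    if (is.null(res)) { dropped <- dropped + 1L; next }
    cells[[length(cells) + 1L]] <- bind_rows(res)
  }
  if (length(cells) == 0) {
    abort("empty web: no resolvable records", class = "cryptwebs_empty_web_error")
  }
  agg <- bind_rows(cells) |>
    group_by(.data$host, .data$parasitoid) |>
    summarise(n = sum(.data$n), .groups = "drop")
  hosts <- sort(unique(agg$host)); paras <- sort(unique(agg$parasitoid))
  m <- matrix(0L, length(hosts), length(paras), dimnames = list(hosts, paras))
  m[cbind(match(agg$host, hosts), match(agg$parasitoid, paras))] <- as.integer(agg$n)
  out <- interaction_matrix(m)
  attr(out, "dropped_records") <- dropped
  out
}

# Allocation of one record side; NULL signals an unresolvable (dropped) record.
allocate_record <- function(label, specimens, map, total) {
  if (total <= 0) return(NULL)
  if (is.null(map)) return(tibble(taxon = label, n = as.integer(total)))
  ents <- unique(map$taxon[map$morphospecies == label])
  if (length(ents) == 0) {
    abort(paste0("label not resolvable by taxonomy map: ", label),
          class = "cryptwebs_mapping_error")
  }
  if (length(ents) == 1) return(tibble(taxon = ents, n = as.integer(total)))
  obs <- map$taxon[match(intersect(specimens, map$specimen_id), map$specimen_id)]
  obs <- obs[obs %in% ents]
  if (length(obs) == 0) return(NULL)
  shares <- largest_remainder(total, table(obs))
  tibble(taxon = names(shares), n = as.integer(shares)) |> filter(.data$n > 0)
}

# Integer apportionment by largest remainder; conserves the total exactly.
largest_remainder <- function(total, weights) {
  w <- as.numeric(weights) / sum(weights)
  exact <- total * w
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(w)) # ties by position
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), names(weights))
}

#' Build the four webs crossing morphological and molecular taxonomies
#'
#' Produces the MOR-MOR, MOR-MOL, MOL-MOR and MOL-MOL interaction matrices
#' (key = host level then parasitoid level) from one set of rearing records.
#' Records that cannot be resolved at the molecular level on either side are
#' removed from all four webs, so the grand total m is identical across
#' them.
#'
#' @param records Rearing-record tibble.
#' @param host_map,para_map Molecular taxonomy maps (see [molecular_map()]).
#' @return A named list of class `cw_webset` with attribute
#'   `dropped_records`.
#' @export
build_webset <- function(records, host_map, para_map) {
  usable <- map_lgl(seq_len(nrow(records)), function(r) {
    records$count[r] > 0 &&
      side_resolvable(records$host_mor[r], records$host_specimens[[r]], host_map) &&
      side_resolvable(records$parasitoid_mor[r], records$parasitoid_specimens[[r]], para_map)
  })
  kept <- records[usable, , drop = FALSE]
  if (nrow(kept) == 0) abort("empty web: no resolvable records",
                             class = "cryptwebs_empty_web_error")
  keys <- list(`MOR-MOR` = list(NULL, NULL), `MOR-MOL` = list(NULL, para_map),
               `MOL-MOR` = list(host_map, NULL), `MOL-MOL` = list(host_map, para_map))
  webs <- imap(keys, function(maps, key) {
    tryCatch(build_web(kept, maps[[1]], maps[[2]]),
             error = function(e) abort(paste0("[", key, "] ", conditionMessage(e)),
                                       class = class(e)[1]))
  })
  structure(webs, class = "cw_webset",
            dropped_records = sum(!usable & records$count > 0))
}

side_resolvable <- function(label, specimens, map) {
  if (is.null(map)) return(TRUE)
  ents <- unique(map$taxon[map$morphospecies == label])
  if (length(ents) == 0) {
    abort(paste0("label not resolvable by taxonomy map: ", label),
          class = "cryptwebs_mapping_error")
  }
  length(ents) == 1 || any(specimens %in% map$specimen_id)
}

#' @export
print.cw_webset <- function(x, ...) {
  cat("<web set>\n")
  for (k in names(x)) {
    cat(sprintf("  %s: %d x %d, m = %d\n", k, nrow(x[[k]]), ncol(x[[k]]),
                grand_total(x[[k]])))
  }
  invisible(x)
}

#' Subset rearing records by province
#'
#' Verbatim string match after whitespace trimming; case-sensitive by
#' default (set `normalize = TRUE` to compare case-insensitively).
#'
#' @param records Rearing-record tibble.
#' @param province Province name to keep.
#' @param normalize Lowercase both sides before matching (default `FALSE`).
#' @return The matching records; warns (without failing) when none match.
#' @export
subset_by_province <- function(records, province, normalize = FALSE) {
  pv <- stringr::str_trim(records$province)
  target <- stringr::str_trim(province)
  if (normalize) { pv <- tolower(pv); target <- tolower(target) }
  out <- records[pv == target, , drop = FALSE]
  if (nrow(out) == 0) warn(paste0("no records for province: ", province))
  out
}
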