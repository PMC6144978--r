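#' Integrate delimitation methods against a morphological baseline
#'
#' Combines per-method molecular partitions into a consensus species
#' delimitation constrained to refine the morphospecies: specimens of
#' different morphospecies are never merged, so the consensus can only split
#' morphospecies, never lump them. Within each morphospecies the consensus
#' adopts the sub-partition supported by at least two of the available
#' COI-based methods (the most-supported one when several qualify, with ties
#' broken toward fewer entities); when no agreement reaches that majority the
#' morphospecies is left unsplit. If only one COI-based method is supplied
#' it decides alone. Specimens without any molecular assignment are carried
#' as their morphospecies and flagged as lacking confirmative molecular data.
#'
#' @param morpho Tibble with columns `specimen_id` and `morphospecies`
#'   covering all specimens.
#' @param per_method List of molecular partitions: tibbles with columns
#'   `specimen_id`, `entity_id`, carrying `method` and `marker` attributes
#'   (as from [abgd_partition()]`$stable`, [gmyc_partition()], or an
#'   externally supplied partition). Only partitions with marker `"COI"`
#'   vote in the consensus; all appear in the agreement report.
#' @return An object of class `cw_consensus`: a list with `partition`
#'   (tibble `specimen_id`, `morphospecies`, `entity_id`, `entity_label`,
#'   `molecular_data`) and `report` (one row per morphospecies with the
#'   final entity count and per-method agreement flags using the
#'   y / y+k / y-k / n vocabulary). `tidy()` returns the report.
#' @export
integrate_delimitations <- function(morpho, per_method) {
  stopifnot(is.data.frame(morpho),
            all(c("specimen_id", "morphospecies") %in% names(morpho)))
  if (length(per_method) == 0) abort("no molecular partitions supplied",
                                     class = "cryptwebs_validation_error")
  meth_names <- map_chr(seq_along(per_method), function(i) {
    m <- attr(per_method[[i]], "method") %||% paste0("method", i)
    mk <- attr(per_method[[i]], "marker")
    if (is.null(mk) || is.na(mk)) m else paste(m, mk, sep = "_")
  })
  names(per_method) <- make.unique(meth_names)
  is_coi <- map_lgl(per_method, function(p) identical(attr(p, "marker"), "COI"))
  if (!any(is_coi)) abort("at least one COI-based partition is required",
                          class = "cryptwebs_validation_error")
  coi_methods <- per_method[is_coi]

  lookup <- map(per_method, ~ setNames(.x$entity_id, .x$specimen_id))
  rows <- list(); report <- list()
  for (sp in unique(morpho$morphospecies)) {
    ids <- morpho$specimen_id[morpho$morphospecies == sp]
    sub <- consensus_blocks(ids, lookup[is_coi])
    f <- length(unique(sub))
    labels <- if (f == 1) rep(sp, length(ids)) else paste0(sp, " [", sub, "]")
    has_mol <- ids %in% unlist(map(per_method, "specimen_id"))
    rows[[sp]] <- tibble(specimen_id = ids, morphospecies = sp,
                         entity_label = labels, molecular_data = has_mol)
    flags <- map_chr(names(per_method), function(mn) {
      asg <- lookup[[mn]][ids]
      covered <- !is.na(asg)
      if (!any(covered)) return(NA_character_)
      agreement_flag(length(unique(asg[covered])), f)
    })
    report[[sp]] <- tibble(morphospecies = sp, n_entities = f,
                           n_specimens = length(ids),
                           no_molecular_data = sum(!has_mol),
                           !!!setNames(as.list(flags), names(per_method)))
  }
  part <- bind_rows(rows)
  part$entity_id <- match(part$entity_label, unique(part$entity_label))
  structure(list(partition = part |>
                   select("specimen_id", "morphospecies", "entity_id",
                          "entity_label", "molecular_data"),
                 report = bind_rows(report)),
            class = "cw_consensus")
}

# Sub-partition of one morphospecies adopted by majority among COI methods.
consensus_blocks <- function(ids, coi_lookup) {
  restrict <- map(coi_lookup, function(lk) {
    asg <- lk[ids]
    if (all(is.na(asg))) NULL else asg
  })
  restrict <- compact(restrict)
  if (length(restrict) == 0) return(rep(1L, length(ids)))
  need <- if (length(restrict) == 1) 1L else 2L
  # support for each candidate = number of methods whose restriction agrees
  # with it on the specimens both cover
  support <- map_int(restrict, function(cand) {
    sum(map_lgl(restrict, function(other) {
      common <- which(!is.na(cand) & !is.na(other))
      if (length(common) == 0) return(FALSE)
      same_partition(cand[common], other[common])
    }))
  })
  sizes <- map_int(restrict, ~ length(unique(.x[!is.na(.x)])))
  ok <- which(support >= need)
  if (length(ok) == 0) return(rep(1L, length(ids)))
  # most support, ties toward fewer entities (toward the morphospecies)
  best <- ok[order(-support[ok], sizes[ok])][1]
  asg <- restrict[[best]]
  out <- canonical_assignment(ifelse(is.na(asg), "unassigned", asg))
  # unassigned specimens fold into the first block rather than new entities
  if (any(is.na(asg))) {
    out[is.na(asg)] <- out[which(!is.na(asg))[1]]
    out <- canonical_assignment(out)
  }
  out
}

agreement_flag <- function(c_m, f) {
  if (c_m == f) return("y")
  if (c_m > f) return(sprintf("y+%d", c_m - f))
  if (c_m == 1 && f > 1) return("n")
  sprintf("y-%d", f - c_m)
}

#' @export
print.cw_consensus <- function(x, ...) {
  cat(sprintf("<consensus delimitation: %d morphospecies -> %d entities (%d specimens)>\n",
              length(unique(x$partition$morphospecies)),
              length(unique(x$partition$entity_id)), nrow(x$partition)))
  invisible(x)
}

#' @rdname integrate_delimitations
#' @param x A `cw_consensus` object.
#' @param ... Unused.
#' @method tidy cw_consensus
#' @export
tidy.cw_consensus <- function(x, ...) x$report

#' Taxonomy map from a consensus (or any labelled) partition
#'
#' Converts a delimitation result into the specimen-to-taxon map consumed by
#' [build_web()].
#'
#' @param x A `cw_consensus`, or a tibble with columns `specimen_id`,
#'   `morphospecies` and one of `entity_label` / `entity_id`.
#' @return Tibble with columns `specimen_id`, `morphospecies`, `taxon`.
#' @export
molecular_map <- function(x) {
  p <- if (inherits(x, "cw_consensus")) x$partition else x
  stopifnot(all(c("specimen_id", "morphospecies") %in% names(p)))
  taxon <- if ("entity_label" %in% names(p)) p$entity_label else
    paste0(p$morphospecies, " [", p$entity_id, "]")
  tibble(specimen_id = p$specimen_id, morphospecies = p$morphospecies,
         taxon = as.character(taxon))
}
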