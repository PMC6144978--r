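#' Construct a species-delimitation partition
#'
#' A partition assigns every specimen to exactly one delimited entity. It is
#' represented as a tibble with columns `specimen_id` and `entity_id` (plus
#' optionally `morphospecies`), and attributes `method` (e.g. `"ABGD"`,
#' `"GMYC"`, `"PTP"`, `"CONSENSUS"`, `"MORPHO"`) and `marker` (`"COI"`,
#' `"28S"`, `"COMBINED"` or `NA`). Entity ids are recoded to be contiguous
#' integers in order of first appearance.
#'
#' @param specimen_id Character vector of specimen ids (unique).
#' @param entity_id Vector assigning each specimen to an entity.
#' @param method,marker Provenance tags stored as attributes.
#' @param morphospecies Optional morphospecies label per specimen.
#' @return A tibble of class `cw_partition`.
#' @export
partition <- function(specimen_id, entity_id, method = NA_character_,
                      marker = NA_character_, morphospecies = NULL) {
  stopifnot(length(specimen_id) == length(entity_id))
  if (anyDuplicated(specimen_id)) {
    abort("specimen ids must be unique within a partition",
          class = "cryptwebs_validation_error")
  }
  ent <- match(entity_id, unique(entity_id))
  out <- tibble(specimen_id = as.character(specimen_id), entity_id = as.integer(ent))
  if (!is.null(morphospecies)) out$morphospecies <- as.character(morphospecies)
  structure(out, class = c("cw_partition", class(out)),
            method = method, marker = marker)
}

#' Number of entities in a partition
#' @param p A `cw_partition` (or any tibble with an `entity_id` column).
#' @return Integer count of distinct entities.
#' @export
n_entities <- function(p) length(unique(p$entity_id))

#' Number of singleton entities in a partition
#' @param p A `cw_partition`.
#' @return Integer count of entities containing exactly one specimen.
#' @export
n_singletons <- function(p) sum(table(p$entity_id) == 1L)

#' @export
print.cw_partition <- function(x, ...) {
  cat(sprintf("<partition: %s/%s, %d specimens, %d entities (%d singletons)>\n",
              attr(x, "method") %||% NA, attr(x, "marker") %||% NA,
              nrow(x), n_entities(x), n_singletons(x)))
  NextMethod()
}

# canonical entity labelling in specimen order, for partition comparison
canonical_assignment <- function(entity_id) {
  match(entity_id, unique(entity_id))
}

# TRUE when two assignments over the same ordered specimen set are equal
same_partition <- function(a, b) {
  identical(canonical_assignment(a), canonical_assignment(b))
}
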