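#' Read a rearing-record table
#'
#' Rearing records are the raw observations of the study design: a field
#' sample of scale-insect hosts is kept until parasitoids emerge, and each
#' row records how many individuals of one parasitoid morphospecies were
#' reared from one host morphospecies at one site. Tables are plain
#' tab-separated text with a header row naming at least `sample_id`,
#' `site_id`, `province`, `host_mor`, `parasitoid_mor` and `count`. Optional
#' columns `host_specimens` and `parasitoid_specimens` carry `;`-joined
#' specimen identifiers linking the record to sequenced vouchers; they are
#' parsed into list-columns.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per rearing record; `count` is integer and
#'   the specimen columns are list-columns of character vectors (possibly
#'   empty).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "sample_id\tsite_id\tprovince\thost_mor\tparasitoid_mor\tcount",
#'   "s1\tA\tYunnan\tAonidiella aurantii\tComperiella bifasciata\t12"
#' ), tf)
#' read_rearing_table(tf)
#' @export
read_rearing_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "site_id", "province", "host_mor", "parasitoid_mor", "count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("rearing table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cryptwebs_schema_error")
  }
  counts <- suppressWarnings(as.numeric(tab$count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad) > 0) {
    abort(paste0("invalid count (must be a non-negative integer) in data row(s): ",
                 paste(bad, collapse = ", ")),
          class = "cryptwebs_validation_error")
  }
  empty_lab <- which(!nzchar(tab$host_mor) | !nzchar(tab$parasitoid_mor))
  if (length(empty_lab) > 0) {
    abort(paste0("empty host/parasitoid label in data row(s): ",
                 paste(empty_lab, collapse = ", ")),
          class = "cryptwebs_validation_error")
  }
  out <- tibble(
    sample_id = tab$sample_id,
    site_id = tab$site_id,
    province = tab$province,
    host_mor = tab$host_mor,
    parasitoid_mor = tab$parasitoid_mor,
    count = as.integer(counts),
    host_specimens = split_specimens(tab[["host_specimens"]], nrow(tab)),
    parasitoid_specimens = split_specimens(tab[["parasitoid_specimens"]], nrow(tab))
  )
  out
}

split_specimens <- function(x, n) {
  if (is.null(x)) return(rep(list(character(0)), n))
  map(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    ids <- stringr::str_trim(strsplit(s, ";", fixed = TRUE)[[1]])
    ids <- ids[nzchar(ids)]
    if (anyDuplicated(ids)) {
      abort("duplicate specimen ids within one record", class = "cryptwebs_validation_error")
    }
    ids
  })
}

#' Write a rearing-record table
#'
#' Inverse of [read_rearing_table()]: specimen list-columns are `;`-joined.
#'
#' @param records Tibble of rearing records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rearing_table <- function(records, path) {
  out <- records
  for (col in c("host_specimens", "parasitoid_specimens")) {
    if (col %in% names(out)) {
      out[[col]] <- map_chr(out[[col]], paste, collapse = ";")
    } else {
      out[[col]] <- ""
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file of barcode sequences
#'
#' Headers are expected to encode the specimen id and its morphospecies label
#' separated by a delimiter, e.g. `IOZ001|Comperiella_bifasciata`. All
#' sequences of one marker must share the aligned length; gaps (`-`) and
#' ambiguous sites (`N`) are preserved and sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker identifier, e.g. `"COI"` or `"28S"`.
#' @param delim Header delimiter between specimen id and morphospecies
#'   (default `"|"`). Text after a second delimiter is ignored.
#' @return A tibble with columns `specimen_id`, `morphospecies`, `marker`,
#'   `sequence`.
#' @export
read_fasta_alignment <- function(path, marker, delim = "|") {
  stopifnot(file.exists(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort("empty FASTA file", class = "cryptwebs_format_error")
  seqs <- unname(toupper(vapply(as.character(dna), paste, character(1), collapse = "")))
  parts <- stringr::str_split(names(dna), stringr::fixed(delim))
  specimen_id <- map_chr(parts, 1)
  morphospecies <- map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_)
  if (anyNA(morphospecies)) {
    abort(paste0("FASTA header(s) lack the '", delim, "' delimiter: ",
                 paste(head(names(dna)[is.na(morphospecies)], 5), collapse = ", ")),
          class = "cryptwebs_format_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    offenders <- specimen_id[lens != mode_len]
    abort(paste0("ragged alignment for marker ", marker, "; offending ids: ",
                 paste(offenders, collapse = ", ")),
          class = "cryptwebs_alignment_error")
  }
  if (anyDuplicated(specimen_id)) {
    dup <- unique(specimen_id[duplicated(specimen_id)])
    abort(paste0("duplicate specimen_id for marker ", marker, ": ",
                 paste(dup, collapse = ", ")),
          class = "cryptwebs_duplicate_error")
  }
  tibble(specimen_id = specimen_id, morphospecies = morphospecies,
         marker = marker, sequence = seqs)
}

#' Write an aligned FASTA file
#'
#' @param seqs Tibble as returned by [read_fasta_alignment()].
#' @param path Output path.
#' @param delim Header delimiter (default `"|"`).
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(seqs, path, delim = "|") {
  lines <- character(2L * nrow(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", seqs$specimen_id, delim, seqs$morphospecies)
  lines[c(FALSE, TRUE)] <- seqs$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate an ultrametric Newick tree
#'
#' Trees for threshold-based delimitation must be ultrametric (all tips
#' equidistant from the root, as produced by rate-smoothing of a phylogram).
#' Validation allows a relative tolerance of `tol` times the tree height to
#' absorb floating-point noise in upstream output.
#'
#' @param path Path to a Newick file containing a single rooted tree with
#'   branch lengths.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path, tol = 1e-6) {
  stopifnot(file.exists(path))
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) abort("expected a single tree", class = "cryptwebs_format_error")
    tr <- tr[[1]]
  }
  validate_ultrametric(tr, tol = tol)
}

#' Validate that a phylo object is ultrametric
#'
#' @param tr An [ape::phylo] object.
#' @param tol Relative tolerance on the tip-height spread.
#' @return `tr`, invisibly usable (returned on success).
#' @export
validate_ultrametric <- function(tr, tol = 1e-6) {
  if (is.null(tr$edge.length)) {
    abort("tree has no branch lengths", class = "cryptwebs_format_error")
  }
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)) || anyNA(tr$tip.label)) {
    abort("tree has unlabeled tips", class = "cryptwebs_format_error")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort("duplicate tip labels", class = "cryptwebs_format_error")
  }
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  height <- max(depths)
  spread <- diff(range(depths))
  if (height <= 0) abort("tree has zero height", class = "cryptwebs_format_error")
  if (spread > tol * height) {
    abort(sprintf("tree is not ultrametric: tip-height spread %.3g exceeds tolerance %.3g",
                  spread, tol * height),
          class = "cryptwebs_ultrametric_error")
  }
  tr
}

#' Tree height of an ultrametric tree
#' @param tr An [ape::phylo] object.
#' @return Root-to-tip distance (maximum over tips).
#' @export
tree_height <- function(tr) {
  max(ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)])
}

#' Write an interaction matrix as a labelled TSV
#'
#' The first column holds host labels; remaining column names are parasitoid
#' labels.
#'
#' @param M An [interaction_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_web_tsv <- function(M, path) {
  df <- as_tibble(as.data.frame(unclass(M), check.names = FALSE), rownames = "host")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an interaction matrix written by [write_web_tsv()]
#'
#' @param path Path to the TSV.
#' @return An [interaction_matrix()].
#' @export
read_web_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(host = readr::col_character(),
                                                      .default = readr::col_double()),
                        progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$host
  interaction_matrix(m)
}
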