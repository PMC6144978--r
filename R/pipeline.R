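#' Pipeline configuration
#'
#' Describes one end-to-end run: either a synthetic study (via
#' [sim_config()]) or paths to real inputs (rearing TSV plus COI/28S FASTA
#' alignments and optional ultrametric trees); exactly one of the two must
#' be active. Stage seeds derive from the configuration.
#'
#' @param out_dir Output directory for the report bundle.
#' @param simulation A [sim_config()], or `NULL` when real inputs are given.
#' @param records_path,coi_path,s28_path,host_tree_path,para_tree_path
#'   Paths to real inputs (used only when `simulation` is `NULL`).
#' @param methods Delimitation methods to run: subset of
#'   `c("abgd", "gmyc")`.
#' @param province Regional subset to analyse alongside the full webs
#'   (default `"Yunnan"`; `NULL` to skip).
#' @param seed Seed for stochastic network metrics (robustness orders).
#' @param n_orders Random removal orders for robustness.
#' @param digits Rounding for the human-readable tables (default 2, with
#'   full-precision companion columns).
#' @return A list of class `cw_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulation = NULL,
                            records_path = NULL, coi_path = NULL,
                            s28_path = NULL, host_tree_path = NULL,
                            para_tree_path = NULL,
                            methods = c("abgd", "gmyc"),
                            province = "Yunnan",
                            seed = NULL, n_orders = 1000, digits = 2) {
  have_sim <- !is.null(simulation)
  have_real <- !is.null(records_path)
  if (have_sim == have_real) {
    abort("exactly one of {simulation, real inputs} must be configured",
          class = "cryptwebs_config_error")
  }
  if (have_sim) stopifnot(inherits(simulation, "cw_sim_config"))
  seed <- seed %||% (if (have_sim) simulation$seed else NULL)
  if (is.null(seed)) abort("a seed is required", class = "cryptwebs_config_error")
  structure(list(out_dir = out_dir, simulation = simulation,
                 records_path = records_path, coi_path = coi_path,
                 s28_path = s28_path, host_tree_path = host_tree_path,
                 para_tree_path = para_tree_path,
                 methods = match.arg(methods, several.ok = TRUE),
                 province = province, seed = as.integer(seed),
                 n_orders = n_orders, digits = digits),
            class = "cw_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> delimit -> integrate -> build the four
#' webs -> species indices -> network metrics -> completeness, writing a
#' TSV report bundle and a run manifest to `cfg$out_dir`. Reruns with an
#' identical configuration reproduce identical numeric tables.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result (class
#'   `cw_pipeline`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cw_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[cryptwebs] ", sprintf(...))

  log_stage("stage inputs: %s", if (!is.null(cfg$simulation)) "simulation" else "files")
  inp <- pipeline_inputs(cfg)

  log_stage("stage delimit: methods %s", paste(cfg$methods, collapse = "+"))
  delim <- map(c(host = "host", parasitoid = "parasitoid"), function(g) {
    delimit_guild(inp, g, cfg$methods)
  })
  for (g in names(delim)) {
    readr::write_tsv(delim[[g]]$consensus$report,
                     file.path(cfg$out_dir, paste0("delimitation_report_", g, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(delim[[g]]$consensus$partition,
                     file.path(cfg$out_dir, paste0("consensus_partition_", g, ".tsv")),
                     progress = FALSE)
  }

  log_stage("stage webs")
  maps <- list(host = molecular_map(delim$host$consensus),
               parasitoid = molecular_map(delim$parasitoid$consensus))
  webs <- build_webset(inp$records, maps$host, maps$parasitoid)
  for (k in names(webs)) {
    write_web_tsv(webs[[k]], file.path(cfg$out_dir, paste0("web_", k, ".tsv")))
  }

  log_stage("stage species indices")
  sp_idx <- imap(webs, function(M, key) {
    format_species_indices(species_indices(M, "parasitoid")) |>
      mutate(web = key, .before = 1)
  }) |> bind_rows()
  readr::write_tsv(sp_idx, file.path(cfg$out_dir, "species_indices.tsv"),
                   progress = FALSE)

  log_stage("stage network metrics")
  metrics <- network_metrics(webs, seed = cfg$seed, n_orders = cfg$n_orders)
  region_records <- NULL
  if (!is.null(cfg$province)) {
    region_records <- subset_by_province(inp$records, cfg$province)
    if (nrow(region_records) > 0) {
      region_web <- tryCatch(
        build_web(resolvable_records(region_records, maps$host, maps$parasitoid),
                  maps$host, maps$parasitoid),
        error = function(e) NULL)
      if (!is.null(region_web)) {
        metrics <- bind_rows(
          metrics,
          network_metrics(region_web, seed = cfg$seed, n_orders = cfg$n_orders) |>
            mutate(web = paste0(cfg$province, " MOL-MOL"), .before = 1))
      }
    }
  }
  readr::write_tsv(round_full(metrics, cfg$digits),
                   file.path(cfg$out_dir, "network_metrics.tsv"), progress = FALSE)

  log_stage("stage completeness")
  comp <- map(c(parasitoid = "parasitoid", host = "host"), function(lv) {
    completeness_curve(abundance_vector(inp$records, lv)) |>
      mutate(level = lv, .before = 1)
  }) |> bind_rows()
  readr::write_tsv(comp, file.path(cfg$out_dir, "completeness.tsv"), progress = FALSE)

  manifest <- tibble(
    key = c("package_version", "r_version", "seed", "methods", "province",
            "n_records", "dropped_records_webset"),
    value = c(as.character(utils::packageVersion("cryptwebs")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.character(cfg$seed), paste(cfg$methods, collapse = "+"),
              cfg$province %||% "", as.character(nrow(inp$records)),
              as.character(attr(webs, "dropped_records")))
  )
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"), progress = FALSE)

  invisible(structure(list(inputs = inp, delimitation = delim, webs = webs,
                           species_indices = sp_idx, network_metrics = metrics,
                           completeness = comp, manifest = manifest),
                      class = "cw_pipeline"))
}

round_full <- function(df, digits) {
  num <- names(df)[map_lgl(df, is.numeric)]
  for (cn in setdiff(num, c("n_hosts", "n_parasitoids", "n_links", "m",
                            "n_compartments", "rng_seed"))) {
    df[[paste0(cn, "_full")]] <- df[[cn]]
    df[[cn]] <- round(df[[cn]], digits)
  }
  df
}

pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    study <- simulate_study(cfg$simulation, alignments = TRUE)
    list(records = study$records,
         sequences = study$alignments$sequences,
         trees = study$alignments$trees,
         specimens = study$community$specimens,
         truth = study$truth)
  } else {
    records <- read_rearing_table(cfg$records_path)
    seqs <- bind_rows(
      if (!is.null(cfg$coi_path)) read_fasta_alignment(cfg$coi_path, "COI"),
      if (!is.null(cfg$s28_path)) read_fasta_alignment(cfg$s28_path, "28S")
    )
    trees <- list(
      host = if (!is.null(cfg$host_tree_path)) read_newick(cfg$host_tree_path),
      parasitoid = if (!is.null(cfg$para_tree_path)) read_newick(cfg$para_tree_path)
    )
    specimens <- seqs |> distinct(.data$specimen_id, .data$morphospecies)
    list(records = records, sequences = seqs, trees = trees,
         specimens = specimens, truth = NULL)
  }
}

delimit_guild <- function(inp, g, methods) {
  seqs <- inp$sequences
  if ("guild" %in% names(seqs)) seqs <- seqs |> filter(.data$guild == g)
  morpho <- inp$specimens
  if ("guild" %in% names(morpho)) morpho <- morpho |> filter(.data$guild == g)
  morpho <- morpho |> distinct(.data$specimen_id, .data$morphospecies)
  parts <- list()
  coi <- seqs |> filter(.data$marker == "COI")
  if ("abgd" %in% methods && nrow(coi) >= 2) {
    parts[["abgd_coi"]] <- structure(abgd_partition(k2p_matrix(coi))$stable,
                                     method = "ABGD", marker = "COI")
    s28 <- seqs |> filter(.data$marker == "28S")
    if (nrow(s28) >= 2) {
      parts[["abgd_28s"]] <- structure(abgd_partition(k2p_matrix(s28))$stable,
                                       method = "ABGD", marker = "28S")
    }
  }
  tr <- inp$trees[[g]]
  if ("gmyc" %in% methods && !is.null(tr) && ape::Ntip(tr) >= 3) {
    fit <- gmyc_fit(tr)
    parts[["gmyc_coi"]] <- structure(gmyc_partition(fit),
                                     method = "GMYC", marker = "COI")
  } else {
    fit <- NULL
  }
  list(consensus = integrate_delimitations(morpho, parts),
       partitions = parts, gmyc = fit)
}

resolvable_records <- function(records, host_map, para_map) {
  keep <- map_lgl(seq_len(nrow(records)), function(r) {
    records$count[r] > 0 &&
      side_resolvable(records$host_mor[r], records$host_specimens[[r]], host_map) &&
      side_resolvable(records$parasitoid_mor[r],
                      records$parasitoid_specimens[[r]], para_map)
  })
  records[keep, , drop = FALSE]
}
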