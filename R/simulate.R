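#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic community, alignment and rearing
#' generators, with defaults mirroring the study conditions of a
#' China-wide diaspidid-encyrtid rearing survey: 37 molecular host species
#' collapsing to 28 morphospecies and 41 molecular parasitoid species
#' collapsing to 18 morphospecies (complex-size frequencies follow the
#' observed cryptic complexes, up to six entities per morphospecies);
#' intraspecific COI divergence capped near 1.9% and interspecific
#' divergence of at least 3.7%; a community dominated by single-host
#' specialists with a couple of "superhosts" attracting many parasitoids;
#' and strongly overdispersed rearing counts.
#'
#' @param seed Integer seed; mandatory, drives all stages.
#' @param n_host_species,n_parasitoid_species Molecular species counts.
#' @param host_complex_probs,parasitoid_complex_probs Probabilities over
#'   complex sizes 1..6 used to draw how many cryptic species share one
#'   morphospecies.
#' @param host_complex_sizes,parasitoid_complex_sizes Optional explicit
#'   complex sizes (must sum to the species count) overriding the draw.
#' @param intra_div_max Target ceiling for intraspecific K2P divergence
#'   (default 0.019).
#' @param inter_div_min Target floor for interspecific K2P divergence
#'   (default 0.037).
#' @param seq_length Alignment length in bp (default 600).
#' @param kappa Transition/transversion rate ratio of the two-rate
#'   substitution process (default 4).
#' @param rate_coi,rate_28s Relative substitution rates of the fast and
#'   slow markers (defaults 1 and 0.1).
#' @param n_specimens Sequenced specimens per molecular species (default 5,
#'   a typical barcode-survey density of about five COI sequences per
#'   delimited entity).
#' @param specialist_fraction Probability a parasitoid uses exactly one
#'   host (default 0.8); otherwise it uses 2-3.
#' @param superhost_count Number of host species with inflated parasitoid
#'   loads (default 2).
#' @param superhost_weight Sampling weight of a superhost relative to an
#'   ordinary host (default 8).
#' @param count_mu,count_size Negative-binomial mean and dispersion of
#'   per-record reared counts (defaults 25 and 0.6; counts are shifted to
#'   be at least 1).
#' @param n_sites,n_provinces Number of sampling sites and provinces
#'   (defaults 15 and 5; the first province is always Yunnan).
#' @return A validated list of class `cw_sim_config`.
#' @export
sim_config <- function(seed,
                       n_host_species = 37, n_parasitoid_species = 41,
                       host_complex_probs = c(`1` = 21, `2` = 5, `3` = 2,
                                              `4` = 0, `5` = 0, `6` = 0),
                       parasitoid_complex_probs = c(`1` = 9, `2` = 3, `3` = 2,
                                                    `4` = 2, `5` = 0, `6` = 2),
                       host_complex_sizes = NULL,
                       parasitoid_complex_sizes = NULL,
                       intra_div_max = 0.019, inter_div_min = 0.037,
                       seq_length = 600, kappa = 4,
                       rate_coi = 1, rate_28s = 0.1,
                       n_specimens = 5,
                       specialist_fraction = 0.8,
                       superhost_count = 2, superhost_weight = 8,
                       count_mu = 25, count_size = 0.6,
                       n_sites = 15, n_provinces = 5) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("a seed is mandatory", class = "cryptwebs_config_error")
  }
  if (!(intra_div_max < inter_div_min)) {
    abort("intra_div_max must be below inter_div_min", class = "cryptwebs_config_error")
  }
  if (specialist_fraction < 0 || specialist_fraction > 1) {
    abort("specialist_fraction must lie in [0, 1]", class = "cryptwebs_config_error")
  }
  for (nm in c("host", "parasitoid")) {
    sizes <- get(paste0(nm, "_complex_sizes"))
    nsp <- get(paste0("n_", nm, "_species"))
    if (!is.null(sizes) && sum(sizes) != nsp) {
      abort(paste0(nm, " complex sizes must sum to the species count"),
            class = "cryptwebs_config_error")
    }
  }
  cfg <- list(seed = as.integer(seed),
              n_host_species = n_host_species,
              n_parasitoid_species = n_parasitoid_species,
              host_complex_probs = host_complex_probs,
              parasitoid_complex_probs = parasitoid_complex_probs,
              host_complex_sizes = host_complex_sizes,
              parasitoid_complex_sizes = parasitoid_complex_sizes,
              intra_div_max = intra_div_max, inter_div_min = inter_div_min,
              seq_length = seq_length, kappa = kappa,
              rate_coi = rate_coi, rate_28s = rate_28s,
              n_specimens = n_specimens,
              specialist_fraction = specialist_fraction,
              superhost_count = superhost_count,
              superhost_weight = superhost_weight,
              count_mu = count_mu, count_size = count_size,
              n_sites = n_sites, n_provinces = n_provinces,
              # derived divergence geometry (see the methods vignette):
              # species-tree splits span a band keeping K2P well away from
              # both the barcode gap and saturation
              split_depth_min = 0.75 * inter_div_min,
              split_depth_max = 3.4 * inter_div_min,
              intra_depth = intra_div_max / 4)
  structure(cfg, class = "cw_sim_config")
}

#' Simulate a host and parasitoid community with cryptic structure
#'
#' Draws, for each guild, an ultrametric species tree whose node heights
#' are rescaled into a fixed divergence band, with morphospecies formed as
#' clades of the configured complex sizes grafted below the
#' between-morphospecies splits. Every split between molecular species
#' (cryptic ones included) therefore exceeds the interspecific divergence
#' floor in expectation, while within-species variation added later stays
#' below the intraspecific ceiling.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `cw_community` with species tables, species-level
#'   trees and the specimen register.
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "cw_sim_config"))
  set.seed(cfg$seed)
  host <- simulate_guild(cfg$n_host_species, cfg$host_complex_sizes,
                         cfg$host_complex_probs, "Diaspididae_sp", cfg)
  para <- simulate_guild(cfg$n_parasitoid_species, cfg$parasitoid_complex_sizes,
                         cfg$parasitoid_complex_probs, "Encyrtidae_sp", cfg)
  specimens <- bind_rows(
    specimen_register(host$species, cfg$n_specimens, "IOZH", "host"),
    specimen_register(para$species, cfg$n_specimens, "IOZP", "parasitoid")
  )
  structure(list(cfg = cfg,
                 host_species = host$species, parasitoid_species = para$species,
                 host_tree = host$tree, parasitoid_tree = para$tree,
                 specimens = specimens),
            class = "cw_community")
}

#' @export
print.cw_community <- function(x, ...) {
  cat(sprintf(paste0("<synthetic community: %d host species in %d morphospecies; ",
                     "%d parasitoid species in %d morphospecies; %d specimens>\n"),
              nrow(x$host_species), length(unique(x$host_species$morphospecies)),
              nrow(x$parasitoid_species),
              length(unique(x$parasitoid_species$morphospecies)),
              nrow(x$specimens)))
  invisible(x)
}

simulate_guild <- function(n_species, sizes, probs, prefix, cfg) {
  if (is.null(sizes)) sizes <- draw_complex_sizes(n_species, probs)
  if (max(sizes) > n_species) {
    abort("complex size exceeds species count", class = "cryptwebs_config_error")
  }
  n_mor <- length(sizes)
  mor_labels <- sprintf("%s%02d", prefix, seq_len(n_mor))
  species <- tibble(
    morphospecies = rep(mor_labels, sizes),
    complex_size = rep(sizes, sizes),
    species_id = unlist(map2(mor_labels, sizes, function(lab, k) {
      if (k == 1) lab else paste0(lab, "_nr", seq_len(k))
    }))
  ) |> select("species_id", "morphospecies", "complex_size")
  lo <- cfg$split_depth_min; hi <- cfg$split_depth_max
  mid <- (lo + hi) / 2
  # between-morphospecies splits occupy the upper half of the band,
  # within-complex (cryptic) splits the lower half
  mor_tree <- scaled_coalescent(n_mor, mid, hi, sprintf("T%03d", seq_len(n_mor)))
  subtrees <- list()
  for (i in seq_len(n_mor)) {
    ids <- species$species_id[species$morphospecies == mor_labels[i]]
    subtrees[[sprintf("T%03d", i)]] <-
      if (length(ids) == 1) ids else scaled_coalescent(length(ids), lo, 0.9 * mid, ids)
  }
  tree <- graft_clades(mor_tree, subtrees)
  list(species = species, tree = tree)
}

draw_complex_sizes <- function(n, probs) {
  vals <- as.integer(names(probs))
  sizes <- integer(0)
  left <- n
  while (left > 0) {
    s <- sample(vals, 1, prob = probs)
    if (s > left) s <- left
    sizes <- c(sizes, s)
    left <- left - s
  }
  sort(sizes, decreasing = TRUE)
}

specimen_register <- function(species, n_specimens, prefix, guild) {
  n <- nrow(species)
  tibble(
    specimen_id = sprintf("%s%04d", prefix, seq_len(n * n_specimens)),
    species_id = rep(species$species_id, each = n_specimens),
    morphospecies = rep(species$morphospecies, each = n_specimens),
    guild = guild
  )
}

# Random coalescent topology with node heights rank-rescaled into [lo, hi].
scaled_coalescent <- function(n, lo, hi, tip_labels) {
  if (n == 1) abort("need >= 2 tips", class = "cryptwebs_config_error")
  tr <- ape::rcoal(n, tip.label = tip_labels)
  rescale_node_heights(tr, lo, hi)
}

rescale_node_heights <- function(tr, lo, hi) {
  ntip <- ape::Ntip(tr)
  bt <- ape::branching.times(tr)
  k <- length(bt)
  new_h <- if (k == 1) setNames(hi, names(bt)) else
    lo + (rank(bt) - 1) / (k - 1) * (hi - lo)
  h <- c(rep(0, ntip), new_h[as.character((ntip + 1):(ntip + tr$Nnode))])
  names(h) <- NULL
  tr$edge.length <- h[tr$edge[, 1]] - h[tr$edge[, 2]]
  tr
}

# Replace tips of `tree` by subtrees (ultrametric, shallower than the tip's
# stem). `subtrees` is a named list keyed by tip label: either a character
# scalar (rename the tip) or a phylo object.
graft_clades <- function(tree, subtrees) {
  nwk <- ape::write.tree(tree)
  for (lab in names(subtrees)) {
    sub <- subtrees[[lab]]
    tip_idx <- match(lab, tree$tip.label)
    el <- tree$edge.length[tree$edge[, 2] == tip_idx]
    pattern <- paste0(lab, ":[0-9eE.+-]+")
    repl <- if (is.character(sub)) {
      paste0(sub, ":", format(el, digits = 15, scientific = FALSE))
    } else {
      depth <- tree_height(sub)
      stem <- el - depth
      if (stem <= 0) abort("subtree deeper than its stem", class = "cryptwebs_config_error")
      paste0(sub(";$", "", ape::write.tree(sub)), ":",
             format(stem, digits = 15, scientific = FALSE))
    }
    nwk <- sub(pattern, repl, nwk)
  }
  ape::read.tree(text = nwk)
}

#' Simulate marker alignments for a community
#'
#' Builds specimen-level ultrametric trees by grafting shallow coalescent
#' subtrees (depth `intra_depth`) onto each species tip, then evolves
#' sequences along them under a two-rate (transition/transversion)
#' substitution process, so the K2P estimator matches the generating model.
#' A slow marker (1/10 rate by default) emulates the lower resolution of a
#' conserved nuclear gene.
#'
#' @param community A `cw_community`.
#' @param markers Markers to simulate, subset of `c("COI", "28S")`.
#' @return A list of class `cw_alignments` with `$sequences` (tibble:
#'   `specimen_id`, `morphospecies`, `species_id`, `guild`, `marker`,
#'   `sequence`) and `$trees` (specimen-level ultrametric phylo per guild).
#' @export
simulate_alignments <- function(community, markers = c("COI", "28S")) {
  stopifnot(inherits(community, "cw_community"))
  cfg <- community$cfg
  set.seed(cfg$seed + 1L)
  seqs <- list()
  trees <- list()
  for (g in c("host", "parasitoid")) {
    sp_tree <- community[[paste0(g, "_tree")]]
    reg <- community$specimens |> filter(.data$guild == g)
    subtrees <- map(setNames(unique(reg$species_id), unique(reg$species_id)),
                    function(sp) {
                      ids <- reg$specimen_id[reg$species_id == sp]
                      # heterogeneous intraspecific depths: most species carry
                      # little variation, a few approach the stated ceiling
                      u <- runif(1, 0.05, 1)
                      if (length(ids) == 1) ids else
                        scaled_coalescent(length(ids), 0.25 * u * cfg$intra_depth,
                                          u * cfg$intra_depth, ids)
                    })
    spec_tree <- graft_clades(sp_tree, subtrees)
    trees[[g]] <- spec_tree
    rates <- c(COI = cfg$rate_coi, `28S` = cfg$rate_28s)
    for (mk in markers) {
      seqs[[paste(g, mk)]] <- reg |>
        left_join(evolve_sequences(spec_tree, cfg$seq_length, cfg$kappa, rates[[mk]]),
                  by = "specimen_id") |>
        mutate(marker = mk) |>
        select("specimen_id", "morphospecies", "species_id", "guild",
               "marker", "sequence")
    }
  }
  structure(list(sequences = bind_rows(seqs), trees = trees),
            class = "cw_alignments")
}

# Two-rate substitution process (K80 rate matrix) along a tree.
evolve_sequences <- function(tree, l, kappa, rate) {
  tr <- tree
  tr$edge.length <- tr$edge.length * rate
  sim <- phangorn::simSeq(tr, l = l, Q = c(1, kappa, 1, 1, kappa, 1),
                          bf = rep(0.25, 4), type = "DNA")
  chars <- toupper(as.character(sim))
  tibble(specimen_id = rownames(chars),
         sequence = apply(chars, 1, paste, collapse = ""))
}

#' Simulate rearing records for a community
#'
#' Assigns each molecular parasitoid species its true host set (one host
#' with probability `specialist_fraction`, otherwise two or three), with
#' the configured superhosts drawing disproportionally many parasitoids;
#' realizes each host-parasitoid link as one or more rearing records at
#' random sites with negative-binomial counts; and distributes each
#' species' sequenced specimens round-robin over its records so molecular
#' taxonomy maps can apportion split morphospecies.
#'
#' @param community A `cw_community`.
#' @return A rearing-record tibble in the [read_rearing_table()] schema,
#'   with attribute `true_links` (the generating host-parasitoid pairs).
#' @export
simulate_rearing <- function(community) {
  stopifnot(inherits(community, "cw_community"))
  cfg <- community$cfg
  set.seed(cfg$seed + 2L)
  provinces <- c("Yunnan", "Fujian", "Guangdong", "Shaanxi", "Hainan",
                 "Sichuan", "Guangxi", "Zhejiang")[seq_len(cfg$n_provinces)]
  site_prov <- c(provinces, sample(provinces, max(0, cfg$n_sites - cfg$n_provinces),
                                   replace = TRUE))[seq_len(cfg$n_sites)]
  sites <- sprintf("site%02d", seq_len(cfg$n_sites))

  hosts <- community$host_species$species_id
  paras <- community$parasitoid_species$species_id
  super <- sample(hosts, min(cfg$superhost_count, length(hosts)))
  w <- ifelse(hosts %in% super, cfg$superhost_weight, 1)
  links <- map(paras, function(p) {
    k <- if (runif(1) < cfg$specialist_fraction) 1L else sample(2:3, 1)
    tibble(parasitoid = p, host = sample(hosts, min(k, length(hosts)), prob = w))
  }) |> bind_rows()

  recs <- pmap(links, function(parasitoid, host) {
    n_rec <- 1L + rpois(1, 0.7)
    tibble(host_sp = host, para_sp = parasitoid,
           site = sample(sites, n_rec, replace = TRUE),
           count = rnbinom(n_rec, mu = cfg$count_mu, size = cfg$count_size) + 1L)
  }) |> bind_rows()

  lut_h <- setNames(community$host_species$morphospecies, hosts)
  lut_p <- setNames(community$parasitoid_species$morphospecies, paras)
  records <- tibble(
    sample_id = sprintf("RU%04d", seq_len(nrow(recs))),
    site_id = recs$site,
    province = site_prov[match(recs$site, sites)],
    host_mor = unname(lut_h[recs$host_sp]),
    parasitoid_mor = unname(lut_p[recs$para_sp]),
    count = as.integer(recs$count),
    host_specimens = distribute_specimens(recs$host_sp, community$specimens, "host"),
    parasitoid_specimens = distribute_specimens(recs$para_sp, community$specimens,
                                                "parasitoid")
  )
  attr(records, "true_links") <- links
  records
}

# Round-robin allocation of each species' specimens over its records.
distribute_specimens <- function(rec_species, register, g) {
  reg <- register[register$guild == g, ]
  out <- rep(list(character(0)), length(rec_species))
  for (sp in unique(rec_species)) {
    rec_idx <- which(rec_species == sp)
    ids <- reg$specimen_id[reg$species_id == sp]
    if (length(ids) == 0) next
    slots <- rep_len(rec_idx, max(length(ids), 0))
    for (k in seq_along(ids)) {
      out[[slots[k]]] <- c(out[[slots[k]]], ids[k])
    }
  }
  out
}

#' True taxonomy maps of a synthetic community
#'
#' The generating truth in the format consumed by [build_web()]: each
#' sequenced specimen mapped to its molecular species.
#'
#' @param community A `cw_community`.
#' @return List with elements `host` and `parasitoid`, each a tibble
#'   (`specimen_id`, `morphospecies`, `taxon`).
#' @export
true_taxonomy_maps <- function(community) {
  reg <- community$specimens
  mk <- function(g) {
    reg |> filter(.data$guild == g) |>
      transmute(specimen_id = .data$specimen_id,
                morphospecies = .data$morphospecies,
                taxon = .data$species_id)
  }
  list(host = mk("host"), parasitoid = mk("parasitoid"))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_community()],
#' [simulate_alignments()] and [simulate_rearing()].
#'
#' @param cfg A [sim_config()].
#' @param alignments Simulate sequences too (default `TRUE`; the rearing
#'   web alone does not need them).
#' @return List of class `cw_study` with `community`, `records`,
#'   `alignments` (or `NULL`) and `truth` (taxonomy maps).
#' @export
simulate_study <- function(cfg, alignments = TRUE) {
  community <- simulate_community(cfg)
  structure(list(
    community = community,
    records = simulate_rearing(community),
    alignments = if (alignments) simulate_alignments(community) else NULL,
    truth = true_taxonomy_maps(community)
  ), class = "cw_study")
}
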