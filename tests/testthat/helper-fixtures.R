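# Fixtures built in code: small record sets, distance matrices, trees and
# matrices reused across the suite.

toy_records <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    site_id = c("A", "A", "B"),
    province = c("Yunnan", "Yunnan", "Fujian"),
    host_mor = c("h1", "h1", "h2"),
    parasitoid_mor = c("p1", "p2", "p2"),
    count = c(5L, 3L, 2L),
    host_specimens = list(character(0), character(0), character(0)),
    parasitoid_specimens = list(character(0), character(0), character(0))
  )
}

write_toy_rearing_tsv <- function(path, counts = c(12, 1, 40),
                                  provinces = c("Yunnan", "Yunnan", "Fujian")) {
  writeLines(c(
    "sample_id\tsite_id\tprovince\thost_mor\tparasitoid_mor\tcount\thost_specimens\tparasitoid_specimens",
    sprintf("s%d\tA\t%s\th%d\tp%d\t%s\tHS%d\tPS%d",
            1:3, provinces, 1:3, 1:3, counts, 1:3, 1:3)
  ), path)
  path
}

# distance matrix with two clean groups: intra constant, inter constant
two_group_distance <- function(n1 = 3, n2 = 3, intra = 0.008, inter = 0.12) {
  n <- n1 + n2
  ids <- sprintf("sp%02d", seq_len(n))
  d <- matrix(inter, n, n, dimnames = list(ids, ids))
  d[seq_len(n1), seq_len(n1)] <- intra
  d[(n1 + 1):n, (n1 + 1):n] <- intra
  diag(d) <- 0
  d
}

# ultrametric tree with k well-separated clusters of n_each tips: cluster
# depths `depth` (recycled over clusters), joined by deep stems at `sep`
clustered_tree <- function(k = 3, n_each = 4, depth = c(0.02, 0.05, 0.08),
                           sep = 1.5, seed = 1) {
  set.seed(seed)
  depth <- rep_len(depth, k)
  subs <- lapply(seq_len(k), function(i) {
    tr <- ape::rcoal(n_each, tip.label = sprintf("c%d_t%d", i, seq_len(n_each)))
    tr$edge.length <- tr$edge.length * depth[i] / max(ape::branching.times(tr))
    tr
  })
  # join clusters on a deep backbone with splits rank-spread in [sep/2, sep]
  backbone <- ape::rcoal(k, tip.label = sprintf("T%03d", seq_len(k)))
  bt <- ape::branching.times(backbone)
  nh <- if (length(bt) == 1) setNames(sep, names(bt)) else
    sep / 2 + (rank(bt) - 1) / (length(bt) - 1) * sep / 2
  hh <- c(rep(0, k), unname(nh[as.character((k + 1):(k + backbone$Nnode))]))
  backbone$edge.length <- hh[backbone$edge[, 1]] - hh[backbone$edge[, 2]]
  nwk <- ape::write.tree(backbone)
  for (i in seq_len(k)) {
    tip_idx <- match(sprintf("T%03d", i), backbone$tip.label)
    el <- backbone$edge.length[backbone$edge[, 2] == tip_idx]
    sub_nwk <- sub(";$", "", ape::write.tree(subs[[i]]))
    stem <- el - depth[i]
    nwk <- sub(paste0("T", sprintf("%03d", i), ":[0-9eE.+-]+"),
               paste0(sub_nwk, ":", format(stem, digits = 15, scientific = FALSE)),
               nwk)
  }
  ape::read.tree(text = nwk)
}

small_sim_config <- function(seed = 42, ...) {
  cryptwebs::sim_config(
    seed = seed,
    n_host_species = 10, n_parasitoid_species = 12,
    host_complex_sizes = c(2, 2, 1, 1, 1, 1, 1, 1),
    parasitoid_complex_sizes = c(3, 2, 2, 1, 1, 1, 1, 1),
    n_sites = 6, n_provinces = 3,
    ...
  )
}

# independent oracle: all compositions of n into k non-negative parts
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (v in 0:n) {
    rest <- compositions_of(n - v, k - 1)
    out[[length(out) + 1L]] <- cbind(v, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}
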