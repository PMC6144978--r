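test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- small_sim_config(101)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_equal(s1$records, s2$records, ignore_attr = TRUE)
  expect_equal(s1$alignments$sequences, s2$alignments$sequences)
  expect_equal(ape::write.tree(s1$alignments$trees$host),
               ape::write.tree(s2$alignments$trees$host))
  # a different seed changes the realization
  s3 <- simulate_study(small_sim_config(102))
  expect_false(identical(s1$records$count, s3$records$count))
})

test_that("explicit complex sizes control the morphospecies count", {
  cfg <- sim_config(seed = 1, n_host_species = 10, n_parasitoid_species = 10,
                    host_complex_sizes = c(6, 4),
                    parasitoid_complex_sizes = c(5, 3, 2))
  com <- simulate_community(cfg)
  expect_equal(length(unique(com$host_species$morphospecies)), 2)
  expect_equal(length(unique(com$parasitoid_species$morphospecies)), 3)
  expect_equal(nrow(com$host_species), 10)
  # infeasible sizes are rejected
  expect_error(sim_config(seed = 1, n_host_species = 10,
                          host_complex_sizes = c(6, 5)),
               class = "cryptwebs_config_error")
})

test_that("all-singleton complexes make morphospecies equal molecular species", {
  cfg <- sim_config(seed = 5, n_host_species = 6, n_parasitoid_species = 6,
                    host_complex_sizes = rep(1, 6),
                    parasitoid_complex_sizes = rep(1, 6),
                    n_sites = 4, n_provinces = 2)
  com <- simulate_community(cfg)
  expect_equal(com$host_species$species_id, com$host_species$morphospecies)
})

test_that("species-tree divergences respect the configured band", {
  cfg <- small_sim_config(11)
  com <- simulate_community(cfg)
  for (tr in list(com$host_tree, com$parasitoid_tree)) {
    expect_setequal(tr$tip.label,
                    if (identical(tr, com$host_tree)) com$host_species$species_id
                    else com$parasitoid_species$species_id)
    d <- ape::cophenetic.phylo(tr)
    dd <- d[upper.tri(d)]
    expect_gte(min(dd), 2 * cfg$split_depth_min - 1e-9)
    expect_lte(max(dd), 2 * cfg$split_depth_max + 1e-9)
  }
})

test_that("a zero substitution rate yields identical sequences", {
  cfg <- small_sim_config(3, rate_coi = 0)
  com <- simulate_community(cfg)
  al <- simulate_alignments(com, markers = "COI")
  host_seqs <- al$sequences |> dplyr::filter(guild == "host")
  expect_equal(length(unique(host_seqs$sequence)), 1)
})

test_that("realized divergences separate intra from inter at defaults", {
  cfg <- small_sim_config(17)
  com <- simulate_community(cfg)
  al <- simulate_alignments(com, markers = "COI")
  seqs <- al$sequences |> dplyr::filter(guild == "parasitoid")
  d <- k2p_matrix(seqs)
  sp <- seqs$species_id[match(rownames(d), seqs$specimen_id)]
  same <- outer(sp, sp, "==") & upper.tri(d)
  diff <- (!outer(sp, sp, "==")) & upper.tri(d)
  expect_gte(mean(d[same] <= cfg$intra_div_max), 0.99)
  expect_gte(mean(d[diff] >= cfg$inter_div_min), 0.99)
})

test_that("the slow marker resolves fewer entities than the fast one", {
  cfg <- small_sim_config(23)
  com <- simulate_community(cfg)
  al <- simulate_alignments(com)
  seqs <- al$sequences |> dplyr::filter(guild == "parasitoid")
  ents <- sapply(c("COI", "28S"), function(mk) {
    suppressWarnings(
      n_entities(abgd_partition(k2p_matrix(seqs[seqs$marker == mk, ]))$stable))
  })
  expect_lt(ents[["28S"]], ents[["COI"]])
})

test_that("pure specialists give a star-forest web with RR = 1 everywhere", {
  cfg <- small_sim_config(31, specialist_fraction = 1)
  com <- simulate_community(cfg)
  rec <- simulate_rearing(com)
  maps <- true_taxonomy_maps(com)
  ws <- build_webset(rec, maps$host, maps$parasitoid)
  M <- ws[["MOL-MOL"]]
  expect_true(all(colSums(unclass(M) > 0) == 1))
  idx <- species_indices(M, "parasitoid")
  expect_true(all(idx$RR == 1))
  # m equals the summed counts of the molecularly resolvable records
  usable <- cryptwebs:::resolvable_records(rec, maps$host, maps$parasitoid)
  expect_equal(grand_total(M), sum(usable$count))
})

test_that("morphospecies merging lowers specialization metrics directionally", {
  cfg <- small_sim_config(47)
  com <- simulate_community(cfg)
  rec <- simulate_rearing(com)
  maps <- true_taxonomy_maps(com)
  ws <- build_webset(rec, maps$host, maps$parasitoid)
  expect_gte(connectance(ws[["MOR-MOR"]]), connectance(ws[["MOL-MOL"]]))
  expect_gte(compartments(ws[["MOL-MOL"]]), compartments(ws[["MOR-MOR"]]))
})
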