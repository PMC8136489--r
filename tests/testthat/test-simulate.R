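test_that("generators are byte-deterministic in the master seed", {
  sc <- synthetic_scenario(seed = 77, n_taxa = 5, n_sites = 15)
  a1 <- simulate_codon_alignment(sc)
  a2 <- simulate_codon_alignment(sc)
  expect_identical(a1$aln$codons, a2$aln$codons)
  expect_identical(a1$true_class, a2$true_class)
  expect_identical(ape::write.tree(a1$tree), ape::write.tree(a2$tree))
  f1 <- make_cavity_fixture(sc); f2 <- make_cavity_fixture(sc)
  expect_identical(f1$structure$atoms, f2$structure$atoms)
  t1 <- make_affinity_tables(sc); t2 <- make_affinity_tables(sc)
  expect_identical(t1$wt$delta_g, t2$wt$delta_g)
  e1 <- make_model_ensemble(sc); e2 <- make_model_ensemble(sc)
  expect_identical(e1$models[[3]]$atoms, e2$models[[3]]$atoms)

  b <- simulate_codon_alignment(synthetic_scenario(seed = 78, n_taxa = 5,
                                                   n_sites = 15))
  expect_false(identical(a1$aln$codons, b$aln$codons))
})

test_that("omega 0 forbids amino-acid change; zero branches forbid any change", {
  sc0 <- synthetic_scenario(seed = 9, n_taxa = 8, n_sites = 40,
                            mixture = list(model = "single", omega = 0))
  sim0 <- simulate_codon_alignment(sc0)
  prot <- translate_alignment(sim0$aln)
  expect_true(all(apply(prot$residues, 2, function(col) length(unique(col)) == 1)))

  sc_t0 <- synthetic_scenario(seed = 9, n_taxa = 8, n_sites = 40,
                              branch_mean = 1e-12)
  sim_t0 <- simulate_codon_alignment(sc_t0)
  expect_true(all(apply(sim_t0$aln$codons, 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("neutral simulation gives counting dN/dS near 1 at scale", {
  # two taxa joined by a long branch; pooled SLAC counts estimate omega
  sc <- synthetic_scenario(seed = 23, n_taxa = 2, n_sites = 1500,
                           branch_mean = 0.4,
                           mixture = list(model = "single", omega = 1))
  sim <- simulate_codon_alignment(sc)
  res <- slac_site_scan(sim$aln, sim$tree)
  dnds_pooled <- (sum(res$n_nonsyn) / sum(res$en)) /
    (sum(res$n_syn) / sum(res$es))
  expect_gt(dnds_pooled, 0.8)
  expect_lt(dnds_pooled, 1.25)
})

test_that("every generated artifact passes its consumer's validators", {
  sc <- synthetic_scenario(seed = 41, n_taxa = 6, n_sites = 30)
  sim <- simulate_codon_alignment(sc)
  # cleaning a simulated alignment is a no-op: no stops, no ambiguity
  cl <- clean_codon_alignment(sim$aln)
  expect_equal(cl$codons, sim$aln$codons)
  expect_no_error(translate_alignment(sim$aln))
  expect_no_error(site_log_likelihood(
    sim$aln, sim$tree, codon_model_params(2, 0.5, unname(build_f3x4(sim$aln)))))
  fx <- make_cavity_fixture(sc)
  expect_no_error(cavity_volume(fx$structure))
  en <- make_model_ensemble(sc)
  expect_no_error(superpose_ensemble(
    lapply(en$models[1:3], lipidshift:::calpha_coords)))
  at <- make_affinity_tables(sc)
  expect_no_error(swap_feasibility(at$wt, at$exo_ligand))
})

test_that("ensemble truth localises divergence at the planted loop", {
  sc <- synthetic_scenario(seed = 15, ensemble = list(
    n_models = 8, n_residues = 50, loop = 20:27, amplitude = 3, rigid = TRUE))
  en <- make_model_ensemble(sc)
  sup <- superpose_ensemble(lapply(en$models, lipidshift:::calpha_coords))
  prof <- per_residue_divergence(sup)
  top <- order(-prof$divergence)[seq_along(en$loop)]
  expect_true(all(sort(top) == en$loop))

  # rigid-motion-only ensembles superpose to zero divergence
  sc0 <- synthetic_scenario(seed = 15, ensemble = list(
    n_models = 6, n_residues = 50, loop = 20:27, amplitude = 0, rigid = TRUE))
  en0 <- make_model_ensemble(sc0)
  sup0 <- superpose_ensemble(lapply(en0$models, lipidshift:::calpha_coords))
  expect_lt(max(per_residue_divergence(sup0)$divergence), 1e-8)
})

test_that("affinity scenarios plant their swap truth exactly", {
  sc <- synthetic_scenario(seed = 3, affinity = list(
    n_endo = 4, endo_dg_mean = -7, endo_dg_sd = 1, gap_factor = 10,
    mut_endo_factor = 1, mut_exo_factor = 1, n_extra_poses = 1))
  at <- make_affinity_tables(sc)
  expect_equal(at$truth$fold_wt, 10, tolerance = 1e-9)
  expect_equal(at$truth$verdict_wt, "swap")

  tight_endo <- synthetic_scenario(seed = 3, affinity = list(
    n_endo = 4, endo_dg_mean = -7, endo_dg_sd = 1, gap_factor = 3,
    mut_endo_factor = 0.05, mut_exo_factor = 1, n_extra_poses = 0))
  at2 <- make_affinity_tables(tight_endo)
  expect_equal(at2$truth$verdict_wt, "swap")
  expect_equal(at2$truth$verdict_mut, "no_swap")
})
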