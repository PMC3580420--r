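test_that("generators are deterministic under a fixed seed", {
  a <- simulate_network(n_genes = 80, seed = 4,
                        modules = list(list(size = 15, within_prob = 0.4)))
  b <- simulate_network(n_genes = 80, seed = 4,
                        modules = list(list(size = 15, within_prob = 0.4)))
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth$modules, b$truth$modules)

  oa <- simulate_omics(n_genes = 50, seed = 4)
  ob <- simulate_omics(n_genes = 50, seed = 4)
  expect_identical(oa$omics, ob$omics)

  va <- simulate_variants(n_sites = 100, seed = 4)
  vb <- simulate_variants(n_sites = 100, seed = 4)
  expect_identical(va$variants, vb$variants)
})

test_that("a within_prob = 1 module is a clique of C(size, 2) edges", {
  sim <- simulate_network(n_genes = 60, background_edge_prob = 0,
                          modules = list(list(size = 10, within_prob = 1)),
                          seed = 2)
  mod <- gene_set("m", sim$truth$modules$module1)
  expect_equal(count_direct_links(sim$network, mod, mod), choose(10, 2))
  expect_equal(n_edges(sim$network), choose(10, 2))
})

test_that("module sizes are validated", {
  expect_error(simulate_network(n_genes = 10,
                                modules = list(list(size = 20,
                                                    within_prob = 0.5))),
               "exceed")
})

test_that("generated data satisfy their type invariants", {
  sim <- simulate_network(n_genes = 100, seed = 9,
                          modules = list(list(size = 20, within_prob = 0.3)))
  expect_equal(sum(degrees(sim$network)), 2L * n_edges(sim$network))
  expect_true(all(sim$truth$modules$module1 %in% sim$network$nodes))

  sv <- simulate_variants(n_sites = 500, seed = 9)
  v <- sv$variants
  expect_true(all(v$dna_alt_depth <= v$dna_depth))
  expect_true(all(v$rna_alt_depth <= v$rna_depth))
  expect_true(all(v$dna_depth >= 0 & v$rna_depth >= 0))
  expect_true(all(sv$truth$ai_genes %in% v$gene))

  so <- simulate_omics(n_genes = 100, seed = 9)
  expect_true(all(so$omics$copy_number >= 0))
  expect_true(all(so$omics$rpkm >= 0))
  expect_equal(nrow(so$omics), 300L)
})

test_that("truth tables round-trip through JSON", {
  sim <- simulate_network(n_genes = 50, seed = 3,
                          modules = list(list(size = 10, within_prob = 0.5)))
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$modules$module1, sim$truth$modules$module1)
  expect_equal(back$seed, sim$truth$seed)
  expect_equal(back$params$n_genes, sim$truth$params$n_genes)
})

test_that("cn_effect = 0 gives cross-line correlations centred on zero", {
  so <- simulate_omics(n_genes = 1000, cn_effect = 0, seed = 3)
  d <- attr(filter_cna_genes(so$omics), "details")
  rho <- d$rho_rpkm[!is.na(d$rho_rpkm)]
  expect_gt(length(rho), 300)
  expect_lt(abs(mean(rho)), 0.1)
})

test_that("noiseless full-attenuation dosage gives perfect correlations", {
  so <- simulate_omics(n_genes = 200, cn_effect = 1, noise_sd = 0,
                       protein_attenuation = 1, protein_noise_sd = 0,
                       responsive_frac = 1, seed = 11)
  d <- attr(filter_cna_genes(so$omics, rpkm_min = 0), "details")
  ok <- !is.na(d$rho_rpkm)
  expect_true(all(d$rho_rpkm[ok] == 1))
  expect_true(all(d$rho_protein[ok & !is.na(d$rho_protein)] == 1))
})

test_that("default omics generator hits the calibrated mRNA-protein band", {
  so <- simulate_omics(seed = 5)
  rho <- vapply(unique(so$omics$line), function(l)
    mrna_protein_correlation(so$omics, l), 0)
  expect_true(all(rho >= 0.55 & rho <= 0.61))
})

test_that("AI planting controls the caller's positives", {
  empty_seeds <- 0
  for (s in 1:10) {
    sv <- simulate_variants(n_sites = 500, ai_fraction = 0, seed = s)
    called <- suppressWarnings(call_allelic_imbalance(sv$variants))
    if (length(called$genes) == 0) empty_seeds <- empty_seeds + 1
  }
  expect_gte(empty_seeds, 9)

  sv1 <- simulate_variants(n_sites = 500, ai_fraction = 1, depth_mean = 100,
                           seed = 1)
  called1 <- call_allelic_imbalance(sv1$variants)
  sens <- length(intersect(called1$genes, sv1$truth$ai_genes)) /
    length(sv1$truth$ai_genes)
  expect_gte(sens, 0.95)
})

test_that("copy-number presets encode the intended gain/loss balance", {
  states <- 0:8
  for (p in c("gain_heavy", "gain_moderate", "balanced")) {
    pr <- cn_profile_preset(p, states)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
  gh <- cn_profile_preset("gain_heavy", states)
  expect_equal(sum(gh[states > 2]), 0.27, tolerance = 1e-12)
  expect_equal(sum(gh[states < 2]), 0.02, tolerance = 1e-12)
  bal <- cn_profile_preset("balanced", states)
  expect_equal(sum(bal[states > 2]), sum(bal[states < 2]), tolerance = 1e-12)
})

test_that("simulate_bundle writes a coherent file bundle", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(seed = 3, dir = dir)
  expect_true(all(file.exists(unlist(b$paths))))
  net <- load_edge_list(b$paths$network)
  expect_equal(net$edges[c("from", "to")],
               b$network$edges[c("from", "to")])
  expect_equal(length(load_gmt(b$paths$fgs)), 3L)
  v <- read_variants(b$paths$variants)
  expect_equal(nrow(v), nrow(b$variants))
  tr <- read_truth(b$paths$truth)
  expect_equal(tr$drivers, b$truth$drivers)
  expect_true(all(b$truth$drivers %in% b$truth$module))
  expect_length(intersect(b$truth$fgs_module,
                          c(b$truth$snv_genes, b$truth$drivers)), 0)
})
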