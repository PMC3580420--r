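toy_omics <- read_omics(fixture_path("toy_omics.tsv"))

test_that("Kruskal-Wallis association matches the hand computation", {
  # two copy-number classes of 3 genes: responses {1,2,3} vs {10,20,30};
  # ranks 1..6 give H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  omics <- data.frame(gene = sprintf("g%d", 1:6), line = "L1",
                      copy_number = rep(c(2, 4), each = 3),
                      rpkm = c(1, 2, 3, 10, 20, 30), protein = NA)
  r <- cn_expression_association(omics, "L1")
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(r$p.value, pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis degenerate inputs behave", {
  omics <- data.frame(gene = sprintf("g%d", 1:6), line = "L1",
                      copy_number = rep(c(2, 4), each = 3),
                      rpkm = rep(5, 6), protein = NA)
  r <- cn_expression_association(omics, "L1")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  one_class <- data.frame(gene = sprintf("g%d", 1:4), line = "L1",
                          copy_number = 2, rpkm = 1:4, protein = NA)
  expect_error(cn_expression_association(one_class, "L1"), "classes")
})

test_that("Kruskal-Wallis p is roughly uniform when there is no CN effect", {
  set.seed(3)
  p <- replicate(60, {
    so <- simulate_omics(n_genes = 60, cn_effect = 0,
                         seed = sample.int(1e6, 1))
    cn_expression_association(so$omics, "line1")$p.value
  })
  expect_gt(mean(p < 0.1), 0.02)
  expect_lt(mean(p < 0.1), 0.25)
  expect_gt(mean(p > 0.5), 0.3)
})

test_that("mrna_protein_correlation is a gene-wise Spearman rho", {
  omics <- data.frame(gene = sprintf("g%d", 1:5), line = "L1",
                      copy_number = 2, rpkm = c(1, 2, 3, 4, 5),
                      protein = c(2, 4, 9, 16, 30))
  expect_equal(mrna_protein_correlation(omics, "L1"), 1)
  omics$protein <- rev(omics$protein)
  expect_equal(mrna_protein_correlation(omics, "L1"), -1)
  expect_error(mrna_protein_correlation(omics[1:2, ], "L1"), ">= 3")
})

test_that("per-gene cross-line correlation handles monotone and tied CN", {
  omics <- data.frame(gene = "g", line = c("L1", "L2", "L3"),
                      copy_number = c(1, 2, 4), rpkm = c(5, 9, 20),
                      protein = NA)
  expect_equal(per_gene_cross_line_correlation(omics, "g"), 1)
  omics$rpkm <- c(20, 9, 5)
  expect_equal(per_gene_cross_line_correlation(omics, "g"), -1)
  omics$copy_number <- c(2, 2, 2)
  expect_true(is.na(per_gene_cross_line_correlation(omics, "g")))
  expect_error(per_gene_cross_line_correlation(omics[1:2, ], "g"), "3 lines")
})

test_that("permutation log-ratio control is flat on noise, rising on signal", {
  noise <- simulate_omics(n_genes = 300, cn_effect = 0, seed = 9)$omics
  curve0 <- permutation_log_ratio(noise, n_perm = 50, seed = 9)
  expect_true(all(abs(curve0$log_ratio) < 0.5))

  strong <- simulate_omics(n_genes = 300, cn_effect = 2, noise_sd = 0.2,
                           responsive_frac = 1, seed = 9)$omics
  curve1 <- permutation_log_ratio(strong, n_perm = 50, seed = 9)
  expect_gt(curve1$log_ratio[curve1$threshold == 0.8], 0.5)
  expect_gt(curve1$log_ratio[curve1$threshold == 0.9],
            curve1$log_ratio[curve1$threshold == 0.1])

  expect_error(permutation_log_ratio(noise, n_perm = 5), "n_perm")
  expect_error(permutation_log_ratio(noise[1:30, ], n_perm = 20), "50 genes")
})

test_that("filter_cna_genes reproduces the hand-evaluated fixture", {
  out <- filter_cna_genes(toy_omics)
  expect_setequal(out$genes, c("g01", "g02", "g06", "g09"))
  rep <- filter_report(out)
  expect_equal(rep$n_in, 9L)  # g04 has constant CN, never a candidate
  expect_equal(rep$n_out, 4L)
  d <- attr(out, "details")
  expect_equal(d$mean_rho[d$gene == "g01"], 1)
  expect_equal(d$mean_rho[d$gene == "g02"], 1)  # protein missing: rpkm only
  expect_equal(d$mean_rho[d$gene == "g03"], 0.75)  # (0.5 + 1)/2, dropped
  expect_false(d$keep[d$gene == "g05"])  # max rpkm below the floor
  # explicit candidate list including the constant-CN gene
  out2 <- filter_cna_genes(toy_omics, cna_genes = c("g01", "g04"))
  expect_equal(out2$genes, "g01")
  expect_error(filter_cna_genes(toy_omics, cna_genes = "nope"), "absent")
})

test_that("filter_cna_genes can ignore the protein term", {
  out <- filter_cna_genes(toy_omics, use_protein = FALSE)
  # g07 has rho_rpkm = -1, still dropped; g08 gains: rho_rpkm = 1
  expect_setequal(out$genes, c("g01", "g02", "g06", "g08", "g09"))
})

test_that("nea_context_filter keeps module members, drops the rest (seed 7)", {
  sim <- simulate_network(seed = 7)
  net <- sim$network
  mod <- sim$truth$modules$module1
  reference <- gene_set("snv", mod[1:15], class = "SNV")
  set.seed(7)
  outside <- sample(setdiff(net$nodes, mod), 10)
  cand <- gene_set("cand", c(mod[16:20], outside), class = "CNA")
  out <- nea_context_filter(net, cand, reference, seed = 70)
  expect_setequal(out$genes, mod[16:20])
  expect_equal(filter_report(out)$n_in, 15L)

  # an untestable (non-network) gene is dropped and counted
  cand2 <- gene_set("cand", c(mod[16], "NOT_IN_NET"), class = "CNA")
  out2 <- nea_context_filter(net, cand2, reference, seed = 70)
  expect_equal(filter_report(out2)$params$n_untestable, 1L)
  expect_false("NOT_IN_NET" %in% out2$genes)

  # infinite threshold empties the set
  out3 <- suppressMessages(
    nea_context_filter(net, cand, reference, z_threshold = Inf, seed = 70))
  expect_length(out3$genes, 0)
})

test_that("call_allelic_imbalance applies the het-DNA / hom-RNA definition", {
  v <- data.frame(chrom = "chr1", pos = 1:6 * 10, ref = "A", alt = "T",
                  gene = sprintf("g%d", 1:6),
                  dna_depth = c(40, 40, 40, 40, 10, 9),
                  dna_alt_depth = c(20, 20, 38, 20, 5, 4),
                  rna_depth = c(30, 30, 30, 30, 10, 30),
                  rna_alt_depth = c(30, 16, 30, 0, 10, 30),
                  damaging = FALSE, common_polymorphism = FALSE)
  out <- call_allelic_imbalance(v)
  # g1: het DNA + RNA AF 1.0 -> AI; g2: RNA AF 0.53 -> no
  # g3: DNA AF 0.95, not heterozygous -> no; g4: RNA AF 0 (other allele) -> AI
  # g5: depth 10 boundary kept; g6: DNA depth 9 below floor
  expect_setequal(out$genes, c("g1", "g4", "g5"))
  expect_equal(filter_report(out)$n_out, 3L)

  v$dna_depth[1] <- 0L; v$dna_alt_depth[1] <- 0L
  expect_warning(out2 <- call_allelic_imbalance(v), "zero-depth")
  expect_setequal(out2$genes, c("g4", "g5"))
})

test_that("filter_snvs reproduces the hand-evaluated fixture", {
  v <- read_variants(fixture_path("toy_variants.tsv"))
  out <- filter_snvs(v)
  expect_setequal(out$genes, paste0("gene", c("A", "B", "C", "D", "E")))
  rep <- filter_report(out)
  expect_equal(rep$n_in, 12L)
  expect_equal(rep$n_out, 6L)  # six surviving records across five genes
  out2 <- filter_snvs(v, require_damaging = FALSE)
  expect_true("geneF" %in% out2$genes)
})

test_that("build_ags assembles class sets plus union", {
  snv <- gene_set("SNV", c("a", "b", "c"), class = "SNV")
  cna <- gene_set("CNA", c("d", "e", "f"), class = "CNA")
  ai <- gene_set("AI", c("g", "h", "i"), class = "AI")
  out <- build_ags(snv, cna, ai)
  expect_length(out, 4)
  expect_length(out$union$genes, 9)

  overlapping <- build_ags(snv, gene_set("CNA", c("a", "d"), class = "CNA"))
  expect_length(overlapping$union$genes, 4)

  only_snv <- build_ags(snv = snv)
  expect_length(only_snv, 2)
  expect_setequal(only_snv$union$genes, snv$genes)
  expect_error(build_ags(), "empty")
})
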