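## ground-truth record shipped alongside every generated object
.truth <- function(type, ..., params, seed) {
  structure(c(list(type = type), list(...),
              list(params = params, seed = seed)),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table (%s), seed %s\n", x$type, x$seed))
  invisible(x)
}

#' Write / read a ground-truth record as JSON
#' @param truth a `truth_table`
#' @param path file path
#' @return `path` invisibly, or the reloaded `truth_table`
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "truth_table")
}

#' Simulate a gene network with planted modules
#'
#' An Erdos-Renyi background with one or more planted densely connected
#' modules: within a module every gene pair is linked with probability
#' `within_prob` instead of `background_edge_prob`. This emulates the
#' topology network enrichment assumes - functionally related genes (and
#' cancer genes in particular) cluster on well-connected sub-networks.
#'
#' Defaults: 500 genes, background density 0.01, one module of 40 genes at
#' within-module density 0.25.
#'
#' @param n_genes number of genes
#' @param background_edge_prob background edge probability
#' @param modules list; each element a list/vector with `size` and
#'   `within_prob`
#' @param seed integer seed (same seed, same edge set)
#' @param genes optional gene names (default `G0001`, ...)
#' @return list with `network` (a [gene_network]) and `truth` (a
#'   `truth_table` whose `modules` element holds the planted memberships)
#' @export
simulate_network <- function(n_genes = 500, background_edge_prob = 0.01,
                             modules = list(list(size = 40,
                                                 within_prob = 0.25)),
                             seed = 1L, genes = NULL) {
  stopifnot(background_edge_prob >= 0, background_edge_prob <= 1)
  sizes <- vapply(modules, function(m) as.integer(m[["size"]]), 0L)
  probs <- vapply(modules, function(m) as.numeric(m[["within_prob"]]), 0)
  stopifnot(all(probs >= 0), all(probs <= 1))
  if (sum(sizes) > n_genes)
    stop("module sizes exceed the number of genes")
  if (is.null(genes))
    genes <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  set.seed(seed)
  shuffled <- sample(genes)
  member <- list()
  offset <- 0
  for (i in seq_along(sizes)) {
    member[[paste0("module", i)]] <- sort(shuffled[offset + seq_len(sizes[i])])
    offset <- offset + sizes[i]
  }
  pair <- utils::combn(n_genes, 2)
  p <- rep(background_edge_prob, ncol(pair))
  for (i in seq_along(sizes)) {
    idx <- match(member[[i]], genes)
    inside <- (pair[1, ] %in% idx) & (pair[2, ] %in% idx)
    p[inside] <- probs[i]
  }
  hit <- stats::runif(ncol(pair)) < p
  net <- gene_network(
    data.frame(from = genes[pair[1, hit]], to = genes[pair[2, hit]],
               stringsAsFactors = FALSE),
    nodes = genes)
  truth <- .truth("network", modules = member,
                  params = list(n_genes = n_genes,
                                background_edge_prob = background_edge_prob,
                                module_sizes = sizes,
                                module_within_prob = probs),
                  seed = seed)
  list(network = net, truth = truth)
}

## default copy-number distribution: mostly diploid, gains and losses at
## comparable total probability, occasional high amplification
.default_cn_probs <- function(cn_states) {
  w <- c("0" = 0.05, "1" = 0.15, "2" = 0.55, "3" = 0.15, "4" = 0.05,
         "5" = 0.02, "6" = 0.015, "7" = 0.01, "8" = 0.005)
  p <- w[as.character(cn_states)]
  p[is.na(p)] <- 0.005
  p / sum(p)
}

#' Per-line copy-number presets emulating heavily rearranged genomes
#'
#' Named gain/loss genome fractions offered for realism (e.g. a line gaining
#' about a quarter of its genome while losing a few percent, or one with
#' balanced gain/loss). Returns a probability vector over `cn_states`.
#'
#' @param preset one of `"gain_heavy"` (27% gain / 2% loss),
#'   `"gain_moderate"` (25% / 2%), `"balanced"` (19% / 19%)
#' @param cn_states integer copy-number states
#' @return probability vector over `cn_states`
#' @export
cn_profile_preset <- function(preset = c("gain_heavy", "gain_moderate",
                                         "balanced"),
                              cn_states = 0:8) {
  preset <- match.arg(preset)
  frac <- switch(preset,
                 gain_heavy = c(gain = 0.27, loss = 0.02),
                 gain_moderate = c(gain = 0.25, loss = 0.02),
                 balanced = c(gain = 0.19, loss = 0.19))
  p <- numeric(length(cn_states))
  names(p) <- cn_states
  loss_states <- cn_states[cn_states < 2]
  gain_states <- cn_states[cn_states > 2]
  if (length(loss_states))
    p[as.character(loss_states)] <- frac["loss"] *
      rev(seq_along(loss_states)) / sum(seq_along(loss_states))
  if (length(gain_states))
    p[as.character(gain_states)] <- frac["gain"] *
      rev(seq_along(gain_states)) / sum(seq_along(gain_states))
  p["2"] <- 1 - sum(p)
  unname(p)
}

#' Simulate a multi-omics table with copy-number-driven expression
#'
#' For each gene and cell line a copy number is drawn from `cn_states`;
#' log expression is `baseline + cn_effect * log(CN / 2) + noise` for
#' copy-number-responsive genes (`baseline` alone otherwise), and log protein
#' intensity is `protein_attenuation * log expression + protein noise` - the
#' dosage signal propagates to protein but attenuated and noisier, so
#' protein-copy-number correlations are systematically weaker than
#' mRNA-copy-number correlations. Baseline RPKM is log-normal,
#' `exp(N(1.5, 1))`, so RPKM floors have something to bite on; copy number 0
#' is mapped to an effective 0.5 copies (residual transcription) before the
#' log.
#'
#' The default protein noise (`protein_noise_sd = 1.1`) is calibrated
#' analytically so that the default configuration lands the gene-wise
#' mRNA-protein Spearman correlation in the 0.55-0.61 band typical of
#' deep proteome/transcriptome comparisons (see the methods vignette for the
#' derivation).
#'
#' @param n_genes number of genes
#' @param lines number of cell lines (>= 3) or character names
#' @param cn_states integer copy-number states to draw from
#' @param cn_probs probabilities over `cn_states`; default mostly diploid
#'   with symmetric gains/losses (see [cn_profile_preset()] for alternatives)
#' @param cn_effect log-scale dosage slope for responsive genes (1 =
#'   expression proportional to copy number)
#' @param responsive_frac fraction of genes that respond to dosage (used
#'   when `responsive_genes` is NULL)
#' @param responsive_genes explicit responsive gene names (overrides
#'   `responsive_frac`)
#' @param protein_attenuation multiplier on the expression signal in protein
#'   (in `[0, 1]`)
#' @param noise_sd expression log-noise sd
#' @param protein_noise_sd protein log-noise sd
#' @param protein_missing_frac fraction of protein values set missing
#' @param cn_overrides named list: gene -> integer copy-number vector (one
#'   per line), for planting specific profiles
#' @param genes optional gene names
#' @param seed integer seed
#' @return list with `omics` (long data.frame `gene`, `line`, `copy_number`,
#'   `rpkm`, `protein`) and `truth` (responsive genes and per-gene effect)
#' @export
simulate_omics <- function(n_genes = 2000, lines = 3, cn_states = 0:8,
                           cn_probs = NULL, cn_effect = 1,
                           responsive_frac = 0.5, responsive_genes = NULL,
                           protein_attenuation = 0.7, noise_sd = 0.5,
                           protein_noise_sd = 1.1,
                           protein_missing_frac = 0,
                           cn_overrides = NULL, genes = NULL, seed = 1L) {
  if (is.numeric(lines)) lines <- sprintf("line%d", seq_len(lines))
  if (length(lines) < 3) stop("need >= 3 cell lines")
  stopifnot(cn_effect >= 0, protein_attenuation >= 0,
            protein_attenuation <= 1, noise_sd >= 0, protein_noise_sd >= 0,
            protein_missing_frac >= 0, protein_missing_frac <= 1)
  if (is.null(cn_probs)) cn_probs <- .default_cn_probs(cn_states)
  stopifnot(length(cn_probs) == length(cn_states))
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  set.seed(seed)
  L <- length(lines)
  if (is.null(responsive_genes)) {
    n_resp <- round(responsive_frac * n_genes)
    responsive_genes <- sort(sample(genes, n_resp))
  } else {
    stopifnot(all(responsive_genes %in% genes))
    responsive_genes <- sort(unique(responsive_genes))
  }
  responsive <- genes %in% responsive_genes
  cn <- matrix(sample(cn_states, n_genes * L, replace = TRUE,
                      prob = cn_probs),
               n_genes, L, dimnames = list(genes, lines))
  if (!is.null(cn_overrides)) {
    for (g in names(cn_overrides)) {
      stopifnot(g %in% genes, length(cn_overrides[[g]]) == L)
      cn[g, ] <- cn_overrides[[g]]
    }
  }
  baseline <- stats::rnorm(n_genes, 1.5, 1)
  dosage <- log(pmax(cn, 0.5) / 2)
  log_expr <- baseline + (responsive * cn_effect) * dosage +
    matrix(stats::rnorm(n_genes * L, 0, noise_sd), n_genes, L)
  log_prot <- protein_attenuation * log_expr +
    matrix(stats::rnorm(n_genes * L, 0, protein_noise_sd), n_genes, L)
  protein <- exp(log_prot)
  if (protein_missing_frac > 0)
    protein[stats::runif(length(protein)) < protein_missing_frac] <- NA
  omics <- data.frame(
    gene = rep(genes, times = L),
    line = rep(lines, each = n_genes),
    copy_number = as.vector(cn),
    rpkm = as.vector(exp(log_expr)),
    protein = as.vector(protein),
    stringsAsFactors = FALSE)
  truth <- .truth("omics",
                  responsive_genes = responsive_genes,
                  cn_effect_per_gene = stats::setNames(
                    as.numeric(responsive) * cn_effect, genes),
                  params = list(n_genes = n_genes, lines = lines,
                                cn_states = cn_states,
                                cn_effect = cn_effect,
                                protein_attenuation = protein_attenuation,
                                noise_sd = noise_sd,
                                protein_noise_sd = protein_noise_sd),
                  seed = seed)
  list(omics = omics, truth = truth)
}

#' Simulate SNVs with DNA and RNA allele depths
#'
#' All sites are heterozygous at the DNA level (alt depth binomial with
#' allele fraction 0.5). Sites in planted allelically imbalanced genes
#' express essentially one allele in RNA (binomial allele fraction 0.98 or
#' 0.02, direction per gene); balanced genes stay at 0.5. Damaging and
#' common-polymorphism flags are assigned at configurable rates, with
#' `damaging_genes` guaranteed at least one damaging, non-polymorphic site
#' each.
#'
#' @param n_sites number of variant sites
#' @param genes character vector of genes to place sites on (default 200
#'   synthetic symbols)
#' @param ai_fraction fraction of genes planted as allelically imbalanced
#'   (ignored when `ai_genes` given)
#' @param ai_genes explicit AI gene names
#' @param damaging_genes genes guaranteed a damaging non-polymorphic site
#' @param depth_mean mean sequencing depth (Poisson) for DNA and RNA
#' @param damaging_rate background rate of the damaging flag
#' @param polymorphism_rate background rate of the common-polymorphism flag
#' @param seed integer seed
#' @return list with `variants` (data.frame, see [read_variants()]) and
#'   `truth` (`ai_genes`, per-site assignments)
#' @export
simulate_variants <- function(n_sites = 2000, genes = NULL,
                              ai_fraction = 0.1, ai_genes = NULL,
                              damaging_genes = character(0),
                              depth_mean = 50, damaging_rate = 0.3,
                              polymorphism_rate = 0.2, seed = 1L) {
  stopifnot(ai_fraction >= 0, ai_fraction <= 1, depth_mean > 0)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(200))
  set.seed(seed)
  if (is.null(ai_genes)) {
    n_ai <- round(ai_fraction * length(genes))
    ai_genes <- sort(sample(genes, n_ai))
  } else {
    stopifnot(all(ai_genes %in% genes))
    ai_genes <- sort(unique(ai_genes))
  }
  gene <- sample(genes, n_sites, replace = TRUE)
  # planted genes are guaranteed representation: a planted alteration that is
  # never sequenced is not a usable ground truth
  damaging_genes <- intersect(damaging_genes, genes)
  planted <- c(damaging_genes, ai_genes)
  if (length(planted) > n_sites)
    stop("more planted (damaging + AI) genes than sites")
  gene[seq_along(planted)] <- planted
  dna_depth <- stats::rpois(n_sites, depth_mean)
  rna_depth <- stats::rpois(n_sites, depth_mean)
  dna_alt <- stats::rbinom(n_sites, dna_depth, 0.5)
  ai_dir <- stats::setNames(sample(c(0.98, 0.02), length(ai_genes),
                                   replace = TRUE), ai_genes)
  rna_p <- ifelse(gene %in% ai_genes, ai_dir[gene], 0.5)
  rna_alt <- stats::rbinom(n_sites, rna_depth, rna_p)
  damaging <- stats::runif(n_sites) < damaging_rate
  poly <- stats::runif(n_sites) < polymorphism_rate
  if (length(damaging_genes) > 0) {
    idx <- seq_along(damaging_genes)
    damaging[idx] <- TRUE
    poly[idx] <- FALSE
  }
  poly[gene %in% ai_genes] <- FALSE
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- data.frame(
    chrom = "chr1", pos = seq_len(n_sites) * 100L, ref = ref, alt = alt,
    gene = gene, dna_depth = dna_depth, dna_alt_depth = dna_alt,
    rna_depth = rna_depth, rna_alt_depth = rna_alt,
    damaging = damaging, common_polymorphism = poly,
    stringsAsFactors = FALSE)
  truth <- .truth("variants", ai_genes = ai_genes,
                  params = list(n_sites = n_sites, n_genes = length(genes),
                                ai_fraction = ai_fraction,
                                depth_mean = depth_mean,
                                damaging_rate = damaging_rate,
                                polymorphism_rate = polymorphism_rate),
                  seed = seed)
  list(variants = variants, truth = truth)
}

#' Simulate a complete synthetic multi-omics bundle with planted drivers
#'
#' Generates a coherent network + functional gene sets + omics table +
#' variant table over one shared gene universe, with known ground truth, for
#' end-to-end exercising of [run_pipeline()]:
#'
#' * a 500-gene network with one planted 50-gene module (within-module edge
#'   probability 0.3 over a 0.01 background) - the "cancer circuitry";
#' * 15 module genes carry damaging, non-polymorphic SNVs (the SNV reference
#'   set), with background damaging/polymorphic variants scattered elsewhere;
#' * 20 further module genes are planted *drivers*: copy-number altered with
#'   a strong, clean dosage effect on expression and protein
#'   (`cn_effect = 2`, `noise_sd = 0.3`, `protein_attenuation = 0.8`,
#'   `protein_noise_sd = 0.4`, copy-number profiles drawn from distinct
#'   states in \{1, 2, 4, 8\}), so that they pass a stringent correlation
#'   filter *and* sit near the SNV reference in the network;
#' * 10 decoy genes outside the module with the same clean dosage response -
#'   they pass the correlation filter but have no network context;
#' * 8 planted allelically imbalanced genes;
#' * three functional gene sets: 15 module genes disjoint from all altered
#'   sets (connected to them but sharing no gene - the case where network
#'   enrichment can see what overlap statistics cannot) and two random
#'   decoy sets.
#'
#' The driver cohort (20) is deliberately planted well above the workflow's
#' irreducible false-positive floor at the default thresholds (about ten
#' genes at this network density, dominated by genes one network hop from
#' the module); see the methods vignette for the power analysis.
#'
#' @param seed integer master seed
#' @param dir optional directory; when given, writes `network.tsv`,
#'   `fgs.gmt`, `omics.tsv`, `variants.tsv`, `truth.json`
#' @param n_genes,module_size,background_edge_prob,within_prob network shape
#' @return list with `network`, `fgs` (an [fgs_collection]), `omics`,
#'   `variants`, `truth` and, when `dir` is given, `paths`
#' @export
simulate_bundle <- function(seed = 7L, dir = NULL, n_genes = 500,
                            module_size = 50, background_edge_prob = 0.01,
                            within_prob = 0.3) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  sim_net <- simulate_network(
    n_genes, background_edge_prob,
    modules = list(list(size = module_size, within_prob = within_prob)),
    seed = seed, genes = genes)
  module <- sim_net$truth$modules$module1
  set.seed(seed + 1L)
  module_shuffled <- sample(module)
  snv_genes <- sort(module_shuffled[1:15])
  drivers <- sort(module_shuffled[16:35])
  fgs_module <- sort(module_shuffled[36:50])
  outside <- setdiff(genes, module)
  decoys <- sort(sample(outside, 10))
  ai_genes <- sort(sample(setdiff(genes, c(snv_genes, drivers)), 8))
  cn_overrides <- lapply(stats::setNames(c(drivers, decoys),
                                         c(drivers, decoys)),
                         function(g) sample(c(1, 2, 4, 8), 3))
  sim_omics <- simulate_omics(
    n_genes = n_genes, lines = 3, cn_effect = 2,
    responsive_genes = c(drivers, decoys),
    protein_attenuation = 0.8, noise_sd = 0.3, protein_noise_sd = 0.4,
    cn_overrides = cn_overrides, genes = genes, seed = seed + 2L)
  sim_var <- simulate_variants(
    n_sites = 150, genes = genes, ai_genes = ai_genes,
    damaging_genes = snv_genes, depth_mean = 50,
    damaging_rate = 0.25, polymorphism_rate = 0.3, seed = seed + 3L)
  set.seed(seed + 4L)
  fgs <- fgs_collection(list(
    gene_set("planted_module_fgs", fgs_module, class = "FGS"),
    gene_set("decoy_fgs_1", sample(outside, 20), class = "FGS"),
    gene_set("decoy_fgs_2", sample(outside, 20), class = "FGS")))
  truth <- .truth("bundle",
                  module = module, snv_genes = snv_genes,
                  drivers = drivers, decoys = decoys,
                  ai_genes = ai_genes, fgs_module = fgs_module,
                  params = list(n_genes = n_genes,
                                module_size = module_size,
                                background_edge_prob = background_edge_prob,
                                within_prob = within_prob),
                  seed = seed)
  out <- list(network = sim_net$network, fgs = fgs,
              omics = sim_omics$omics, variants = sim_var$variants,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(network = file.path(dir, "network.tsv"),
                  fgs = file.path(dir, "fgs.gmt"),
                  omics = file.path(dir, "omics.tsv"),
                  variants = file.path(dir, "variants.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_edge_list(out$network, paths$network)
    write_gmt(out$fgs, paths$fgs)
    write_omics(out$omics, paths$omics)
    write_variants(out$variants, paths$variants)
    write_truth(truth, paths$truth)
    out$paths <- paths
  }
  out
}
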