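#' Build a pipeline configuration
#'
#' Collects all inputs and thresholds of the integrative workflow in one
#' declarative object. Inputs may be file paths (edge-list TSV, GMT, omics
#' TSV, variant TSV) or in-memory objects. Defaults mirror the conventional
#' operating point of the analysis: 50 network permutations, context
#' z > 1.96, mean copy-number/expression correlation > 0.8, significance
#' P < 0.05 with FDR < 0.10, pathway connectivity at >= 5 links and z > 2.
#'
#' All randomness flows from the single `seed`, expanded into fixed
#' per-stage seeds, so a rerun of the same configuration is byte-identical.
#'
#' @param network path(s) to edge-list TSV(s) (merged by union) or a
#'   [gene_network]
#' @param gmt path to a GMT file or an [fgs_collection]
#' @param omics path to an omics TSV or a data.frame
#' @param variants path to a variant TSV or a data.frame
#' @param min_score optional score floor applied when loading edge lists
#' @param corr_threshold,rpkm_min,use_protein see [filter_cna_genes()]
#' @param z_threshold,context_mode see [nea_context_filter()]
#' @param require_damaging,het_floor see [filter_snvs()]
#' @param dna_af_band,rna_af_hom,min_depth see [call_allelic_imbalance()]
#' @param nea_mode statistic for the set-vs-set matrix (`"direct"` or
#'   `"indirect"`)
#' @param n_perm,swap_factor randomization-null parameters
#' @param fdr_method,p_max,fdr_max,gsea_q significance machinery
#' @param min_links,min_z pathway-connectivity filter
#' @param seed master seed
#' @param out_dir optional output directory for [write_pipeline_report()]
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(network, gmt, omics, variants,
                            min_score = NULL,
                            corr_threshold = 0.8, rpkm_min = 1,
                            use_protein = TRUE,
                            z_threshold = 1.96, context_mode = "indirect",
                            require_damaging = TRUE, het_floor = 0.2,
                            dna_af_band = c(0.3, 0.7), rna_af_hom = 0.95,
                            min_depth = 10,
                            nea_mode = "direct", n_perm = 50,
                            swap_factor = 10,
                            fdr_method = "left_tail", p_max = 0.05,
                            fdr_max = 0.10, gsea_q = 0.05,
                            min_links = 5, min_z = 2,
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$corr_threshold >= -1, cfg$corr_threshold <= 1,
            cfg$n_perm >= 2, cfg$swap_factor > 0,
            cfg$p_max > 0, cfg$p_max <= 1, cfg$fdr_max > 0, cfg$fdr_max <= 1)
  for (nm in c("network", "gmt", "omics", "variants")) {
    x <- cfg[[nm]]
    if (is.character(x) && !all(file.exists(x)))
      stop("config: file not found for '", nm, "': ",
           paste(x[!file.exists(x)], collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the integrative multi-omics network-enrichment pipeline
#'
#' Executes the full workflow: network loading and merging; damaging-SNV set
#' construction; allelic-imbalance calling; the two-stage copy-number filter
#' (cross-line correlation, then network context against the SNV reference
#' set); altered-gene-set assembly; set-vs-set network enrichment with FDR;
#' hypergeometric GSEA on the same pairs; the NEA-vs-GSEA agreement table;
#' and per-gene pathway-connectivity of the surviving copy-number genes.
#' Every filtering stage logs input/output counts; the run is fully
#' deterministic given the config seed.
#'
#' @param config a [pipeline_config] (or a path to a JSON file of arguments)
#' @return object of class `pipeline_report`; see Details
#' @details The report contains `filters` (per-stage `filter_report`s),
#'   `contingency` (copy-number candidates cross-tabulated as correlation
#'   +/- x network context +/-; cells sum to the candidate count), `ags`
#'   (the altered gene sets), `nea`, `gsea`, `comparison` (2 x 2 agreement),
#'   `cna_pathway_connectivity`, `final_cna` and `meta` (seeds, version).
#'   When `config$out_dir` is set, [write_pipeline_report()] is called.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seed_ctx <- cfg$seed + 11L
  seed_matrix <- cfg$seed + 22L

  net <- .stage("load_network", {
    if (inherits(cfg$network, "gene_network")) cfg$network
    else merge_networks(lapply(cfg$network, load_edge_list,
                               min_score = cfg$min_score))
  })
  fgs <- .stage("load_gmt", {
    if (inherits(cfg$gmt, "fgs_collection")) cfg$gmt else load_gmt(cfg$gmt)
  })
  omics <- .stage("load_omics", {
    if (is.data.frame(cfg$omics)) cfg$omics else read_omics(cfg$omics)
  })
  variants <- .stage("load_variants", {
    if (is.data.frame(cfg$variants)) cfg$variants
    else read_variants(cfg$variants)
  })

  snv_set <- .stage("filter_snvs",
    filter_snvs(variants, require_damaging = cfg$require_damaging,
                het_floor = cfg$het_floor))
  ai_set <- .stage("call_allelic_imbalance",
    call_allelic_imbalance(variants, dna_af_band = cfg$dna_af_band,
                           rna_af_hom = cfg$rna_af_hom,
                           min_depth = cfg$min_depth))
  cna_corr <- .stage("filter_cna_genes",
    filter_cna_genes(omics, corr_threshold = cfg$corr_threshold,
                     rpkm_min = cfg$rpkm_min,
                     use_protein = cfg$use_protein))
  corr_details <- attr(cna_corr, "details")
  candidates <- corr_details$gene

  ctx <- .stage("nea_context_filter", {
    if (length(snv_set$genes) == 0)
      stop("SNV reference set is empty")
    nea_context_filter(net,
                       gene_set("CNA_candidates", candidates, class = "CNA"),
                       snv_set, z_threshold = cfg$z_threshold,
                       mode = cfg$context_mode, n_perm = cfg$n_perm,
                       swap_factor = cfg$swap_factor, seed = seed_ctx)
  })
  ctx_details <- attr(ctx, "details")
  nea_pos_genes <- ctx_details$gene[ctx_details$keep]
  corr_pos_genes <- corr_details$gene[corr_details$keep]
  contingency <- matrix(
    c(sum(candidates %in% corr_pos_genes & candidates %in% nea_pos_genes),
      sum(candidates %in% corr_pos_genes & !candidates %in% nea_pos_genes),
      sum(!candidates %in% corr_pos_genes & candidates %in% nea_pos_genes),
      sum(!candidates %in% corr_pos_genes & !candidates %in% nea_pos_genes)),
    nrow = 2, byrow = TRUE,
    dimnames = list(`CN/TRX` = c("CN/TRX+", "CN/TRX-"),
                    NEA = c("NEA+", "NEA-")))
  final_genes <- intersect(corr_pos_genes, nea_pos_genes)
  final_cna <- if (length(final_genes) > 0)
    gene_set("CNA", final_genes, class = "CNA")
  else structure(list(name = "CNA", genes = character(0), class = "CNA"),
                 class = "gene_set")

  ags <- .stage("build_ags", build_ags(snv_set, final_cna, ai_set))
  ags_in_net <- Filter(function(s) any(s$genes %in% net$nodes), ags)
  if (length(ags_in_net) < length(ags))
    message("dropped AGS with no network presence: ",
            paste(setdiff(names(ags), names(ags_in_net)), collapse = ", "))

  nea <- .stage("nea_matrix",
    nea_matrix(net, ags_in_net, fgs, mode = cfg$nea_mode,
               n_perm = cfg$n_perm, swap_factor = cfg$swap_factor,
               seed = seed_matrix, include_ags_ags = TRUE,
               fdr_method = cfg$fdr_method, p_max = cfg$p_max,
               fdr_max = cfg$fdr_max))
  universe <- .stage("gsea", unique(c(
    net$nodes, fgs$universe, unlist(lapply(ags, `[[`, "genes")))))
  gsea <- .stage("gsea",
    gsea_matrix(ags_in_net, fgs, universe, q_max = cfg$gsea_q))
  comparison <- .stage("compare_nea_gsea",
    compare_nea_gsea(nea[nea$fgs %in% names(fgs$sets), , drop = FALSE],
                     gsea, nea_p = cfg$p_max, nea_fdr = cfg$fdr_max,
                     gsea_q = cfg$gsea_q))

  cna_pathway <- .stage("pathway_connectivity", {
    if (length(final_genes) > 0) {
      singles <- lapply(final_genes, function(g) gene_set(g, g))
      tab <- nea_matrix(net, singles, fgs, mode = cfg$nea_mode,
                        n_perm = cfg$n_perm, swap_factor = cfg$swap_factor,
                        seed = seed_matrix)
      pathway_connectivity_filter(tab, min_links = cfg$min_links,
                                  min_z = cfg$min_z)
    } else NULL
  })

  report <- structure(list(
    filters = list(snv = filter_report(snv_set),
                   ai = filter_report(ai_set),
                   cna_correlation = filter_report(cna_corr),
                   cna_context = filter_report(ctx)),
    contingency = contingency,
    ags = ags,
    final_cna = final_cna,
    nea = nea,
    gsea = gsea,
    comparison = comparison,
    cna_pathway_connectivity = cna_pathway,
    details = list(cna_correlation = corr_details,
                   cna_context = ctx_details),
    meta = list(seed = cfg$seed, seed_context = seed_ctx,
                seed_matrix = seed_matrix,
                n_perm = cfg$n_perm, swap_factor = cfg$swap_factor,
                version = as.character(utils::packageVersion("neamix")))),
    class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (f in x$filters)
    cat(sprintf("  %-24s %5d -> %d\n", f$stage, f$n_in, f$n_out))
  cat("  contingency (CN/TRX x NEA):\n")
  print(x$contingency)
  cat(sprintf("  AGS: %s\n",
              paste(sprintf("%s (%d)", names(x$ags),
                            vapply(x$ags, function(s) length(s$genes), 0L)),
                    collapse = ", ")))
  cat(sprintf("  NEA pairs: %d (%d significant); GSEA pairs: %d (%d significant)\n",
              nrow(x$nea), sum(x$nea$significant),
              nrow(x$gsea), sum(x$gsea$significant)))
  invisible(x)
}

#' Write pipeline outputs to a run directory
#'
#' Emits `nea.tsv`, `gsea.tsv`, `contingency.tsv`, `comparison.tsv`,
#' `ags.gmt`, `filters.json` and `meta.json`. The files contain no
#' timestamps: reruns of the same configuration are byte-identical.
#'
#' @param report a `pipeline_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$nea, "nea.tsv")
  w(report$gsea, "gsea.tsv")
  utils::write.table(report$contingency, file.path(dir, "contingency.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(report$comparison, file.path(dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(report$cna_pathway_connectivity))
    w(report$cna_pathway_connectivity, "cna_pathway_connectivity.tsv")
  sets <- Filter(function(s) length(s$genes) > 0, report$ags)
  if (length(sets) > 0) write_gmt(sets, file.path(dir, "ags.gmt"))
  jsonlite::write_json(lapply(report$filters, unclass),
                       file.path(dir, "filters.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
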