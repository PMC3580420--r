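#' Read a per-gene multi-omics table
#'
#' Long-format TSV with columns `gene`, `line`, `copy_number`, `rpkm`,
#' `protein`; an empty `protein` field means the protein was not quantified.
#'
#' @param path path to the TSV
#' @return data.frame with those five columns
#' @export
read_omics <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "line", "copy_number", "rpkm", "protein")
  if (!all(need %in% names(df)))
    stop("omics table must have columns: ", paste(need, collapse = ", "))
  df$copy_number <- as.numeric(df$copy_number)
  df$rpkm <- as.numeric(df$rpkm)
  df$protein <- as.numeric(df$protein)
  if (any(df$copy_number < 0, na.rm = TRUE) || any(df$rpkm < 0, na.rm = TRUE))
    stop("copy_number and rpkm must be non-negative")
  df
}

#' Write an omics table to TSV
#' @param omics data.frame as from [read_omics()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_omics <- function(omics, path) {
  utils::write.table(omics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## wide gene x line matrices for one measurement
.omics_wide <- function(omics, what) {
  genes <- unique(omics$gene)
  lines <- unique(omics$line)
  m <- matrix(NA_real_, length(genes), length(lines),
              dimnames = list(genes, lines))
  m[cbind(match(omics$gene, genes), match(omics$line, lines))] <- omics[[what]]
  m
}

## row-wise Spearman between two matrices (midranks; zero-variance rows NA)
.row_spearman <- function(a, b) {
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  ra <- ra - rowMeans(ra)
  rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  out[apply(is.na(a) | is.na(b), 1, any)] <- NA_real_
  unname(out)
}

#' Copy-number / expression association within one cell line
#'
#' Kruskal-Wallis rank ANOVA of an expression response across copy-number
#' classes: are genes at higher copy number expressed at higher levels?
#'
#' @param omics omics data.frame (see [read_omics()])
#' @param line cell line identifier
#' @param response `"rpkm"` or `"protein"`
#' @return list with `statistic` (H), `df`, and `p.value`
#' @export
cn_expression_association <- function(omics, line,
                                      response = c("rpkm", "protein")) {
  response <- match.arg(response)
  sub <- omics[omics$line == line & !is.na(omics[[response]]), ]
  if (nrow(sub) == 0) stop("no data for line '", line, "'")
  cls <- factor(sub$copy_number)
  sizes <- table(cls)
  if (sum(sizes >= 2) < 2)
    stop("need at least 2 copy-number classes with >= 2 genes each")
  y <- sub[[response]]
  if (stats::var(y) == 0)
    return(list(statistic = 0, df = nlevels(cls) - 1L, p.value = 1))
  kw <- stats::kruskal.test(y, cls)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value)
}

#' mRNA-protein correlation within one cell line
#'
#' Spearman rank correlation between RPKM and protein intensity across genes;
#' genes with missing protein values are dropped pairwise.
#'
#' @inheritParams cn_expression_association
#' @return Spearman rho
#' @export
mrna_protein_correlation <- function(omics, line) {
  sub <- omics[omics$line == line, ]
  ok <- !is.na(sub$rpkm) & !is.na(sub$protein)
  if (sum(ok) < 3) stop("need >= 3 genes with both rpkm and protein in '",
                        line, "'")
  stats::cor(sub$rpkm[ok], sub$protein[ok], method = "spearman")
}

#' Cross-line copy-number correlation for one gene
#'
#' Spearman correlation between a gene's copy numbers and its expression (or
#' protein) across cell lines. With few lines the statistic is coarse (for 3
#' lines it takes values in \{-1, -0.5, 0.5, 1\} plus ties); a gene whose copy
#' number (or response) does not vary has an undefined correlation and
#' returns `NA`, to be excluded downstream rather than scored 0.
#'
#' @inheritParams cn_expression_association
#' @param gene gene symbol
#' @return Spearman rho, or `NA` when undefined
#' @export
per_gene_cross_line_correlation <- function(omics, gene,
                                            response = c("rpkm", "protein")) {
  response <- match.arg(response)
  sub <- omics[omics$gene == gene & !is.na(omics[[response]]) &
                 !is.na(omics$copy_number), ]
  if (nrow(sub) < 3) stop("gene '", gene, "' observed in fewer than 3 lines")
  if (stats::sd(sub$copy_number) == 0 || stats::sd(sub[[response]]) == 0)
    return(NA_real_)
  stats::cor(sub$copy_number, sub[[response]], method = "spearman")
}

#' Permutation control for the cross-line correlation filter
#'
#' For each threshold `t` on a grid, records the natural log of the ratio
#' between the number of genes whose observed cross-line copy-number/response
#' correlation is `>= t` and the mean such count after permuting, per gene,
#' the assignment of response values to cell lines. A pseudo-count of 0.5 is
#' added to numerator and denominator so empty tails stay finite. A curve
#' near zero everywhere means the observed correlations are
#' indistinguishable from noise; a positive, increasing curve indicates
#' genuine copy-number-driven expression.
#'
#' @param omics omics data.frame covering >= 50 genes
#' @param n_perm number of permutations (>= 10)
#' @param seed integer seed
#' @param response `"rpkm"` or `"protein"`
#' @param thresholds correlation grid (default 0, 0.1, ..., 1)
#' @return data.frame with `threshold`, `n_observed`, `mean_permuted`,
#'   `log_ratio`
#' @export
permutation_log_ratio <- function(omics, n_perm = 100, seed = 1L,
                                  response = c("rpkm", "protein"),
                                  thresholds = seq(0, 1, 0.1)) {
  response <- match.arg(response)
  if (n_perm < 10) stop("n_perm must be >= 10")
  cn <- .omics_wide(omics, "copy_number")
  resp <- .omics_wide(omics, response)
  if (nrow(cn) < 50) stop("permutation control needs >= 50 genes")
  obs <- .row_spearman(cn, resp)
  set.seed(seed)
  n_lines <- ncol(resp)
  perm_counts <- matrix(0, n_perm, length(thresholds))
  for (k in seq_len(n_perm)) {
    shuffled <- t(apply(resp, 1, sample, size = n_lines))
    rho <- .row_spearman(cn, shuffled)
    perm_counts[k, ] <- vapply(thresholds, function(t)
      sum(rho >= t, na.rm = TRUE), 0)
  }
  n_obs <- vapply(thresholds, function(t) sum(obs >= t, na.rm = TRUE), 0)
  mean_perm <- colMeans(perm_counts)
  data.frame(threshold = thresholds, n_observed = n_obs,
             mean_permuted = mean_perm,
             log_ratio = log((n_obs + 0.5) / (mean_perm + 0.5)))
}

## audit-trail record emitted by every filtering stage
filter_report_record <- function(stage, n_in, n_out, params) {
  stopifnot(n_out <= n_in)
  structure(list(stage = stage, n_in = as.integer(n_in),
                 n_out = as.integer(n_out), params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d -> %d\n", x$stage, x$n_in, x$n_out))
  invisible(x)
}

#' Extract the filter report attached to a filtered gene set
#' @param x object returned by a filtering stage
#' @return a `filter_report` (stage name, input/output counts, parameters)
#' @export
filter_report <- function(x) attr(x, "report")

#' Correlation-based copy-number gene filter
#'
#' Keeps candidate copy-number-altered genes whose copy number tracks their
#' expression across cell lines: the mean of the available cross-line
#' Spearman correlations (copy number vs RPKM and, when `use_protein`, copy
#' number vs protein) must exceed `corr_threshold`, and the gene's maximum
#' RPKM across lines must reach `rpkm_min` (weakly expressed genes cannot be
#' assessed). Genes with an undefined RPKM correlation (e.g. constant copy
#' number) are dropped; a missing/undefined protein term reduces the mean to
#' the RPKM term alone.
#'
#' @param omics omics data.frame
#' @param cna_genes candidate genes; default: all genes whose copy number
#'   varies across lines
#' @param corr_threshold mean-correlation threshold (default 0.8)
#' @param rpkm_min minimum max-RPKM (default 1)
#' @param use_protein include the protein correlation term (default TRUE)
#' @return a `gene_set` of class `CNA` (possibly with zero genes when
#'   nothing survives), with attributes `report` (a `filter_report`) and
#'   `details` (per-gene data.frame of correlations and decisions).
#' @export
filter_cna_genes <- function(omics, cna_genes = NULL, corr_threshold = 0.8,
                             rpkm_min = 1, use_protein = TRUE) {
  cn <- .omics_wide(omics, "copy_number")
  rp <- .omics_wide(omics, "rpkm")
  pr <- .omics_wide(omics, "protein")
  if (is.null(cna_genes)) {
    v <- apply(cn, 1, function(x) stats::sd(x, na.rm = TRUE))
    cna_genes <- rownames(cn)[!is.na(v) & v > 0]
  }
  missing_genes <- setdiff(cna_genes, rownames(cn))
  if (length(missing_genes))
    stop("candidate genes absent from the omics table: ",
         paste(missing_genes, collapse = ", "))
  idx <- match(cna_genes, rownames(cn))
  rho_rpkm <- .row_spearman(cn[idx, , drop = FALSE], rp[idx, , drop = FALSE])
  rho_prot <- if (use_protein)
    .row_spearman(cn[idx, , drop = FALSE], pr[idx, , drop = FALSE])
  else rep(NA_real_, length(idx))
  mean_rho <- ifelse(is.na(rho_prot), rho_rpkm, (rho_rpkm + rho_prot) / 2)
  max_rpkm <- apply(rp[idx, , drop = FALSE], 1, max, na.rm = TRUE)
  keep <- !is.na(mean_rho) & mean_rho > corr_threshold & max_rpkm >= rpkm_min
  details <- data.frame(gene = cna_genes, rho_rpkm = rho_rpkm,
                        rho_protein = rho_prot, mean_rho = mean_rho,
                        max_rpkm = max_rpkm, keep = keep,
                        stringsAsFactors = FALSE)
  report <- filter_report_record(
    "filter_cna_genes", length(cna_genes), sum(keep),
    list(corr_threshold = corr_threshold, rpkm_min = rpkm_min,
         use_protein = use_protein))
  if (!any(keep)) {
    message("filter_cna_genes: no gene passed the filter")
    out <- structure(list(name = "CNA", genes = character(0), class = "CNA"),
                     class = "gene_set")
  } else {
    out <- gene_set("CNA", cna_genes[keep], class = "CNA")
  }
  attr(out, "report") <- report
  attr(out, "details") <- details
  out
}

#' Network-context filter for copy-number genes
#'
#' Second-stage filter after [filter_cna_genes()]: each candidate gene is
#' individually tested for enriched network connectivity to a reference set
#' of SNV-impaired genes from the same sample ([nea_single_gene()] style),
#' and kept when its z-score exceeds `z_threshold`. All genes share one
#' ensemble of permuted networks. The default statistic is `"indirect"`: a
#' single gene contributes very few direct edges, so direct link counts are
#' small discrete numbers for which the normal z approximation (and hence a
#' 1.96 cutoff) is poorly calibrated, whereas two-step path counts pool over
#' all shared neighbours and are much better behaved - and copy-number
#' alterations act through transcription, whose couplings surface
#' predominantly as shared-neighbour relations. `"direct"` uses the edge
#' statistic; `"both"` keeps a gene when either statistic passes.
#'
#' Candidate genes absent from the network (untestable) are dropped and
#' counted in the report.
#'
#' @param net a [gene_network]
#' @param cna_set `gene_set` of candidate CNA genes
#' @param snv_reference `gene_set` of SNV-impaired reference genes
#' @param z_threshold keep genes with z > this (default 1.96)
#' @param mode `"both"`, `"direct"` or `"indirect"`
#' @param n_perm,swap_factor,seed permutation-null parameters
#' @return `gene_set` of class `CNA` with `report` and `details` attributes
#'   (per-gene z-scores for both statistics)
#' @export
nea_context_filter <- function(net, cna_set, snv_reference,
                               z_threshold = 1.96,
                               mode = c("indirect", "direct", "both"),
                               n_perm = 50, swap_factor = 10, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "gene_network"))
  genes_all <- cna_set$genes
  genes <- intersect(genes_all, net$nodes)
  ref_ids <- .set_ids(snv_reference$genes, net)
  if (length(ref_ids) == 0)
    stop("snv_reference has no genes in the network")
  emat <- .edge_matrix(net)
  n_nodes <- length(net$nodes)
  gid <- match(genes, net$nodes) - 1L
  if (length(gid) > 0) {
    obs <- cpp_count_single_vs_ref(emat, n_nodes, gid, ref_ids)
    null_d <- matrix(0, n_perm, length(gid))
    null_i <- matrix(0, n_perm, length(gid))
    for (k in seq_len(n_perm)) {
      set.seed(seed + k - 1L)
      perm <- .rewire_edges(emat, n_nodes, swap_factor)$edges
      cnt <- cpp_count_single_vs_ref(perm, n_nodes, gid, ref_ids)
      null_d[k, ] <- cnt[, 1]
      null_i[k, ] <- cnt[, 2]
    }
    zcalc <- function(o, m) {
      mu <- colMeans(m)
      s <- apply(m, 2, stats::sd)
      ifelse(s > 0, (o - mu) / s,
             ifelse(o == mu, NA_real_, sign(o - mu) * Inf))
    }
    z_direct <- zcalc(obs[, 1], null_d)
    z_indirect <- zcalc(obs[, 2], null_i)
    details <- data.frame(
      gene = genes,
      n_obs_direct = obs[, 1], mean_direct = colMeans(null_d),
      sd_direct = apply(null_d, 2, stats::sd), z_direct = z_direct,
      n_obs_indirect = obs[, 2], mean_indirect = colMeans(null_i),
      sd_indirect = apply(null_i, 2, stats::sd), z_indirect = z_indirect,
      stringsAsFactors = FALSE)
  } else {
    details <- data.frame(gene = character(0), n_obs_direct = numeric(0),
                          mean_direct = numeric(0), sd_direct = numeric(0),
                          z_direct = numeric(0), n_obs_indirect = numeric(0),
                          mean_indirect = numeric(0), sd_indirect = numeric(0),
                          z_indirect = numeric(0), stringsAsFactors = FALSE)
  }
  pass <- function(z) !is.na(z) & z > z_threshold
  details$keep <- switch(mode,
    both = pass(details$z_direct) | pass(details$z_indirect),
    direct = pass(details$z_direct),
    indirect = pass(details$z_indirect))
  kept <- details$gene[details$keep]
  report <- filter_report_record(
    "nea_context_filter", length(genes_all), length(kept),
    list(z_threshold = z_threshold, mode = mode, n_perm = n_perm,
         swap_factor = swap_factor,
         n_untestable = length(genes_all) - length(genes)))
  out <- if (length(kept) == 0) {
    message("nea_context_filter: no gene passed the filter")
    structure(list(name = cna_set$name, genes = character(0), class = "CNA"),
              class = "gene_set")
  } else gene_set(cna_set$name, kept, class = "CNA")
  attr(out, "report") <- report
  attr(out, "details") <- details
  out
}
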