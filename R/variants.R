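#' Read SNVs with DNA and RNA allele depths
#'
#' Flat TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `dna_depth`,
#' `dna_alt_depth`, `rna_depth`, `rna_alt_depth` and logical `damaging`,
#' `common_polymorphism`. The two flags come from external annotation
#' (damage prediction and polymorphism catalogues are upstream of this
#' package); [annotate_variants()] can fill them from plain gene/variant
#' lists.
#'
#' @param path path to the TSV
#' @return data.frame of variant records
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "dna_depth",
            "dna_alt_depth", "rna_depth", "rna_alt_depth")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  for (col in c("damaging", "common_polymorphism"))
    if (!col %in% names(df)) df[[col]] <- FALSE
  df$damaging <- as.logical(df$damaging)
  df$common_polymorphism <- as.logical(df$common_polymorphism)
  for (col in c("dna_depth", "dna_alt_depth", "rna_depth", "rna_alt_depth")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  }
  if (any(df$dna_alt_depth > df$dna_depth, na.rm = TRUE) ||
      any(df$rna_alt_depth > df$rna_depth, na.rm = TRUE))
    stop("alt depth cannot exceed total depth")
  df
}

#' Write variant records to TSV
#' @param variants variant data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate variants from external gene / variant lists
#'
#' Sets the `damaging` flag for variants whose gene is in `damaging_genes`
#' (or whose `chrom:pos` is in `damaging_sites`), and `common_polymorphism`
#' for variants whose `chrom:pos` is in `polymorphic_sites`.
#'
#' @param variants variant data.frame
#' @param damaging_genes character vector of gene symbols
#' @param damaging_sites,polymorphic_sites character vectors of `chrom:pos`
#' @return the annotated data.frame
#' @export
annotate_variants <- function(variants, damaging_genes = character(0),
                              damaging_sites = character(0),
                              polymorphic_sites = character(0)) {
  site <- paste(variants$chrom, variants$pos, sep = ":")
  variants$damaging <- variants$gene %in% damaging_genes |
    site %in% damaging_sites
  variants$common_polymorphism <- site %in% polymorphic_sites
  variants
}

#' Call allelically imbalanced genes
#'
#' A variant supports allelic imbalance when it is heterozygous at the DNA
#' level (DNA allele fraction inside `dna_af_band`) but essentially
#' monoallelic in RNA (RNA allele fraction `>= rna_af_hom` or
#' `<= 1 - rna_af_hom`), with both depths at least `min_depth`. A gene is
#' called AI when at least one of its variants is supporting. Records with
#' zero DNA or RNA depth are skipped with a warning.
#'
#' @param variants variant data.frame (see [read_variants()])
#' @param dna_af_band numeric length-2: heterozygous DNA allele-fraction
#'   band (default `c(0.3, 0.7)`)
#' @param rna_af_hom RNA homozygosity threshold (default 0.95)
#' @param min_depth minimum DNA and RNA depth (default 10)
#' @return `gene_set` of class `AI` with attributes `report` and `evidence`
#'   (the supporting variant records)
#' @export
call_allelic_imbalance <- function(variants, dna_af_band = c(0.3, 0.7),
                                   rna_af_hom = 0.95, min_depth = 10) {
  stopifnot(length(dna_af_band) == 2, dna_af_band[1] <= dna_af_band[2])
  zero <- variants$dna_depth == 0 | variants$rna_depth == 0
  if (any(zero)) {
    warning(sum(zero), " zero-depth record(s) skipped")
    variants <- variants[!zero, , drop = FALSE]
  }
  dna_af <- variants$dna_alt_depth / variants$dna_depth
  rna_af <- variants$rna_alt_depth / variants$rna_depth
  supporting <- dna_af >= dna_af_band[1] & dna_af <= dna_af_band[2] &
    (rna_af >= rna_af_hom | rna_af <= 1 - rna_af_hom) &
    variants$dna_depth >= min_depth & variants$rna_depth >= min_depth
  genes <- sort(unique(variants$gene[supporting]))
  report <- filter_report_record(
    "call_allelic_imbalance", length(unique(variants$gene)), length(genes),
    list(dna_af_band = dna_af_band, rna_af_hom = rna_af_hom,
         min_depth = min_depth))
  out <- if (length(genes) == 0) {
    structure(list(name = "AI", genes = character(0), class = "AI"),
              class = "gene_set")
  } else gene_set("AI", genes, class = "AI")
  attr(out, "report") <- report
  attr(out, "evidence") <- variants[supporting, , drop = FALSE]
  out
}

#' Build the damaging-SNV gene set
#'
#' Drops common polymorphisms, drops variants whose DNA allele fraction is
#' below a heterogeneity floor (an approximation of subclonal filtering: a
#' very low allele fraction suggests a minor subclone or artefact), keeps
#' externally-predicted damaging variants when `require_damaging`, and
#' collapses the survivors to a gene set.
#'
#' @param variants variant data.frame
#' @param require_damaging keep only variants flagged damaging (default TRUE)
#' @param het_floor minimum DNA allele fraction (default 0.2)
#' @return `gene_set` of class `SNV` with attributes `report` and `variants`
#'   (the surviving records)
#' @export
filter_snvs <- function(variants, require_damaging = TRUE, het_floor = 0.2) {
  n_in <- nrow(variants)
  keep <- !variants$common_polymorphism
  af <- ifelse(variants$dna_depth > 0,
               variants$dna_alt_depth / variants$dna_depth, 0)
  keep <- keep & af >= het_floor
  if (require_damaging) keep <- keep & variants$damaging
  kept <- variants[keep, , drop = FALSE]
  genes <- sort(unique(kept$gene))
  report <- filter_report_record(
    "filter_snvs", n_in, nrow(kept),
    list(require_damaging = require_damaging, het_floor = het_floor,
         n_genes = length(genes)))
  out <- if (length(genes) == 0) {
    structure(list(name = "SNV", genes = character(0), class = "SNV"),
              class = "gene_set")
  } else gene_set("SNV", genes, class = "SNV")
  attr(out, "report") <- report
  attr(out, "variants") <- kept
  out
}

#' Assemble altered gene sets
#'
#' Combines the three classes of genomic alteration into the list of altered
#' gene sets used for set-vs-set network analysis: each non-empty class set
#' plus their deduplicated union.
#'
#' @param snv,cna,ai `gene_set` objects (any may be empty or NULL)
#' @return named list of `gene_set`: the non-empty inputs plus `"union"`
#' @export
build_ags <- function(snv = NULL, cna = NULL, ai = NULL) {
  sets <- Filter(function(s) !is.null(s) && length(s$genes) > 0,
                 list(snv, cna, ai))
  if (length(sets) == 0) stop("all alteration sets are empty")
  all_genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  out <- c(sets, list(gene_set("union", all_genes, class = "custom")))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
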