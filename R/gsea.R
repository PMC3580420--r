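#' Hypergeometric overlap test (classical GSEA)
#'
#' Tests whether the overlap `k` between an altered gene set (size `n`) and a
#' functional gene set (size `K`) drawn from a universe of `N` genes is
#' larger than expected: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param ags,fgs `gene_set` objects or character vectors, both contained in
#'   `universe`
#' @param universe character vector of all testable gene symbols
#' @return object of class `overlap_result`: list with `ags_name`,
#'   `fgs_name`, `k`, `n`, `K`, `N`, `p` and (unfilled) `q`
#' @export
hypergeom_test <- function(ags, fgs, universe) {
  a_name <- if (inherits(ags, "gene_set")) ags$name else "ags"
  f_name <- if (inherits(fgs, "gene_set")) fgs$name else "fgs"
  a <- unique(if (inherits(ags, "gene_set")) ags$genes else as.character(ags))
  f <- unique(if (inherits(fgs, "gene_set")) fgs$genes else as.character(fgs))
  universe <- unique(as.character(universe))
  if (!all(a %in% universe))
    stop("ags '", a_name, "' is not contained in the universe: ",
         paste(setdiff(a, universe), collapse = ", "))
  if (!all(f %in% universe))
    stop("fgs '", f_name, "' is not contained in the universe: ",
         paste(setdiff(f, universe), collapse = ", "))
  k <- length(intersect(a, f))
  n <- length(a); K <- length(f); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(ags_name = a_name, fgs_name = f_name,
                 k = k, n = n, K = K, N = N, p = p, q = NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result %s ~ %s: k=%d (n=%d, K=%d, N=%d), p=%.3g\n",
              x$ags_name, x$fgs_name, x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' Hypergeometric GSEA over lists of gene sets
#'
#' Runs [hypergeom_test()] for every (AGS, FGS) pair and fills `q` with
#' Benjamini-Hochberg adjusted P-values over all pairs.
#'
#' @param ags_list list of `gene_set`
#' @param fgs_list list of `gene_set` or an [fgs_collection]
#' @param universe character vector; by convention the union of network nodes
#'   and the FGS universe
#' @param q_max threshold for the `significant` column (default `q < 0.05`)
#' @return data.frame with columns `ags`, `fgs`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, `significant`
#' @export
gsea_matrix <- function(ags_list, fgs_list, universe, q_max = 0.05) {
  ags_list <- .as_set_list(ags_list)
  fgs_list <- .as_set_list(fgs_list)
  pairs <- expand.grid(a = names(ags_list), f = names(fgs_list),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- hypergeom_test(ags_list[[pairs$a[i]]], fgs_list[[pairs$f[i]]],
                        universe)
    data.frame(ags = r$ags_name, fgs = r$fgs_name, k = r$k, n = r$n,
               K = r$K, N = r$N, p = r$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < q_max
  res
}

#' Agreement table between NEA and overlap-based GSEA
#'
#' Cross-tabulates matched (AGS, FGS) pairs by significance under the network
#' test and under the hypergeometric overlap test. Pairs present in only one
#' input are an error.
#'
#' @param nea_results data.frame from [nea_matrix()] (columns `ags`, `fgs`,
#'   `p`, `fdr`)
#' @param overlap_results data.frame from [gsea_matrix()] (columns `ags`,
#'   `fgs`, `q`)
#' @param nea_p,nea_fdr NEA significance thresholds (defaults 0.05 / 0.10)
#' @param gsea_q GSEA significance threshold on the BH-adjusted p (default 0.05)
#' @return 2 x 2 integer matrix with dimnames `NEA+/-` x `GSEA+/-`
#' @export
compare_nea_gsea <- function(nea_results, overlap_results,
                             nea_p = 0.05, nea_fdr = 0.10, gsea_q = 0.05) {
  key_n <- paste(nea_results$ags, nea_results$fgs, sep = "\r")
  key_g <- paste(overlap_results$ags, overlap_results$fgs, sep = "\r")
  miss_n <- setdiff(key_n, key_g)
  miss_g <- setdiff(key_g, key_n)
  if (length(miss_n) || length(miss_g))
    stop("unmatched (ags, fgs) pairs: ",
         paste(gsub("\r", " ~ ", c(miss_n, miss_g)), collapse = "; "))
  m <- match(key_n, key_g)
  nea_pos <- !is.na(nea_results$z) & is.finite(nea_results$z) &
    nea_results$p < nea_p & nea_results$fdr < nea_fdr
  gsea_pos <- overlap_results$q[m] < gsea_q
  tab <- matrix(c(sum(nea_pos & gsea_pos), sum(nea_pos & !gsea_pos),
                  sum(!nea_pos & gsea_pos), sum(!nea_pos & !gsea_pos)),
                nrow = 2, byrow = TRUE,
                dimnames = list(NEA = c("NEA+", "NEA-"),
                                GSEA = c("GSEA+", "GSEA-")))
  tab
}
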