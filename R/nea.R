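#' Count direct links between two gene sets
#'
#' The number of distinct network edges with one endpoint in `ags` and the
#' other in `fgs`. Genes belonging to both sets are kept in both; an edge
#' internal to the intersection is counted once. Symmetric in its arguments.
#'
#' @param net a [gene_network]
#' @param ags,fgs `gene_set` objects (genes outside the network are ignored)
#' @return integer link count
#' @export
count_direct_links <- function(net, ags, fgs) {
  a <- .set_ids(ags$genes, net)
  f <- .set_ids(fgs$genes, net)
  if (length(a) == 0 || length(f) == 0) return(0L)
  as.integer(cpp_count_links(.edge_matrix(net), length(net$nodes), a, f, 1L))
}

#' Count indirect links between two gene sets
#'
#' The number of distinct two-step paths `a - x - f` with `a` in `ags`, `f`
#' in `fgs`, `a != f`, and intermediate `x` not an endpoint of the path. Each
#' unordered path is counted once; a gene pair may contribute many paths (one
#' per shared neighbour), and the presence of a direct `a - f` edge neither
#' requires nor excludes counting. Symmetric in its arguments.
#'
#' @inheritParams count_direct_links
#' @return integer path count
#' @export
count_indirect_links <- function(net, ags, fgs) {
  a <- .set_ids(ags$genes, net)
  f <- .set_ids(fgs$genes, net)
  if (length(a) == 0 || length(f) == 0) return(0L)
  as.integer(cpp_count_links(.edge_matrix(net), length(net$nodes), a, f, 2L))
}

#' Convert a network enrichment z-score to a P-value
#'
#' One-sided upper-tail standard normal probability: enrichment is tested,
#' depletion is reported as a negative z only.
#'
#' @param z finite numeric z-score (vectorized)
#' @return P-value(s) in `[0, 1]`
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

.new_nea_result <- function(ags_name, fgs_name, mode, n_obs, null_mom) {
  if (is.na(null_mom$sd) || null_mom$sd == 0) {
    if (n_obs == null_mom$mean) {
      z <- NA_real_; p <- 1
    } else {
      # constant null that the observation escapes: infinitely significant
      z <- if (n_obs > null_mom$mean) Inf else -Inf
      p <- if (n_obs > null_mom$mean) 0 else 1
    }
  } else {
    z <- (n_obs - null_mom$mean) / null_mom$sd
    p <- z_to_p(z)
  }
  structure(list(ags_name = ags_name, fgs_name = fgs_name, mode = mode,
                 n_obs = n_obs, null = null_mom, z = z, p = p,
                 fdr = NA_real_),
            class = "nea_result")
}

#' @export
print.nea_result <- function(x, ...) {
  cat(sprintf(
    "nea_result %s ~ %s [%s]: n_obs %d, expected %.2f (sd %.2f), z %s, p %.3g\n",
    x$ags_name, x$fgs_name, x$mode, x$n_obs, x$null$mean, x$null$sd,
    if (is.na(x$z)) "undefined" else sprintf("%.2f", x$z), x$p))
  invisible(x)
}

#' Network enrichment test for one pair of gene sets
#'
#' Computes the observed link count between `ags` and `fgs`, learns the null
#' mean and standard deviation from `n_perm` degree-preserving network
#' permutations, and reports `z = (n_obs - mean) / sd` with a one-sided
#' upper-tail normal P-value. When the null is degenerate (`sd == 0`) and the
#' observation equals the null mean, `z` is undefined (`NA`) and `p = 1`.
#'
#' @inheritParams estimate_null
#' @return an object of class `nea_result`
#' @export
nea_test <- function(net, ags, fgs, mode = c("direct", "indirect"),
                     n_perm = 50, swap_factor = 10, seed = 1L) {
  mode <- match.arg(mode)
  null_mom <- estimate_null(net, ags, fgs, mode, n_perm, swap_factor, seed)
  counter <- if (mode == "direct") count_direct_links else count_indirect_links
  n_obs <- counter(net, ags, fgs)
  .new_nea_result(ags$name, fgs$name, mode, n_obs, null_mom)
}

#' Single-gene network enrichment test
#'
#' Tests one gene for enriched connectivity to a reference set (typically the
#' other altered genes of the same sample), i.e. runs [nea_test()] with
#' `ags = {gene}` and `fgs = reference \\ {gene}`.
#'
#' @param net a [gene_network]
#' @param gene a gene symbol present in the network
#' @param reference a `gene_set`
#' @inheritParams estimate_null
#' @return an object of class `nea_result`
#' @export
nea_single_gene <- function(net, gene, reference,
                            mode = c("direct", "indirect"),
                            n_perm = 50, swap_factor = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (!gene %in% net$nodes) stop("gene '", gene, "' is not in the network")
  rest <- setdiff(reference$genes, gene)
  if (length(rest) == 0)
    stop("reference set is empty after removing '", gene, "'")
  nea_test(net, gene_set(gene, gene), gene_set(reference$name, rest),
           mode, n_perm, swap_factor, seed)
}

.as_set_list <- function(x) {
  if (inherits(x, "fgs_collection")) x <- x$sets
  if (inherits(x, "gene_set")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "gene_set")))
  names(x) <- vapply(x, `[[`, "", "name")
  x
}

#' Set-vs-set network enrichment matrix
#'
#' Runs the NEA test for every (AGS, FGS) pair, optionally adding the
#' AGS-vs-AGS pairs (relations among the altered gene sets themselves). All
#' pairs share one ensemble of permuted networks (seeded `seed + k - 1` for
#' permutation `k`, exactly as [estimate_null()]), so a 1 x 1 call reproduces
#' [nea_test()]. FDR is filled by [estimate_fdr()] and the default
#' significance filter is `p < 0.05` and `FDR < 0.10`.
#'
#' @param net a [gene_network]
#' @param ags_list list of `gene_set` (or a single set)
#' @param fgs_list list of `gene_set` or an [fgs_collection]
#' @param mode `"direct"` or `"indirect"`
#' @param n_perm,swap_factor,seed permutation-null parameters
#' @param include_ags_ags also test every unordered AGS pair
#' @param fdr_method passed to [estimate_fdr()]
#' @param n_random randomizations for `fdr_method = "random_sets"`
#' @param p_max,fdr_max thresholds for the `significant` column
#' @return data.frame with columns `ags`, `fgs`, `mode`, `n_obs`, `mean`,
#'   `sd`, `z`, `p`, `fdr`, `significant`
#' @export
nea_matrix <- function(net, ags_list, fgs_list,
                       mode = c("direct", "indirect"),
                       n_perm = 50, swap_factor = 10, seed = 1L,
                       include_ags_ags = FALSE,
                       fdr_method = c("left_tail", "random_sets"),
                       n_random = 10, p_max = 0.05, fdr_max = 0.10) {
  mode <- match.arg(mode)
  fdr_method <- match.arg(fdr_method)
  ags_list <- .as_set_list(ags_list)
  fgs_list <- .as_set_list(fgs_list)
  if (length(ags_list) == 0 || length(fgs_list) == 0)
    stop("ags_list and fgs_list must be non-empty")
  pairs <- expand.grid(a = names(ags_list), f = names(fgs_list),
                       stringsAsFactors = FALSE)
  pairs$fset <- pairs$f
  pairs$from_fgs <- TRUE
  if (include_ags_ags && length(ags_list) >= 2) {
    cmb <- utils::combn(names(ags_list), 2)
    pairs <- rbind(pairs, data.frame(a = cmb[1, ], f = cmb[2, ],
                                     fset = cmb[2, ], from_fgs = FALSE,
                                     stringsAsFactors = FALSE))
  }
  emat <- .edge_matrix(net)
  n_nodes <- length(net$nodes)
  aid <- lapply(ags_list, function(s) .set_ids(s$genes, net))
  fid <- lapply(fgs_list, function(s) .set_ids(s$genes, net))
  get_ids <- function(i) {
    f <- if (pairs$from_fgs[i]) fid[[pairs$fset[i]]] else aid[[pairs$fset[i]]]
    list(a = aid[[pairs$a[i]]], f = f)
  }
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    ids <- get_ids(i); length(ids$a) > 0 && length(ids$f) > 0
  }, TRUE)
  if (!all(ok))
    stop("these sets have no genes in the network: ",
         paste(unique(c(pairs$a[!ok], pairs$f[!ok])), collapse = ", "))
  mcode <- if (mode == "direct") 1L else 2L
  n_pairs <- nrow(pairs)
  null_counts <- matrix(0, n_perm, n_pairs)
  for (k in seq_len(n_perm)) {
    set.seed(seed + k - 1L)
    perm <- .rewire_edges(emat, n_nodes, swap_factor)$edges
    for (i in seq_len(n_pairs)) {
      ids <- get_ids(i)
      null_counts[k, i] <- cpp_count_links(perm, n_nodes, ids$a, ids$f, mcode)
    }
  }
  res <- data.frame(ags = pairs$a, fgs = pairs$f, mode = mode,
                    n_obs = NA_integer_, mean = NA_real_, sd = NA_real_,
                    z = NA_real_, p = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    ids <- get_ids(i)
    n_obs <- cpp_count_links(emat, n_nodes, ids$a, ids$f, mcode)
    r <- .new_nea_result(pairs$a[i], pairs$f[i], mode, as.integer(n_obs),
                         structure(list(mean = mean(null_counts[, i]),
                                        sd = stats::sd(null_counts[, i]),
                                        n_perm = n_perm),
                                   class = "null_moments"))
    res$n_obs[i] <- r$n_obs; res$mean[i] <- r$null$mean
    res$sd[i] <- r$null$sd; res$z[i] <- r$z; res$p[i] <- r$p
  }
  res <- estimate_fdr(res, method = fdr_method, net = net,
                      n_random = n_random, seed = seed,
                      ags_list = ags_list,
                      fgs_list = c(fgs_list, ags_list),
                      mode = mode, n_perm = n_perm, swap_factor = swap_factor)
  res$significant <- !is.na(res$z) & is.finite(res$z) &
    res$p < p_max & res$fdr < fdr_max
  res
}

## degree-matched random set: same size, same binned degree profile
## (bins at powers of 2; degree 0 is its own bin; short bins widened)
.degree_bins <- function(d) ifelse(d == 0, -1L, floor(log2(d)))

.sample_matched_set <- function(net, genes) {
  d <- degrees(net)
  bins <- .degree_bins(d)
  target <- .degree_bins(d[genes])
  need <- table(target)
  picked <- character(0)
  for (b in names(need)) {
    b_num <- as.integer(b)
    width <- 0
    repeat {
      pool <- setdiff(names(d)[abs(bins - b_num) <= width], picked)
      if (length(pool) >= need[[b]] || width > max(abs(bins)) + 1) break
      width <- width + 1
    }
    picked <- c(picked, sample(pool, min(need[[b]], length(pool))))
  }
  picked
}

#' Estimate false discovery rates for NEA results
#'
#' Two empirical strategies:
#' \describe{
#'   \item{`left_tail`}{uses the depletion side of the z distribution, where
#'     no true findings are expected: `FDR(z0) = #(z <= -z0) / #(z >= z0)`
#'     over the result list, clipped to `[0, 1]`.}
#'   \item{`random_sets`}{re-runs the test on random altered gene sets of
#'     matching size and binned degree profile (bins at powers of two):
#'     `FDR(z0)` is the mean per-randomization count of random-set z-scores
#'     `>= z0`, divided by the observed count `>= z0`.}
#' }
#' Rows with undefined z receive FDR 1.
#'
#' @param results data.frame as produced by [nea_matrix()] (needs a `z`
#'   column; `random_sets` also needs `ags`/`fgs` columns)
#' @param method `"left_tail"` or `"random_sets"`
#' @param net required for `random_sets`
#' @param n_random number of random-set replicates
#' @param seed integer seed
#' @param ags_list,fgs_list named lists of `gene_set` (required for
#'   `random_sets`; names must cover `results$ags` / `results$fgs`)
#' @param mode,n_perm,swap_factor null parameters for `random_sets`
#' @return `results` with the `fdr` column filled
#' @export
estimate_fdr <- function(results, method = c("left_tail", "random_sets"),
                         net = NULL, n_random = 10, seed = 1L,
                         ags_list = NULL, fgs_list = NULL,
                         mode = "direct", n_perm = 50, swap_factor = 10) {
  method <- match.arg(method)
  stopifnot(is.data.frame(results), "z" %in% names(results),
            nrow(results) >= 1)
  z <- results$z
  usable <- !is.na(z)
  fdr <- rep(1, length(z))
  if (method == "left_tail") {
    for (i in which(usable)) {
      num <- sum(z[usable] <= -z[i])
      den <- sum(z[usable] >= z[i])
      fdr[i] <- if (den == 0) 0 else min(1, num / den)
    }
  } else {
    if (is.null(net)) stop("random_sets FDR requires the network")
    if (is.null(ags_list) || is.null(fgs_list))
      stop("random_sets FDR requires ags_list and fgs_list")
    ags_list <- .as_set_list(ags_list)
    fgs_list <- .as_set_list(fgs_list)
    emat <- .edge_matrix(net)
    n_nodes <- length(net$nodes)
    mcode <- if (mode == "direct") 1L else 2L
    rows <- which(usable)
    z_rand <- matrix(NA_real_, length(rows), n_random)
    for (r in seq_len(n_random)) {
      set.seed(seed + 100000L + r)
      rand_ids <- lapply(rows, function(i) {
        g <- .sample_matched_set(net, intersect(
          ags_list[[results$ags[i]]]$genes, net$nodes))
        match(g, net$nodes) - 1L
      })
      counts <- matrix(0, n_perm, length(rows))
      for (k in seq_len(n_perm)) {
        set.seed(seed + k - 1L)
        perm <- .rewire_edges(emat, n_nodes, swap_factor)$edges
        for (j in seq_along(rows)) {
          i <- rows[j]
          fid <- .set_ids(fgs_list[[results$fgs[i]]]$genes, net)
          counts[k, j] <- cpp_count_links(perm, n_nodes, rand_ids[[j]],
                                          fid, mcode)
        }
      }
      for (j in seq_along(rows)) {
        i <- rows[j]
        fid <- .set_ids(fgs_list[[results$fgs[i]]]$genes, net)
        n_obs <- cpp_count_links(emat, n_nodes, rand_ids[[j]], fid, mcode)
        mu <- mean(counts[, j]); s <- stats::sd(counts[, j])
        z_rand[j, r] <- if (s > 0) (n_obs - mu) / s else
          if (n_obs == mu) NA_real_ else sign(n_obs - mu) * Inf
      }
    }
    for (j in seq_along(rows)) {
      i <- rows[j]
      den <- sum(z[usable] >= z[i])
      num <- mean(colSums(z_rand >= z[i], na.rm = TRUE))
      fdr[i] <- if (den == 0) 0 else min(1, num / den)
    }
  }
  results$fdr <- fdr
  results
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted P-values, order-preserving with the input and
#' monotone (output >= input, <= 1).
#'
#' @param pvals numeric vector of P-values in `[0, 1]`
#' @return adjusted values, same length and order
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  ord <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(pvals[ord] * n / seq(n, 1)))
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Filter results by pathway connectivity
#'
#' Keeps results with at least `min_links` observed links and a z-score above
#' `min_z` (defaults 5 links and z > 2, the conventional "connected to the
#' pathway" criterion).
#'
#' @param results data.frame with `n_obs` and `z` columns
#' @param min_links minimum observed link count (kept when `n_obs >= min_links`)
#' @param min_z z threshold (kept when `z > min_z`)
#' @return the filtered data.frame
#' @export
pathway_connectivity_filter <- function(results, min_links = 5, min_z = 2) {
  stopifnot(is.data.frame(results), all(c("n_obs", "z") %in% names(results)))
  keep <- !is.na(results$z) & results$n_obs >= min_links & results$z > min_z
  results[keep, , drop = FALSE]
}

#' Write NEA results to disk
#' @param results data.frame from [nea_matrix()]
#' @param path output path
#' @param format `"tsv"` or `"json"`
#' @return `path`, invisibly
#' @export
write_nea_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
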