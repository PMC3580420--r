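## internal: integer edge matrix (0-based) + node index for C++ calls
.edge_matrix <- function(net) {
  cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes)) - 1L
}

.set_ids <- function(genes, net) match(intersect(genes, net$nodes), net$nodes) - 1L

.rewire_edges <- function(emat, n_nodes, swap_factor) {
  cpp_rewire(emat, n_nodes, ceiling(swap_factor * nrow(emat)))
}

#' Degree-preserving network randomization
#'
#' Randomizes a network by repeated double-edge swaps: two edges `a-b`,
#' `c-d` are replaced by `a-c`, `b-d` (or `a-d`, `b-c`), which preserves
#' every node's degree and the total edge count. `ceiling(swap_factor * |E|)`
#' swap proposals are made; a proposal that would create a self-loop or a
#' duplicate edge is rejected, leaving the graph unchanged for that step.
#' Rejected proposals deliberately consume the step budget: because the
#' proposal distribution does not depend on the current graph, the resulting
#' lazy chain samples *uniformly* from all simple graphs with the given
#' degree sequence (retrying until success would instead oversample graphs
#' that admit many valid swaps; see the methods vignette). Graphs admitting
#' no valid swap at all (e.g. stars) are returned unchanged with a warning.
#'
#' Evidence tags and scores are dropped from the randomized edges: a rewired
#' network is a topological null, not a biological object.
#'
#' @param net a [gene_network] with at least 2 edges
#' @param swap_factor successful swaps per edge (default 10, a standard
#'   mixing heuristic)
#' @param seed integer seed; identical seeds give identical permutations
#' @return a `gene_network` with the same nodes, degrees and edge count
#' @export
rewire <- function(net, swap_factor = 10, seed = 1L) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$edges) < 2) {
    warning("network has fewer than 2 edges; returned unchanged")
    return(net)
  }
  set.seed(seed)
  res <- .rewire_edges(.edge_matrix(net), length(net$nodes), swap_factor)
  if (res$n_success == 0) {
    warning("no valid swap exists; network returned unchanged")
    return(net)
  }
  e <- res$edges + 1L
  gene_network(data.frame(from = net$nodes[e[, 1]], to = net$nodes[e[, 2]],
                          stringsAsFactors = FALSE),
               nodes = net$nodes)
}

#' Null moments of a link-count statistic
#'
#' Estimates the expected number of links \eqn{\hat n_{ij}} and its standard
#' deviation \eqn{\sigma_{ij}} between two gene sets under degree-preserving
#' randomization. Each of the `n_perm` permutations starts from the original
#' network (ensemble members are independent, not chained) and is seeded with
#' `seed + k - 1` for permutation `k`. The sample standard deviation uses the
#' n-1 denominator.
#'
#' @param net a [gene_network]
#' @param ags,fgs `gene_set` objects (genes outside the network are ignored)
#' @param mode `"direct"` (edges between the sets) or `"indirect"`
#'   (two-step paths through a shared neighbour)
#' @param n_perm number of permutations (>= 2; default 50)
#' @param swap_factor successful swaps per edge per permutation
#' @param seed integer base seed
#' @return object of class `null_moments`: list with `mean`, `sd`, `n_perm`,
#'   and the per-permutation `counts`
#' @export
estimate_null <- function(net, ags, fgs, mode = c("direct", "indirect"),
                          n_perm = 50, swap_factor = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 2) stop("n_perm must be >= 2 (sd undefined otherwise)")
  emat <- .edge_matrix(net)
  n_nodes <- length(net$nodes)
  a <- .set_ids(ags$genes, net)
  f <- .set_ids(fgs$genes, net)
  if (length(a) == 0 || length(f) == 0)
    stop("both gene sets must have at least one gene in the network")
  mcode <- if (mode == "direct") 1L else 2L
  counts <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    set.seed(seed + k - 1L)
    perm <- .rewire_edges(emat, n_nodes, swap_factor)$edges
    counts[k] <- cpp_count_links(perm, n_nodes, a, f, mcode)
  }
  structure(list(mean = mean(counts), sd = stats::sd(counts),
                 n_perm = n_perm, counts = counts),
            class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat(sprintf("null_moments: mean %.3f, sd %.3f (%d permutations)\n",
              x$mean, x$sd, x$n_perm))
  invisible(x)
}
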