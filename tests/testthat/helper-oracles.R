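# Independent test oracles and small fixture builders. Everything here is
# deliberately written against plain adjacency matrices, independent of the
# package's edge-list / C++ code paths.

net_from_pairs <- function(pairs, nodes = NULL) {
  gene_network(data.frame(from = vapply(pairs, `[[`, "", 1),
                          to = vapply(pairs, `[[`, "", 2),
                          stringsAsFactors = FALSE),
               nodes = nodes)
}

adj_from_net <- function(net) {
  n <- length(net$nodes)
  a <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges)))
    a[net$edges$from[i], net$edges$to[i]] <-
      a[net$edges$to[i], net$edges$from[i]] <- TRUE
  a
}

## brute-force link counters on an adjacency matrix (indices)
oracle_direct <- function(adj, a, f) {
  cnt <- 0
  n <- nrow(adj)
  for (u in seq_len(n - 1)) for (v in (u + 1):n)
    if (adj[u, v] && ((u %in% a && v %in% f) || (u %in% f && v %in% a)))
      cnt <- cnt + 1
  cnt
}

oracle_indirect <- function(adj, a, f) {
  cnt <- 0
  pairs <- unique(t(apply(expand.grid(a, f), 1, sort)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    u <- pairs[i, 1]; v <- pairs[i, 2]
    cnt <- cnt + sum(adj[u, ] & adj[v, ])
  }
  cnt
}

## exhaustive enumeration of all simple graphs with a given degree sequence:
## repeatedly saturate the lowest-index vertex with remaining degree, so each
## graph is produced exactly once
enumerate_degseq_graphs <- function(degs) {
  n <- length(degs)
  out <- list()
  recurse <- function(rem, adj) {
    v <- which(rem > 0)[1]
    if (is.na(v)) { out[[length(out) + 1]] <<- adj; return(invisible()) }
    cand <- which(rem > 0 & !adj[v, ] & seq_len(n) != v)
    if (length(cand) < rem[v]) return(invisible())
    for (s in utils::combn(cand, rem[v], simplify = FALSE)) {
      adj2 <- adj; rem2 <- rem
      adj2[v, s] <- adj2[s, v] <- TRUE
      rem2[v] <- 0L; rem2[s] <- rem2[s] - 1L
      recurse(rem2, adj2)
    }
  }
  recurse(as.integer(degs), matrix(FALSE, n, n))
  out
}

## population moments (and 4th central moment, for the MC standard error of
## an estimated sd) over a full ensemble of counts
pop_moments <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  list(mean = mu, sd = sqrt(s2), mu4 = mean((x - mu)^4))
}

## brute-force hypergeometric upper tail via binomial coefficients
oracle_hyper_upper <- function(k, N, K, n) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- seq(max(k, lo), hi)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

## Erdos-Renyi gene network
er_net <- function(n, p, seed, prefix = "N") {
  set.seed(seed)
  nodes <- sprintf(paste0(prefix, "%04d"), seq_len(n))
  pr <- utils::combn(n, 2)
  hit <- stats::runif(ncol(pr)) < p
  gene_network(data.frame(from = nodes[pr[1, hit]], to = nodes[pr[2, hit]],
                          stringsAsFactors = FALSE),
               nodes = nodes)
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "neamix")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", name)
  p
}
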