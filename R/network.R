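#' Construct a gene network
#'
#' A `gene_network` is a simple undirected graph over gene symbols: no
#' self-loops, no duplicate edges, every edge endpoint present in the node
#' set. Per-edge evidence tags (e.g. `ppi`, `mrna_coexpr`, `kegg`) and an
#' optional confidence score are retained but not used by the enrichment
#' statistics.
#'
#' Gene identity is the bare symbol string, case-sensitive; no alias
#' resolution is attempted.
#'
#' @param edges data.frame with character columns `from` and `to`, and
#'   optionally `evidence` (comma-separated tags) and `score` (numeric).
#' @param nodes optional character vector of node symbols; the union of edge
#'   endpoints is always included, so this only adds isolated nodes.
#' @return An object of class `gene_network` with elements `nodes`
#'   (character) and `edges` (data.frame `from`, `to`, `evidence`, `score`).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        evidence = character(), score = numeric(),
                        stringsAsFactors = FALSE)
  }
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have columns 'from' and 'to'")
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  if (any(from == to)) stop("self-loops are not allowed in a gene_network")
  evidence <- if ("evidence" %in% names(edges))
    as.character(edges$evidence) else rep("", length(from))
  evidence[is.na(evidence)] <- ""
  score <- if ("score" %in% names(edges))
    as.numeric(edges$score) else rep(NA_real_, length(from))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed; collapse first")
  ord <- order(from, to, method = "radix")
  edges <- data.frame(from = from[ord], to = to[ord],
                      evidence = evidence[ord], score = score[ord],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a network
#' @param net a `gene_network`
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node degrees
#' @param net a `gene_network`
#' @return named integer vector, one entry per node (isolated nodes included
#'   with degree 0)
#' @export
degrees <- function(net) {
  d <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  stats::setNames(as.integer(d), net$nodes)
}

.split_tags <- function(x) {
  out <- strsplit(x, "[,;|]")
  lapply(out, function(t) sort(unique(t[nzchar(t)])))
}

.join_tags <- function(tags) vapply(tags, paste, "", collapse = ",")

## collapse duplicate unordered pairs: evidence tags unioned, score = max
.collapse_edges <- function(from, to, evidence, score) {
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  ev <- .split_tags(evidence)
  ev_merged <- lapply(split(ev, idx), function(l) sort(unique(unlist(l))))
  sc_merged <- vapply(split(score, idx), function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE), 0)
  data.frame(from = from[first], to = to[first],
             evidence = .join_tags(ev_merged[as.character(seq_along(ev_merged))]),
             score = unname(sc_merged[as.character(seq_along(sc_merged))]),
             stringsAsFactors = FALSE)
}

#' Load a gene network from an edge-list TSV
#'
#' Expected format: tab-separated, two or more columns
#' `geneA geneB [evidence] [score]`; lines starting with `#` are headers and
#' skipped. A third column is read as comma/semicolon-separated evidence tags
#' unless every non-empty value parses as a number, in which case it is read
#' as the score column. Self-loop rows are dropped; duplicate pairs are
#' collapsed with evidence tags unioned and the maximum score kept.
#'
#' @param path path to the TSV file.
#' @param min_score optional numeric; rows with a score below this are
#'   dropped before collapsing.
#' @return a [gene_network]
#' @export
load_edge_list <- function(path, min_score = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no edge rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("malformed row at line %d of %s: fewer than 2 columns",
                 lineno[which(nf < 2)[1]], path))
  from <- vapply(fields, `[[`, "", 1)
  to <- vapply(fields, `[[`, "", 2)
  col3 <- ifelse(nf >= 3, vapply(fields, function(f) f[3], ""), "")
  col4 <- ifelse(nf >= 4, vapply(fields, function(f) f[4], ""), "")
  if (any(nf >= 4)) {
    evidence <- col3
    score_chr <- col4
  } else if (any(nf >= 3)) {
    num <- suppressWarnings(as.numeric(col3))
    if (all(is.na(num) == !nzchar(col3))) { # all non-empty values numeric
      evidence <- rep("", length(from)); score_chr <- col3
    } else {
      evidence <- col3; score_chr <- rep("", length(from))
    }
  } else {
    evidence <- rep("", length(from)); score_chr <- rep("", length(from))
  }
  score <- suppressWarnings(as.numeric(score_chr))
  bad_score <- nzchar(score_chr) & is.na(score)
  if (any(bad_score))
    stop(sprintf("malformed row at line %d of %s: non-numeric score '%s'",
                 lineno[which(bad_score)[1]], path, score_chr[which(bad_score)[1]]))
  if (!is.null(min_score)) {
    keep <- !is.na(score) & score >= min_score
    from <- from[keep]; to <- to[keep]
    evidence <- evidence[keep]; score <- score[keep]
  }
  drop_loop <- from == to
  from <- from[!drop_loop]; to <- to[!drop_loop]
  evidence <- evidence[!drop_loop]; score <- score[!drop_loop]
  if (length(from) == 0)
    stop("no edges left after filtering in ", path)
  gene_network(.collapse_edges(from, to, evidence, score))
}

#' Write a network back to edge-list TSV
#'
#' Inverse of [load_edge_list()]: a written network reloads to an identical
#' edge set.
#'
#' @param net a `gene_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  df$score <- ifelse(is.na(df$score), "", format(df$score, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#geneA\tgeneB\tevidence\tscore", con)
  writeLines(paste(df$from, df$to, df$evidence, df$score, sep = "\t"), con)
  invisible(path)
}

#' Merge networks by union
#'
#' Node set and edge set are unions; evidence tags of shared edges are
#' unioned, scores combined by maximum. Merging is commutative, associative
#' and idempotent in the resulting edge set.
#'
#' @param networks list of `gene_network` objects (length >= 1)
#' @return a `gene_network`
#' @export
merge_networks <- function(networks) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  if (length(networks) == 0) stop("merge_networks needs at least one network")
  stopifnot(all(vapply(networks, inherits, TRUE, "gene_network")))
  from <- unlist(lapply(networks, function(n) n$edges$from))
  to <- unlist(lapply(networks, function(n) n$edges$to))
  evidence <- unlist(lapply(networks, function(n) n$edges$evidence))
  score <- unlist(lapply(networks, function(n) n$edges$score))
  nodes <- unique(unlist(lapply(networks, function(n) n$nodes)))
  if (length(from) == 0) return(gene_network(NULL, nodes = nodes))
  gene_network(.collapse_edges(from, to, evidence, score), nodes = nodes)
}

#' Construct a gene set
#'
#' @param name set name
#' @param genes character vector of gene symbols (deduplicated)
#' @param class one of `"SNV"`, `"CNA"`, `"AI"`, `"FGS"`, `"custom"`
#' @return object of class `gene_set`
#' @export
gene_set <- function(name, genes, class = "custom") {
  class <- match.arg(class, c("SNV", "CNA", "AI", "FGS", "custom"))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  if (length(genes) == 0) stop("gene_set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes, class = class),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes\n", x$name, x$class,
              length(x$genes)))
  invisible(x)
}

#' Construct a collection of functional gene sets
#'
#' Multiple membership is allowed; the universe is the union of all member
#' symbols.
#'
#' @param sets list of `gene_set` objects (coerced to class `FGS`)
#' @return object of class `fgs_collection` with elements `sets` (named list)
#'   and `universe`
#' @export
fgs_collection <- function(sets) {
  if (length(sets) == 0) stop("fgs_collection needs at least one set")
  sets <- lapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    s$class <- "FGS"
    s
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  structure(list(sets = sets,
                 universe = sort(unique(unlist(lapply(sets, `[[`, "genes"))))),
            class = "fgs_collection")
}

#' @export
print.fgs_collection <- function(x, ...) {
  cat(sprintf("fgs_collection: %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.fgs_collection <- function(x) length(x$sets)

#' Load functional gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate genes within a line are collapsed.
#'
#' @param path path to the GMT file
#' @return an [fgs_collection]
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed GMT line %d of %s: fewer than 3 fields",
                 lineno[which(nf < 3)[1]], path))
  sets <- lapply(fields, function(f)
    gene_set(f[1], f[-(1:2)], class = "FGS"))
  fgs_collection(sets)
}

#' Write gene sets to a GMT file
#' @param sets an `fgs_collection` or list of `gene_set`
#' @param path output path
#' @param description description field written for every set
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "fgs_collection")) sets <- sets$sets
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene set to network nodes
#'
#' Genes absent from the network cannot participate in any link statistic.
#' Dropped symbols are reported via `message()`.
#'
#' @param s a `gene_set`
#' @param net a `gene_network`
#' @return a `gene_set` containing only genes present in `net`; errors if no
#'   gene survives.
#' @export
restrict_to_network <- function(s, net) {
  stopifnot(inherits(s, "gene_set"), inherits(net, "gene_network"))
  keep <- s$genes %in% net$nodes
  if (!any(keep))
    stop("gene_set '", s$name, "' has no genes in the network")
  if (any(!keep))
    message(sprintf("restrict_to_network: dropped %d/%d genes from '%s': %s",
                    sum(!keep), length(keep), s$name,
                    paste(s$genes[!keep], collapse = ", ")))
  s$genes <- s$genes[keep]
  s
}
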