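test_that("direct link counting follows the stated conventions", {
  nodes <- c("1", "2", "3", "4")
  pairs <- utils::combn(nodes, 2)
  k4 <- gene_network(data.frame(from = pairs[1, ], to = pairs[2, ]))
  expect_equal(count_direct_links(k4, gene_set("a", c("1", "2")),
                                  gene_set("f", c("3", "4"))), 4L)

  tri <- net_from_pairs(list(c("a", "b"), c("b", "c"), c("a", "c")))
  # b sits in both sets; every edge has one endpoint per set and counts once
  expect_equal(count_direct_links(tri, gene_set("x", c("a", "b")),
                                  gene_set("y", c("b", "c"))), 3L)

  # sets in different connected components share no edge
  comp <- net_from_pairs(list(c("a", "b"), c("x", "y")))
  expect_equal(count_direct_links(comp, gene_set("a", c("a", "b")),
                                  gene_set("f", c("x", "y"))), 0L)
  expect_equal(count_direct_links(comp, gene_set("a", "a"),
                                  gene_set("f", "x")), 0L)
})

test_that("indirect link counting counts two-step paths once each", {
  path <- net_from_pairs(list(c("a", "x"), c("x", "f")))
  expect_equal(count_indirect_links(path, gene_set("a", "a"),
                                    gene_set("f", "f")), 1L)

  nodes <- c("1", "2", "3", "4")
  pairs <- utils::combn(nodes, 2)
  k4 <- gene_network(data.frame(from = pairs[1, ], to = pairs[2, ]))
  expect_equal(count_indirect_links(k4, gene_set("a", "1"),
                                    gene_set("f", "2")), 2L) # 1-3-2, 1-4-2

  far <- net_from_pairs(list(c("a", "m1"), c("m1", "m2"), c("m2", "f")))
  expect_equal(count_indirect_links(far, gene_set("a", "a"),
                                    gene_set("f", "f")), 0L)
})

test_that("link counts are symmetric and match the brute-force oracle", {
  for (seed in 1:5) {
    net <- er_net(20, 0.25, seed)
    set.seed(seed)
    g <- sample(net$nodes, 9)
    a <- gene_set("a", g[1:5])
    f <- gene_set("f", g[4:9]) # overlapping on purpose
    adj <- adj_from_net(net)
    ai <- match(a$genes, net$nodes); fi <- match(f$genes, net$nodes)
    expect_equal(count_direct_links(net, a, f), oracle_direct(adj, ai, fi))
    expect_equal(count_direct_links(net, f, a), count_direct_links(net, a, f))
    expect_equal(count_indirect_links(net, a, f),
                 oracle_indirect(adj, ai, fi))
    expect_equal(count_indirect_links(net, f, a),
                 count_indirect_links(net, a, f))
  }
})

test_that("adding a cross edge never decreases the direct count", {
  for (seed in 1:3) {
    net <- er_net(15, 0.2, seed)
    set.seed(seed)
    g <- sample(net$nodes, 8)
    a <- gene_set("a", g[1:4]); f <- gene_set("f", g[5:8])
    before <- count_direct_links(net, a, f)
    missing <- NULL
    for (u in a$genes) for (v in f$genes) {
      key <- paste(sort(c(u, v)), collapse = "-")
      present <- any(paste(net$edges$from, net$edges$to, sep = "-") == key)
      if (!present) { missing <- c(u, v); break }
    }
    if (is.null(missing)) next
    net2 <- merge_networks(list(net, gene_network(
      data.frame(from = missing[1], to = missing[2]))))
    expect_gte(count_direct_links(net2, a, f), before)
  }
})

test_that("z_to_p implements the one-sided upper tail", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(z_to_p(1.6449), 0.05, tolerance = 1e-3)
  expect_gt(z_to_p(-4), 0.9999)
  expect_error(z_to_p(Inf), "finite")
  expect_error(z_to_p(NA_real_), "finite")
})

test_that("nea_test flags degenerate nulls and finds planted modules", {
  net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")),
                      nodes = c("a", "b", "c", "iso1", "iso2"))
  r <- nea_test(net, gene_set("a", c("iso1", "iso2")),
                gene_set("f", c("a", "c")), n_perm = 10)
  expect_equal(r$n_obs, 0L)
  expect_true(is.na(r$z))
  expect_equal(r$p, 1)

  sim <- simulate_network(seed = 7)
  mod <- sim$truth$modules$module1
  r2 <- nea_test(sim$network, gene_set("ags", mod[1:15]),
                 gene_set("fgs", mod[16:40]), "direct", n_perm = 50,
                 seed = 42)
  expect_gt(r2$z, 3)
})

test_that("nea_single_gene tests a gene against the rest of a set", {
  star <- net_from_pairs(list(c("hub", "r1"), c("hub", "r2"), c("hub", "r3")))
  r <- nea_single_gene(star, "hub", gene_set("ref", c("r1", "r2", "r3")),
                       "direct", n_perm = 10)
  expect_equal(r$n_obs, 3L) # forced by topology

  net <- gene_network(data.frame(from = "a", to = "b"),
                      nodes = c("a", "b", "lonely", "r1"))
  r2 <- nea_single_gene(net, "lonely", gene_set("ref", c("a", "b")),
                        n_perm = 10)
  expect_equal(r2$p, 1)
  expect_error(nea_single_gene(net, "a", gene_set("ref", "a"), n_perm = 10),
               "empty")
  expect_error(nea_single_gene(net, "nope", gene_set("ref", "a")), "not in")

  sim <- simulate_network(seed = 7)
  mod <- sim$truth$modules$module1
  r3 <- nea_single_gene(sim$network, mod[1], gene_set("ref", mod[2:26]),
                        "indirect", n_perm = 50, seed = 5)
  expect_gt(r3$z, 3)
})

test_that("nea_matrix reproduces nea_test and has the right shape", {
  net <- er_net(40, 0.15, 3)
  set.seed(3)
  g <- sample(net$nodes, 12)
  a <- gene_set("a1", g[1:6]); f <- gene_set("f1", g[7:12])
  single <- nea_test(net, a, f, "direct", n_perm = 25, seed = 9)
  tab <- nea_matrix(net, list(a), list(f), "direct", n_perm = 25, seed = 9)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_obs, single$n_obs)
  expect_equal(tab$z, single$z)
  expect_equal(tab$mean, single$null$mean)

  ags <- lapply(1:3, function(i) gene_set(paste0("a", i),
                                          sample(net$nodes, 5)))
  fgs <- lapply(1:4, function(i) gene_set(paste0("f", i),
                                          sample(net$nodes, 5)))
  tab2 <- nea_matrix(net, ags, fgs, n_perm = 10, seed = 1,
                     include_ags_ags = TRUE)
  expect_equal(nrow(tab2), 3L * 4L + choose(3, 2))
})

test_that("nea_matrix separates planted pairs from decoys (seed 7)", {
  sim <- simulate_network(seed = 7)
  net <- sim$network
  mod <- sim$truth$modules$module1
  set.seed(7)
  rnd <- sample(setdiff(net$nodes, mod), 24)
  ags <- gene_set("ags", mod[1:15])
  fgs <- list(gene_set("true1", mod[16:27]), gene_set("true2", mod[28:40]),
              gene_set("decoy1", rnd[1:12]), gene_set("decoy2", rnd[13:24]))
  tab <- nea_matrix(net, list(ags), fgs, "direct", n_perm = 50, seed = 77)
  sig <- tab$significant
  names(sig) <- tab$fgs
  expect_true(all(sig[c("true1", "true2")]))
  expect_false(any(sig[c("decoy1", "decoy2")]))
})

test_that("left-tail FDR follows its defining formula", {
  res <- data.frame(ags = c("a", "a"), fgs = c("f1", "f2"), z = c(-3, 3))
  out <- estimate_fdr(res, "left_tail")
  expect_equal(out$fdr[out$z == 3], 1) # one depleted vs one enriched
  res2 <- data.frame(ags = "a", fgs = c("f1", "f2", "f3"),
                     z = c(-1, -2, -3))
  expect_equal(estimate_fdr(res2, "left_tail")$fdr, c(1, 1, 1))
  # undefined z gets FDR 1
  res3 <- data.frame(ags = "a", fgs = c("f1", "f2"), z = c(2, NA))
  expect_equal(estimate_fdr(res3, "left_tail")$fdr[2], 1)
})

test_that("random-set FDR separates planted signal from null", {
  sim <- simulate_network(seed = 5)
  net <- sim$network
  mod <- sim$truth$modules$module1
  set.seed(5)
  rnd <- sample(setdiff(net$nodes, mod), 24)
  ags_list <- list(gene_set("planted", mod[1:12]), gene_set("null", rnd[1:12]))
  fgs_list <- list(gene_set("target", mod[13:24]), gene_set("far", rnd[13:24]))
  tab <- nea_matrix(net, ags_list, fgs_list, n_perm = 20, seed = 31,
                    fdr_method = "random_sets", n_random = 5)
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  planted <- tab$fdr[tab$ags == "planted" & tab$fgs == "target"]
  null_rows <- tab$fdr[tab$ags == "null" | tab$fgs == "far"]
  expect_lt(planted, 0.1)
  expect_true(all(null_rows > planted))
  expect_error(estimate_fdr(tab, "random_sets"), "network")
})

test_that("pathway_connectivity_filter applies both boundaries", {
  res <- data.frame(ags = "a", fgs = c("f1", "f2", "f3"),
                    n_obs = c(5, 4, 10), z = c(2.1, 9, 1.9))
  kept <- pathway_connectivity_filter(res)
  expect_equal(kept$fgs, "f1") # n_obs >= 5 AND z > 2
  expect_equal(nrow(pathway_connectivity_filter(res[0, ])), 0L)
})
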