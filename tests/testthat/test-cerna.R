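test_that("pearson_edge handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  e1 <- pearson_edge(x, x)
  expect_equal(e1$r, 1)
  expect_equal(e1$p, 0)
  e2 <- pearson_edge(x, -x + 3)
  expect_equal(e2$r, -1)
  expect_equal(e2$p, 0)
  expect_error(pearson_edge(x, x[1:3]), "equal length")
  expect_error(pearson_edge(x, rep(2, 5)), "zero variance")
  expect_error(pearson_edge(c(1, 2), c(3, 4)), "at least 3")
})

test_that("pearson p matches cor.test and the permutation oracle", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      x <- rnorm(n)
      y <- rnorm(n) + 0.5 * x
      e <- pearson_edge(x, y)
      ct <- cor.test(x, y)
      expect_equal(e$r, unname(ct$estimate))
      expect_equal(e$p, ct$p.value, tolerance = 1e-12)
    }
  })
  # exact-ish permutation check at n = 8
  withr::with_seed(29, {
    x <- rnorm(8)
    y <- rnorm(8) + x
  })
  e <- pearson_edge(x, y)
  expect_lt(abs(e$p - perm_p_pearson(x, y, B = 1e5)), 0.02)
})

test_that("correlation filters apply sign and threshold rules", {
  n <- 10
  base <- seq_len(n)
  expr <- rbind(
    mi1 = -base + rnorm(n, sd = 1e-3),
    mi2 = base + rnorm(n, sd = 1e-3),   # positively correlated miRNA
    t1 = base,
    t2 = -0.5 * base + 3 + rnorm(n, sd = 2.5)  # weakly anti-correlated
  )
  colnames(expr) <- sprintf("s%02d", 1:n)
  pairs <- tibble::tibble(mirna_id = c("mi1", "mi2", "mi1"),
                          target_id = c("t1", "t1", "t2"))
  kept <- filter_mirna_target(pairs, expr, expr)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mirna_id, "mi1")
  expect_lt(kept$r, -0.9)
  expect_error(filter_mirna_target(tibble::tibble(mirna_id = "nope",
                                                  target_id = "t1"),
                                   expr, expr), "missing")

  co <- withr::with_seed(61, rbind(
    ce_hi = base + rnorm(n, sd = 1e-3),
    ce_lo = sample(base),  # shuffled: uncorrelated with g
    ce_neg = -base,
    g = base
  ))
  colnames(co) <- colnames(expr)
  kept2 <- filter_coexpression(c("ce_hi", "ce_lo", "ce_neg"), "g", co)
  expect_equal(kept2$ce_id, "ce_hi")
  expect_gt(kept2$r, 0.8)
})

test_that("the sponge test equals exhaustive enumeration and is monotone", {
  expect_equal(hypergeom_sponge_test(10, 4, 5, 0), 1)
  expect_equal(hypergeom_sponge_test(10, 10, 6, 6), 1)  # K = N forces overlap
  expect_equal(hypergeom_sponge_test(20, 5, 6, 3), hyper_enum(20, 5, 6, 3),
               tolerance = 1e-12)
  expect_equal(round(hypergeom_sponge_test(20, 5, 6, 3), 4), 0.1313)

  withr::with_seed(37, {
    for (i in 1:200) {
      N <- sample(1:25, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_sponge_test(N, K, n, k), hyper_enum(N, K, n, k),
                   tolerance = 1e-12)
    }
  })
  ks <- 0:5
  ps <- hypergeom_sponge_test(20, 8, 10, ks)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_sponge_test(10, 5, 5, 6), "inconsistent")
  expect_error(hypergeom_sponge_test(10, 11, 5, 2), "inconsistent")
})

# Near-noiseless one-triplet fixture: the network must be exactly the
# planted star (1 ce + 3 miRNA + 1 mRNA; 3 + 3 + 1 edges). Background DE
# features keep the hypergeometric population non-degenerate; near zero
# noise none of them carries the binding evidence needed for an edge.
one_triplet_bundle <- function(seed = 3) {
  cfg <- pipeline_config(
    sim = small_sim_config(seed = seed, n_planted_triplets = 1,
                           n_hub_mrnas = 0, samples_per_group = 6,
                           n_features = c(mRNA = 80, lncRNA = 30,
                                          circRNA = 24, miRNA = 80),
                           noise_sd = 0, nb_dispersion = 0.005),
    rng_seed = seed, n_perm = 100
  )
  suppressMessages(run_pipeline(cfg))
}

test_that("a single planted triplet yields the 5-node, 7-edge star", {
  b <- one_triplet_bundle()
  net <- b$networks[[b$dataset$truth_triplets$ce_class[1]]]
  tr <- b$dataset$truth_triplets
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 7)
  s <- network_summary(net)
  expect_equal(s$n_ce_mrna_edges, 1)
  expect_equal(sum(net$nodes$rna_type == "miRNA"), 3)
  expect_setequal(
    net$nodes$id,
    c(tr$ce_id, tr$mrna_id, unlist(tr$mirna_ids))
  )
  # the other sponge class has nothing planted, hence an empty network
  other <- setdiff(c("lncRNA", "circRNA"), tr$ce_class)
  expect_equal(nrow(b$networks[[other]]$edges), 0)
})

test_that("network summaries are consistent and order-invariant", {
  b <- one_triplet_bundle()
  net <- b$networks[[b$dataset$truth_triplets$ce_class[1]]]
  s <- network_summary(net)
  expect_equal(sum(s$nodes$n), s$n_nodes)
  expect_equal(sum(s$edges$n), s$n_edges)
  shuffled <- net
  shuffled$nodes <- net$nodes[rev(seq_len(nrow(net$nodes))), ]
  s2 <- network_summary(shuffled)
  expect_equal(dplyr::arrange(s2$nodes, rna_type, direction),
               dplyr::arrange(s$nodes, rna_type, direction))

  empty <- spongenet:::empty_network("lncRNA", list())
  se <- network_summary(empty)
  expect_equal(se$n_nodes, 0)
  expect_equal(se$n_edges, 0)
})

test_that("pairs sharing fewer than three filtered miRNAs are excluded", {
  b <- one_triplet_bundle()
  tr <- b$dataset$truth_triplets
  net_args <- list(
    de_tables = b$de, target_pairs = b$target_pairs, expr = b$expr,
    ce_class = tr$ce_class[1]
  )
  # raising the shared-miRNA floor above the planted count empties the net
  net4 <- do.call(assemble_network, c(net_args, min_shared_mirnas = 4))
  expect_equal(nrow(net4$edges), 0)
  net3 <- do.call(assemble_network, c(net_args, min_shared_mirnas = 3))
  expect_equal(nrow(net3$edges), 7)
})

test_that("empty differential-expression input gives an empty valid network", {
  b <- one_triplet_bundle()
  de_none <- lapply(b$de, function(d) {
    d$direction <- "ns"
    d
  })
  net <- assemble_network(de_none, b$target_pairs, b$expr, "lncRNA")
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("hub intersection is plain sorted set arithmetic", {
  mk <- function(ids, ce_class = "lncRNA") {
    net <- spongenet:::empty_network(ce_class, list())
    net$nodes <- tibble::tibble(id = ids, rna_type = "mRNA",
                                direction = "up")
    net
  }
  expect_equal(intersect_hub_mrnas(mk(c("a", "b", "c")), mk(c("b", "c", "d"))),
               c("b", "c"))
  expect_equal(intersect_hub_mrnas(mk(c("a")), mk(c("b"))), character(0))
  expect_equal(intersect_hub_mrnas(mk(c("c", "a")), mk(c("a", "c"))),
               c("a", "c"))
})

test_that("network export round-trips and writes well-formed SIF/GraphML", {
  b <- one_triplet_bundle()
  net <- b$networks[[b$dataset$truth_triplets$ce_class[1]]]
  dir <- withr::local_tempdir()
  files <- export_network(net, dir, name = "nw")
  expect_error(export_network(net, dir, formats = "dot"), "unknown format")

  back <- read_network(dir, name = "nw", ce_class = net$ce_class)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  sif <- readLines(file.path(dir, "nw.sif"))
  expect_equal(length(sif), 7)
  expect_true(all(lengths(strsplit(sif, "\t")) == 3))

  g <- igraph::read_graph(file.path(dir, "nw.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 7)
  expect_setequal(igraph::vertex_attr(g, "rna_type"), net$nodes$rna_type)

  empty <- spongenet:::empty_network("lncRNA", list())
  export_network(empty, dir, name = "empty", formats = "sif")
  expect_equal(length(readLines(file.path(dir, "empty.sif"))), 0)
})

test_that("tightening any threshold never adds nodes or edges", {
  key <- function(net) paste(net$edges$id_a, net$edges$id_b,
                             net$edges$edge_type)
  for (seed in 1:4) {
    cfg <- pipeline_config(sim = small_sim_config(seed = seed), rng_seed = seed,
                           n_perm = 100)
    b <- suppressMessages(run_pipeline(cfg))
    for (cl in c("lncRNA", "circRNA")) {
      base_args <- list(de_tables = b$de, target_pairs = b$target_pairs,
                        expr = b$expr, ce_class = cl)
      base <- do.call(assemble_network, base_args)
      tighter <- list(
        list(r_max = -0.95), list(r_min = 0.9), list(p_max = 0.01),
        list(min_shared_mirnas = 4), list(p_hyper_cut = 0.005)
      )
      for (tw in tighter) {
        net <- do.call(assemble_network, c(base_args, tw))
        expect_true(all(key(net) %in% key(base)))
        expect_true(all(net$nodes$id %in% base$nodes$id))
      }
    }
  }
})
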