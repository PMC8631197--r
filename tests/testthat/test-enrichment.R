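test_that("over-representation shares the hypergeometric kernel", {
  pop <- sprintf("g%02d", 1:20)
  study <- pop[1:6]
  set <- c(pop[c(1, 2, 3, 10, 15)])  # K = 5, k = 3
  r <- ora_test(study, pop, set)
  expect_equal(r$N, 20)
  expect_equal(r$K, 5)
  expect_equal(r$n, 6)
  expect_equal(r$k, 3)
  expect_equal(r$p, hyper_enum(20, 5, 6, 3), tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.1313)

  disjoint <- ora_test(study, pop, pop[10:12])
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$p, 1)

  all_in <- ora_test(pop, pop, set)
  expect_equal(all_in$k, all_in$K)
  expect_equal(all_in$p, 1)

  expect_error(ora_test(c(study, "missing"), pop, set), "contained")
  expect_error(ora_test(study, character(0), set), "non-empty")
})

test_that("ora_batch adjusts with BH and sorts by p", {
  pop <- sprintf("g%02d", 1:40)
  study <- pop[1:10]
  gmt <- tibble::tibble(
    name = c("hit_set", "null_set", "dup_set"),
    description = "d",
    genes = list(pop[1:8], pop[30:40], pop[1:8])
  )
  out <- ora_batch(study, pop, gmt)
  expect_equal(out$padj, bh_bruteforce(out$p)[order(order(out$p))],
               tolerance = 1e-12)
  expect_true(!is.unsorted(out$p))
  # identical sets get identical p
  expect_equal(out$p[out$set_name == "hit_set"],
               out$p[out$set_name == "dup_set"])
  single <- ora_batch(study, pop, gmt[1, ])
  expect_equal(single$padj, single$p)
  expect_error(ora_batch(study, pop, gmt[0, ]), "empty")
})

test_that("feature ranking is deterministic with lexicographic ties", {
  de <- tibble::tibble(feature_id = c("b", "a", "c"), stat = c(2, -1, 2))
  r <- rank_features(de)
  expect_equal(r$feature_id, c("b", "c", "a"))
  expect_equal(rank_features(de[c(3, 1, 2), ]), r)
  expect_error(rank_features(tibble::tibble(feature_id = "a", stat = NA)),
               "finite")
})

test_that("the running sum hits the textbook extremes", {
  ranked <- tibble::tibble(feature_id = letters[1:10], score = 10:1)
  top <- gsea_es(ranked, "a", weight = 0)
  expect_equal(top$es, 1)

  r4 <- tibble::tibble(feature_id = c("w", "x", "y", "z"), score = 4:1)
  bottom <- gsea_es(r4, "z", weight = 0)
  # running sum -1/3, -2/3, -1, then +1 at the hit: extremum is -1
  expect_equal(bottom$es, -1)
  expect_equal(bottom$running_sum, c(-1 / 3, -2 / 3, -1, 0))

  expect_error(gsea_es(ranked, "not_there"), "no member")
  expect_error(gsea_es(ranked, letters[1:10]), "whole ranked list")
})

test_that("weight-0 |ES| equals the KS statistic and flips with the ranking", {
  withr::with_seed(71, {
    for (i in 1:25) {
      N <- sample(30:120, 1)
      ids <- sprintf("f%03d", seq_len(N))
      scores <- sort(rnorm(N), decreasing = TRUE)
      ranked <- tibble::tibble(feature_id = ids, score = scores)
      set <- sample(ids, sample(3:15, 1))
      es <- gsea_es(ranked, set, weight = 0)
      hit_ranks <- which(ranked$feature_id %in% set)
      miss_ranks <- setdiff(seq_len(N), hit_ranks)
      ks <- suppressWarnings(ks.test(hit_ranks, miss_ranks))
      expect_equal(abs(es$es), unname(ks$statistic), tolerance = 1e-9)

      rev_es <- gsea_es(ranked[N:1, ], set, weight = 0)
      expect_equal(rev_es$es, -es$es, tolerance = 1e-12)

      # conservation: the running sum returns to zero
      expect_lt(abs(es$running_sum[N]), 1e-9)
    }
  })
})

test_that("weight-1 scores agree with the reference implementation", {
  withr::with_seed(73, {
    for (i in 1:10) {
      N <- 80
      ranked <- tibble::tibble(
        feature_id = sprintf("f%03d", 1:N),
        score = sort(rnorm(N, sd = 2), decreasing = TRUE)
      )
      set <- sample(ranked$feature_id, 10)
      es <- gsea_es(ranked, set, weight = 1)
      ref <- fgsea::calcGseaStat(
        setNames(ranked$score, ranked$feature_id),
        selectedStats = which(ranked$feature_id %in% set),
        gseaParam = 1
      )
      expect_equal(es$es, ref, tolerance = 1e-9)
    }
  })
})

test_that("permutation significance is seeded and detects planted sets", {
  ranked <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:200),
    score = sort(rnorm(200, sd = 1.5), decreasing = TRUE)
  )
  top_set <- ranked$feature_id[1:15]  # all members in the top decile
  r1 <- gsea_permutation(ranked, top_set, n_perm = 1000, seed = 5)
  r2 <- gsea_permutation(ranked, top_set, n_perm = 1000, seed = 5)
  expect_equal(glance(r1), glance(r2))
  expect_lte(r1$p_perm, 0.01)
  expect_gt(r1$nes, 1)

  r3 <- gsea_permutation(ranked, top_set, n_perm = 1000, seed = 6)
  expect_lte(r3$p_perm, 0.01)
  expect_error(gsea_permutation(ranked, top_set, n_perm = 50), "n_perm")
})

test_that("random sets give calibrated permutation p-values", {
  ranked <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:300),
    score = sort(rnorm(300), decreasing = TRUE)
  )
  withr::with_seed(81, {
    ps <- vapply(1:100, function(i) {
      set <- sample(ranked$feature_id, 20)
      gsea_permutation(ranked, set, n_perm = 200, seed = 1000 + i)$p_perm
    }, numeric(1))
  })
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.09)
})

test_that("gsea_batch computes a cross-set FDR on the shared null", {
  ranked <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:150),
    score = sort(rnorm(150, sd = 2), decreasing = TRUE)
  )
  gmt <- tibble::tibble(
    name = c("top", "random", "bottom"),
    description = "d",
    genes = list(ranked$feature_id[1:10],
                 withr::with_seed(9, sample(ranked$feature_id, 10)),
                 ranked$feature_id[141:150])
  )
  out <- gsea_batch(ranked, gmt, n_perm = 500, seed = 11)
  expect_setequal(out$set_name, gmt$name)
  expect_gt(out$nes[out$set_name == "top"], 0)
  expect_lt(out$nes[out$set_name == "bottom"], 0)
  expect_lt(out$fdr[out$set_name == "top"], 0.05)
  expect_lt(out$fdr[out$set_name == "bottom"], 0.05)
  expect_gt(out$fdr[out$set_name == "random"],
            out$fdr[out$set_name == "top"])
  out2 <- gsea_batch(ranked, gmt, n_perm = 500, seed = 11)
  expect_equal(out, out2)
})
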