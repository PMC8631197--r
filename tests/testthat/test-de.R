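nb_table <- function(mu, n_per_group, size, seed = 1, lfc = 0) {
  withr::with_seed(seed, {
    nf <- length(mu)
    muB <- mu * 2^lfc
    m <- cbind(
      matrix(rnbinom(nf * n_per_group, mu = rep(mu, n_per_group), size = size),
             nrow = nf),
      matrix(rnbinom(nf * n_per_group, mu = rep(muB, n_per_group), size = size),
             nrow = nf)
    )
  })
  colnames(m) <- sprintf("s%02d", seq_len(2 * n_per_group))
  dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%04d", seq_along(mu)),
                   class = "mRNA", length = 1000),
    tibble::as_tibble(m)
  )
}

test_that("identical group distributions give log2FC 0 and p 1", {
  x <- nb_table(mu = c(50, 500, 2000), n_per_group = 3, size = 10)
  # duplicate the first group's samples as the second group
  x[, 7:9] <- x[, 4:6]
  res <- nb_wald_test(x, rep(c("A", "B"), each = 3))
  expect_equal(res$log2FC, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("swapping group labels negates log2FC and keeps p", {
  x <- nb_table(mu = rep(c(100, 800), each = 20), n_per_group = 4, size = 10,
                lfc = 1.5, seed = 3)
  g <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  swapped <- factor(rep(c("B", "A"), each = 4), levels = c("A", "B"))
  r1 <- nb_wald_test(x, g)
  r2 <- nb_wald_test(x, swapped)
  expect_equal(r2$log2FC, -r1$log2FC)
  expect_equal(r2$p, r1$p)
  # relabeling samples within a group changes nothing
  x3 <- x[, c(1:3, 5, 4, 6, 7, 9, 8, 10, 11)]
  names(x3) <- names(x)
  r3 <- nb_wald_test(x3, g)
  expect_equal(r3$p, r1$p)
})

test_that("the Wald test is calibrated under the null", {
  mu <- withr::with_seed(11, exp(runif(1000, log(50), log(2000))))
  x <- nb_table(mu, n_per_group = 5, size = 10, seed = 11)
  res <- nb_wald_test(x, rep(c("A", "B"), each = 5))
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.07)
})

test_that("a planted 8-fold change is detected with high power", {
  # 300 planted features among 700 nulls, so size factors stay anchored
  mu <- rep(c(100, 400, 1500), length.out = 1000)
  lfc <- rep(c(3, 0), times = c(300, 700))
  withr::with_seed(5, {
    m <- cbind(
      matrix(rnbinom(1000 * 6, mu = rep(mu, 6), size = 100), nrow = 1000),
      matrix(rnbinom(1000 * 6, mu = rep(mu * 2^lfc, 6), size = 100),
             nrow = 1000)
    )
  })
  colnames(m) <- sprintf("s%02d", 1:12)
  x <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%04d", 1:1000), class = "mRNA",
                   length = 1000),
    tibble::as_tibble(m)
  )
  res <- nb_wald_test(x, rep(c("A", "B"), each = 6))
  planted <- res[1:300, ]
  expect_gt(mean(planted$p < 1e-3), 0.95)
  expect_gt(mean(planted$log2FC), 2.6)
  expect_lt(mean(planted$log2FC), 3.4)
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(17, {
    for (i in 1:50) {
      p <- runif(sample(1:200, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_bruteforce(p))
      expect_true(all(adj >= p))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("call_de applies the two-threshold rule and counts add up", {
  rec <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    class = "mRNA", base_mean = 10,
    log2FC = c(1.5, -0.8, -2.0, 0.2),
    se = 0.1, stat = 1,
    p = c(0.001, 1e-6, 0.01, 0.9),
    padj = c(0.01, 1e-6, 0.049, 0.95)
  )
  out <- call_de(rec, lfc_cut = 1, padj_cut = 0.05)
  expect_equal(out$direction, c("up", "ns", "down", "ns"))
  g <- glance(out)
  expect_equal(g$n_de, g$n_up + g$n_down)
  # feature order does not change the counts
  out2 <- call_de(rec[c(3, 1, 4, 2), ], lfc_cut = 1, padj_cut = 0.05)
  expect_equal(glance(out2), g)
  expect_error(call_de(rec, lfc_cut = -1), "lfc_cut")
  expect_error(call_de(rec, padj_cut = 0), "padj_cut")
})

test_that("the looser FDR-0.1 convention is a superset of the default", {
  mu <- rep(300, 200)
  x <- nb_table(mu, n_per_group = 4, size = 5, seed = 9, lfc = 1)
  sf <- setNames(rep(1, 8), sprintf("s%02d", 1:8))
  res <- nb_wald_test(x, rep(c("A", "B"), each = 4), sf = sf)
  strict <- call_de(res, lfc_cut = 1, padj_cut = 0.05)
  loose <- call_de(res, lfc_cut = 1, padj_cut = 0.1)
  de_strict <- strict$feature_id[strict$direction != "ns"]
  de_loose <- loose$feature_id[loose$direction != "ns"]
  expect_true(all(de_strict %in% de_loose))
})
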