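test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(samples_per_group = 0), "samples_per_group")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(shared_mirnas_per_triplet = 2), ">= 3")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(
    sim_config(n_planted_triplets = 200,
               n_features = c(mRNA = 10, lncRNA = 10, circRNA = 10,
                              miRNA = 10)),
    "not enough"
  )
})

test_that("identical seeds give identical datasets", {
  a <- simulate_experiment(small_sim_config(seed = 7))
  b <- simulate_experiment(small_sim_config(seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth_triplets, b$truth_triplets)
  c <- simulate_experiment(small_sim_config(seed = 8))
  expect_false(identical(a$counts$mRNA, c$counts$mRNA))
})

test_that("zero DE fraction and no triplets mark every feature non-DE", {
  sim <- simulate_experiment(
    small_sim_config(seed = 2, de_fraction = 0, n_planted_triplets = 0)
  )
  expect_true(all(!sim$truth_de$is_de))
  expect_true(all(sim$truth_de$true_log2fc == 0))
  expect_equal(nrow(sim$truth_triplets), 0)
  expect_equal(nrow(sim$truth_sites), 0)
})

test_that("planted couplings exceed the correlation thresholds at low noise", {
  # near-noiseless limit: both generator noise sources taken to (near) zero
  sim <- simulate_experiment(
    sim_config(rng_seed = 13, noise_sd = 0, nb_dispersion = 0.005)
  )
  e <- log2(do.call(rbind, lapply(sim$counts, spongenet:::count_values)) + 1)
  tr <- sim$truth_triplets
  for (i in seq_len(nrow(tr))) {
    expect_gt(cor(e[tr$ce_id[i], ], e[tr$mrna_id[i], ]), 0.8)
    for (m in tr$mirna_ids[[i]]) {
      expect_lt(cor(e[m, ], e[tr$ce_id[i], ]), -0.9)
      expect_lt(cor(e[m, ], e[tr$mrna_id[i], ]), -0.9)
    }
  }
})

test_that("counts are over-dispersed relative to Poisson", {
  sim <- simulate_experiment(
    sim_config(rng_seed = 4, de_fraction = 0, n_planted_triplets = 0,
               n_features = c(mRNA = 600, lncRNA = 10, circRNA = 10,
                              miRNA = 10))
  )
  m <- spongenet:::count_values(sim$counts$mRNA)
  v <- apply(m, 1, var)
  mu <- rowMeans(m)
  # aggregate mean-variance relation: var > mean for dispersion > 0
  expect_gt(mean(v > mu), 0.95)
  # and the implied dispersion is near the configured one
  alpha_hat <- median((v - mu) / mu^2)
  expect_gt(alpha_hat, 0.02)
  expect_lt(alpha_hat, 0.1)
})

test_that("planted fold changes are calibrated", {
  sim <- simulate_experiment(sim_config(rng_seed = 6))
  treated <- sim$samples$group == "treated"
  de <- sim$truth_de[sim$truth_de$is_de, ]
  e <- do.call(rbind, lapply(sim$counts, spongenet:::count_values))
  emp <- log2(rowMeans(e[de$feature_id, treated, drop = FALSE]) + 0.5) -
    log2(rowMeans(e[de$feature_id, !treated, drop = FALSE]) + 0.5)
  expect_lt(abs(mean(emp * sign(de$true_log2fc)) -
                  sim$config$de_log2fc_magnitude), 0.3)
})

test_that("scanning generated sequences recovers exactly the recorded sites", {
  sim <- simulate_experiment(small_sim_config(seed = 31))
  planted_mirnas <- unique(unlist(sim$truth_triplets$mirna_ids))
  found <- build_target_table(sim$sequences$mirna[planted_mirnas],
                              sim$sequences$target, min_class = "6mer")
  sites <- attr(found, "sites")
  truth <- sim$truth_sites
  expect_tables_equal(
    sites[c("mirna_id", "target_id", "start", "end", "site_class")],
    truth[c("mirna_id", "target_id", "start", "end", "site_class")]
  )
})

test_that("target sequences honor the requested site class", {
  for (cls in c("6mer", "7mer-m8")) {
    sim <- simulate_experiment(small_sim_config(seed = 41, site_class = cls))
    expect_true(all(sim$truth_sites$site_class == cls))
    tr <- sim$truth_triplets[1, ]
    pat <- seed_patterns(sim$sequences$mirna[[tr$mirna_ids[[1]][1]]])[[cls]]
    expect_true(grepl(pat, sim$sequences$target[[tr$ce_id]], fixed = TRUE))
  }
  expect_true(all(strsplit(paste(simulate_experiment(
    small_sim_config(seed = 42))$sequences$target, collapse = ""),
    "")[[1]] %in% c("A", "C", "G", "U")))
})
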