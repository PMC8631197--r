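#' Configuration for the synthetic two-condition experiment
#'
#' Defines the study conditions the generator emulates: a two-group
#' (control vs treated) design with negative-binomial counts for four RNA
#' classes, a stated fraction of differentially expressed features per
#' class, and planted ceRNA triplets — a sponge (lncRNA or circRNA) and an
#' mRNA positively co-expressed through a shared latent factor, both
#' anti-regulated by the triplet's shared miRNAs, with real seed sites
#' embedded in the target sequences.
#'
#' @param samples_per_group Biological replicates per condition (default 6;
#'   replicate counts in this design space are rarely larger).
#' @param n_features Named integer vector: features per RNA class.
#' @param nb_mean_range Range of per-feature baseline mean counts; baselines
#'   are drawn log-uniformly within it.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha\mu^2}), shared across features.
#' @param de_fraction Fraction of features per class that are differentially
#'   expressed (scalar or named per class), in \[0, 1\].
#' @param de_log2fc_magnitude Absolute true log2 fold change of DE features.
#' @param n_planted_triplets Number of planted sponge triplets, alternating
#'   lncRNA- and circRNA-based.
#' @param shared_mirnas_per_triplet miRNAs shared by each triplet (>= 3,
#'   matching the downstream network rule).
#' @param n_hub_mrnas mRNAs planted in both a lncRNA- and a circRNA-triplet,
#'   giving the hub-intersection step a known truth.
#' @param coupling_log2_sd Magnitude (log2 units) of the per-sample latent
#'   sponge factor added to sponge and mRNA and subtracted from the shared
#'   miRNAs.
#' @param noise_sd Extra log2-scale Gaussian noise per feature and sample.
#' @param site_class Seed-site class embedded in planted target sequences.
#' @param seq_length Length (nt) of generated target sequences.
#' @param mirna_length Length (nt) of generated miRNA sequences.
#' @param rng_seed Integer seed; identical configs give identical datasets.
#' @return A validated `sim_config` list.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(samples_per_group = 6,
                       n_features = c(mRNA = 400, lncRNA = 200,
                                      circRNA = 150, miRNA = 150),
                       nb_mean_range = c(50, 2000),
                       nb_dispersion = 0.05,
                       de_fraction = 0.2,
                       de_log2fc_magnitude = 3,
                       n_planted_triplets = 30,
                       shared_mirnas_per_triplet = 3,
                       n_hub_mrnas = 5,
                       coupling_log2_sd = 1.1,
                       noise_sd = 0.1,
                       site_class = "8mer",
                       seq_length = 500,
                       mirna_length = 22,
                       rng_seed = 1) {
  classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
  if (length(de_fraction) == 1) {
    de_fraction <- setNames(rep(de_fraction, 4), classes)
  }
  cfg <- list(
    samples_per_group = samples_per_group, n_features = n_features,
    nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_log2fc_magnitude = de_log2fc_magnitude,
    n_planted_triplets = n_planted_triplets,
    shared_mirnas_per_triplet = shared_mirnas_per_triplet,
    n_hub_mrnas = n_hub_mrnas, coupling_log2_sd = coupling_log2_sd,
    noise_sd = noise_sd, site_class = site_class, seq_length = seq_length,
    mirna_length = mirna_length, rng_seed = rng_seed
  )
  if (samples_per_group < 1) abort("samples_per_group must be >= 1")
  if (!all(classes %in% names(n_features)) || any(n_features < 1)) {
    abort("n_features must name all four RNA classes with positive counts")
  }
  if (nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (any(de_fraction < 0 | de_fraction > 1)) {
    abort("de_fraction must lie in [0, 1]")
  }
  if (de_log2fc_magnitude <= 0) abort("de_log2fc_magnitude must be > 0")
  if (n_planted_triplets < 0) abort("n_planted_triplets must be >= 0")
  if (n_planted_triplets > 0 && shared_mirnas_per_triplet < 3) {
    abort("shared_mirnas_per_triplet must be >= 3")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!site_class %in% SITE_CLASSES) abort("unknown site_class")
  need_mirna <- n_planted_triplets * shared_mirnas_per_triplet
  if (need_mirna > n_features[["miRNA"]]) {
    abort("not enough miRNA features for the requested triplets")
  }
  if (n_planted_triplets > 0) {
    n_lnc <- ceiling(n_planted_triplets / 2)
    n_circ <- floor(n_planted_triplets / 2)
    if (n_lnc > n_features[["lncRNA"]] || n_circ > n_features[["circRNA"]]) {
      abort("not enough lncRNA/circRNA features for the requested triplets")
    }
    if (n_planted_triplets - min(n_hub_mrnas, n_circ) > n_features[["mRNA"]]) {
      abort("not enough mRNA features for the requested triplets")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-condition multi-class RNA-seq experiment
#'
#' Draws negative-binomial counts for mRNA, lncRNA, circRNA and miRNA under
#' a two-group design with known differential expression and planted ceRNA
#' structure, and generates miRNA/target sequences with embedded seed sites
#' so that every downstream stage (normalization, DE, MRE scanning,
#' correlation filters, the sponge test, enrichment) has a ground truth.
#'
#' The count model for feature i, sample j is
#' \eqn{c_{ij} \sim NB(\mu_{ij}, \alpha)} with
#' \deqn{\log_2 \mu_{ij} = b_i + \beta_i 1[j \in treated]
#'   + s_i \, \lambda z_{t(i),j} + \epsilon_{ij},}
#' where \eqn{b_i} is the log-uniform baseline, \eqn{\beta_i} the true log2
#' fold change (0 for non-DE features), \eqn{z_{t,j} \sim N(0,1)} a latent
#' per-sample sponge factor for triplet t with magnitude
#' \eqn{\lambda} = `coupling_log2_sd`, sign \eqn{s_i} +1 for the sponge and
#' mRNA and −1 for the shared miRNAs, and
#' \eqn{\epsilon_{ij} \sim N(0, \mathrm{noise\_sd}^2)}. Triplet members are
#' forced DE (sponge and mRNA share the triplet direction; the miRNAs take
#' the opposite one) and their baselines are drawn from the upper half of
#' `nb_mean_range` so the planted correlations are measurable at small n.
#' The two triplets sharing a hub mRNA share one latent factor.
#'
#' @param config A [sim_config()].
#' @return A `sponge_sim` list: `counts` (one wide tibble per class),
#'   `samples` (sample sheet), `mapped_reads`, `truth_de`, `truth_triplets`,
#'   `truth_sites`, `sequences` (`$mirna`, `$target`), and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   samples_per_group = 3,
#'   n_features = c(mRNA = 40, lncRNA = 20, circRNA = 15, miRNA = 30),
#'   n_planted_triplets = 2, n_hub_mrnas = 1
#' ))
#' glance(sim)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  spg <- cfg$samples_per_group
  n_samp <- 2L * spg
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = rep(c("control", "treated"), each = spg)
  )
  treated <- samples$group == "treated"

  classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
  prefix <- c(mRNA = "mRNA", lncRNA = "lnc", circRNA = "circ", miRNA = "miR")
  ids <- purrr::imap(cfg$n_features[classes], function(n, cl) {
    sprintf("%s_%04d", prefix[[cl]], seq_len(n))
  })

  feat <- purrr::imap(ids, function(v, cl) tibble(feature_id = v, class = cl)) |>
    bind_rows()
  nf <- nrow(feat)
  feat$base_log2 <- runif(nf, log2(cfg$nb_mean_range[1]),
                          log2(cfg$nb_mean_range[2]))
  feat$true_log2fc <- 0
  for (cl in classes) {
    idx <- which(feat$class == cl)
    n_de <- floor(cfg$de_fraction[[cl]] * length(idx))
    if (n_de > 0) {
      pick <- sample(idx, n_de)
      feat$true_log2fc[pick] <- sample(c(-1, 1), n_de, replace = TRUE) *
        cfg$de_log2fc_magnitude
    }
  }

  planted <- plan_triplets(cfg, ids)
  triplets <- planted$triplets
  # force triplet members DE with consistent directions, high baselines
  if (nrow(triplets) > 0) {
    hi <- log2(cfg$nb_mean_range)
    lo_hi <- hi[1] + 0.75 * (hi[2] - hi[1])  # top quartile: keep shot noise small
    for (i in seq_len(nrow(triplets))) {
      sgn <- if (triplets$direction[i] == "up") 1 else -1
      members <- c(triplets$ce_id[i], triplets$mrna_id[i])
      mi <- triplets$mirna_ids[[i]]
      j <- match(c(members, mi), feat$feature_id)
      feat$true_log2fc[j] <- c(rep(sgn, 2), rep(-sgn, length(mi))) *
        cfg$de_log2fc_magnitude
      feat$base_log2[j] <- pmax(feat$base_log2[j], runif(length(j), lo_hi, hi[2]))
    }
  }

  # latent sponge factors (hub-paired triplets share one)
  log2mu <- outer(feat$base_log2, rep(1, n_samp)) +
    outer(feat$true_log2fc, as.numeric(treated))
  if (nrow(triplets) > 0) {
    z <- matrix(rnorm(nrow(triplets) * n_samp), nrow(triplets), n_samp)
    # standardize each factor across samples so the planted co-variation has
    # exactly the configured magnitude in every dataset (a low-spread draw
    # would otherwise silently weaken the planted correlations)
    z <- (z - rowMeans(z)) / apply(z, 1, sd)
    for (i in seq_len(nrow(triplets))) {
      if (!is.na(triplets$latent_of[i])) z[i, ] <- z[triplets$latent_of[i], ]
    }
    coupled <- logical(nf)  # a hub mRNA joins two triplets but couples once
    for (i in seq_len(nrow(triplets))) {
      up <- match(c(triplets$ce_id[i], triplets$mrna_id[i]), feat$feature_id)
      up <- up[!coupled[up]]
      dn <- match(triplets$mirna_ids[[i]], feat$feature_id)
      if (length(up)) {
        log2mu[up, ] <- log2mu[up, ] +
          outer(rep(cfg$coupling_log2_sd, length(up)), z[i, ])
        coupled[up] <- TRUE
      }
      log2mu[dn, ] <- log2mu[dn, ] -
        outer(rep(cfg$coupling_log2_sd, length(dn)), z[i, ])
    }
  }
  if (cfg$noise_sd > 0) {
    log2mu <- log2mu + matrix(rnorm(nf * n_samp, sd = cfg$noise_sd), nf, n_samp)
  }

  mu <- 2^log2mu
  counts <- matrix(
    rnbinom(nf * n_samp, mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
    nf, n_samp, dimnames = list(feat$feature_id, samples$sample_id)
  )

  count_tables <- purrr::map(setNames(classes, classes), function(cl) {
    idx <- feat$class == cl
    len <- switch(cl,
      mRNA = cfg$seq_length, lncRNA = cfg$seq_length,
      circRNA = NA_real_, miRNA = cfg$mirna_length
    )
    dplyr::bind_cols(
      tibble(feature_id = feat$feature_id[idx], class = cl, length = len),
      as_tibble(counts[idx, , drop = FALSE])
    )
  })
  mapped_reads <- setNames(colSums(counts), samples$sample_id)

  truth_de <- tibble(
    feature_id = feat$feature_id, class = feat$class,
    is_de = feat$true_log2fc != 0, true_log2fc = feat$true_log2fc
  )
  dataset <- structure(list(
    counts = count_tables, samples = samples, mapped_reads = mapped_reads,
    truth_de = truth_de,
    truth_triplets = triplets[c("triplet_id", "ce_id", "ce_class",
                                "mrna_id", "mirna_ids", "direction")],
    truth_sites = NULL, sequences = NULL, config = cfg
  ), class = "sponge_sim")

  seqs <- generate_mirna_sequences(ids$miRNA, cfg$mirna_length)
  dataset$sequences <- list(mirna = seqs, target = NULL)
  tg <- generate_target_sequences(dataset, cfg$site_class)
  dataset$sequences$target <- tg
  dataset$truth_sites <- attr(tg, "sites")
  dataset
}

# Triplet layout: alternate lncRNA/circRNA sponges, distinct miRNAs, the
# first n_hub mRNAs appear in one lncRNA- and one circRNA-triplet (which
# then share direction and latent factor).
plan_triplets <- function(cfg, ids) {
  nt <- cfg$n_planted_triplets
  empty <- tibble(
    triplet_id = character(), ce_id = character(), ce_class = character(),
    mrna_id = character(), mirna_ids = list(), direction = character(),
    latent_of = integer()
  )
  if (nt == 0) return(list(triplets = empty))
  spt <- cfg$shared_mirnas_per_triplet
  ce_class <- rep(c("lncRNA", "circRNA"), length.out = nt)
  lnc_idx <- which(ce_class == "lncRNA")
  circ_idx <- which(ce_class == "circRNA")
  n_hub <- min(cfg$n_hub_mrnas, length(lnc_idx), length(circ_idx))

  ce_id <- character(nt)
  ce_id[lnc_idx] <- sample(ids$lncRNA, length(lnc_idx))
  ce_id[circ_idx] <- sample(ids$circRNA, length(circ_idx))
  mir_pool <- sample(ids$miRNA, nt * spt)
  mirna_ids <- split(mir_pool, rep(seq_len(nt), each = spt))

  n_distinct_mrna <- nt - n_hub
  mrna_pool <- sample(ids$mRNA, n_distinct_mrna)
  mrna_id <- character(nt)
  latent_of <- rep(NA_integer_, nt)
  direction <- sample(c("up", "down"), nt, replace = TRUE)
  used <- 0
  if (n_hub > 0) {
    for (h in seq_len(n_hub)) {
      used <- used + 1
      mrna_id[lnc_idx[h]] <- mrna_pool[used]
      mrna_id[circ_idx[h]] <- mrna_pool[used]
      direction[circ_idx[h]] <- direction[lnc_idx[h]]
      latent_of[circ_idx[h]] <- lnc_idx[h]
    }
  }
  rest <- which(mrna_id == "")
  for (i in rest) {
    used <- used + 1
    mrna_id[i] <- mrna_pool[used]
  }
  list(triplets = tibble(
    triplet_id = sprintf("T%02d", seq_len(nt)),
    ce_id = ce_id, ce_class = ce_class, mrna_id = mrna_id,
    mirna_ids = unname(mirna_ids), direction = direction,
    latent_of = latent_of
  ))
}

# Random miRNA sequences with globally distinct 6mer seeds. To keep planted
# binding evidence unambiguous, no miRNA's seed may occur anywhere inside
# another miRNA's 8mer site pattern (whose 6-nt windows are fixed pattern
# bases that scrubbing cannot touch), and each 8mer pattern contains its own
# seed exactly once.
generate_mirna_sequences <- function(mirna_ids, len) {
  n <- length(mirna_ids)
  seqs <- character(n)
  seeds_seen <- character(0)
  windows_seen <- character(0)
  six_windows <- function(pat) {
    vapply(seq_len(nchar(pat) - 5L), function(i) substr(pat, i, i + 5L),
           character(1))
  }
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                 collapse = "")
      pat <- seed_patterns(s)
      seed <- pat[["6mer"]]
      win <- six_windows(pat[["8mer"]])
      ok <- !seed %in% seeds_seen &&
        sum(win == seed) == 1 &&
        !seed %in% windows_seen &&
        !any(win %in% seeds_seen)
      if (ok) {
        seeds_seen <- c(seeds_seen, seed)
        windows_seen <- c(windows_seen, win)
        seqs[i] <- s
        break
      }
    }
  }
  setNames(seqs, mirna_ids)
}

#' Generate target sequences with embedded seed sites
#'
#' Produces one random-background RNA sequence per mRNA, lncRNA and circRNA
#' feature. Planted targets (the sponge and mRNA of each truth triplet)
#' carry one embedded site of `site_class` per shared miRNA at a recorded
#' position; everywhere else, occurrences of any planted miRNA's 6mer seed
#' are resampled away window by window, so non-target sequences are
#' site-free for the planted miRNAs and a scan recovers exactly the
#' recorded sites.
#'
#' @param dataset A `sponge_sim` from [simulate_experiment()] (miRNA
#'   sequences must be present).
#' @param site_class One of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @return Named character vector of RNA sequences with a `"sites"`
#'   attribute: tibble `target_id`, `mirna_id`, `start`, `end`,
#'   `site_class` (0-based half-open).
#' @export
generate_target_sequences <- function(dataset, site_class = "8mer") {
  stopifnot(inherits(dataset, "sponge_sim"))
  if (!site_class %in% SITE_CLASSES) abort("unknown site_class")
  cfg <- dataset$config
  mirna_seqs <- dataset$sequences$mirna
  if (is.null(mirna_seqs)) abort("dataset has no miRNA sequences")
  L <- cfg$seq_length
  target_ids <- c(dataset$counts$mRNA$feature_id,
                  dataset$counts$lncRNA$feature_id,
                  dataset$counts$circRNA$feature_id)
  alph <- c("A", "C", "G", "U")
  seqs <- vapply(target_ids, function(id) {
    paste(sample(alph, L, replace = TRUE), collapse = "")
  }, character(1))

  trip <- dataset$truth_triplets
  planted_mirnas <- unique(unlist(trip$mirna_ids))
  # site plan: per planted target, one site per shared miRNA
  plan <- list()
  if (nrow(trip) > 0) {
    plan <- purrr::pmap(trip, function(ce_id, mrna_id, mirna_ids, ...) {
      tibble(target_id = c(rep(ce_id, length(mirna_ids)),
                           rep(mrna_id, length(mirna_ids))),
             mirna_id = rep(mirna_ids, 2))
    }) |> bind_rows()
    # a hub mRNA appears in two triplets: collapse duplicate rows per target
    plan <- distinct(plan, .data$target_id, .data$mirna_id)
  } else {
    plan <- tibble(target_id = character(), mirna_id = character())
  }

  sites <- tibble(target_id = character(), mirna_id = character(),
                  start = integer(), end = integer(), site_class = character())
  if (nrow(plan) > 0) {
    spacing <- 40L
    offset0 <- 20L
    per_target <- split(plan$mirna_id, plan$target_id)
    max_sites <- max(lengths(per_target))
    if (offset0 + max_sites * spacing > L) {
      abort("seq_length too short for the planted sites")
    }
    emb <- purrr::imap(per_target, function(mids, tid) {
      s <- seqs[[tid]]
      st <- integer(length(mids)); en <- integer(length(mids))
      for (j in seq_along(mids)) {
        pat <- seed_patterns(mirna_seqs[[mids[j]]])[[site_class]]
        pos <- offset0 + (j - 1L) * spacing  # 0-based
        substr(s, pos + 1L, pos + nchar(pat)) <- pat
        st[j] <- pos
        en[j] <- pos + nchar(pat)
      }
      seqs[[tid]] <<- s
      tibble(target_id = tid, mirna_id = mids, start = st, en = en,
             site_class = site_class)
    }) |> bind_rows() |> rename(end = "en")
    sites <- emb
  }

  if (length(planted_mirnas) > 0) {
    seeds <- vapply(planted_mirnas, function(m) {
      seed_patterns(mirna_seqs[[m]])[["6mer"]]
    }, character(1))
    prot <- split(sites[c("mirna_id", "start", "end")], sites$target_id)
    for (tid in names(seqs)) {
      seqs[[tid]] <- scrub_seeds(seqs[[tid]], seeds, prot[[tid]], alph)
    }
  }
  attr(seqs, "sites") <- arrange(sites, .data$target_id, .data$start)
  seqs
}

# Remove unintended occurrences of the planted 6mer seeds from one sequence
# by resampling a base inside each stray occurrence until none remain.
# `protected` gives the intended sites (mirna_id, start, end; 0-based).
scrub_seeds <- function(s, seeds, protected, alph, max_iter = 200) {
  pstart <- if (is.null(protected)) integer(0) else protected$start
  pend <- if (is.null(protected)) integer(0) else protected$end
  pmir <- if (is.null(protected)) character(0) else protected$mirna_id
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (mi in seq_along(seeds)) {
      h <- gregexpr(seeds[mi], s, fixed = TRUE)[[1]]
      if (h[1] == -1) next
      for (p in as.integer(h)) {  # 1-based occurrence start
        occ0 <- p - 1L
        intended <- any(pmir == names(seeds)[mi] &
                          occ0 >= pstart & (occ0 + 6L) <= pend)
        if (intended) next
        # mutate a base of the occurrence lying outside every protected site
        cand <- (occ0):(occ0 + 5L)
        free <- cand[!vapply(cand, function(x) {
          any(x >= pstart & x < pend)
        }, logical(1))]
        if (length(free) == 0) next  # fully inside another site; leave it
        pos <- free[sample.int(length(free), 1)] + 1L
        old <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(alph, old), 1)
        dirty <- TRUE
      }
    }
    if (!dirty) return(s)
  }
  abort("could not scrub planted seeds from a sequence")
}

#' @export
glance.sponge_sim <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_mrna = nrow(x$counts$mRNA), n_lncrna = nrow(x$counts$lncRNA),
    n_circrna = nrow(x$counts$circRNA), n_mirna = nrow(x$counts$miRNA),
    n_de = sum(x$truth_de$is_de),
    n_triplets = nrow(x$truth_triplets),
    n_planted_sites = if (is.null(x$truth_sites)) 0L else nrow(x$truth_sites)
  )
}

#' @export
print.sponge_sim <- function(x, ...) {
  g <- glance(x)
  cat("Synthetic two-condition ceRNA dataset\n")
  cat(sprintf("  %d samples (%d per group); features: %d mRNA, %d lncRNA, %d circRNA, %d miRNA\n",
              g$n_samples, g$n_samples / 2, g$n_mrna, g$n_lncrna,
              g$n_circrna, g$n_mirna))
  cat(sprintf("  %d DE features; %d planted triplets; %d recorded seed sites\n",
              g$n_de, g$n_triplets, g$n_planted_sites))
  invisible(x)
}
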