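# Independent oracles used across the suite. Each re-derives the quantity
# from its definition by a different route than the package implementation.

# Benjamini-Hochberg step-up from the definition: sort ascending, take the
# running minimum of p_(j) * m / j from the largest rank down, cap at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- Inf
  for (j in m:1) {
    cur <- min(cur, ps[j] * m / j)
    adj[j] <- min(cur, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric mass by exhaustive enumeration with choose().
hyper_enum <- function(N, K, n, k) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Monte-Carlo permutation p for the Pearson correlation (two-sided).
perm_p_pearson <- function(x, y, B = 1e5, seed = 1) {
  r_obs <- abs(cor(x, y))
  withr::with_seed(seed, {
    hits <- vapply(seq_len(B), function(b) {
      abs(cor(x, sample(y))) >= r_obs - 1e-12
    }, logical(1))
  })
  mean(hits)
}

# Exhaustive window-by-window seed-site scan, built on Biostrings
# reverse-complementation rather than the package's own pattern machinery.
scan_oracle <- function(mirna_seq, target_seq, mirna_id = "mirna",
                        target_id = "target") {
  rc <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }
  mi <- chartr("Tt", "Uu", toupper(mirna_seq))
  tg <- chartr("Tt", "Uu", toupper(target_seq))
  seed6 <- rc(substr(mi, 2, 7))
  m8 <- rc(substr(mi, 8, 8))
  L <- nchar(tg)
  rows <- list()
  for (p in seq_len(max(L - 5, 0))) {
    if (substr(tg, p, p + 5) != seed6) next
    has_m8 <- p > 1 && substr(tg, p - 1, p - 1) == m8
    has_a1 <- p + 6 <= L && substr(tg, p + 6, p + 6) == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1]] <- tibble::tibble(
      mirna_id = mirna_id, target_id = target_id,
      start = (p - 1L) - as.integer(has_m8),
      end = (p + 5L) + as.integer(has_a1),
      site_class = cls
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mirna_id = character(), target_id = character(),
                          start = integer(), end = integer(),
                          site_class = character()))
  }
  dplyr::bind_rows(rows)
}

# Top-down memoized Smith-Waterman with affine gaps, written as a recursion
# over (i, j, state) independently of the package's iterative matrices.
sw_oracle <- function(a_seq, b_seq, match = 5, wobble = 1, mismatch = -3,
                      gap_open = -8, gap_extend = -2) {
  a <- rev(strsplit(chartr("T", "U", toupper(a_seq)), "")[[1]])
  b <- strsplit(chartr("T", "U", toupper(b_seq)), "")[[1]]
  ps <- function(x, y) {
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    if (comp[[x]] == y) return(match)
    if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(wobble)
    mismatch
  }
  memo <- new.env(hash = TRUE)
  # best score of an alignment ENDING at (i, j) in the given state
  f <- function(i, j, state) {
    if (i < 1 || j < 1) return(if (state == "M") -Inf else -Inf)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (state == "M") {
      prev <- max(0,
                  f(i - 1, j - 1, "M"), f(i - 1, j - 1, "X"),
                  f(i - 1, j - 1, "Y"))
      prev + ps(a[i], b[j])
    } else if (state == "X") {  # gap consuming b
      max(f(i, j - 1, "M") + gap_open + gap_extend,
          f(i, j - 1, "X") + gap_extend)
    } else {                    # gap consuming a
      max(f(i - 1, j, "M") + gap_open + gap_extend,
          f(i - 1, j, "Y") + gap_extend)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      best <- max(best, f(i, j, "M"))
    }
  }
  best
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Small simulated dataset shared by IO/pipeline tests.
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    samples_per_group = 4,
    n_features = c(mRNA = 60, lncRNA = 30, circRNA = 24, miRNA = 40),
    n_planted_triplets = 4, n_hub_mrnas = 2, rng_seed = seed
  ), list(...))
  do.call(sim_config, args)
}

expect_tables_equal <- function(a, b) {
  a <- dplyr::arrange(as.data.frame(a), dplyr::across(dplyr::everything()))
  b <- dplyr::arrange(as.data.frame(b), dplyr::across(dplyr::everything()))
  expect_equal(a, b, ignore_attr = TRUE)
}
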