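#' Canonical seed patterns of a miRNA
#'
#' Target-strand search patterns for the four canonical seed-site classes.
#' With miRNA nucleotides numbered from the 5' end, the 6mer pattern is the
#' reverse complement of nucleotides 2-7; 7mer-m8 extends the pairing to
#' nucleotide 8; 7mer-A1 is the 6mer followed by an A on the target opposite
#' miRNA position 1; 8mer combines both. Site strength ranks
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA or DNA alphabet (T is read
#'   as U), length >= 8.
#' @return Named character vector of patterns for `6mer`, `7mer-A1`,
#'   `7mer-m8`, `8mer` (RNA alphabet, target sense strand).
#' @examples
#' seed_patterns("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a
#' @export
seed_patterns <- function(mirna_seq) {
  s <- normalize_rna(mirna_seq)
  if (nchar(s) < 8) abort("miRNA sequence must be at least 8 nt")
  seed6 <- revcomp_rna(substr(s, 2, 7))
  m8 <- revcomp_rna(substr(s, 8, 8))
  c(
    "6mer" = seed6,
    "7mer-A1" = paste0(seed6, "A"),
    "7mer-m8" = paste0(m8, seed6),
    "8mer" = paste0(m8, seed6, "A")
  )
}

normalize_rna <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  if (any(grepl("[^ACGU]", x))) abort("sequence contains non-ACGU/T characters")
  x
}

revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a target sequence for miRNA response elements
#'
#' Finds every occurrence of the miRNA's 6mer seed complement on the target
#' sense strand and reports each anchor once at its strongest class (an
#' 8mer site is not additionally reported as 7mer/6mer). Coordinates are
#' 0-based half-open over the full matched pattern.
#'
#' @inheritParams seed_patterns
#' @param target_seq Target sequence, 5'->3', RNA or DNA alphabet.
#' @param mirna_id,target_id Identifiers carried into the result.
#' @return Tibble `mirna_id`, `target_id`, `start`, `end`, `site_class`,
#'   ordered by `start`.
#' @export
scan_sites <- function(mirna_seq, target_seq, mirna_id = "mirna",
                       target_id = "target") {
  if (nchar(target_seq) == 0) abort("empty target sequence")
  pat <- seed_patterns(mirna_seq)
  tg <- normalize_rna(target_seq)
  hits <- gregexpr(pat[["6mer"]], tg, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(tibble(mirna_id = character(), target_id = character(),
                  start = integer(), end = integer(), site_class = character()))
  }
  p <- as.integer(hits)  # 1-based seed start
  m8chr <- substr(pat[["7mer-m8"]], 1, 1)
  tgv <- rep(tg, length(p))  # substr() only vectorizes over its first arg
  has_m8 <- p > 1 & substr(tgv, p - 1, p - 1) == m8chr
  a1pos <- p + 6
  has_a1 <- a1pos <= nchar(tg) & substr(tgv, a1pos, a1pos) == "A"
  cls <- ifelse(has_m8 & has_a1, "8mer",
         ifelse(has_m8, "7mer-m8",
         ifelse(has_a1, "7mer-A1", "6mer")))
  start0 <- (p - 1L) - as.integer(has_m8)
  end0 <- (p + 5L) + as.integer(has_a1)
  tibble(
    mirna_id = mirna_id, target_id = target_id,
    start = start0, end = end0, site_class = cls
  )
}

#' miRanda-style duplex alignment score
#'
#' Best local anti-parallel alignment score between a miRNA and a target
#' window under a simple affine-gap scheme: Watson-Crick pair +5, G:U wobble
#' +1, mismatch -3, gap open -8, gap extend -2 (all configurable). The
#' miRNA is reversed so both strings read in the target's 5'->3' frame;
#' Smith-Waterman with a zero floor gives a deterministic non-negative score.
#'
#' @inheritParams seed_patterns
#' @param target_window Target subsequence, length >= miRNA length.
#' @param match,wobble,mismatch,gap_open,gap_extend Scoring parameters.
#' @return Single non-negative numeric score.
#' @export
duplex_score <- function(mirna_seq, target_window, match = 5, wobble = 1,
                         mismatch = -3, gap_open = -8, gap_extend = -2) {
  mi <- normalize_rna(mirna_seq)
  tw <- normalize_rna(target_window)
  if (nchar(tw) < nchar(mi)) abort("target window shorter than miRNA")
  a <- rev(strsplit(mi, "")[[1]])  # antiparallel orientation
  b <- strsplit(tw, "")[[1]]
  pair_score <- function(x, y) {
    if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(match)
    if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(wobble)
    mismatch
  }
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                             E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                             F[i, j + 1] + gap_extend)
      h <- max(0,
               H[i, j] + pair_score(a[i], b[j]),
               E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Aggregate binding evidence into a miRNA-target pair table
#'
#' Scans every miRNA against every target, collapses sites per pair
#' (`n_sites`, strongest class, optionally the best duplex score over
#' windows ending at each site), and keeps pairs meeting the evidence rule:
#' `best_class` at least `min_class` and, if `min_score` is given,
#' `best_score >= min_score`. This table is the binding-evidence input to
#' [assemble_network()].
#'
#' @param mirnas,targets Named character vectors of sequences (names are
#'   identifiers), or the `sequences` element of a [simulate_experiment()]
#'   dataset.
#' @param min_class Weakest acceptable site class
#'   (`"6mer" < "7mer-A1" < "7mer-m8" < "8mer"`).
#' @param min_score Optional duplex-score cutoff; scores are only computed
#'   when set.
#' @param score_window Window length (nt) ending at each site used for
#'   [duplex_score()].
#' @return Tibble `mirna_id`, `target_id`, `n_sites`, `best_class`,
#'   `best_score`, plus a `"sites"` attribute holding the full site table.
#' @export
build_target_table <- function(mirnas, targets, min_class = "7mer-A1",
                               min_score = NULL, score_window = 30) {
  if (!min_class %in% SITE_CLASSES) abort("unknown min_class")
  if (length(mirnas) == 0 || length(targets) == 0) {
    empty <- tibble(mirna_id = character(), target_id = character(),
                    n_sites = integer(), best_class = character(),
                    best_score = numeric())
    attr(empty, "sites") <- tibble(mirna_id = character(),
                                   target_id = character(), start = integer(),
                                   end = integer(), site_class = character())
    return(empty)
  }
  if (is.null(names(mirnas)) || is.null(names(targets))) {
    abort("mirnas and targets must be named by identifier")
  }
  sites <- scan_all_sites(mirnas, targets)
  pairs <- sites |>
    mutate(rank = site_class_rank(.data$site_class)) |>
    group_by(.data$mirna_id, .data$target_id) |>
    summarise(
      n_sites = dplyr::n(),
      best_class = SITE_CLASSES[max(.data$rank)],
      .groups = "drop"
    )
  pairs$best_score <- NA_real_
  if (!is.null(min_score)) {
    best <- sites |>
      mutate(rank = site_class_rank(.data$site_class)) |>
      group_by(.data$mirna_id, .data$target_id) |>
      dplyr::slice_max(.data$rank, n = 1, with_ties = FALSE) |>
      ungroup()
    sc <- purrr::pmap_dbl(best, function(mirna_id, target_id, start, end, ...) {
      tg <- normalize_rna(targets[[target_id]])
      from <- max(1, end - score_window + 1)
      win <- substr(tg, from, max(end, from + nchar(mirnas[[mirna_id]]) - 1))
      duplex_score(mirnas[[mirna_id]], win)
    })
    pairs$best_score <- sc[match(
      paste(pairs$mirna_id, pairs$target_id),
      paste(best$mirna_id, best$target_id)
    )]
    pairs <- dplyr::filter(pairs, .data$best_score >= min_score)
  }
  out <- dplyr::filter(
    pairs, site_class_rank(.data$best_class) >= site_class_rank(min_class)
  )
  attr(out, "sites") <- sites
  out
}

# Vectorized scan of every miRNA against every target: one fixed-string
# gregexpr call per miRNA over the whole target vector.
scan_all_sites <- function(mirnas, targets) {
  tg <- vapply(targets, normalize_rna, character(1))
  tgn <- nchar(tg)
  res <- purrr::imap(mirnas, function(ms, mid) {
    pat <- seed_patterns(ms)
    m8chr <- substr(pat[["7mer-m8"]], 1, 1)
    hits <- gregexpr(pat[["6mer"]], tg, fixed = TRUE)
    found <- vapply(hits, function(h) h[1] != -1, logical(1))
    if (!any(found)) return(NULL)
    purrr::map2(which(found), hits[found], function(ti, h) {
      p <- as.integer(h)
      s <- tg[[ti]]
      has_m8 <- p > 1 & substr(rep(s, length(p)), p - 1, p - 1) == m8chr
      a1 <- p + 6
      has_a1 <- a1 <= tgn[[ti]] & substr(rep(s, length(p)), a1, a1) == "A"
      tibble(
        mirna_id = mid, target_id = names(tg)[ti],
        start = (p - 1L) - as.integer(has_m8),
        end = (p + 5L) + as.integer(has_a1),
        site_class = ifelse(has_m8 & has_a1, "8mer",
                     ifelse(has_m8, "7mer-m8",
                     ifelse(has_a1, "7mer-A1", "6mer")))
      )
    }) |> bind_rows()
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(mirna_id = character(), target_id = character(),
                  start = integer(), end = integer(), site_class = character()))
  }
  arrange(out, .data$mirna_id, .data$target_id, .data$start)
}
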