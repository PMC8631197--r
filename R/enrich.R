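#' Hypergeometric over-representation test
#'
#' Tests whether a study list (e.g. DE mRNAs) is enriched for a gene set
#' relative to a population (all tested mRNAs): with N = |population|,
#' K = |set intersect population|, n = |study| and k = |set intersect
#' study|, p = P(X >= k) for X ~ Hypergeometric(N, K, n) — the same kernel
#' as [hypergeom_sponge_test()].
#'
#' @param study Character vector, must be a subset of `population`.
#' @param population Character vector of all eligible genes.
#' @param gene_set Character vector of set members, or a list/one-row tibble
#'   with `name` and `genes`.
#' @return One-row tibble: `set_name`, `N`, `K`, `n`, `k`, `p`.
#' @export
ora_test <- function(study, population, gene_set) {
  study <- unique(study)
  population <- unique(population)
  if (length(population) == 0) abort("population must be non-empty")
  if (!all(study %in% population)) {
    abort("study genes must all be contained in the population")
  }
  if (is.list(gene_set) && !is.null(gene_set$genes)) {
    name <- gene_set$name %||% "set"
    genes <- unlist(gene_set$genes)
  } else {
    name <- "set"
    genes <- gene_set
  }
  genes <- unique(genes)
  if (length(genes) == 0) abort("gene set must be non-empty")
  N <- length(population)
  K <- length(intersect(genes, population))
  n <- length(study)
  k <- length(intersect(genes, study))
  tibble(set_name = name, N = N, K = K, n = n, k = k,
         p = hypergeom_sponge_test(N, K, n, k))
}

#' @rdname ora_test
#' @param gmt Gene-set collection from [read_gmt()] (tibble with `name`,
#'   `description`, list-column `genes`).
#' @return `ora_batch()`: one [ora_test()] row per set with BH-adjusted
#'   `padj`, sorted by `p`.
#' @export
ora_batch <- function(study, population, gmt) {
  if (nrow(gmt) == 0) abort("empty gene-set collection")
  out <- purrr::map2(gmt$name, gmt$genes, function(nm, g) {
    r <- ora_test(study, population, g)
    r$set_name <- nm
    r
  }) |> bind_rows()
  out$padj <- bh_adjust(out$p)
  arrange(out, .data$p, .data$set_name)
}

#' Rank features for GSEA
#'
#' Orders a differential-expression table by the signed Wald statistic,
#' descending, with a deterministic lexicographic tie-break on the feature
#' identifier.
#'
#' @param de_table Tibble with `feature_id` and `stat` columns.
#' @return Tibble `feature_id`, `score`, in ranking order.
#' @export
rank_features <- function(de_table) {
  x <- as_tibble(de_table)
  if (!all(c("feature_id", "stat") %in% names(x))) {
    abort("de_table needs feature_id and stat columns")
  }
  if (anyNA(x$stat) || any(!is.finite(x$stat))) {
    abort("ranking statistics must be finite")
  }
  x |>
    dplyr::transmute(feature_id = .data$feature_id, score = .data$stat) |>
    arrange(dplyr::desc(.data$score), .data$feature_id)
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight / sum over hits` at
#' each gene-set member and `-1/(N - set size)` elsewhere; the enrichment
#' score is the signed extremum of this running sum. With `weight = 0` the
#' |ES| equals the two-sample Kolmogorov-Smirnov statistic between hit and
#' miss rank distributions; `weight = 1` is the classic weighted statistic.
#'
#' @param ranked Tibble from [rank_features()] (order is taken as given).
#' @param gene_set Character vector of member identifiers (or list with
#'   `name`/`genes`); must intersect the ranked list.
#' @param weight Exponent on |score| for hit increments.
#' @param set_name Label carried into the result.
#' @return A `gsea_es` object: `set_name`, `es`, `running_sum`, `hits`,
#'   `size`. `tidy()` gives the per-rank running sum.
#' @export
gsea_es <- function(ranked, gene_set, weight = 1, set_name = NULL) {
  ranked <- as_tibble(ranked)
  if (is.list(gene_set) && !is.null(gene_set$genes)) {
    set_name <- set_name %||% gene_set$name
    gene_set <- unlist(gene_set$genes)
  }
  set_name <- set_name %||% "set"
  hits <- ranked$feature_id %in% gene_set
  if (!any(hits)) abort("gene set has no member in the ranked list")
  if (all(hits)) abort("gene set covers the whole ranked list")
  es <- es_from_hits(ranked$score, hits, weight)
  structure(list(
    set_name = set_name, es = es$es, running_sum = es$running,
    hits = hits, size = sum(hits)
  ), class = "gsea_es")
}

# Core running-sum computation shared with the permutation null.
es_from_hits <- function(scores, hits, weight) {
  N <- length(scores)
  w <- abs(scores[hits])^weight
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / sum(hits), sum(hits))
  step <- rep(-1 / (N - sum(hits)), N)
  step[hits] <- inc
  running <- cumsum(step)
  i <- which.max(abs(running))
  list(es = running[i], running = running)
}

#' @export
tidy.gsea_es <- function(x, ...) {
  tibble(rank = seq_along(x$running_sum), running_sum = x$running_sum,
         hit = x$hits)
}

#' Permutation significance for a GSEA score
#'
#' Draws `n_perm` random gene-label sets of the observed size from the
#' ranked list, recomputes the enrichment score for each, and reports: NES
#' (observed ES divided by the mean |null ES| of matching sign), the
#' one-tailed permutation p
#' \eqn{(1 + \#\{null\ at\ least\ as\ extreme,\ same\ sign\}) /
#' (1 + \#\{same\ sign\ null\})}, and an FDR q-value from the
#' positive/negative normalized-score ratio method. Identical seeds give
#' identical results.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return A `gsea_result`: fields `set_name`, `size`, `es`, `nes`,
#'   `p_perm`, `fdr`, `running_sum`, `null_es`. `glance()` gives the
#'   one-row summary.
#' @export
gsea_permutation <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                             weight = 1, set_name = NULL) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  obs <- gsea_es(ranked, gene_set, weight = weight, set_name = set_name)
  scores <- as_tibble(ranked)$score
  N <- length(scores)
  m <- obs$size
  null_es <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(N, m)
    h <- logical(N)
    h[idx] <- TRUE
    es_from_hits(scores, h, weight)$es
  }, numeric(1)))
  stats <- nes_p_fdr(obs$es, null_es)
  structure(c(
    list(set_name = obs$set_name, size = m, es = obs$es),
    stats,
    list(running_sum = obs$running_sum, null_es = null_es)
  ), class = "gsea_result")
}

nes_p_fdr <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  if (length(same) == 0) {
    return(list(nes = NA_real_, p_perm = 1, fdr = 1))
  }
  denom <- mean(abs(same))
  nes <- if (denom > 0) es / denom else NA_real_
  # single-set specialization of the positive/negative ratio method:
  # fraction of same-sign null NES at least as extreme as the observed NES
  null_nes <- same / denom
  fdr <- min(1, sum(abs(null_nes) >= abs(nes)) / length(null_nes))
  if (is.na(nes)) fdr <- 1
  list(nes = nes, p_perm = p_perm, fdr = fdr)
}

#' @export
glance.gsea_result <- function(x, ...) {
  tibble(set_name = x$set_name, size = x$size, es = x$es, nes = x$nes,
         p_perm = x$p_perm, fdr = x$fdr)
}

#' @export
print.gsea_result <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @rdname gsea_permutation
#' @param gmt Gene-set collection tibble (`name`, `genes`); sets with no
#'   ranked member are skipped.
#' @return `gsea_batch()`: tibble `set_name`, `size`, `es`, `nes`,
#'   `p_perm`, `fdr` with the ratio-method FDR computed across all sets.
#' @export
gsea_batch <- function(ranked, gmt, n_perm = 1000, seed = 1, weight = 1) {
  keep <- purrr::map_lgl(gmt$genes, function(g) {
    n_in <- sum(as_tibble(ranked)$feature_id %in% g)
    n_in > 0 && n_in < nrow(as_tibble(ranked))
  })
  gmt <- gmt[keep, ]
  if (nrow(gmt) == 0) abort("no gene set overlaps the ranked list")
  res <- purrr::map(seq_len(nrow(gmt)), function(i) {
    gsea_permutation(ranked, gmt$genes[[i]], n_perm = n_perm,
                     seed = seed + i - 1, weight = weight,
                     set_name = gmt$name[i])
  })
  obs <- purrr::map_dfr(res, glance)
  # cross-set ratio-method FDR on the pooled normalized null
  null_nes <- purrr::map(res, function(r) {
    same_pos <- r$null_es[r$null_es >= 0]
    same_neg <- r$null_es[r$null_es < 0]
    c(if (length(same_pos)) same_pos / mean(abs(same_pos)),
      if (length(same_neg)) same_neg / mean(abs(same_neg)))
  }) |> unlist()
  obs$fdr <- vapply(obs$nes, function(nes) {
    if (is.na(nes)) return(1)
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(obs$nes[!is.na(obs$nes) & obs$nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(obs$nes[!is.na(obs$nes) & obs$nes < 0] <= nes)
    }
    if (!is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))
  arrange(obs, .data$p_perm, .data$set_name)
}
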