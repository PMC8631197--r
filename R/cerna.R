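#' Pearson correlation edge
#'
#' Sample Pearson correlation between two expression vectors with the
#' two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. At
#' \eqn{|r| = 1} the p-value is reported as the limit 0.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param id_a,id_b Identifiers carried into the result.
#' @return One-row tibble: `id_a`, `id_b`, `r`, `p`, `n_samples`.
#' @export
pearson_edge <- function(x, y, id_a = "x", id_b = "y") {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("expression values must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in an expression vector")
  r <- cor(x, y)
  tibble(id_a = id_a, id_b = id_b, r = r, p = pearson_p(r, n), n_samples = n)
}

# vectorized two-sided p from the t transform; |r| = 1 -> 0
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  lim <- abs(r) >= 1
  p[lim] <- 0
  t <- r[!lim] * sqrt((n - 2) / (1 - r[!lim]^2))
  p[!lim] <- 2 * pt(-abs(t), df = n - 2)
  pmin(p, 1)
}

#' @importFrom stats pt
NULL

# Row-wise Pearson r between two conformable matrices.
row_cor <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- rowSums(ac * bc) / den
  r[den == 0] <- NA_real_
  r
}

expr_values <- function(expr) {
  if (is.data.frame(expr)) count_values(expr) else as.matrix(expr)
}

#' Anti-correlation filter for miRNA-target pairs
#'
#' Annotates binding-evidence pairs with the Pearson correlation between
#' miRNA and target expression across samples and keeps the negatively
#' regulated ones: `r < r_max` and `p < p_max` (defaults −0.9 and 0.05).
#' Pairs whose members have zero expression variance are dropped.
#'
#' @param pairs Tibble with `mirna_id` and `target_id` columns (extra
#'   columns, e.g. from [build_target_table()], are preserved).
#' @param expr_mirna,expr_target Expression tables or matrices (features x
#'   samples, same sample order).
#' @param r_max Upper bound on r (negative).
#' @param p_max Upper bound on the correlation p-value.
#' @return The retained pairs with `r`, `p` and `n_samples` columns.
#' @export
filter_mirna_target <- function(pairs, expr_mirna, expr_target,
                                r_max = -0.9, p_max = 0.05) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, r = numeric(0), p = numeric(0),
                         n_samples = integer(0)))
  }
  em <- expr_values(expr_mirna)
  et <- expr_values(expr_target)
  miss <- setdiff(pairs$mirna_id, rownames(em))
  if (length(miss)) abort(paste0("miRNA missing from expression: ", miss[1]))
  miss <- setdiff(pairs$target_id, rownames(et))
  if (length(miss)) abort(paste0("target missing from expression: ", miss[1]))
  if (ncol(em) != ncol(et)) abort("expression matrices must share samples")
  r <- row_cor(em[pairs$mirna_id, , drop = FALSE],
               et[pairs$target_id, , drop = FALSE])
  p <- rep(NA_real_, length(r))
  p[!is.na(r)] <- pearson_p(r[!is.na(r)], ncol(em))
  out <- dplyr::mutate(pairs, r = unname(r), p = unname(p),
                       n_samples = ncol(em))
  dplyr::filter(out, !is.na(r), r < r_max, p < p_max)
}

#' Positive co-expression filter for ce-mRNA pairs
#'
#' Computes Pearson correlations for every (ce, mRNA) combination and keeps
#' pairs with `r > r_min` and `p < p_max` (defaults 0.8 and 0.05) — the
#' sponge/target co-expression requirement of ceRNA inference.
#'
#' @param ce_ids,mrna_ids Feature identifiers present in `expr`.
#' @param expr Expression table or matrix covering both sets.
#' @inheritParams filter_mirna_target
#' @param r_min Lower bound on r (positive).
#' @return Tibble `ce_id`, `mrna_id`, `r`, `p`, `n_samples` of retained pairs.
#' @export
filter_coexpression <- function(ce_ids, mrna_ids, expr,
                                r_min = 0.8, p_max = 0.05) {
  e <- expr_values(expr)
  miss <- setdiff(c(ce_ids, mrna_ids), rownames(e))
  if (length(miss)) abort(paste0("feature missing from expression: ", miss[1]))
  if (length(ce_ids) == 0 || length(mrna_ids) == 0) {
    return(tibble(ce_id = character(), mrna_id = character(), r = numeric(),
                  p = numeric(), n_samples = integer()))
  }
  rmat <- suppressWarnings(
    cor(t(e[ce_ids, , drop = FALSE]), t(e[mrna_ids, , drop = FALSE]))
  )
  out <- tibble(
    ce_id = rep(ce_ids, times = length(mrna_ids)),
    mrna_id = rep(mrna_ids, each = length(ce_ids)),
    r = as.vector(rmat),
    n_samples = ncol(e)
  )
  out <- dplyr::filter(out, !is.na(.data$r))
  out$p <- pearson_p(out$r, ncol(e))
  out <- dplyr::filter(out, .data$r > r_min, .data$p < p_max)
  dplyr::select(out, "ce_id", "mrna_id", "r", "p", "n_samples")
}

#' Hypergeometric sponge test
#'
#' Upper-tail (inclusive) probability that a candidate sponge and an mRNA
#' share at least `k` targeting miRNAs by chance: with `N` miRNAs in the
#' population, `K` targeting the sponge and `n` targeting the mRNA,
#' \eqn{p = P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n). The same
#' kernel drives over-representation analysis ([ora_test()]).
#'
#' @param N Population size (miRNAs under consideration).
#' @param K miRNAs targeting the candidate sponge.
#' @param n miRNAs targeting the mRNA.
#' @param k Shared miRNAs. All arguments are vectorized.
#' @return p-values in (0, 1].
#' @examples
#' hypergeom_sponge_test(20, 5, 6, 3)
#' @export
hypergeom_sponge_test <- function(N, K, n, k) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) abort("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
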