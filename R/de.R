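#' Negative-binomial Wald test for two-group differential expression
#'
#' Per-feature test of the log2 fold change between two sample groups under a
#' negative-binomial count model with variance \eqn{\mu + \alpha\mu^2}.
#' Counts are scaled by median-of-ratios size factors (or caller-supplied
#' factors, e.g. mapped-read totals for circRNA BSJ counts), group means are
#' compared on the log2 scale with a pseudocount for stability at zero, the
#' dispersion \eqn{\alpha} is estimated per feature by method of moments and
#' shrunk toward the across-feature mean, the standard error of the log2
#' fold change follows from the delta method, and the Wald statistic
#' log2FC/SE is referred to the standard normal.
#'
#' @param counts A count table (see [as_count_table()]).
#' @param groups Two-level factor/character vector aligned with the sample
#'   columns, or a sample sheet tibble with columns `sample_id` and `group`.
#'   The first level is the reference; log2FC is second level vs reference.
#' @param sf Optional size factors (named by sample). Default
#'   [size_factors()] on `counts`.
#' @param pseudocount Added to both group means before the log2 ratio.
#' @param shrink Weight in \[0,1\] pulling the per-feature dispersion toward
#'   the across-feature mean (0 = raw per-feature estimate). The moment
#'   estimator is mean-unbiased but very noisy at small n; pooling keeps the
#'   Wald test calibrated.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#'
#' @return A tibble with one row per feature: `feature_id`, `class`,
#'   `base_mean` (mean normalized count), `log2FC`, `se`, `stat`, `p`.
#' @seealso [bh_adjust()], [call_de()]
#' @export
nb_wald_test <- function(counts, groups, sf = NULL, pseudocount = 0.5,
                         shrink = 0.7, dispersion_floor = 1e-8) {
  counts <- as_count_table(counts, require_integer = FALSE)
  samp <- sample_cols(counts)
  groups <- resolve_groups(groups, samp)
  lev <- levels(groups)
  if (length(lev) != 2) abort("nb_wald_test() needs exactly two group levels")
  if (any(table(groups) < 2)) abort("each group needs at least 2 samples")

  if (is.null(sf)) sf <- size_factors(counts)
  if (!is.null(names(sf))) sf <- sf[samp]
  vals <- count_values(counts)
  q <- sweep(vals, 2, sf, "/")

  a <- groups == lev[1]
  b <- groups == lev[2]
  nA <- sum(a); nB <- sum(b)
  mA <- rowMeans(q[, a, drop = FALSE])
  mB <- rowMeans(q[, b, drop = FALSE])
  vA <- apply(q[, a, drop = FALSE], 1, var)
  vB <- apply(q[, b, drop = FALSE], 1, var)

  # method-of-moments dispersion pooled over within-group estimates
  alpha_g <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  am <- cbind(alpha_g(mA, vA), alpha_g(mB, vB))
  alpha <- rowMeans(am, na.rm = TRUE)
  alpha[is.nan(alpha)] <- dispersion_floor
  if (shrink > 0) {
    pooled <- mean(pmax(alpha, 0))
    alpha <- (1 - shrink) * alpha + shrink * pooled
  }
  alpha <- pmax(alpha, dispersion_floor)

  log2fc <- log2((mB + pseudocount) / (mA + pseudocount))
  # delta method on log2 of the pseudocounted group means
  varA <- (mA + alpha * mA^2) / nA
  varB <- (mB + alpha * mB^2) / nB
  se <- sqrt(varA / (mA + pseudocount)^2 + varB / (mB + pseudocount)^2) / log(2)
  se <- pmax(se, 1e-8)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  tibble(
    feature_id = counts$feature_id,
    class = counts$class,
    base_mean = unname(rowMeans(q)),
    log2FC = unname(log2fc),
    se = unname(se),
    stat = unname(stat),
    p = unname(p)
  )
}

resolve_groups <- function(groups, samp) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("sample sheet must have columns sample_id and group")
    }
    if (!all(samp %in% groups$sample_id)) {
      abort("sample sheet is missing samples present in the count table")
    }
    groups <- groups$group[match(samp, groups$sample_id)]
  }
  if (length(groups) != length(samp)) {
    abort("groups must have one entry per sample column")
  }
  if (is.factor(groups)) factor(groups) else factor(groups, levels = unique(groups))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' adjusted values are capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise no smaller than `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential expression at fold-change and FDR cutoffs
#'
#' Applies the two-threshold rule — `direction = "up"` if
#' `log2FC >= lfc_cut` and `padj < padj_cut`, `"down"` if
#' `log2FC <= -lfc_cut` and `padj < padj_cut`, otherwise `"ns"`. The default
#' cutoffs (|log2FC| >= 1, adjusted p < 0.05) are the stricter of the two
#' conventions in routine use; `padj_cut = 0.1` is the common alternative.
#'
#' @param records Output of [nb_wald_test()] (a `padj` column is added with
#'   [bh_adjust()] if absent).
#' @param lfc_cut Non-negative log2 fold-change cutoff.
#' @param padj_cut FDR cutoff in (0, 1].
#' @return A `de_table` tibble with `padj` and `direction` columns; use
#'   [glance()] for the up/down totals.
#' @export
call_de <- function(records, lfc_cut = 1, padj_cut = 0.05) {
  if (!is.numeric(lfc_cut) || lfc_cut < 0) abort("lfc_cut must be >= 0")
  if (!is.numeric(padj_cut) || padj_cut <= 0 || padj_cut > 1) {
    abort("padj_cut must lie in (0, 1]")
  }
  records <- as_tibble(records)
  if (!"padj" %in% names(records)) {
    records$padj <- bh_adjust(records$p)
  }
  records$direction <- dplyr::case_when(
    records$padj < padj_cut & records$log2FC >= lfc_cut ~ "up",
    records$padj < padj_cut & records$log2FC <= -lfc_cut ~ "down",
    TRUE ~ "ns"
  )
  class(records) <- c("de_table", class(records))
  attr(records, "cutoffs") <- c(lfc_cut = lfc_cut, padj_cut = padj_cut)
  records
}

#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_de = sum(x$direction != "ns")
  )
}
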