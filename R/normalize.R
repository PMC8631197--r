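#' Within-sample expression normalization
#'
#' Per-class normalizations for whole-transcriptome data: FPKM for mRNA and
#' lncRNA fragment counts, TPM (reads-per-million for length-less miRNA
#' counts), and SRPBM — spliced reads per billion mapped reads — for circRNA
#' back-splice-junction (BSJ) counts.
#'
#' Formulas, per feature i and sample j with count \eqn{c_{ij}}, length
#' \eqn{L_i} (nt) and column total \eqn{T_j}:
#' \describe{
#'   \item{FPKM}{\eqn{c_{ij} / ((L_i/10^3)(T_j/10^6))}}
#'   \item{TPM}{\eqn{10^6 r_{ij} / \sum_i r_{ij}} with rate
#'     \eqn{r_{ij} = c_{ij}/L_i}; each column sums to \eqn{10^6}. For miRNA
#'     rows the length is taken as 1 (reads-per-million convention).}
#'   \item{SRPBM}{\eqn{c_{ij} / (M_j/10^9)} with \eqn{M_j} total mapped reads
#'     of sample j (not the BSJ column total).}
#' }
#'
#' @param counts A count table (see [as_count_table()]).
#' @param mapped_reads Named (or sample-ordered) vector of total mapped reads
#'   per sample, required for SRPBM.
#'
#' @return A tibble of the same shape with normalized values and an `"unit"`
#'   attribute (`"FPKM"`, `"TPM"` or `"SRPBM"`).
#' @examples
#' x <- tibble::tibble(
#'   feature_id = c("g1", "g2"), class = "mRNA", length = c(1000, 2000),
#'   s1 = c(10L, 20L)
#' )
#' fpkm(x)
#' tpm(x)
#' @export
fpkm <- function(counts) {
  counts <- as_count_table(counts, require_integer = FALSE)
  if (anyNA(counts$length) || any(counts$length <= 0)) {
    abort("fpkm() needs a positive length for every feature")
  }
  vals <- count_values(counts)
  tot <- colSums(vals)
  if (any(tot == 0)) abort("fpkm(): all-zero sample column")
  out <- vals / (counts$length / 1e3)
  out <- sweep(out, 2, tot / 1e6, "/")
  rebuild_table(counts, out, unit = "FPKM")
}

#' @rdname fpkm
#' @export
tpm <- function(counts) {
  counts <- as_count_table(counts, require_integer = FALSE)
  len <- ifelse(counts$class == "miRNA", 1, counts$length)
  if (anyNA(len) || any(len <= 0)) {
    abort("tpm() needs a positive length for every non-miRNA feature")
  }
  vals <- count_values(counts)
  rate <- vals / len
  tot <- colSums(rate)
  if (any(tot == 0)) abort("tpm(): all-zero sample column")
  out <- sweep(rate, 2, tot, "/") * 1e6
  rebuild_table(counts, out, unit = "TPM")
}

#' @rdname fpkm
#' @export
srpbm <- function(counts, mapped_reads) {
  counts <- as_count_table(counts, require_integer = FALSE)
  samp <- sample_cols(counts)
  if (!is.null(names(mapped_reads))) {
    if (!all(samp %in% names(mapped_reads))) {
      abort("mapped_reads missing entries for some samples")
    }
    mapped_reads <- mapped_reads[samp]
  }
  if (length(mapped_reads) != length(samp)) {
    abort("mapped_reads must have one entry per sample")
  }
  if (any(mapped_reads <= 0)) abort("mapped_reads must be positive")
  vals <- count_values(counts)
  out <- sweep(vals, 2, mapped_reads / 1e9, "/")
  rebuild_table(counts, out, unit = "SRPBM")
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median ratio of each sample's
#' counts to the per-feature geometric mean, over features with positive
#' counts in every sample (the DESeq-style estimator the negative-binomial
#' Wald test normalizes with).
#'
#' @param counts A count table.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as_count_table(counts, require_integer = FALSE)
  vals <- count_values(counts)
  keep <- rowSums(vals > 0) == ncol(vals)
  if (!any(keep)) abort("size_factors(): no feature is positive in all samples")
  lv <- log(vals[keep, , drop = FALSE])
  geo <- rowMeans(lv)
  apply(lv, 2, function(col) exp(median(col - geo)))
}
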