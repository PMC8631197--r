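#' Count and expression tables
#'
#' Throughout spongenet a count matrix is an ordinary tibble in wide form:
#' three metadata columns (`feature_id`, `class`, `length`) followed by one
#' numeric column per sample. `class` is one of `"mRNA"`, `"lncRNA"`,
#' `"circRNA"`, `"miRNA"`; `length` is the transcript length in nucleotides
#' and may be `NA` for circRNA back-splice-junction counts, which have no
#' meaningful linear length. Expression tables produced by [fpkm()], [tpm()]
#' and [srpbm()] have the same shape with an `"unit"` attribute.
#'
#' @param x A data frame to validate as a count table.
#' @param require_integer Require whole-number counts (TRUE for raw counts).
#'
#' @return `as_count_table()` returns the validated tibble (invisibly
#'   unchanged apart from tibble coercion).
#' @export
as_count_table <- function(x, require_integer = TRUE) {
  x <- as_tibble(x)
  meta <- c("feature_id", "class", "length")
  if (!all(meta %in% names(x))) {
    abort(paste0("count table must have columns ", paste(meta, collapse = ", ")))
  }
  if (anyDuplicated(x$feature_id)) {
    dup <- x$feature_id[duplicated(x$feature_id)][1]
    abort(paste0("duplicate feature_id: '", dup, "'"))
  }
  samp <- sample_cols(x)
  if (length(samp) == 0) abort("count table has no sample columns")
  vals <- as.matrix(x[samp])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (anyNA(vals) || any(!is.finite(vals))) abort("counts must be finite")
  if (any(vals < 0)) {
    bad <- x$feature_id[which(rowSums(vals < 0) > 0)[1]]
    abort(paste0("negative count in row for feature '", bad, "'"))
  }
  if (require_integer && any(vals != round(vals))) {
    bad <- x$feature_id[which(rowSums(vals != round(vals)) > 0)[1]]
    abort(paste0("non-integer count in row for feature '", bad, "'"))
  }
  x
}

#' @rdname as_count_table
#' @export
sample_cols <- function(x) {
  setdiff(names(x), c("feature_id", "class", "length"))
}

# Numeric matrix of the sample columns, feature_ids as rownames.
count_values <- function(x) {
  m <- as.matrix(x[sample_cols(x)])
  rownames(m) <- x$feature_id
  m
}

# Rebuild a wide table from a values matrix plus the metadata of `template`.
rebuild_table <- function(template, values, unit = NULL) {
  out <- dplyr::bind_cols(
    template[c("feature_id", "class", "length")],
    as_tibble(values)
  )
  if (!is.null(unit)) attr(out, "unit") <- unit
  out
}
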