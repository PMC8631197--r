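#' Immunohistochemistry H-score
#'
#' Staining summary H = 1 x (% weak) + 2 x (% moderate) + 3 x (% strong),
#' ranging 0 (all negative) to 300 (all strong). Inputs are percentages of
#' cells per intensity bin by default; set `proportions = TRUE` for 0-1
#' fractions (the result is still on the 0-300 scale). All arguments are
#' vectorized.
#'
#' @param weak,moderate,strong Percent (or proportion) of cells at
#'   intensity 1, 2, 3.
#' @param negative Optional percent at intensity 0, used only to check that
#'   the fractions sum to at most 100%.
#' @param proportions Interpret inputs as 0-1 proportions.
#' @return Numeric H-scores in \[0, 300\].
#' @examples
#' h_score(weak = 10, moderate = 20, strong = 30)  # 140
#' @export
h_score <- function(weak, moderate, strong, negative = NULL,
                    proportions = FALSE) {
  full <- if (proportions) 1 else 100
  vals <- c(weak, moderate, strong, negative)
  if (anyNA(vals) || any(vals < 0) || any(vals > full)) {
    abort(sprintf("intensity fractions must lie in [0, %g]", full))
  }
  total <- weak + moderate + strong + (if (is.null(negative)) 0 else negative)
  if (any(total > full + 1e-9)) {
    abort("intensity fractions sum to more than the whole")
  }
  scale <- if (proportions) 100 else 1
  scale * (1 * weak + 2 * moderate + 3 * strong)
}

#' qPCR relative expression (2^-ddCT)
#'
#' Fold change of a target gene in a sample relative to a control
#' condition, each normalized to an internal reference gene:
#' dCT = CT(target) - CT(reference) per condition,
#' ddCT = dCT(sample) - dCT(control), fold change = 2^-ddCT. All arguments
#' are vectorized.
#'
#' @param ct_target_sample,ct_ref_sample Cycle thresholds in the sample.
#' @param ct_target_control,ct_ref_control Cycle thresholds in the control.
#' @return Positive fold changes (1 when sample and control agree).
#' @examples
#' relative_expression(20, 15, 22, 15)  # 4
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0)) {
    abort("CT values must be finite positive cycle numbers")
  }
  dct_sample <- ct_target_sample - ct_ref_sample
  dct_control <- ct_target_control - ct_ref_control
  2^(-(dct_sample - dct_control))
}
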