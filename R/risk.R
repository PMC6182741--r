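#' Nottingham Prognostic Index
#'
#' NPI = 0.2 x tumour diameter (cm) + histological grade + nodal stage,
#' with nodal stage 1/2/3 for 0, 1-3 and 4-or-more positive axillary
#' nodes. Scores above 3.4 are treated as high risk downstream.
#'
#' @param diameterCm largest tumour diameter in cm.
#' @param grade histological grade, 1/2/3.
#' @param nodeCategory nodal category: factor/character in
#'   \code{c("0", "1-3", "4+")} or a non-negative count of positive nodes.
#' @return numeric NPI score(s).
#' @examples
#' computeNpi(2.0, 2, "1-3")   # 3.4 (not high risk under the strict > 3.4)
#' computeNpi(1.3, 3, "1-3")   # 4.26
#' @export
computeNpi <- function(diameterCm, grade, nodeCategory) {
  if (anyNA(diameterCm) || anyNA(grade) || anyNA(nodeCategory))
    stop("NPI inputs must be non-missing; impute upstream")
  if (any(!grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  if (is.numeric(nodeCategory)) {
    if (any(nodeCategory < 0)) stop("node counts must be >= 0")
    stage <- cut(nodeCategory, c(-Inf, 0, 3, Inf), labels = FALSE)
  } else {
    nodeCategory <- as.character(nodeCategory)
    if (any(!nodeCategory %in% c("0", "1-3", "4+")))
      stop("nodeCategory must be one of '0', '1-3', '4+'")
    stage <- match(nodeCategory, c("0", "1-3", "4+"))
  }
  0.2 * diameterCm + grade + stage
}

#' Select the high-risk subgroup by an established risk model
#'
#' Returns the subset of patients at high risk: NPI strictly above 3.4, or
#' a PREDICT 10-year overall survival strictly below 85\%. PREDICT scores
#' are consumed from an externally supplied \code{predict_os10} column
#' (probability in [0,1]); the PREDICT equations themselves are not part
#' of this package. Tertile labels are inherited from the full-cohort
#' trichotomisation; re-analysis of the subgroup (propensity, weights,
#' weighted Cox) is done by passing the returned records back through the
#' survival functions, refitting the weights within the subgroup.
#'
#' @param records cohort data.frame; for \code{model = "npi"} the columns
#'   \code{tumour_diameter_cm}, \code{grade}, \code{nodes_cat} must be
#'   complete; for \code{model = "predict"} a \code{predict_os10} column
#'   must be present.
#' @param model \code{"npi"} or \code{"predict"}.
#' @param npiThreshold high risk when NPI exceeds this (default 3.4).
#' @param predictThreshold high risk when PREDICT 10-year OS is below this
#'   (default 0.85).
#' @return the high-risk subset of \code{records}, with an added
#'   \code{npi} or unchanged \code{predict_os10} column.
#' @export
selectHighRisk <- function(records, model = c("npi", "predict"),
                           npiThreshold = 3.4, predictThreshold = 0.85) {
  model <- match.arg(model)
  if (model == "npi") {
    records$npi <- computeNpi(records$tumour_diameter_cm, records$grade,
                              records$nodes_cat)
    records[records$npi > npiThreshold, , drop = FALSE]
  } else {
    p <- records$predict_os10
    if (is.null(p) || all(is.na(p)))
      stop("model = 'predict' requires a predict_os10 column with values")
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop("predict_os10 must be a probability in [0,1]")
    records[!is.na(p) & p < predictThreshold, , drop = FALSE]
  }
}
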