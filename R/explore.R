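#' Compare a continuous variable between two groups
#'
#' Unpaired t-test for normal variables or Mann-Whitney U test for
#' non-normal ones, returning the statistic and two-tailed p-value.
#'
#' @param valuesA,valuesB numeric vectors (each of length >= 2).
#' @param test \code{"mann_whitney"} (default) or \code{"t_test"}.
#' @return list with \code{statistic}, \code{p.value}, \code{test}.
#' @export
compareGroups <- function(valuesA, valuesB,
                          test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("each group needs at least 2 observations")
  ht <- if (test == "t_test") stats::t.test(valuesA, valuesB)
        else stats::wilcox.test(valuesA, valuesB, exact = FALSE,
                                correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value, test = test)
}

#' Fisher's exact test of a 2 x K contingency table
#'
#' @param tab integer matrix (2 rows) of counts; no margin may be all zero.
#' @return two-tailed p-value.
#' @export
categoricalAssociation <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin")
  stats::fisher.test(tab)$p.value
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return list with \code{rho} and \code{p.value}.
#' @export
rankCorrelation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ht <- stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
  list(rho = unname(ht$estimate), p.value = ht$p.value)
}

#' CPE versus menopausal status and menstrual-cycle timing
#'
#' Two Mann-Whitney comparisons of the CPE value: (1) premenopausal versus
#' peri- and postmenopausal patients pooled; (2) among premenopausal
#' patients with a recorded last menstrual period, early cycle (weeks up
#' to \code{weekSplit}) versus later weeks. Patients without a recorded
#' LMP are excluded from the second comparison. A comparison whose strata
#' are not both populated is skipped with a warning and reported as NA.
#'
#' @param records cohort data.frame with \code{cpe},
#'   \code{menopausal_status} and \code{weeks_since_lmp}.
#' @param weekSplit last week counted as early cycle (default 2, i.e.
#'   weeks 1-2 vs 3+).
#' @return list with \code{menopausal_p}, \code{menstrual_week_p}, and the
#'   group sizes used.
#' @export
menstrualCycleAnalysis <- function(records, weekSplit = 2) {
  pre <- records$menopausal_status == "pre"
  menopP <- NA_real_
  if (sum(pre) >= 2 && sum(!pre) >= 2) {
    menopP <- compareGroups(records$cpe[pre], records$cpe[!pre])$p.value
  } else {
    warning("menopausal comparison skipped: a stratum has < 2 patients")
  }
  lmp <- pre & !is.na(records$weeks_since_lmp)
  early <- lmp & records$weeks_since_lmp <= weekSplit
  late <- lmp & records$weeks_since_lmp > weekSplit
  weekP <- NA_real_
  if (sum(early) >= 2 && sum(late) >= 2) {
    weekP <- compareGroups(records$cpe[early], records$cpe[late])$p.value
  } else {
    warning("menstrual-week comparison skipped: a stratum has < 2 patients")
  }
  list(menopausal_p = menopP, menstrual_week_p = weekP,
       n = c(pre = sum(pre), periPost = sum(!pre),
             earlyCycle = sum(early), lateCycle = sum(late)))
}
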