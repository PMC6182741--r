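#' Administrative censoring at a horizon
#'
#' Recodes events after the horizon as censored at the horizon, and
#' truncates all follow-up times to the horizon, for both the IDFS and OS
#' endpoints (survival at 10 years = 120 months by default).
#'
#' @param records cohort data.frame (see \code{\link{generateCohort}} for
#'   the column contract).
#' @param horizonMonths administrative horizon in months (default 120).
#' @return the records with \code{idfs_time_months}, \code{idfs_event},
#'   \code{os_time_months}, \code{os_event} recoded.
#' @export
administrativeCensor <- function(records, horizonMonths = 120) {
  stopifnot(horizonMonths > 0)
  for (ep in c("idfs", "os")) {
    tcol <- paste0(ep, "_time_months"); ecol <- paste0(ep, "_event")
    late <- records[[tcol]] > horizonMonths
    records[[ecol]][late] <- 0L
    records[[tcol]][late] <- horizonMonths
  }
  records
}

# draw from the Bayesian posterior of a normal linear model and predict
# with noise (proper imputation draws for a continuous variable)
#' @noRd
drawLinear <- function(X, y, Xmis) {
  fit <- stats::lm.fit(X, y)
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  df <- length(y) - qrX$rank
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, max(df, 1))
  R <- qr.R(qrX)
  beta <- fit$coefficients[keep] +
    backsolve(R, stats::rnorm(ncol(Xk))) * sqrt(sigma2)
  as.vector(Xmis[, keep, drop = FALSE] %*% beta) +
    stats::rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

# draw categories for missing rows from a multinomial model refitted on a
# bootstrap resample of the observed rows (approximates parameter draws)
#' @noRd
drawCategorical <- function(data, var, predictors, mis) {
  obs <- which(!mis)  # original observed values (initialised copies excluded)
  boot <- sample(obs, length(obs), replace = TRUE)
  f <- stats::reformulate(predictors, response = var)
  dObs <- data[boot, , drop = FALSE]
  dObs[[var]] <- factor(dObs[[var]])
  if (nlevels(dObs[[var]]) < 2) return(rep(levels(dObs[[var]]), sum(mis)))
  fit <- nnet::multinom(f, data = dObs, trace = FALSE, maxit = 200)
  p <- stats::predict(fit, newdata = data[mis, , drop = FALSE],
                      type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # binary case
  lev <- fit$lev
  apply(p, 1, function(pr) sample(lev, 1, prob = pr))
}

#' Multiple imputation of missing tumour characteristics
#'
#' Chained-equation imputation of grade, tumour diameter and axillary
#' nodal category, the tumour characteristics allowed to be missing. Each
#' of the m imputed datasets is produced by iterating over the incomplete
#' variables: diameter is imputed on the log scale from a Bayesian linear
#' regression draw (posterior draws of the coefficients and residual
#' variance, prediction with noise); grade and nodal category are drawn
#' from multinomial models refitted on bootstrap resamples of the observed
#' rows. Predictors include the other covariates, the CPE tertile, the
#' event indicators and log follow-up time, so the imputation model is
#' compatible with the survival analysis.
#'
#' @param records cohort data.frame with missing values only in
#'   \code{grade}, \code{tumour_diameter_cm}, \code{nodes_cat}.
#' @param m number of imputations (default 20). \code{m = 1} is allowed
#'   but warned against (no between-imputation variance).
#' @param seed integer RNG seed.
#' @param maxIter chained-equation sweeps per dataset (default 5).
#' @return list of m completed data.frames.
#' @export
imputeMissing <- function(records, m = 20, seed = 1L, maxIter = 5) {
  if (m < 1) stop("m must be >= 1")
  if (m == 1)
    warning("m = 1 gives no between-imputation variance; ",
            "Rubin pooling will understate uncertainty")
  vars <- c("grade", "tumour_diameter_cm", "nodes_cat")
  misList <- lapply(vars, function(v) is.na(records[[v]]))
  names(misList) <- vars
  for (v in vars)
    if (all(misList[[v]]))
      stop("cannot impute '", v, "': all values are missing")
  other <- setdiff(names(records), vars)
  if (anyNA(records[
        setdiff(other, c("weeks_since_lmp", "er_pct", "pr_pct",
                         "recurrence_site"))]))
    stop("missing values outside the tumour characteristics ",
         "(grade/diameter/nodes) are not supported")
  if (!any(unlist(misList)))
    return(rep(list(records), m))

  set.seed(as.integer(seed))
  basePreds <- c("age_years", "pr_status", "therapy", "cpe",
                 "idfs_event", "os_event")
  out <- vector("list", m)
  for (im in seq_len(m)) {
    d <- records
    d$logTime <- log(pmax(d$idfs_time_months, 0.5))
    # initialise missing entries by sampling observed values
    for (v in vars) {
      mis <- misList[[v]]
      if (any(mis))
        d[[v]][mis] <- sample(records[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(maxIter)) {
      if (any(misList$tumour_diameter_cm)) {
        mis <- misList$tumour_diameter_cm
        X <- stats::model.matrix(
          ~ age_years + pr_status + therapy + cpe + idfs_event + os_event +
            logTime + factor(grade) + nodes_cat, d)
        y <- log(records$tumour_diameter_cm)
        d$tumour_diameter_cm[mis] <-
          exp(drawLinear(X[!mis, , drop = FALSE], y[!mis],
                         X[mis, , drop = FALSE]))
      }
      preds <- c(basePreds, "logTime", "tumour_diameter_cm")
      if (any(misList$grade)) {
        d$grade <- factor(d$grade, levels = 1:3)
        g <- drawCategorical(d, "grade", c(preds, "nodes_cat"),
                             misList$grade)
        d$grade[misList$grade] <- g
        d$grade <- as.integer(as.character(d$grade))
      }
      if (any(misList$nodes_cat)) {
        dd <- d; dd$grade <- factor(dd$grade, levels = 1:3)
        nc <- drawCategorical(dd, "nodes_cat", c(preds, "grade"),
                              misList$nodes_cat)
        d$nodes_cat[misList$nodes_cat] <-
          factor(nc, levels = levels(records$nodes_cat))
      }
    }
    d$logTime <- NULL
    out[[im]] <- d
  }
  out
}
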