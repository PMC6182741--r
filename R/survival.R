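#' Fit the propensity model for tertile membership
#'
#' Three-category multinomial logistic regression of the CPE tertile on
#' the confounders: age at diagnosis and largest tumour diameter through
#' restricted cubic splines (3 knots at the 10th/50th/90th percentiles by
#' default; natural cubic splines, linear beyond the boundary knots), and
#' histological grade, PR status, axillary nodal category and systemic
#' therapy as categorical terms.
#'
#' @param records complete-covariate cohort data.frame with a
#'   \code{tertile} factor.
#' @param knotProbs quantile positions of the 3 spline knots.
#' @return a \code{\linkS4class{PropensityFit}}.
#' @export
fitPropensity <- function(records, knotProbs = c(0.1, 0.5, 0.9)) {
  covars <- c("age_years", "tumour_diameter_cm", "grade", "pr_status",
              "nodes_cat", "therapy")
  if (anyNA(records[covars]))
    stop("propensity model requires complete covariates; impute first")
  if (any(table(records$tertile) == 0))
    stop("propensity model requires at least one patient per tertile")

  ageKnots <- stats::quantile(records$age_years, knotProbs, names = FALSE)
  diamKnots <- stats::quantile(records$tumour_diameter_cm, knotProbs,
                               names = FALSE)
  d <- data.frame(
    tertile = records$tertile,
    ageRcs = rcsBasis(records$age_years, ageKnots),
    diamRcs = rcsBasis(records$tumour_diameter_cm, diamKnots),
    grade = factor(records$grade, levels = 1:3),
    pr_status = records$pr_status,
    nodes_cat = records$nodes_cat,
    therapy = droplevels(records$therapy))
  fit <- nnet::multinom(tertile ~ ., data = d, trace = FALSE, maxit = 500)
  if (fit$convergence != 0)
    stop("propensity model did not converge (nnet::multinom convergence ",
         fit$convergence, "); check for separation or sparse categories")
  p <- stats::fitted(fit)
  if (nrow(p) != nrow(records))  # multinom drops nothing here, but guard
    stop("propensity fit returned ", nrow(p), " rows for ",
         nrow(records), " patients")
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  p <- p / rowSums(p)
  new("PropensityFit", model = fit, probabilities = p,
      levels = levels(records$tertile),
      knots = list(age = ageKnots, diameter = diamKnots))
}

#' Compute inverse-probability-of-tertile weights
#'
#' Each patient is weighted by the inverse of the modelled probability of
#' their observed tertile. By default weights are stabilised by the
#' marginal tertile frequency (so they average about 1 and sum to about n)
#' and truncated at the 1st/99th weight percentiles to limit the influence
#' of extreme propensities.
#'
#' @param fit a \code{\linkS4class{PropensityFit}} for these records.
#' @param records the cohort data.frame the fit was computed on.
#' @param stabilise multiply by the marginal tertile frequency
#'   (default TRUE).
#' @param truncate length-2 probabilities at which the weights are
#'   winsorised, or NULL to disable (default \code{c(0.01, 0.99)}).
#' @return numeric vector of weights, one per patient.
#' @export
computeIpwWeights <- function(fit, records, stabilise = TRUE,
                              truncate = c(0.01, 0.99)) {
  stopifnot(is(fit, "PropensityFit"))
  obsIdx <- match(as.character(records$tertile), fit@levels)
  p <- fit@probabilities[cbind(seq_len(nrow(records)), obsIdx)]
  if (any(p < 1e-6)) {
    bad <- records$patient_id[p < 1e-6]
    stop("propensity below 1e-6 for patient(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; weights would be unstable")
  }
  w <- 1 / p
  if (stabilise) {
    marg <- as.vector(table(records$tertile)) / nrow(records)
    w <- w * marg[obsIdx]
  }
  if (!is.null(truncate)) {
    lim <- stats::quantile(w, truncate, names = FALSE)
    w <- pmin(pmax(w, lim[1]), lim[2])
  }
  w
}

#' @noRd
endpointColumns <- function(endpoint) {
  endpoint <- match.arg(endpoint, c("idfs", "os"))
  list(time = paste0(endpoint, "_time_months"),
       event = paste0(endpoint, "_event"), endpoint = endpoint)
}

#' Weighted Cox model of an endpoint on CPE tertiles
#'
#' Inverse-probability-weighted Cox proportional hazards fit of the
#' endpoint on the tertile factor (low = reference), with robust
#' (sandwich) variance, since naive model-based variance is invalid under
#' weighting. Hazard ratios, 95\% CIs and Wald p-values are reported per
#' non-reference tertile, together with a trend test: the Wald test of the
#' tertile coded ordinally 0/1/2 in the same weighted model.
#'
#' @param records cohort data.frame.
#' @param weights numeric vector of IPW weights (unit weights reduce the
#'   fit exactly to the unweighted Cox model).
#' @param endpoint \code{"idfs"} or \code{"os"}.
#' @return a \code{\linkS4class{WeightedCoxFit}}.
#' @export
fitWeightedCox <- function(records, weights = rep(1, nrow(records)),
                           endpoint = c("idfs", "os")) {
  cols <- endpointColumns(match.arg(endpoint))
  time <- records[[cols$time]]
  event <- records[[cols$event]]
  if (sum(event) < 1) stop("no events; cannot fit a Cox model")
  refEvents <- sum(event[records$tertile == "low"])
  if (refEvents == 0)
    stop("degenerate fit: zero events in the reference (low) tertile")

  d <- data.frame(time = time, event = event, tertile = records$tertile,
                  w = weights)
  fit <- survival::coxph(survival::Surv(time, event) ~ tertile, data = d,
                         weights = w, robust = TRUE)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))  # robust variance when robust = TRUE
  z <- beta / se
  tab <- data.frame(
    tertile = sub("^tertile", "", names(beta)),
    logHr = as.vector(beta), se = se,
    hr = exp(beta), lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  counts <- stats::aggregate(event ~ tertile, d, sum)
  atRisk <- as.data.frame(table(d$tertile))
  tab$nEvents <- counts$event[match(tab$tertile, counts$tertile)]
  tab$nAtRisk <- atRisk$Freq[match(tab$tertile, atRisk$Var1)]

  dTrend <- transform(d, ord = as.integer(tertile) - 1L)
  trendFit <- survival::coxph(survival::Surv(time, event) ~ ord,
                              data = dTrend, weights = w, robust = TRUE)
  tb <- stats::coef(trendFit)[1]
  tse <- sqrt(trendFit$var[1, 1])
  trend <- list(coef = unname(tb), se = unname(tse),
                p = unname(2 * stats::pnorm(-abs(tb / tse))))

  new("WeightedCoxFit", endpoint = cols$endpoint, table = tab,
      reference = data.frame(nEvents = refEvents,
                             nAtRisk = sum(d$tertile == "low")),
      trend = trend, pooled = FALSE, m = 1L)
}

#' Pool weighted Cox fits across imputations (Rubin's rules)
#'
#' Combines per-imputation fits on the log hazard-ratio scale: the pooled
#' point estimate is the mean; the pooled variance is the within-imputation
#' variance plus (1 + 1/m) times the between-imputation variance. Wald CIs
#' and p-values use the t reference with Barnard-Rubin degrees of freedom
#' (reducing to the single-fit normal interval when the between-imputation
#' variance is zero). The trend test is pooled the same way.
#'
#' @param fits list of \code{\linkS4class{WeightedCoxFit}} objects from the
#'   same endpoint and tertile coding, one per imputation.
#' @return a pooled \code{\linkS4class{WeightedCoxFit}}.
#' @export
poolFits <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, is, logical(1), "WeightedCoxFit")))
  m <- length(fits)
  if (m == 1) return(fits[[1]])
  ep <- unique(vapply(fits, function(f) f@endpoint, character(1)))
  if (length(ep) != 1) stop("cannot pool fits from different endpoints")

  rubin <- function(q, se2) {
    qbar <- mean(q)
    W <- mean(se2)
    B <- if (m > 1) stats::var(q) else 0
    Tv <- W + (1 + 1 / m) * B
    df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
    crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
    pfun <- function(stat) if (is.finite(df))
      2 * stats::pt(-abs(stat), df) else 2 * stats::pnorm(-abs(stat))
    list(est = qbar, se = sqrt(Tv), lo = qbar - crit * sqrt(Tv),
         hi = qbar + crit * sqrt(Tv), p = pfun(qbar / sqrt(Tv)))
  }

  tab0 <- fits[[1]]@table
  tab <- tab0
  for (i in seq_len(nrow(tab0))) {
    q <- vapply(fits, function(f) f@table$logHr[i], numeric(1))
    s2 <- vapply(fits, function(f) f@table$se[i]^2, numeric(1))
    r <- rubin(q, s2)
    tab$logHr[i] <- r$est; tab$se[i] <- r$se
    tab$hr[i] <- exp(r$est); tab$lo[i] <- exp(r$lo); tab$hi[i] <- exp(r$hi)
    tab$p[i] <- r$p
  }
  qT <- vapply(fits, function(f) f@trend$coef, numeric(1))
  sT <- vapply(fits, function(f) f@trend$se^2, numeric(1))
  rT <- rubin(qT, sT)
  new("WeightedCoxFit", endpoint = ep, table = tab,
      reference = fits[[1]]@reference,
      trend = list(coef = rT$est, se = rT$se, p = rT$p),
      pooled = TRUE, m = as.integer(m))
}

#' IPW survival analysis across multiply imputed datasets
#'
#' Convenience wrapper running the full adjusted analysis: for each
#' completed dataset, fit the propensity model, compute stabilised
#' truncated IPW weights and the weighted Cox model, then pool with
#' Rubin's rules.
#'
#' @param imputations list of completed cohort data.frames (from
#'   \code{\link{imputeMissing}}), or a single data.frame for
#'   complete-case analysis.
#' @param endpoint \code{"idfs"} or \code{"os"}.
#' @param stabilise,truncate passed to \code{\link{computeIpwWeights}}.
#' @return a (pooled) \code{\linkS4class{WeightedCoxFit}}.
#' @export
ipwSurvival <- function(imputations, endpoint = c("idfs", "os"),
                        stabilise = TRUE, truncate = c(0.01, 0.99)) {
  endpoint <- match.arg(endpoint)
  if (is.data.frame(imputations)) imputations <- list(imputations)
  fits <- lapply(imputations, function(d) {
    pf <- fitPropensity(d)
    w <- computeIpwWeights(pf, d, stabilise = stabilise,
                           truncate = truncate)
    fitWeightedCox(d, w, endpoint)
  })
  poolFits(fits)
}
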