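# Synthetic per-slot show probabilities. Real show/no-show behaviour is
# patient-specific - appointment lead time, time of day, and demographics all
# shift the odds - and in practice one would fit a (penalized) logistic
# regression on historical appointment records. Patient-level records are
# rarely shareable, so this module emulates the downstream product of such a
# model: for every booked slot it samples a covariate vector, pushes the
# linear predictor through the inverse logit, and returns one show
# probability per slot. The intercept can be calibrated so the population
# mean show probability hits a chosen target.

#' Specify a synthetic show-probability model
#'
#' Each covariate is sampled independently per slot from its own distribution
#' and enters a logistic model linearly. The default specification carries
#' three generic predictors: a standardized appointment lead time (longer
#' lead, lower show probability), an afternoon-slot indicator, and a
#' standardized age-like score.
#'
#' @param intercept intercept of the linear predictor (logit scale).
#' @param covariates list of covariate definitions; each element is a list
#'   with `name`, `dist` ("normal", "uniform" or "bernoulli"), `par1`, `par2`
#'   (mean/sd, min/max, or prob/unused) and `coef`.
#' @return object of class `noshow_spec`.
#' @export
noshow_spec <- function(intercept = 1.5,
                        covariates = list(
                          list(name = "lead_time", dist = "normal",
                               par1 = 0, par2 = 1, coef = -0.5),
                          list(name = "afternoon", dist = "bernoulli",
                               par1 = 0.5, par2 = 0, coef = -0.3),
                          list(name = "age_score", dist = "normal",
                               par1 = 0, par2 = 1, coef = 0.4))) {
  for (cv in covariates) {
    if (!all(c("name", "dist", "par1", "coef") %in% names(cv)))
      stop("each covariate needs name, dist, par1 (and par2), coef")
    if (!cv$dist %in% c("normal", "uniform", "bernoulli"))
      stop("unsupported covariate distribution: ", cv$dist)
  }
  structure(list(intercept = intercept, covariates = covariates),
            class = "noshow_spec")
}

# n draws of the linear predictor (without intercept)
sample_linear_predictor <- function(spec, n) {
  lp <- numeric(n)
  for (cv in spec$covariates) {
    x <- switch(cv$dist,
                normal = stats::rnorm(n, cv$par1, cv$par2),
                uniform = stats::runif(n, cv$par1, cv$par2),
                bernoulli = as.numeric(stats::runif(n) < cv$par1))
    lp <- lp + cv$coef * x
  }
  lp
}

#' Generate per-slot show probabilities for a schedule
#'
#' Draws one covariate vector per booked outpatient slot and returns the
#' inverse-logit show probability, shaped exactly like the schedule (one
#' vector per period, of length `schedule[i]`). Probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` so the transition model stays well-posed.
#'
#' @param spec a `noshow_spec`.
#' @param schedule integer vector: outpatients booked per period.
#' @return list of numeric vectors, one per period.
#' @export
generate_show_probabilities <- function(spec, schedule) {
  stopifnot(inherits(spec, "noshow_spec"), all(schedule >= 0))
  total <- sum(schedule)
  p <- stats::plogis(spec$intercept + sample_linear_predictor(spec, total))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  split_at <- rep(seq_along(schedule), schedule)
  out <- vector("list", length(schedule))
  for (i in seq_along(schedule)) out[[i]] <- p[split_at == i]
  out
}

#' Calibrate the intercept to a target mean show probability
#'
#' Bisection on the intercept: the Monte-Carlo mean of the inverse-logit show
#' probability is monotone increasing in the intercept, so the root of
#' `mean(p) - target_mean` is bracketed and halved until within tolerance.
#'
#' @param spec a `noshow_spec`.
#' @param target_mean desired mean show probability, strictly in (0, 1).
#' @param n_mc Monte-Carlo sample size per evaluation.
#' @param tol stop when the Monte-Carlo mean is within `tol` of the target.
#' @return the spec with its intercept replaced by the calibrated value.
#' @export
calibrate_intercept <- function(spec, target_mean, n_mc = 100000L, tol = 0.005) {
  stopifnot(target_mean > 0, target_mean < 1)
  lp <- sample_linear_predictor(spec, n_mc)  # one sample, reused across evaluations
  mean_at <- function(b) mean(stats::plogis(b + lp))
  lo <- -20; hi <- 20
  if (mean_at(lo) > target_mean || mean_at(hi) < target_mean)
    stop("target mean not bracketed by intercepts in [-20, 20]")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    m <- mean_at(mid)
    if (abs(m - target_mean) < tol) break
    if (m < target_mean) lo <- mid else hi <- mid
  }
  spec$intercept <- mid
  spec
}
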