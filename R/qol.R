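## ---------------------------------------------------------------------------
## EQ-5D utility model: annual utility prediction with the event-phase
## decrement structure, and OLS estimation from survey-style utility records.
## ---------------------------------------------------------------------------

#' Predict annual EQ-5D utility
#'
#' Intercept plus dot product over resolvable covariates, with event-phase
#' selection: MI and stroke carry a year-of-event decrement for exactly one
#' annual cycle and a subsequent-years decrement afterwards (prevalent entry
#' history counts as subsequent years); the diabetes decrement switches at 10
#' years of duration; cancer carries a single any-history decrement.
#' Predictions are clamped to the EQ-5D-3L utility range `[-0.594, 1]`.
#'
#' @param cohort validated cohort.
#' @param state `sim_state` aligned with `cohort` (or `NULL` for entry state).
#' @param qol a [qol_model()].
#' @param centring centring constants.
#' @return utilities in `[-0.594, 1]`.
#' @export
predict_utility <- function(cohort, state = NULL, qol,
                            centring = default_centring()) {
  u <- rep(qol$intercept, nrow(cohort))
  if (length(qol$coefficients)) {
    X <- resolve_covariates(names(qol$coefficients), cohort, state, centring)
    u <- u + drop(X %*% qol$coefficients)
  }
  clamp_utility(u)
}

## fast in-simulation variant using the precomputed static part
ctx_utility <- function(ctx, state) {
  u <- ctx$coefset$qol$intercept + ctx$qol_static_lp
  if (length(ctx$qol_dyn)) {
    Xd <- resolve_covariates(ctx$qol_dyn, ctx$cohort, state, ctx$centring)
    u <- u + drop(Xd %*% ctx$coefset$qol$coefficients[ctx$qol_dyn])
  }
  clamp_utility(u)
}

#' Fit the EQ-5D utility model by ordinary least squares
#'
#' Survey records carry an observed `utility` column plus covariate columns
#' named after registry covariates (as produced by
#' [generate_utility_survey()], standing in for pooled health-survey data).
#'
#' @param survey data frame with `utility` and covariate columns.
#' @param covariates covariate names to include (default: every registry name
#'   present as a column).
#' @return a [qol_model()] with standard errors and residual SD attached.
#' @export
fit_qol_model <- function(survey, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(names(survey), covariate_names())
  }
  unknown <- setdiff(covariates, covariate_names())
  if (length(unknown)) {
    cvd_error("cvd_config_error",
              paste0("unknown covariate(s): ", paste(unknown, collapse = ", ")))
  }
  X <- as.matrix(survey[covariates])
  storage.mode(X) <- "double"
  y <- as.numeric(survey$utility)
  if (nrow(unique(X)) < 2) {
    cvd_error("cvd_estimation_error",
              "need at least 2 distinct covariate patterns")
  }
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(cbind(`(Intercept)` = 1, X)),
                       colnames(cbind(`(Intercept)` = 1, X))[keep])
    cvd_error("cvd_estimation_error",
              paste0("design matrix is rank deficient; collinear column(s): ",
                     paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  names(cf) <- names(se) <- c("(Intercept)", covariates)
  qol_model(intercept = cf[["(Intercept)"]],
            coefficients = cf[-1],
            se = se,
            sigma = stats::sigma(fit))
}
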