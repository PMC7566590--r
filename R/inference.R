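# The statistical engine: truncated Poisson log-likelihood, saturated
# likelihood, deviance, BIC, maximum-likelihood fitting of the global
# parameters (alpha analytically, beta by bounded search) with
# Hessian-based standard errors, and the legacy Gaussian-era metrics.

# Sentinel for "include zero flows" in the truncation threshold.
FMIN_INCLUDE_ZEROS <- -1

resolve_fmin <- function(f_min) {
  if (is.character(f_min)) {
    if (identical(f_min, "include-zeros")) return(FMIN_INCLUDE_ZEROS)
    f_num <- suppressWarnings(as.numeric(f_min))
    if (is.na(f_num)) stop_usage("invalid f_min: ", f_min)
    return(f_num)
  }
  f_min
}

fmin_label <- function(f_min) {
  if (resolve_fmin(f_min) == FMIN_INCLUDE_ZEROS) "include-zeros"
  else as.character(resolve_fmin(f_min))
}

# Ordered pairs entering the truncated sums: i != j and F_ij strictly
# greater than f_min (theta strict). f_min = -1 keeps every pair.
included_pairs <- function(F, f_min) {
  f_min <- resolve_fmin(f_min)
  (row(F) != col(F)) & (F > f_min)
}

#' Truncated Poisson log-likelihood of predicted flows
#'
#' Treats each observed flow as a Poisson draw with mean \eqn{\hat F_{ij}}
#' and sums \eqn{-\hat F_{ij} + F_{ij}\ln\hat F_{ij} - \ln F_{ij}!} over
#' ordered pairs \eqn{i \ne j} with \eqn{F_{ij} > F_{\min}} (strict step
#' function, so `f_min = 0` drops the zero flows). The sentinel
#' `f_min = -1` (or `"include-zeros"`) keeps every pair. \eqn{\ln F!} is
#' computed via the log-gamma function.
#'
#' @param F Observed flow matrix (integer counts).
#' @param Fhat Predicted flow matrix; must be positive on included pairs.
#' @param f_min Truncation threshold (default includes zeros).
#' @return The log-likelihood, a single number.
#' @export
poisson_loglik <- function(F, Fhat, f_min = FMIN_INCLUDE_ZEROS) {
  inc <- included_pairs(F, f_min)
  fh <- Fhat[inc]
  if (any(fh <= 0)) {
    stop_numeric("zero or negative predicted flow on an included pair; ",
                 "Poisson log-likelihood undefined")
  }
  fo <- F[inc]
  sum(-fh + fo * log(fh) - lgamma(fo + 1))
}

#' Saturated Poisson log-likelihood
#'
#' The log-likelihood attained when the prediction matches the data
#' termwise (\eqn{\hat F = F}): \eqn{\sum (-F + F\ln F - \ln F!)}, with the
#' \eqn{F = 0} term equal to zero. It upper-bounds [poisson_loglik()] for
#' any model on the same included pairs and anchors the deviance.
#'
#' @inheritParams poisson_loglik
#' @return The saturated log-likelihood.
#' @export
saturated_loglik <- function(F, f_min = FMIN_INCLUDE_ZEROS) {
  fo <- F[included_pairs(F, f_min)]
  xlogx <- ifelse(fo > 0, fo * log(fo), 0)
  sum(-fo + xlogx - lgamma(fo + 1))
}

#' Poisson deviance of predicted flows
#'
#' \eqn{D = 2\sum ((\hat F_{ij} - F_{ij}) + F_{ij}\ln(F_{ij}/\hat F_{ij}))}
#' over the same included pairs as [poisson_loglik()], with
#' \eqn{0 \ln(0/\hat F) = 0}. Equivalently \eqn{D = 2(\ln L_s - \ln L)};
#' \eqn{D \ge 0}, and \eqn{D = 0} iff the model is saturated on the
#' included pairs.
#'
#' @inheritParams poisson_loglik
#' @return The deviance, a nonnegative number.
#' @export
flow_deviance <- function(F, Fhat, f_min = FMIN_INCLUDE_ZEROS) {
  inc <- included_pairs(F, f_min)
  fh <- Fhat[inc]
  if (any(fh <= 0)) {
    stop_numeric("zero or negative predicted flow on an included pair; ",
                 "deviance undefined")
  }
  fo <- F[inc]
  ratio <- ifelse(fo > 0, fo * log(fo / fh), 0)
  2 * sum((fh - fo) + ratio)
}

#' Bayesian information criterion
#'
#' \eqn{\mathrm{BIC} = k \ln(n) - 2 \ln L} for `k` fitted global parameters
#' and `n` data points. Lower is better.
#'
#' @param loglik Log-likelihood of the model.
#' @param k Number of fitted global parameters (0 or 1 here).
#' @param n_data Number of data points used.
#' @return The BIC value.
#' @export
bic_score <- function(loglik, k, n_data) {
  if (n_data < 1) stop_data("BIC needs at least one data point")
  if (k < 0) stop_usage("k must be >= 0")
  k * log(n_data) - 2 * loglik
}

#' Closed-form maximum-likelihood fit of a multiplicative factor
#'
#' For models whose predictions scale linearly in a single global factor
#' (\eqn{\hat F(\alpha) = \alpha \hat F^{(0)}}, true of radiation variants
#' F, G and H where \eqn{t_i = \alpha\,\mathrm{base}_i}), the Poisson MLE is
#' \eqn{\hat\alpha = \sum F_{ij} / \sum \hat F^{(0)}_{ij}} over included
#' pairs, with Hessian standard error \eqn{\hat\alpha / \sqrt{\sum F_{ij}}}.
#'
#' @param F Observed flow matrix.
#' @param Fhat0 Predicted flows at \eqn{\alpha = 1}.
#' @param f_min Truncation threshold.
#' @return A list with `alpha`, `se` and `loglik` (evaluated at the MLE).
#' @export
fit_alpha <- function(F, Fhat0, f_min = FMIN_INCLUDE_ZEROS) {
  inc <- included_pairs(F, f_min)
  sF <- sum(F[inc])
  sH <- sum(Fhat0[inc])
  if (sH <= 0) stop_numeric("predicted flows sum to zero on included pairs")
  if (sF <= 0) stop_numeric("observed flows sum to zero on included pairs")
  alpha <- sF / sH
  list(alpha = alpha,
       se = alpha / sqrt(sF),
       loglik = poisson_loglik(F, alpha * Fhat0, f_min))
}

#' Maximum-likelihood fit of the gravity deterrence parameter
#'
#' Maximises the truncated Poisson log-likelihood of the
#' production-constrained gravity model over \eqn{\beta} by bounded scalar
#' search on `interval` (default \eqn{[10^{-3}, 20]}, covering plausible
#' deterrence exponents for mobility data) with convergence tolerance
#' `tol`. By default the site parameters follow the commuting convention
#' \eqn{t_i = O_i}, \eqn{n_i = I_i}; pass `t` and `n` explicitly to fit with
#' other mappings (e.g. the known attractiveness in a simulation study).
#' The standard error comes from the observed information,
#' \eqn{(-d^2 \ln L / d\beta^2)^{-1/2}}, by central finite difference with
#' step \eqn{10^{-4}\max(1, |\hat\beta|)}. An optimum within `0.01` of a
#' search bound is flagged (`boundary = TRUE`) with a warning, never
#' silently accepted.
#'
#' @param F Observed flow matrix.
#' @param sites A [site_table] supplying the default `t` and `n`.
#' @param D Distance matrix.
#' @param deterrence `"power"` or `"exponential"`.
#' @param f_min Truncation threshold.
#' @param t,n Optional explicit site parameter vectors overriding the
#'   defaults `sites$out_flow` and `sites$in_flow`.
#' @param interval Search bracket for \eqn{\beta}.
#' @param tol Convergence tolerance of the scalar search.
#' @return A list with `beta`, `se`, `loglik` and `boundary`.
#' @export
fit_beta <- function(F, sites, D, deterrence = c("power", "exponential"),
                     f_min = FMIN_INCLUDE_ZEROS, t = NULL, n = NULL,
                     interval = c(1e-3, 20), tol = 1e-6) {
  deterrence <- match.arg(deterrence)
  if (is.null(t)) t <- sites$out_flow
  if (is.null(n)) n <- sites$in_flow
  obj <- function(beta) {
    ll <- poisson_loglik(F, gravity_predict(t, n, D, beta, deterrence), f_min)
    if (!is.finite(ll)) stop_numeric("non-finite log-likelihood at beta = ",
                                     beta)
    ll
  }
  opt <- stats::optimize(obj, interval = interval, maximum = TRUE, tol = tol)
  beta_hat <- opt$maximum
  boundary <- (beta_hat - interval[1] < 1e-2) || (interval[2] - beta_hat < 1e-2)
  if (boundary) {
    warning("beta optimum at or near the search bound [",
            interval[1], ", ", interval[2], "]; estimate flagged",
            call. = FALSE)
  }
  h <- 1e-4 * max(1, abs(beta_hat))
  d2 <- (obj(beta_hat + h) - 2 * opt$objective + obj(beta_hat - h)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  list(beta = beta_hat, se = se, loglik = opt$objective, boundary = boundary)
}

#' Sorensen-Dice coefficient (common part of commuters)
#'
#' \eqn{\sum \min(\hat F_{ij}, F_{ij}) / \sum F_{ij}} over ordered pairs
#' \eqn{i \ne j}. A heuristic overlap measure in \eqn{[0, 1]} widely used
#' for flow comparison; it has no likelihood basis and is provided for
#' comparison with the older literature only.
#'
#' @param F Observed flow matrix with positive total.
#' @param Fhat Predicted flow matrix.
#' @return A number in \eqn{[0, 1]}.
#' @export
dice_coefficient <- function(F, Fhat) {
  off <- row(F) != col(F)
  tot <- sum(F[off])
  if (tot <= 0) stop_data("Sorensen-Dice undefined: total observed flow is 0")
  sum(pmin(F[off], Fhat[off])) / tot
}

#' Coefficient of determination of predicted flows
#'
#' \eqn{R^2 = 1 - \sum(F - \hat F)^2 / \sum(F - \bar F)^2} over ordered
#' pairs \eqn{i \ne j}. Assumes Gaussian errors, which count data with many
#' zeros violate; provided for comparison with the older literature only.
#' May be negative; equals 1 only for a perfect fit.
#'
#' @param F Observed flow matrix, not constant across pairs.
#' @param Fhat Predicted flow matrix.
#' @return A number \eqn{\le 1}.
#' @export
r_squared <- function(F, Fhat) {
  off <- row(F) != col(F)
  fo <- F[off]
  ss_tot <- sum((fo - mean(fo))^2)
  if (ss_tot <= 0) stop_data("R^2 undefined: observed flows are constant")
  1 - sum((fo - Fhat[off])^2) / ss_tot
}
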