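# Model evaluation: fit any global parameter, score a model at one or more
# truncation thresholds, and assemble the comparison table that ranks the
# whole model family on a dataset.

#' Fit and score one model on observed flows
#'
#' Fits the model's global parameter, if any, by maximum likelihood at the
#' given truncation threshold (gravity: \eqn{\beta} via [fit_beta()];
#' radiation variants F, G, H: \eqn{\alpha} via [fit_alpha()]), then reports
#' log-likelihood, BIC, deviance, saturated log-likelihood, and the legacy
#' Sorensen-Dice and \eqn{R^2} metrics.
#'
#' The `n` in the BIC penalty defaults to the number of included ordered
#' pairs (`bic_n = "pairs"`); `bic_n = "sites"` uses the number of sites
#' instead. The choice is immaterial for ranking models with equal `k` but
#' is recorded in the result.
#'
#' @param model An `od_model` from [gravity_model()] or [make_variant()].
#' @param sites A [site_table].
#' @param D Distance matrix in canonical site order.
#' @param F Observed flow matrix.
#' @param f_min Truncation threshold (`-1`/`"include-zeros"` keeps zeros).
#' @param bic_n `"pairs"` or `"sites"`: what counts as `n` in the BIC.
#' @param io Optional precomputed [intervening_opportunities()] for the
#'   model's attractiveness column.
#' @return An object of class `od_fit`: a list with the fitted model, the
#'   parameter estimate and standard error, and all scores.
#' @export
evaluate_model <- function(model, sites, D, F, f_min = FMIN_INCLUDE_ZEROS,
                           bic_n = c("pairs", "sites"), io = NULL) {
  bic_n <- match.arg(bic_n)
  f_min <- resolve_fmin(f_min)
  warnings <- character(0)
  param_name <- "none"
  param_value <- NA_real_
  param_se <- NA_real_
  k <- 0L

  if (model$family == "gravity") {
    param_name <- "beta"
    if (is.na(model$beta)) {
      fit <- withCallingHandlers(
        fit_beta(F, sites, D, model$deterrence, f_min),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      model$beta <- fit$beta
      param_se <- fit$se
      k <- 1L  # parameter fitted here; a fixed beta costs no BIC penalty
      if (fit$boundary) warnings <- c(warnings, "beta at search boundary")
    }
    param_value <- model$beta
    Fhat <- predict_flows(model, sites, D)
  } else {
    p <- model_site_params(
      if (model$fitted) make_variant(sites, model$variant, alpha = 1)
      else model, sites)
    if (is.null(io)) io <- intervening_opportunities(p$n, D)
    if (model$fitted) {
      param_name <- "alpha"
      Fhat0 <- radiation_predict(p$t, p$m, p$n, io, model$normalised)
      if (is.na(model$alpha)) {
        fit <- fit_alpha(F, Fhat0, f_min)
        model$alpha <- fit$alpha
        param_se <- fit$se
        k <- 1L
      }
      param_value <- model$alpha
      Fhat <- model$alpha * Fhat0
    } else {
      Fhat <- radiation_predict(p$t, p$m, p$n, io, model$normalised)
    }
  }

  inc <- included_pairs(F, f_min)
  n_data <- if (bic_n == "pairs") sum(inc) else nrow(sites)
  ll <- poisson_loglik(F, Fhat, f_min)
  ll_sat <- saturated_loglik(F, f_min)
  structure(list(
    model = model,
    model_id = model_id(model),
    f_min = f_min,
    param_name = param_name,
    param_value = param_value,
    param_se = param_se,
    k = k,
    n_data = n_data,
    bic_n_mode = bic_n,
    loglik = ll,
    loglik_saturated = ll_sat,
    bic = bic_score(ll, k, n_data),
    deviance = flow_deviance(F, Fhat, f_min),
    dsc = dice_coefficient(F, Fhat),
    r2 = r_squared(F, Fhat),
    warnings = warnings
  ), class = "od_fit")
}

#' @export
print.od_fit <- function(x, ...) {
  cat("Model ", x$model_id, " at f_min = ", fmin_label(x$f_min), "\n",
      sep = "")
  if (x$k > 0) {
    cat("  ", x$param_name, " = ", format(x$param_value),
        " (se ", format(x$param_se), ")\n", sep = "")
  }
  cat("  lnL = ", format(x$loglik), ", BIC = ", format(x$bic),
      " (n = ", x$n_data, ", ", x$bic_n_mode, "), D = ",
      format(x$deviance), "\n", sep = "")
  cat("  DSC = ", format(x$dsc), ", R^2 = ", format(x$r2), "\n", sep = "")
  if (length(x$warnings) > 0) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Evaluate a set of models across truncation thresholds
#'
#' Runs [evaluate_model()] for every (model, `f_min`) combination and
#' returns one comparison row per combination. A failure in one model (for
#' example, zero predicted flow on an included pair) is recorded in the
#' `error` column and does not abort the remaining evaluations.
#'
#' @param models A list of `od_model` objects.
#' @param sites A [site_table].
#' @param D Distance matrix.
#' @param F Observed flow matrix.
#' @param f_min_list Vector of truncation thresholds (may mix numbers and
#'   the `"include-zeros"` sentinel).
#' @param bic_n `"pairs"` or `"sites"` (see [evaluate_model()]).
#' @return A list with `table` (data.frame, one row per model and
#'   threshold) and `fits` (the underlying `od_fit` objects, errors as
#'   `NULL`).
#' @export
evaluate_models <- function(models, sites, D, F,
                            f_min_list = FMIN_INCLUDE_ZEROS,
                            bic_n = c("pairs", "sites")) {
  bic_n <- match.arg(bic_n)
  if (length(models) == 0) stop_usage("no models to evaluate")
  # intervening opportunities depend only on the attractiveness column;
  # compute each needed column once and share across variants
  io_cache <- list()
  rows <- list()
  fits <- list()
  for (model in models) {
    io <- NULL
    if (model$family == "radiation") {
      col <- model$n_col
      if (is.null(io_cache[[col]])) {
        io_cache[[col]] <- intervening_opportunities(sites[[col]], D)
      }
      io <- io_cache[[col]]
    }
    for (f_min in f_min_list) {
      key <- paste0(model_id(model), "@", fmin_label(f_min))
      res <- tryCatch(
        evaluate_model(model, sites, D, F, f_min, bic_n, io = io),
        od_error = function(e) e)
      if (inherits(res, "od_fit")) {
        fits[[key]] <- res
        rows[[key]] <- data.frame(
          model = res$model_id, f_min = fmin_label(f_min),
          param = res$param_name, value = res$param_value,
          se = res$param_se, k = res$k, n_data = res$n_data,
          loglik = res$loglik, bic = res$bic, deviance = res$deviance,
          loglik_saturated = res$loglik_saturated,
          dsc = res$dsc, r2 = res$r2,
          warnings = paste(res$warnings, collapse = "; "),
          error = "", stringsAsFactors = FALSE)
      } else {
        fits[key] <- list(NULL)
        rows[[key]] <- data.frame(
          model = model_id(model), f_min = fmin_label(f_min),
          param = NA_character_, value = NA_real_, se = NA_real_,
          k = NA_integer_, n_data = NA_integer_, loglik = NA_real_,
          bic = NA_real_, deviance = NA_real_,
          loglik_saturated = NA_real_, dsc = NA_real_, r2 = NA_real_,
          warnings = "", error = conditionMessage(res),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits)
}

#' Serialise a fit result to a report list
#'
#' Plain list mirroring the JSON report layout: model identity, threshold,
#' parameter estimate with standard error, all scores and any warnings.
#'
#' @param fit An `od_fit`.
#' @return A named list ready for [jsonlite::write_json()].
#' @export
fit_report <- function(fit) {
  list(
    model = fit$model_id,
    family = fit$model$family,
    f_min = fmin_label(fit$f_min),
    k = fit$k,
    n_data = fit$n_data,
    bic_n_mode = fit$bic_n_mode,
    param = list(name = fit$param_name,
                 value = fit$param_value,
                 se = fit$param_se),
    loglik = fit$loglik,
    bic = fit$bic,
    deviance = fit$deviance,
    loglik_saturated = fit$loglik_saturated,
    dsc = fit$dsc,
    r2 = fit$r2,
    warnings = as.list(fit$warnings)
  )
}
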