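# Predicted-flow computation: production-constrained gravity, the radiation
# family with intervening opportunities, and the eight mappings of site data
# values (P, O, I) onto the radiation site parameters (m, n, t).

#' Production-constrained gravity model predictions
#'
#' Predicts \eqn{\hat F_{ij} = t_i n_j f(d_{ij}) / \sum_{k \ne i} n_k
#' f(d_{ik})} with a power-law (\eqn{f(d) = d^{-\beta}}) or exponential
#' (\eqn{f(d) = e^{-\beta d}}) deterrence function. The denominator excludes
#' \eqn{k = i}: with \eqn{d_{ii} = 0} the power-law term would be singular,
#' and only this reading satisfies the production constraint
#' \eqn{\sum_{j \ne i} \hat F_{ij} = t_i} exactly.
#'
#' @param t Per-site outflow parameter \eqn{t_i} (nonnegative).
#' @param n Per-site attractiveness \eqn{n_j} (nonnegative, not all zero).
#' @param D Distance matrix (km); off-diagonal entries must be positive for
#'   power-law deterrence.
#' @param beta Global deterrence parameter \eqn{\beta \ge 0}.
#' @param deterrence `"power"` or `"exponential"`.
#' @return Matrix of predicted flows; diagonal is zero by convention.
#' @export
gravity_predict <- function(t, n, D, beta,
                            deterrence = c("power", "exponential")) {
  deterrence <- match.arg(deterrence)
  N <- nrow(D)
  stopifnot(length(t) == N, length(n) == N)
  if (any(t < 0) || any(n < 0)) stop_data("site parameters must be >= 0")
  off <- row(D) != col(D)
  if (deterrence == "power") {
    if (any(D[off] <= 0)) {
      stop_data("power-law deterrence undefined: zero inter-site distance")
    }
    W <- D^(-beta)
  } else {
    W <- exp(-beta * D)
  }
  diag(W) <- 0
  denom <- as.vector(W %*% n)
  if (any(denom <= 0 & t > 0)) {
    stop_data("all-zero attractiveness seen from a site with t_i > 0")
  }
  scale <- ifelse(denom > 0, t / denom, 0)
  Fhat <- W * outer(scale, n)
  diag(Fhat) <- 0
  dimnames(Fhat) <- dimnames(D)
  Fhat
}

#' Intervening opportunities
#'
#' For each ordered pair computes \eqn{s_{ij}}, the total attractiveness of
#' all sites strictly closer to \eqn{i} than \eqn{j} is, excluding both
#' \eqn{i} and \eqn{j} themselves: \eqn{s_{ij} = \sum_{k \ne i} n_k
#' \theta(d_{ij} - d_{ik})} with a strict step function (\eqn{\theta(0) =
#' 0}). Sites tied exactly at \eqn{d_{ij}} therefore do not count towards
#' each other's \eqn{s}; exact ties are detected and reported with a
#' warning because they break the telescoping row-sum identity of the
#' radiation model. [jitter_distances()] offers a seeded tie-break.
#'
#' @param n Per-site attractiveness.
#' @param D Distance matrix.
#' @return A list with `s` (matrix of \eqn{s_{ij}}, zero diagonal) and `N_c`
#'   (total opportunities \eqn{\sum_i n_i}).
#' @export
intervening_opportunities <- function(n, D) {
  N <- nrow(D)
  stopifnot(length(n) == N)
  s <- matrix(0, N, N, dimnames = dimnames(D))
  ties <- FALSE
  for (i in seq_len(N)) {
    d <- D[i, -i]
    nn <- n[-i]
    o <- order(d)
    ds <- d[o]
    if (anyDuplicated(ds)) ties <- TRUE
    cs <- cumsum(nn[o])
    first <- match(ds, ds)  # first index of each tie group
    closer <- c(0, cs)[first]  # mass strictly closer than each distance
    out <- numeric(N - 1)
    out[o] <- closer
    s[i, -i] <- out
  }
  if (ties) {
    warning("exact distance ties present; tied sites excluded from each ",
            "other's intervening opportunities (strict theta)", call. = FALSE)
  }
  list(s = s, N_c = sum(n))
}

#' Break exact distance ties with a seeded jitter
#'
#' Adds a reproducible perturbation of magnitude `eps` km to the
#' off-diagonal entries of a distance matrix (kept symmetric) so that
#' [intervening_opportunities()] sees no exact ties. Off by default
#' everywhere; intended for gridded or rounded coordinate data.
#'
#' @param D Distance matrix.
#' @param seed Integer seed for the perturbation.
#' @param eps Jitter magnitude in km.
#' @return A distance matrix with jittered off-diagonal entries.
#' @export
jitter_distances <- function(D, seed, eps = 1e-9) {
  N <- nrow(D)
  old <- .Random.seed_restore(seed)
  on.exit(old())
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- stats::runif(N * (N - 1) / 2, 0, eps)
  J <- J + t(J)
  D + J
}

# Temporarily seed the RNG; returns a restorer closure.
.Random.seed_restore <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Per-site normalisation factors for the radiation model
#'
#' \eqn{N_c / (N_c - m_i)}, the factor that restores the production
#' constraint exactly in the normalised radiation model. It is \eqn{\ge 1}
#' and close to 1 whenever \eqn{N_c \gg m_i}.
#'
#' @param m Per-site aspiration parameter.
#' @param N_c Total opportunities \eqn{\sum_i n_i}.
#' @return Numeric vector of factors.
#' @export
normalisation_factors <- function(m, N_c) {
  if (any(m >= N_c)) {
    stop_data("normalisation undefined: m_i >= N_c for some site")
  }
  N_c / (N_c - m)
}

#' Radiation model predictions
#'
#' Predicts \eqn{\hat F_{ij} = t_i m_i n_j / ((m_i + s_{ij})(m_i + n_j +
#' s_{ij}))}, optionally multiplied by the normalisation factor
#' \eqn{N_c/(N_c - m_i)} that enforces the production constraint exactly.
#' Without normalisation, when \eqn{m = n} and all distances from a site are
#' distinct, the row sums telescope to \eqn{t_i (N_c - m_i)/N_c}.
#'
#' @param t,m,n Per-site outflow, aspiration and attractiveness parameters.
#' @param io Intervening opportunities from [intervening_opportunities()]
#'   computed with the same `n`.
#' @param normalised Logical; apply the exact production-constraint factor.
#' @return Matrix of predicted flows; diagonal is zero by convention.
#' @export
radiation_predict <- function(t, m, n, io, normalised = FALSE) {
  s <- io$s
  N_c <- io$N_c
  N <- nrow(s)
  stopifnot(length(t) == N, length(m) == N, length(n) == N)
  if (any(m < 0) || any(n < 0) || any(t < 0)) {
    stop_data("site parameters must be >= 0")
  }
  if (any(m == 0 & t > 0)) {
    stop_data("inconsistent parameters: m_i = 0 with t_i > 0 predicts no ",
              "outflow distribution")
  }
  if (normalised && any(m >= N_c)) {
    stop_data("normalised radiation undefined: m_i >= N_c for some site")
  }
  A <- s + m                               # m_i + s_ij (recycled by row)
  B <- A + matrix(n, N, N, byrow = TRUE)   # m_i + n_j + s_ij
  num <- outer(t * m, n)
  Fhat <- ifelse(num > 0, num / (A * B), 0)
  if (normalised) {
    Fhat <- Fhat * normalisation_factors(m, N_c)
  }
  diag(Fhat) <- 0
  dimnames(Fhat) <- dimnames(s)
  Fhat
}

# Table of radiation-variant mappings: which site data value feeds each of
# (m, n, t), whether t is scaled by the fitted factor alpha, and whether the
# normalised form is used.
RADIATION_VARIANTS <- list(
  A = list(m = "population", n = "population", t = "population",
           fitted = FALSE, normalised = FALSE,
           label = "Total population"),
  B = list(m = "out_flow", n = "out_flow", t = "out_flow",
           fitted = FALSE, normalised = FALSE,
           label = "Departing commuters"),
  C = list(m = "out_flow", n = "out_flow", t = "out_flow",
           fitted = FALSE, normalised = TRUE,
           label = "Departing commuters, normalised"),
  D = list(m = "out_flow", n = "in_flow", t = "out_flow",
           fitted = FALSE, normalised = FALSE,
           label = "Arriving & departing, naive split"),
  E = list(m = "in_flow", n = "in_flow", t = "out_flow",
           fitted = FALSE, normalised = TRUE,
           label = "Arriving & departing, revised split"),
  F = list(m = "population", n = "population", t = "population",
           fitted = TRUE, normalised = FALSE,
           label = "Total population, fitted factor"),
  G = list(m = "out_flow", n = "out_flow", t = "out_flow",
           fitted = TRUE, normalised = FALSE,
           label = "Departing commuters, fitted factor"),
  H = list(m = "in_flow", n = "in_flow", t = "out_flow",
           fitted = TRUE, normalised = TRUE,
           label = "Arriving & departing, revised, fitted factor")
)

#' Instantiate a radiation-model variant
#'
#' Maps the site data values (population \eqn{P}, departing commuters
#' \eqn{O}, arriving commuters \eqn{I}) onto the radiation site parameters
#' \eqn{(m, n, t)} for one of the eight standard variants:
#'
#' | Variant | m | n | t | normalised |
#' |---|---|---|---|---|
#' | A | P | P | P  | no  |
#' | B | O | O | O  | no  |
#' | C | O | O | O  | yes |
#' | D | O | I | O  | no  |
#' | E | I | I | O  | yes |
#' | F | P | P | aP | no  |
#' | G | O | O | aO | no  |
#' | H | I | I | aO | yes |
#'
#' Variants F, G and H scale the outflow parameter by a single fitted global
#' factor `alpha`; `alpha = NA` leaves it to be fitted by maximum
#' likelihood. Variant D deliberately disentangles inflow and outflow the
#' way a gravity model does, without the derivation that justifies it; it
#' fits data very poorly and serves as a framework check.
#'
#' @param sites A [site_table].
#' @param variant One of `"A"` to `"H"`.
#' @param alpha Fitted global factor, only for variants F, G, H; `NA`
#'   requests fitting.
#' @return An object of class `od_model`.
#' @export
make_variant <- function(sites, variant, alpha = NULL) {
  if (!variant %in% names(RADIATION_VARIANTS)) {
    stop_usage("unknown radiation variant: ", variant)
  }
  v <- RADIATION_VARIANTS[[variant]]
  if (v$fitted) {
    if (is.null(alpha)) alpha <- NA_real_
    if (!is.na(alpha) && alpha <= 0) stop_usage("alpha must be > 0")
  } else if (!is.null(alpha)) {
    stop_usage("variant ", variant, " has no fitted factor alpha")
  }
  structure(list(family = "radiation", variant = variant, label = v$label,
                 m_col = v$m, n_col = v$n, t_col = v$t,
                 fitted = v$fitted, normalised = v$normalised,
                 alpha = if (v$fitted) alpha else NULL),
            class = "od_model")
}

#' Specify a production-constrained gravity model
#'
#' Uses departing commuters as the outflow parameter (\eqn{t_i = O_i}) and
#' arriving commuters as the attractiveness (\eqn{n_i = I_i}), with a single
#' global deterrence parameter \eqn{\beta}; `beta = NA` requests maximum
#' likelihood fitting.
#'
#' @param beta Deterrence parameter; `NA` to fit.
#' @param deterrence `"power"` or `"exponential"`.
#' @return An object of class `od_model`.
#' @export
gravity_model <- function(beta = NA_real_,
                          deterrence = c("power", "exponential")) {
  deterrence <- match.arg(deterrence)
  if (!is.na(beta) && beta < 0) stop_usage("beta must be >= 0")
  structure(list(family = "gravity", label = "Production-constrained gravity",
                 deterrence = deterrence, t_col = "out_flow",
                 n_col = "in_flow", fitted = TRUE, beta = beta),
            class = "od_model")
}

model_id <- function(model) {
  if (model$family == "gravity") "gravity" else model$variant
}

#' @export
print.od_model <- function(x, ...) {
  if (x$family == "gravity") {
    cat("Production-constrained gravity model (", x$deterrence,
        " deterrence), beta = ", format(x$beta), "\n", sep = "")
  } else {
    cat("Radiation model ", x$variant, ": ", x$label,
        if (x$normalised) " [normalised]", "\n", sep = "")
    cat("  m = ", x$m_col, ", n = ", x$n_col, ", t = ",
        if (x$fitted) "alpha * " else "", x$t_col,
        if (x$fitted) paste0(" (alpha = ", format(x$alpha), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

# Resolve a model's site parameter vectors against a site table.
model_site_params <- function(model, sites) {
  need <- unique(c(model$t_col, model$n_col, model$m_col))
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0) {
    stop_data("model requires site column(s) not present: ",
              paste(missing_cols, collapse = ", "))
  }
  p <- list(t = sites[[model$t_col]], n = sites[[model$n_col]])
  if (model$family == "radiation") {
    p$m <- sites[[model$m_col]]
    if (model$fitted) {
      if (is.na(model$alpha)) stop_usage("alpha not set; fit it first")
      p$t <- model$alpha * p$t
    }
  }
  p
}

#' Predicted flows for a model specification
#'
#' Evaluates an `od_model` (from [gravity_model()] or [make_variant()]) on a
#' site table and distance matrix. Global parameters must be set; use
#' [evaluate_model()] to fit them by maximum likelihood first.
#'
#' @param model An `od_model`.
#' @param sites A [site_table].
#' @param D Distance matrix in canonical site order.
#' @param io Optional precomputed [intervening_opportunities()] for the
#'   model's attractiveness column (radiation only); recomputed if missing.
#' @return Matrix of predicted flows.
#' @export
predict_flows <- function(model, sites, D, io = NULL) {
  p <- model_site_params(model, sites)
  if (model$family == "gravity") {
    if (is.na(model$beta)) stop_usage("beta not set; fit it first")
    gravity_predict(p$t, p$n, D, model$beta, model$deterrence)
  } else {
    if (is.null(io)) io <- intervening_opportunities(p$n, D)
    radiation_predict(p$t, p$m, p$n, io, model$normalised)
  }
}

#' Serialise / deserialise a model specification
#'
#' `model_to_config()` renders an `od_model` as a plain list suitable for
#' YAML/JSON (family, variant, deterrence, beta, alpha, normalised and the
#' site columns used); `model_from_config()` rebuilds the model, enabling
#' exact re-runs.
#'
#' @param model An `od_model`.
#' @return A named list.
#' @export
model_to_config <- function(model) {
  cfg <- list(family = model$family)
  if (model$family == "gravity") {
    cfg$deterrence <- model$deterrence
    cfg$beta <- model$beta
  } else {
    cfg$variant <- model$variant
    cfg$normalised <- model$normalised
    if (model$fitted) cfg$alpha <- model$alpha
  }
  cfg$site_columns <- list(t = model$t_col, n = model$n_col)
  if (model$family == "radiation") cfg$site_columns$m <- model$m_col
  cfg
}

#' @rdname model_to_config
#' @param config A list as produced by `model_to_config()`.
#' @param sites A [site_table] used to rebuild radiation variants.
#' @export
model_from_config <- function(config, sites = NULL) {
  if (identical(config$family, "gravity")) {
    gravity_model(beta = config$beta %||% NA_real_,
                  deterrence = config$deterrence %||% "power")
  } else if (identical(config$family, "radiation")) {
    make_variant(sites, config$variant,
                 alpha = config$alpha)
  } else {
    stop_usage("unknown model family in config: ", config$family)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
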