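# Seeded generator of synthetic commuter-flow systems: heavy-tailed site
# populations scattered over a region, flows drawn from a ground-truth
# spatial interaction model via independent Poisson sampling, and realised
# marginals written back so every model variant can be fitted to the
# generated data exactly as it would be to census data.

#' Configuration for the synthetic system generator
#'
#' Defaults describe a scaled-down continental commuting system:
#' heavy-tailed lognormal populations (median \eqn{e^{8} \approx 3000}
#' persons, log-scale sd 1.5 — the relative spread of US county
#' populations — floored at 100, roughly the smallest inhabited counties),
#' sites scattered uniformly over a 1000 km square, 10% of residents
#' commuting out of their site, and a production-constrained gravity truth
#' with power-law exponent \eqn{\beta = 2}. The resulting flow matrices are
#' dominated by zeros and small counts with a long right tail (about 70%
#' of ordered pairs are zero at the default size), every site has positive
#' realised in- and out-flow, and individual sites show strong in/out-flow
#' asymmetry — the qualitative features of county-to-county worker-flow
#' data.
#'
#' @param n_sites Number of sites (>= 2).
#' @param geometry `"square"` (planar, Euclidean distances in km) or
#'   `"latlon"` (uniform in a lat/lon box, great-circle distances).
#' @param side_km Side length of the square region, km.
#' @param lat_range,lon_range Bounds of the lat/lon box, decimal degrees.
#' @param pop_meanlog,pop_sdlog Log-scale mean and sd of the lognormal site
#'   populations.
#' @param pop_min Lower floor on site population, persons.
#' @param outflow_fraction Fraction of each site's population commuting
#'   out: the truth model's \eqn{t_i = \mathrm{round}(f \cdot P_i)}.
#' @param truth Ground-truth model: a list with `family` (`"gravity"` or
#'   `"radiation"`) and, for gravity, `beta` and `deterrence`; for
#'   radiation, `normalised`. The truth uses population as attractiveness
#'   (and aspiration, for radiation).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A list of class `od_sim_config`.
#' @export
synthetic_config <- function(n_sites = 200,
                             geometry = c("square", "latlon"),
                             side_km = 1000,
                             lat_range = c(30, 48),
                             lon_range = c(-120, -80),
                             pop_meanlog = 8,
                             pop_sdlog = 1.5,
                             pop_min = 100,
                             outflow_fraction = 0.1,
                             truth = list(family = "gravity", beta = 2,
                                          deterrence = "power"),
                             seed) {
  geometry <- match.arg(geometry)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_usage("seed is mandatory: the generator has no implicit randomness")
  }
  if (n_sites < 2) stop_usage("n_sites must be >= 2")
  if (geometry == "square" && side_km <= 0) {
    stop_usage("degenerate region: side_km must be > 0")
  }
  if (geometry == "latlon" &&
      (diff(range(lat_range)) <= 0 || diff(range(lon_range)) <= 0)) {
    stop_usage("degenerate region: lat/lon box has zero area")
  }
  if (outflow_fraction <= 0 || outflow_fraction > 1) {
    stop_usage("outflow_fraction must be in (0, 1]")
  }
  if (pop_min < 1) stop_usage("pop_min must be >= 1")
  vals <- c(side_km, lat_range, lon_range, pop_meanlog, pop_sdlog,
            pop_min, outflow_fraction)
  if (!all(is.finite(vals))) stop_usage("all parameters must be finite")
  if (!identical(truth$family, "gravity") &&
      !identical(truth$family, "radiation")) {
    stop_usage("truth$family must be 'gravity' or 'radiation'")
  }
  structure(list(n_sites = as.integer(n_sites), geometry = geometry,
                 side_km = side_km, lat_range = lat_range,
                 lon_range = lon_range, pop_meanlog = pop_meanlog,
                 pop_sdlog = pop_sdlog, pop_min = pop_min,
                 outflow_fraction = outflow_fraction,
                 truth = truth, seed = as.integer(seed)),
            class = "od_sim_config")
}

# Deterministic per-stage sub-seed, kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage) %% .Machine$integer.max)
}

#' Generate synthetic sites and their distance matrix
#'
#' Coordinates are uniform over the configured region; populations are
#' lognormal, rounded up to at least 1. Deterministic given the seed.
#'
#' @param config An [synthetic_config()] object.
#' @return A list with `sites` (a [site_table], marginals zeroed) and
#'   `distances` (matrix, km).
#' @export
generate_sites <- function(config) {
  restore <- .Random.seed_restore(stage_seed(config$seed, 1L))
  on.exit(restore())
  n <- config$n_sites
  ids <- sprintf("s%04d", seq_len(n))
  P <- pmax(config$pop_min %||% 1,
            ceiling(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog)))
  if (config$geometry == "square") {
    x <- stats::runif(n, 0, config$side_km)
    y <- stats::runif(n, 0, config$side_km)
    D <- as.matrix(stats::dist(cbind(x, y)))
    dimnames(D) <- list(ids, ids)
    sites <- site_table(data.frame(site_id = ids, population = P,
                                   out_flow = 0, in_flow = 0))
  } else {
    lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
    lon <- stats::runif(n, config$lon_range[1], config$lon_range[2])
    sites <- site_table(data.frame(site_id = ids, lat = lat, lon = lon,
                                   population = P, out_flow = 0,
                                   in_flow = 0))
    D <- haversine_distances(sites)
  }
  list(sites = sites, distances = D)
}

#' Poisson-sample an observed flow matrix from predicted means
#'
#' Independent Poisson draws with mean \eqn{\hat F_{ij}} for every ordered
#' pair \eqn{i \ne j}; deterministic given the seed.
#'
#' @param Fhat Matrix of predicted means (finite, nonnegative).
#' @param seed Integer seed.
#' @return An integer-valued flow matrix with zero diagonal.
#' @export
sample_flows <- function(Fhat, seed) {
  if (!all(is.finite(Fhat))) stop_numeric("non-finite predicted mean")
  restore <- .Random.seed_restore(seed)
  on.exit(restore())
  off <- row(Fhat) != col(Fhat)
  F <- matrix(0, nrow(Fhat), ncol(Fhat), dimnames = dimnames(Fhat))
  F[off] <- stats::rpois(sum(off), Fhat[off])
  F
}

#' Generate a complete synthetic origin-destination system
#'
#' Pipeline: [generate_sites()], predict mean flows under the ground-truth
#' model (outflow \eqn{t_i = \mathrm{round}(f P_i)}, attractiveness and
#' aspiration \eqn{P_i}), Poisson-sample observed flows, then write the
#' realised marginals \eqn{O_i, I_i} back into the site table. Fitting thus
#' sees data values, not latent truths — the same situation as with real
#' census tables. The returned `truth` element carries the generating model
#' and its parameter for recovery studies.
#'
#' @param config An [synthetic_config()] object.
#' @return A list with `sites`, `distances`, `flows`, `truth` (list:
#'   `model` config, `t`, `attractiveness` vectors) and `config`.
#' @export
generate_system <- function(config) {
  gs <- generate_sites(config)
  sites <- gs$sites
  D <- gs$distances
  P <- sites$population
  t_true <- round(config$outflow_fraction * P)
  tr <- config$truth
  if (tr$family == "gravity") {
    beta <- tr$beta %||% 2
    det <- tr$deterrence %||% "power"
    Fhat <- gravity_predict(t_true, P, D, beta, det)
    truth_model <- list(family = "gravity", beta = beta, deterrence = det)
  } else {
    io <- intervening_opportunities(P, D)
    normalised <- isTRUE(tr$normalised)
    Fhat <- radiation_predict(t_true, P, P, io, normalised)
    truth_model <- list(family = "radiation", normalised = normalised,
                        alpha = config$outflow_fraction)
  }
  F <- sample_flows(Fhat, stage_seed(config$seed, 2L))
  marg <- derive_marginals(F)
  sites$out_flow <- marg$out_flow
  sites$in_flow <- marg$in_flow
  list(sites = sites, distances = D, flows = F,
       truth = list(model = truth_model, t = t_true, attractiveness = P),
       config = config)
}
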