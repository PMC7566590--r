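# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (per-pair loops, grid searches) so
# they share no code path with the vectorised implementations they check.

# A random site system with distinct pairwise distances, positive site
# parameters, integer observed flows and positive predicted flows.
rand_system <- function(n_sites, seed, max_flow = 20) {
  set.seed(seed)
  ids <- paste0("s", seq_len(n_sites))
  x <- runif(n_sites, 0, 100)
  y <- runif(n_sites, 0, 100)
  D <- as.matrix(dist(cbind(x, y)))
  dimnames(D) <- list(ids, ids)
  F <- matrix(rpois(n_sites^2, sample(0:3, n_sites^2, TRUE)), n_sites)
  F[F > max_flow] <- max_flow
  diag(F) <- 0
  dimnames(F) <- list(ids, ids)
  Fhat <- matrix(runif(n_sites^2, 0.01, 10), n_sites)
  diag(Fhat) <- 0
  dimnames(Fhat) <- list(ids, ids)
  list(ids = ids, D = D, F = F, Fhat = Fhat,
       n = runif(n_sites, 0.5, 50), t = runif(n_sites, 1, 100),
       m = runif(n_sites, 0.5, 50))
}

make_sites <- function(P, O, I, lat = NULL, lon = NULL) {
  df <- data.frame(site_id = paste0("s", seq_along(P)), population = P,
                   out_flow = O, in_flow = I)
  if (!is.null(lat)) {
    df$lat <- lat
    df$lon <- lon
  }
  site_table(df)
}

# Per-pair loop over the Poisson log-likelihood terms; strict truncation.
naive_loglik <- function(F, Fhat, f_min) {
  total <- 0
  for (i in seq_len(nrow(F))) for (j in seq_len(ncol(F))) {
    if (i == j || F[i, j] <= f_min) next
    total <- total - Fhat[i, j] + F[i, j] * log(Fhat[i, j]) -
      lgamma(F[i, j] + 1)
  }
  total
}

naive_deviance <- function(F, Fhat, f_min) {
  total <- 0
  for (i in seq_len(nrow(F))) for (j in seq_len(ncol(F))) {
    if (i == j || F[i, j] <= f_min) next
    term <- Fhat[i, j] - F[i, j]
    if (F[i, j] > 0) term <- term + F[i, j] * log(F[i, j] / Fhat[i, j])
    total <- total + 2 * term
  }
  total
}

# Direct enumeration of intervening opportunities: sum of n_k over sites
# strictly closer to i than j, excluding i and j.
naive_intervening <- function(n, D) {
  N <- nrow(D)
  s <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    for (k in seq_len(N)) {
      if (k != i && D[i, k] < D[i, j]) s[i, j] <- s[i, j] + n[k]
    }
  }
  s
}

# 1-D numerical maximisation oracle for the multiplicative factor.
grid_alpha <- function(F, Fhat0, f_min) {
  obj <- function(a) poisson_loglik(F, a * Fhat0, f_min)
  optimize(obj, c(1e-6, 1e3), maximum = TRUE, tol = 1e-10)$maximum
}
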