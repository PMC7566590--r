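# Predicted flows: gravity, intervening opportunities, radiation family,
# variant mappings.

test_that("gravity predictions match hand evaluation and obey the constraint", {
  # 3 sites, t_1 = 10, n = (., 2, 1), d_12 = 1, d_13 = 2, beta = 1, power:
  # denominator 2/1 + 1/2 = 2.5 -> F_12 = 10*2/2.5 = 8, F_13 = 10*0.5/2.5 = 2
  D <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3, 3)
  Fhat <- gravity_predict(c(10, 0, 0), c(5, 2, 1), D, beta = 1, "power")
  expect_equal(Fhat[1, 2], 8)
  expect_equal(Fhat[1, 3], 2)

  # beta = 0: distance-independent split proportional to n
  for (det in c("power", "exponential")) {
    F0 <- gravity_predict(c(10, 4, 6), c(5, 2, 1), D, 0, det)
    expect_equal(F0[1, 2], 10 * 2 / 3)
    expect_equal(F0[2, 1], 4 * 5 / 6)
  }

  # power-law predictions are invariant under rescaling all distances
  F1 <- gravity_predict(c(10, 4, 6), c(5, 2, 1), D, 1.7, "power")
  expect_equal(gravity_predict(c(10, 4, 6), c(5, 2, 1), 7 * D, 1.7, "power"),
               F1, tolerance = 1e-12)

  # production constraint on random systems, both deterrence forms
  for (seed in 1:10) {
    sys <- rand_system(25, seed)
    beta <- runif(1, 0.2, 4)
    for (det in c("power", "exponential")) {
      Fh <- gravity_predict(sys$t, sys$n, sys$D, beta, det)
      expect_equal(rowSums(Fh), sys$t, tolerance = 1e-9,
                   ignore_attr = TRUE)
      off <- row(Fh) != col(Fh)
      expect_true(all(Fh[off] > 0))
    }
  }

  Dz <- D; Dz[1, 2] <- Dz[2, 1] <- 0
  expect_error(gravity_predict(c(1, 1, 1), c(1, 1, 1), Dz, 1, "power"),
               class = "od_data_error")
  expect_error(gravity_predict(c(1, 1, 1), c(0, 0, 0), D, 1, "power"),
               class = "od_data_error")
})

test_that("intervening opportunities enumerate strictly closer sites", {
  # site A with neighbours at d = (1, 2, 3), n = (10, 20, 30)
  D <- matrix(c(0, 1, 2, 3,
                1, 0, 1.1, 2.2,
                2, 1.1, 0, 1.3,
                3, 2.2, 1.3, 0), 4, 4)
  n <- c(99, 10, 20, 30)  # n_A irrelevant to s_Aj
  io <- intervening_opportunities(n, D)
  expect_equal(io$s[1, 2], 0)        # nearest: nothing closer
  expect_equal(io$s[1, 3], 10)
  expect_equal(io$s[1, 4], 30)       # 10 + 20
  expect_equal(io$N_c, sum(n))

  # two-site system: both directions have no intervening mass
  io2 <- intervening_opportunities(c(4, 7), matrix(c(0, 5, 5, 0), 2))
  expect_true(all(io2$s == 0))

  # brute-force oracle on random systems; monotone along sorted sweeps
  for (seed in 1:8) {
    sys <- rand_system(20, seed)
    io <- intervening_opportunities(sys$n, sys$D)
    expect_equal(unname(io$s), naive_intervening(sys$n, sys$D),
                 tolerance = 1e-12)
    for (i in 1:20) {
      ord <- order(sys$D[i, -i])
      expect_true(all(diff(io$s[i, -i][ord]) >= 0))
    }
    # s_ij <= N_c - n_i - n_j
    bound <- io$N_c - outer(sys$n, sys$n, "+")
    off <- row(io$s) != col(io$s)
    expect_true(all(io$s[off] <= bound[off] + 1e-9))
  }

  # exact distance ties are detected
  Dt <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
  expect_warning(intervening_opportunities(c(1, 1, 1), Dt), "ties")
})

test_that("radiation predictions match hand values and row-sum identities", {
  # t_A = 100, m_A = 5, n_B = 10, s_AB = 0 -> 100 * 50 / (5 * 15) = 66.667
  io <- list(s = matrix(0, 2, 2), N_c = 15)
  Fh <- radiation_predict(t = c(100, 0), m = c(5, 1), n = c(5, 10), io)
  expect_equal(Fh[1, 2], 100 * 50 / (5 * 15))

  # telescoping: m_A = n_A = 5, n_B = 10, n_C = 20, distinct distances
  D <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3, 3)
  n <- c(5, 10, 20)
  io3 <- intervening_opportunities(n, D)
  Fh3 <- radiation_predict(c(100, 0, 0), n, n, io3, normalised = FALSE)
  expect_equal(sum(Fh3[1, ]), 100 * 30 / 35, tolerance = 1e-12)
  Fh3n <- radiation_predict(c(100, 0, 0), n, n, io3, normalised = TRUE)
  expect_equal(sum(Fh3n[1, ]), 100, tolerance = 1e-12)

  # identities on random tie-free systems, checked against direct sums
  for (seed in 1:10) {
    sys <- rand_system(30, seed)
    io_r <- intervening_opportunities(sys$n, sys$D)
    N_c <- io_r$N_c
    raw <- radiation_predict(sys$t, sys$n, sys$n, io_r, normalised = FALSE)
    expect_equal(rowSums(raw), sys$t * (N_c - sys$n) / N_c,
                 tolerance = 1e-9, ignore_attr = TRUE)
    norm <- radiation_predict(sys$t, sys$n, sys$n, io_r, normalised = TRUE)
    expect_equal(rowSums(norm), sys$t, tolerance = 1e-9,
                 ignore_attr = TRUE)
    off <- row(raw) != col(raw)
    expect_true(all(raw[off] > 0))
  }

  expect_error(radiation_predict(c(1, 1), c(0, 1), c(1, 1), io),
               class = "od_data_error")  # m = 0 with t > 0
  expect_silent(radiation_predict(c(0, 1), c(0, 1), c(1, 1), io))
  expect_error(radiation_predict(c(1, 1), c(20, 1), c(1, 1), io,
                                 normalised = TRUE),
               class = "od_data_error")  # m >= N_c
})

test_that("variant factory maps site data per the standard table", {
  sites <- make_sites(P = c(3, 4), O = c(5, 6), I = c(1, 2))
  expected <- list(
    A = list(m = "population", n = "population", t = "population",
             norm = FALSE, fitted = FALSE),
    B = list(m = "out_flow", n = "out_flow", t = "out_flow",
             norm = FALSE, fitted = FALSE),
    C = list(m = "out_flow", n = "out_flow", t = "out_flow",
             norm = TRUE, fitted = FALSE),
    D = list(m = "out_flow", n = "in_flow", t = "out_flow",
             norm = FALSE, fitted = FALSE),
    E = list(m = "in_flow", n = "in_flow", t = "out_flow",
             norm = TRUE, fitted = FALSE),
    F = list(m = "population", n = "population", t = "population",
             norm = FALSE, fitted = TRUE),
    G = list(m = "out_flow", n = "out_flow", t = "out_flow",
             norm = FALSE, fitted = TRUE),
    H = list(m = "in_flow", n = "in_flow", t = "out_flow",
             norm = TRUE, fitted = TRUE))
  for (v in names(expected)) {
    e <- expected[[v]]
    model <- make_variant(sites, v, alpha = if (e$fitted) 2)
    expect_identical(model$m_col, e$m, info = v)
    expect_identical(model$n_col, e$n, info = v)
    expect_identical(model$t_col, e$t, info = v)
    expect_identical(model$normalised, e$norm, info = v)
    p <- odmodels:::model_site_params(model, sites)
    expect_equal(p$m, sites[[e$m]], info = v)
    expect_equal(p$n, sites[[e$n]], info = v)
    expect_equal(p$t, (if (e$fitted) 2 else 1) * sites[[e$t]], info = v)
  }

  # variant A: m = n = t = P; variant E: m = n = I, t = O, normalised
  a <- make_variant(sites, "A")
  expect_false(a$normalised)
  e <- make_variant(sites, "E")
  expect_true(e$normalised)

  expect_error(make_variant(sites, "A", alpha = 2),
               class = "od_usage_error")
  m_f <- make_variant(sites, "F")  # alpha left to fit
  expect_true(is.na(m_f$alpha))
  expect_error(odmodels:::model_site_params(m_f, sites),
               class = "od_usage_error")
  expect_error(make_variant(sites, "Z"), class = "od_usage_error")
})

test_that("normalisation factors follow N_c / (N_c - m)", {
  expect_equal(normalisation_factors(0, 10), 1)
  expect_equal(normalisation_factors(5, 10), 2)
  expect_equal(normalisation_factors(c(1, 2), 1e9), c(1, 1),
               tolerance = 1e-6)
  expect_error(normalisation_factors(10, 10), class = "od_data_error")
})

test_that("model specs serialise to config lists and back", {
  sites <- make_sites(P = c(3, 4), O = c(5, 6), I = c(1, 2))
  g <- gravity_model(beta = 1.5, deterrence = "exponential")
  g2 <- model_from_config(model_to_config(g))
  expect_equal(g2$beta, 1.5)
  expect_equal(g2$deterrence, "exponential")

  h <- make_variant(sites, "H", alpha = 0.4)
  cfg <- model_to_config(h)
  expect_true(cfg$normalised)
  h2 <- model_from_config(cfg, sites)
  expect_equal(h2$alpha, 0.4)
  expect_identical(h2$variant, "H")
})
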