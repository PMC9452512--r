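mk_series <- function(time_h, od, gfp) {
  data.frame(time_h = time_h, od600 = od, gfp = gfp)
}

test_that("series normalization subtracts blanks and divides by OD", {
  s <- mk_series(0:2, c(1, 1, 1), c(100, 100, 100))
  expect_equal(normalize_series(s)$norm_expr, rep(100, 3))
  s2 <- mk_series(0:2, c(2, 2, 2), c(110, 110, 110))
  expect_equal(normalize_series(s2, blank_gfp = 10)$norm_expr, rep(50, 3))
  # proportional GFP on a logistic growth curve gives a flat normalized signal
  t <- seq(0, 20, by = 1 / 6)
  od <- 1.5 / (1 + 14 * exp(-0.4 * t))
  s3 <- mk_series(t, od + 0.04, 80 * od + 5)
  ns <- normalize_series(s3, blank_gfp = 5, blank_od = 0.04)
  expect_equal(ns$norm_expr[!is.na(ns$norm_expr)],
               rep(80, sum(!is.na(ns$norm_expr))))
  # scale consistency: doubling both channels (zero blanks) changes nothing
  s4 <- mk_series(t, 2 * od, 2 * 80 * od)
  expect_equal(normalize_series(s4)$norm_expr,
               normalize_series(mk_series(t, od, 80 * od))$norm_expr)
  # OD floor masks early points; all-masked input errors
  expect_true(any(is.na(normalize_series(
    mk_series(0:2, c(0.005, 0.05, 1), c(1, 1, 1)))$norm_expr)))
  expect_error(normalize_series(mk_series(0:2, rep(0.001, 3), rep(1, 3))),
               "below OD floor")
})

test_that("window averaging covers 8.5-9.5 h inclusively at 10-min cadence", {
  t <- seq(0, 20, by = 1 / 6)
  s <- normalize_series(mk_series(t, rep(1, length(t)), rep(42, length(t))))
  w <- window_average(s)
  expect_equal(w$mean, 42)
  expect_equal(w$n_readings, 7)
  # linear ramp averages to its 9.0 h midpoint value
  ramp <- normalize_series(mk_series(t, rep(1, length(t)), 10 * t))
  expect_equal(window_average(ramp)$mean, 90, tolerance = 1e-9)
  expect_error(window_average(s, window = c(30, 31)), "empty window")
})

test_that("specific and non-specific responses are linear differences", {
  expect_equal(specific_response(c(5, 5), c(5, 5))$response, 0)
  expect_equal(specific_response(1000, 200)$response, 800)
  expect_error(specific_response(numeric(0), 1), "missing condition")
  expect_equal(nonspecific_response(c(1, 1), c(1, 1))$response, 0)
  expect_equal(nonspecific_response(300, 100)$response, 200)
  expect_equal(nonspecific_response(100, 300)$response, -200)
  expect_error(nonspecific_response(1, numeric(0)), "reference missing")
})

test_that("copies-per-cell conversion reproduces the published estimates", {
  expect_equal(copies_to_concentration(538, 4.2), 213, tolerance = 0.005)
  expect_equal(copies_to_concentration(0, 4.2), 0)
  expect_equal(copies_to_concentration(3334, 4.2), 1318, tolerance = 0.005)
  expect_error(copies_to_concentration(10, 0), "volume")
})

test_that("occupancy predictions delegate to the binding model", {
  w3 <- n_identical_sites(3, kd = 100)
  p <- predict_occupancy(list(w3), 100)
  expect_equal(p$n_mean, 1.5)
  s1 <- cluster_design("s1", list(binding_site("a", 0, 9, "S", kd = 10)))
  expect_equal(predict_occupancy(list(s1), 10)$n_mean, 0.5)
  # adding sites never decreases independent-model occupancy
  lib <- fixture_library()
  for (cc in c(10, 100, 1000)) {
    p2 <- predict_occupancy(lib[c("W3", "W3Vm3")], cc)
    expect_gte(p2$n_mean[p2$target_id == "W3Vm3"],
               p2$n_mean[p2$target_id == "W3"])
  }
})

test_that("threshold model is exactly recovered from noiseless data and behaves", {
  occ <- seq(0.1, 3, length.out = 15)
  y <- 20 + 500 * pmax(0, occ - 1)
  tm <- fit_threshold_model(occ, y, n_boot = 0)
  expect_equal(tm$theta, 1, tolerance = 1e-6)
  expect_equal(tm$slope, 500, tolerance = 1e-4)
  expect_equal(tm$baseline, 20, tolerance = 1e-4)
  # predictions continuous and nondecreasing for positive slope
  g <- seq(0, 3, by = 0.01)
  pr <- tm$predict(g)
  expect_true(all(diff(pr) >= -1e-9))
  expect_lt(max(abs(diff(pr))), 500 * 0.011)
  expect_error(fit_threshold_model(runif(10, 0, 0.2),
                                   rep(20, 10) + rnorm(10, 0, 1e-3)),
               "unidentifiable")
})

test_that("threshold recovered within 0.15 from noisy promoter libraries", {
  set.seed(3)
  occ <- seq(0.05, 3.2, length.out = 20)
  y <- 20 + 500 * pmax(0, occ - 1)
  y <- y + rnorm(20, 0, 0.10 * max(y))
  tm <- fit_threshold_model(occ, y, n_boot = 100, seed = 3)
  expect_lt(abs(tm$theta - 1), 0.15)
  expect_true(!is.null(tm$theta_ci))
})

test_that("simulated platereader library reproduces the hinge and leak structure", {
  lib <- fixture_library()[c("NS", "Vm3", "W1", "W2", "W3", "W4", "W5", "W6",
                             "S1", "S3", "S6")]
  sim <- simulate_platereader(lib, seed = 9)
  win <- function(strain, cond) {
    d <- sim$series[sim$series$strain_id == strain &
                      sim$series$condition == cond, ]
    vapply(split(d, d$replicate), function(r) {
      window_average(normalize_series(r, blank_gfp = sim$blanks$gfp,
                                      blank_od = sim$blanks$od))$mean
    }, numeric(1))
  }
  spec <- vapply(names(lib), function(s) {
    specific_response(win(s, "induced"), win(s, "uninduced"))$response
  }, numeric(1))
  nonspec <- vapply(names(lib), function(s) {
    nonspecific_response(win(s, "uninduced"), win("NS", "uninduced"))$response
  }, numeric(1))
  truth <- sim$truth
  below <- truth$target_id[truth$n_mean_induced < truth$theta[1]]
  above <- truth$target_id[truth$n_mean_induced > truth$theta[1] + 0.3]
  # promoters below threshold: near-zero specific response
  expect_true(all(abs(spec[below]) < 15))
  expect_true(all(spec[above] > 50))
  # non-specific response monotone in site count (leak proportional to sites)
  ord <- order(truth$n_sites[match(names(lib), truth$target_id)])
  expect_true(all(diff(nonspec[ord]) > -5))
  # response ordering tracks the generator's occupancy ordering (W family)
  wfam <- paste0("W", 1:6)
  occ_w <- truth$n_mean_induced[match(wfam, truth$target_id)]
  expect_gt(cor(spec[wfam], pmax(0, occ_w - 1), method = "spearman"), 0.9)
})

test_that("platereader simulation is reproducible and respects the leak knob", {
  lib <- fixture_library()[c("NS", "W3")]
  a <- simulate_platereader(lib, seed = 4)
  b <- simulate_platereader(lib, seed = 4)
  expect_identical(a$series, b$series)
  # leak = 0, uninduced: all strains at baseline
  z <- simulate_platereader(lib, leak_per_site = 0, gfp_noise_sd = 0,
                            od_noise_sd = 0, seed = 5)
  for (s in names(lib)) {
    d <- z$series[z$series$strain_id == s & z$series$condition == "uninduced" &
                    z$series$replicate == 1, ]
    w <- window_average(normalize_series(d, blank_gfp = z$blanks$gfp,
                                         blank_od = z$blanks$od))
    expect_equal(w$mean, 20, tolerance = 1e-6)
  }
})
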