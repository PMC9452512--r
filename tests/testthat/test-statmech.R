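test_that("state enumeration matches the overlap structure", {
  d <- two_overlapping_sites()
  expect_equal(nrow(enumerate_states(d, "exclusive")), 3)
  expect_equal(nrow(enumerate_states(d, "permissive")), 4)
  # 4-site chain where only consecutive pairs overlap: 8 exclusive states
  chain <- cluster_design("chain", lapply(1:4, function(i) {
    binding_site(paste0("s", i), (i - 1) * 6, 9, "S", kd = 10)
  }), target_length = 40)
  expect_equal(nrow(enumerate_states(chain, "exclusive")), 8)
  expect_equal(nrow(enumerate_states(chain, "permissive")), 16)
  # brute-force independent-set count agrees
  bf <- bf_statmech(c(0, 6, 12, 18), rep(9, 4), rep(10, 4), 1,
                    mode = "exclusive")
  expect_equal(bf$n_states, 8)
  expect_error(
    enumerate_states(n_identical_sites(4), cap = 3), "capped")
})

test_that("weights, partition function and occupancy match worked examples", {
  d <- two_overlapping_sites(kd = 10)
  m <- statmech_model("permissive", clash_energy = log(2))
  states <- enumerate_states(d, "permissive")
  empty <- states[states$n_bound == 0, ]
  both <- states[states$n_bound == 2, ]
  expect_equal(state_weight(empty, 123, d, m), 1)
  expect_equal(state_weight(both, 10, d, m), 0.5)
  expect_equal(partition_function(d, 10, m), 3.5)
  expect_equal(partition_function(d, 0, m), 1)
  expect_equal(mean_occupancy(d, 10, m), 6 / 7)
  # single site at c = K_d: Z = 2, Langmuir midpoint
  s1 <- cluster_design("s1", list(binding_site("a", 0, 9, "S", kd = 50)))
  expect_equal(partition_function(s1, 50, statmech_model("permissive")), 2)
  expect_equal(mean_occupancy(s1, 50, statmech_model("independent")), 0.5)
  # two non-overlapping identical sites at c = K_d
  expect_equal(mean_occupancy(n_identical_sites(2, kd = 100), 100,
                              statmech_model("permissive")), 1.0)
  expect_error(partition_function(d, -1, m), "negative")
})

test_that("state probabilities normalise and have the right limits", {
  d <- two_overlapping_sites(kd = 10)
  m <- statmech_model("permissive", clash_energy = 1.5)
  conc <- c(0, 0.1, 1, 10, 1e3, 1e6)
  sp <- state_probabilities(d, conc, m)
  for (cc in conc) {
    expect_equal(sum(sp$prob[sp$conc_nM == cc]), 1, tolerance = 1e-12)
  }
  p0 <- sp[sp$conc_nM == 0, ]
  expect_equal(p0$prob[p0$n_bound == 0], 1)
  expect_equal(sum(p0$prob[p0$n_bound > 0]), 0)
  # doubly-bound state dominates at high c for any finite clash energy
  ph <- sp[sp$conc_nM == 1e6, ]
  expect_gt(ph$prob[ph$n_bound == 2], 0.99)
  expect_equal(sp$occ_contrib, sp$n_bound * sp$prob)
})

test_that("enumeration agrees with brute force and the 2-site closed form", {
  # closed form, asymmetric K_ds, across eps and concentration
  d <- cluster_design("asym", list(
    binding_site("a", 0, 9, "S", kd = 8),
    binding_site("b", 6, 9, "W", kd = 90)
  ))
  for (eps in c(0, 0.7, 2, 5)) {
    m <- statmech_model("permissive", clash_energy = eps)
    for (cc in c(0.01, 1, 8, 90, 1e4)) {
      cf <- bf_two_site_closed_form(8, 90, cc, eps)
      expect_equal(partition_function(d, cc, m), cf$Z, tolerance = 1e-12)
      expect_equal(mean_occupancy(d, cc, m), cf$n_mean, tolerance = 1e-12)
      sp <- state_probabilities(d, cc, m)
      expect_equal(sort(sp$prob), sort(cf$probs), tolerance = 1e-12)
    }
  }
  # brute-force subset loop across assorted designs and modes
  lib <- fixture_library()
  pick <- lib[c("W3", "ovl3_S3", "ovl1_W4", "W3Vm3", "spacing_W_d00")]
  for (d in pick) {
    starts <- vapply(d$sites, `[[`, integer(1), "start")
    lens <- vapply(d$sites, `[[`, integer(1), "length")
    kds <- site_kds(d)
    for (mode in c("permissive", "exclusive")) {
      eps <- 1.3
      m <- statmech_model(mode, clash_energy = if (mode == "permissive") eps else 0)
      for (cc in c(0.5, 20, 500)) {
        bf <- bf_statmech(starts, lens, kds, cc, eps, mode)
        expect_equal(partition_function(d, cc, m), bf$Z, tolerance = 1e-12)
        expect_equal(mean_occupancy(d, cc, m), bf$n_mean, tolerance = 1e-12)
      }
    }
  }
})

test_that("permissive model has independent and exclusive limits", {
  d <- two_overlapping_sites(kd = 25)
  conc <- 10^seq(-2, 3, length.out = 30) * 25
  ind <- mean_occupancy(d, conc, statmech_model("independent"))
  expect_equal(mean_occupancy(d, conc, statmech_model("permissive", 0)),
               ind, tolerance = 1e-10)
  # a design with no overlaps is independent under any clash energy
  d2 <- n_identical_sites(3, kd = 40)
  expect_equal(
    mean_occupancy(d2, conc, statmech_model("permissive", clash_energy = 7)),
    mean_occupancy(d2, conc, statmech_model("independent")),
    tolerance = 1e-10)
  excl <- mean_occupancy(d, conc, statmech_model("exclusive"))
  expect_equal(mean_occupancy(d, conc, statmech_model("permissive", 30)),
               excl, tolerance = 1e-8)
})

test_that("occupancy curves are monotone, bounded, and report the right n_max", {
  conc <- 10^seq(-2, 5, length.out = 40)
  # monotone nondecreasing in c, in [0, n_sites]
  for (nm in c("W3", "ovl3_S2", "ovl1_W3")) {
    d <- fixture_library()[[nm]]
    for (m in list(statmech_model("independent"),
                   statmech_model("exclusive"),
                   statmech_model("permissive", clash_energy = 2))) {
      oc <- occupancy_curve(d, conc, m)
      expect_true(all(diff(oc$n_mean) >= -1e-12))
      expect_true(all(oc$n_mean >= 0 & oc$n_mean <= d$n_sites + 1e-12))
    }
  }
  d <- two_overlapping_sites()
  expect_equal(attr(occupancy_curve(d, conc, statmech_model("exclusive")),
                    "n_max"), 1)
  expect_equal(attr(occupancy_curve(d, conc,
                                    statmech_model("permissive", 4)),
                    "n_max"), 2)
  # occupancy despite clash: <N> exceeds 1 at high c for any finite eps
  for (eps in c(0.5, 2, 6, 12)) {
    m <- statmech_model("permissive", clash_energy = eps)
    expect_gt(max(mean_occupancy(d, 10^seq(0, 9, length.out = 50), m)), 1)
  }
  # <N> nonincreasing in clash energy at fixed c
  occ_by_eps <- vapply(seq(0, 10, by = 0.5), function(e) {
    mean_occupancy(d, 100, statmech_model("permissive", clash_energy = e))
  }, numeric(1))
  expect_true(all(diff(occ_by_eps) <= 1e-12))
})

test_that("replacing a strong site by a weak one never increases occupancy", {
  mk <- function(classes) {
    cluster_design("x", lapply(seq_along(classes), function(i) {
      binding_site(paste0("s", i), (i - 1) * 6, 9, classes[i],
                   consensus_kd = 10)
    }), target_length = 30)
  }
  m <- statmech_model("permissive", clash_energy = 2)
  conc <- 10^seq(-1, 4, length.out = 25)
  strong <- mean_occupancy(mk(c("S", "S", "S")), conc, m)
  for (weakened in list(c("W", "S", "S"), c("S", "W", "S"), c("S", "S", "W"))) {
    expect_true(all(mean_occupancy(mk(weakened), conc, m) <= strong + 1e-12))
  }
})

test_that("K_d to binding-energy conversion is exact and invertible", {
  expect_equal(kd_to_energy(5, 5), 0)
  expect_equal(kd_to_energy(10, 1), log(10))
  for (kd in c(0.03, 1, 17, 4e5)) {
    expect_equal(energy_to_kd(kd_to_energy(kd, 2), 2), kd, tolerance = 1e-12)
  }
  expect_error(kd_to_energy(-1, 1))
})
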