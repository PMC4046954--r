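test_that("turbulent velocity follows the structure-function scaling", {
  expect_equal(turbulent_velocity(0, 3.5), 0)
  expect_equal(turbulent_velocity(1e-7, 3.5),
               sqrt(1.62 * 0.35^(2 / 3)), tolerance = 1e-12)
  expect_equal(turbulent_velocity(1e-7, 3.5), 0.897, tolerance = 1e-3)
  # w scales as epsilon^(1/3)
  expect_equal(turbulent_velocity(1e-4, 3.5),
               10 * turbulent_velocity(1e-7, 3.5), tolerance = 1e-12)
  expect_error(turbulent_velocity(-1e-9, 3.5),
               class = "larvforage_domain_error")
})

test_that("predation-sequence success terms are correct fractions", {
  # observation: type-2 response with half-detection at y_det
  expect_equal(observation_success(0.07, 0.07), 0.5)
  expect_equal(observation_success(0.21, 0.07), 0.75)
  expect_gt(observation_success(1e6, 0.07), 0.9999)
  l <- seq(0.045, 1.995, by = 0.01)
  expect_true(all(diff(observation_success(l, 0.07)) > 0))

  # pursuit: linear ramp down in turbulent velocity
  expect_equal(pursuit_success(0, 7, 1), 1)
  expect_equal(pursuit_success(7, 7, 1), 0)
  expect_equal(pursuit_success(0.897, 7, 1), 1 - 0.897 / 7)
  expect_equal(pursuit_success(100, 7, 1), 0) # floored at zero

  # capture: linear ramp down to the maximum ingestible length
  expect_equal(capture_success(0.157 * 7 / 2, 7, 0.157), 0.5)
  expect_equal(round(capture_success(1.10, 7, 0.157), 3), 0)
  expect_equal(capture_success(0.2, 7, 0.0384), 1 - 0.2 / 0.2688,
               tolerance = 1e-12)
  expect_true(all(capture_success(l, 7, 0.157) >= 0) &&
              all(capture_success(l, 7, 0.157) <= 1))

  # velocities
  expect_equal(prey_velocity(0.2), 0.6)
  expect_equal(prey_velocity(1.0), 3.0)
  expect_equal(prey_velocity(0.5, model_config(prey_speed_coeff = 0)), 0)
  expect_equal(combined_velocity(5.25, 0, 0), 5.25)
  expect_equal(combined_velocity(3, 4, 0), 5)
  expect_equal(combined_velocity(9.75, 0.6, 0), sqrt(95.0625 + 0.36))
})

test_that("clearance rates reproduce the published foraging geometry", {
  env0 <- geometry_env()
  # swept-cylinder geometry alone (no prey swimming, perfect detection)
  cfg_geom <- model_config(prey_speed_coeff = 0)
  geom <- function(sp) {
    lt <- larval_type(sp, y_det = 1e-9)
    clearance_rate(0.2, lt, env0, cfg_geom)
  }
  expect_equal(signif(geom("anchovy"), 1), 0.5)
  expect_equal(signif(geom("cod"), 2), 1.0)
  expect_equal(signif(geom("sprat"), 2), 1.0)
  expect_equal(signif(geom("herring"), 2), 6.7)
  # detection-corrected clearance on 0.2-mm prey, default prey speed
  expect_equal(signif(clearance_rate(0.2, larval_type("herring"), env0), 2), 5.0)
  expect_equal(round(clearance_rate(0.2, larval_type("cod"), env0), 2), 0.78)
  expect_equal(round(clearance_rate(0.2, larval_type("anchovy"), env0), 2), 0.38)
})

test_that("encounter rates are linear in concentration and zero without prey", {
  cod <- larval_type("cod")
  env <- foraging_env(5, 12, epsilon = 1e-7, b_total = 10)
  pf0 <- build_spectrum(0, -1.2)
  br0 <- encounter_rates(pf0, cod, env)
  expect_true(all(br0$E == 0))

  pf1 <- explicit_field(0.205, 4)
  pf2 <- explicit_field(0.205, 8)
  E1 <- encounter_rates(pf1, cod, env)$E
  E2 <- encounter_rates(pf2, cod, env)$E
  expect_equal(E2, 2 * E1, tolerance = 1e-12)
  expect_true(all(br0$O >= 0 & br0$O <= 1))
  expect_true(all(br0$C >= 0 & br0$C <= 1))
})

test_that("optimal-diet capacity equals the exhaustive-subset oracle", {
  cod <- larval_type("cod")
  env <- foraging_env(5, 12, epsilon = 1e-7, b_total = 10)
  centers <- build_spectrum(0, -1.2)$l
  set.seed(42)
  for (rep in 1:6) {
    nb <- sample(4:10, 1)
    bins <- sort(sample(centers[centers < 1.2], nb))
    biom <- stats::runif(nb, 0, 400) # high biomass forces diet exclusion
    pf <- explicit_field(bins, biom)
    br <- foraging_capacity(pf, cod, env)
    oracle <- brute_force_diet_rate(br$E, br$e, cod$y_hand)
    expect_equal(attr(br, "F"), oracle, tolerance = 1e-12)
    # diet-included bins are exactly those of the greedy-optimal prefix
    kept <- sum(br$E[br$in_diet] * br$e[br$in_diet]) /
      (1 + cod$y_hand * sum(br$E[br$in_diet]))
    expect_equal(kept, oracle, tolerance = 1e-12)
  }
  # empty field
  br0 <- foraging_capacity(build_spectrum(0, -1.2), cod, env)
  expect_equal(attr(br0, "F"), 0)
})

test_that("capacity saturates with handling time and grows with biomass", {
  cod <- larval_type("cod")
  env <- foraging_env(5, 12, epsilon = 1e-7, b_total = 10)
  Fs <- vapply(c(1, 5, 25, 125, 3000), function(b) {
    attr(foraging_capacity(build_spectrum(b, -1.2), cod, env), "F")
  }, numeric(1))
  expect_true(all(diff(Fs) > 0)) # nondecreasing in b_total
  pf <- build_spectrum(3000, -1.2)
  br <- foraging_capacity(pf, cod, env)
  expect_lt(attr(br, "F"), max(br$e) / cod$y_hand) # Holling ceiling

  # vanishing handling time: no saturation, F -> sum of E*e
  tiny <- larval_type("cod", y_hand = 1e-9)
  pf2 <- build_spectrum(10, -1.2)
  br2 <- foraging_capacity(pf2, tiny, env)
  expect_equal(attr(br2, "F"), sum(br2$E * br2$e), tolerance = 1e-6)
})

test_that("net turbulence effect is negative at parameterized speeds", {
  # d/dw [V * P] < 0 at w -> 0+ for every built-in type
  for (sp in builtin_types()$species) {
    lt <- larval_type(sp)
    L <- lt$x_len
    u <- lt$y_swim * L
    v <- prey_velocity(0.2)
    VP <- function(w) combined_velocity(u, v, w) * pursuit_success(w, L, lt$y_turb)
    h <- 1e-4
    expect_lt((VP(h) - VP(0)) / h, 0)
  }
})

test_that("Chesson's alpha is a normalized, concentration-invariant index", {
  her <- larval_type("herring")
  env0 <- geometry_env()
  pf <- build_spectrum(10, -1.2)
  a1 <- chesson_alpha(pf, her, env0, L = 13.5)
  expect_equal(sum(a1$alpha), 1, tolerance = 1e-12)
  # invariant to scaling total biomass
  a2 <- chesson_alpha(build_spectrum(500, -1.2), her, env0, L = 13.5)
  expect_equal(a1$alpha, a2$alpha, tolerance = 1e-12)
  # peak for 13.5-mm herring sits in the 0.21-0.22 mm bin
  expect_equal(attr(a1, "peak_l"), 0.215)
  # matches the kernel product recomputed directly
  V <- combined_velocity(0.75 * 13.5, prey_velocity(pf$l), 0)
  expect_equal(a1$alpha,
               (V * observation_success(pf$l, 0.07) *
                  capture_success(pf$l, 13.5, 0.0784)) /
                 sum(V * observation_success(pf$l, 0.07) *
                       capture_success(pf$l, 13.5, 0.0784)),
               tolerance = 1e-12)
  expect_error(chesson_alpha(build_spectrum(0, -1.2), her, env0),
               class = "larvforage_domain_error")
})
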