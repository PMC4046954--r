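test_that("light schedule places one night before one day", {
  expect_equal(light_schedule(0), rep(0, 24))
  expect_equal(light_schedule(24), rep(1, 24))
  lam <- light_schedule(11.8)
  expect_equal(lam, c(rep(0, 12), 0.8, rep(1, 11)))
  for (p in c(0, 3.25, 11.8, 16, 24)) {
    lam <- light_schedule(p)
    expect_equal(sum(lam), p)                      # fractions sum to photoperiod
    expect_true(all(diff(lam) >= 0) || sum(lam == 0) + sum(lam == 1) >= 23)
    expect_lte(sum(lam > 0 & lam < 1), 1)          # at most one fractional hour
    expect_true(all(which(lam == 0) < min(c(which(lam > 0), Inf)))) # dark first
  }
  expect_error(light_schedule(25), class = "larvforage_domain_error")
})

test_that("respiration, activity and digestion follow the Q10 forms", {
  anc <- larval_type("anchovy")
  cod <- larval_type("cod")
  # published per-hour reading (respiration_scale = 1)
  cfg1 <- model_config(respiration_scale = 1)
  expect_equal(routine_respiration(38, 10, anc, cfg1), 0.0411 * 38,
               tolerance = 1e-12)
  expect_equal(round(routine_respiration(38, 10, anc, cfg1), 3), 1.562)
  # package default scales the same loss over the day
  expect_equal(routine_respiration(38, 10, anc), 0.0411 * 38 / 24,
               tolerance = 1e-12)
  # Q10: +10 degC multiplies the rate by x_rQ10
  expect_equal(routine_respiration(38, 20, anc) / routine_respiration(38, 10, anc),
               anc$x_rQ10, tolerance = 1e-12)
  # thermal exclusion above x_tol
  expect_error(routine_respiration(300, 16, cod),
               class = "larvforage_thermal_exclusion")
  expect_error(simulate_day(cod, foraging_env(16, 12, b_total = 10)),
               class = "larvforage_thermal_exclusion")

  expect_equal(activity_multiplier(0, 2), 1)
  expect_equal(activity_multiplier(1, 2), 2)
  expect_equal(activity_multiplier(0.5, 2), 1.5)

  expect_equal(digestive_capacity(358, 10, cod), 0.025 * 358, tolerance = 1e-12)
  expect_equal(round(digestive_capacity(358, 10, cod), 2), 8.95)
  expect_equal(digestive_capacity(358, 20, cod) / digestive_capacity(358, 10, cod),
               2.5, tolerance = 1e-12)
  expect_equal(digestive_capacity(200, 12, cod), 2 * digestive_capacity(100, 12, cod))

  expect_equal(hourly_ingestion(8.95, 10, 0), 0)
  expect_equal(hourly_ingestion(8.95, 1e9, 1), 8.95)
  expect_equal(hourly_ingestion(8.95, 0.001, 0.5), 1.8)
})

test_that("hourly update conserves mass and never shrinks the larva", {
  cod <- larval_type("cod")
  env <- foraging_env(5.1, 11.8, epsilon = 1e-7, b_total = 15)
  state <- list(L = 7, M = 356.72, hour = 1, dead = FALSE)
  field <- build_spectrum(15, -1.2)
  for (t in 1:24) {
    prev <- state
    state <- step_hour(state, env, cod, field = field)
    d <- state$diag
    expect_equal(state$M - prev$M, cod$y_eff * d$I - d$A * d$R,
                 tolerance = 1e-12)
    expect_gte(state$L, prev$L)
    expect_lte(state$M, cod$x_body * state$L^3 + 1e-9)
  }
  # dark hour with zero prey: closed-form decay, length unchanged
  dark_env <- foraging_env(10, 0, epsilon = 0, b_total = 0)
  st <- list(L = 7, M = 100, hour = 1, dead = FALSE)
  st2 <- step_hour(st, dark_env, cod)
  r_eff <- model_config()$respiration_scale * cod$x_res
  expect_equal(st2$M, 100 * (1 - r_eff), tolerance = 1e-12)
  expect_equal(st2$L, 7)
  # at maximum condition with a net gain, growth is isometric
  fat <- list(L = 5, M = larval_type("cod")$x_body * 125, hour = 24, dead = FALSE)
  rich <- foraging_env(10, 24, epsilon = 0, b_total = 1e4)
  st3 <- step_hour(fat, rich, cod, ad_libitum = TRUE)
  expect_gt(st3$M, fat$M)
  expect_equal(st3$M / st3$L^3, cod$x_body, tolerance = 1e-12)
})

test_that("a simulated day closes its mass budget and honours invariants", {
  for (sp in c("cod", "sprat")) {
    lt <- larval_type(sp)
    env <- reference_env(sp)
    res <- simulate_day(lt, env)
    tr <- res$trace
    expect_equal(nrow(tr), 24)
    expect_equal(res$M24 - res$M0, sum(lt$y_eff * tr$I - tr$A * tr$R),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$L) >= 0))
    expect_true(all(tr$M <= lt$x_body * tr$L^3 + 1e-9))
    expect_equal(res$G, log(res$M24 / res$M0), tolerance = 1e-12)
  }
})

test_that("initial masses follow the body-shape trait", {
  m0 <- function(sp) {
    lt <- larval_type(sp)
    simulate_day(lt, foraging_env(10, 12, b_total = 1))$M0
  }
  expect_equal(round(m0("anchovy")), 38)
  expect_equal(round(m0("herring")), 369)
  expect_equal(round(m0("sprat")), 23)
  expect_equal(m0("cod"), 1.04 * 7^3, tolerance = 1e-12)
})

test_that("a dark day without prey decays at the closed-form rate", {
  for (sp in c("anchovy", "herring")) {
    lt <- larval_type(sp)
    cfg <- model_config()
    env <- foraging_env(10, 0, epsilon = 0, b_total = 0)
    res <- simulate_day(lt, env, cfg)
    r_eff <- cfg$respiration_scale * lt$x_res # T = 10: Q10 factor is 1
    expect_equal(res$G, 24 * log(1 - r_eff), tolerance = 1e-12)
  }
  # arithmetic growth definition
  cfgA <- model_config(growth_def = "arithmetic")
  lt <- larval_type("cod")
  resA <- simulate_day(lt, foraging_env(10, 0, epsilon = 0, b_total = 0), cfgA)
  r_eff <- cfgA$respiration_scale * lt$x_res
  expect_equal(resA$G, (1 - r_eff)^24 - 1, tolerance = 1e-12)
})

test_that("growth saturates: monotone in prey, flat above satiation", {
  cod <- larval_type("cod")
  env <- reference_env("cod")
  g <- function(b) {
    e <- env; e$b_total <- b
    simulate_day(cod, e)$G
  }
  bs <- c(0.5, 2, 8, 32)
  gs <- vapply(bs, g, numeric(1))
  expect_true(all(diff(gs) >= 0))
  g_pot <- growth_potential(cod, env$temperature, env$photoperiod)
  sat <- satiation_point(cod, env)
  expect_equal(g(2 * sat), g_pot, tolerance = 1e-6)
  expect_equal(g(10 * sat), g_pot, tolerance = 1e-6)
  # ad libitum: every lit hour digestion-limited with I = D
  res <- simulate_day(cod, env, ad_libitum = TRUE)
  lit <- res$trace$lambda > 0
  expect_true(all(res$trace$limitation[lit] == "digestion-limited"))
  expect_equal(res$trace$I[lit], res$trace$D[lit], tolerance = 1e-12)
  expect_true(all(res$trace$I[!lit] == 0))
})

test_that("tidy, glance and autoplot expose the day result", {
  cod <- larval_type("cod")
  res <- simulate_day(cod, reference_env("cod"))
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(gl$G, res$G)
  expect_equal(gl$lit_hours, 12)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(build_spectrum(10, -1.2)), "ggplot")
  br <- foraging_capacity(build_spectrum(10, -1.2), cod,
                          reference_env("cod"))
  expect_s3_class(autoplot(br), "ggplot")
})
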