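quiet_cfg <- function(...) {
  simulation_config(...)
}

noise_free_cfg <- function(...) {
  simulation_config(
    noise_sd = list(hba1c = 0, weight = 0, fasting_glucose = 0,
                    triglycerides = 0, alt = 0, mmtt_glucose = 0,
                    mmtt_insulin = 0, mmtt_cpeptide = 0, cgm = 0),
    ...)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_per_arm = c(eTRC = 1, Med = 5)), ">= 2")
  expect_error(simulation_config(mmtt_sampling_times = c(15, 30)), "start")
  expect_error(simulation_config(mmtt_sampling_times = c(0, 30, 30)),
               "increasing")
  expect_error(simulation_config(cgm_days = 0), "cgm_days")
  expect_error(
    simulation_config(effect_sizes = list(
      nosuchvar = c(diet = 1, group = 0, interaction = 0))),
    "unknown variable")
})

test_that("the generator is reproducible under a fixed seed", {
  cfg <- quiet_cfg()
  s1 <- simulate_subjects(cfg)
  s2 <- simulate_subjects(cfg)
  expect_identical(s1$subjects, s2$subjects)
  m1 <- simulate_mmtt(s1$truth[[3]], cfg, seed = 42)
  m2 <- simulate_mmtt(s2$truth[[3]], cfg, seed = 42)
  expect_identical(m1$data, m2$data)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$table, t2$table)
  expect_identical(t1$diaries, t2$diaries)
  c1 <- simulate_cgm("Med", cfg, seed = 3)
  c2 <- simulate_cgm("Med", cfg, seed = 3)
  expect_identical(c1$glucose, c2$glucose)
  # and the seed actually matters
  expect_false(identical(simulate_cgm("Med", cfg, seed = 4)$glucose,
                         c1$glucose))
})

test_that("constant glucose at 5.5 with flat potentiation gives ISR at 5.5", {
  cfg <- noise_free_cfg()
  subj <- list(
    betacell = beta_cell_params(100, 120, 0),   # no rate term, P = 1
    kinetics = population_kinetics(65, "M", 170, 80, diabetes = TRUE),
    clearance = 1.5, fasting_glucose = 5.5)
  curve <- data.frame(time = 0:180, glucose = rep(5.5, 181))
  prof <- simulate_mmtt(subj, cfg, seed = 1, glucose_curve = curve)
  expect_equal(prof$truth$isr$isr, rep(120, 181))
  # C-peptide stays at the fasting steady state of that secretion
  css <- 120 / (subj$kinetics$k01 * subj$kinetics$V)
  expect_equal(prof$data$cpeptide, rep(css, 9), tolerance = 1e-8)
  # and insulin at ISR / clearance
  expect_equal(prof$data$insulin, rep(120 / 1.5, 9), tolerance = 1e-8)
})

test_that("simulated C-peptide matches the adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  cfg <- noise_free_cfg()
  s <- simulate_subjects(cfg)
  subj <- s$truth[[1]]
  tt <- seq(0, 180, by = 1)
  gf <- subj$fasting_glucose
  curve <- data.frame(time = tt,
                      glucose = gf + 2.4 * (tt / 45) * exp(1 - tt / 45))
  prof <- simulate_mmtt(subj, cfg, seed = 5, glucose_curve = curve)
  isr_fun <- stats::approxfun(tt, prof$truth$isr$isr, method = "constant",
                              rule = 2)
  oracle <- ode_cpeptide_oracle(isr_fun, subj$kinetics, prof$truth$c0, tt)
  rel <- abs(prof$truth$cpeptide_fine - oracle) / oracle
  expect_lt(max(rel), 0.001)
})

test_that("impossible meal-test inputs are rejected", {
  cfg <- quiet_cfg()
  s <- simulate_subjects(cfg)
  bad_grid <- data.frame(time = c(0, 2, 1, 3), glucose = rep(6, 4))
  expect_error(simulate_mmtt(s$truth[[1]], cfg, glucose_curve = bad_grid),
               "increasing")
  coarse <- data.frame(time = seq(0, 180, 5), glucose = rep(6, 37))
  expect_error(simulate_mmtt(s$truth[[1]], cfg, glucose_curve = coarse),
               "fine grid")
  neg <- data.frame(time = 0:180, glucose = c(rep(6, 180), -1))
  expect_error(simulate_mmtt(s$truth[[1]], cfg, glucose_curve = neg),
               "positive")
})

test_that("CGM traces have the exact configured length and flatten without noise", {
  cfg <- simulation_config(
    cgm_days = 5, noise_sd = list(hba1c = 3, weight = 1,
                                  fasting_glucose = 0.4,
                                  triglycerides = 0.15, alt = 3,
                                  mmtt_glucose = 0.15, mmtt_insulin = 8,
                                  mmtt_cpeptide = 25, cgm = 0),
    cgm_bump_amplitude = c(breakfast = 0, lunch = 0, dinner = 0),
    cgm_circadian_amplitude = 0)
  tr <- simulate_cgm("eTRC", cfg, seed = 1, baseline_glucose = 6)
  expect_length(tr$glucose, 5 * 24 * 60 / 15)
  expect_equal(tr$glucose, rep(6, length(tr$glucose)))
  expect_equal(cgm_summary(tr)$cv, 0)
})

test_that("dinner excursions separate the arms in the evening window", {
  cfg <- quiet_cfg()
  te <- simulate_cgm("eTRC", cfg, seed = 9, baseline_glucose = 6.5)
  tm <- simulate_cgm("Med", cfg, seed = 9, baseline_glucose = 6.5)
  tod <- as.POSIXlt(te$timestamps, tz = "UTC")
  evening <- tod$hour >= 18 & tod$hour < 22
  expect_gt(mean(tm$glucose[evening]) - mean(te$glucose[evening]), 0.5)
  # same seed, same construction outside the dinner window
  morning <- tod$hour < 12
  expect_equal(te$glucose[morning], tm$glucose[morning])
})

test_that("smoothed average profiles show 2 peaks for eTRC and 3 for Med", {
  cfg <- quiet_cfg()
  for (seed in 1:3) {
    te <- simulate_cgm("eTRC", cfg, seed = seed)
    tm <- simulate_cgm("Med", cfg, seed = seed)
    expect_equal(count_postprandial_peaks(te), 2L)
    expect_equal(count_postprandial_peaks(tm), 3L)
  }
})

test_that("null trial effects with zero noise give flat subject trajectories", {
  cfg <- simulation_config(
    effect_sizes = list(hba1c = c(diet = 0, group = 0, interaction = 0)),
    noise_sd = list(hba1c = 0, weight = 1, fasting_glucose = 0.4,
                    triglycerides = 0.15, alt = 3, mmtt_glucose = 0.15,
                    mmtt_insulin = 8, mmtt_cpeptide = 25, cgm = 0.4))
  tri <- simulate_trial(cfg)
  for (d in split(tri$table, tri$table$subject_id)) {
    expect_true(all(d$value == d$value[1]))
  }
})

test_that("a pure diet effect reproduces itself exactly without noise", {
  cfg <- simulation_config(
    effect_sizes = list(hba1c = c(diet = -4, group = 0, interaction = 0)),
    noise_sd = list(hba1c = 0, weight = 1, fasting_glucose = 0.4,
                    triglycerides = 0.15, alt = 3, mmtt_glucose = 0.15,
                    mmtt_insulin = 8, mmtt_cpeptide = 25, cgm = 0.4))
  tri <- simulate_trial(cfg)
  tab <- tri$table
  w12 <- tab[tab$visit_week == 12, ]
  w0 <- tab[tab$visit_week == 0, ]
  chg <- merge(w0, w12, by = "subject_id")
  expect_equal(mean(chg$value.y - chg$value.x), -4)
  expect_equal(var(chg$value.y - chg$value.x), 0)
})

test_that("large cohorts recover the generating diet effect with no interaction", {
  cfg <- simulation_config(
    n_per_arm = c(eTRC = 400, Med = 400),
    dropouts_per_arm = c(eTRC = 0, Med = 0),
    visit_weeks = c(0, 12),
    effect_sizes = list(hba1c = c(diet = -4, group = 0, interaction = 0)))
  tri <- simulate_trial(cfg)
  tab <- tri$table
  chg <- merge(tab[tab$visit_week == 0, c("subject_id", "arm", "value")],
               tab[tab$visit_week == 12, c("subject_id", "value")],
               by = "subject_id")
  chg$delta <- chg$value.y - chg$value.x
  # mean change equals the diet effect within Monte-Carlo error (sd 3*sqrt2/sqrt800)
  expect_equal(mean(chg$delta), -4, tolerance = 0.5)
  # arms do not differ (interaction zero): difference within MC error
  diff_arms <- mean(chg$delta[chg$arm == "eTRC"]) -
    mean(chg$delta[chg$arm == "Med"])
  expect_lt(abs(diff_arms), 1)
  # and the ANOVA sees a strong diet effect but no credible interaction
  fit <- rm_anova(tab, "hba1c")
  expect_lt(fit$p[fit$term == "diet"], 1e-6)
  expect_gt(fit$p[fit$term == "diet_x_group"], 0.001)
})

test_that("diary construction hits the configured after-lunch carbohydrate shares", {
  cfg <- quiet_cfg()
  tri <- simulate_trial(cfg)
  shares <- after_lunch_carb_share(tri$diaries)
  shares <- merge(shares, tri$subjects, by.x = "subject_id", by.y = "id")
  med_e <- median(shares$after_lunch_pct[shares$arm == "eTRC"])
  med_m <- median(shares$after_lunch_pct[shares$arm == "Med"])
  expect_lt(med_e, 15)
  expect_gt(med_m, 20)
  expect_gt(med_m / med_e, 2)
})
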