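test_that("Mann-Whitney power simulation is calibrated under the null", {
  res <- power_mannwhitney(11, delta = 0, sd = 3, alpha = 0.05, reps = 2000,
                           seed = 10)
  # the exact test is conservative, so the null rate sits at or below alpha
  expect_lt(res$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(res$power, 0.01)
})

test_that("the precomputed p-value lookup agrees with wilcox.test", {
  pow <- power_mannwhitney(6, delta = 1, sd = 1, reps = 1000, seed = 3)
  # replicate the internal decision rule against wilcox.test directly
  set.seed(99)
  agree <- vapply(1:50, function(i) {
    x <- rnorm(6)
    y <- rnorm(6, 1)
    u <- sum(rank(c(x, y))[1:6]) - 6 * 7 / 2
    pv <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    lower <- stats::pwilcox(u, 6, 6)
    upper <- if (u == 0) 1 else 1 - stats::pwilcox(u - 1, 6, 6)
    abs(min(1, 2 * min(lower, upper)) - pv) < 1e-12
  }, logical(1))
  expect_true(all(agree))
  expect_true(pow$power >= 0 && pow$power <= 1)
})

test_that("power is monotone in sample size and effect size", {
  p_n <- vapply(c(5, 11, 25), function(n) {
    power_mannwhitney(n, delta = 3, sd = 3, reps = 2000, seed = 7)$power
  }, numeric(1))
  expect_true(all(diff(p_n) > -0.03))   # non-decreasing within MC error
  p_d <- vapply(c(1, 3, 5), function(d) {
    power_mannwhitney(11, delta = d, sd = 3, reps = 2000, seed = 7)$power
  }, numeric(1))
  expect_true(all(diff(p_d) > 0))
  expect_error(power_mannwhitney(2, 1, 1), "n_per_group")
  expect_error(power_mannwhitney(11, 1, 1, reps = 10), "reps")
})

make_trial_table <- function(n_per_arm = 8, visits = c(0, 4, 8, 12),
                             diet = 0, group = 0, interaction = 0,
                             sd = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(2 * n_per_arm))
  arm <- rep(c("eTRC", "Med"), each = n_per_arm)
  W <- max(visits)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    b <- rnorm(1, 50, 3)
    data.frame(subject_id = ids[i], arm = arm[i], visit_week = visits,
               variable = "y",
               value = b + diet * visits / W +
                 interaction * (visits / W) * (arm[i] == "eTRC") +
                 group * (arm[i] == "eTRC") + rnorm(length(visits), 0, sd))
  }))
}

test_that("repeated-measures ANOVA type-I error is at the nominal level", {
  rej <- vapply(1:400, function(i) {
    tab <- make_trial_table(n_per_arm = 6, visits = c(0, 12), seed = 2000 + i)
    fit <- rm_anova(tab, "y")
    fit$p < 0.05
  }, logical(3))
  rates <- rowMeans(rej)   # diet, group, interaction
  se3 <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_true(all(abs(rates - 0.05) < se3))
})

test_that("a pure visit effect loads on the diet term only", {
  tab <- make_trial_table(n_per_arm = 40, diet = -4, sd = 1, seed = 5)
  fit <- rm_anova(tab, "y")
  expect_lt(fit$p[fit$term == "diet"], 1e-10)
  expect_gt(fit$p[fit$term == "diet_x_group"], 0.01)
})

test_that("all F statistics are invariant to swapping the arm labels", {
  tab <- make_trial_table(n_per_arm = 8, diet = -3, sd = 1, seed = 6)
  f1 <- rm_anova(tab, "y")
  tab2 <- tab
  tab2$arm <- ifelse(tab$arm == "eTRC", "Med", "eTRC")
  f2 <- rm_anova(tab2, "y")
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(f1$p, f2$p)
})

test_that("incomplete subjects are dropped and counted", {
  tab <- make_trial_table(n_per_arm = 6, seed = 9)
  tab <- tab[!(tab$subject_id == "S01" & tab$visit_week == 12), ]
  fit <- rm_anova(tab, "y")
  expect_equal(attr(fit, "n_dropped"), 1)
  expect_equal(attr(fit, "n_complete"), 11)
  expect_error(rm_anova(tab[tab$visit_week == 0, ], "y"), "2 visits")
})

test_that("greenhouse-geisser correction shrinks within-subject p-values", {
  tab <- make_trial_table(n_per_arm = 8, diet = -2, seed = 12)
  f0 <- rm_anova(tab, "y")
  f1 <- rm_anova(tab, "y", gg_correction = TRUE)
  eps <- attr(f1, "gg_epsilon")
  expect_true(eps > 0 && eps <= 1)
  expect_gte(f1$p[f1$term == "diet"], f0$p[f0$term == "diet"])
  expect_equal(f1$p[f1$term == "group"], f0$p[f0$term == "group"])
})

test_that("within-test ANOVA isolates the time effect", {
  set.seed(21)
  ids <- sprintf("S%02d", 1:12)
  arm <- rep(c("eTRC", "Med"), each = 6)
  grid <- expand.grid(subject_id = ids, visit_week = c(0, 12),
                      time_min = c(0, 30, 60, 120, 180),
                      stringsAsFactors = FALSE)
  grid$arm <- arm[match(grid$subject_id, ids)]
  grid$variable <- "glucose"
  base <- rnorm(12, 7, 0.5)
  grid$value <- base[match(grid$subject_id, ids)] +
    2 * exp(-((grid$time_min - 45) / 50)^2) + rnorm(nrow(grid), 0, 0.2)
  fit <- mmtt_anova(grid, "glucose")
  expect_lt(fit$p[fit$term == "time"], 1e-8)
  expect_gt(fit$p[fit$term == "diet"], 0.01)
  expect_gt(fit$p[fit$term == "time_x_group"], 0.01)
  # swapping the arm labels leaves every F unchanged
  grid2 <- grid
  grid2$arm <- ifelse(grid$arm == "eTRC", "Med", "eTRC")
  fit2 <- mmtt_anova(grid2, "glucose")
  expect_equal(fit$statistic, fit2$statistic)
})

test_that("Mann-Whitney agrees with full enumeration on small samples", {
  x <- c(1.2, 3.4, 2.2, 5.6)
  y <- c(2.8, 6.1, 4.4, 7.0)
  res <- compare_groups(x, y, "mannwhitney")
  expect_true(res$exact)
  expect_equal(res$p, mw_exact_oracle(x, y))
  # identical pooled distributions give p = 1
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), "mannwhitney")
  expect_equal(same$p, 1)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  res <- compare_groups(tab, kind = "fisher")
  # both extreme tables have probability 1/252 under fixed margins
  expect_equal(res$p, 2 / 252, tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    t2 <- matrix(rpois(4, 4) + 1, 2, 2)
    expect_equal(compare_groups(t2, kind = "fisher")$p,
                 fisher_exact_oracle(t2), tolerance = 1e-10)
  }
  expect_error(compare_groups(matrix(1:6, 2, 3), kind = "fisher"), "2x2")
})

test_that("Spearman correlation handles monotone cases and matches enumeration", {
  expect_equal(spearman_test(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_test(1:6, -c(2, 4, 9, 11, 30, 31))$rho, -1)
  x <- c(3.1, 1.2, 5.4, 2.2, 4.4)
  y <- c(0.4, 2.2, 1.1, 3.3, 0.2)
  res <- spearman_test(x, y)
  expect_true(res$exact)
  expect_equal(res$p, spearman_exact_oracle(x, y))
  expect_error(spearman_test(1:3, 1:3), "4 pairs")
})

test_that("tertile stratification recovers constructed shares and sizes", {
  diaries <- do.call(rbind, lapply(1:9, function(i) {
    pct <- i * 5   # distinct shares 5..45%
    data.frame(subject_id = sprintf("S%02d", i), day = rep(1:2, each = 3),
               meal = rep(c("breakfast", "lunch", "dinner"), 2),
               carb_g = rep(c(60 * (1 - pct / 100), 40 * (1 - pct / 100),
                              pct), 2))
  }))
  # construction: dinner carb equals pct when breakfast+lunch = 100 - pct
  m <- after_lunch_carb_share(diaries)
  expect_equal(sort(m$after_lunch_pct), (1:9) * 5)
  strat <- tertile_stratify(diaries)
  expect_equal(as.numeric(table(strat$metric$tertile)), c(3, 3, 3))
  outcomes <- data.frame(subject_id = sprintf("S%02d", 1:9),
                         variable = "y", change = c(1:3, 4:6, 40:42))
  res <- tertile_stratify(diaries, outcomes)
  expect_equal(res$comparisons$n1, 3)
  expect_equal(res$comparisons$n3, 3)
  expect_lt(res$comparisons$p, 0.2)
  # degenerate inputs rejected
  flat <- diaries
  flat$carb_g <- rep(c(50, 30, 20), 18)
  expect_error(tertile_stratify(flat), "degenerate")
  expect_error(tertile_stratify(diaries[diaries$subject_id < "S06", ]),
               "6 subjects")
})

test_that("diary reconciliation applies the 20% dispute rule", {
  a <- data.frame(subject_id = "A", assessor = 1:2,
                  energy_kj = c(8000, 8000), carb_g = c(200, 200))
  r <- reconcile_diaries(a)
  expect_false(r$flagged)
  expect_equal(r$energy_kj, 8000)
  # 100 vs 125: relative difference 22.2% -> flagged
  b <- data.frame(subject_id = "B", assessor = 1:2,
                  energy_kj = c(100, 125), carb_g = c(50, 50))
  rb <- reconcile_diaries(b)
  expect_true(rb$flagged)
  expect_false(rb$resolved)
  expect_equal(rb$rel_diff_energy, 25 / 112.5)
  # 100 vs 119: 17.4% -> consensus mean, no flag
  c2 <- data.frame(subject_id = "C", assessor = 1:2,
                   energy_kj = c(100, 119), carb_g = c(50, 50))
  rc <- reconcile_diaries(c2)
  expect_false(rc$flagged)
  expect_equal(rc$energy_kj, 109.5)
  # a third assessment resolves a dispute by median
  d <- data.frame(subject_id = "D", assessor = 1:3,
                  energy_kj = c(100, 130, 104), carb_g = c(50, 65, 52))
  rd <- reconcile_diaries(d)
  expect_true(rd$flagged)
  expect_true(rd$resolved)
  expect_equal(rd$energy_kj, 104)
  # single assessments pass through flagged
  e <- data.frame(subject_id = "E", assessor = 1,
                  energy_kj = 9000, carb_g = 210)
  re <- reconcile_diaries(e)
  expect_true(re$flagged)
  expect_equal(re$n_assessors, 1L)
})
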