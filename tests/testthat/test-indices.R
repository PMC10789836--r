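test_that("HOMA-IR reproduces hand arithmetic and is linear", {
  expect_equal(homa_ir(5, 27), 1)
  expect_equal(homa_ir(5, 54), 2)              # linear in insulin
  expect_equal(homa_ir(10, 27), 2)             # linear in glucose
  expect_equal(homa_ir(7.8, 95), 7.8 * (95 / 6) / 22.5)
  expect_error(homa_ir(0, 50), "glucose")
  expect_error(homa_ir(5, -1), "insulin")
})

test_that("Matsuda index matches the formula and its scaling laws", {
  # constants chosen so G*I = 10^4 in mg/dl x uU/ml units -> index 1
  tt <- c(0, 30, 60, 120, 180)
  expect_equal(matsuda(tt, rep(100 / 18.016, 5), rep(600, 5)), 1)
  # insulin enters twice (fasting and mean), so a uniform scaling by s
  # divides the index by s: quadrupling insulin quarters it
  g <- c(7, 9, 10, 8, 7)
  i <- c(90, 300, 420, 240, 120)
  expect_equal(matsuda(tt, g, i * 4), matsuda(tt, g, i) / 4)
  expect_equal(matsuda(tt, g * 4, i), matsuda(tt, g, i) / 4)
  # brute-force evaluation on a toy grid
  gm <- mealtrial:::trapz_mean(tt, g * 18.016)
  im <- mealtrial:::trapz_mean(tt, i / 6)
  byhand <- 10000 / sqrt(g[1] * 18.016 * (i[1] / 6) * gm * im)
  expect_equal(matsuda(tt, g, i), byhand)
  expect_error(matsuda(c(15, 30), c(7, 8), c(100, 120)), "t = 0")
})

test_that("insulin clearance modes agree with hand computation", {
  tt <- seq(0, 180, by = 1)
  isr <- isr_trace(tt, 100 + 2 * tt)
  k <- 0.8
  ins_t <- seq(0, 180, by = 15)
  ins <- (100 + 2 * ins_t) / k
  expect_equal(insulin_clearance(isr, ins_t, ins, "fasting"), k)
  # triangular traces: AUC ratio by hand
  isr2 <- isr_trace(0:180, c(seq(0.5, 300, length.out = 91),
                             seq(300, 0.5, length.out = 91)[-1]))
  ins2_t <- c(0, 90, 180)
  ins2 <- c(200, 400, 200)
  by_hand <- auc_trapezoid(0:180, isr2$isr) / auc_trapezoid(ins2_t, ins2)
  expect_equal(insulin_clearance(isr2, ins2_t, ins2, "total"), by_hand)
  expect_error(insulin_clearance(isr, c(0, 15), c(0.1, -5), "fasting"),
               "insulin")
})

test_that("fatty liver index matches the printed formula", {
  # inputs solved so the linear predictor is zero -> logistic midpoint 50
  bmi0 <- (15.745 - 0.953 * log(100) - 0.718 * log(20) - 0.053 * 90) / 0.139
  expect_equal(fatty_liver_index(100, bmi0, 20, 90), 50)
  # independent evaluation of the printed formula
  y <- 0.953 * log(110) + 0.139 * 29.4 + 0.718 * log(25) + 0.053 * 98 - 15.745
  expect_equal(fatty_liver_index(110, 29.4, 25, 98),
               exp(y) / (1 + exp(y)) * 100)
  # strictly increasing in each argument, always inside (0, 100)
  base <- fatty_liver_index(110, 29.4, 25, 98)
  expect_gt(fatty_liver_index(120, 29.4, 25, 98), base)
  expect_gt(fatty_liver_index(110, 30.4, 25, 98), base)
  expect_gt(fatty_liver_index(110, 29.4, 30, 98), base)
  expect_gt(fatty_liver_index(110, 29.4, 25, 103), base)
  vals <- fatty_liver_index(c(10, 5000), c(18, 45), c(5, 500), c(60, 160))
  expect_true(all(vals > 0 & vals < 100))
  # mmol/l triglycerides are converted internally
  expect_equal(fatty_liver_index(1.5, 29.4, 25, 98, tg_units = "mmol_l"),
               fatty_liver_index(1.5 * 88.57, 29.4, 25, 98))
})

test_that("HbA1c conversion reproduces paired-unit reporting", {
  expect_equal(hba1c_ifcc_to_ngsp(49), 6.6)
  expect_equal(hba1c_ifcc_to_ngsp(44), 6.2)
  expect_equal(hba1c_ifcc_to_ngsp(64), 8.0)
  # affine, monotone, and invertible up to display rounding
  raw <- hba1c_ifcc_to_ngsp(20:140, round = FALSE)
  expect_true(all(diff(raw) > 0))
  expect_equal(hba1c_ngsp_to_ifcc(raw), 20:140)
  back <- hba1c_ifcc_to_ngsp(hba1c_ngsp_to_ifcc(6.6), round = TRUE)
  expect_equal(back, 6.6)
  expect_error(hba1c_ifcc_to_ngsp(10), "20-200")
})

test_that("test-meal energy fractions match label arithmetic", {
  fr <- energy_fractions(37, 12, 12, 1255)
  expect_equal(fr[["carb"]], 49.3)
  expect_equal(fr[["protein"]], 16.0)
  expect_equal(energy_fractions(0, 12, 12, 1255)[["carb"]], 0)
  # degree-1 homogeneity in grams at fixed stated energy
  raw <- energy_fractions(37, 12, 12, 1255, digits = NULL)
  expect_equal(energy_fractions(74, 24, 24, 1255, digits = NULL), raw * 2)
})

test_that("energy prescriptions follow Harris-Benedict plus deficit", {
  ree <- harris_benedict("M", 60, 70, 170)
  expect_equal(ree, (66.4730 + 13.7516 * 70 + 5.0033 * 170 - 6.7550 * 60) *
                 4.184)
  rx0 <- energy_requirement("M", 60, 70, 170, activity_kj = 1000,
                            target_loss_fraction = 0)
  expect_equal(rx0$prescription_kj, ree + 1000)
  # REE strictly increasing in weight
  rees <- vapply(c(60, 75, 90), function(w) harris_benedict("F", 60, w, 165),
                 numeric(1))
  expect_true(all(diff(rees) > 0))
  # 5% loss over 12 weeks: cumulative deficit = 0.05 * w * 32220 kJ
  rx <- energy_requirement("M", 60, 70, 170, activity_kj = 1000,
                           target_loss_fraction = 0.05, weeks = 12)
  expect_equal(rx$deficit_kj * 12 * 7, 0.05 * 70 * 32220)
  expect_warning(
    energy_requirement("F", 70, 60, 160, target_loss_fraction = 0.19,
                       weeks = 4),
    "80%")
})

test_that("trapezoid AUC matches hand geometry", {
  expect_equal(auc_trapezoid(c(0, 60, 180), c(0, 10, 0)), 900)
  expect_equal(auc_trapezoid(c(0, 10), c(5, 5)), 50)
  expect_error(auc_trapezoid(c(0, 0, 10), c(1, 2, 3)), "increasing")
})
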