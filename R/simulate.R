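#' Simulation configuration for a synthetic dietary trial cohort
#'
#' Collects every knob of the synthetic cohort generator: arm sizes and
#' dropout counts, visit structure, MMTT sampling grid, flash-monitoring
#' layout, per-variable treatment effects and noise levels, meal clock times
#' and carbohydrate-timing behaviour.  Defaults emulate a two-arm 12-week
#' trial of early time-restricted carbohydrate intake (eTRC) versus a
#' Mediterranean-style control (Med) in type 2 diabetes: 14/13 randomised
#' with 2 dropouts per arm, visits at weeks 0/4/8/12, a 180-min MMTT sampled
#' at 0/15/30/45/60/90/120/150/180 min at weeks 0 and 12, and 14-day
#' flash-monitoring at 15-min intervals with postprandial excursions after
#' breakfast and lunch in both arms and after dinner in the Med arm only.
#'
#' `effect_sizes` gives, per variable, the additive change reached at the
#' final visit (`diet`), a constant eTRC-arm offset (`group`), and an extra
#' final-visit change in the eTRC arm (`interaction`); intermediate visits
#' interpolate linearly in week.
#'
#' @param seed integer; fixes all generator output bit-for-bit.
#' @param n_per_arm named integer vector `c(eTRC=, Med=)`, each >= 2.
#' @param dropouts_per_arm named integer vector of withdrawals per arm.
#' @param visit_weeks trial visit weeks.
#' @param mmtt_weeks weeks at which an MMTT is performed.
#' @param mmtt_sampling_times minutes; strictly increasing, starting at 0.
#' @param cgm_days days of flash monitoring per period (>= 1).
#' @param cgm_interval sensor sampling interval, minutes.
#' @param meal_hours named vector of meal clock times (hours).
#' @param effect_sizes named list; per variable a vector
#'   `c(diet=, group=, interaction=)`.
#' @param baselines named list; per variable `c(mean=, sd=)` of the
#'   between-subject baseline distribution.
#' @param noise_sd named list of residual/measurement SDs (trial variables
#'   plus `mmtt_glucose`, `mmtt_insulin`, `mmtt_cpeptide`, `cgm`).
#' @param cgm_bump_amplitude named vector, postprandial excursion heights in
#'   mmol/l (`dinner` applies to the Med arm only).
#' @param cgm_bump_sd_min width (SD) of the postprandial excursions, min.
#' @param cgm_circadian_amplitude amplitude of the circadian baseline
#'   component, mmol/l.
#' @param cgm_ar1 lag-1 autocorrelation of the sensor noise at the sampling
#'   interval.
#' @param after_lunch_share named vector; target fraction of daily
#'   carbohydrate consumed after lunch per arm.
#' @param diary_days food-diary days per subject.
#' @param assessor_cv relative SD of the dual-assessor diary estimates.
#' @param dispute_prob probability that the second assessor's estimate is
#'   inflated enough to trigger the 20% dispute rule.
#' @param insulin_lag_rate first-order rate (per min) of the hepatic/
#'   peripheral lag shaping plasma insulin appearance.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 20230401,
    n_per_arm = c(eTRC = 14, Med = 13),
    dropouts_per_arm = c(eTRC = 2, Med = 2),
    visit_weeks = c(0, 4, 8, 12),
    mmtt_weeks = c(0, 12),
    mmtt_sampling_times = c(0, 15, 30, 45, 60, 90, 120, 150, 180),
    cgm_days = 14,
    cgm_interval = 15,
    meal_hours = c(breakfast = 8, lunch = 13, dinner = 20),
    effect_sizes = list(
      hba1c = c(diet = -4, group = 0, interaction = 1),
      weight = c(diet = -4, group = 0, interaction = 0),
      fasting_glucose = c(diet = -0.6, group = 0, interaction = 0),
      triglycerides = c(diet = -0.24, group = 0, interaction = 0),
      alt = c(diet = -5, group = 0, interaction = 0)
    ),
    baselines = list(
      hba1c = c(mean = 49, sd = 5),
      weight = c(mean = 80, sd = 10),
      fasting_glucose = c(mean = 7.6, sd = 0.7),
      triglycerides = c(mean = 1.3, sd = 0.35),
      alt = c(mean = 21, sd = 6)
    ),
    noise_sd = list(
      hba1c = 3, weight = 1, fasting_glucose = 0.4, triglycerides = 0.15,
      alt = 3, mmtt_glucose = 0.15, mmtt_insulin = 8, mmtt_cpeptide = 25,
      cgm = 0.4
    ),
    cgm_bump_amplitude = c(breakfast = 2.5, lunch = 2.2, dinner = 3.0),
    cgm_bump_sd_min = 40,
    cgm_circadian_amplitude = 0.3,
    cgm_ar1 = 0.8,
    after_lunch_share = c(eTRC = 0.08, Med = 0.305),
    diary_days = 6,
    assessor_cv = 0.05,
    dispute_prob = 0.1,
    insulin_lag_rate = 0.15) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (any(n_per_arm < 2)) stop("'n_per_arm' must be >= 2 in each arm")
  if (!all(c("eTRC", "Med") %in% names(n_per_arm))) {
    stop("'n_per_arm' must be named with arms eTRC and Med")
  }
  if (any(dropouts_per_arm >= n_per_arm)) {
    stop("dropouts must be fewer than randomised per arm")
  }
  st <- mmtt_sampling_times
  if (st[1] != 0 || any(diff(st) <= 0)) {
    stop("'mmtt_sampling_times' must be strictly increasing and start at 0")
  }
  if (cgm_days < 1) stop("'cgm_days' must be >= 1")
  if ((24 * 60) %% cgm_interval != 0) {
    stop("'cgm_interval' must divide 24 hours")
  }
  unknown <- setdiff(names(effect_sizes), names(baselines))
  if (length(unknown)) {
    stop("effect_sizes given for unknown variable(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(mget(names(formals()), envir = environment()),
            class = "simulation_config")
}

# deterministic per-task sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

#' Draw ground-truth subjects for the synthetic cohort
#'
#' Samples anthropometrics and true physiology for every randomised subject:
#' age/sex/height/weight bracketing the target population (type 2 diabetes,
#' overweight, age around 67), fasting glucose uniform on 6.6-8.9 mmol/l,
#' beta cell parameters (log-normal glucose sensitivity around 100
#' pmol/min per mmol/l, ISR at 5.5 around 80 pmol/min, rate sensitivity
#' 300-800 pmol per mmol/l, linear mean-1 potentiation with end/start ratio
#' 1.3-1.9), a constant insulin clearance 1.2-2.0 l/min, and population
#' C-peptide kinetics from each subject's own anthropometrics.
#'
#' @param config a [simulation_config()].
#' @return a list with `subjects` (data.frame) and `truth` (named list per
#'   subject id with elements `betacell`, `kinetics`, `clearance`,
#'   `fasting_glucose`, `pot_ratio`).
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1), {
    arms <- rep(c("eTRC", "Med"), times = config$n_per_arm[c("eTRC", "Med")])
    n <- length(arms)
    id <- sprintf("S%03d", seq_len(n))
    sex <- ifelse(runif(n) < 0.478, "F", "M")
    age <- pmin(pmax(round(rnorm(n, 67, 8)), 40), 75)
    height <- ifelse(sex == "M", rnorm(n, 172, 6), rnorm(n, 160, 6))
    bmi <- pmin(pmax(rnorm(n, 29.4, 3), 25.1), 40)
    weight <- round(bmi * (height / 100)^2, 1)
    dropout <- unlist(lapply(c("eTRC", "Med"), function(a) {
      na <- config$n_per_arm[[a]]
      out <- rep(FALSE, na)
      out[sample.int(na, config$dropouts_per_arm[[a]])] <- TRUE
      out
    }))
    subjects <- data.frame(
      id = id, arm = arms, sex = sex, age = age, height_cm = round(height, 1),
      weight_kg = weight, bmi = round(bmi, 1), dropout = dropout,
      stringsAsFactors = FALSE
    )
    truth <- lapply(seq_len(n), function(i) {
      r <- runif(1, 1.3, 1.9)
      list(
        id = id[i],
        betacell = beta_cell_params(
          glucose_sensitivity = exp(rnorm(1, log(100), 0.3)),
          isr_at_5_5 = exp(rnorm(1, log(80), 0.3)),
          rate_sensitivity = runif(1, 300, 800),
          potentiation = linear_potentiation(r)
        ),
        kinetics = population_kinetics(age[i], sex[i], height[i], weight[i],
                                       diabetes = TRUE),
        clearance = runif(1, 1.2, 2.0),
        fasting_glucose = runif(1, 6.6, 8.9),
        pot_ratio = r
      )
    })
    names(truth) <- id
    list(subjects = subjects, truth = truth)
  })
}

#' Linear mean-1 potentiation profile
#'
#' Builds the linear potentiation factor `P(t) = 1 + s (t - 90)` over a
#' 180-min test, with slope `s` chosen so that the 160-180 vs 0-20 min ratio
#' equals `ratio`; the time mean over the window is 1 by construction.
#'
#' @param ratio target potentiation ratio (> 0).
#' @return a function of time (minutes).
#' @export
linear_potentiation <- function(ratio) {
  check_positive(ratio, "ratio")
  s <- (ratio - 1) / (80 * (ratio + 1))
  function(t) 1 + s * (t - 90)
}

#' Forward-simulate one mixed meal tolerance test
#'
#' Given a subject's true beta cell parameters, C-peptide kinetics and
#' insulin clearance, simulates a full MMTT: insulin secretion from the
#' two-component beta cell model driven by a fine-grid glucose excursion,
#' plasma C-peptide by exact forward two-compartment kinetics (fasting
#' steady state at t = 0), and plasma insulin as `ISR / clearance` passed
#' through a first-order lag.  All series are down-sampled to the clinical
#' sampling grid and measurement noise of the configured SD is added; the
#' noise-free ground-truth ISR trace is retained alongside.
#'
#' @param subject one element of the `truth` list from
#'   [simulate_subjects()].
#' @param config a [simulation_config()].
#' @param seed integer seed for the measurement noise (and the default
#'   glucose excursion amplitude).
#' @param glucose_curve optional data.frame `(time, glucose)` on a fine
#'   (<= 1 min) strictly increasing grid covering 0-180 min; defaults to a
#'   rising-falling excursion from the subject's fasting glucose.
#' @param fasting_glucose overrides the subject's fasting glucose for the
#'   default excursion (e.g. post-intervention visits).
#' @return an object of class `mmtt_profile`: list with `data` (data.frame
#'   `time`, `glucose`, `insulin`, `cpeptide` at the sampling times) and
#'   `truth` (fine-grid ISR trace, glucose, parameters, clearance).
#' @export
simulate_mmtt <- function(subject, config, seed = config$seed,
                          glucose_curve = NULL, fasting_glucose = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    if (is.null(glucose_curve)) {
      gf <- fasting_glucose %||% subject$fasting_glucose
      amp <- runif(1, 2.0, 3.5)
      tp <- runif(1, 40, 55)
      tt <- seq(0, 180, by = 1)
      glucose_curve <- data.frame(
        time = tt, glucose = gf + amp * (tt / tp) * exp(1 - tt / tp))
    }
    tt <- glucose_curve$time
    gg <- glucose_curve$glucose
    if (any(diff(tt) <= 0)) stop("glucose curve grid must be increasing")
    if (max(diff(tt)) > 1 + 1e-9) {
      stop("glucose curve must be on a fine grid (<= 1 min)")
    }
    if (min(tt) > 0 || max(tt) < max(config$mmtt_sampling_times)) {
      stop("glucose curve must cover the full sampling window")
    }
    if (any(gg <= 0)) stop("glucose curve must be strictly positive")

    dgdt <- c(diff(gg) / diff(tt), 0)
    isr <- model_isr(subject$betacell, tt, gg, dgdt)
    if (any(isr$isr < 0)) {
      stop("impossible parameters: negative noise-free secretion")
    }

    kin <- subject$kinetics
    c0 <- isr$isr[1] / (kin$k01 * kin$V)
    cpep <- forward_cpeptide(isr, kin, c0 = c0)

    # plasma insulin: ISR/clearance through a first-order lag, exact per step
    kI <- config$insulin_lag_rate
    h <- tt[2] - tt[1]
    ins <- numeric(length(tt))
    ins[1] <- isr$isr[1] / subject$clearance
    ek <- exp(-kI * h)
    for (i in seq_len(length(tt) - 1)) {
      ins[i + 1] <- ins[i] * ek + (1 - ek) * isr$isr[i] / subject$clearance
    }
    if (any(cpep < 0) || any(ins < 0)) {
      stop("impossible parameters: negative noise-free concentrations")
    }

    st <- config$mmtt_sampling_times
    pick <- match(st, tt)
    if (anyNA(pick)) stop("sampling times must lie on the glucose curve grid")
    data <- data.frame(
      time = st,
      glucose = gg[pick] + rnorm(length(st), 0, config$noise_sd$mmtt_glucose),
      insulin = ins[pick] + rnorm(length(st), 0, config$noise_sd$mmtt_insulin),
      cpeptide = cpep[pick] +
        rnorm(length(st), 0, config$noise_sd$mmtt_cpeptide)
    )
    structure(
      list(data = data,
           truth = list(isr = isr, glucose_fine = glucose_curve,
                        cpeptide_fine = cpep, insulin_fine = ins,
                        params = subject$betacell,
                        clearance = subject$clearance, c0 = c0)),
      class = "mmtt_profile")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a flash glucose monitoring trace
#'
#' Interstitial glucose over `cgm_days` days at `cgm_interval` minutes:
#' a circadian baseline (cosine with mid-afternoon crest), Gaussian-bump
#' postprandial excursions after breakfast and lunch in both arms and after
#' dinner in the Med arm only, plus AR(1) sensor noise.  The trace has
#' exactly `cgm_days * 24 * 60 / cgm_interval` samples.
#'
#' @param arm `"eTRC"` or `"Med"`.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param baseline_glucose subject's basal interstitial glucose, mmol/l.
#' @param start first timestamp (POSIXct, UTC midnight by default).
#' @return a [cgm_trace()].
#' @export
simulate_cgm <- function(arm = c("eTRC", "Med"), config, seed = config$seed,
                         baseline_glucose = 6.5,
                         start = as.POSIXct("2023-01-02 00:00:00",
                                            tz = "UTC")) {
  arm <- match.arg(arm)
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    minutes <- seq(0, config$cgm_days * 24 * 60 - config$cgm_interval,
                   by = config$cgm_interval)
    tod <- minutes %% (24 * 60)
    g <- baseline_glucose +
      config$cgm_circadian_amplitude * cos(2 * pi * (tod - 900) / (24 * 60))
    amps <- config$cgm_bump_amplitude
    if (arm == "eTRC") amps[["dinner"]] <- 0
    for (meal in names(config$meal_hours)) {
      mu <- config$meal_hours[[meal]] * 60 + 40  # peak ~40 min after the meal
      g <- g + amps[[meal]] *
        exp(-0.5 * ((tod - mu) / config$cgm_bump_sd_min)^2)
    }
    sigma <- config$noise_sd$cgm
    if (sigma > 0) {
      rho <- config$cgm_ar1
      eps <- rnorm(length(minutes), 0, sigma * sqrt(1 - rho^2))
      noise <- numeric(length(minutes))
      noise[1] <- rnorm(1, 0, sigma)
      for (i in seq_along(minutes)[-1]) {
        noise[i] <- rho * noise[i - 1] + eps[i]
      }
      g <- g + noise
    }
    cgm_trace(start + minutes * 60, pmax(g, 0.1),
              interval_min = config$cgm_interval)
  })
}

#' Simulate the longitudinal trial table and food diaries
#'
#' Generates the long subject-by-visit-by-variable table realizing the
#' configured diet (within-subject time), group and interaction effects on
#' top of subject random intercepts and residual noise, plus per-meal food
#' diaries whose after-lunch carbohydrate share follows the configured
#' arm-specific targets, and dual-assessor diary totals for the
#' reconciliation stage.  Dropout subjects contribute only their baseline
#' visit.
#'
#' @param config a [simulation_config()].
#' @param cohort optionally, a pre-built [simulate_subjects()] result (so
#'   the trial table and MMTT profiles can share ground truth).
#' @return a list with `table` (data.frame `subject_id`, `arm`,
#'   `visit_week`, `variable`, `value`), `diaries`, `assessments`,
#'   `subjects`, `truth`.
#' @export
simulate_trial <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(cohort)) cohort <- simulate_subjects(config)
  subjects <- cohort$subjects
  W <- max(config$visit_weeks)
  with_seed(derive_seed(config$seed, 2), {
    rows <- list()
    for (v in names(config$effect_sizes)) {
      eff <- config$effect_sizes[[v]]
      base <- config$baselines[[v]]
      sdn <- config$noise_sd[[v]] %||% 0
      b_i <- rnorm(nrow(subjects), base[["mean"]], base[["sd"]])
      for (w in config$visit_weeks) {
        keep <- !subjects$dropout | w == 0
        is_e <- subjects$arm == "eTRC"
        val <- b_i + eff[["group"]] * is_e +
          eff[["diet"]] * (w / W) +
          eff[["interaction"]] * (w / W) * is_e +
          rnorm(nrow(subjects), 0, sdn)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects$id[keep], arm = subjects$arm[keep],
          visit_week = w, variable = v, value = val[keep],
          stringsAsFactors = FALSE)
      }
    }
    table <- do.call(rbind, rows)

    diaries <- list()
    assessments <- list()
    for (i in seq_len(nrow(subjects))) {
      if (subjects$dropout[i]) next
      sid <- subjects$id[i]
      share <- config$after_lunch_share[[subjects$arm[i]]] *
        exp(rnorm(1, 0, 0.25))
      share <- min(max(share, 0.01), 0.6)
      for (d in seq_len(config$diary_days)) {
        total_carb <- rnorm(1, 190, 25)
        after <- share * total_carb
        carbs <- c(breakfast = 0.45 * (total_carb - after),
                   lunch = 0.55 * (total_carb - after),
                   dinner = 0.8 * after, other = 0.2 * after)
        fat_g <- rep(rnorm(1, 70, 8) / 4, 4)
        prot_g <- rep(rnorm(1, 90, 10) / 4, 4)
        energy <- (4 * (carbs + prot_g) + 9 * fat_g) * 4.184
        diaries[[length(diaries) + 1L]] <- data.frame(
          subject_id = sid, day = d,
          meal = names(carbs), carb_g = round(unname(carbs), 1),
          fat_g = round(fat_g, 1), protein_g = round(prot_g, 1),
          energy_kj = round(unname(energy)), stringsAsFactors = FALSE)
      }
      sub_d <- do.call(rbind, diaries[vapply(diaries, function(x)
        x$subject_id[1] == sid, logical(1))])
      true_e <- sum(sub_d$energy_kj)
      true_c <- sum(sub_d$carb_g)
      f1 <- exp(rnorm(1, 0, config$assessor_cv))
      f2 <- exp(rnorm(1, 0, config$assessor_cv))
      disputed <- runif(1) < config$dispute_prob
      if (disputed) f2 <- f2 * 1.3
      assess <- data.frame(
        subject_id = sid, assessor = c(1L, 2L),
        energy_kj = round(true_e * c(f1, f2)),
        carb_g = round(true_c * c(f1, f2), 1), stringsAsFactors = FALSE)
      if (disputed) {
        f3 <- exp(rnorm(1, 0, config$assessor_cv))
        assess <- rbind(assess, data.frame(
          subject_id = sid, assessor = 3L,
          energy_kj = round(true_e * f3), carb_g = round(true_c * f3, 1)))
      }
      assessments[[length(assessments) + 1L]] <- assess
    }
    list(table = table,
         diaries = do.call(rbind, diaries),
         assessments = do.call(rbind, assessments),
         subjects = subjects, truth = cohort$truth)
  })
}

#' Generate the complete synthetic cohort
#'
#' One-call generator of everything the analysis pipeline consumes: the
#' trial table, food diaries and assessments ([simulate_trial()]), per
#' subject-visit MMTT profiles ([simulate_mmtt()]; fasting glucose at the
#' final visit is shifted by the configured `fasting_glucose` diet effect)
#' and per-subject flash monitoring traces ([simulate_cgm()]).
#'
#' @param config a [simulation_config()].
#' @return a list with `trial`, `mmtt` (nested list by subject id then
#'   visit week) and `cgm` (list by subject id).
#' @export
simulate_cohort <- function(config) {
  trial <- simulate_trial(config)
  completers <- trial$subjects$id[!trial$subjects$dropout]
  eff_fg <- if ("fasting_glucose" %in% names(config$effect_sizes)) {
    config$effect_sizes$fasting_glucose[["diet"]]
  } else 0
  W <- max(config$visit_weeks)
  mmtt <- list()
  cgm <- list()
  for (k in seq_along(completers)) {
    sid <- completers[k]
    subj <- trial$truth[[sid]]
    mmtt[[sid]] <- list()
    for (w in config$mmtt_weeks) {
      gf <- subj$fasting_glucose + eff_fg * (w / W)
      mmtt[[sid]][[as.character(w)]] <- simulate_mmtt(
        subj, config, seed = derive_seed(config$seed, 100 + 10 * k + w),
        fasting_glucose = gf)
    }
    arm <- trial$subjects$arm[trial$subjects$id == sid]
    cgm[[sid]] <- simulate_cgm(
      arm, config, seed = derive_seed(config$seed, 5000 + k),
      baseline_glucose = subj$fasting_glucose - 1)
  }
  list(trial = trial, mmtt = mmtt, cgm = cgm)
}
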