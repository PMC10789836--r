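#' Monte-Carlo power of the two-sided Mann-Whitney U test
#'
#' Estimates power by simulation: for each replicate, two samples of size
#' `n_per_group` are drawn from normal(0, sd) and normal(delta, sd) and the
#' two-sided Mann-Whitney U test is applied at level `alpha`.  With
#' continuous data and no ties the exact two-sided p-value for an observed U
#' depends only on U, so the p-value lookup is precomputed once from the
#' exact Wilcoxon distribution, making 10,000 replicates take seconds.
#'
#' @param n_per_group sample size per group (>= 3).
#' @param delta true between-group difference in means (>= 0).
#' @param sd common standard deviation (> 0).
#' @param alpha two-sided significance level.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @return a list with `power`, `se` (binomial standard error), `reps`.
#' @examples
#' \donttest{
#' power_mannwhitney(11, delta = 4, sd = 3, reps = 2000, seed = 1)
#' }
#' @export
power_mannwhitney <- function(n_per_group, delta, sd, alpha = 0.05,
                              reps = 10000, seed = 1) {
  if (n_per_group < 3) stop("'n_per_group' must be >= 3")
  if (reps < 1000) stop("'reps' must be >= 1000")
  check_nonnegative(delta, "delta")
  check_positive(sd, "sd")
  n <- n_per_group
  # exact two-sided p-value for each possible U (no ties)
  u_vals <- 0:(n * n)
  lower <- pwilcox(u_vals, n, n)
  upper <- c(1, 1 - pwilcox(u_vals[-1] - 1, n, n))
  pvals <- pmin(1, 2 * pmin(lower, upper))
  rejected <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      x <- rnorm(n, 0, sd)
      y <- rnorm(n, delta, sd)
      u <- sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
      pvals[u + 1] < alpha
    }, logical(1))
  })
  p <- mean(rejected)
  list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

# complete-case filter: keep subjects observed at every required level
complete_subjects <- function(df) {
  counts <- tapply(seq_len(nrow(df)), df$subject_id, length)
  full <- max(counts)
  keep_ids <- names(counts)[counts == full]
  list(df = df[df$subject_id %in% keep_ids, , drop = FALSE],
       n_dropped = sum(counts < full))
}

# Box / Greenhouse-Geisser epsilon from the pooled covariance of the
# within-subject measures (k levels)
gg_epsilon <- function(wide) {
  k <- ncol(wide)
  S <- var(wide)
  C <- diag(k) - matrix(1 / k, k, k)
  A <- C %*% S %*% C
  sum(diag(A))^2 / ((k - 1) * sum(A * A))
}

#' Two-way repeated-measures ANOVA for trial outcomes
#'
#' Classical within/between partition for a two-arm longitudinal trial:
#' within-subject factor `visit_week` (the diet/time effect), between-subject
#' factor `arm` (group), and their interaction, fitted by [stats::aov()] with
#' an `Error(subject/visit)` stratum on complete cases (subjects missing any
#' visit are dropped and counted).  Optionally applies the
#' Greenhouse-Geisser sphericity correction to the within-subject terms.
#'
#' @param table long-format data.frame with columns `subject_id`, `arm`,
#'   `visit_week`, `variable`, `value`.
#' @param variable which variable to analyse.
#' @param gg_correction apply the Greenhouse-Geisser df correction
#'   (default FALSE).
#' @return a data.frame with rows `diet`, `group`, `diet_x_group` and columns
#'   `df1`, `df2`, `statistic`, `p`; attributes `n_complete`, `n_dropped`,
#'   `gg_epsilon` (when corrected).
#' @export
rm_anova <- function(table, variable, gg_correction = FALSE) {
  df <- table[table$variable == variable, , drop = FALSE]
  if (!nrow(df)) stop("variable not present in table: ", variable)
  cc <- complete_subjects(df)
  df <- cc$df
  if (length(unique(df$visit_week)) < 2) {
    stop("need at least 2 visits per subject")
  }
  narm <- base::table(unique(df[c("subject_id", "arm")])$arm)
  if (any(narm < 2) || length(narm) < 2) {
    stop("each group needs at least 2 complete subjects")
  }
  df$subject_id <- factor(df$subject_id)
  df$arm <- factor(df$arm)
  df$visit <- factor(df$visit_week)
  fit <- aov(value ~ arm * visit + Error(subject_id / visit), data = df)
  sm <- summary(fit)
  between <- sm[["Error: subject_id"]][[1]]
  within <- sm[["Error: subject_id:visit"]][[1]]
  g_row <- grep("^arm\\s*$", rownames(between))
  d_row <- grep("^visit\\s*$", rownames(within))
  i_row <- grep("arm:visit", rownames(within))
  res_b <- grep("Residuals", rownames(between))
  res_w <- grep("Residuals", rownames(within))
  out <- data.frame(
    term = c("diet", "group", "diet_x_group"),
    df1 = c(within[d_row, "Df"], between[g_row, "Df"], within[i_row, "Df"]),
    df2 = c(within[res_w, "Df"], between[res_b, "Df"], within[res_w, "Df"]),
    statistic = c(within[d_row, "F value"], between[g_row, "F value"],
                  within[i_row, "F value"]),
    row.names = NULL
  )
  eps <- NA_real_
  if (gg_correction) {
    wide <- do.call(cbind, lapply(split(df, df$visit), function(d) {
      d$value[order(d$subject_id)]
    }))
    eps <- gg_epsilon(wide)
  }
  adj <- ifelse(out$term == "group", 1,
                ifelse(rep(gg_correction, 3), eps, 1))
  out$p <- stats::pf(out$statistic, out$df1 * adj, out$df2 * adj,
                     lower.tail = FALSE)
  attr(out, "n_complete") <- length(unique(df$subject_id))
  attr(out, "n_dropped") <- cc$n_dropped
  attr(out, "gg_epsilon") <- eps
  out
}

#' Repeated-measures ANOVA for within-test (MMTT) time courses
#'
#' Extends [rm_anova()] with the within-test time factor: the model has
#' between-subject factor `arm` (group), within-subject factors `visit_week`
#' (diet) and `time_min` (time during the MMTT), and all interactions,
#' fitted on complete cases via `Error(subject/(visit*time))`.
#'
#' @param table long-format data.frame with columns `subject_id`, `arm`,
#'   `visit_week`, `time_min`, `variable`, `value`.
#' @param variable which variable to analyse.
#' @return a data.frame of all seven effect terms with `df1`, `df2`,
#'   `statistic`, `p`; attributes as in [rm_anova()].
#' @export
mmtt_anova <- function(table, variable) {
  df <- table[table$variable == variable, , drop = FALSE]
  if (!nrow(df)) stop("variable not present in table: ", variable)
  cc <- complete_subjects(df)
  df <- cc$df
  narm <- base::table(unique(df[c("subject_id", "arm")])$arm)
  if (any(narm < 2) || length(narm) < 2) {
    stop("each group needs at least 2 complete subjects")
  }
  df$subject_id <- factor(df$subject_id)
  df$arm <- factor(df$arm)
  df$visit <- factor(df$visit_week)
  df$time <- factor(df$time_min)
  fit <- aov(value ~ arm * visit * time +
               Error(subject_id / (visit * time)), data = df)
  sm <- summary(fit)
  grab <- function(stratum, pattern) {
    tb <- sm[[stratum]][[1]]
    row <- grep(pattern, rownames(tb))
    res <- grep("Residuals", rownames(tb))
    c(df1 = tb[row, "Df"], df2 = tb[res, "Df"],
      statistic = tb[row, "F value"])
  }
  spec <- list(
    group = c("Error: subject_id", "^arm\\s*$"),
    diet = c("Error: subject_id:visit", "^visit\\s*$"),
    diet_x_group = c("Error: subject_id:visit", "^arm:visit\\s*$"),
    time = c("Error: subject_id:time", "^time\\s*$"),
    time_x_group = c("Error: subject_id:time", "^arm:time\\s*$"),
    time_x_diet = c("Error: subject_id:visit:time", "^visit:time\\s*$"),
    time_x_diet_x_group = c("Error: subject_id:visit:time",
                            "^arm:visit:time\\s*$")
  )
  rows <- lapply(spec, function(s) grab(s[1], s[2]))
  out <- data.frame(term = names(spec), do.call(rbind, rows),
                    row.names = NULL)
  out$p <- stats::pf(out$statistic, out$df1, out$df2, lower.tail = FALSE)
  attr(out, "n_complete") <- length(unique(df$subject_id))
  attr(out, "n_dropped") <- cc$n_dropped
  out
}

#' Two-group comparisons: Mann-Whitney U or Fisher's exact test
#'
#' Mann-Whitney uses exact enumeration when both groups have at most 10
#' observations and there are no ties, and the tie-corrected normal
#' approximation (with continuity correction) otherwise.  Fisher's exact
#' test takes a 2x2 count table and computes the exact two-sided p by
#' hypergeometric enumeration.
#'
#' @param x first group (numeric), or for `kind = "fisher"` a 2x2 matrix of
#'   counts.
#' @param y second group (numeric); ignored for Fisher.
#' @param kind `"mannwhitney"` or `"fisher"`.
#' @return a list with `statistic`, `p`, `exact` (logical), `kind`.
#' @export
compare_groups <- function(x, y = NULL, kind = c("mannwhitney", "fisher")) {
  kind <- match.arg(kind)
  if (kind == "fisher") {
    if (!is.matrix(x) || !all(dim(x) == c(2, 2))) {
      stop("Fisher's test requires a 2x2 count table")
    }
    ft <- stats::fisher.test(x)
    return(list(statistic = unname(ft$estimate), p = ft$p.value,
                exact = TRUE, kind = "fisher"))
  }
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact,
       kind = "mannwhitney")
}

# all permutations of 1..n as an n! x n matrix (used for exact p-values)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value is
#' computed by full permutation enumeration for n <= 8 and by the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return a list with `rho`, `p`, `n`, `exact`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    pm <- all_permutations(n)
    rhos <- apply(pm, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, exact = TRUE))
  }
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  list(rho = rho, p = min(1, 2 * pt(-abs(tt), n - 2)), n = n, exact = FALSE)
}

#' Per-subject after-lunch carbohydrate share from food diaries
#'
#' For each diary day, the percentage of total carbohydrate consumed after
#' lunch (meal slots `dinner` and `other`); the subject-level metric is the
#' median across days.
#'
#' @param diaries data.frame with columns `subject_id`, `day`, `meal`,
#'   `carb_g`.
#' @return a data.frame with `subject_id`, `after_lunch_pct`.
#' @export
after_lunch_carb_share <- function(diaries) {
  stopifnot(all(c("subject_id", "day", "meal", "carb_g") %in%
                  names(diaries)))
  sp <- split(diaries, list(diaries$subject_id, diaries$day), drop = TRUE)
  daily <- do.call(rbind, lapply(sp, function(d) {
    data.frame(subject_id = d$subject_id[1],
               pct = sum(d$carb_g[d$meal %in% c("dinner", "other")]) /
                 sum(d$carb_g) * 100)
  }))
  out <- aggregate(pct ~ subject_id, daily, median)
  names(out)[2] <- "after_lunch_pct"
  out
}

#' Extreme-tertile comparison by after-lunch carbohydrate intake
#'
#' Stratifies subjects into tertiles of their after-lunch carbohydrate share
#' (cut at the empirical 33.3/66.7 percentiles) and compares each outcome
#' change between the first and third tertiles with the Mann-Whitney U test.
#'
#' @param diaries food diaries (see [after_lunch_carb_share()]).
#' @param outcomes optional data.frame with `subject_id`, `variable`,
#'   `change`.
#' @return a list with `metric` (per-subject share and tertile), `cuts`,
#'   and `comparisons` (one row per outcome variable).
#' @export
tertile_stratify <- function(diaries, outcomes = NULL) {
  metric <- after_lunch_carb_share(diaries)
  if (nrow(metric) < 6) stop("need at least 6 subjects for tertiles")
  cuts <- quantile(metric$after_lunch_pct, c(1, 2) / 3, type = 7,
                   names = FALSE)
  if (diff(cuts) < 1e-9) {
    stop("degenerate tertiles: after-lunch shares are (near-)identical")
  }
  metric$tertile <- cut(metric$after_lunch_pct,
                        c(-Inf, cuts, Inf), labels = c("T1", "T2", "T3"))
  comparisons <- NULL
  if (!is.null(outcomes)) {
    comparisons <- do.call(rbind, lapply(split(outcomes, outcomes$variable),
      function(o) {
        o <- merge(o, metric, by = "subject_id")
        x <- o$change[o$tertile == "T1"]
        y <- o$change[o$tertile == "T3"]
        cmp <- compare_groups(x, y, "mannwhitney")
        data.frame(variable = o$variable[1], n1 = length(x), n3 = length(y),
                   statistic = cmp$statistic, p = cmp$p,
                   stringsAsFactors = FALSE)
      }))
    rownames(comparisons) <- NULL
  }
  list(metric = metric, cuts = cuts, comparisons = comparisons)
}

#' Reconcile dual-assessor food-diary estimates
#'
#' Applies the 20% dispute rule to independent assessments of each diary's
#' total energy and carbohydrate: if the first two assessors' estimates
#' differ by >= 20% of their mean on either quantity the diary is flagged,
#' and a third assessment (when available) resolves it by taking the median
#' of the three; otherwise the consensus is the mean of the two.  Diaries
#' with a single assessment are passed through flagged.
#'
#' @param assessments data.frame with columns `subject_id`, `assessor`,
#'   `energy_kj`, `carb_g`.
#' @return a data.frame per subject with consensus `energy_kj` and `carb_g`,
#'   `rel_diff_energy`, `rel_diff_carb`, `flagged`, `resolved`,
#'   `n_assessors`.
#' @export
reconcile_diaries <- function(assessments) {
  stopifnot(all(c("subject_id", "assessor", "energy_kj", "carb_g") %in%
                  names(assessments)))
  do.call(rbind, lapply(split(assessments, assessments$subject_id),
    function(a) {
      a <- a[order(a$assessor), ]
      if (nrow(a) == 1) {
        return(data.frame(
          subject_id = a$subject_id[1], energy_kj = a$energy_kj,
          carb_g = a$carb_g, rel_diff_energy = NA_real_,
          rel_diff_carb = NA_real_, flagged = TRUE, resolved = FALSE,
          n_assessors = 1L, stringsAsFactors = FALSE))
      }
      rel <- function(v) abs(v[1] - v[2]) / mean(v[1:2])
      rde <- rel(a$energy_kj)
      rdc <- rel(a$carb_g)
      flagged <- rde >= 0.20 || rdc >= 0.20
      if (flagged && nrow(a) >= 3) {
        cons_e <- median(a$energy_kj[1:3])
        cons_c <- median(a$carb_g[1:3])
        resolved <- TRUE
      } else {
        cons_e <- mean(a$energy_kj[1:2])
        cons_c <- mean(a$carb_g[1:2])
        resolved <- !flagged
      }
      data.frame(
        subject_id = a$subject_id[1], energy_kj = cons_e, carb_g = cons_c,
        rel_diff_energy = rde, rel_diff_carb = rdc, flagged = flagged,
        resolved = resolved, n_assessors = nrow(a), stringsAsFactors = FALSE)
    })) -> out
  rownames(out) <- NULL
  out
}
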