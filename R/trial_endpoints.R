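# Longitudinal endpoints: square-root-transformed change from baseline,
# least-squares means and treatment contrasts from a mixed-effects model,
# Wilcoxon baseline comparisons, and percent growth-rate reduction.
#
# The endpoint model (response = sqrt-area change at post-baseline visits):
#   sqrt_change ~ arm + visit + arm:visit + baseline_c + visit:baseline_c
#                 + (1 | eye)
# with visit categorical, the baseline lesion area centred at its grand
# mean, REML estimation, and Wald z inference on fixed-effect contrasts
# (no denominator-df approximation). LS means are model predictions per
# arm x visit at the grand-mean baseline.

#' Build or validate the long endpoint table
#'
#' One row per eye x visit x feature with `area_mm2`; derives
#' `sqrt_area_mm`, `baseline_area_mm2` and `sqrt_change_mm` (0 at baseline
#' by construction).
#'
#' @param df Data frame with columns `eye_id`, `arm`, `visit_month`,
#'   `feature`, `area_mm2`. A `ga_cohort`'s truth areas may be passed
#'   directly via [cohort_long_table()].
#' @return A `long_table` data frame.
#' @export
as_long_table <- function(df) {
  need <- c("eye_id", "arm", "visit_month", "feature", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("long table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$area_mm2 < 0, na.rm = TRUE)) {
    stop("negative areas in long table", call. = FALSE)
  }
  key <- paste(df$eye_id, df$visit_month, df$feature)
  if (anyDuplicated(key)) {
    stop("long table must have one row per eye x visit x feature",
         call. = FALSE)
  }
  # recompute any derived columns (keeps the constructor idempotent, e.g.
  # after a CSV round trip)
  df <- df[, setdiff(names(df), c("sqrt_area_mm", "baseline_area_mm2",
                                  "sqrt_change_mm")), drop = FALSE]
  df$sqrt_area_mm <- sqrt(df$area_mm2)
  base <- df[df$visit_month == 0, c("eye_id", "feature", "area_mm2")]
  names(base)[3] <- "baseline_area_mm2"
  df <- merge(df, base, by = c("eye_id", "feature"), all.x = TRUE,
              sort = FALSE)
  df$sqrt_change_mm <- df$sqrt_area_mm - sqrt(df$baseline_area_mm2)
  df <- df[order(df$eye_id, df$feature, df$visit_month), ]
  rownames(df) <- NULL
  class(df) <- c("long_table", "data.frame")
  df
}

#' Long endpoint table from a simulated cohort's ground truth
#'
#' @param cohort A `ga_cohort` (uses `truth$areas`).
#' @return A `long_table`.
#' @export
cohort_long_table <- function(cohort) {
  stopifnot(inherits(cohort, "ga_cohort"))
  as_long_table(cohort$truth$areas)
}

#' Square-root-area change from baseline
#'
#' @param area_t,area_0 Areas in mm^2 (vectorised); must be non-negative.
#' @return `sqrt(area_t) - sqrt(area_0)` in mm (may be negative).
#' @export
sqrt_change <- function(area_t, area_0) {
  if (any(area_t < 0, na.rm = TRUE) || any(area_0 < 0, na.rm = TRUE)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  sqrt(area_t) - sqrt(area_0)
}

#' Percent reduction in growth rate
#'
#' `100 * (1 - mean_active / mean_sham)`, rounded to the nearest integer
#' for reporting (e.g. mean sqrt-area changes 0.151 vs 0.277 mm give 45).
#'
#' @param mean_active,mean_sham Mean growth (e.g. sqrt-area change, mm) in
#'   the active and sham arms; `mean_sham` must be positive.
#' @param digits Rounding digits for reporting.
#' @return Percent reduction.
#' @export
percent_reduction <- function(mean_active, mean_sham, digits = 0) {
  if (any(mean_sham <= 0)) {
    stop("mean_sham must be positive", call. = FALSE)
  }
  round(100 * (1 - mean_active / mean_sham), digits)
}

#' Fit the mixed-effects endpoint model and extract LS means
#'
#' @param table A `long_table` (or data frame with its columns).
#' @param feature Feature whose areas form the endpoint (default `"RORA"`).
#' @param ref_arm Reference (control) arm for contrasts.
#' @return An `lsmeans_fit` with elements `lsmeans` (arm x visit estimate,
#'   SE, 95% CI, n), `contrasts` (per visit, each arm vs `ref_arm`, Wald z
#'   and two-sided p), `varcomp` (random-intercept and residual SD),
#'   `grand_mean_baseline`, and the `lme4` fit in `model`.
#' @export
fit_lsmeans <- function(table, feature = "RORA", ref_arm = "SHAM") {
  d <- table[table$feature == feature, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for feature ", feature, call. = FALSE)
  arms <- unique(d$arm)
  if (length(arms) < 2L) {
    stop("need >= 2 arms to form contrasts; got: ",
         paste(arms, collapse = ", "), call. = FALSE)
  }
  if (!ref_arm %in% arms) {
    stop("reference arm ", ref_arm, " absent from the table", call. = FALSE)
  }
  post <- d[d$visit_month > 0, , drop = FALSE]
  visits <- sort(unique(post$visit_month))
  if (length(visits) < 2L) {
    stop("need >= 2 post-baseline visits", call. = FALSE)
  }
  cells <- table(factor(post$arm, levels = arms),
                 factor(post$visit_month, levels = visits))
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)
    stop("empty arm x visit cell(s): ",
         paste(sprintf("%s x month %s", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  # grand-mean centring of the baseline covariate, one value per eye
  eye_base <- tapply(d$baseline_area_mm2, d$eye_id, function(x) x[1])
  gm <- mean(eye_base)
  post$arm_f <- factor(post$arm, levels = c(ref_arm, setdiff(arms, ref_arm)))
  post$visit_f <- factor(post$visit_month, levels = visits)
  post$base_c <- post$baseline_area_mm2 - gm
  fit <- withCallingHandlers(
    lme4::lmer(
      sqrt_change_mm ~ arm_f * visit_f + base_c + visit_f:base_c +
        (1 | eye_id),
      data = post, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        stop("mixed model failed to converge: ", conditionMessage(w),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  fe <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  # design rows for LS means: every arm x visit at base_c = 0
  grid <- expand.grid(arm_f = levels(post$arm_f),
                      visit_f = levels(post$visit_f))
  grid$base_c <- 0
  X <- model.matrix(~ arm_f * visit_f + base_c + visit_f:base_c, grid)
  X <- X[, names(fe), drop = FALSE]
  est <- drop(X %*% fe)
  se <- sqrt(rowSums((X %*% V) * X))
  nn <- cells[cbind(as.character(grid$arm_f), as.character(grid$visit_f))]
  lsm <- data.frame(
    arm = as.character(grid$arm_f), visit_month = as.integer(
      as.character(grid$visit_f)),
    estimate_mm = est, se_mm = se,
    ci_lower_mm = est - 1.96 * se, ci_upper_mm = est + 1.96 * se,
    n = as.integer(nn)
  )
  # contrasts vs the reference arm, per visit (Wald z)
  cons <- list()
  for (a in setdiff(levels(post$arm_f), ref_arm)) {
    for (v in levels(post$visit_f)) {
      i1 <- which(grid$arm_f == a & grid$visit_f == v)
      i0 <- which(grid$arm_f == ref_arm & grid$visit_f == v)
      cvec <- X[i1, ] - X[i0, ]
      ce <- sum(cvec * fe)
      cse <- sqrt(drop(t(cvec) %*% V %*% cvec))
      z <- ce / cse
      cons[[length(cons) + 1L]] <- data.frame(
        contrast = paste0(a, " - ", ref_arm),
        visit_month = as.integer(v), estimate_mm = ce, se_mm = cse,
        z = z, p_value = 2 * pnorm(-abs(z))
      )
    }
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    feature = feature,
    lsmeans = lsm,
    contrasts = do.call(rbind, cons),
    varcomp = data.frame(component = c("eye (intercept)", "residual"),
                         sd = c(vc$sdcor[vc$grp == "eye_id"],
                                vc$sdcor[vc$grp == "Residual"])),
    grand_mean_baseline = gm,
    model = fit
  ), class = "lsmeans_fit")
}

#' @export
print.lsmeans_fit <- function(x, ...) {
  cat("Mixed-model LS means of sqrt-area change (", x$feature, "), mm\n",
      sep = "")
  print(transform(x$lsmeans,
                  estimate_mm = signif(estimate_mm, 3),
                  se_mm = signif(se_mm, 3),
                  ci_lower_mm = signif(ci_lower_mm, 3),
                  ci_upper_mm = signif(ci_upper_mm, 3)),
        row.names = FALSE)
  cat("\nContrasts vs control (Wald z):\n")
  print(transform(x$contrasts, estimate_mm = signif(estimate_mm, 3),
                  se_mm = signif(se_mm, 3), z = signif(z, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}

#' Wilcoxon rank-sum comparison of baseline areas between two arms
#'
#' @param table A `long_table` (baseline rows, `visit_month == 0`, are
#'   used).
#' @param feature Feature to compare.
#' @param arms Length-2 character vector of arms.
#' @return Two-sided p-value, with the test object as attribute `"test"`.
#' @export
baseline_compare <- function(table, feature = "RORA",
                             arms = c("PM", "SHAM")) {
  stopifnot(length(arms) == 2L)
  d <- table[table$feature == feature & table$visit_month == 0, ,
             drop = FALSE]
  x <- d$area_mm2[d$arm == arms[1]]
  y <- d$area_mm2[d$arm == arms[2]]
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty arm in baseline comparison: ",
         arms[which(c(length(x), length(y)) == 0L)[1]], call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  structure(unname(wt$p.value), test = wt)
}
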