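# A small hand-built long table with all six features at baseline and the
# growth feature at month 12.
make_prediction_long_table <- function(n = 40, seed = 20,
                                       growth_fun = NULL) {
  set.seed(seed)
  rpe <- rgamma(n, 4.3, 0.57)
  prd <- rpe * (1 + rgamma(n, 2, 3))
  iso <- prd - rpe
  intact <- pmax(28.3 - prd - rgamma(n, 2, 1), 0.5)
  htr <- rpe * runif(n, 0.9, 1)
  rora <- pmin(rpe, htr)
  g <- if (is.null(growth_fun)) rnorm(n, 0.28, 0.1) else growth_fun(iso)
  rows <- list()
  feats0 <- list(RPE_LOSS = rpe, PRD = prd, PRD_ISOLATED = iso,
                 INTACT_MACULA = intact, HTR = htr, RORA = rora)
  for (f in names(feats0)) {
    rows[[f]] <- data.frame(eye_id = sprintf("e%03d", 1:n),
                            arm = rep_len(c("PM", "PEOM", "SHAM"), n),
                            visit_month = 0, feature = f,
                            area_mm2 = feats0[[f]])
  }
  rows$m12 <- data.frame(eye_id = sprintf("e%03d", 1:n),
                         arm = rep_len(c("PM", "PEOM", "SHAM"), n),
                         visit_month = 12, feature = "RORA",
                         area_mm2 = (sqrt(rora) + pmax(g, 0))^2)
  as_long_table(do.call(rbind, rows))
}

test_that("predictor table extracts ratio, isolated PRD and intact macula", {
  lt <- make_prediction_long_table()
  pt <- predictor_table(lt)
  expect_equal(nrow(pt), 40)
  expect_true(all(pt$ratio_prd_rpe >= 1))   # PRD contains RPE loss here
  b <- lt[lt$visit_month == 0, ]
  eye1 <- pt[pt$eye_id == "e001", ]
  expect_equal(eye1$ratio_prd_rpe,
               b$area_mm2[b$feature == "PRD" & b$eye_id == "e001"] /
                 b$area_mm2[b$feature == "RPE_LOSS" & b$eye_id == "e001"])
  # growth is the 12-month sqrt-change of RORA
  g12 <- lt[lt$feature == "RORA" & lt$visit_month == 12 &
              lt$eye_id == "e001", ]
  expect_equal(eye1$growth_12m, g12$sqrt_change_mm)
  # area-change response differs but is available
  pt2 <- predictor_table(lt, response = "area_change")
  expect_equal(pt2$growth_12m[1], g12$area_mm2 - g12$baseline_area_mm2)
})

test_that("a perfectly linear response gives bootstrap R^2 of one", {
  pt <- simulate_predictor_table(60, coef_ratio = 0.05, noise_sd = 0,
                                 seed = 3)
  # a zero-residual fit makes lm's inference summary complain; the R^2
  # path under test is unaffected
  rep <- suppressWarnings(univariable_ratio_model(pt, n_boot = 50, seed = 9))
  expect_true(all(abs(rep$r2_boot - 1) < 1e-9))
  expect_true(all(rep$r2_boot >= 0 & rep$r2_boot <= 1))
  expect_equal(rep$coefficients$estimate[2], 0.05, tolerance = 1e-9)
})

test_that("bootstrap R^2 tracks a constructed true R^2", {
  # response = 0.05 x ratio + noise with SD chosen for R^2 = 0.25
  pt0 <- simulate_predictor_table(4000, coef_ratio = 0.05, noise_sd = 0,
                                  seed = 5)
  sd_signal <- sd(pt0$growth_12m)
  noise_sd <- sd_signal * sqrt(1 / 0.25 - 1)
  pt <- simulate_predictor_table(200, coef_ratio = 0.05,
                                 noise_sd = noise_sd, seed = 6)
  rep <- univariable_ratio_model(pt, n_boot = 100, seed = 7)
  expect_gt(rep$r2_boot_mean, 0.15)
  expect_lt(rep$r2_boot_mean, 0.35)
})

test_that("degenerate predictor designs are rejected with names", {
  pt <- simulate_predictor_table(30, seed = 8)
  pt$ratio_prd_rpe <- 2
  expect_error(univariable_ratio_model(pt), "zero variance")
  expect_error(multivariable_growth_model(pt), "ratio_prd_rpe")
  pt2 <- simulate_predictor_table(30, seed = 8)
  pt2$intact_macula_mm2 <- 2 * pt2$prd_isolated_mm2 + 1
  expect_error(multivariable_growth_model(pt2),
               "collinear.*intact_macula_mm2")
})

test_that("multivariable model pins a planted coefficient", {
  pt <- simulate_predictor_table(300, coef_prd_iso = 0.02, noise_sd = 0.15,
                                 seed = 10)
  rep <- multivariable_growth_model(pt, n_boot = 100, seed = 11)
  co <- rep$coefficients
  iso <- co[co$term == "prd_isolated_mm2", ]
  expect_lt(abs(iso$estimate - 0.02), 3 * iso$se)
  expect_lt(iso$p_value, 0.01)
  expect_true(iso$boot_ci_lower < 0.02 && 0.02 < iso$boot_ci_upper)
  # the two dormant predictors stay quiet
  expect_gt(co$p_value[co$term == "ratio_prd_rpe"], 0.01)
})

test_that("permuting the response destroys the association", {
  set.seed(12)
  rej <- replicate(120, {
    pt <- simulate_predictor_table(80, coef_prd_iso = 0.02,
                                   noise_sd = 0.15,
                                   seed = sample.int(1e6, 1))
    pt$growth_12m <- sample(pt$growth_12m)
    rep <- multivariable_growth_model(pt, n_boot = 2, seed = 1)
    co <- rep$coefficients
    co$p_value[co$term != "(Intercept)"] < 0.05
  })
  rate <- mean(rej)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)
})

test_that("quartile stratification: groups, ties, invariance, monotonicity", {
  # n = 8 with distinct values: groups of 2
  pt8 <- simulate_predictor_table(8, seed = 13)
  qs8 <- quartile_stratify(pt8, "prd_isolated_mm2")
  expect_equal(qs8$summary$n, rep(2L, 4))

  # stratifying by the response itself: strictly increasing means
  ptr <- simulate_predictor_table(48, seed = 14)
  ptr$self <- ptr$growth_12m
  qsr <- quartile_stratify(ptr, "self")
  expect_true(all(diff(qsr$summary$mean_growth) > 0))
  expect_equal(qsr$spearman_rho, 1)

  # invariance under a strictly monotone transform of the variable
  pt <- simulate_predictor_table(60, coef_prd_iso = 0.02, seed = 15)
  q1 <- quartile_stratify(pt, "prd_isolated_mm2")
  pt$warped <- exp(pt$prd_isolated_mm2 / 3)
  q2 <- quartile_stratify(pt, "warped")
  expect_equal(q1$summary$n, q2$summary$n)
  expect_equal(q1$summary$mean_growth, q2$summary$mean_growth)

  # heavy ties collapse the bins
  ptt <- simulate_predictor_table(40, seed = 16)
  ptt$flat <- rep(c(1, 2), 20)
  expect_error(quartile_stratify(ptt, "flat"), "fewer bins")

  # growth increasing in isolated PRD: greatest growth in top quartile
  ptg <- simulate_predictor_table(120, coef_prd_iso = 0.02,
                                  noise_sd = 0.1, seed = 17)
  qs <- quartile_stratify(ptg, "prd_isolated_mm2", by_arm = TRUE)
  expect_equal(which.max(qs$summary$mean_growth), 4L)
  expect_s3_class(qs$by_arm, "data.frame")
})
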