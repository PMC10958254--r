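test_that("an empty configuration yields an empty cohort and truth", {
  cfg <- tiny_config(n_per_arm = c(PM = 0, SHAM = 0))
  coh <- simulate_cohort(cfg)
  expect_length(coh$groups, 0)
  expect_equal(nrow(coh$truth$eyes), 0)
  expect_equal(nrow(simulate_growth_table(cfg)), 0)
})

test_that("degenerate halo: PRD = RPE loss = HTR, isolated PRD empty", {
  cfg <- tiny_config(prd_halo_mm = 0, htr_agreement = 1)
  coh <- simulate_cohort(cfg, keep_truth_maps = TRUE)
  for (tm in coh$truth_maps) {
    expect_identical(tm$PRD, tm$RPE_LOSS)
    expect_identical(tm$HTR, tm$RPE_LOSS)
    expect_identical(tm$RORA, tm$RPE_LOSS)
    expect_false(any(tm$PRD_ISOLATED))
  }
  iso <- coh$truth$areas[coh$truth$areas$feature == "PRD_ISOLATED", ]
  expect_true(all(iso$area_mm2 == 0))
})

test_that("rendered lesions follow the affine sqrt-area growth law", {
  # single sham eye, baseline sqrt-area 2.0 mm, growth 0.277 mm/yr
  cfg <- cohort_config(
    n_per_arm = c(SHAM = 1), visit_months = c(0, 6, 12),
    baseline_area_range_mm2 = c(4, 4), growth_sd_frac = 0,
    htr_agreement = 1, rng_seed = 5)
  coh <- simulate_cohort(cfg, keep_volumes = FALSE)
  rpe <- coh$truth$areas[coh$truth$areas$feature == "RPE_LOSS", ]
  rpe <- rpe[order(rpe$visit_month), ]
  target <- (2 + 0.277 * rpe$visit_month / 12)^2
  # the renderer hits the target pixel count exactly; tolerance one pixel
  expect_lt(max(abs(rpe$area_mm2 - target)), 2 * cfg$px_mm^2)
  expect_equal(sqrt(rpe$area_mm2[rpe$visit_month == 12]), 2.277,
               tolerance = 1e-3)
})

test_that("constituent containment and RORA oracle hold on rendered truth", {
  cfg <- tiny_config(htr_agreement = 1, n_per_arm = c(PM = 1, SHAM = 1),
                     rng_seed = 21)
  coh <- simulate_cohort(cfg, keep_truth_maps = TRUE)
  for (tm in coh$truth_maps) {
    expect_true(all(tm$PRD[tm$RPE_LOSS]))          # RPE loss inside PRD
    expect_identical(tm$HTR, tm$RPE_LOSS)          # exact agreement
    expect_identical(tm$RORA, tm$RPE_LOSS)         # closed-form oracle
  }
  ar <- coh$truth$areas
  wide <- reshape(ar[, c("eye_id", "visit_month", "feature", "area_mm2")],
                  direction = "wide", idvar = c("eye_id", "visit_month"),
                  timevar = "feature")
  expect_equal(wide$area_mm2.RORA, wide$area_mm2.RPE_LOSS)
  expect_equal(wide$area_mm2.PRD_ISOLATED,
               wide$area_mm2.PRD - wide$area_mm2.RPE_LOSS)
})

test_that("identical seed gives a bitwise-identical cohort", {
  cfg <- tiny_config(rng_seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$groups, b$groups)
  c <- simulate_cohort(tiny_config(rng_seed = 43))
  expect_false(identical(a$truth$eyes, c$truth$eyes))
})

test_that("per-eye regression on true sqrt-areas recovers the growth rate", {
  cfg <- cohort_config(n_per_arm = c(PM = 2, SHAM = 2),
                       visit_months = c(0, 6, 12, 18),
                       growth_sd_frac = 0, htr_agreement = 1, rng_seed = 9)
  coh <- simulate_cohort(cfg, keep_volumes = FALSE)
  d <- coh$truth$areas[coh$truth$areas$feature == "RORA", ]
  for (eye in unique(d$eye_id)) {
    di <- d[d$eye_id == eye, ]
    slope <- coef(lm(sqrt(di$area_mm2) ~ I(di$visit_month / 12)))[2]
    expected <- cfg$arm_effect[[di$arm[1]]] * 0.277
    expect_lt(abs(slope - expected) / expected, 0.05)
  }
})

test_that("write_cohort produces a verifiable, round-trippable directory", {
  cfg <- tiny_config(n_per_arm = c(PM = 1), visit_months = c(0, 12),
                     rng_seed = 3)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(file.exists(man))
  j <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(j$n_volumes, 2 * 3)
  # checksums verify (read_cohort does so), masks identical to the render
  back <- read_cohort(dir)
  expect_setequal(names(back$groups), names(coh$groups))
  for (key in names(coh$groups)) {
    for (f in ga_constituent_features()) {
      expect_identical(back$groups[[key]][[f]]$masks,
                       coh$groups[[key]][[f]]$masks)
    }
  }
  # manifest collision unless overwrite
  expect_error(write_cohort(coh, dir), "manifest")
  expect_silent(write_cohort(coh, dir, overwrite = TRUE))
  # corrupting a file breaks verification
  tifs <- list.files(dir, pattern = "RPE_LOSS\\.tif$", full.names = TRUE)
  writeBin(as.raw(0:255), tifs[1])
  expect_error(read_cohort(dir), "checksum")
})

test_that("analytic growth table matches the latent parameters it shares", {
  cfg <- cohort_config(n_per_arm = c(PM = 3, SHAM = 3),
                       visit_months = c(0, 12), measurement_sd_mm = 0,
                       rng_seed = 77)
  gt <- simulate_growth_table(cfg)
  expect_s3_class(gt, "long_table")
  expect_true(all(gt$sqrt_change_mm[gt$visit_month == 0] == 0))
  # with zero measurement noise the 12-month change equals the true rate
  coh_eyes <- simulate_cohort(cfg, keep_volumes = FALSE)$truth$eyes
  m <- merge(gt[gt$visit_month == 12, ], coh_eyes, by = "eye_id")
  expect_equal(m$sqrt_change_mm, m$growth_mm_per_year, tolerance = 1e-10)
})
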