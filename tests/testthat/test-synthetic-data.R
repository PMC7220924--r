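test_that("gen_precip honours the Markov-chain limits and determinism", {
  # p_dry_to_wet = 1: a dry day is always followed by a wet day, so no dry
  # run can reach the 5-day rule
  p <- gen_precip(400, p_wet_to_wet = 0.5, p_dry_to_wet = 1, seed = 11)
  expect_equal(nrow(detect_dry_spells(p)), 0)

  # p_dry_to_wet ~ 0 with a dry start: one spell spanning the whole record
  p0 <- gen_precip(400, p_wet_to_wet = 0.5, p_dry_to_wet = 1e-12,
                   start = "dry", seed = 11)
  sp <- detect_dry_spells(p0)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$duration, 400)

  expect_identical(gen_precip(500, seed = 42), gen_precip(500, seed = 42))
  expect_false(identical(gen_precip(500, seed = 42)$precip_mm,
                         gen_precip(500, seed = 43)$precip_mm))

  expect_error(gen_precip(400, p_dry_to_wet = 0), class = "rwlr_parameter")
  expect_error(gen_precip(400, p_wet_to_wet = 1.2), class = "rwlr_parameter")
  expect_error(gen_precip(100), class = "rwlr_parameter")
})

test_that("gen_precip dry-run lengths are approximately geometric", {
  p <- gen_precip(20000, p_wet_to_wet = 0.5, p_dry_to_wet = 0.25, seed = 4)
  r <- rle(p$precip_mm == 0)
  runs <- r$lengths[r$values]
  # geometric mean run length = 1 / p_dry_to_wet
  expect_lt(abs(mean(runs) - 4), 0.3)
})

test_that("scene stack follows the bucket recursion exactly when noise-free", {
  p <- gen_precip(400, seed = 2)
  st <- gen_scene_stack(p, noise_sd = 0, seed = 3, nrow = 6, ncol = 6)
  S <- st$moisture_daily
  infil <- st$infiltration
  loss <- st$loss_rate
  for (t in 2:dim(S)[3]) {
    prev <- S[, , t - 1]
    step <- pmin(pmax(prev + pmin(infil[t], 1 - prev) - loss * prev, 0), 1)
    expect_identical(S[, , t], step)
  }
  expect_true(all(st$moisture_truth >= 0 & st$moisture_truth <= 1))
  # composite sampling picks the daily states at the composite days
  expect_identical(st$moisture_truth[, , 3], S[, , st$times[3]])
})

test_that("scene stack moisture = 1 pins the temperature to the wet edge", {
  p <- gen_precip(365, p_wet_to_wet = 0.9, p_dry_to_wet = 0.9,
                  mean_depth = 50, seed = 5)
  p$precip_mm[] <- 100  # saturating rain every day
  st <- gen_scene_stack(p, noise_sd = 0, et_rate = 0, leakage = 0,
                        seed = 5, nrow = 4, ncol = 4, init_moisture = 1)
  e <- st$params$edges_truth
  expect_equal(as.vector(st$lst),
               as.vector(e$c + e$d * st$ndvi), tolerance = 1e-12)
})

test_that("higher leakage dries the bucket strictly faster during dry spells", {
  p <- gen_precip(600, seed = 9)
  st_lo <- gen_scene_stack(p, leakage = 0.02, noise_sd = 0, seed = 7)
  st_hi <- gen_scene_stack(p, leakage = 0.10, noise_sd = 0, seed = 7)
  spells <- detect_dry_spells(p)
  expect_gt(nrow(spells), 0)
  day0 <- as.numeric(spells$start_date[1] - p$date[1]) + 1
  day1 <- as.numeric(spells$end_date[1] - p$date[1]) + 1
  drop_lo <- st_lo$moisture_daily[, , day0] - st_lo$moisture_daily[, , day1]
  drop_hi <- st_hi$moisture_daily[, , day0] - st_hi$moisture_daily[, , day1]
  expect_true(all(drop_hi > drop_lo))
  # determinism
  expect_identical(st_lo, gen_scene_stack(p, leakage = 0.02, noise_sd = 0,
                                          seed = 7))
})

test_that("gen_scene_stack validates its triangle and rates", {
  p <- gen_precip(365, seed = 1)
  expect_error(gen_scene_stack(p, edges_truth = list(a = 280, b = 0, c = 290, d = 0)),
               class = "rwlr_parameter")
  expect_error(gen_scene_stack(p, leakage = -0.1), class = "rwlr_parameter")
})

test_that("gen_czu_table encodes the planted path structure", {
  # noise-free: rwlr is an exact linear map of br_ca
  t0 <- gen_czu_table(n = 23, noise_sd = 0, seed = 1)
  expect_equal(cor(t0$rwlr, t0$br_ca), 1, tolerance = 1e-12)

  # all betas zero: no predictor should correlate with npp at n = 200
  tz <- gen_czu_table(n = 200,
                      betas = list(rwlr_brca = 0, npp_rwlr = 0, npp_mat = 0,
                                   si_ca = 0),
                      seed = 77)
  rs <- abs(cor(tz$npp, tz[, c("rwlr", "mat", "ap", "sd", "pdsi", "soil_n",
                               "br_si", "br_ca")]))
  expect_true(all(rs < 0.3))

  # defaults: strong negative Si-Ca correlation, signs as planted
  td <- gen_czu_table(n = 200, seed = 3)
  expect_lt(cor(td$br_si, td$br_ca), -0.8)
  expect_gt(cor(td$rwlr, td$br_ca), 0.6)
  expect_lt(cor(td$npp, td$rwlr), -0.3)
  expect_gt(cor(td$npp, td$mat), 0.1)

  expect_identical(gen_czu_table(seed = 8), gen_czu_table(seed = 8))
  expect_error(gen_czu_table(n = 5), class = "rwlr_parameter")
  expect_error(gen_czu_table(betas = list(npp_rwlr = Inf)),
               class = "rwlr_parameter")
  tr <- attr(gen_czu_table(seed = 1), "truth")
  expect_named(tr$betas, c("rwlr_brca", "npp_rwlr", "npp_mat", "si_ca"))
})

test_that("CZU table round-trips through the canonical CSV", {
  tab <- gen_czu_table(seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_czu_csv(tab, f)
  hdr <- readLines(f, n = 1)
  expect_equal(hdr, paste0('"czu_id","rwlr","npp","mat","ap","sd","pdsi",',
                           '"soil_n","br_si","br_ca","br_mg","br_fe","br_al"'))
  back <- read_czu_csv(f)
  expect_equal(back$npp, tab$npp, tolerance = 1e-12)
  expect_equal(attr(back, "truth")$betas$npp_rwlr,
               attr(tab, "truth")$betas$npp_rwlr)
})

test_that("gen_global_grid plants the requested correlation structure", {
  g <- gen_global_grid(nrow = 10, ncol = 10, r_inside = 0, r_outside = 0.6,
                       years = 500, seed = 21)
  fld <- pixel_correlation(g$ndvi_series, g$temp_series)
  # zone means converge on the planted targets (tolerance 0.1 at 500 years)
  expect_lt(abs(mean(fld$r[g$karst_mask == 1])), 0.1)
  expect_lt(abs(mean(fld$r[g$karst_mask == 0]) - 0.6), 0.1)

  expect_identical(gen_global_grid(seed = 5, years = 12),
                   gen_global_grid(seed = 5, years = 12))
  expect_error(gen_global_grid(r_inside = 1), class = "rwlr_parameter")
  expect_error(gen_global_grid(years = 5), class = "rwlr_parameter")
})
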