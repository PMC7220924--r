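test_that("dry-spell detection applies the >= 5-day rule on toy series", {
  p <- precip_from(c(0, 0, 0, 0, 0, 2, 0, 0, 0, 0))
  sp <- detect_dry_spells(p)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start_date, p$date[1])
  expect_equal(sp$end_date, p$date[5])
  expect_equal(sp$duration, 5)

  expect_equal(nrow(detect_dry_spells(precip_from(rep(3, 30)))), 0)

  # trace-rain threshold: 0.05 mm days count as dry at wet_threshold = 0.1
  p2 <- precip_from(c(rep(0.05, 6), 5, rep(0, 4)))
  expect_equal(nrow(detect_dry_spells(p2)), 0)
  expect_equal(detect_dry_spells(p2, wet_threshold = 0.1)$duration, 6)

  gap <- precip_from(rep(0, 10))
  gap$date[5] <- gap$date[5] + 30
  expect_error(detect_dry_spells(gap), class = "rwlr_input")
  expect_error(detect_dry_spells(p, min_length = 1), class = "rwlr_parameter")
})

test_that("dry-spell detection matches the exhaustive window-scan oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    p <- precip_from(ifelse(runif(1000) < 0.45, 0, rexp(1000, 1 / 6)))
    got <- detect_dry_spells(p)
    want <- oracle_spells(p)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_date, want$start_date)
    expect_equal(got$end_date, want$end_date)
  }
})

test_that("CZU disc means are exact on constructed scenes", {
  mk_scene <- function(vals) structure(
    list(tvdi = vals, qc_mask = !is.na(vals), time = 1,
         grid = list(nrow = nrow(vals), ncol = ncol(vals), xmin = 0,
                     ymin = 0, dx = 1, dy = 1)),
    class = "tvdi_scene")

  uni <- mk_scene(matrix(0.3, 10, 10))
  out <- czu_mean_tvdi(list(uni), list(x = 5, y = 5, radius = 3))
  expect_equal(out$tvdi, 0.3)
  out2 <- czu_mean_tvdi(list(uni), list(x = 2, y = 8, radius = 1.2))
  expect_equal(out2$tvdi, 0.3)

  # half 0.2 / half 0.4 with the disc centred on the dividing line:
  # symmetric pixel counts, so the mean is exactly 0.3
  half <- matrix(0.2, 10, 10); half[, 6:10] <- 0.4
  out3 <- czu_mean_tvdi(list(mk_scene(half)), list(x = 5, y = 5, radius = 4.9))
  expect_equal(out3$tvdi, 0.3, tolerance = 1e-12)

  expect_error(czu_mean_tvdi(list(uni), list(x = 100, y = 100, radius = 2)),
               class = "rwlr_geometry")

  # composites failing the valid-fraction screen are dropped and recorded
  holey <- matrix(NA_real_, 10, 10); holey[1, 1] <- 0.5
  both <- czu_mean_tvdi(list(uni, mk_scene(holey)),
                        list(x = 5, y = 5, radius = 3))
  expect_equal(nrow(both), 1)
  expect_equal(attr(both, "dropped_times"), 1)
})

test_that("RWLR worked examples match hand arithmetic", {
  # one spell, composites at day 0 (0.20) and day 5 (0.40)
  series <- data.frame(time = c(0, 5), tvdi = c(0.20, 0.40))
  spell <- data.frame(start_date = 0, end_date = 5)
  res <- compute_rwlr(series, spell)
  expect_equal(res$per_spell_means, 0.04)
  expect_equal(res$rwlr, 4.0)
  expect_equal(res$n_spells_used, 1)

  # constant TVDI: zero under either aggregate
  cser <- data.frame(time = seq(0, 30, 5), tvdi = rep(0.5, 7))
  spl <- data.frame(start_date = c(0, 16), end_date = c(14, 30))
  expect_equal(compute_rwlr(cser, spl)$rwlr, 0)
  expect_equal(compute_rwlr(cser, spl, aggregate = "sum")$rwlr, 0)

  # three spells with per-spell means 0.01, 0.02, 0.03 / day
  ser3 <- data.frame(time = c(0, 10, 100, 110, 200, 210),
                     tvdi = c(0, 0.1, 0, 0.2, 0, 0.3))
  spl3 <- data.frame(start_date = c(0, 100, 200), end_date = c(10, 110, 210))
  expect_equal(compute_rwlr(ser3, spl3)$rwlr, 2.0)
  expect_equal(compute_rwlr(ser3, spl3, aggregate = "sum")$rwlr, 6.0)

  # no usable spell: NA signal, not zero
  empty <- compute_rwlr(series, data.frame(start_date = 50, end_date = 60))
  expect_true(is.na(empty$rwlr))
  expect_equal(empty$n_spells_used, 0)

  # class mismatch between series clock and spell dates
  expect_error(compute_rwlr(series,
                            data.frame(start_date = as.Date("2001-01-01"),
                                       end_date = as.Date("2001-01-06"))),
               class = "rwlr_interface")
})

test_that("RWLR is time-shift invariant and scales with TVDI differences", {
  set.seed(10)
  series <- data.frame(time = sort(sample(0:400, 60)),
                       tvdi = runif(60, 0.2, 0.8))
  spl <- data.frame(start_date = c(10, 150, 300), end_date = c(40, 190, 350))
  base <- compute_rwlr(series, spl)

  shifted <- compute_rwlr(transform(series, time = time + 1000),
                          transform(spl, start_date = start_date + 1000,
                                    end_date = end_date + 1000))
  expect_equal(shifted$rwlr, base$rwlr, tolerance = 1e-12)

  scaled <- compute_rwlr(transform(series, tvdi = tvdi * 3), spl)
  expect_equal(scaled$rwlr, base$rwlr * 3, tolerance = 1e-12)
})

test_that("per-spell drying slope rises with the leakage parameter", {
  p <- gen_precip(1000, seed = 17)
  spells <- detect_dry_spells(p)
  spn <- data.frame(start_date = as.numeric(spells$start_date - p$date[1]) + 1,
                    end_date = as.numeric(spells$end_date - p$date[1]) + 1)
  vals <- sapply(c(0.02, 0.05, 0.10), function(leak) {
    st <- gen_scene_stack(p, leakage = leak, noise_sd = 0, seed = 23,
                          nrow = 8, ncol = 8)
    scenes <- stack_tvdi(st, edges = "truth")
    ser <- czu_mean_tvdi(scenes, list(x = 4, y = 4, radius = 3.5))
    compute_rwlr(ser, spn)$rwlr
  })
  expect_true(all(diff(vals) > 0))
})

test_that("site screening mirrors the 30 -> 23 selection narrative", {
  expect_equal(filter_sites(data.frame(czu_id = "A", n_years = 10,
                                       relocated = FALSE, n_spells = 9))$excluded$reason,
               "min_spells")
  expect_equal(filter_sites(data.frame(czu_id = "B", n_years = 10,
                                       relocated = TRUE, n_spells = 30))$excluded$reason,
               "relocated")

  set.seed(1)
  sites <- data.frame(czu_id = sprintf("S%02d", 1:30),
                      n_years = c(rep(10, 27), 6, 7, 8),
                      relocated = c(rep(FALSE, 25), TRUE, TRUE, FALSE, FALSE, FALSE),
                      n_spells = c(rep(25, 23), 5, 8, 30, 30, 20, 20, 20))
  out <- filter_sites(sites)
  expect_equal(nrow(out$retained), 23)
  expect_equal(sort(out$retained$czu_id), sprintf("S%02d", 1:23))
  expect_equal(sort(unique(out$excluded$reason)),
               c("min_spells", "record_span", "relocated"))
})
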