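test_that("path spec parsing builds the graph and rejects cycles", {
  sp <- parse_path_spec(c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
  expect_setequal(sp$endogenous, c("npp", "rwlr"))
  expect_setequal(sp$exogenous, c("mat", "br_ca"))
  # topological: parents precede children
  expect_lt(match("br_ca", sp$vars), match("rwlr", sp$vars))
  expect_lt(match("rwlr", sp$vars), match("npp", sp$vars))

  expect_error(parse_path_spec(c("a ~ b", "b ~ a")), class = "rwlr_graph")
  expect_error(parse_path_spec("gibberish"), class = "rwlr_parse")
})

test_that("saturated recursive model reproduces the covariance: chisq 0, CFI 1", {
  set.seed(4)
  d <- data.frame(x = rnorm(30))
  d$m <- 0.5 * d$x + rnorm(30)
  d$y <- 0.3 * d$x - 0.4 * d$m + rnorm(30)
  fit <- fit_path_model(d, c("y ~ x + m", "m ~ x"))
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-8)
  expect_equal(fit$cfi, 1)
  expect_equal(unname(fit$rmsea["point"]), 0)
  expect_true(fit$accepted)
  expect_match(paste(fit$notes, collapse = " "), "zero df")
})

test_that("standardized coefficients hit the generator's sample truth as noise -> 0", {
  tab <- gen_czu_table(n = 23, noise_sd = 0, seed = 6)
  truth <- attr(tab, "truth")$std_sample
  fit <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
  std <- function(from, to)
    fit$paths$est_std[fit$paths$from == from & fit$paths$to == to]
  expect_equal(std("rwlr", "npp"), truth$npp_rwlr, tolerance = 1e-3)
  expect_equal(std("mat", "npp"), truth$npp_mat, tolerance = 1e-3)
  expect_equal(std("br_ca", "rwlr"), truth$rwlr_brca, tolerance = 1e-3)
  # singular (exactly collinear) data: indices flagged unavailable, not wrong
  expect_match(paste(fit$notes, collapse = " "), "singular")
  expect_true(is.na(fit$accepted))
})

test_that("sign pattern (+, -, +) is recovered across generator seeds", {
  signs <- sapply(1:60, function(seed) {
    tab <- gen_czu_table(n = 23, seed = seed)
    fit <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
    p <- fit$paths
    c(ca = sign(p$est_std[p$from == "br_ca"]),
      rw = sign(p$est_std[p$from == "rwlr"]),
      mat = sign(p$est_std[p$from == "mat"]))
  })
  expect_equal(unname(apply(signs, 1, stats::median)), c(1, -1, 1))
})

test_that("total-effect decomposition follows the product/addition rules", {
  mk <- function(df) list(paths = df)
  # chain X -> M (0.8), M -> Y (-0.5): total effect of X = -0.4
  chain <- mk(data.frame(from = c("X", "M"), to = c("M", "Y"),
                         est_std = c(0.8, -0.5)))
  te <- total_effects(chain, "Y")
  expect_equal(te$total[te$variable == "X"], -0.4)
  expect_equal(te$direct[te$variable == "X"], 0)

  # direct-only path
  dir_only <- mk(data.frame(from = "X", to = "Y", est_std = 0.3))
  expect_equal(total_effects(dir_only, "Y")$total, 0.3)

  # two chains (0.2 and -0.05) plus a direct 0.1: total 0.25
  two <- mk(data.frame(from = c("X", "M1", "X", "M2", "X"),
                       to = c("M1", "Y", "M2", "Y", "Y"),
                       est_std = c(0.4, 0.5, 0.1, -0.5, 0.1)))
  teX <- total_effects(two, "Y")
  row <- teX[teX$variable == "X", ]
  expect_equal(row$direct, 0.1)
  expect_equal(row$indirect, 0.15)
  expect_equal(row$total, 0.25)

  cyc <- mk(data.frame(from = c("X", "M"), to = c("M", "X"),
                       est_std = c(1, 1)))
  expect_error(total_effects(cyc, "Y"), class = "rwlr_graph")
})

test_that("single-mediator total effect equals the simple standardized slope", {
  x <- runif(23)
  m <- 2 * x
  y <- -0.5 * m
  d <- data.frame(x = x, m = m, y = y)
  fit <- fit_path_model(d, c("y ~ m", "m ~ x"))
  te <- fit$total_effects
  total_x <- te$total[te$variable == "x"]
  simple_std <- fit_lm(y, cbind(x = x))$coefficients["x", "estimate"] *
    sd(x) / sd(y)
  expect_equal(total_x, unname(simple_std), tolerance = 1e-6)
})

test_that("acceptance verdict applies the three fit criteria", {
  base <- list(chisq_p = 0.30, cfi = 0.97, rmsea = c(point = 0.02,
                                                     lower90 = 0,
                                                     upper90 = 0.1), df = 3)
  expect_true(accept_model(base)$accepted)

  bad_cfi <- base; bad_cfi$cfi <- 0.85
  v <- accept_model(bad_cfi)
  expect_false(v$accepted)
  expect_equal(v$reasons, "CFI")

  bad_all <- list(chisq_p = 0.01, cfi = 0.5,
                  rmsea = c(point = 0.3, lower90 = 0.2, upper90 = 0.4), df = 3)
  expect_setequal(accept_model(bad_all)$reasons,
                  c("chisq_p", "CFI", "RMSEA_lower90"))
})

test_that("Si- and Ca-variant models mirror each other and refuse to merge", {
  tab <- gen_czu_table(n = 23, seed = 14)
  f_si <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_si"))
  f_ca <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
  expect_lt(abs(f_si$r2[["npp"]] - f_ca$r2[["npp"]]), 0.05)
  # opposite signs into rwlr, same sign out of it
  s_si <- f_si$paths$est_std[f_si$paths$from == "br_si"]
  s_ca <- f_ca$paths$est_std[f_ca$paths$from == "br_ca"]
  expect_lt(s_si, 0); expect_gt(s_ca, 0)

  expect_error(fit_path_model(tab, c("npp ~ rwlr", "rwlr ~ br_si + br_ca")),
               class = "rwlr_parameter")
  expect_error(fit_path_model(tab, "npp ~ nonexistent"),
               class = "rwlr_interface")
})

test_that("indirect effects equal products of standardized path coefficients", {
  tab <- gen_czu_table(n = 23, seed = 25)
  fit <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
  p <- fit$paths
  prod_chain <- p$est_std[p$from == "br_ca" & p$to == "rwlr"] *
    p$est_std[p$from == "rwlr" & p$to == "npp"]
  te <- fit$total_effects
  expect_equal(te$indirect[te$variable == "br_ca"], prod_chain,
               tolerance = 1e-8)
  expect_equal(te$total, te$direct + te$indirect, tolerance = 1e-12)
})

test_that("path fits serialize to JSON", {
  tab <- gen_czu_table(n = 23, seed = 30)
  fit <- fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
  f <- withr::local_tempfile(fileext = ".json")
  write_path_fit_json(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$fit_indices$cfi, fit$cfi, tolerance = 1e-12)
  expect_equal(back$r2$npp, unname(fit$r2["npp"]), tolerance = 1e-12)
})
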