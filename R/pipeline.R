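#' Default pipeline configuration
#'
#' Every parameter the pipeline touches, with defaults matching the method
#' description where one is stated (dry spells of >= 5 days, collinearity
#' threshold 0.70, buffer width 1 pixel, growing season April-September,
#' 95% cumulative-weight best subset) and a package design decision
#' otherwise. The structure round-trips through JSON unchanged.
#'
#' @return nested named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    stages = c("simulate", "tvdi", "rwlr", "rank", "sem", "karst"),
    inputs = list(precip_csv = NULL, czu_csv = NULL),
    precip = list(n_days = 1825L, p_wet_to_wet = 0.7, p_dry_to_wet = 0.15,
                  mean_depth = 8),
    scene = list(nrow = 16L, ncol = 16L, leakage = 0.05, et_rate = 0.03,
                 noise_sd = 0, composite_interval = 5L, infil_per_mm = 0.1,
                 edges = list(a = 320, b = -15, c = 290, d = 0)),
    czu = list(n = 23L, noise_sd = 1),
    global = list(nrow = 40L, ncol = 40L, years = 30L,
                  r_inside = -0.2, r_outside = 0.3),
    tvdi = list(edges_mode = "pooled", n_bins = 20L, edge_percentile = 1,
                min_pixels_per_bin = 5L, ndvi_min = 0.05),
    rwlr = list(min_length = 5L, wet_threshold = 0, aggregate = "mean",
                min_composites = 2L, disc_radius = 7,
                min_valid_frac = 0.5),
    rank = list(cum_weight = 0.95, collinearity_threshold = 0.70,
                include_null = TRUE),
    sem = list(spec_si = c("npp ~ rwlr + mat", "rwlr ~ br_si"),
               spec_ca = c("npp ~ rwlr + mat", "rwlr ~ br_ca")),
    karst = list(width_pixels = 1L, ndvi_floor = 0.1, inner_mode = "ring",
                 connectivity = 8L, alpha = 0.05),
    log_level = "info"
  ), class = "run_config")
}

config_ranges <- function() list(
  "precip.n_days" = c(365, Inf),
  "precip.p_wet_to_wet" = c(0, 1),
  "precip.p_dry_to_wet" = c(1e-12, 1),
  "rwlr.min_length" = c(2, Inf),
  "rwlr.min_composites" = c(2, Inf),
  "rank.cum_weight" = c(0, 1),
  "rank.collinearity_threshold" = c(0, 1),
  "karst.width_pixels" = c(0, Inf),
  "czu.n" = c(10, Inf),
  "global.years" = c(10, Inf),
  "tvdi.n_bins" = c(5, Inf)
)

#' Validate a pipeline configuration
#'
#' Accepts a (possibly partial) list or a JSON file path; fills defaults,
#' rejects unknown keys (suggesting the nearest valid key), and
#' range-checks numeric parameters.
#'
#' @param raw list, JSON path, or `NULL` (pure defaults).
#' @return a validated `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  defaults <- default_config()
  if (is.null(raw)) return(defaults)
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (file.size(raw) == 0) list()
           else jsonlite::read_json(raw, simplifyVector = TRUE)
  }
  check_keys <- function(user, ref, prefix = "") {
    for (key in names(user)) {
      if (!key %in% names(ref)) {
        near <- names(ref)[which.min(utils::adist(key, names(ref)))]
        stop_rwlr("config",
                  sprintf("unknown config key '%s%s' (did you mean '%s%s'?)",
                          prefix, key, prefix, near))
      }
      if (is.list(ref[[key]]) && !is.null(names(ref[[key]])) &&
          is.list(user[[key]]))
        check_keys(user[[key]], ref[[key]], paste0(prefix, key, "."))
    }
  }
  check_keys(raw, defaults)
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  class(cfg) <- "run_config"

  for (path in names(config_ranges())) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- config_ranges()[[path]]
    if (!is.null(val) && (!is.numeric(val) || val < rng[1] || val > rng[2]))
      stop_rwlr("config", sprintf("config key '%s' = %s out of range [%g, %g]",
                                  path, format(val), rng[1], rng[2]))
  }
  bad_stage <- setdiff(cfg$stages, default_config()$stages)
  if (length(bad_stage))
    stop_rwlr("config", paste("unknown stage:", paste(bad_stage, collapse = ", ")))
  cfg
}

stage_seed <- function(seed, index) (seed + 104729L * index) %% 2147483647L

#' Run the synthetic analysis pipeline
#'
#' Executes enabled stages in dependency order: `simulate` (generators) ->
#' `tvdi` (triangle edges + index scenes) -> `rwlr` (dry spells + index
#' slopes) -> `rank` (all-subsets importance for NPP and RWLR, with the
#' Si/Ca collinearity split) -> `sem` (the two path-model variants) ->
#' `karst` (buffer-zone contrast). Tabular outputs are CSV, scalar/fit
#' results JSON; a manifest records the config hash, per-file MD5 checksums,
#' per-stage wall time and the per-stage seed registry, so reruns are
#' verifiably reproducible.
#'
#' @param config a `run_config` (or partial list / JSON path, validated
#'   here).
#' @param seed master integer seed, expanded into per-stage seeds by a
#'   counter scheme.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = tempfile("rwlr_run_")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(st) st %in% cfg$stages
  if (!on("simulate")) {
    if (on("rwlr") && is.null(cfg$inputs$precip_csv))
      stop_rwlr("config",
                "inputs$precip_csv is required when stage 'simulate' is disabled")
    if ((on("rank") || on("sem")) && is.null(cfg$inputs$czu_csv))
      stop_rwlr("config",
                "inputs$czu_csv is required when stage 'simulate' is disabled")
    if (on("tvdi"))
      stop_rwlr("config",
                "stage 'tvdi' needs simulated scenes: enable 'simulate' (grid inputs are not read from disk in this build)")
  }

  manifest <- list(package_version = as.character(utils::packageVersion("rwlr")),
                   seed = seed, stages = list())
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest$config_hash <- unname(tools::md5sum(
    local({ f <- file.path(out_dir, "config.json")
            writeLines(cfg_json, f); f })))

  env <- new.env()
  record <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(seed, match(stage, default_config()$stages)),
      files = as.list(tools::md5sum(files)),
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  }

  if (on("simulate")) {
    t0 <- as.numeric(Sys.time()); s <- stage_seed(seed, 1L)
    env$precip <- gen_precip(cfg$precip$n_days, cfg$precip$p_wet_to_wet,
                             cfg$precip$p_dry_to_wet, cfg$precip$mean_depth,
                             seed = s)
    env$stack <- gen_scene_stack(env$precip, leakage = cfg$scene$leakage,
                                 et_rate = cfg$scene$et_rate,
                                 edges_truth = cfg$scene$edges,
                                 noise_sd = cfg$scene$noise_sd, seed = s + 1L,
                                 nrow = cfg$scene$nrow, ncol = cfg$scene$ncol,
                                 composite_interval = cfg$scene$composite_interval,
                                 infil_per_mm = cfg$scene$infil_per_mm)
    env$czu <- gen_czu_table(cfg$czu$n, noise_sd = cfg$czu$noise_sd,
                             seed = s + 2L)
    env$global <- gen_global_grid(cfg$global$nrow, cfg$global$ncol,
                                  r_inside = cfg$global$r_inside,
                                  r_outside = cfg$global$r_outside,
                                  years = cfg$global$years, seed = s + 3L)
    f1 <- file.path(out_dir, "precip.csv"); write_precip_csv(env$precip, f1)
    f2 <- file.path(out_dir, "czu.csv"); write_czu_csv(env$czu, f2)
    record("simulate", c(f1, f2, paste0(f2, ".json")), t0)
  } else {
    if (!is.null(cfg$inputs$precip_csv))
      env$precip <- read_precip_csv(cfg$inputs$precip_csv)
    if (!is.null(cfg$inputs$czu_csv))
      env$czu <- read_czu_csv(cfg$inputs$czu_csv)
  }

  if (on("tvdi")) {
    t0 <- as.numeric(Sys.time())
    env$scenes <- stack_tvdi(env$stack, edges = cfg$tvdi$edges_mode,
                             n_bins = cfg$tvdi$n_bins,
                             edge_percentile = cfg$tvdi$edge_percentile,
                             min_pixels_per_bin = cfg$tvdi$min_pixels_per_bin,
                             ndvi_min = cfg$tvdi$ndvi_min)
    edges <- attr(env$scenes, "edges")
    f <- file.path(out_dir, "edges.json")
    jsonlite::write_json(unclass(edges), f, auto_unbox = TRUE, digits = NA)
    record("tvdi", f, t0)
  }

  if (on("rwlr")) {
    t0 <- as.numeric(Sys.time())
    spells <- detect_dry_spells(env$precip, cfg$rwlr$min_length,
                                cfg$rwlr$wet_threshold)
    if (!is.null(env$scenes)) {
      g <- env$stack$grid
      disc <- list(x = g$ncol * g$dx / 2, y = g$nrow * g$dy / 2,
                   radius = cfg$rwlr$disc_radius)
      series <- czu_mean_tvdi(env$scenes, disc, cfg$rwlr$min_valid_frac)
      # spell dates -> day index of the series clock
      sp_num <- data.frame(
        start_date = as.numeric(spells$start_date - env$precip$date[1]) + 1,
        end_date = as.numeric(spells$end_date - env$precip$date[1]) + 1)
      res <- compute_rwlr(series, sp_num, aggregate = cfg$rwlr$aggregate,
                          min_composites = cfg$rwlr$min_composites,
                          czu_id = "SYN01")
      env$rwlr <- res
      f <- file.path(out_dir, "rwlr.csv")
      utils::write.csv(data.frame(czu_id = res$czu_id, rwlr = res$rwlr,
                                  n_spells_used = res$n_spells_used,
                                  n_composites = nrow(series)),
                       f, row.names = FALSE)
      record("rwlr", f, t0)
    } else {
      f <- file.path(out_dir, "dry_spells.csv")
      utils::write.csv(spells, f, row.names = FALSE)
      record("rwlr", f, t0)
    }
  }

  if (on("rank")) {
    t0 <- as.numeric(Sys.time())
    npp_cand <- as.matrix(env$czu[, c("rwlr", "soil_n", "sd", "ap", "mat", "pdsi")])
    r_npp <- all_subsets_rank(env$czu$npp, npp_cand,
                              include_null = cfg$rank$include_null,
                              cum_weight = cfg$rank$cum_weight)
    f1 <- file.path(out_dir, "rank_npp_models.csv")
    f2 <- file.path(out_dir, "rank_npp_rvi.csv")
    write_ranking_csv(r_npp, f1, f2, response_name = "npp")

    br_cand <- as.matrix(env$czu[, c("br_si", "br_ca", "br_mg", "br_fe", "br_al")])
    screen <- collinearity_screen(br_cand, env$czu$rwlr,
                                  threshold = cfg$rank$collinearity_threshold,
                                  keep_both = c("br_si", "br_ca"))
    files <- c(f1, f2)
    for (i in seq_along(screen$subsets)) {
      rk <- all_subsets_rank(env$czu$rwlr,
                             br_cand[, screen$subsets[[i]], drop = FALSE],
                             include_null = cfg$rank$include_null,
                             cum_weight = cfg$rank$cum_weight)
      fi <- file.path(out_dir, sprintf("rank_rwlr_subset%d_rvi.csv", i))
      write_ranking_csv(rk, NULL, fi, response_name = "rwlr")
      files <- c(files, fi)
    }
    env$screen <- screen
    record("rank", files, t0)
  }

  if (on("sem")) {
    t0 <- as.numeric(Sys.time())
    fits <- list(si = fit_path_model(env$czu, cfg$sem$spec_si),
                 ca = fit_path_model(env$czu, cfg$sem$spec_ca))
    f1 <- file.path(out_dir, "sem_si.json"); write_path_fit_json(fits$si, f1)
    f2 <- file.path(out_dir, "sem_ca.json"); write_path_fit_json(fits$ca, f2)
    env$sem <- fits
    record("sem", c(f1, f2), t0)
  }

  if (on("karst")) {
    t0 <- as.numeric(Sys.time())
    ks <- karst_signal(env$global$ndvi_series, env$global$temp_series,
                       env$global$karst_mask,
                       width_pixels = cfg$karst$width_pixels,
                       ndvi_floor = cfg$karst$ndvi_floor,
                       inner_mode = cfg$karst$inner_mode,
                       connectivity = cfg$karst$connectivity,
                       alpha = cfg$karst$alpha)
    f <- file.path(out_dir, "karst_contrast.json")
    jsonlite::write_json(unclass(ks$contrast), f, auto_unbox = TRUE,
                         digits = NA)
    env$karst <- ks
    record("karst", f, t0)
  }

  manifest$out_dir <- out_dir
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "env") <- env
  invisible(manifest)
}
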