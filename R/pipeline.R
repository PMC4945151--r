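# Experiment presets and orchestration: generate -> place -> (align) ->
# count -> test -> report. Every preset fully determines line lengths,
# offsets, band sizes and the statistics plan; calibration targets live in
# inst/extdata/calibration.yaml. Seeds are derived per stage and per scene
# from the root seed, so presets never share RNG streams and reruns are
# exactly reproducible.

preset_names <- function() c("barrel_layer4", "barrel_layer3_5",
                             "auditory_A1A2", "human_IIIaIIIb",
                             "human_blobs", "thickness_4v8")

# Internal preset builder: everything the engine needs to run one
# calibrated measurement chain.
build_preset <- function(name, cal = calibration_constants(),
                         overrides = list()) {
  ov <- function(key, default) overrides[[key]] %||% default
  if (name %in% c("barrel_layer4", "barrel_layer3", "barrel_layer5",
                  "thickness_4v8")) {
    layer_key <- if (name %in% c("barrel_layer4", "thickness_4v8"))
      "barrel_layer4" else name
    cc <- cal[[layer_key]]
    rows <- ov("rows", 5L); arcs <- ov("arcs", 5L)
    L <- cc$line_length %||% 375
    win <- unlist(cal$barrel_layer4$core_span_window)
    list(name = name, static_map = FALSE, line_length = L,
         make_map = function(seed) sample_barrel_map(
           rows, arcs, core_span = ov("core_span", c(360, 440)),
           septum_width = ov("septum_width", 50),
           margin = ov("margin", 150), seed = seed),
         place = function(map) place_septal_and_core_lines(
           map, line_length = L, core_span_window = win),
         group_of = function(tab) tab$class,
         cal_groups = c(septal = "septum", core = "core"),
         astro_targets = c(septal = cc$astro$septal, core = cc$astro$core),
         capillary_targets = if (!is.null(cc$capillary))
           c(septal = cc$capillary$septal, core = cc$capillary$core),
         n_pilot = ov("n_pilot", 180L), n_scenes = ov("n_scenes", 180L))
  } else if (name == "auditory_A1A2") {
    cc <- cal$auditory_A1A2
    L <- cc$line_length %||% 50
    list(name = name, static_map = TRUE, line_length = L,
         make_map = function(seed) sample_area_map(
           "A1_in_A2", list(radius = ov("radius", 750),
                            pad = ov("pad", 400)), seed),
         place = function(map) place_offset_lines(
           map, find_region_border(map, c("A1", "A2")),
           offsets = unlist(cc$offsets), line_length = L,
           station_spacing = ov("station_spacing", 100)),
         group_of = function(tab) paste0(tab$side, "_", tab$offset),
         cal_groups = c(A1_50 = "A1", A2_50 = "A2"),
         astro_targets = c(A1_50 = cc$astro$A1_50, A2_50 = cc$astro$A2_50),
         report_groups = names(cc$astro),
         band = cc$band, band_inner = "A1",
         drop_target = cc$density_drop_pct,
         n_pilot = ov("n_pilot", 40L), n_scenes = ov("n_scenes", 40L))
  } else if (name == "human_IIIaIIIb") {
    cc <- cal$human_IIIaIIIb
    L <- cc$line_length %||% 375
    list(name = name, static_map = TRUE, line_length = L,
         make_map = function(seed) sample_area_map(
           "laminar_IIIa_IIIb", list(width = ov("width", 6000),
                                     height = ov("height", 1200)), seed),
         place = function(map) place_offset_lines(
           map, find_region_border(map, c("IIIa", "IIIb")),
           offsets = unlist(cc$offsets), line_length = L,
           station_spacing = ov("station_spacing", 400)),
         group_of = function(tab) paste0(tab$side, "_", tab$offset),
         cal_groups = c(IIIa_50 = "IIIa", IIIb_50 = "IIIb"),
         astro_targets = c(IIIa_50 = cc$astro$IIIa_50,
                           IIIb_50 = cc$astro$IIIb_50),
         report_groups = names(cc$astro),
         band = cc$band, band_inner = "IIIa",
         drop_target = cc$density_drop_pct,
         n_pilot = ov("n_pilot", 90L), n_scenes = ov("n_scenes", 90L))
  } else if (name == "human_blobs") {
    cc <- cal$human_blobs
    L <- cc$line_length %||% 500
    list(name = name, static_map = TRUE, line_length = L,
         make_map = function(seed) sample_area_map(
           "blob_interblob", list(period = cc$period %||% 1000,
                                  n_blobs = ov("n_blobs", 10L),
                                  blob_rx = ov("blob_rx", 200),
                                  blob_ry = ov("blob_ry", 300),
                                  height = ov("height", 800)), seed),
         place = function(map) place_blob_lines(
           map, line_length = L, margin_gap = ov("margin_gap", 50)),
         group_of = function(tab) tab$class,
         cal_groups = c(blob_center = "blob", interblob_center = "interblob"),
         astro_targets = c(blob_center = cc$astro$blob_center,
                           interblob_center = cc$astro$interblob_center),
         report_groups = names(cc$astro),
         n_pilot = ov("n_pilot", 380L), n_scenes = ov("n_scenes", 380L))
  } else stop(sprintf("unknown preset '%s'", name))
}

#' Find the border between two given classes
#' @param map a `region_map`.
#' @param classes length-2 character vector.
#' @return a `border_polyline`.
#' @export
find_region_border <- function(map, classes) {
  for (b in extract_borders(map))
    if (setequal(b$classes, classes)) return(b)
  stop(sprintf("no border between '%s' and '%s'", classes[1], classes[2]))
}

# ---- calibrated measurement engine -----------------------------------------

# Run n scenes under a fixed config; returns the stacked crossing table
# (astro and, optionally, capillary) and the last scene for serialization.
measure_scenes <- function(ps, cfg, seed, n, capillary_density = NULL,
                           keep_scene = FALSE) {
  tabs <- vector("list", n); ctabs <- vector("list", n)
  map <- NULL; lines <- NULL; last <- NULL
  if (ps$static_map) {
    map <- ps$make_map(derive_seed(seed, "map"))
    lines <- ps$place(map)
  }
  for (s in seq_len(n)) {
    if (!ps$static_map) {
      map <- ps$make_map(derive_seed(seed, paste0("map", s)))
      lines <- ps$place(map)
    }
    if (nrow(lines) == 0L) {
      ab_log("%s scene %d: no qualifying lines; skipped", ps$name, s)
      next
    }
    astro <- grow_astrocyte_arbors(map, cfg, derive_seed(seed,
                                                         paste0("astro", s)))
    tab <- count_line_crossings(lines, astro)
    tab$group <- ps$group_of(tab)
    tab$scene <- rep(s, nrow(tab))
    tabs[[s]] <- tab
    cap <- NULL
    if (!is.null(capillary_density)) {
      cap <- sample_capillary_network(map, capillary_density,
                                      derive_seed(seed, paste0("cap", s)),
                                      segment_length = cfg$capillary_segment_length)
      ctab <- count_line_crossings(lines, cap)
      ctab$group <- paste0("cap_", ps$group_of(ctab))
      ctab$scene <- rep(s, nrow(ctab))
      ctabs[[s]] <- ctab
    }
    if (keep_scene && s == n) {
      last <- structure(list(region_map = map, astro = astro,
                             capillary = cap %||% empty_curve_set("capillary"),
                             landmarks = with_seed(
                               derive_seed(seed, paste0("lm", s)),
                               cbind(stats::runif(6, map$extent[1], map$extent[2]),
                                     stats::runif(6, map$extent[3], map$extent[4]))),
                             config = cfg, seed = derive_seed(seed, paste0("astro", s))),
                        class = "synthetic_scene")
    }
    ab_log("%s scene %d/%d: %d lines, %d astro polylines", ps$name, s, n,
           nrow(lines), n_curves(astro))
  }
  tab <- do.call(rbind, tabs)
  class(tab) <- c("crossing_table", "data.frame")
  ctab <- if (!is.null(capillary_density)) {
    ct <- do.call(rbind, ctabs)
    class(ct) <- c("crossing_table", "data.frame")
    ct
  }
  list(tab = tab, cap_tab = ctab, last_scene = last, lines = lines)
}

# Pilot-calibrate the per-class soma intensity so expected group means hit
# the targets: Buffon inversion for the provisional densities, then linear
# rescaling against a pilot run of the full chain.
calibrate_preset <- function(ps, seed, n_pilot = ps$n_pilot,
                             base_config = list()) {
  targets <- ps$astro_targets
  rho0 <- calibrate_generator(targets, ps$line_length)
  names(rho0) <- ps$cal_groups[names(targets)]
  args <- utils::modifyList(list(fiber_density = rho0, p_cross = 0,
                                 seed = seed), base_config)
  cfg0 <- do.call(generator_config, args)
  pilot <- measure_scenes(ps, cfg0, derive_seed(seed, "pilot"), n_pilot)
  m0 <- tapply(pilot$tab$count, pilot$tab$group, mean)[names(targets)]
  if (any(!is.finite(m0)) || any(m0 <= 0))
    stop("pilot produced empty groups; cannot calibrate")
  scale <- as.numeric(targets / m0)
  cfg <- cfg0
  cls <- ps$cal_groups[names(targets)]
  cfg$soma_intensity[cls] <- cfg$soma_intensity[cls] * scale
  list(config = cfg, pilot_means = m0, scale = stats::setNames(scale, cls),
       densities0 = rho0, n_pilot = n_pilot)
}

# Full calibrated chain for one preset: calibrate, measure, summarize.
run_calibrated <- function(ps, seed, n_pilot = ps$n_pilot,
                           n_scenes = ps$n_scenes, with_capillary = TRUE,
                           keep_scene = FALSE, base_config = list()) {
  calib <- calibrate_preset(ps, seed, n_pilot, base_config)
  cap_density <- NULL
  if (with_capillary && !is.null(ps$capillary_targets)) {
    cap_density <- calibrate_generator(ps$capillary_targets, ps$line_length)
    names(cap_density) <- ps$cal_groups[names(ps$capillary_targets)]
  }
  meas <- measure_scenes(ps, calib$config, derive_seed(seed, "measure"),
                         n_scenes, capillary_density = cap_density,
                         keep_scene = keep_scene)
  full <- if (is.null(meas$cap_tab)) meas$tab else {
    t <- rbind(meas$tab, meas$cap_tab)
    class(t) <- c("crossing_table", "data.frame")
    t
  }
  gs <- do.call(rbind, lapply(split(full$count, full$group), function(v) {
    g <- group_summary(v)
    data.frame(n = g$n, mean = g$mean, sem = g$sem,
               ci_lo = g$ci[1], ci_hi = g$ci[2])
  }))
  gs <- data.frame(group = rownames(gs), gs, row.names = NULL)
  list(preset = ps, calibration = calib, table = full,
       group_summaries = gs, last_scene = meas$last_scene,
       lines = meas$lines, capillary_density = cap_density)
}

group_counts <- function(tab, group) tab$count[tab$group == group]

# ---- density bands and profiles for the border presets ----------------------

# Band profiles across the preset's border on freshly generated scenes.
preset_band_profiles <- function(ps, cfg, seed, n_scenes, step = 1) {
  map <- ps$make_map(derive_seed(seed, "map"))
  border <- find_region_border(map, unname(ps$cal_groups))
  bands <- place_density_bands(border, width = ps$band$width,
                               length = ps$band$length,
                               count = ps$band$count, region_map = map,
                               inner_class = ps$band_inner)
  profs <- list()
  for (s in seq_len(n_scenes)) {
    astro <- grow_astrocyte_arbors(map, cfg, derive_seed(seed,
                                                         paste0("bands", s)))
    for (b in seq_len(nrow(bands)))
      profs[[length(profs) + 1L]] <- band_density_profile(bands[b, ], astro,
                                                          step = step)
  }
  list(bands = bands, profiles = profs,
       aggregate = aggregate_profiles(profs))
}

# ---- experiment presets ------------------------------------------------------

#' Run one experiment preset end to end
#'
#' Generates calibrated scenes, places the preset's measurement constructs,
#' counts crossings, runs the preset's statistics plan and assembles a run
#' report. With `out_dir`, writes the crossing table and group summaries as
#' CSV, the report as JSON, and one example scene plus its lines as GeoJSON.
#'
#' @param preset one of `"barrel_layer4"`, `"barrel_layer3_5"`,
#'   `"auditory_A1A2"`, `"human_IIIaIIIb"`, `"human_blobs"`,
#'   `"thickness_4v8"`.
#' @param seed integer root seed.
#' @param config optional named list of overrides (or a YAML path):
#'   `n_pilot`, `n_scenes`, map geometry parameters, `band_scenes`.
#' @param out_dir optional output directory.
#' @return a `run_report` list.
#' @export
run_experiment <- function(preset = preset_names(), seed = 1L, config = NULL,
                           out_dir = NULL) {
  preset <- match.arg(preset)
  if (is.character(config)) config <- read_config_yaml(config)
  config <- config %||% list()
  if (!is.null(config$seed)) seed <- config$seed
  cal <- calibration_constants()
  stage <- "setup"
  report <- tryCatch({
    if (preset == "barrel_layer4") {
      stage <- "barrel_layer4"
      ps <- build_preset("barrel_layer4", cal, config)
      rc <- run_calibrated(ps, seed, keep_scene = TRUE)
      tests <- list(
        astro_septal_vs_core = students_t_pooled(
          group_counts(rc$table, "septal"), group_counts(rc$table, "core")),
        capillary_septal_vs_core = students_t_pooled(
          group_counts(rc$table, "cap_septal"),
          group_counts(rc$table, "cap_core")))
      astro_tab <- rc$table[rc$table$group %in% c("septal", "core"), ]
      cap_tab <- rc$table[rc$table$group %in% c("cap_septal", "cap_core"), ]
      cap_tab$class <- sub("^cap_", "", cap_tab$group)
      ratios <- list(astro = septa_core_ratio(astro_tab),
                     capillary = septa_core_ratio(cap_tab))
      tests$ratio_astro_vs_capillary <- students_t_pooled(
        ratios$astro$per_scene$ratio, ratios$capillary$per_scene$ratio)
      make_run_report(preset, seed, config, rc, tests, ratios = ratios,
                      out_dir = out_dir)
    } else if (preset == "barrel_layer3_5") {
      stage <- "barrel_layer3_5"
      run_layered_experiment(seed, cal, config, out_dir)
    } else if (preset %in% c("auditory_A1A2", "human_IIIaIIIb")) {
      stage <- preset
      ps <- build_preset(preset, cal, config)
      rc <- run_calibrated(ps, seed, keep_scene = TRUE)
      g <- function(gr) group_counts(rc$table, gr)
      near <- names(ps$cal_groups)       # e.g. A1_50, A2_50
      far <- sub("_50$", "_200", near)
      tests <- list(
        across_border_50 = students_t_pooled(g(near[1]), g(near[2])),
        across_border_200 = students_t_pooled(g(far[1]), g(far[2])),
        within_inner_50_vs_200 = students_t_pooled(g(near[1]), g(far[1])),
        within_outer_50_vs_200 = students_t_pooled(g(near[2]), g(far[2])))
      stage <- paste0(preset, "/bands")
      bp <- preset_band_profiles(ps, rc$calibration$config,
                                 derive_seed(seed, "bands"),
                                 n_scenes = config$band_scenes %||% 6L)
      drop <- percent_drop(bp$aggregate)
      make_run_report(preset, seed, config, rc, tests,
                      extras = list(percent_drop = drop,
                                    drop_target = ps$drop_target,
                                    n_band_profiles = length(bp$profiles)),
                      out_dir = out_dir)
    } else if (preset == "human_blobs") {
      stage <- "human_blobs"
      ps <- build_preset(preset, cal, config)
      rc <- run_calibrated(ps, seed, keep_scene = TRUE)
      g <- function(gr) group_counts(rc$table, gr)
      tests <- list(
        interblob_center_vs_blob = students_t_pooled(g("interblob_center"),
                                                     g("blob_center")),
        interblob_margin_vs_blob = students_t_pooled(g("interblob_margin"),
                                                     g("blob_center")),
        interblob_center_vs_margin = students_t_pooled(g("interblob_center"),
                                                       g("interblob_margin")))
      stage <- "human_blobs/correlation"
      co <- co_astro_correlation(ps, rc$calibration$config,
                                 derive_seed(seed, "co"),
                                 n_lines = config$co_lines %||% 3L)
      make_run_report(preset, seed, config, rc, tests,
                      extras = list(co_correlation = co), out_dir = out_dir)
    } else {
      stage <- "thickness_4v8"
      run_thickness_experiment(seed, cal, config, out_dir)
    }
  }, error = function(e) {
    stop(sprintf("experiment stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report
}

# CO-transmission vs astrocyte-density correlation along horizontal
# measurement lines across the blob band (one profile per line).
co_astro_correlation <- function(ps, cfg, seed, n_lines = 3L, bin = 25) {
  map <- ps$make_map(derive_seed(seed, "map"))
  ext <- map$extent
  lay <- map$layout
  rs <- numeric(0); details <- list()
  for (k in seq_len(n_lines)) {
    astro <- grow_astrocyte_arbors(map, cfg, derive_seed(seed,
                                                         paste0("co", k)))
    # horizontal "band" spanning the strip: stations are x-bins
    band <- list(band = k, cx = mean(ext[1:2]), cy = 0, nx = 1, ny = 0,
                 tx = 0, ty = 1, width = 500,
                 length = ext[2] - ext[1])
    prof <- band_density_profile(band, astro, step = bin)
    x <- prof$position + mean(ext[1:2])
    # CO transmission: bright (high transmission) between blobs, dark at
    # blobs; smooth profile from the distance to the nearest blob center
    kb <- pmin(pmax(round(x / lay$period + 0.5), 1), lay$n_blobs)
    d <- abs(x - lay$centers[kb])
    co <- 1 - 0.6 * exp(-(d / lay$rx)^2)
    series <- co_density_series(data.frame(position = x, value = co),
                                data.frame(position = x,
                                           density = prof$density))
    r <- pearson_r(series$co, series$astro)
    rs <- c(rs, r$statistic)
    details[[k]] <- list(r = r$statistic, p = r$p_value)
  }
  list(r_values = rs, mean_r = mean(rs), lines = details)
}

# Layers III/IV/V: per-layer calibration; layers III and V counted after
# landmark alignment of their (independently framed) drawings onto the
# layer-IV line matrix; ANOVA on log per-scene septa/core ratios across
# layers.
run_layered_experiment <- function(seed, cal, config, out_dir) {
  layers <- c(layer3 = "barrel_layer3", layer4 = "barrel_layer4",
              layer5 = "barrel_layer5")
  n_pilot <- config$n_pilot %||% 25L
  n_scenes <- config$n_scenes %||% 25L
  ratio_sets <- list(); summaries <- list(); tests <- list()
  align_rms <- numeric(0)
  for (ly in names(layers)) {
    ps <- build_preset(layers[[ly]], cal,
                       utils::modifyList(config, list(n_pilot = n_pilot,
                                                      n_scenes = n_scenes)))
    ps$name <- ly
    calib <- calibrate_preset(ps, derive_seed(seed, ly), n_pilot)
    tabs <- list()
    for (s in seq_len(n_scenes)) {
      sseed <- derive_seed(seed, paste0(ly, "_scene", s))
      map <- ps$make_map(derive_seed(sseed, "map"))
      lines <- ps$place(map)
      astro <- grow_astrocyte_arbors(map, calib$config,
                                     derive_seed(sseed, "astro"))
      if (ly != "layer4") {
        # the off-layer drawing lives in its own frame; align by landmarks
        ext <- map$extent
        lm_ref <- with_seed(derive_seed(sseed, "lm"),
                            cbind(stats::runif(6, ext[1], ext[2]),
                                  stats::runif(6, ext[3], ext[4])))
        tr_true <- with_seed(derive_seed(sseed, "frame"), structure(
          list(rotation = stats::runif(1, -0.15, 0.15),
               translation = stats::runif(2, -300, 300), scale = 1,
               rms = 0), class = "rigid_transform"))
        astro_frame <- apply_transform(tr_true, astro)
        lm_frame <- apply_transform(tr_true, lm_ref) +
          with_seed(derive_seed(sseed, "lmnoise"),
                    matrix(stats::rnorm(12, 0, 1), ncol = 2))
        est <- estimate_landmark_transform(lm_frame, lm_ref)
        align_rms <- c(align_rms, est$rms)
        astro <- apply_transform(est, astro_frame)
      }
      tab <- count_line_crossings(lines, astro)
      tab$group <- tab$class
      tab$scene <- rep(s, nrow(tab))
      tabs[[s]] <- tab
    }
    tab <- do.call(rbind, tabs)
    class(tab) <- c("crossing_table", "data.frame")
    ratio_sets[[ly]] <- septa_core_ratio(tab)$per_scene$ratio
    tests[[paste0(ly, "_septal_vs_core")]] <- students_t_pooled(
      tab$count[tab$group == "septal"], tab$count[tab$group == "core"])
    for (gr in c("septal", "core")) {
      g <- group_summary(tab$count[tab$group == gr])
      summaries[[paste(ly, gr, sep = "_")]] <- data.frame(
        group = paste(ly, gr, sep = "_"), n = g$n, mean = g$mean,
        sem = g$sem, ci_lo = g$ci[1], ci_hi = g$ci[2])
    }
  }
  tests$anova_ratios_across_layers <- anova_log_ratios(ratio_sets)
  rep <- list(preset = "barrel_layer3_5", seed = seed,
              config_echo = utils::modifyList(list(n_pilot = n_pilot,
                                                   n_scenes = n_scenes),
                                              config),
              group_summaries = do.call(rbind, summaries),
              tests = lapply(tests, unclass),
              ratios = lapply(ratio_sets, mean),
              alignment_rms_um = mean(align_rms),
              files = character(0),
              version = as.character(utils::packageVersion("astroborder")))
  class(rep) <- "run_report"
  if (!is.null(out_dir)) rep$files <- write_report_files(rep, NULL, out_dir)
  rep
}

# Section thickness control: same calibrated layer-IV scenes measured at
# full retention (thick sections) and thinned to `retention` (thin
# sections); counts drop ~(1 - retention) while the septa/core ratio is
# invariant.
run_thickness_experiment <- function(seed, cal, config, out_dir) {
  ps <- build_preset("thickness_4v8", cal, config)
  retention <- cal$thickness_4v8$retention %||% 0.65
  calib <- calibrate_preset(ps, seed, ps$n_pilot)
  n_scenes <- ps$n_scenes
  tabs8 <- list(); tabs4 <- list()
  for (s in seq_len(n_scenes)) {
    sseed <- derive_seed(seed, paste0("thick", s))
    map <- ps$make_map(derive_seed(sseed, "map"))
    lines <- ps$place(map)
    astro <- grow_astrocyte_arbors(map, calib$config,
                                   derive_seed(sseed, "astro"))
    thin <- thin_by_section(astro, retention, derive_seed(sseed, "thin"))
    t8 <- count_line_crossings(lines, astro)
    t8$group <- t8$class; t8$scene <- rep(s, nrow(t8))
    t4 <- count_line_crossings(lines, thin)
    t4$group <- t4$class; t4$scene <- rep(s, nrow(t4))
    tabs8[[s]] <- t8; tabs4[[s]] <- t4
  }
  tab8 <- do.call(rbind, tabs8); class(tab8) <- c("crossing_table", "data.frame")
  tab4 <- do.call(rbind, tabs4); class(tab4) <- c("crossing_table", "data.frame")
  r8 <- septa_core_ratio(tab8); r4 <- septa_core_ratio(tab4)
  reduction <- 100 * (1 - mean(tab4$count) / mean(tab8$count))
  tests <- list(ratio_thin_vs_thick = students_t_pooled(
    r4$per_scene$ratio, r8$per_scene$ratio))
  summ <- do.call(rbind, lapply(
    list(thick_septal = tab8$count[tab8$group == "septal"],
         thick_core = tab8$count[tab8$group == "core"],
         thin_septal = tab4$count[tab4$group == "septal"],
         thin_core = tab4$count[tab4$group == "core"]),
    function(v) {
      g <- group_summary(v)
      data.frame(n = g$n, mean = g$mean, sem = g$sem, ci_lo = g$ci[1],
                 ci_hi = g$ci[2])
    }))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  rep <- list(preset = "thickness_4v8", seed = seed,
              config_echo = utils::modifyList(
                list(retention = retention, n_pilot = ps$n_pilot,
                     n_scenes = n_scenes), config),
              group_summaries = summ,
              tests = lapply(tests, unclass),
              ratios = list(thick = r8$ratio, thin = r4$ratio),
              count_reduction_pct = reduction,
              files = character(0),
              version = as.character(utils::packageVersion("astroborder")))
  class(rep) <- "run_report"
  if (!is.null(out_dir)) rep$files <- write_report_files(rep, NULL, out_dir)
  rep
}

make_run_report <- function(preset, seed, config, rc, tests, ratios = NULL,
                            extras = NULL, out_dir = NULL) {
  rep <- list(preset = preset, seed = seed,
              config_echo = utils::modifyList(
                list(n_pilot = rc$calibration$n_pilot,
                     n_scenes = max(rc$table$scene)), config),
              calibration = list(
                targets = as.list(rc$preset$astro_targets),
                pilot_means = as.list(rc$calibration$pilot_means),
                intensity_scale = as.list(rc$calibration$scale),
                capillary_density = as.list(rc$capillary_density %||% list())),
              group_summaries = rc$group_summaries,
              tests = lapply(tests, unclass),
              files = character(0),
              version = as.character(utils::packageVersion("astroborder")))
  if (!is.null(ratios))
    rep$ratios <- lapply(ratios, function(r)
      list(ratio = r$ratio, method = r$method))
  if (!is.null(extras)) rep <- c(rep, extras)
  class(rep) <- "run_report"
  if (!is.null(out_dir)) rep$files <- write_report_files(rep, rc, out_dir)
  rep
}

write_report_files <- function(rep, rc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stem <- file.path(out_dir, rep$preset)
  if (!is.null(rc)) {
    files["crossings"] <- paste0(stem, "_crossings.csv")
    write_crossing_table(rc$table, files["crossings"])
    if (!is.null(rc$last_scene)) {
      files["scene"] <- paste0(stem, "_scene.geojson")
      write_scene_geojson(rc$last_scene, files["scene"])
    }
    if (!is.null(rc$lines)) {
      files["lines"] <- paste0(stem, "_lines.geojson")
      write_lines_geojson(rc$lines, files["lines"])
    }
  }
  if (!is.null(rep$group_summaries)) {
    files["summaries"] <- paste0(stem, "_summaries.csv")
    utils::write.csv(rep$group_summaries, files["summaries"],
                     row.names = FALSE)
  }
  files["report"] <- paste0(stem, "_report.json")
  clean <- rep
  clean$files <- NULL
  jsonlite::write_json(unclass(clean), files["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  files
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %s, seed %d>\n", x$preset, x$seed))
  if (!is.null(x$group_summaries)) {
    cat("group summaries:\n")
    print(x$group_summaries, digits = 4)
  }
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %s: statistic %.4g, p %.3g\n", nm, t$statistic,
                t$p_value))
  }
  invisible(x)
}

# ---- confinement sweep and simulated experiment batteries -------------------

#' Sweep the septa/core ratio against the crossing probability
#'
#' Simulates small barrel scenes over a grid of `p_cross` values and
#' reports the pooled septa/core ratio (grand mean septal count over grand
#' mean core count across replicates; per-scene ratios of means are biased
#' upward by the noisy few-line denominator) with a delta-method standard
#' error over scenes. `mode = "core_only"` places somata in cores only
#' (ratio is exactly 0 at p_cross = 0 and rises monotonically);
#' `mode = "uniform"` uses equal intensity everywhere (exchangeable at
#' p_cross = 1, so the ratio is 1).
#'
#' @param p_grid numeric vector of crossing probabilities in \[0, 1\].
#' @param replicates scenes per grid point.
#' @param seed integer root seed.
#' @param mode `"core_only"` (default) or `"uniform"`.
#' @param rows,arcs barrel map size for the replicate scenes.
#' @return data frame: p_cross, mean_ratio, se, n.
#' @export
sweep_confinement <- function(p_grid = c(0, 0.25, 0.5, 0.75, 1),
                              replicates = 50L, seed = 1L,
                              mode = c("core_only", "uniform"),
                              rows = 2L, arcs = 2L) {
  if (any(p_grid < 0 | p_grid > 1)) stop("p_cross grid must lie in [0, 1]")
  mode <- match.arg(mode)
  cal <- calibration_constants()
  rho_core <- calibrate_generator(cal$barrel_layer4$astro$core,
                                  cal$barrel_layer4$line_length)
  dens <- if (mode == "core_only") c(core = rho_core, septum = 0)
          else c(core = rho_core, septum = rho_core, background = rho_core)
  out <- list()
  for (p in p_grid) {
    cfg <- generator_config(fiber_density = dens, p_cross = p, seed = seed)
    sep_m <- core_m <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sseed <- derive_seed(seed, sprintf("sweep_%g_%d", p, r))
      map <- sample_barrel_map(rows, arcs, core_span = c(380, 440),
                               septum_width = 50, margin = 120, seed = sseed)
      astro <- grow_astrocyte_arbors(map, cfg, sseed)
      lines <- place_septal_and_core_lines(map)
      tab <- count_line_crossings(lines, astro)
      sep_m[r] <- mean(tab$count[tab$class == "septal"])
      core_m[r] <- mean(tab$count[tab$class == "core"])
    }
    ms <- mean(sep_m); mc <- mean(core_m)
    ratio <- ms / mc
    # delta-method s.e. of the ratio of means over replicate scenes,
    # keeping the within-scene covariance
    se <- if (ms > 0) ratio * sqrt(
      stats::var(sep_m) / replicates / ms^2 +
        stats::var(core_m) / replicates / mc^2 -
        2 * stats::cov(sep_m, core_m) / replicates / (ms * mc)) else 0
    out[[length(out) + 1L]] <- data.frame(
      p_cross = p, mean_ratio = ratio, se = se, n = replicates)
    ab_log("sweep p=%.2f: ratio %.3f +- %.3f", p, ratio, se)
  }
  do.call(rbind, out)
}

#' Simulated null experiments (type-I calibration)
#'
#' Under the no-confinement null (`p_cross = 1`, uniform fiber density) the
#' septal and core line populations are exchangeable; each simulated
#' experiment draws `scenes_per_exp` single-septum scenes and runs the
#' pooled t-test on septal vs core counts. Returns the vector of p-values
#' (their rejection rate at alpha = 0.05 calibrates the test's type-I
#' error).
#'
#' @param n_experiments number of simulated experiments.
#' @param scenes_per_exp independent scenes (one septal/core line pair
#'   each) per experiment.
#' @param seed integer root seed.
#' @return numeric vector of two-sided p-values.
#' @export
null_experiments <- function(n_experiments = 500L, scenes_per_exp = 6L,
                             seed = 1L) {
  cal <- calibration_constants()
  rho <- calibrate_generator(cal$barrel_layer4$astro$core,
                             cal$barrel_layer4$line_length)
  cfg <- generator_config(fiber_density = c(core = rho, septum = rho,
                                            background = rho),
                          p_cross = 1, seed = seed)
  pvals <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    sep <- numeric(scenes_per_exp); core <- numeric(scenes_per_exp)
    for (s in seq_len(scenes_per_exp)) {
      sseed <- derive_seed(seed, sprintf("null_%d_%d", e, s))
      # spans drawn above the line length so every scene yields its pair
      map <- sample_barrel_map(1L, 2L, core_span = c(380, 440),
                               septum_width = 50, margin = 120, seed = sseed)
      astro <- grow_astrocyte_arbors(map, cfg, sseed)
      tab <- count_line_crossings(place_septal_and_core_lines(map), astro)
      sep[s] <- tab$count[tab$class == "septal"][1]
      core[s] <- tab$count[tab$class == "core"][1]
    }
    pvals[e] <- students_t_pooled(sep, core)$p_value
  }
  pvals
}

#' Simulated power experiments at the layer-IV calibration
#'
#' Each experiment measures the published sample sizes (146 septal / 154
#' core lines) on freshly generated scenes calibrated to the layer-IV group
#' means and runs the pooled t-test. The fraction with p < 0.001 is the
#' power property standing in for the (unrecoverable) printed t values.
#'
#' @param n_experiments number of simulated experiments.
#' @param seed integer root seed.
#' @param n_septal,n_core per-experiment line counts.
#' @param n_pilot pilot scenes for the one-off calibration.
#' @return numeric vector of p-values.
#' @export
power_experiments <- function(n_experiments = 200L, seed = 1L,
                              n_septal = 146L, n_core = 154L,
                              n_pilot = 30L) {
  ps <- build_preset("barrel_layer4", overrides = list(n_pilot = n_pilot))
  calib <- calibrate_preset(ps, derive_seed(seed, "power_cal"), n_pilot)
  per_scene <- 2L * ps_lines_per_scene(ps)
  scenes_needed <- ceiling(max(n_septal, n_core) / ps_lines_per_scene(ps))
  pvals <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    sep <- numeric(0); core <- numeric(0)
    s <- 0L
    while (length(sep) < n_septal || length(core) < n_core) {
      s <- s + 1L
      sseed <- derive_seed(seed, sprintf("power_%d_%d", e, s))
      map <- ps$make_map(derive_seed(sseed, "map"))
      astro <- grow_astrocyte_arbors(map, calib$config, sseed)
      tab <- count_line_crossings(ps$place(map), astro)
      sep <- c(sep, tab$count[tab$class == "septal"])
      core <- c(core, tab$count[tab$class == "core"])
    }
    pvals[e] <- students_t_pooled(sep[seq_len(n_septal)],
                                  core[seq_len(n_core)])$p_value
  }
  pvals
}

ps_lines_per_scene <- function(ps) {
  # septal lines on an r x a grid: r*(a-1) + (r-1)*a
  r <- environment(ps$make_map)$rows %||% 5L
  a <- environment(ps$make_map)$arcs %||% 5L
  r * (a - 1L) + (r - 1L) * a
}
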