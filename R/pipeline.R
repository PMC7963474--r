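#' Default pipeline configuration
#'
#' All numeric parameters default to the measurement constants of the
#' workflow: 100 nm peak-search window, 5-pixel rolling average,
#' 1000 x 250 nm profile, 0.4-2 um^2 size filter, 3 SD positivity rule,
#' 200 nm ANOVA window. The `simulate` block defines the synthetic
#' experiment (two genotypes; the knockout renders the protein channel at
#' amplitude 0, background only).
#'
#' @return nested list, the full configuration with defaults filled in.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "synappose_run",
    stages = "all",
    genotypes = list(control = "control", ko = "cTKO"),
    simulate = list(
      n_cultures = 2L, scenes_per_culture = 2L, synapses_per_scene = 4L,
      image_size_px = c(256L, 256L), pixel_size_nm = 20,
      offset_mean_nm = 24, offset_sd_nm = 17,
      amp_protein = 100, amp_scaffold = 120, amp_vesicle = 80,
      cloud_radius_nm = 500,
      psf_sted_nm = 50, psf_confocal_nm = 250,
      noise = "poisson+gaussian", read_sigma = 2, distractors = 2L,
      min_separation_nm = 1500),
    segment = list(threshold_method = "otsu", min_area_um2 = 0.4,
                   max_area_um2 = 2, connectivity = 8L,
                   channel = "vesicle"),
    profile = list(roi_source = "truth", roi_csv = NULL, window_nm = 100,
                   smooth_px = 5L, length_nm = 1000, width_nm = 250),
    classify = list(n_sd = 3),
    stats = list(anova_window_nm = 200, alpha = 0.05),
    ephys = list(n_cells = 6L, amplitude_mean_pA = 800,
                 amplitude_cv = 0.3, tau_rise_ms = 1, tau_decay_ms = 10,
                 onset_latency_ms = 2, noise_sigma_pA = 5,
                 intervals_ms = c(25, 50, 100, 200, 400),
                 ppr_true = c(0.7, 0.75, 0.85, 0.9, 0.95)))
}

## deep-merge user config over defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  sg <- cfg$segment
  if (!(sg$min_area_um2 > 0 && sg$min_area_um2 < sg$max_area_um2))
    stop("config error: need 0 < segment$min_area_um2 < segment$max_area_um2")
  if (!sg$connectivity %in% c(4, 8))
    stop("config error: segment$connectivity must be 4 or 8")
  pr <- cfg$profile
  if (pr$window_nm <= 0 || pr$length_nm <= 0 || pr$width_nm <= 0)
    stop("config error: profile window/length/width must be positive")
  if (pr$smooth_px < 1 || pr$smooth_px %% 2 != 1)
    stop("config error: profile$smooth_px must be odd and >= 1")
  if (!pr$roi_source %in% c("truth", "auto", "manual"))
    stop("config error: profile$roi_source must be truth, auto or manual")
  if (pr$roi_source == "manual" && is.null(pr$roi_csv))
    stop("config error: roi_source = 'manual' requires profile$roi_csv")
  if (cfg$simulate$pixel_size_nm <= 0)
    stop("config error: simulate$pixel_size_nm must be positive")
  if (cfg$stats$anova_window_nm <= 0)
    stop("config error: stats$anova_window_nm must be positive")
  ep <- cfg$ephys
  if (!(ep$tau_decay_ms > ep$tau_rise_ms && ep$tau_rise_ms > 0))
    stop("config error: need ephys tau_decay > tau_rise > 0")
  if (length(ep$ppr_true) != length(ep$intervals_ms))
    cfg$ephys$ppr_true <- rep_len(ep$ppr_true, length(ep$intervals_ms))
  if (identical(cfg$stages, "all"))
    cfg$stages <- c("simulate", "segment", "profile", "classify",
                    "stats", "ephys")
  bad <- setdiff(cfg$stages, c("simulate", "segment", "profile",
                               "classify", "stats", "ephys"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg
}

## deterministic scene catalogue for the synthetic experiment
scene_catalogue <- function(cfg) {
  sim <- cfg$simulate
  g <- expand.grid(scene = seq_len(sim$scenes_per_culture),
                   culture = seq_len(sim$n_cultures),
                   genotype = unlist(cfg$genotypes, use.names = FALSE),
                   stringsAsFactors = FALSE)
  g$name <- sprintf("%s_c%d_s%d", g$genotype, g$culture, g$scene)
  g$seed <- cfg$seed + seq_len(nrow(g))
  g
}

## jittered-grid placement: a fixed number of centers with a guaranteed
## minimum separation (deterministic synapse count per scene)
place_centers <- function(n, lo, hi, min_sep) {
  cells <- ceiling(sqrt(n))
  cell <- (hi - lo) / cells
  jit <- max(0, (cell - min_sep)) / 2
  if (cell < min_sep)
    warning("field too small for the requested separation; ",
            "centers placed on a bare grid")
  idx <- utils::head(sample(cells^2), n)
  rowi <- (idx - 1) %/% cells
  coli <- (idx - 1) %% cells
  cbind(lo + (coli + 0.5) * cell + stats::runif(n, -jit, jit),
        lo + (rowi + 0.5) * cell + stats::runif(n, -jit, jit))
}

## build and render one scene of the synthetic experiment
simulate_scene <- function(cfg, genotype, scene_seed) {
  sim <- cfg$simulate
  set.seed(scene_seed)
  px <- sim$pixel_size_nm
  w_nm <- (sim$image_size_px[2] - 1) * px
  h_nm <- (sim$image_size_px[1] - 1) * px
  margin <- cfg$profile$length_nm / 2 + cfg$profile$width_nm / 2 + 3 * px
  centers <- place_centers(sim$synapses_per_scene, margin,
                           min(w_nm, h_nm) - margin, sim$min_separation_nm)
  ko <- genotype == cfg$genotypes$ko
  synapses <- lapply(seq_len(nrow(centers)), function(i) {
    th <- stats::runif(1, 0, pi)
    synapse_truth(
      center_nm = centers[i, ],
      orientation = c(cos(th), sin(th)),
      cloud_side = sample(c(-1L, 1L), 1),
      cloud_radius_nm = sim$cloud_radius_nm,
      true_offset_nm = stats::rnorm(1, sim$offset_mean_nm,
                                    sim$offset_sd_nm),
      amplitudes = c(vesicle = sim$amp_vesicle,
                     scaffold = sim$amp_scaffold,
                     protein = if (ko) 0 else sim$amp_protein))
  })
  chans <- list(
    channel_spec("vesicle", "confocal", sim$psf_confocal_nm),
    channel_spec("scaffold", "sted", sim$psf_sted_nm),
    channel_spec("protein", "sted", sim$psf_sted_nm))
  render_scene(scene_spec(
    image_size_px = sim$image_size_px, pixel_size_nm = px,
    channels = chans, synapses = synapses,
    distractors = sim$distractors, noise = sim$noise,
    read_sigma = sim$read_sigma, seed = scene_seed))
}

## load scenes from a run directory (stage-only runs); NULL when absent
load_scenes <- function(out_dir, catalogue) {
  dir <- file.path(out_dir, "scenes")
  if (!dir.exists(dir)) return(NULL)
  scenes <- list()
  for (i in seq_len(nrow(catalogue))) {
    nm <- catalogue$name[i]
    if (!file.exists(file.path(dir, paste0(nm, "_meta.json")))) return(NULL)
    scenes[[nm]] <- read_scene(dir, nm)
  }
  scenes
}

#' Run the quantification pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic scenes
#' with ground truth), `segment` (puncta detection on the vesicle
#' channel), `profile` (side-view profile extraction, smoothing,
#' apposition measurement, aligned averaging), `classify`
#' (knockout-referenced positivity), `stats` (gated two-sample tests and
#' the profile ANOVA), `ephys` (simulated IPSC traces and their metrics)
#' — writing CSV/JSON outputs and a run manifest into `out_dir`. All
#' randomness derives from the single master seed, so a repeated run with
#' the same configuration is byte-identical. The configuration is
#' validated before any work starts.
#'
#' @param config a nested list (merged over [default_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return invisibly, a list with the output directory, the effective
#'   config, and the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cat_log <- function(...) message("[synappose] ", ...)

  state <- list(catalogue = scene_catalogue(cfg))
  counts <- list()

  if ("simulate" %in% cfg$stages) {
    cat_log("simulate: ", nrow(state$catalogue), " scenes")
    scenes <- list()
    for (i in seq_len(nrow(state$catalogue))) {
      row <- state$catalogue[i, ]
      sc <- simulate_scene(cfg, row$genotype, row$seed)
      sc$truth$genotype <- row$genotype
      sc$truth$culture <- row$culture
      sc$truth$scene <- row$name
      scenes[[row$name]] <- sc
      write_scene(sc, file.path(cfg$out_dir, "scenes"), row$name)
    }
    state$scenes <- scenes
    truth_all <- do.call(rbind, lapply(scenes, `[[`, "truth"))
    utils::write.csv(truth_all, file.path(cfg$out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    counts$simulate <- nrow(truth_all)
  }

  need_scenes <- function(stage) {
    if (is.null(state$scenes))
      state$scenes <<- load_scenes(cfg$out_dir, state$catalogue)
    if (is.null(state$scenes))
      stop("stage '", stage, "' requires scenes: run the 'simulate' ",
           "stage first (or point out_dir at an existing run)")
    state$scenes
  }

  if ("segment" %in% cfg$stages) {
    scenes <- need_scenes("segment")
    sg <- cfg$segment
    params <- segmentation_params(sg$threshold_method, sg$min_area_um2,
                                  sg$max_area_um2, sg$connectivity)
    per_image <- list(); per_punctum <- list()
    for (nm in names(scenes)) {
      sc <- scenes[[nm]]
      tab <- detect_puncta(sc$channels[[sg$channel]], params,
                           sc$pixel_size_nm)
      meta <- state$catalogue[state$catalogue$name == nm, ]
      s <- attr(tab, "summary")
      per_image[[nm]] <- data.frame(scene = nm, genotype = meta$genotype,
                                    culture = meta$culture, s)
      if (nrow(tab) > 0)
        per_punctum[[nm]] <- data.frame(scene = nm,
                                        genotype = meta$genotype,
                                        culture = meta$culture,
                                        as.data.frame(tab))
    }
    state$puncta_summary <- do.call(rbind, per_image)
    rownames(state$puncta_summary) <- NULL
    state$puncta <- if (length(per_punctum) > 0)
      do.call(rbind, per_punctum) else NULL
    utils::write.csv(state$puncta_summary,
                     file.path(cfg$out_dir, "puncta_summary.csv"),
                     row.names = FALSE)
    if (!is.null(state$puncta)) {
      rownames(state$puncta) <- NULL
      utils::write.csv(state$puncta, file.path(cfg$out_dir, "puncta.csv"),
                       row.names = FALSE)
    }
    counts$segment <- sum(state$puncta_summary$count)
    cat_log("segment: ", counts$segment, " puncta across ",
            nrow(state$puncta_summary), " images")
  }

  if ("profile" %in% cfg$stages) {
    scenes <- need_scenes("profile")
    pr <- cfg$profile
    meas_rows <- list(); aligned_rows <- list()
    profiles_by_genotype <- list()
    for (nm in names(scenes)) {
      sc <- scenes[[nm]]
      meta <- state$catalogue[state$catalogue$name == nm, ]
      rois <- switch(pr$roi_source,
        truth = lapply(seq_len(nrow(sc$truth)), function(i)
          roi_from_truth(sc$truth[i, ], pr$length_nm, pr$width_nm)),
        auto = detect_sideview_candidates(
          sc$channels$scaffold, sc$channels$vesicle, sc$pixel_size_nm,
          profile_length_nm = pr$length_nm, profile_width_nm = pr$width_nm),
        manual = {
          all_rois <- read_roi_csv(pr$roi_csv, pr$length_nm, pr$width_nm)
          keep <- attr(all_rois, "meta")$image == nm
          all_rois[keep]
        })
      for (k in seq_along(rois)) {
        prof <- smooth_profile(extract_profile(sc, rois[[k]]),
                               pr$smooth_px)
        m <- measure_apposition(prof, window_nm = pr$window_nm)
        syn_id <- rois[[k]]$id %||% k
        meas_rows[[length(meas_rows) + 1]] <- data.frame(
          scene = nm, genotype = meta$genotype, culture = meta$culture,
          synapse = syn_id, roi_source = rois[[k]]$source,
          scaffold_peak_nm = m$scaffold_peak_nm,
          protein_peak_nm = m$protein_peak_nm,
          protein_peak_intensity = m$protein_peak_intensity,
          distance_nm = m$distance_nm,
          window_truncated = m$window_truncated,
          true_offset_nm = if (pr$roi_source == "truth")
            sc$truth$true_offset_nm[k] else NA_real_)
        profiles_by_genotype[[meta$genotype]] <-
          c(profiles_by_genotype[[meta$genotype]], list(prof))
        shifted_pos <- prof$position_nm - m$scaffold_peak_nm
        for (ch in setdiff(names(prof), "position_nm"))
          aligned_rows[[length(aligned_rows) + 1]] <- data.frame(
            scene = nm, genotype = meta$genotype, culture = meta$culture,
            synapse = syn_id, channel = ch, position_nm = shifted_pos,
            intensity = prof[[ch]])
      }
    }
    if (length(meas_rows) == 0) stop("profile stage found no ROIs")
    state$measurements <- do.call(rbind, meas_rows)
    state$aligned <- do.call(rbind, aligned_rows)
    state$profiles_by_genotype <- profiles_by_genotype
    utils::write.csv(state$measurements,
                     file.path(cfg$out_dir, "sideview_measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(state$aligned,
                     file.path(cfg$out_dir, "aligned_profiles.csv"),
                     row.names = FALSE)
    avg <- lapply(names(profiles_by_genotype), function(g) {
      a <- align_and_average(profiles_by_genotype[[g]])
      data.frame(genotype = g, as.data.frame(a))
    })
    state$average_profiles <- do.call(rbind, avg)
    utils::write.csv(state$average_profiles,
                     file.path(cfg$out_dir, "average_profile.csv"),
                     row.names = FALSE)
    counts$profile <- nrow(state$measurements)
    cat_log("profile: ", counts$profile, " side-view measurements")
  }

  if ("classify" %in% cfg$stages) {
    if (is.null(state$measurements))
      stop("stage 'classify' requires side-view measurements: ",
           "run the 'profile' stage first")
    me <- state$measurements
    ko_lab <- cfg$genotypes$ko
    ko <- me[me$genotype == ko_lab, ]
    ct <- me[me$genotype != ko_lab, ]
    if (nrow(ko) == 0 || nrow(ct) == 0)
      stop("classification needs measurements for both genotypes")
    res <- classify_positive(ct$protein_peak_intensity, ct$culture,
                             ko$protein_peak_intensity, ko$culture,
                             n_sd = cfg$classify$n_sd)
    calls <- data.frame(scene = ct$scene, culture = ct$culture,
                        synapse = ct$synapse, res$calls[, -2])
    utils::write.csv(calls, file.path(cfg$out_dir, "positivity.csv"),
                     row.names = FALSE)
    summ <- data.frame(
      culture = c(res$thresholds$culture, "pooled"),
      threshold = c(res$thresholds$threshold, NA),
      fraction_positive = c(res$fraction_by_culture,
                            res$fraction_positive))
    utils::write.csv(summ,
                     file.path(cfg$out_dir, "positivity_summary.csv"),
                     row.names = FALSE)
    state$positivity <- res
    counts$classify <- nrow(calls)
    cat_log("classify: ", sprintf("%.1f%% positive",
                                  100 * res$fraction_positive))
  }

  if ("stats" %in% cfg$stages) {
    rows <- list()
    add_test <- function(label, a, b) {
      r <- tryCatch(choose_and_run_test(a, b, cfg$stats$alpha),
                    error = function(e) NULL)
      if (is.null(r)) return()
      rows[[length(rows) + 1]] <<- data.frame(
        comparison = label, test_used = r$test_used,
        statistic = r$statistic, p = r$p_value, n1 = r$n1, n2 = r$n2,
        stars = r$stars)
    }
    ko_lab <- cfg$genotypes$ko
    if (!is.null(state$puncta_summary)) {
      ps <- state$puncta_summary
      for (v in c("density_per_100um2", "mean_intensity", "mean_area_um2"))
        add_test(paste0("puncta_", v), ps[[v]][ps$genotype != ko_lab],
                 ps[[v]][ps$genotype == ko_lab])
    }
    if (!is.null(state$measurements)) {
      me <- state$measurements
      add_test("protein_peak_intensity",
               me$protein_peak_intensity[me$genotype != ko_lab],
               me$protein_peak_intensity[me$genotype == ko_lab])
    }
    anova_tab <- NULL
    if (!is.null(state$aligned)) {
      al <- state$aligned[state$aligned$channel == "protein", ]
      al$synapse <- paste(al$scene, al$synapse)
      fit <- profile_anova(al[, c("synapse", "genotype", "position_nm",
                                  "intensity")],
                          cfg$stats$anova_window_nm)
      anova_tab <- data.frame(analysis = "protein_profile_anova",
                              fit$table)
      state$profile_anova <- fit
    }
    state$stats <- if (length(rows) > 0) do.call(rbind, rows) else NULL
    if (!is.null(state$stats))
      utils::write.csv(state$stats, file.path(cfg$out_dir, "stats.csv"),
                       row.names = FALSE)
    if (!is.null(anova_tab))
      utils::write.csv(anova_tab,
                       file.path(cfg$out_dir, "profile_anova.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(tests = state$stats, profile_anova = anova_tab),
      file.path(cfg$out_dir, "stats.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    counts$stats <- length(rows)
    cat_log("stats: ", length(rows), " comparisons",
            if (!is.null(anova_tab)) " + profile ANOVA" else "")
  }

  if ("ephys" %in% cfg$stages) {
    ep <- cfg$ephys
    metr <- list(); pprs <- list()
    cell_idx <- 0
    for (g in unlist(cfg$genotypes, use.names = FALSE)) {
      for (cell in seq_len(ep$n_cells)) {
        cell_idx <- cell_idx + 1
        set.seed(cfg$seed * 1000L + cell_idx)
        amp <- max(stats::rnorm(1, ep$amplitude_mean_pA,
                                ep$amplitude_cv * ep$amplitude_mean_pA),
                   ep$amplitude_mean_pA * 0.1)
        base_par <- list(amplitude = amp, tau_rise = ep$tau_rise_ms,
                         tau_decay = ep$tau_decay_ms,
                         onset_latency = ep$onset_latency_ms,
                         noise_sigma = ep$noise_sigma_pA)
        tr <- generate_ipsc_trace(do.call(ipsc_params,
          c(base_par, list(stimulus_times_ms = 10))))
        m <- measure_ipsc(tr)
        metr[[length(metr) + 1]] <- data.frame(
          genotype = g, cell = cell, amplitude_pA = m$amplitude_pA,
          rise_20_80_ms = m$rise_20_80_ms,
          decay_100_33_ms = m$decay_100_33_ms)
        for (j in seq_along(ep$intervals_ms)) {
          iv <- ep$intervals_ms[j]
          tr2 <- generate_ipsc_trace(do.call(ipsc_params,
            c(base_par, list(stimulus_times_ms = c(10, 10 + iv),
                             ppr_true = ep$ppr_true[j]))))
          p <- suppressWarnings(paired_pulse_ratio(tr2))
          pprs[[length(pprs) + 1]] <- data.frame(
            genotype = g, cell = cell, interval_ms = iv,
            ppr = p$ratio, ppr_true = ep$ppr_true[j])
        }
      }
    }
    state$ipsc_metrics <- do.call(rbind, metr)
    state$ppr <- do.call(rbind, pprs)
    utils::write.csv(state$ipsc_metrics,
                     file.path(cfg$out_dir, "ipsc_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(state$ppr, file.path(cfg$out_dir, "ppr.csv"),
                     row.names = FALSE)
    counts$ephys <- nrow(state$ipsc_metrics)
    cat_log("ephys: ", counts$ephys, " cells, ",
            nrow(state$ppr), " paired-pulse measurements")
  }

  manifest <- list(
    package = "synappose",
    version = as.character(utils::packageVersion("synappose")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg,
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, config = cfg, state = state))
}
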