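#' Pipeline orchestration and command-line interface
#'
#' A single reproducible run: simulate a synthetic cohort, preprocess each
#' recording, compute band power / ERD tables, score sung imitations, run the
#' group statistics, and write a report bundle (CSV tables, a JSON stats
#' report, and a ground-truth-vs-estimate recovery summary). Every output
#' file embeds the configuration hash and master seed; rerunning the same
#' configuration reproduces every CSV byte for byte.
#'
#' @name pipeline_cli
NULL

# seed stream indices for derive_seed(); one block per stage
SEED_STIMULI <- 1L
SEED_COHORT <- 2L
SEED_EEG <- 3L
SEED_SUNG <- 4L
SEED_SCHEDULE <- 5L

#' Default run configuration
#'
#' All knobs of a full run in one serializable list: master seed, cohort and
#' schedule sizes, coupling, synthesis perturbation targets, montage choice,
#' preprocessing thresholds, bands, ROIs, artifact rates and permutation
#' count. The ERD ground truth is the package default ([default_erd_truth])
#' serialized into the configuration.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_participants = 19L,
    n_trials = 120L,
    coupling_rho = 0.49,
    inaccuracy_median = 52,
    inaccuracy_log_sd = 0.35,
    effect_mean = 0.15,
    effect_sd = 0.06,
    noise_scale = 1,
    montage = "roi",            # "roi" (fast) or "full" (64-channel)
    fs = 512,
    audio_sr = 44100,
    perturbation = unclass(perturbation_params()),
    amp_uv = 100, prob_sd = 5, kurt_sd = 5,
    blink_rate_hz = 0.08, spike_prob = 0, spike_uv = 150,
    bands = default_bands(),
    roi = default_roi(),
    erd_truth = as.list(default_erd_truth()),
    n_perm = 10000L,
    write_audio = FALSE
  ), class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [load_config]: a `run_config`; [save_config]: `path`, invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg$seed <- as.integer(cfg$seed)
  cfg$bands <- lapply(cfg$bands, as.numeric)
  cfg$roi <- lapply(cfg$roi, as.character)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' MD5 hash of a configuration
#'
#' Hash of the canonical YAML serialization; recorded in every output file
#' so tables can be traced back to the exact configuration that produced
#' them.
#'
#' @param cfg a `run_config`.
#' @return 32-character hash string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

cfg_erd_truth <- function(cfg) {
  tr <- as.data.frame(cfg$erd_truth, stringsAsFactors = FALSE)
  class(tr) <- c("erd_truth", "data.frame")
  validate_erd_truth(tr)
  tr
}

cfg_montage <- function(cfg) {
  switch(cfg$montage,
         roi = roi_montage(cfg$roi),
         full = default_montage(),
         stop("unknown montage choice: ", cfg$montage))
}

# write a data.frame as CSV with provenance comment lines; deterministic
write_csv_stamped <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# config_hash: ", config_hash(cfg)),
               paste0("# seed: ", cfg$seed)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# -- stage helpers -----------------------------------------------------------

pl_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %s (%.1f s)", stage, msg,
                  as.numeric(proc.time()[3] - state$t0))
  state$log <- c(state$log, line)
  if (!state$quiet) message(line)
  state
}

pl_schedule <- function(cfg) {
  make_schedule(n_trials = cfg$n_trials,
                rng_seed = derive_seed(cfg$seed, SEED_SCHEDULE))
}

pl_cohort <- function(cfg) {
  make_cohort(n_participants = cfg$n_participants,
              rng_seed = derive_seed(cfg$seed, SEED_COHORT),
              coupling_rho = cfg$coupling_rho,
              erd = cfg_erd_truth(cfg),
              inaccuracy_median = cfg$inaccuracy_median,
              inaccuracy_log_sd = cfg$inaccuracy_log_sd,
              effect_mean = cfg$effect_mean, effect_sd = cfg$effect_sd,
              noise_scale = cfg$noise_scale)
}

# stimuli shared by the whole cohort: melody i is presented on trial i, in
# the timbre of that trial's condition
pl_stimuli <- function(cfg, schedule) {
  p <- do.call(perturbation_params, cfg$perturbation)
  melodies <- lapply(seq_len(cfg$n_trials), function(i)
    generate_melody(derive_seed(cfg$seed, SEED_STIMULI, i), "female",
                    id = sprintf("mel_%03d", i)))
  clips <- lapply(seq_len(cfg$n_trials), function(i) {
    if (schedule$condition[i] == "vocal")
      synth_vocal_like(melodies[[i]], p,
                       rng_seed = derive_seed(cfg$seed, SEED_STIMULI, i, 1L),
                       sr = cfg$audio_sr)
    else synth_triangle(melodies[[i]], sr = cfg$audio_sr)
  })
  clips <- normalize_intensity(clips)
  descriptors <- do.call(rbind, lapply(seq_along(clips), function(i) {
    js <- jitter_shimmer(clips[[i]])
    data.frame(stimulus = i, condition = schedule$condition[i],
               jitter_pct = mean(js$jitter_pct),
               shimmer_pct = mean(js$shimmer_pct),
               f0_sd_cents = mean(js$f0_sd_cents),
               median_dur_s = stats::median(js$duration_s))
  }))
  list(melodies = melodies, clips = clips, descriptors = descriptors)
}

pl_simulate_one <- function(cfg, profile, schedule, p_index) {
  simulate_eeg(profile, schedule, cfg_montage(cfg),
               erd = cfg_erd_truth(cfg),
               rng_seed = derive_seed(cfg$seed, SEED_EEG, p_index),
               fs = cfg$fs, roi = cfg$roi,
               artifacts = list(blink_rate_hz = cfg$blink_rate_hz,
                                spike_prob = cfg$spike_prob,
                                spike_uv = cfg$spike_uv))
}

# preprocess + band power + EMG for one recording; returns tidy tables and
# the per-trial fronto-central effect-window ERD used by the stimulus
# feature regression
pl_analyze_one <- function(cfg, rec, participant_id) {
  pp <- preprocess(rec, amp_uv = cfg$amp_uv, prob_sd = cfg$prob_sd,
                   kurt_sd = cfg$kurt_sd)
  bp_perc <- erd(pp$perception, roi = cfg$roi, bands = cfg$bands)
  bp_prod <- erd(pp$production, roi = cfg$roi, bands = cfg$bands)
  emg <- rbind(
    cbind(phase = "perception", emg_band_power(pp$perception)),
    cbind(phase = "production", emg_band_power(pp$production)))
  fc_el <- unique(c(cfg$roi$FC_L, cfg$roi$FC_R))
  per <- attr(bp_perc, "per_trial")
  kept_idx <- pp$perception$mask$trial_index[pp$perception$mask$kept]
  fc_effect <- do.call(rbind, lapply(names(cfg$bands), function(b) {
    v <- per[, fc_el, b, "effect", drop = FALSE]
    dim(v) <- c(dim(per)[1], length(fc_el))
    data.frame(trial = kept_idx, band = b, fc_erd_effect = rowMeans(v))
  }))
  onset <- do.call(rbind, lapply(names(cfg$bands), function(b)
    data.frame(band = b,
               onset_vocal_s = erd_onset(bp_perc, b, c("FC_L", "FC_R"),
                                         "vocal"),
               onset_nonvocal_s = erd_onset(bp_perc, b, c("FC_L", "FC_R"),
                                            "nonvocal"),
               depth_vocal = erd_depth(bp_perc, b, c("FC_L", "FC_R"),
                                       "vocal", "w1", "w3"),
               depth_nonvocal = erd_depth(bp_perc, b, c("FC_L", "FC_R"),
                                          "nonvocal", "w1", "w5"))))
  tidy <- function(bp, phase) {
    df <- as.data.frame(bp)
    cbind(participant = participant_id, phase = phase, df)
  }
  list(
    band_power = rbind(tidy(bp_perc, "perception"),
                       tidy(bp_prod, "production")),
    emg = cbind(participant = participant_id, emg),
    fc_effect = cbind(participant = participant_id, fc_effect),
    onset = cbind(participant = participant_id, onset),
    counts = data.frame(
      participant = participant_id,
      perception_kept = sum(pp$perception$mask$kept),
      perception_total = nrow(pp$perception$mask),
      production_kept = sum(pp$production$mask$kept),
      production_total = nrow(pp$production$mask))
  )
}

pl_score_one <- function(cfg, profile, melodies, schedule, p_index) {
  scores <- lapply(seq_along(melodies), function(i) {
    tr <- simulate_sung_response(
      profile, melodies[[i]],
      rng_seed = derive_seed(cfg$seed, SEED_SUNG, p_index, i))
    score_accuracy(tr, melodies[[i]])
  })
  agg <- aggregate_accuracy(scores, schedule$condition)
  all_dev <- unlist(lapply(scores, function(s) s$deviations))
  cbind(participant = profile$id,
        rbind(agg, data.frame(condition = "all",
                              mean_abs_dev_cents = mean(all_dev),
                              n_intervals = length(all_dev),
                              n_excluded = sum(vapply(scores, function(s)
                                s$excluded, logical(1))))))
}

# -- statistics on the assembled tables --------------------------------------

anova_to_list <- function(fit) {
  lapply(seq_len(nrow(fit)), function(i) as.list(as.data.frame(fit)[i, ]))
}

complete_participants <- function(df, dv = "erd") {
  bad <- unique(df$participant[is.na(df[[dv]])])
  list(data = df[!(df$participant %in% bad), , drop = FALSE], dropped = bad)
}

pl_stats <- function(cfg, band_power, accuracy, emg, descriptors = NULL,
                     fc_effect = NULL) {
  out <- list()
  notes <- character(0)
  perc <- band_power[band_power$phase == "perception" &
                       band_power$condition %in% c("vocal", "nonvocal"), ]
  info <- roi_region_info(perc$region)
  perc$gradient <- info$gradient
  perc$side <- info$side

  # three-way Humanness (condition) x Anteroposterior gradient x Side ANOVA
  # on the main perception window, per band
  for (b in names(cfg$bands)) {
    d <- perc[perc$band == b & perc$window == "main", ]
    cp <- complete_participants(d)
    if (length(cp$dropped))
      notes <- c(notes, paste0("perception ANOVA (", b, "): dropped ",
                               paste(cp$dropped, collapse = ", "),
                               " (empty cells after rejection)"))
    fit <- rm_anova(cp$data, "erd", "participant",
                    c("condition", "gradient", "side"))
    out$perception_anova[[b]] <- anova_to_list(fit)
    out$perception_posthoc[[b]] <- posthoc(fit, c("condition", "gradient"),
                                           "tukey_hsd")
  }

  # fronto-central time course: Humanness x Window ANOVA + Fisher LSD
  for (b in names(cfg$bands)) {
    d <- perc[perc$band == b & perc$window %in% paste0("w", 1:5) &
                perc$gradient == "FC", ]
    d <- stats::aggregate(erd ~ participant + condition + window, d, mean,
                          na.action = stats::na.pass)
    cp <- complete_participants(d)
    fit <- rm_anova(cp$data, "erd", "participant", c("condition", "window"))
    out$timecourse_anova[[b]] <- anova_to_list(fit)
    out$timecourse_lsd[[b]] <- posthoc(fit, c("condition", "window"),
                                       "fisher_lsd")
  }

  # production: gradient x side ANOVA per band
  prod <- band_power[band_power$phase == "production" &
                       band_power$window == "main", ]
  pinfo <- roi_region_info(prod$region)
  prod$gradient <- pinfo$gradient
  prod$side <- pinfo$side
  for (b in names(cfg$bands)) {
    # production is analyzed irrespective of the preceding stimulus timbre
    d <- stats::aggregate(erd ~ participant + gradient + side,
                          prod[prod$band == b, ], mean,
                          na.action = stats::na.pass)
    cp <- complete_participants(d)
    fit <- rm_anova(cp$data, "erd", "participant", c("gradient", "side"))
    out$production_anova[[b]] <- anova_to_list(fit)
  }

  # imitation accuracy: vocal vs non-vocal Wilcoxon
  acc_w <- stats::reshape(
    accuracy[accuracy$condition %in% c("vocal", "nonvocal"),
             c("participant", "condition", "mean_abs_dev_cents")],
    direction = "wide", idvar = "participant", timevar = "condition")
  if (nrow(acc_w) >= 5) {
    out$accuracy_wilcoxon <- wilcoxon_paired(
      acc_w$mean_abs_dev_cents.vocal, acc_w$mean_abs_dev_cents.nonvocal)
  } else {
    notes <- c(notes, "accuracy Wilcoxon skipped: fewer than 5 participants")
  }
  out$accuracy_means <- list(
    vocal = mean(acc_w$mean_abs_dev_cents.vocal),
    nonvocal = mean(acc_w$mean_abs_dev_cents.nonvocal))

  # inaccuracy vs fronto-central beta humanness effect (effect window)
  fc <- perc[perc$band == "beta" & perc$window == "effect" &
               perc$gradient == "FC", ]
  fc <- stats::aggregate(erd ~ participant + condition, fc, mean)
  fc_w <- stats::reshape(fc, direction = "wide", idvar = "participant",
                         timevar = "condition")
  eff <- fc_w$erd.nonvocal - fc_w$erd.vocal   # positive = deeper vocal ERD
  inacc <- accuracy$mean_abs_dev_cents[accuracy$condition == "all"]
  inacc <- inacc[match(fc_w$participant,
                       accuracy$participant[accuracy$condition == "all"])]
  ok <- stats::complete.cases(eff, inacc)
  out$accuracy_effect_spearman <- spearman_perm(
    inacc[ok], eff[ok], n_perm = cfg$n_perm,
    rng_seed = derive_seed(cfg$seed, 6L))

  # EMG: production vs perception band power, paired t-test
  emg_mean <- stats::aggregate(power ~ participant + phase, emg, mean)
  emg_w <- stats::reshape(emg_mean, direction = "wide", idvar = "participant",
                          timevar = "phase")
  tt <- stats::t.test(emg_w$power.production, emg_w$power.perception,
                      paired = TRUE)
  out$emg_ttest <- list(t = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value,
                        mean_production = mean(emg_w$power.production),
                        mean_perception = mean(emg_w$power.perception))

  # stimulus-feature multiple regression (per band), if per-trial fronto-
  # central effect-window ERD and stimulus descriptors are available
  if (!is.null(descriptors) && !is.null(fc_effect)) {
    for (b in names(cfg$bands)) {
      fe <- fc_effect[fc_effect$band == b, ]
      resp <- stats::aggregate(fc_erd_effect ~ trial, fe, mean)
      idx <- match(resp$trial, descriptors$stimulus)
      des <- descriptors[idx, c("jitter_pct", "shimmer_pct", "f0_sd_cents",
                                "median_dur_s")]
      fr <- feature_regression(des, resp$fc_erd_effect)
      fr$coefficients <- NULL
      out$feature_regression[[b]] <- fr
    }
  }
  out$notes <- notes
  out
}

pl_recovery <- function(cfg, onset, truth) {
  rows <- lapply(names(cfg$bands), function(b) {
    o <- onset[onset$band == b, ]
    tv <- truth[truth$band == b & truth$gradient == "FC", ]
    dv <- tv$depth[tv$condition == "vocal"]
    dn <- tv$depth[tv$condition == "nonvocal"]
    if (b == "beta") dv <- dv + cfg$effect_mean
    data.frame(
      band = b,
      onset_vocal_mean_s = mean(o$onset_vocal_s[is.finite(o$onset_vocal_s)]),
      onset_nonvocal_mean_s =
        mean(o$onset_nonvocal_s[is.finite(o$onset_nonvocal_s)]),
      prop_vocal_earlier = mean(o$onset_vocal_s < o$onset_nonvocal_s),
      true_onset_vocal_s = tv$onset_s[tv$condition == "vocal"],
      true_onset_nonvocal_s = tv$onset_s[tv$condition == "nonvocal"],
      depth_vocal_mean = mean(o$depth_vocal),
      expected_drop_vocal = 1 - (1 - dv)^2,
      depth_nonvocal_mean = mean(o$depth_nonvocal),
      expected_drop_nonvocal = 1 - (1 - dn)^2)
  })
  do.call(rbind, rows)
}

# -- full run -----------------------------------------------------------------

#' Run the complete pipeline
#'
#' Simulation, preprocessing, spectral analysis, imitation scoring,
#' statistics and recovery summary, written to `out_dir`:
#' `config.yaml`, `cohort.csv` (simulated ground-truth profiles),
#' `stimuli.csv` (acoustic descriptors), `band_power.csv`, `accuracy.csv`,
#' `emg.csv`, `epoch_counts.csv`, `recovery.csv`, `stats.json` and
#' `run_log.txt`. Deterministic: the same configuration reproduces every
#' CSV byte for byte (the log contains wall-clock timings and is exempt).
#'
#' @param cfg a `run_config` (default [default_config]).
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages (default FALSE).
#' @return invisibly, a list with all assembled tables and the stats report.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$n_participants < 6)
    warning("fewer than 6 participants: group statistics will be unstable")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(t0 = proc.time()[3], log = character(0), quiet = quiet)
  save_config(cfg, file.path(out_dir, "config.yaml"))
  hash <- config_hash(cfg)
  state <- pl_log(state, "config", paste0("hash ", hash))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(state$log, paste0("[", stage, "] FAILED: ",
                                     conditionMessage(e))),
                 file.path(out_dir, "run_log.txt"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  schedule <- pl_schedule(cfg)
  cohort <- run_stage("cohort", pl_cohort(cfg))
  write_csv_stamped(as.data.frame(cohort), file.path(out_dir, "cohort.csv"),
                    cfg)
  state <- pl_log(state, "cohort",
                  paste0(nrow(cohort), " participants, ",
                         nrow(schedule), " trials"))

  stim <- run_stage("stimuli", pl_stimuli(cfg, schedule))
  write_csv_stamped(stim$descriptors, file.path(out_dir, "stimuli.csv"), cfg)
  if (isTRUE(cfg$write_audio)) {
    adir <- file.path(out_dir, "audio")
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_along(stim$clips))
      write_wav(stim$clips[[i]],
                file.path(adir, sprintf("stim_%03d.wav", i)))
  }
  state <- pl_log(state, "stimuli",
                  paste0(length(stim$clips), " clips synthesized"))

  res <- vector("list", nrow(cohort))
  for (p in seq_len(nrow(cohort))) {
    rec <- run_stage("simulate", pl_simulate_one(cfg, cohort[p, ],
                                                 schedule, p))
    res[[p]] <- run_stage("erd", pl_analyze_one(cfg, rec, cohort$id[p]))
    state <- pl_log(state, "eeg", sprintf(
      "%s: %d/%d perception, %d/%d production epochs kept", cohort$id[p],
      res[[p]]$counts$perception_kept, res[[p]]$counts$perception_total,
      res[[p]]$counts$production_kept, res[[p]]$counts$production_total))
  }
  band_power <- do.call(rbind, lapply(res, `[[`, "band_power"))
  emg <- do.call(rbind, lapply(res, `[[`, "emg"))
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  fc_effect <- do.call(rbind, lapply(res, `[[`, "fc_effect"))
  onset <- do.call(rbind, lapply(res, `[[`, "onset"))
  write_csv_stamped(band_power, file.path(out_dir, "band_power.csv"), cfg)
  write_csv_stamped(emg, file.path(out_dir, "emg.csv"), cfg)
  write_csv_stamped(counts, file.path(out_dir, "epoch_counts.csv"), cfg)

  accuracy <- run_stage("score", do.call(rbind, lapply(
    seq_len(nrow(cohort)), function(p)
      pl_score_one(cfg, cohort[p, ], stim$melodies, schedule, p))))
  write_csv_stamped(accuracy, file.path(out_dir, "accuracy.csv"), cfg)
  state <- pl_log(state, "score", paste0(
    sum(accuracy$n_intervals[accuracy$condition == "all"]),
    " intervals scored"))

  stats_report <- run_stage("stats", pl_stats(cfg, band_power, accuracy,
                                              emg, stim$descriptors,
                                              fc_effect))
  recovery <- pl_recovery(cfg, onset, cfg_erd_truth(cfg))
  write_csv_stamped(recovery, file.path(out_dir, "recovery.csv"), cfg)
  report <- c(list(config_hash = hash, seed = cfg$seed), stats_report)
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state <- pl_log(state, "stats", "report written")
  writeLines(state$log, file.path(out_dir, "run_log.txt"))

  invisible(list(config = cfg, cohort = cohort, schedule = schedule,
                 stimuli = stim$descriptors, band_power = band_power,
                 accuracy = accuracy, emg = emg, counts = counts,
                 recovery = recovery, stats = report, log = state$log))
}

#' @rdname run_pipeline
#' @export
run_all <- run_pipeline

# -- command-line interface ---------------------------------------------------

#' Command-line entry point
#'
#' Dispatches the subcommands `run`, `simulate`, `preproc`, `erd`, `score`
#' and `stats`. `run` executes the whole pipeline; the other subcommands
#' operate on the files a previous stage wrote (EDF recordings with event
#' sidecars, sung-response CSVs, tidy band-power/accuracy tables), so stages
#' can be rerun individually. Invoked by the installed `erdvoice.R` script:
#' `Rscript erdvoice.R run --config cfg.yaml --out DIR`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `c("run", "--out", "results")`.
#' @return 0 on success, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: erdvoice.R <run|simulate|preproc|erd|score|stats> ",
         "[--config cfg.yaml] [--in DIR] [--out DIR]")
  sub <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--in", type = "character", default = NULL,
                            dest = "input"),
      optparse::make_option("--out", type = "character", default = "."))),
    args = args[-1])
  cfg <- if (is.null(opts$config)) default_config() else
    load_config(opts$config)
  input <- opts$input %||% opts$out
  switch(sub,
    run = run_pipeline(cfg, opts$out),
    simulate = cli_simulate(cfg, opts$out),
    preproc = cli_preproc(cfg, input, opts$out),
    erd = cli_erd(cfg, input, opts$out),
    score = cli_score(cfg, input, opts$out),
    stats = cli_stats(cfg, input, opts$out),
    stop("unknown subcommand: ", sub))
  invisible(0L)
}

# write per-participant EDF recordings, sung-response tracks and the shared
# cohort/schedule/stimulus tables
cli_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(cfg, file.path(out_dir, "config.yaml"))
  schedule <- pl_schedule(cfg)
  cohort <- pl_cohort(cfg)
  write_csv_stamped(as.data.frame(cohort), file.path(out_dir, "cohort.csv"),
                    cfg)
  write_csv_stamped(as.data.frame(schedule),
                    file.path(out_dir, "schedule.csv"), cfg)
  stim <- pl_stimuli(cfg, schedule)
  write_csv_stamped(stim$descriptors, file.path(out_dir, "stimuli.csv"), cfg)
  for (p in seq_len(nrow(cohort))) {
    rec <- pl_simulate_one(cfg, cohort[p, ], schedule, p)
    write_edf(rec, file.path(out_dir, sprintf("%s.edf", cohort$id[p])))
    sung <- do.call(rbind, lapply(seq_along(stim$melodies), function(i) {
      tr <- simulate_sung_response(
        cohort[p, ], stim$melodies[[i]],
        rng_seed = derive_seed(cfg$seed, SEED_SUNG, p, i))
      med <- note_median_f0(tr)
      data.frame(participant = cohort$id[p], trial = i,
                 note_index = seq_along(med), f0_hz = med,
                 target_semitone = stim$melodies[[i]]$pitches)
    }))
    write_csv_stamped(sung,
                      file.path(out_dir, sprintf("sung_%s.csv",
                                                 cohort$id[p])), cfg)
  }
  invisible(out_dir)
}

cli_edf_files <- function(in_dir) {
  files <- sort(list.files(in_dir, pattern = "^P[0-9]+\\.edf$",
                           full.names = TRUE))
  if (!length(files)) stop("no participant EDF files found in ", in_dir)
  files
}

cli_preproc <- function(cfg, in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mont <- cfg_montage(cfg)
  rows <- lapply(cli_edf_files(in_dir), function(f) {
    rec <- read_edf(f, channels = mont)
    pp <- preprocess(rec, amp_uv = cfg$amp_uv, prob_sd = cfg$prob_sd,
                     kurt_sd = cfg$kurt_sd)
    data.frame(participant = sub("\\.edf$", "", basename(f)),
               perception_kept = sum(pp$perception$mask$kept),
               perception_total = nrow(pp$perception$mask),
               production_kept = sum(pp$production$mask$kept),
               production_total = nrow(pp$production$mask))
  })
  write_csv_stamped(do.call(rbind, rows),
                    file.path(out_dir, "epoch_counts.csv"), cfg)
  invisible(out_dir)
}

cli_erd <- function(cfg, in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mont <- cfg_montage(cfg)
  res <- lapply(cli_edf_files(in_dir), function(f) {
    rec <- read_edf(f, channels = mont)
    pl_analyze_one(cfg, rec, sub("\\.edf$", "", basename(f)))
  })
  write_csv_stamped(do.call(rbind, lapply(res, `[[`, "band_power")),
                    file.path(out_dir, "band_power.csv"), cfg)
  write_csv_stamped(do.call(rbind, lapply(res, `[[`, "emg")),
                    file.path(out_dir, "emg.csv"), cfg)
  write_csv_stamped(do.call(rbind, lapply(res, `[[`, "counts")),
                    file.path(out_dir, "epoch_counts.csv"), cfg)
  write_csv_stamped(do.call(rbind, lapply(res, `[[`, "onset")),
                    file.path(out_dir, "onset.csv"), cfg)
  invisible(out_dir)
}

cli_score <- function(cfg, in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- pl_schedule(cfg)
  melodies <- lapply(seq_len(cfg$n_trials), function(i)
    generate_melody(derive_seed(cfg$seed, SEED_STIMULI, i), "female",
                    id = sprintf("mel_%03d", i)))
  files <- sort(list.files(in_dir, pattern = "^sung_P[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no sung-response CSV files found in ", in_dir)
  accuracy <- do.call(rbind, lapply(files, function(f) {
    sung <- read_csv_stamped(f)
    scores <- lapply(seq_len(cfg$n_trials), function(i) {
      s <- sung[sung$trial == i, ]
      tr <- f0_track_from_notes(s$f0_hz, note_dur = 0.75)
      score_accuracy(tr, melodies[[i]])
    })
    agg <- aggregate_accuracy(scores, schedule$condition)
    all_dev <- unlist(lapply(scores, function(s) s$deviations))
    cbind(participant = sung$participant[1],
          rbind(agg, data.frame(condition = "all",
                                mean_abs_dev_cents = mean(all_dev),
                                n_intervals = length(all_dev),
                                n_excluded = sum(vapply(scores, function(s)
                                  s$excluded, logical(1))))))
  }))
  write_csv_stamped(accuracy, file.path(out_dir, "accuracy.csv"), cfg)
  invisible(out_dir)
}

cli_stats <- function(cfg, in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  band_power <- read_csv_stamped(file.path(in_dir, "band_power.csv"))
  accuracy <- read_csv_stamped(file.path(in_dir, "accuracy.csv"))
  emg <- read_csv_stamped(file.path(in_dir, "emg.csv"))
  report <- c(list(config_hash = config_hash(cfg), seed = cfg$seed),
              pl_stats(cfg, band_power, accuracy, emg))
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  onset_f <- file.path(in_dir, "onset.csv")
  if (file.exists(onset_f)) {
    recovery <- pl_recovery(cfg, read_csv_stamped(onset_f),
                            cfg_erd_truth(cfg))
    write_csv_stamped(recovery, file.path(out_dir, "recovery.csv"), cfg)
  }
  invisible(out_dir)
}
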