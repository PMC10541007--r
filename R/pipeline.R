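# End-to-end session orchestration and the paired syllable-feature
# statistics used to compare stimulation-induced with female-induced USVs.

#' Paired per-animal comparison of syllable features
#'
#' Compares the per-animal mean duration, mean frequency and bandwidth of
#' syllables between two conditions (e.g. stimulation-induced vs
#' female-induced) with a paired two-sided Student's t test per feature.
#' Inputs must cover the same animals. If the per-animal differences have
#' zero variance the t statistic is undefined: identical inputs are
#' reported as `t = 0, p = 1` by convention, a constant nonzero difference
#' is flagged `degenerate`.
#'
#' @param features_a,features_b data.frames with one row per animal:
#'   `animal` plus numeric feature columns (default `duration_ms`,
#'   `mean_freq_khz`, `bandwidth_khz`).
#' @param features character vector of feature column names to compare.
#' @return data.frame: `feature`, `t`, `df`, `p`, `mean_diff`,
#'   `degenerate`.
#' @export
compare_feature_sets <- function(features_a, features_b,
                                 features = c("duration_ms", "mean_freq_khz",
                                              "bandwidth_khz")) {
  if (!setequal(features_a$animal, features_b$animal))
    stop("the two feature sets must cover the same animals")
  if (nrow(features_a) < 2L) stop("need at least 2 animals for a paired test")
  b <- features_b[match(features_a$animal, features_b$animal), , drop = FALSE]
  out <- lapply(features, function(f) {
    d <- features_a[[f]] - b[[f]]
    if (sd(d) == 0) {
      if (all(d == 0)) {
        data.frame(feature = f, t = 0, df = length(d) - 1L, p = 1,
                   mean_diff = 0, degenerate = FALSE)
      } else {
        data.frame(feature = f, t = NA_real_, df = length(d) - 1L,
                   p = NA_real_, mean_diff = mean(d), degenerate = TRUE)
      }
    } else {
      tt <- t.test(features_a[[f]], b[[f]], paired = TRUE)
      data.frame(feature = f, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_diff = unname(tt$estimate), degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}

write_csv_quiet <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run a full synthetic session end to end
#'
#' Generates a synthetic courtship session, segments the audio, runs the
#' photometry and spike-train analyses that the configuration enables, and
#' writes all artifacts (CSV tables, summary JSON, config snapshot with
#' hash and seed registry) to `out_dir`. Stages for disabled modalities
#' are skipped.
#'
#' @param config nested list (or path to a YAML file) with sections:
#'   `synth` (arguments of [synth_config()]), optional `photometry`
#'   (`lead_s`, `amp`, `noise_sd`, `fs`, `n_perm`), optional `ephys`
#'   (`n_units`, `class`, `baseline_hz`, `amp_hz`, `gain`, `n_perm`),
#'   optional `conditioning` (arguments of [conditioning_config()]).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage seeds are derived from it.
#' @param write_audio if `TRUE`, also write the synthesized waveform as
#'   `audio.wav` (float32).
#' @return invisibly, a list describing the bundle: file paths, the config
#'   snapshot, the seed registry and per-stage counts.
#' @export
run_session <- function(config, out_dir, seed = 1L, write_audio = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(synth = seed, photometry = seed + 1000L,
                ephys = seed + 2000L, conditioning = seed + 3000L)
  log_lines <- character(0)
  log_stage <- function(...) {
    msg <- sprintf(...)
    message("[songpeth] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  scfg <- do.call(synth_config, c(config$synth, list(seed = seeds$synth)))
  ses <- synth_usv_audio(scfg)
  log_stage("synth: %d SEs, %d songs, %d syllables",
            nrow(ses$truth$se), nrow(ses$truth$songs),
            nrow(ses$truth$syllables))
  files <- list()
  files$se_events <- write_csv_quiet(ses$truth$se,
                                     file.path(out_dir, "se_events.csv"))
  files$songs_truth <- write_csv_quiet(ses$truth$songs,
                                       file.path(out_dir, "songs_truth.csv"))
  files$syllables_truth <- write_csv_quiet(
    ses$truth$syllables, file.path(out_dir, "syllables_truth.csv"))
  if (write_audio) {
    files$audio <- write_wav(ses$waveform / max(abs(ses$waveform)), ses$fs,
                             file.path(out_dir, "audio.wav"), "float32")
  }

  seg <- segment_usv(ses$waveform, ses$fs)
  log_stage("segment: %d syllables in %d songs",
            nrow(seg$syllables), nrow(seg$songs))
  syl_out <- seg$syllables
  syl_out$mean_freq_khz <- syl_out$mean_freq_hz / 1000
  syl_out$bandwidth_khz <- syl_out$bandwidth_hz / 1000
  files$syllables <- write_csv_quiet(
    syl_out[, c("start_s", "end_s", "duration_ms", "mean_freq_khz",
                "bandwidth_khz", "song_id")],
    file.path(out_dir, "syllables.csv"))
  files$songs <- write_csv_quiet(seg$songs, file.path(out_dir, "songs.csv"))

  summary <- list(n_se = nrow(ses$truth$se),
                  n_songs_truth = nrow(ses$truth$songs),
                  n_syllables_truth = nrow(ses$truth$syllables),
                  n_syllables_detected = nrow(seg$syllables),
                  n_songs_detected = nrow(seg$songs))

  if (!is.null(config$photometry) && nrow(seg$songs) > 0L) {
    p <- config$photometry
    fs <- p$fs %||% 1000
    raw <- synth_photometry(ses$truth, fs = fs,
                            lead_s = p$lead_s %||% 2.3,
                            amp = p$amp %||% 0.5,
                            noise_sd = p$noise_sd %||% 0.02,
                            duration_s = scfg$duration_s,
                            seed = seeds$photometry)
    ph <- photometry_session(raw, fs, seg$songs$onset_s,
                             n_perm = p$n_perm %||% 1000,
                             search_s = c(-(p$lead_s %||% 2.3) - 2, 2),
                             seed = seeds$photometry)
    files$triggered_average <- write_csv_quiet(
      data.frame(t = ph$avg$t, mean = ph$avg$mean,
                 null_mean = ph$avg$null_mean, null_sd = ph$avg$null_sd),
      file.path(out_dir, "triggered_average.csv"))
    summary$photometry <- list(p_value = ph$avg$p_value,
                               onset_s = ph$onset_s,
                               n_events = ph$avg$n_events)
    log_stage("photometry: p = %.4g, onset = %.2f s, %d events",
              ph$avg$p_value, ph$onset_s, ph$avg$n_events)
  }

  if (!is.null(config$ephys)) {
    e <- config$ephys
    units <- synth_units(e$n_units %||% 8L, class = e$class %||% "SE",
                         baseline_hz = e$baseline_hz %||% 5,
                         amp_hz = e$amp_hz %||% 10, gain = e$gain %||% 1)
    spikes <- synth_spikes(ses$truth, units, scfg$duration_s,
                           seed = seeds$ephys)
    files$spikes <- write_csv_quiet(spikes, file.path(out_dir, "spikes.csv"))
    files$units <- write_csv_quiet(units, file.path(out_dir, "units.csv"))

    cats <- lapply(seq_len(nrow(units)), function(k) {
      st <- spikes$time_s[spikes$unit_id == units$unit_id[k]]
      song_p <- responsiveness_test(st, seg$songs$onset_s,
                                    span = c(0, scfg$duration_s),
                                    n_perm = e$n_perm %||% 500,
                                    seed = seeds$ephys + k)
      se_p <- responsiveness_test(st, ses$truth$se$onset_s,
                                  span = c(0, scfg$duration_s),
                                  n_perm = e$n_perm %||% 500,
                                  seed = seeds$ephys + 500L + k)
      categorize_unit(song_p, se_p)
    })
    cat_df <- data.frame(
      unit_id = units$unit_id,
      se_responsive = vapply(cats, `[[`, logical(1), "se_responsive"),
      song_responsive = vapply(cats, `[[`, logical(1), "song_responsive"),
      category = vapply(cats, `[[`, character(1), "category"))
    files$units_summary <- write_csv_quiet(
      cat_df, file.path(out_dir, "units_summary.csv"))
    summary$ephys <- summarize_unit_categories(cat_df)[
      c("n_units", "n_responsive", "n_se", "n_song", "pct_se_of_responsive")]
    log_stage("ephys: %d/%d units responsive", summary$ephys$n_responsive,
              summary$ephys$n_units)

    if (!is.null(config$conditioning)) {
      ccfg <- do.call(conditioning_config,
                      c(config$conditioning, list(seed = seeds$conditioning)))
      se_log <- label_se_outcomes(ses$truth$se, seg$songs, ccfg)
      files$se_log <- write_csv_quiet(se_log$se,
                                      file.path(out_dir, "se_log.csv"))
      dpa <- delta_peth_analysis(spikes, se_log, ccfg)
      if (length(dpa$results)) {
        dp_df <- data.frame(
          unit_id = names(dpa$results),
          delta_hz = vapply(dpa$results, `[[`, numeric(1), "delta_hz"),
          null_lo = vapply(dpa$results, `[[`, numeric(1), "null_lo"),
          null_hi = vapply(dpa$results, `[[`, numeric(1), "null_hi"),
          category = vapply(dpa$results, `[[`, character(1), "category"))
        files$delta_peth <- write_csv_quiet(
          dp_df, file.path(out_dir, "delta_peth.csv"))
      }
      summary$conditioning <- list(
        pct_song_inducing_se = se_log$pct_song_inducing,
        n_units_admitted = length(dpa$results),
        n_units_excluded = nrow(dpa$excluded),
        categories = as.list(dpa$table))
      log_stage("conditioning: %d units admitted, %d excluded",
                length(dpa$results), nrow(dpa$excluded))
    }
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  provenance <- list(seed = seed, seeds = seeds,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     log = log_lines)
  files$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(provenance, files$provenance, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(files = files, config = config, seeds = seeds,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
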