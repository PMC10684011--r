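#' Study-level configuration
#'
#' Bundles the synthetic-session generator configuration with per-stage
#' analysis configurations and the study size. Defaults mirror the
#' targeted study design (36 participants, 416 real + 416 sham pulses);
#' every entry is a knob.
#'
#' @param synth A `synth_config` for per-participant sessions;
#'   participant p runs with seed `synth$seed + 1000 * p`.
#' @param n_participants Number of synthetic participants.
#' @param tep,hep,tfr Stage configurations.
#' @param n_perm Permutations for cluster tests.
#' @param run_tep,run_hep,run_pinch Stage switches.
#' @return A `study_config` list.
#' @export
study_config <- function(synth = synth_config(), n_participants = 36,
                         tep = tep_config(), hep = hep_config(),
                         tfr = tfr_config(), n_perm = 1000,
                         run_tep = TRUE, run_hep = TRUE, run_pinch = TRUE) {
  structure(as.list(environment()), class = "study_config")
}

# cardiac preprocessing for one session: artifact interpolation, R-peaks,
# T-ends, map, event classification
.session_cardiac <- function(rec, events) {
  ecg_ch <- rec$channels[rec$roles == "ecg"][1]
  ecg <- interpolate_stim_artifact_ecg(rec$data[ecg_ch, ],
                                       events$onset_s, rec$rate)
  r_peaks <- detect_r_peaks(ecg, rec$rate)
  t_ends <- detect_t_end(ecg, r_peaks, rec$rate)
  map <- build_cardiac_map(r_peaks, t_ends)
  cls <- classify_events(events$onset_s, map)
  list(map = map, r_peaks = r_peaks, classified = cls)
}

# analyse one participant's TMS session: phases, MEPs, IBI triplets
.participant_session <- function(cfg_p, tep_cfg, hep_cfg, run_tep, run_hep,
                                 seed) {
  ses <- gen_session(cfg_p)
  card <- .session_cardiac(ses$recording, ses$events)
  cls <- card$classified
  cond <- ses$events$label
  emg_ep <- epoch(ses$recording, ses$events, "tms", -0.2, 0.1,
                  channels = ses$recording$channels[ses$recording$roles == "emg"])
  amp_tms <- mep_amplitudes(emg_ep)
  sham_idx <- which(cond == "sham")
  amp_sham <- if (length(sham_idx) > 0) {
    sh_ep <- epoch(ses$recording, ses$events, "sham", -0.2, 0.1,
                   channels = ses$recording$channels[ses$recording$roles == "emg"])
    mep_amplitudes(sh_ep)
  } else numeric(0)
  rec_tbl <- data.frame(
    onset_s = c(ses$events$onset_s[cond == "tms"],
                ses$events$onset_s[cond == "sham"]),
    condition = c(rep("tms", length(amp_tms)), rep("sham", length(amp_sham))),
    amplitude = c(amp_tms, amp_sham))
  rec_tbl <- merge(rec_tbl, cls[, c("onset_s", "phase", "distance_ms")],
                   by = "onset_s", sort = TRUE)
  rec_tbl <- validate_trials(rec_tbl)
  tms_tbl <- rec_tbl[rec_tbl$condition == "tms" & rec_tbl$valid, ]
  ibi_real <- ibi_triplets(tms_tbl$onset_s, card$r_peaks, tms_tbl$phase)
  sham_tbl <- rec_tbl[rec_tbl$condition == "sham" & rec_tbl$valid, ]
  ibi_sham <- ibi_triplets(sham_tbl$onset_s, card$r_peaks, sham_tbl$phase)
  out <- list(records = rec_tbl, ibi_real = ibi_real, ibi_sham = ibi_sham,
              truth = ses$truth)
  if (run_tep) {
    out$tep <- tryCatch({
      ep <- run_tep_pipeline(ses$recording, ses$events, "tms", tep_cfg,
                             seed = seed)
      phases <- cls$phase[match(round(ep$trial_meta$onset_s, 6),
                                round(cls$onset_s, 6))]
      tep_contrast(ep, phases, tep_cfg)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  if (run_hep) {
    out$hep <- tryCatch({
      cls_tms <- cls[cond == "tms", ]
      sel <- select_late_tms_trials(cls_tms, hep_cfg)
      tms_t <- cls_tms$onset_s[sel$keep]
      tmpl <- estimate_mock_artifact(ses$recording, tms_t, sel$distances_s,
                                     hep_cfg, seed = seed,
                                     channels = intersect(hep_cfg$electrodes,
                                                          ses$recording$channels))
      hep_ep <- extract_hep(ses$recording, tms_t - sel$distances_s, tmpl,
                            hep_cfg)
      amps <- tms_tbl$amplitude[match(round(tms_t, 6),
                                      round(tms_tbl$onset_s, 6))]
      keep <- !is.na(amps)
      hep_ep$data <- hep_ep$data[keep, , , drop = FALSE]
      hep_ep$trial_meta <- hep_ep$trial_meta[keep, , drop = FALSE]
      hep_bin_contrast(hep_ep, amps[keep], hep_cfg)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  out
}

#' Run the full synthetic study
#'
#' Generates `n_participants` synthetic sessions and executes the
#' complete analysis graph: cardiac phase classification, MEP contrast
#' (Wilcoxon + Cohen's d, with sham-EMG correction), interbeat-interval
#' ANOVA with sham correction, TEP and HEP cluster tests, pinch-task
#' EMG-envelope and ERD contrasts, the hierarchical distance LME and the
#' binned MEP profile. Returns a structured report; with `out_dir` set,
#' also writes it as JSON plus per-stage TSV tables. Deterministic for a
#' fixed `study$synth$seed`.
#'
#' @param study A `study_config`.
#' @param out_dir Optional output directory.
#' @return Report list of class `study_report`.
#' @export
run_study <- function(study = study_config(), out_dir = NULL) {
  seed0 <- study$synth$seed
  parts <- vector("list", study$n_participants)
  for (p in seq_len(study$n_participants)) {
    cfg_p <- study$synth
    cfg_p$seed <- as.integer((seed0 + 1000 * p) %% .Machine$integer.max)
    parts[[p]] <- .participant_session(cfg_p, study$tep, study$hep,
                                       study$run_tep, study$run_hep,
                                       seed = cfg_p$seed)
  }
  report <- list(seed = seed0, n_participants = study$n_participants)

  # MEP phase contrast: per-participant mean amplitudes, Wilcoxon + d
  mean_phase <- function(p, ph, cond = "tms") {
    r <- parts[[p]]$records
    mean(r$amplitude[r$condition == cond & r$valid & r$phase == ph])
  }
  np <- study$n_participants
  sys_m <- vapply(seq_len(np), mean_phase, 1, ph = "systole")
  dia_m <- vapply(seq_len(np), mean_phase, 1, ph = "diastole")
  d <- sys_m - dia_m
  report$mep <- c(wilcoxon_signed_rank(d)[c("V", "p")],
                  list(d = cohens_d_paired(d),
                       mean_systole = mean(sys_m), mean_diastole = mean(dia_m)))
  if (any(vapply(parts, function(x) sum(x$records$condition == "sham") > 0, TRUE))) {
    sys_s <- vapply(seq_len(np), mean_phase, 1, ph = "systole", cond = "sham")
    dia_s <- vapply(seq_len(np), mean_phase, 1, ph = "diastole", cond = "sham")
    dc <- (sys_m - sys_s) - (dia_m - dia_s)
    dc <- dc[is.finite(dc)]
    if (length(dc) >= 2)
      report$mep_sham_corrected <- c(wilcoxon_signed_rank(dc)[c("V", "p")],
                                     list(d = cohens_d_paired(dc)))
  }

  # IBI: per-participant cell means -> rm-ANOVA, plus sham correction
  ibi_cells <- function(p, which = "ibi_real") {
    tri <- parts[[p]][[which]]
    tri <- tri[tri$phase %in% c("systole", "diastole"), ]
    if (nrow(tri) == 0) return(NULL)
    do.call(rbind, lapply(c("ibi_pre", "ibi_tms", "ibi_post"), function(cl)
      data.frame(participant = p, a = cl,
                 b = tri$phase, value = tri[[cl]])))
  }
  long <- do.call(rbind, lapply(seq_len(np), ibi_cells))
  report$ibi_anova <- tryCatch(
    as.list(rm_anova_2way(long, c("time", "phase"))["time:phase", c("F", "df1", "df2", "p", "ges")]),
    error = function(e) list(error = conditionMessage(e)))
  decel <- vapply(seq_len(np), function(p) {
    tri <- parts[[p]]$ibi_real
    mean(tri$ibi_tms[tri$phase == "systole"] - tri$ibi_pre[tri$phase == "systole"])
  }, 1)
  report$ibi_systole_decel_ms <- mean(decel, na.rm = TRUE)

  # TEP cluster test over participants (hotspot mean difference traces)
  if (study$run_tep) {
    teps <- lapply(parts, `[[`, "tep")
    ok <- vapply(teps, function(x) is.null(x$error), TRUE)
    if (sum(ok) >= 2) {
      nt <- min(vapply(teps[ok], function(x) length(x$systole), 1L))
      a <- t(vapply(teps[ok], function(x) x$systole[seq_len(nt)], numeric(nt)))
      b <- t(vapply(teps[ok], function(x) x$diastole[seq_len(nt)], numeric(nt)))
      ct <- cluster_perm_test(array(a, c(sum(ok), 1, nt)),
                              array(b, c(sum(ok), 1, nt)),
                              n_perm = study$n_perm, seed = seed0)
      report$tep <- list(n_clusters = length(ct$clusters),
                         min_p = if (length(ct$clusters))
                           min(vapply(ct$clusters, `[[`, 1, "p")) else NA,
                         mean_diff = mean(a - b))
    }
  }

  # HEP strong-vs-weak contrast across participants
  if (study$run_hep) {
    heps <- lapply(parts, `[[`, "hep")
    ok <- vapply(heps, function(x) is.null(x$error), TRUE)
    if (sum(ok) >= 2) {
      nt <- min(vapply(heps[ok], function(x) length(x$contrast), 1L))
      cmat <- t(vapply(heps[ok], function(x) x$contrast[seq_len(nt)],
                       numeric(nt)))
      ct <- cluster_perm_test(array(cmat, c(sum(ok), 1, nt)),
                              array(0, c(sum(ok), 1, nt)),
                              n_perm = study$n_perm, seed = seed0 + 1)
      report$hep <- list(n_clusters = length(ct$clusters),
                         min_p = if (length(ct$clusters))
                           min(vapply(ct$clusters, `[[`, 1, "p")) else NA,
                         mean_contrast = mean(cmat))
    }
  }

  # pooled single-trial LME and binned profile
  pool <- do.call(rbind, lapply(seq_len(np), function(p) {
    r <- parts[[p]]$records
    r <- r[r$condition == "tms" & r$valid & !is.na(r$distance_ms), ]
    data.frame(participant = p, mep_uv = r$amplitude,
               distance_ms = r$distance_ms)
  }))
  report$lme <- tryCatch({
    cmp <- lme_distance_models(pool$mep_uv, pool$distance_ms, pool$participant)
    list(linear_vs_null_p = cmp$tests$p[1], quadratic_vs_linear_p = cmp$tests$p[2],
         linear_chisq = cmp$tests$chisq[1])
  }, error = function(e) list(error = conditionMessage(e)))
  report$profile <- binned_mep_profile(pool$mep_uv, pool$distance_ms)

  # pinch task: EMG envelope and ERD phase contrast (first participant's
  # session scale; group level uses per-participant means)
  if (study$run_pinch) {
    env_sys <- c(); env_dia <- c(); erd_sys <- c(); erd_dia <- c()
    for (p in seq_len(np)) {
      cfg_p <- study$synth
      cfg_p$seed <- as.integer((seed0 + 1000 * p) %% .Machine$integer.max)
      pt <- gen_pinch_task(cfg_p)
      cardp <- .session_cardiac(pt$recording, pt$events)
      clsp <- classify_events(pt$events$onset_s, cardp$map)
      rate <- pt$recording$rate
      env <- emg_envelope(pt$recording$data["EMG", ], rate,
                          band = c(10, min(500, 0.45 * rate)))
      win_mean <- function(t0) {
        lo <- round(t0 * rate) + 1; hi <- min(round((t0 + 1) * rate), length(env))
        mean(env[lo:hi])
      }
      ev <- vapply(pt$events$onset_s, win_mean, 1)
      env_sys <- c(env_sys, mean(ev[clsp$phase == "systole"]))
      env_dia <- c(env_dia, mean(ev[clsp$phase == "diastole"]))
      ep <- epoch(pt$recording, pt$events, "pinch_on",
                  study$tfr$epoch_s[1], study$tfr$epoch_s[2])
      tfrp <- compute_tfr(ep, study$tfr)
      erd <- erd_contrast(tfrp, clsp$phase, study$tfr)
      tw <- tfrp$times >= study$tfr$test_window_s[1] &
        tfrp$times <= study$tfr$test_window_s[2]
      fb <- tfrp$freqs >= study$tfr$test_band[1] &
        tfrp$freqs <= study$tfr$test_band[2]
      if (!is.null(erd$systole)) erd_sys <- c(erd_sys, mean(erd$systole[, fb, tw]))
      if (!is.null(erd$diastole)) erd_dia <- c(erd_dia, mean(erd$diastole[, fb, tw]))
    }
    dd <- env_sys - env_dia; dd <- dd[is.finite(dd)]
    report$pinch_envelope <- list(mean_systole = mean(env_sys, na.rm = TRUE),
                                  mean_diastole = mean(env_dia, na.rm = TRUE))
    if (length(dd) >= 2) report$pinch_envelope$wilcoxon_p <-
      wilcoxon_signed_rank(dd)$p
    report$erd <- list(mean_systole = mean(erd_sys, na.rm = TRUE),
                       mean_diastole = mean(erd_dia, na.rm = TRUE))
  }

  class(report) <- "study_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(report$profile, file.path(out_dir, "mep_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
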