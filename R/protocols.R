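# Pacing protocols and experiment orchestration: sinus-rhythm pacing, the
# PV burst pAF-initiation protocol, cross-field spiral induction for sheet
# experiments, sustained-arrhythmia detection, and the timed
# initiation -> ablation -> analysis experiment driver.

#' Sinus pacing schedule
#'
#' Periodic stimuli at 60000/rate ms intervals, first stimulus at `t_start`
#' (t = 0 by convention).
#'
#' @param site integer node indices of the pacing site.
#' @param rate_bpm sinus rate (default 86 beats/min).
#' @param t_start,t_end schedule window (ms).
#' @param amp_papf,dur_ms stimulus strength and duration.
#' @return list of [stimulus()] entries.
#' @export
sinus_schedule <- function(site, rate_bpm = 86, t_start = 0, t_end,
                           amp_papf = -30, dur_ms = 2) {
  if (rate_bpm <= 0) stop("rate must be positive")
  interval <- 60000 / rate_bpm
  times <- seq(t_start, t_end, by = interval)
  lapply(times, function(tt) stimulus(tt, site, dur_ms, amp_papf))
}

#' PV burst pacing schedule
#'
#' Five stimuli at the PV sleeve, the first at
#' `last_sinus_t + coupling interval` (240 ms for the right superior PV,
#' 400 ms for the left superior PV), spaced at a 160 ms cycle length.
#'
#' @param mesh a `la_mesh` (for the sleeve node lookup).
#' @param pv "RSPV" or "LSPV".
#' @param last_sinus_t time of the reference sinus stimulus (ms).
#' @param cl_ms burst cycle length (default 160).
#' @param ci_ms named coupling intervals (defaults RSPV 240, LSPV 400).
#' @param n_beats number of burst stimuli (default 5).
#' @param amp_papf,dur_ms stimulus strength and duration.
#' @param focal_radius_mm if set, pace only a focal patch of the sleeve
#'   (sleeve nodes within this radius of the rim point facing the atrial
#'   centre) instead of the whole sleeve, mimicking a focal ectopic
#'   trigger.
#' @return list of [stimulus()] entries.
#' @export
pv_burst_schedule <- function(mesh, pv, last_sinus_t, cl_ms = 160,
                              ci_ms = c(RSPV = 240, LSPV = 400), n_beats = 5,
                              amp_papf = -30, dur_ms = 2,
                              focal_radius_mm = NULL) {
  if (!pv %in% names(ci_ms)) stop("unknown PV label '", pv, "'")
  site <- pv_sleeve_nodes(mesh, pv)
  if (!is.null(focal_radius_mm)) {
    ost <- mesh$config$ostia
    k <- match(pv, ost$label)
    ctr <- mesh$config$size_mm / 2
    dir <- ctr - c(ost$x[k], ost$y[k])
    dir <- dir / sqrt(sum(dir^2))
    p_rim <- c(ost$x[k], ost$y[k]) + dir * ost$radius[k]
    d <- sqrt((mesh$nodes[site, 1] - p_rim[1])^2 +
              (mesh$nodes[site, 2] - p_rim[2])^2)
    focal <- site[d <= focal_radius_mm]
    if (length(focal) > 0) site <- focal
  }
  times <- last_sinus_t + ci_ms[[pv]] + (seq_len(n_beats) - 1) * cl_ms
  lapply(times, function(tt) stimulus(tt, site, dur_ms, amp_papf))
}

#' Is an arrhythmia self-sustained?
#'
#' TRUE iff self-activation (threshold upstrokes anywhere in the tissue
#' later than 50 ms after the last scheduled stimulus) is present and
#' persists to the end of the observation window: at least one
#' self-activation in the final `tail_ms` of the window. A zero-length
#' window degenerates to "any self-activation exists".
#'
#' @param recording a `tissue_recording`.
#' @param stim_times scheduled stimulus onset times (ms); defaults to the
#'   recording's own.
#' @param window_s observation window after the last stimulus (s).
#' @param tail_ms width of the terminal interval that must contain
#'   activity (default 250 ms).
#' @param threshold_mv activation threshold.
#' @return logical.
#' @export
is_sustained <- function(recording, stim_times = recording$stim_times,
                         window_s = 2, tail_ms = 250, threshold_mv = -40) {
  last_stim <- if (length(stim_times)) max(stim_times) else min(recording$times)
  t_end <- last_stim + window_s * 1000
  if (max(recording$times) < t_end - recording$record_dt / 2)
    stop("recording too short for the requested window")
  ts <- unlist(upstroke_times(recording, threshold_mv))
  self <- ts[ts > last_stim + 50]
  if (length(self) == 0) return(FALSE)
  if (window_s <= 0) return(TRUE)
  any(self >= t_end - tail_ms)
}

#' Induce a spiral wave by cross-field stimulation
#'
#' An S1 train of plane waves from the left edge conditions the tissue
#' (rate-dependent APD shortening keeps the first reentrant rotation
#' short); once the last S1 wave has activated the sheet centre and its
#' repolarization tail recedes past it (centre Vm falls below
#' `recovery_mv`), an S2 stimulus is applied over the lower-left quadrant
#' (or the whole lower half), whose broken wavefront end curls into a
#' spiral.
#'
#' @param system a `monodomain_system` over a sheet.
#' @param state initial tissue state.
#' @param dt_ms integration step.
#' @param n_s1 number of S1 conditioning beats (default 2).
#' @param s1_cl_ms S1 cycle length (default 330 ms).
#' @param recovery_mv centre-recovery voltage triggering S2 (default -60).
#' @param s2_delay_ms extra delay after recovery detection (default 0).
#' @param s2_quadrant limit S2 to the lower-left quadrant (default TRUE)
#'   instead of the whole lower half.
#' @param max_wait_ms abort if the centre has not recovered by then
#'   (measured after the last S1).
#' @param chunk_ms monitoring granularity.
#' @return list with `state` (pre-S2 state), `t` (current time, ms),
#'   `t_s2` (S2 onset), `s2` (the S2 [stimulus()]), `recording` (frames up
#'   to S2).
#' @export
cross_field_s2 <- function(system, state, dt_ms = 0.02, n_s1 = 2,
                           s1_cl_ms = 330, recovery_mv = -60,
                           s2_delay_ms = 10, s2_quadrant = TRUE,
                           max_wait_ms = 600, chunk_ms = 10) {
  mesh <- system$mesh
  ctr <- c(mesh$config$size_mm[1] / 2, mesh$config$size_mm[2] / 2)
  probe <- which.min((mesh$nodes[, 1] - ctr[1])^2 +
                     (mesh$nodes[, 2] - ctr[2])^2)
  s1_nodes <- which(mesh$nodes[, 1] < 1.2)
  s1_times <- 1 + (seq_len(n_s1) - 1) * s1_cl_ms
  last_s1 <- max(s1_times)
  tcur <- 0
  activated <- FALSE
  recs <- list()
  st <- state
  repeat {
    stims <- Filter(function(s) s$start >= tcur &
                      s$start < tcur + chunk_ms,
                    lapply(s1_times, function(ts) stimulus(ts, s1_nodes)))
    rec <- simulate_tissue(system, st, tcur, tcur + chunk_ms, stims,
                           dt_ms = dt_ms, record_dt = 1)
    recs[[length(recs) + 1]] <- rec
    st <- rec$state
    v <- rec$frames[probe, ]
    if (tcur >= last_s1) {
      if (!activated && any(v > 0)) activated <- TRUE
      if (activated && tail(v, 1) < recovery_mv) break
    } else activated <- FALSE
    tcur <- tcur + chunk_ms
    if (tcur > last_s1 + max_wait_ms)
      stop("centre node did not recover within max_wait_ms")
  }
  t_s2 <- tcur + chunk_ms + s2_delay_ms
  if (s2_delay_ms > 0) {
    rec <- simulate_tissue(system, st, tcur + chunk_ms, t_s2, list(),
                           dt_ms = dt_ms, record_dt = 1)
    recs[[length(recs) + 1]] <- rec
    st <- rec$state
  }
  in_s2 <- mesh$nodes[, 2] < ctr[2]
  if (s2_quadrant) in_s2 <- in_s2 & mesh$nodes[, 1] < ctr[1]
  s2 <- stimulus(t_s2, which(in_s2))
  list(state = st, t = t_s2, t_s2 = t_s2, s2 = s2,
       recording = merge_recordings(recs))
}

#' Concatenate recordings from chained simulation segments
#' @param recs list of `tissue_recording`s with contiguous time windows.
#' @return a single `tissue_recording`.
#' @export
merge_recordings <- function(recs) {
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 1) return(recs[[1]])
  frames <- recs[[1]]$frames
  times <- recs[[1]]$times
  for (k in 2:length(recs)) {
    # drop the duplicated initial frame of each continuation segment
    frames <- cbind(frames, recs[[k]]$frames[, -1, drop = FALSE])
    times <- c(times, recs[[k]]$times[-1])
  }
  structure(list(times = times, frames = frames,
                 state = recs[[length(recs)]]$state,
                 stim_times = unlist(lapply(recs, `[[`, "stim_times")),
                 dt = recs[[1]]$dt, record_dt = recs[[1]]$record_dt,
                 ok = all(vapply(recs, `[[`, logical(1), "ok"))),
            class = "tissue_recording")
}

#' Experiment plan
#'
#' Timing of an initiation -> ablation -> analysis experiment. Defaults are
#' desk-scale: sustainment is checked 2 s after initiation, lesions applied
#' at `rfa_time_s`, and the post-ablation analysis window is
#' `analysis_window_s` (both scalable to clinical durations).
#'
#' @param pv PV to burst ("RSPV"/"LSPV").
#' @param sinus_rate_bpm sinus rate.
#' @param rfa_time_s lesion application time after initiation onset (s).
#' @param analysis_window_s post-ablation analysis window (s).
#' @param sustained_threshold_s sustainment window (s).
#' @param dt_ms integration step.
#' @return list of class `experiment_plan`.
#' @export
experiment_plan <- function(pv = "RSPV", sinus_rate_bpm = 86,
                            rfa_time_s = 2, analysis_window_s = 3,
                            sustained_threshold_s = 2, dt_ms = 0.02) {
  if (rfa_time_s >= rfa_time_s + analysis_window_s)
    stop("analysis window must be positive")
  structure(list(pv = pv, sinus_rate_bpm = sinus_rate_bpm,
                 rfa_time_s = rfa_time_s,
                 analysis_window_s = analysis_window_s,
                 sustained_threshold_s = sustained_threshold_s,
                 dt_ms = dt_ms),
            class = "experiment_plan")
}

#' Run a pAF initiation / ablation experiment
#'
#' Executes sinus pacing with the PV burst, checks that the induced
#' arrhythmia is self-sustained, optionally applies a lesion set at the
#' planned ablation time, and continues through the analysis window.
#'
#' @param plan an [experiment_plan()].
#' @param system a `monodomain_system`.
#' @param sinus_site node indices of the sinus-surrogate pacing site (the
#'   earliest-activation region of the LA); defaults to a 1.5 mm disc just
#'   below the RSPV ostium.
#' @param lesions optional `lesion_set` (or list of them) applied at
#'   `rfa_time_s`.
#' @param state optional initial state.
#' @param record_dt frame interval (ms).
#' @param initiation_stimuli optional list of [stimulus()] entries that
#'   replaces the sinus + PV-burst schedule (e.g. cross-field induction on
#'   sheet geometries).
#' @return list with `pre` (initiation recording), `post` (post-ablation
#'   recording or NULL), `sustained`, `system_post` (system with lesions),
#'   `log` (timing data.frame).
#' @export
run_experiment <- function(plan, system, sinus_site = NULL, lesions = NULL,
                           state = NULL, record_dt = 1,
                           initiation_stimuli = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  mesh <- system$mesh
  if (is.null(state)) state <- init_tissue_state(system)
  rfa_ms <- plan$rfa_time_s * 1000
  if (is.null(initiation_stimuli)) {
    if (is.null(sinus_site)) {
      ost <- mesh$config$ostia
      k <- match("RSPV", ost$label)
      ctr <- c(ost$x[k], ost$y[k] - ost$radius[k] - 2)
      sinus_site <- nodes_near(mesh, ctr, 1.5)
    }
    sinus <- sinus_schedule(sinus_site, plan$sinus_rate_bpm, 0, rfa_ms)
    # burst couples to the first sinus beat; later sinus beats are withheld
    # because initiation converts the rhythm. The burst paces a focal
    # sleeve patch (ectopic trigger), breaking the annular symmetry.
    burst <- pv_burst_schedule(mesh, plan$pv, last_sinus_t = 0,
                               focal_radius_mm = 2.5)
    sinus <- Filter(function(s) s$start <= 0, sinus)
    initiation_stimuli <- c(sinus, burst)
  }
  last_burst <- max(vapply(initiation_stimuli, `[[`, numeric(1), "start"))
  pre <- simulate_tissue(system, state, 0, rfa_ms, initiation_stimuli,
                         dt_ms = plan$dt_ms, record_dt = record_dt)
  sust <- is_sustained(pre, window_s = min(plan$sustained_threshold_s,
                                           (rfa_ms - last_burst) / 1000))
  stim_starts <- vapply(initiation_stimuli, `[[`, numeric(1), "start")
  log <- data.frame(event = c("stim_start", "stim_end", "rfa"),
                    t_ms = c(min(stim_starts), last_burst, rfa_ms))
  if (!sust) {
    return(list(pre = pre, post = NULL, sustained = FALSE,
                system_post = system, log = log))
  }
  sys2 <- system
  if (!is.null(lesions)) {
    if (inherits(lesions, "lesion_set")) lesions <- list(lesions)
    cond <- system$conductivity
    for (l in lesions) cond <- apply_lesion(cond, l)
    sys2 <- update_conductivity(system, cond)
  }
  post <- simulate_tissue(sys2, pre$state, rfa_ms,
                          rfa_ms + plan$analysis_window_s * 1000, list(),
                          dt_ms = plan$dt_ms, record_dt = record_dt)
  list(pre = pre, post = post, sustained = TRUE, system_post = sys2,
       log = log)
}
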