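# Courtemanche-Ramirez-Nattel human atrial ionic model: regional parameter
# construction (pAF electrical remodeling, PV and appendage variants),
# single-cell pacing and APD measurement. The model equations live in
# src/courtemanche.cpp; this file owns the parameter policy.

# published baseline maximal conductances (nS/pF); gKur is voltage-dependent
# in the model, so its entry is a dimensionless scale factor
crn_baseline <- c(gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKur = 1.0,
                  gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375)

#' Regional ionic parameter sets
#'
#' Builds the conductance vector for a tissue region class. Starting from
#' the published baseline: sodium conductance is doubled (realistic upstroke
#' velocity in coupled tissue) and the inward rectifier reduced by 20%
#' (rate-adaptation match). Persistent-AF electrical remodeling then scales
#' Ito x 0.5, IKur x 0.5, ICaL x 0.3. Region variants: pulmonary-vein (PV)
#' sleeves additionally scale gto x 0.75, gCaL x 0.75, gKr x 2.4,
#' gKs x 1.87, gK1 x 0.67; the left atrial appendage carries a 1.6-fold
#' greater IKr than its right-sided counterpart.
#'
#' @param region_class one of "LA_body", "PV", "LAA", "RA_body", "RAA".
#' @param paf_remodeled apply the pAF remodeling multipliers (default TRUE).
#' @param tissue_adjusted apply the tissue-level gNa x 2 and gK1 x 0.8
#'   modifiers (default TRUE; disable for the published single-cell model).
#' @param extra_multipliers optional named numeric vector of additional
#'   per-conductance multipliers (hook for finer regional gradients).
#' @return named numeric vector with elements gNa, gK1, gto, gKur, gKr,
#'   gKs, gCaL (nS/pF; gKur is a scale factor).
#' @export
make_region_params <- function(region_class = c("LA_body", "PV", "LAA",
                                                "RA_body", "RAA"),
                               paf_remodeled = TRUE, tissue_adjusted = TRUE,
                               extra_multipliers = NULL) {
  region_class <- match.arg(region_class)
  p <- crn_baseline
  if (tissue_adjusted) {
    p["gNa"] <- p["gNa"] * 2
    p["gK1"] <- p["gK1"] * 0.8
  }
  if (paf_remodeled) {
    p["gto"] <- p["gto"] * 0.5
    p["gKur"] <- p["gKur"] * 0.5
    p["gCaL"] <- p["gCaL"] * 0.3
  }
  if (region_class == "PV") {
    p["gto"] <- p["gto"] * 0.75
    p["gCaL"] <- p["gCaL"] * 0.75
    p["gKr"] <- p["gKr"] * 2.4
    p["gKs"] <- p["gKs"] * 1.87
    p["gK1"] <- p["gK1"] * 0.67
  } else if (region_class == "LAA") {
    p["gKr"] <- p["gKr"] * 1.6  # relative to the RA appendage
  }
  if (!is.null(extra_multipliers)) {
    nm <- intersect(names(extra_multipliers), names(p))
    p[nm] <- p[nm] * extra_multipliers[nm]
  }
  if (any(p < 0)) stop("negative conductance")
  p
}

#' Published resting state of the cell model
#' @return named numeric vector of the 21 state variables.
#' @export
crn_initial_state <- function() cpp_crn_initial_state()

#' Ionic model right-hand side
#'
#' Time-derivatives of all 21 state variables (mV/ms, 1/ms, mM/ms) at a
#' given state under a transmembrane stimulus current (pA/pF, depolarizing
#' negative).
#'
#' @param state numeric(21) as from [crn_initial_state()].
#' @param params conductance vector as from [make_region_params()].
#' @param stim stimulus current density (pA/pF).
#' @return named numeric(21) of derivatives.
#' @export
ionic_rhs <- function(state, params, stim = 0) {
  dy <- cpp_crn_rhs(as.numeric(state), as.numeric(params[param_order(params)]),
                    stim)
  names(dy) <- names(cpp_crn_initial_state())
  dy
}

param_order <- function(p) {
  if (is.null(names(p))) return(seq_along(p))
  match(c("gNa", "gK1", "gto", "gKur", "gKr", "gKs", "gCaL"), names(p))
}

#' Pace a single cell and measure APD90 per beat
#'
#' Integrates the cell model with Rush-Larsen gate updates and forward-Euler
#' concentration updates, stimulating at a fixed cycle length. Activation is
#' the upward crossing of -40 mV; APD90 runs from activation to 90%
#' repolarization relative to that beat's amplitude (peak minus the
#' pre-stimulus potential).
#'
#' @param params conductance vector.
#' @param cl_ms cycle length (ms).
#' @param n_beats number of stimuli (>= 1).
#' @param dt_ms integration step (ms; default 0.02).
#' @param state0 initial state (defaults to the published resting state).
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms).
#' @param record_dt trace sampling interval (ms).
#' @return list with `t`, `Vm` (sampled trace), `apd90` (per captured
#'   beat, ms; NA for beats without capture), `captured` (logical per
#'   beat), `state` (final).
#' @export
pace_single_cell <- function(params, cl_ms, n_beats, dt_ms = 0.02,
                             state0 = crn_initial_state(), stim_amp = -30,
                             stim_dur = 2, record_dt = 0.5) {
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (cl_ms <= 0) stop("cycle length must be positive")
  r <- cpp_pace_cell(as.numeric(state0),
                     as.numeric(params[param_order(params)]), cl_ms,
                     as.integer(n_beats), dt_ms, stim_amp, stim_dur,
                     record_dt, tail_ms = min(cl_ms, 400))
  apd <- rep(NA_real_, n_beats)
  captured <- logical(n_beats)
  for (b in seq_len(n_beats)) {
    t0 <- (b - 1) * cl_ms
    t1 <- t0 + cl_ms + if (b == n_beats) min(cl_ms, 400) else 0
    res <- measure_apd90(r$t, r$Vm, t0, t1)
    apd[b] <- res["apd90"]
    captured[b] <- is.finite(res["apd90"])
  }
  list(t = r$t, Vm = r$Vm, apd90 = apd, captured = captured, state = r$state)
}

# APD90 of the beat contained in [t0, t1)
measure_apd90 <- function(t, Vm, t0, t1) {
  w <- t >= t0 & t < t1
  tb <- t[w]; Vb <- Vm[w]
  if (length(tb) < 5) return(c(apd90 = NA_real_))
  up <- which(Vb[-length(Vb)] <= -40 & Vb[-1] > -40)
  if (length(up) == 0) return(c(apd90 = NA_real_))
  i_up <- up[1]
  vrest <- Vb[1]
  vmax <- max(Vb[i_up:length(Vb)])
  lvl <- vmax - 0.9 * (vmax - vrest)
  after <- which(tb > tb[i_up] + 5 & Vb < lvl)
  if (length(after) == 0) return(c(apd90 = NA_real_))
  c(apd90 = tb[after[1]] - tb[i_up])
}

#' Steady-state APD90 at a cycle length (last of n beats)
#' @inheritParams pace_single_cell
#' @return APD90 (ms) of the final beat.
#' @export
steady_state_apd90 <- function(params, cl_ms, n_beats = 10, dt_ms = 0.02) {
  r <- pace_single_cell(params, cl_ms, n_beats, dt_ms)
  tail(r$apd90, 1)
}
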