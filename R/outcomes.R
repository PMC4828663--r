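# Post-ablation outcome classification (sinus / atrial tachycardia / pAF)
# and the correlation statistics between lesion outcomes, PS density and
# fibrosis density across the eight LA subdivisions.

#' Classify a post-ablation recording
#'
#' Rules: `sinus` if no self-activation occurs in the final
#' `quiet_tail_s` of the analysis window; `AT` if activity persists with a
#' time-median concurrent rotor count of exactly one and regular activation
#' (cycle-length coefficient of variation < 10%); `pAF` otherwise.
#'
#' @param recording the post-ablation `tissue_recording`.
#' @param trajectories `ps_trajectories` computed over the same window.
#' @param rotor_ids rotor ids ([classify_rotors()]).
#' @param quiet_tail_s terminal quiescence window for the sinus call (s).
#' @param threshold_mv activation threshold.
#' @return object of class `outcome_record`: list with `classification`,
#'   `success` (1 for sinus or AT), `median_rotor_count`, `cl_cv`.
#' @export
classify_outcome <- function(recording, trajectories, rotor_ids,
                             quiet_tail_s = 1, threshold_mv = -40) {
  t_end <- max(recording$times)
  t_tail <- t_end - quiet_tail_s * 1000
  if (t_tail < min(recording$times))
    stop("analysis window shorter than the quiescence tail")
  us <- unlist(upstroke_times(recording, threshold_mv))
  tail_act <- us[us >= t_tail]
  if (length(tail_act) == 0) {
    out <- list(classification = "sinus", success = 1L,
                median_rotor_count = 0, cl_cv = NA_real_)
    class(out) <- "outcome_record"
    return(out)
  }
  # concurrent rotor count per frame over the tail half of the window
  rot <- trajectories[trajectories$id %in% rotor_ids, , drop = FALSE]
  frames <- recording$times[recording$times >= min(recording$times) +
                              0.25 * (t_end - min(recording$times))]
  cnt <- if (nrow(rot)) tabulate(match(rot$t, frames),
                                 nbins = length(frames)) else
    rep(0L, length(frames))
  med_rot <- median(cnt)
  cl <- node_cycle_lengths(recording, t_start = min(frames))
  cl <- cl[!is.na(cl)]
  cl_cv <- if (length(cl) >= 4) sd(cl) / mean(cl) else NA_real_
  classification <- if (med_rot == 1 && !is.na(cl_cv) && cl_cv < 0.10)
    "AT" else "pAF"
  out <- list(classification = classification,
              success = as.integer(classification != "pAF"),
              median_rotor_count = med_rot, cl_cv = cl_cv)
  class(out) <- "outcome_record"
  out
}

#' Pearson product-moment correlation
#'
#' Two-sided test from the t distribution with n - 2 degrees of freedom.
#' Zero variance in either vector makes the coefficient undefined; the
#' result is flagged rather than an error (matching the dashes reported
#' for degenerate all-0/all-1 outcome vectors).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `pearson_result`: `r`, `p`, `n`, `defined`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE)
    class(out) <- "pearson_result"
    return(out)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
              defined = TRUE)
  class(out) <- "pearson_result"
  out
}

#' @export
print.pearson_result <- function(x, ...) {
  if (!x$defined) cat("pearson: undefined (zero variance), n =", x$n, "\n")
  else cat(sprintf("pearson: r = %.2f, p = %.2f, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Normalize per-subdivision densities to the 0-1 scale
#'
#' Each value divided by the maximum across subdivisions. Binary vectors
#' (already in {0, 1}, e.g. termination outcomes) pass through unchanged,
#' as do all-zero vectors.
#'
#' @param values numeric per subdivision.
#' @return numeric of the same length.
#' @export
normalize_densities <- function(values) {
  if (all(values %in% c(0, 1))) return(values)
  mx <- max(values)
  if (mx <= 0) return(values)
  values / mx
}

#' Correlation table of lesion outcomes vs densities
#'
#' For every lesion shape x size, the binary per-subdivision termination
#' outcomes are correlated against the normalized PS density and fibrosis
#' density vectors. Undefined entries (zero-variance outcome rows) are
#' rendered as "-".
#'
#' @param outcomes data.frame with columns `shape`, `size_cm`,
#'   `subdivision`, `success` (0/1).
#' @param ps_density numeric(8) normalized PS density.
#' @param fib_density numeric(8) normalized fibrosis density.
#' @return data.frame with one row per shape x size: `r_fib`, `p_fib`,
#'   `r_ps`, `p_ps` plus display columns with "-" for undefined entries.
#' @export
correlation_table <- function(outcomes, ps_density, fib_density) {
  stopifnot(all(outcomes$success %in% c(0, 1)))
  combos <- unique(outcomes[, c("shape", "size_cm")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- outcomes$shape == combos$shape[k] &
      outcomes$size_cm == combos$size_cm[k]
    d <- outcomes[sel, ]
    d <- d[order(d$subdivision), ]
    y <- d$success
    pf <- pearson(fib_density[d$subdivision], y)
    pp <- pearson(ps_density[d$subdivision], y)
    data.frame(shape = combos$shape[k], size_cm = combos$size_cm[k],
               r_fib = pf$r, p_fib = pf$p, r_ps = pp$r, p_ps = pp$p)
  })
  out <- do.call(rbind, rows)
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  out$r_fib_disp <- fmt(out$r_fib); out$p_fib_disp <- fmt(out$p_fib)
  out$r_ps_disp <- fmt(out$r_ps); out$p_ps_disp <- fmt(out$p_ps)
  out
}
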