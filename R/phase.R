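# Phase-singularity analysis: Hilbert-transform phase of the transmembrane
# voltage, PS detection by topological charge on mesh elements, trajectory
# tracking, rotor classification, density maps and regional statistics.

#' Instantaneous phase of a recording
#'
#' Per node, the mean over the analysis window is subtracted and the phase
#' computed as `atan2(H[v], v)` with `H` the Hilbert transform over the
#' window (analytic signal via FFT). Nodes whose voltage excursion is below
#' `min_amplitude_mv` have undefined phase and are masked.
#'
#' @param recording a `tissue_recording` (or list with `times`, `frames`).
#' @param t_start,t_end analysis window (defaults: whole recording).
#' @param min_amplitude_mv mask threshold on peak-to-peak amplitude.
#' @return object of class `phase_movie`: list with `phase` (n x T in
#'   (-pi, pi]), `times`, `mask` (TRUE = phase defined).
#' @export
compute_phase <- function(recording, t_start = -Inf, t_end = Inf,
                          min_amplitude_mv = 1) {
  w <- recording$times >= t_start & recording$times <= t_end
  if (sum(w) < 8) stop("analysis window too short")
  X <- recording$frames[, w, drop = FALSE]
  tt <- recording$times[w]
  n <- nrow(X); Tn <- ncol(X)
  amp <- apply(X, 1, function(r) diff(range(r)))
  mask <- amp >= min_amplitude_mv
  ph <- matrix(NA_real_, n, Tn)
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(Tn)
  h[1] <- 1
  if (Tn %% 2 == 0) {
    h[Tn / 2 + 1] <- 1
    h[2:(Tn / 2)] <- 2
  } else {
    h[2:((Tn + 1) / 2)] <- 2
  }
  idx <- which(mask)
  chunk <- 2000L
  for (s in seq(1, length(idx), by = chunk)) {
    rows <- idx[s:min(s + chunk - 1L, length(idx))]
    Z <- t(X[rows, , drop = FALSE])
    Z <- sweep(Z, 2, colMeans(Z))
    A <- mvfft(mvfft(Z) * h, inverse = TRUE) / Tn
    ph[rows, ] <- t(atan2(Im(A), Re(A)))
  }
  structure(list(phase = ph, times = tt, mask = mask),
            class = "phase_movie")
}

# wrap angle difference into (-pi, pi]
wrap_phase <- function(d) d - 2 * pi * round(d / (2 * pi))

#' Detect phase singularities in one frame
#'
#' Computes the topological charge of every triangle: the sum of wrapped
#' phase differences around its (counter-clockwise) vertices. Elements with
#' winding +/- 2 pi (|sum| > pi) are singularities; chirality is the sign.
#' Elements touching a masked node are skipped.
#'
#' @param phase_frame numeric per node (radians) or a `phase_movie` plus
#'   `frame` index.
#' @param mesh a `la_mesh`.
#' @param mask optional logical per node (TRUE = defined).
#' @return data.frame with columns `element`, `chirality`, `x`, `y`, `z`
#'   (element centroid).
#' @export
detect_ps <- function(phase_frame, mesh, mask = NULL) {
  tri <- mesh$triangles
  p1 <- phase_frame[tri[, 1]]
  p2 <- phase_frame[tri[, 2]]
  p3 <- phase_frame[tri[, 3]]
  s <- wrap_phase(p2 - p1) + wrap_phase(p3 - p2) + wrap_phase(p1 - p3)
  ok <- !is.na(s)
  if (!is.null(mask))
    ok <- ok & mask[tri[, 1]] & mask[tri[, 2]] & mask[tri[, 3]]
  hit <- which(ok & abs(s) > pi)
  cent <- triangle_centroids(mesh$nodes, tri)
  data.frame(element = hit, chirality = sign(s[hit]),
             x = cent[hit, 1], y = cent[hit, 2], z = cent[hit, 3])
}

#' Detect phase singularities in every frame of a phase movie
#' @param movie a `phase_movie`.
#' @param mesh a `la_mesh`.
#' @return list of data.frames (one per frame), as [detect_ps()].
#' @export
detect_ps_movie <- function(movie, mesh) {
  lapply(seq_along(movie$times), function(k)
    detect_ps(movie$phase[, k], mesh, movie$mask))
}

#' Track phase singularities over time
#'
#' Greedy frame-to-frame matching by centroid distance: the globally
#' closest detection/trajectory pair (same chirality) within `max_jump_mm`
#' is linked first; unmatched detections are births, unmatched trajectories
#' deaths.
#'
#' @param detections list of per-frame data.frames from [detect_ps()].
#' @param times frame times (ms).
#' @param max_jump_mm maximum inter-frame movement (default 5).
#' @return object of class `ps_trajectories`: data.frame with columns
#'   `id`, `t`, `element`, `chirality`, `x`, `y`, `z`, plus attribute
#'   `summary` (per-id birth, death, duration, chirality).
#' @export
track_ps <- function(detections, times, max_jump_mm = 5) {
  stopifnot(length(detections) == length(times))
  rows <- list()
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), chirality = numeric(0))
  next_id <- 1L
  for (k in seq_along(detections)) {
    det <- detections[[k]]
    assigned <- rep(NA_integer_, nrow(det))
    if (nrow(det) > 0 && nrow(active) > 0) {
      dmat <- outer(seq_len(nrow(det)), seq_len(nrow(active)),
                    Vectorize(function(a, b)
                      sqrt((det$x[a] - active$x[b])^2 +
                           (det$y[a] - active$y[b])^2 +
                           (det$z[a] - active$z[b])^2)))
      dmat[outer(det$chirality, active$chirality, "!=")] <- Inf
      while (TRUE) {
        mn <- which.min(dmat)
        if (length(mn) == 0 || !is.finite(dmat[mn])) break
        a <- (mn - 1) %% nrow(det) + 1
        b <- (mn - 1) %/% nrow(det) + 1
        if (dmat[mn] > max_jump_mm) break
        assigned[a] <- active$id[b]
        dmat[a, ] <- Inf; dmat[, b] <- Inf
      }
    }
    if (nrow(det) > 0) {
      births <- which(is.na(assigned))
      if (length(births) > 0) {
        assigned[births] <- next_id + seq_along(births) - 1L
        next_id <- next_id + length(births)
      }
      rows[[k]] <- cbind(data.frame(id = assigned, t = times[k]),
                         det[, c("element", "chirality", "x", "y", "z")])
      active <- data.frame(id = assigned, x = det$x, y = det$y, z = det$z,
                           chirality = det$chirality)
    } else {
      active <- active[0, ]
    }
  }
  traj <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), t = numeric(0), element = integer(0),
               chirality = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0))
  summ <- if (nrow(traj)) {
    ag <- do.call(rbind, lapply(split(traj, traj$id), function(d)
      data.frame(id = d$id[1], birth = min(d$t), death = max(d$t),
                 chirality = d$chirality[1])))
    ag$duration <- ag$death - ag$birth
    ag[order(ag$id), ]
  } else data.frame(id = integer(0), birth = numeric(0), death = numeric(0),
                    chirality = numeric(0), duration = numeric(0))
  structure(traj, class = c("ps_trajectories", "data.frame"),
            summary = summ)
}

#' Trajectory summary (birth, death, duration, chirality per id)
#' @param trajectories a `ps_trajectories`.
#' @return data.frame.
#' @export
trajectory_summary <- function(trajectories) attr(trajectories, "summary")

#' Classify rotors
#'
#' Trajectories persisting longer than `min_duration_ms` (default 120 ms,
#' below the shortest fibrillatory cycle length) are rotors.
#'
#' @param trajectories a `ps_trajectories`.
#' @param min_duration_ms rotor duration threshold.
#' @return integer vector of rotor trajectory ids.
#' @export
classify_rotors <- function(trajectories, min_duration_ms = 120) {
  s <- trajectory_summary(trajectories)
  s$id[s$duration > min_duration_ms]
}

#' Phase-singularity density map
#'
#' Counts PS occurrences per element over all frames, smooths with inverse
#' distance squared weighting within `radius_mm` (with an epsilon of one
#' mean squared edge length to bound the self-term), and normalizes the
#' result to a maximum of 1.
#'
#' @param trajectories a `ps_trajectories` (or data.frame with `element`).
#' @param mesh a `la_mesh`.
#' @param radius_mm smoothing radius (default 5).
#' @param ids optional subset of trajectory ids (e.g. rotors only).
#' @return object of class `density_map`: list with `density` (per element,
#'   max 1 when any PS present), `counts`, `radius_mm`.
#' @export
density_map <- function(trajectories, mesh, radius_mm = 5, ids = NULL) {
  m <- nrow(mesh$triangles)
  d <- trajectories
  if (!is.null(ids)) d <- d[d$id %in% ids, ]
  counts <- tabulate(d$element, nbins = m)
  if (sum(counts) == 0) {
    return(structure(list(density = numeric(m), counts = counts,
                          radius_mm = radius_mm), class = "density_map"))
  }
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  eps <- mean(mesh$edge_length)^2
  occ <- which(counts > 0)
  # grid binning over occupied elements for the radius query
  sm <- numeric(m)
  cell <- radius_mm
  gx <- floor(cent[, 1] / cell); gy <- floor(cent[, 2] / cell)
  key_occ <- paste(gx[occ], gy[occ])
  occ_by_cell <- split(occ, key_occ)
  for (i in seq_len(m)) {
    acc <- 0
    for (dxk in -1:1) for (dyk in -1:1) {
      cands <- occ_by_cell[[paste(gx[i] + dxk, gy[i] + dyk)]]
      if (is.null(cands)) next
      dd2 <- (cent[cands, 1] - cent[i, 1])^2 +
             (cent[cands, 2] - cent[i, 2])^2 +
             (cent[cands, 3] - cent[i, 3])^2
      inr <- dd2 <= radius_mm^2
      if (any(inr))
        acc <- acc + sum(counts[cands[inr]] / (dd2[inr] + eps))
    }
    sm[i] <- acc
  }
  structure(list(density = sm / max(sm), counts = counts,
                 radius_mm = radius_mm), class = "density_map")
}

#' Regional (per-subdivision) pAF statistics
#'
#' For each of the eight subdivisions: time mean and SD of the concurrent
#' PS count, mean concurrent rotor count, mean and minimum per-vertex
#' average activation cycle length, and normalized PS density (subdivision
#' mean of the smoothed density / max over subdivisions).
#'
#' @param trajectories a `ps_trajectories`.
#' @param rotor_ids rotor ids from [classify_rotors()].
#' @param recording the analyzed `tissue_recording` (for cycle lengths).
#' @param mesh a `la_mesh`.
#' @param dmap optional precomputed [density_map()].
#' @param t_start,t_end cycle-length analysis window.
#' @return data.frame with one row per subdivision.
#' @export
regional_stats <- function(trajectories, rotor_ids, recording, mesh,
                           dmap = NULL, t_start = -Inf, t_end = Inf) {
  if (is.null(mesh$subdivision)) stop("mesh lacks subdivision labels")
  if (is.null(dmap)) dmap <- density_map(trajectories, mesh)
  sub_of_el <- mesh$subdivision
  frames <- sort(unique(trajectories$t))
  nT <- max(1L, length(frames))
  count_mat <- matrix(0, nT, 8)
  rotor_mat <- matrix(0, nT, 8)
  if (nrow(trajectories) > 0) {
    fidx <- match(trajectories$t, frames)
    sidx <- sub_of_el[trajectories$element]
    for (r in seq_len(nrow(trajectories))) {
      count_mat[fidx[r], sidx[r]] <- count_mat[fidx[r], sidx[r]] + 1
      if (trajectories$id[r] %in% rotor_ids)
        rotor_mat[fidx[r], sidx[r]] <- rotor_mat[fidx[r], sidx[r]] + 1
    }
  }
  cl_node <- node_cycle_lengths(recording, t_start, t_end)
  # per-vertex average CL pooled into the subdivisions of adjacent elements
  node_sub <- rep(NA_integer_, nrow(mesh$nodes))
  node_sub[as.vector(mesh$triangles)] <-
    sub_of_el[rep(seq_len(nrow(mesh$triangles)), 3L)]
  ps_density <- vapply(1:8, function(s) {
    el <- sub_of_el == s
    if (!any(el)) 0 else mean(dmap$density[el])
  }, numeric(1))
  ps_density <- if (max(ps_density) > 0) ps_density / max(ps_density)
                else ps_density
  out <- data.frame(
    subdivision = 1:8,
    ps_mean = colMeans(count_mat),
    ps_sd = apply(count_mat, 2, sd),
    rotor_mean = colMeans(rotor_mat),
    cl_mean_ms = vapply(1:8, function(s) {
      v <- cl_node[which(node_sub == s)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    cl_min_ms = vapply(1:8, function(s) {
      v <- cl_node[which(node_sub == s)]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1)),
    ps_density = ps_density
  )
  out
}
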