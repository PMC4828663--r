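# Monodomain reaction-diffusion solver on triangulated surfaces: P1 finite
# element assembly with an anisotropic conductivity tensor per triangle,
# operator-split time stepping (Rush-Larsen ionic update + explicit
# diffusion, implemented in C++), lesion application, recordings and
# activation-time extraction.
#
# Units: mm, ms, mV. Conductivities are S/m; they are converted to an
# effective diffusion tensor D = sigma / (beta * Cm) with beta = 1400 1/cm
# and Cm = 1 uF/cm^2, giving D [mm^2/ms] = 0.7143 * sigma [S/m].

SIGMA_TO_D <- 1 / 1.4  # mm^2/ms per S/m

#' Conductivity field for a mesh
#'
#' Per-triangle longitudinal and transverse conductivities (S/m). Defaults
#' are calibrated so that a plane wave in non-fibrotic remodeled LA tissue
#' propagates at about 70 cm/s along fibers, with a 4:1 anisotropy ratio
#' (CV ratio about 2:1). A floor of 0.001 S/m is enforced everywhere;
#' ablated elements sit exactly at the floor.
#'
#' @param mesh a `la_mesh`.
#' @param sigma_l,sigma_t longitudinal/transverse conductivity (S/m).
#' @param floor_sm non-conducting floor (S/m).
#' @return object of class `conductivity_field`.
#' @export
conductivity_field <- function(mesh, sigma_l = 0.22, sigma_t = 0.055,
                               floor_sm = 0.001) {
  m <- nrow(mesh$triangles)
  structure(list(sigma_l = pmax(floor_sm, rep_len(sigma_l, m)),
                 sigma_t = pmax(floor_sm, rep_len(sigma_t, m)),
                 ablated = logical(m), floor_sm = floor_sm),
            class = "conductivity_field")
}

#' Apply an ablation lesion to a conductivity field
#'
#' Sets both conductivities of the lesion's elements to the non-conducting
#' floor (0.001 S/m) and flags them as ablated. Idempotent.
#'
#' @param conductivity a `conductivity_field`.
#' @param lesion a `lesion_set` (or integer triangle indices).
#' @return the modified `conductivity_field`.
#' @export
apply_lesion <- function(conductivity, lesion) {
  el <- if (inherits(lesion, "lesion_set")) lesion$elements else lesion
  if (length(el) == 0) {
    warning("empty lesion: no elements ablated")
    return(conductivity)
  }
  conductivity$sigma_l[el] <- conductivity$floor_sm
  conductivity$sigma_t[el] <- conductivity$floor_sm
  conductivity$ablated[el] <- TRUE
  conductivity
}

#' Assemble the discrete diffusion operator
#'
#' Linear (P1) finite-element stiffness and lumped-mass operators on the
#' surface with per-triangle tensor `D_l f f' + D_t (I - f f')` expressed in
#' each triangle's plane. No-flux boundaries are implicit; split edges
#' (duplicated nodes) carry no flux because they share no degrees of
#' freedom.
#'
#' @param mesh a `la_mesh`.
#' @param conductivity a `conductivity_field`.
#' @return list with `K` (sparse symmetric stiffness, mm^2/ms weighted),
#'   `M` (lumped mass per node, mm^2).
#' @export
assemble_diffusion <- function(mesh, conductivity) {
  tri <- mesh$triangles
  nod <- mesh$nodes
  m <- nrow(tri); n <- nrow(nod)
  p1 <- nod[tri[, 1], , drop = FALSE]
  e1 <- nod[tri[, 2], , drop = FALSE] - p1
  e2 <- nod[tri[, 3], , drop = FALSE] - p1
  l1 <- sqrt(rowSums(e1^2))
  t1 <- e1 / l1
  nr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(nr^2))          # 2 * area
  area <- a2 / 2
  if (any(area < 1e-12)) stop("degenerate triangle (area < 1e-12 mm^2)")
  nr <- nr / a2
  t2 <- cbind(nr[, 2] * t1[, 3] - nr[, 3] * t1[, 2],
              nr[, 3] * t1[, 1] - nr[, 1] * t1[, 3],
              nr[, 1] * t1[, 2] - nr[, 2] * t1[, 1])
  # local 2D coordinates of the three vertices: (0,0), (l1,0), (x3,y3)
  x3 <- rowSums(e2 * t1)
  y3 <- rowSums(e2 * t2)
  # P1 basis gradients in local coords; vertices P1=(0,0), P2=(l1,0),
  # P3=(x3,y3): grad lambda_i = ((y_{i+1}-y_{i+2}), (x_{i+2}-x_{i+1})) / 2A
  gx <- cbind(0 - y3, y3 - 0, 0 - 0) / a2
  gy <- cbind(x3 - l1, 0 - x3, l1 - 0) / a2
  # fiber in local frame
  fl1 <- rowSums(mesh$fiber * t1)
  fl2 <- rowSums(mesh$fiber * t2)
  fn <- sqrt(fl1^2 + fl2^2); fl1 <- fl1 / fn; fl2 <- fl2 / fn
  Dl <- SIGMA_TO_D * conductivity$sigma_l
  Dt <- SIGMA_TO_D * conductivity$sigma_t
  dxx <- Dl * fl1^2 + Dt * fl2^2
  dyy <- Dl * fl2^2 + Dt * fl1^2
  dxy <- (Dl - Dt) * fl1 * fl2
  ii <- jj <- xx <- vector("list", 9)
  q <- 0
  for (a in 1:3) for (b in 1:3) {
    q <- q + 1
    val <- area * (gx[, a] * (dxx * gx[, b] + dxy * gy[, b]) +
                   gy[, a] * (dxy * gx[, b] + dyy * gy[, b]))
    ii[[q]] <- tri[, a]; jj[[q]] <- tri[, b]; xx[[q]] <- val
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  M <- as.vector(Matrix::sparseMatrix(i = as.vector(tri),
                                      j = rep(1L, 3 * m),
                                      x = rep(area / 3, 3), dims = c(n, 1)))
  list(K = methods::as(K, "CsparseMatrix"), M = pmax(M, 1e-12))
}

#' Build a ready-to-simulate monodomain system
#'
#' Bundles mesh, conductivity, assembled operators and per-node ionic
#' region classes. Node classes follow triangle region labels with
#' precedence PV sleeve > appendage > LA body (mitral rim is electrically
#' LA body).
#'
#' @param mesh a `la_mesh`.
#' @param conductivity optional `conductivity_field` (defaults calibrated).
#' @param paf_remodeled build remodeled (TRUE) or baseline parameter sets.
#' @return object of class `monodomain_system`.
#' @export
monodomain_system <- function(mesh, conductivity = NULL,
                              paf_remodeled = TRUE) {
  if (is.null(conductivity)) conductivity <- conductivity_field(mesh)
  ops <- assemble_diffusion(mesh, conductivity)
  pv_labels <- mesh$config$ostia$label
  tri_class <- ifelse(mesh$region %in% pv_labels, "PV",
                      ifelse(mesh$region == "LAA", "LAA", "LA_body"))
  classes <- c("LA_body", "PV", "LAA")
  prec <- c(LA_body = 1, LAA = 2, PV = 3)
  n <- nrow(mesh$nodes)
  node_prec <- rep(1, n)
  for (cl in c("LAA", "PV")) {
    nn <- unique(as.vector(mesh$triangles[tri_class == cl, ]))
    node_prec[nn] <- pmax(node_prec[nn], prec[cl])
  }
  node_class <- classes[match(node_prec, prec)]
  params <- vapply(classes, function(cl)
    make_region_params(cl, paf_remodeled = paf_remodeled), numeric(7))
  structure(list(mesh = mesh, conductivity = conductivity, K = ops$K,
                 M = ops$M, params = params,
                 region_idx = match(node_class, classes) - 1L,
                 classes = classes, paf_remodeled = paf_remodeled),
            class = "monodomain_system")
}

#' Rebuild operators after a conductivity change (e.g. lesions)
#' @param system a `monodomain_system`.
#' @param conductivity the new `conductivity_field`.
#' @return the updated system.
#' @export
update_conductivity <- function(system, conductivity) {
  ops <- assemble_diffusion(system$mesh, conductivity)
  system$conductivity <- conductivity
  system$K <- ops$K
  system$M <- ops$M
  system
}

#' Initial tissue state (all nodes at the resting state)
#' @param system a `monodomain_system`.
#' @return n x 21 state matrix.
#' @export
init_tissue_state <- function(system) {
  y0 <- cpp_crn_initial_state()
  matrix(rep(as.numeric(y0), each = nrow(system$mesh$nodes)),
         nrow = nrow(system$mesh$nodes))
}

#' Stimulus descriptor
#' @param start_ms onset time; @param dur_ms duration;
#' @param amp_papf current density (pA/pF, depolarizing negative);
#' @param nodes node indices.
#' @return list usable in `simulate_tissue(stimuli=)`.
#' @export
stimulus <- function(start_ms, nodes, dur_ms = 2, amp_papf = -30) {
  if (length(nodes) == 0) stop("stimulus with no nodes")
  list(start = start_ms, dur = dur_ms, amp = amp_papf,
       nodes = as.integer(nodes))
}

#' Run the monodomain solver
#'
#' Operator-split integration: Rush-Larsen/forward-Euler ionic update then
#' explicit diffusion, at a fixed time step. Voltage frames are recorded at
#' `record_dt` intervals.
#'
#' @param system a `monodomain_system`.
#' @param state n x 21 state matrix (see [init_tissue_state()]).
#' @param t0,t_end simulation window (ms).
#' @param stimuli list of [stimulus()] entries (times absolute).
#' @param dt_ms time step (ms, default 0.02).
#' @param record_dt frame interval (ms, default 1).
#' @param use_table use tabulated voltage-dependent kinetics (default TRUE;
#'   exact kinetics available for verification).
#' @return object of class `tissue_recording`: list with `times`, `frames`
#'   (n x n_frames Vm in mV), `state` (final), `stim_times`, `dt`, `ok`.
#' @export
simulate_tissue <- function(system, state, t0, t_end, stimuli = list(),
                            dt_ms = 0.02, record_dt = 1, use_table = TRUE) {
  stopifnot(inherits(system, "monodomain_system"))
  if (t_end <= t0) stop("t_end must exceed t0")
  ns <- length(stimuli)
  spec <- matrix(0, ns, 3)
  nds <- vector("list", max(1, ns))
  if (ns > 0) for (q in seq_len(ns)) {
    spec[q, ] <- c(stimuli[[q]]$start, stimuli[[q]]$dur, stimuli[[q]]$amp)
    nds[[q]] <- stimuli[[q]]$nodes
  } else nds <- list()
  K <- system$K
  r <- cpp_run_tissue(state, system$params, system$region_idx, K@p, K@i,
                      K@x, system$M, dt_ms, t0, t_end, spec, nds, record_dt,
                      use_table)
  if (!r$ok) warning("simulation aborted (non-finite Vm) at t=", r$t_bad)
  structure(list(times = r$times, frames = r$frames, state = r$state,
                 stim_times = if (ns) spec[, 1] else numeric(0), dt = dt_ms,
                 record_dt = record_dt, ok = r$ok),
            class = "tissue_recording")
}

#' Upward threshold crossings per node
#'
#' Linear-interpolated times at which each node's Vm crosses the threshold
#' from below.
#'
#' @param recording a `tissue_recording` (or list with `times`, `frames`).
#' @param threshold_mv threshold (default -40 mV).
#' @return list of numeric vectors (one per node).
#' @export
upstroke_times <- function(recording, threshold_mv = -40) {
  A <- recording$frames
  tt <- recording$times
  nT <- ncol(A)
  cross <- A[, -nT, drop = FALSE] <= threshold_mv &
    A[, -1, drop = FALSE] > threshold_mv
  idx <- which(cross, arr.ind = TRUE)
  out <- vector("list", nrow(A))
  if (nrow(idx) > 0) {
    v0 <- A[cbind(idx[, 1], idx[, 2])]
    v1 <- A[cbind(idx[, 1], idx[, 2] + 1L)]
    tc <- tt[idx[, 2]] + (threshold_mv - v0) / (v1 - v0) *
      (tt[idx[, 2] + 1L] - tt[idx[, 2]])
    sp <- split(tc, idx[, 1])
    out[as.integer(names(sp))] <- lapply(sp, sort)
  }
  out
}

#' Local activation times
#'
#' First upward crossing of the threshold after a blanking time; nodes that
#' never cross are NA (unactivated).
#'
#' @param recording a `tissue_recording`.
#' @param threshold_mv activation threshold (default -40 mV).
#' @param blank_ms ignore crossings before this time.
#' @return object of class `activation_map`: list with `lat` (ms per node,
#'   NA when unactivated), `crossings` (all per-node crossing times),
#'   `threshold_mv`.
#' @export
activation_times <- function(recording, threshold_mv = -40, blank_ms = -Inf) {
  cr <- upstroke_times(recording, threshold_mv)
  lat <- vapply(cr, function(v) {
    v <- v[v >= blank_ms]
    if (length(v) == 0) NA_real_ else v[1]
  }, numeric(1))
  structure(list(lat = lat, crossings = cr, threshold_mv = threshold_mv),
            class = "activation_map")
}

#' Per-node mean activation cycle length
#'
#' Mean interval between successive threshold upstrokes within a window.
#'
#' @param recording a `tissue_recording`.
#' @param t_start,t_end analysis window (ms).
#' @param threshold_mv threshold (default -40).
#' @param min_beats minimum number of intervals required (else NA).
#' @return numeric vector (ms per node).
#' @export
node_cycle_lengths <- function(recording, t_start = -Inf, t_end = Inf,
                               threshold_mv = -40, min_beats = 2) {
  cr <- upstroke_times(recording, threshold_mv)
  vapply(cr, function(v) {
    v <- v[v >= t_start & v <= t_end]
    if (length(v) < min_beats + 1) return(NA_real_)
    mean(diff(v))
  }, numeric(1))
}

#' Couple two node-matched layers resistively
#'
#' Builds a two-layer system whose layers exchange current through
#' node-wise resistive links: `dV_a += g_link * (V_b - V_a)` (g_link in
#' 1/ms). With strong coupling the layers behave as a monolayer.
#'
#' @param sys_a,sys_b `monodomain_system`s over meshes with equal node
#'   counts (e.g. endocardial/epicardial copies).
#' @param g_link link conductance (1/ms); must satisfy explicit-stepping
#'   stability (`g_link * dt < 1`).
#' @return a `monodomain_system` over the stacked 2n-node system.
#' @export
couple_layers <- function(sys_a, sys_b, g_link) {
  na <- nrow(sys_a$mesh$nodes); nb <- nrow(sys_b$mesh$nodes)
  if (na != nb) stop("layers must have matching node counts")
  K <- Matrix::bdiag(sys_a$K, sys_b$K)
  M <- c(sys_a$M, sys_b$M)
  if (g_link > 0) {
    i0 <- seq_len(na)
    L <- Matrix::sparseMatrix(
      i = c(i0, i0, i0 + na, i0 + na),
      j = c(i0, i0 + na, i0 + na, i0),
      x = c(g_link * sys_a$M, -g_link * sys_a$M,
            g_link * sys_b$M, -g_link * sys_b$M),
      dims = c(2 * na, 2 * na))
    K <- K + L
  }
  structure(list(mesh = list(a = sys_a$mesh, b = sys_b$mesh),
                 conductivity = list(a = sys_a$conductivity,
                                     b = sys_b$conductivity),
                 K = methods::as(K, "CsparseMatrix"), M = M,
                 params = sys_a$params,
                 region_idx = c(sys_a$region_idx, sys_b$region_idx),
                 classes = sys_a$classes, two_layer = TRUE,
                 g_link = g_link,
                 paf_remodeled = sys_a$paf_remodeled),
            class = "monodomain_system")
}

#' @export
print.tissue_recording <- function(x, ...) {
  cat("tissue_recording:", nrow(x$frames), "nodes x", ncol(x$frames),
      "frames (", min(x$times), "-", max(x$times), "ms, every",
      x$record_dt, "ms)\n")
  invisible(x)
}
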