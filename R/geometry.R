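# Synthetic left-atrial surface geometry: triangulated sheet (optionally a
# gentle dome) with four pulmonary-vein ostium holes, a mitral (outer)
# boundary, a per-triangle fiber field with an abrupt ~90 degree rotation in
# a band around each ostium, region labels and eight analysis subdivisions.

#' Geometry configuration for the synthetic left atrium
#'
#' Default geometry is a 50 x 50 mm monolayer sheet at 0.5 mm mean edge
#' length with four circular PV ostia (two per posterior/anterior half),
#' an appendage patch and the outer rectangle standing in for the mitral
#' annulus. All lengths are millimetres.
#'
#' @param size_mm numeric(2), sheet extent in x and y.
#' @param edge_length_mm target mean edge length of the triangulation.
#' @param ostia data.frame with columns `label`, `x`, `y`, `radius` for the
#'   four PV ostium holes.
#' @param sleeve_width_mm width of the PV sleeve band (PV ionic parameters)
#'   around each ostium rim.
#' @param fiber_angle base fiber angle (radians, in the sheet plane).
#' @param fiber_rot_band_mm width of the band around each ostium over which
#'   the fiber direction is rotated by 90 degrees.
#' @param laa_center,laa_radius_mm centre and radius of the left atrial
#'   appendage patch (region label only; no hole).
#' @param dome_height_mm if positive, the sheet is bent into a paraboloid
#'   cap of this apex height (a curved-shell variant of the geometry).
#' @param seed integer seed recorded with the mesh (geometry construction is
#'   deterministic; the seed is metadata for downstream stochastic steps).
#' @return a list of class `la_geometry_config`.
#' @export
la_geometry_config <- function(size_mm = c(50, 50),
                               edge_length_mm = 0.5,
                               ostia = NULL,
                               sleeve_width_mm = 3,
                               fiber_angle = 0,
                               fiber_rot_band_mm = 2,
                               laa_center = c(30, 43),
                               laa_radius_mm = 3,
                               dome_height_mm = 0,
                               seed = 1L) {
  if (is.null(ostia)) {
    ostia <- data.frame(
      label = c("RSPV", "LSPV", "RIPV", "LIPV"),
      x = c(37.5, 12.5, 37.5, 12.5) / 50 * size_mm[1],
      y = c(37.5, 37.5, 12.5, 12.5) / 50 * size_mm[2],
      radius = 4,
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(size_mm = size_mm, edge_length_mm = edge_length_mm,
              ostia = ostia, sleeve_width_mm = sleeve_width_mm,
              fiber_angle = fiber_angle, fiber_rot_band_mm = fiber_rot_band_mm,
              laa_center = laa_center, laa_radius_mm = laa_radius_mm,
              dome_height_mm = dome_height_mm, seed = as.integer(seed))
  class(cfg) <- "la_geometry_config"
  cfg
}

#' Build the synthetic left-atrial surface mesh
#'
#' Generates a structured triangulation of the configured sheet, cuts the
#' four PV ostium holes, assigns per-triangle fibers (base direction with a
#' 90 degree rotation inside a band of width `fiber_rot_band_mm` around each
#' ostium), labels regions (`LA_body`, PV sleeves, `LAA`, `mitral_rim`) and
#' the eight analysis subdivisions, and extracts ordered boundary loops.
#'
#' @param config a [la_geometry_config()].
#' @return an object of class `la_mesh`: list with `nodes` (n x 3, mm),
#'   `triangles` (m x 3 node indices, counter-clockwise), `edges` (E x 2),
#'   `edge_length` (mm), `edge_tri` (E x 2 adjacent triangles, NA at
#'   boundary), `fiber` (m x 3 unit vectors), `region` (character per
#'   triangle), `subdivision` (integer 1-8 per triangle), `boundary_loops`
#'   (named list of ordered node vectors, one per ostium plus `mitral`),
#'   `config`.
#' @export
build_la_surface <- function(config = la_geometry_config()) {
  stopifnot(inherits(config, "la_geometry_config"))
  if (config$edge_length_mm <= 0) stop("edge-length target must be positive")
  ost <- config$ostia
  # ostia must not overlap each other or touch the outer boundary
  for (i in seq_len(nrow(ost))) {
    oi <- ost[i, ]
    if (oi$x - oi$radius <= 0 || oi$x + oi$radius >= config$size_mm[1] ||
        oi$y - oi$radius <= 0 || oi$y + oi$radius >= config$size_mm[2])
      stop("ostium '", oi$label, "' touches the domain boundary")
    if (i < nrow(ost)) for (j in (i + 1):nrow(ost)) {
      d <- sqrt((oi$x - ost$x[j])^2 + (oi$y - ost$y[j])^2)
      if (d <= oi$radius + ost$radius[j] + config$fiber_rot_band_mm)
        stop("ostia '", oi$label, "' and '", ost$label[j], "' overlap")
    }
  }

  # grid spacing chosen so that the mean edge length (two axis-aligned edges
  # and one diagonal per cell pair) matches the configured target
  s <- config$edge_length_mm * 3 / (2 + sqrt(2))
  nx <- max(3L, round(config$size_mm[1] / s) + 1L)
  ny <- max(3L, round(config$size_mm[2] / s) + 1L)
  xs <- seq(0, config$size_mm[1], length.out = nx)
  ys <- seq(0, config$size_mm[2], length.out = ny)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)

  idx <- function(i, j) (j - 1L) * nx + i  # i along x, j along y
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  alt <- (i + j) %% 2L == 0L
  # alternate the cell diagonal for isotropy; both triangles CCW in xy
  t1 <- ifelse(rep(alt, 3L), c(a, b, c), c(a, b, d))
  t2 <- ifelse(rep(alt, 3L), c(a, c, d), c(b, c, d))
  tri <- rbind(matrix(t1, ncol = 3L), matrix(t2, ncol = 3L))

  # dome option: lift into a paraboloid cap, keeping (x, y)
  if (config$dome_height_mm > 0) {
    cx <- config$size_mm[1] / 2; cy <- config$size_mm[2] / 2
    r2 <- (nodes[, 1] - cx)^2 + (nodes[, 2] - cy)^2
    nodes[, 3] <- config$dome_height_mm * (1 - r2 / (cx^2 + cy^2))
  }

  # cut ostium holes by centroid-in-disc
  cent <- triangle_centroids(nodes, tri)
  keep <- rep(TRUE, nrow(tri))
  for (k in seq_len(nrow(ost))) {
    dk <- sqrt((cent[, 1] - ost$x[k])^2 + (cent[, 2] - ost$y[k])^2)
    keep <- keep & dk > ost$radius[k]
  }
  tri <- tri[keep, , drop = FALSE]

  # drop isolated nodes, remap indices
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3L)

  mesh <- structure(list(nodes = nodes, triangles = tri, config = config),
                    class = "la_mesh")
  mesh <- rebuild_mesh_topology(mesh)

  # region labels
  cent <- triangle_centroids(nodes, tri)
  region <- rep("LA_body", nrow(tri))
  for (k in seq_len(nrow(ost))) {
    dk <- sqrt((cent[, 1] - ost$x[k])^2 + (cent[, 2] - ost$y[k])^2)
    region[dk <= ost$radius[k] + config$sleeve_width_mm] <- ost$label[k]
  }
  dl <- sqrt((cent[, 1] - config$laa_center[1])^2 +
             (cent[, 2] - config$laa_center[2])^2)
  region[dl <= config$laa_radius_mm & region == "LA_body"] <- "LAA"
  brim <- pmin(cent[, 1], config$size_mm[1] - cent[, 1],
               cent[, 2], config$size_mm[2] - cent[, 2])
  region[brim <= config$edge_length_mm & region == "LA_body"] <- "mitral_rim"
  mesh$region <- region

  # fibers: base direction, rotated 90 degrees inside the ostium bands,
  # projected into each triangle's plane
  ang <- rep(config$fiber_angle, nrow(tri))
  for (k in seq_len(nrow(ost))) {
    dk <- sqrt((cent[, 1] - ost$x[k])^2 + (cent[, 2] - ost$y[k])^2)
    inband <- dk <= ost$radius[k] + config$fiber_rot_band_mm
    ang[inband] <- config$fiber_angle + pi / 2
  }
  u <- cbind(cos(ang), sin(ang), 0)
  nrm <- triangle_normals(nodes, tri)
  proj <- u - nrm * rowSums(u * nrm)
  len <- sqrt(rowSums(proj^2))
  bad <- len < 1e-8
  if (any(bad)) {  # fiber parallel to normal: fall back to first edge direction
    e <- nodes[tri[bad, 2], , drop = FALSE] - nodes[tri[bad, 1], , drop = FALSE]
    proj[bad, ] <- e; len[bad] <- sqrt(rowSums(e^2))
  }
  mesh$fiber <- proj / len

  mesh <- assign_subdivisions(mesh)
  mesh <- identify_boundary_loops(mesh)
  mesh
}

#' Assign the eight analysis subdivisions
#'
#' Posterior half (lower half of the sheet) is split into subdivisions 1-4
#' by x-quartile; the anterior half into 5-8. Idempotent.
#'
#' @param mesh a `la_mesh`.
#' @return the mesh with an updated integer `subdivision` field.
#' @export
assign_subdivisions <- function(mesh) {
  stopifnot(inherits(mesh, "la_mesh"))
  cfg <- mesh$config
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  anterior <- cent[, 2] >= cfg$size_mm[2] / 2
  qx <- pmin(3L, pmax(0L, floor(cent[, 1] / (cfg$size_mm[1] / 4))))
  mesh$subdivision <- as.integer(1L + qx + ifelse(anterior, 4L, 0L))
  mesh
}

# ---- mesh internals --------------------------------------------------------

triangle_centroids <- function(nodes, tri) {
  (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
     nodes[tri[, 3], , drop = FALSE]) / 3
}

triangle_normals <- function(nodes, tri) {
  e1 <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  e2 <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Triangle areas of a mesh (mm^2)
#' @param mesh a `la_mesh`.
#' @return numeric vector, one area per triangle.
#' @export
triangle_areas <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$triangles
  e1 <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  e2 <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

# Recompute edges, edge lengths and edge-triangle adjacency from triangles.
rebuild_mesh_topology <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri)
  ek <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
              cbind(tri[, 3], tri[, 1]))
  ek_s <- cbind(pmin(ek[, 1], ek[, 2]), pmax(ek[, 1], ek[, 2]))
  key <- ek_s[, 1] * (max(tri) + 1) + ek_s[, 2]
  tri_of <- rep(seq_len(m), times = 3L)
  o <- order(key)
  key_o <- key[o]; tri_o <- tri_of[o]
  first <- !duplicated(key_o)
  eid_o <- cumsum(first)
  E <- eid_o[length(eid_o)]
  edges <- ek_s[o[first], , drop = FALSE]
  if (any(tabulate(eid_o, E) > 2L))
    stop("non-manifold edge (more than two triangles)")
  edge_tri <- matrix(NA_integer_, nrow = E, ncol = 2L)
  edge_tri[eid_o[first], 1L] <- tri_o[first]
  dup <- !first
  edge_tri[eid_o[dup], 2L] <- tri_o[dup]
  mesh$edges <- edges
  mesh$edge_length <- sqrt(rowSums((mesh$nodes[edges[, 1], , drop = FALSE] -
                                    mesh$nodes[edges[, 2], , drop = FALSE])^2))
  mesh$edge_tri <- edge_tri
  mesh
}

# Identify and order boundary loops; label each as an ostium or the mitral
# opening by proximity of the loop centroid to the configured ostium centres.
identify_boundary_loops <- function(mesh) {
  be <- which(is.na(mesh$edge_tri[, 2]))
  if (length(be) == 0) { mesh$boundary_loops <- list(); return(mesh) }
  ed <- mesh$edges[be, , drop = FALSE]
  verts <- sort(unique(as.vector(ed)))
  vid <- match(ed, verts); dim(vid) <- dim(ed)
  adj <- vector("list", length(verts))
  for (r in seq_len(nrow(vid))) {
    adj[[vid[r, 1]]] <- c(adj[[vid[r, 1]]], vid[r, 2])
    adj[[vid[r, 2]]] <- c(adj[[vid[r, 2]]], vid[r, 1])
  }
  seen <- logical(length(verts))
  loops <- list()
  for (v0 in seq_along(verts)) {
    if (seen[v0]) next
    # walk the cycle if degrees are all 2 within this component
    ord <- integer(0); cur <- v0; prev <- 0L
    repeat {
      ord <- c(ord, cur); seen[cur] <- TRUE
      nb <- adj[[cur]]
      nxt <- nb[nb != prev & !seen[nb]]
      if (length(nxt) == 0) break
      prev <- cur; cur <- nxt[1]
    }
    loops[[length(loops) + 1L]] <- verts[ord]
  }
  # label loops
  ost <- mesh$config$ostia
  nm <- character(length(loops))
  cent <- t(vapply(loops, function(l) colMeans(mesh$nodes[l, , drop = FALSE]),
                   numeric(3)))
  for (k in seq_len(nrow(ost))) {
    d <- sqrt((cent[, 1] - ost$x[k])^2 + (cent[, 2] - ost$y[k])^2)
    best <- which.min(d)
    if (d[best] < 2 * ost$radius[k]) nm[best] <- ost$label[k]
  }
  nm[nm == ""] <- c("mitral", paste0("loop", seq_len(sum(nm == ""))))[
    seq_len(sum(nm == ""))]
  names(loops) <- nm
  mesh$boundary_loops <- loops
  mesh
}

#' Validate structural invariants of a mesh
#'
#' Checks manifoldness (every edge borders one or two triangles), absence of
#' duplicate triangles and isolated nodes, unit in-plane fibers, and that the
#' Euler characteristic V - E + F equals 2 - 2g - b for genus g = 0 with b
#' boundary loops.
#'
#' @param mesh a `la_mesh`.
#' @param check_euler logical; skip for split meshes whose slit loops are not
#'   tracked as boundary loops.
#' @return invisibly TRUE; stops with a message on violation.
#' @export
validate_mesh <- function(mesh, check_euler = TRUE) {
  tri <- mesh$triangles
  key <- apply(tri, 1, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate triangles")
  if (length(setdiff(seq_len(nrow(mesh$nodes)), unique(as.vector(tri)))) > 0)
    stop("isolated nodes")
  nt <- rowSums(!is.na(mesh$edge_tri))
  if (!all(nt %in% c(1L, 2L))) stop("non-manifold edges")
  if (!is.null(mesh$fiber)) {
    nrm <- triangle_normals(mesh$nodes, tri)
    if (max(abs(rowSums(mesh$fiber * nrm))) > 1e-9)
      stop("fibers not in triangle plane")
    if (max(abs(sqrt(rowSums(mesh$fiber^2)) - 1)) > 1e-9)
      stop("fibers not unit length")
  }
  if (check_euler && !is.null(mesh$boundary_loops)) {
    chi <- nrow(mesh$nodes) - nrow(mesh$edges) + nrow(tri)
    if (chi != 2 - length(mesh$boundary_loops))
      stop("Euler characteristic inconsistent with boundary loop count")
  }
  invisible(TRUE)
}

#' Plain rectangular sheet mesh (no ostia)
#'
#' Convenience wrapper over [build_la_surface()] with an empty ostium table:
#' a uniform fibrotic-free sheet used for conduction-velocity calibration,
#' refinement studies and spiral-wave experiments.
#'
#' @param size_mm numeric(2) sheet extent.
#' @param edge_length_mm target mean edge length.
#' @param fiber_angle base fiber angle (radians).
#' @return a `la_mesh`.
#' @export
sheet_mesh <- function(size_mm = c(50, 50), edge_length_mm = 0.5,
                       fiber_angle = 0) {
  cfg <- la_geometry_config(size_mm = size_mm,
                            edge_length_mm = edge_length_mm,
                            ostia = data.frame(label = character(0),
                                               x = numeric(0), y = numeric(0),
                                               radius = numeric(0)),
                            fiber_angle = fiber_angle,
                            laa_center = c(-100, -100), laa_radius_mm = 0)
  build_la_surface(cfg)
}

#' Nodes within a disc of a point (surface distance approximated by ambient)
#' @param mesh a `la_mesh`.
#' @param center numeric(2) or (3) position (mm).
#' @param radius_mm disc radius.
#' @return integer node indices.
#' @export
nodes_near <- function(mesh, center, radius_mm = 1) {
  if (length(center) == 2) center <- c(center, 0)
  d <- sqrt((mesh$nodes[, 1] - center[1])^2 + (mesh$nodes[, 2] - center[2])^2)
  which(d <= radius_mm)
}

#' Nodes of a PV sleeve (by region label of adjacent triangles)
#' @param mesh a `la_mesh`.
#' @param pv one of the configured ostium labels.
#' @return integer node indices.
#' @export
pv_sleeve_nodes <- function(mesh, pv) {
  if (!pv %in% mesh$region) stop("unknown PV label '", pv, "'")
  sort(unique(as.vector(mesh$triangles[mesh$region == pv, ])))
}

#' @export
print.la_mesh <- function(x, ...) {
  cat("la_mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles), "triangles,",
      nrow(x$edges), "edges,", length(x$boundary_loops), "boundary loops\n")
  cat("  mean edge length:", round(mean(x$edge_length), 4), "mm\n")
  cat("  regions:", paste(names(table(x$region)), collapse = ", "), "\n")
  invisible(x)
}
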