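# Construction of radiofrequency-ablation lesion geometries on the mesh:
# PV isolation rings, geodesic (roof / mitral) lines, parameterized shapes
# (circle, perforated circle, line, cross) placed by PS density, and
# activation-sequence streamlining lines following the sinus LAT gradient.

new_lesion_set <- function(name, shape, elements, center = c(NA, NA, NA),
                           size_cm = NA, width_mm = NA) {
  structure(list(name = name, shape = shape,
                 elements = sort(unique(as.integer(elements))),
                 center = center, size_cm = size_cm, width_mm = width_mm),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("lesion_set '", x$name, "' (", x$shape, "): ", length(x$elements),
      " elements\n", sep = "")
  invisible(x)
}

# node-sharing connectivity among a subset of triangles; returns membership
# for the subset (NA elsewhere)
subset_components <- function(mesh, keep) {
  tri <- mesh$triangles[keep, , drop = FALSE]
  memb <- rep(NA_integer_, nrow(mesh$triangles))
  if (nrow(tri) == 0) return(memb)
  memb[keep] <- tri_component_membership_local(tri)
  memb
}
tri_component_membership_local <- function(tri) {
  m <- nrow(tri)
  n <- max(tri)
  el <- cbind(rep(seq_len(m), 3L), as.vector(tri) + m)
  g <- igraph::make_graph(edges = as.vector(t(el)), n = m + n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  as.integer(factor(memb[seq_len(m)]))
}

#' Pulmonary-vein isolation ring
#'
#' A closed band of elements encircling the ostium, verified to
#' disconnect the PV sleeve from the LA body (no conducting path among
#' non-lesion elements).
#'
#' @param mesh a `la_mesh`.
#' @param pv ostium label (e.g. "RSPV").
#' @param width_mm band width (> 0; default 2).
#' @param margin_mm gap between the sleeve band and the lesion (default:
#'   just outside the sleeve).
#' @return a `lesion_set`.
#' @export
pvi_ring <- function(mesh, pv, width_mm = 2, margin_mm = NULL) {
  if (width_mm <= 0) stop("lesion width must be positive")
  ost <- mesh$config$ostia
  k <- match(pv, ost$label)
  if (is.na(k)) stop("unknown PV label '", pv, "'")
  if (is.null(margin_mm)) margin_mm <- mesh$config$sleeve_width_mm
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  d <- sqrt((cent[, 1] - ost$x[k])^2 + (cent[, 2] - ost$y[k])^2)
  r0 <- ost$radius[k] + margin_mm
  el <- which(d >= r0 & d <= r0 + width_mm)
  les <- new_lesion_set(paste0("PVI_", pv), "pvi_ring", el,
                        c(ost$x[k], ost$y[k], NA), NA, width_mm)
  chk <- pvi_isolates(mesh, les, pv)
  if (!chk$isolated)
    stop("PVI ring around ", pv, " is not closed (conducting gap remains)")
  les
}

# does the lesion disconnect the sleeve from the LA body?
pvi_isolates <- function(mesh, lesion, pv) {
  keep <- setdiff(seq_len(nrow(mesh$triangles)), lesion$elements)
  memb <- subset_components(mesh, keep)
  sleeve <- intersect(which(mesh$region == pv), keep)
  body <- intersect(which(mesh$region == "LA_body"), keep)
  if (length(sleeve) == 0 || length(body) == 0)
    return(list(isolated = TRUE))
  list(isolated = length(intersect(unique(memb[sleeve]),
                                   unique(memb[body]))) == 0)
}

#' Geodesic line lesion
#'
#' Elements within `width_mm / 2` of the shortest surface path between two
#' points (Dijkstra over the mesh edge graph). Used for roof and mitral
#' lines.
#'
#' @param mesh a `la_mesh`.
#' @param p_start,p_end numeric(2) endpoints (mm).
#' @param width_mm band width.
#' @param name lesion name.
#' @return a `lesion_set` with attribute `path` (node indices).
#' @export
geodesic_line <- function(mesh, p_start, p_end, width_mm = 2,
                          name = "line") {
  if (width_mm <= 0) stop("lesion width must be positive")
  n1 <- which.min((mesh$nodes[, 1] - p_start[1])^2 +
                  (mesh$nodes[, 2] - p_start[2])^2)
  n2 <- which.min((mesh$nodes[, 1] - p_end[1])^2 +
                  (mesh$nodes[, 2] - p_end[2])^2)
  g <- igraph::make_graph(edges = as.vector(t(mesh$edges)),
                          n = nrow(mesh$nodes), directed = FALSE)
  sp <- igraph::shortest_paths(g, from = n1, to = n2,
                               weights = mesh$edge_length)
  path <- as.integer(sp$vpath[[1]])
  if (length(path) == 0) stop("endpoints are not connected on the mesh")
  pts <- mesh$nodes[path, , drop = FALSE]
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  d <- dist_to_polyline(cent, pts)
  el <- which(d <= pmax(width_mm / 2, 0.51 * mean(mesh$edge_length)))
  les <- new_lesion_set(name, "line", el, c(NA, NA, NA), NA, width_mm)
  attr(les, "path") <- path
  attr(les, "path_length_mm") <- sum(sqrt(rowSums(diff(pts)^2)))
  les
}

# distance from points (q x 3) to a polyline (p x 3)
dist_to_polyline <- function(pts, poly) {
  d <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 < 1e-12) next
    tpar <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
             (pts[, 3] - a[3]) * ab[3]) / L2
    tpar <- pmin(1, pmax(0, tpar))
    dx <- pts[, 1] - (a[1] + tpar * ab[1])
    dy <- pts[, 2] - (a[2] + tpar * ab[2])
    dz <- pts[, 3] - (a[3] + tpar * ab[3])
    d <- pmin(d, sqrt(dx^2 + dy^2 + dz^2))
  }
  d
}

#' Parameterized small lesion shapes
#'
#' Circle: closed annular band of the given diameter. Perforated circle:
#' the same with `n_gaps` symmetric gaps of `gap_mm` arc length (wavefront
#' penetration prevents the lesion from becoming an anatomical obstacle).
#' Line: straight band of the given length. Cross: two orthogonal lines
#' sharing the centre.
#'
#' @param mesh a `la_mesh`.
#' @param center numeric(2) lesion centre (mm).
#' @param shape one of "circle", "perforated_circle", "line", "cross".
#' @param size_cm diameter / length in cm, in `[0.5, 1.5]`.
#' @param width_mm band width (default 2).
#' @param n_gaps,gap_mm perforation layout (defaults 4 gaps of 2 mm).
#' @param angle line orientation (radians; default 0).
#' @return a `lesion_set`.
#' @export
lesion_shape <- function(mesh, center, shape = c("circle",
                                                 "perforated_circle",
                                                 "line", "cross"),
                         size_cm, width_mm = 2, n_gaps = 4, gap_mm = 2,
                         angle = 0) {
  shape <- match.arg(shape)
  if (size_cm < 0.5 - 1e-9 || size_cm > 1.5 + 1e-9)
    stop("size must lie in [0.5, 1.5] cm")
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  dx <- cent[, 1] - center[1]; dy <- cent[, 2] - center[2]
  size_mm <- size_cm * 10
  half_w <- pmax(width_mm / 2, 0.51 * mean(mesh$edge_length))
  el <- switch(shape,
    circle = ,
    perforated_circle = {
      r <- sqrt(dx^2 + dy^2)
      ring <- abs(r - size_mm / 2) <= half_w
      if (shape == "perforated_circle") {
        th <- atan2(dy, dx) %% (2 * pi)
        gap_half_angle <- (gap_mm / 2) / (size_mm / 2)
        centers <- (seq_len(n_gaps) - 1) * 2 * pi / n_gaps
        ingap <- rep(FALSE, length(th))
        for (gc in centers) {
          dang <- abs(((th - gc + pi) %% (2 * pi)) - pi)
          ingap <- ingap | dang <= gap_half_angle
        }
        ring <- ring & !ingap
      }
      which(ring)
    },
    line = {
      u <- dx * cos(angle) + dy * sin(angle)
      v <- -dx * sin(angle) + dy * cos(angle)
      which(abs(u) <= size_mm / 2 & abs(v) <= half_w)
    },
    cross = {
      u <- dx * cos(angle) + dy * sin(angle)
      v <- -dx * sin(angle) + dy * cos(angle)
      which((abs(u) <= size_mm / 2 & abs(v) <= half_w) |
            (abs(v) <= size_mm / 2 & abs(u) <= half_w))
    })
  if (length(el) == 0) stop("lesion lies entirely off-mesh")
  # clipping warning if part of the ideal footprint is off-mesh
  r_out <- sqrt((center[1] - pmin(pmax(center[1], 0),
                                  mesh$config$size_mm[1]))^2)
  if (center[1] - size_mm / 2 < 0 ||
      center[1] + size_mm / 2 > mesh$config$size_mm[1] ||
      center[2] - size_mm / 2 < 0 ||
      center[2] + size_mm / 2 > mesh$config$size_mm[2])
    warning("lesion footprint clipped at the mesh boundary")
  new_lesion_set(paste0(shape, "_", size_cm, "cm"), shape, el,
                 c(center, 0), size_cm, width_mm)
}

#' Placement of a lesion by PS density
#'
#' Centroid of the maximum-density element within a subdivision; ties break
#' to the lowest element index. An all-zero density yields the subdivision
#' geometric centroid with a warning.
#'
#' @param dmap a `density_map`.
#' @param mesh a `la_mesh`.
#' @param subdivision subdivision number (1-8).
#' @return numeric(2) centre (mm).
#' @export
place_by_density <- function(dmap, mesh, subdivision) {
  el <- which(mesh$subdivision == subdivision)
  if (length(el) == 0) stop("empty subdivision")
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  dens <- dmap$density[el]
  if (max(dens) <= 0) {
    warning("all-zero PS density in subdivision ", subdivision,
            "; using its geometric centroid")
    return(colMeans(cent[el, 1:2, drop = FALSE]))
  }
  best <- el[which.max(dens)]  # which.max returns the first (lowest) index
  cent[best, 1:2]
}

#' Streamlining lesion lines along the sinus activation sequence
#'
#' Seeds are spaced evenly (by arc length) along the isochrone 10 ms after
#' the earliest LA activation; each line follows the gradient of the local
#' activation time field (fixed 0.5 mm steps, barycentric interpolation)
#' until it reaches the mitral (outer) boundary, and is rasterized into a
#' band of the given width.
#'
#' @param mesh a `la_mesh`.
#' @param activation_map an `activation_map` from sinus pacing (full LA
#'   coverage).
#' @param n_lines number of lines (>= 2; study range 4-8).
#' @param width_mm band width (default 2).
#' @param isochrone_offset_ms isochrone level above the earliest LA
#'   activation (default 10).
#' @param step_mm integration step (default 0.5).
#' @param max_length_mm abort a line exceeding this arc length.
#' @return list of `lesion_set`s with attribute `paths` (list of polyline
#'   matrices).
#' @export
streamline_lines <- function(mesh, activation_map, n_lines, width_mm = 2,
                             isochrone_offset_ms = 10, step_mm = 0.5,
                             max_length_mm = 200) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  lat <- activation_map$lat
  if (all(is.na(lat))) stop("activation map is empty")
  lvl <- min(lat, na.rm = TRUE) + isochrone_offset_ms
  iso <- isochrone_polyline(mesh, lat, lvl)
  if (nrow(iso$points) < 2) stop("isochrone level not crossed on the mesh")
  seeds <- even_arc_points(iso$points, n_lines, closed = iso$closed)
  tri_lookup <- build_tri_lookup(mesh)
  grads <- lat_gradients(mesh, lat)
  paths <- vector("list", n_lines)
  lesions <- vector("list", n_lines)
  for (k in seq_len(n_lines)) {
    paths[[k]] <- trace_gradient_path(mesh, lat, grads, tri_lookup,
                                      seeds[k, ], step_mm, max_length_mm)
    cent <- triangle_centroids(mesh$nodes, mesh$triangles)
    d <- dist_to_polyline(cent, paths[[k]])
    el <- which(d <= pmax(width_mm / 2, 0.51 * mean(mesh$edge_length)))
    lesions[[k]] <- new_lesion_set(paste0("streamline_", k), "streamline",
                                   el, c(seeds[k, ], NA), NA, width_mm)
  }
  attr(lesions, "paths") <- paths
  attr(lesions, "seeds") <- seeds
  lesions
}

# extract an ordered polyline along the LAT isochrone at `lvl`
isochrone_polyline <- function(mesh, lat, lvl) {
  tri <- mesh$triangles
  segs <- list()
  for (tcol in 1:3) {
    a <- tri[, tcol]; b <- tri[, tcol %% 3 + 1]
    la <- lat[a]; lb <- lat[b]
    hit <- which(!is.na(la) & !is.na(lb) &
                 ((la <= lvl & lb > lvl) | (lb <= lvl & la > lvl)))
    if (length(hit)) {
      w <- (lvl - la[hit]) / (lb[hit] - la[hit])
      segs[[tcol]] <- mesh$nodes[a[hit], , drop = FALSE] * (1 - w) +
        mesh$nodes[b[hit], , drop = FALSE] * w
    }
  }
  pts <- do.call(rbind, segs)
  if (is.null(pts) || nrow(pts) < 2)
    return(list(points = matrix(numeric(0), 0, 3), closed = FALSE))
  # order points along the curve by nearest-neighbour chaining
  used <- logical(nrow(pts))
  ord <- integer(nrow(pts))
  cur <- which.min(pts[, 2])  # start at the lowest-y crossing
  for (q in seq_len(nrow(pts))) {
    ord[q] <- cur; used[cur] <- TRUE
    if (all(used)) break
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    d2[used] <- Inf
    cur <- which.min(d2)
  }
  opts <- pts[ord, , drop = FALSE]
  closed <- sqrt(sum((opts[1, ] - opts[nrow(opts), ])^2)) <
    3 * mean(mesh$edge_length)
  list(points = opts, closed = closed)
}

# n points evenly spaced in arc length along a polyline; for open curves
# the endpoints are excluded (they typically lie on the domain boundary)
even_arc_points <- function(pts, n, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  want <- if (closed) seq(0, total, length.out = n + 1)[1:n]
          else seq(0, total, length.out = n + 2)[2:(n + 1)]
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    i <- findInterval(want[k], s, rightmost.closed = TRUE)
    i <- min(i, nrow(pts) - 1)
    w <- if (seg[i] > 0) (want[k] - s[i]) / seg[i] else 0
    out[k, ] <- pts[i, ] * (1 - w) + pts[i + 1, ] * w
  }
  out
}

# per-triangle LAT gradient (P1 interpolation, in-plane, 2D xy)
lat_gradients <- function(mesh, lat) {
  tri <- mesh$triangles
  p1 <- mesh$nodes[tri[, 1], 1:2, drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], 1:2, drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], 1:2, drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  l1 <- lat[tri[, 1]]; l2 <- lat[tri[, 2]]; l3 <- lat[tri[, 3]]
  gx <- ((l2 - l1) * (p3[, 2] - p1[, 2]) -
         (l3 - l1) * (p2[, 2] - p1[, 2])) / det
  gy <- ((l3 - l1) * (p2[, 1] - p1[, 1]) -
         (l2 - l1) * (p3[, 1] - p1[, 1])) / det
  cbind(gx, gy)
}

# spatial lookup grid: triangles by cell
build_tri_lookup <- function(mesh) {
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  cell <- 2 * max(mesh$edge_length)
  key <- paste(floor(cent[, 1] / cell), floor(cent[, 2] / cell))
  list(cells = split(seq_len(nrow(mesh$triangles)), key), cell = cell,
       cent = cent)
}

nearest_triangle <- function(lookup, p) {
  cx <- floor(p[1] / lookup$cell); cy <- floor(p[2] / lookup$cell)
  cands <- integer(0)
  for (dxk in -1:1) for (dyk in -1:1)
    cands <- c(cands, lookup$cells[[paste(cx + dxk, cy + dyk)]])
  if (length(cands) == 0) cands <- seq_len(nrow(lookup$cent))
  cands[which.min((lookup$cent[cands, 1] - p[1])^2 +
                  (lookup$cent[cands, 2] - p[2])^2)]
}

# advance along +grad(LAT) until the outer boundary (or max length)
trace_gradient_path <- function(mesh, lat, grads, lookup, seed, step_mm,
                                max_length_mm) {
  sz <- mesh$config$size_mm
  p <- seed[1:2]
  path <- matrix(c(p, 0), 1, 3)
  lastdir <- c(1, 0)
  n_max <- ceiling(max_length_mm / step_mm)
  for (q in seq_len(n_max)) {
    tr <- nearest_triangle(lookup, p)
    g <- grads[tr, ]
    gn <- sqrt(sum(g^2))
    dir <- if (is.finite(gn) && gn > 1e-9) g / gn else lastdir  # plateau
    lastdir <- dir
    p <- p + step_mm * dir
    path <- rbind(path, c(p, 0))
    if (p[1] <= 0 || p[1] >= sz[1] || p[2] <= 0 || p[2] >= sz[2]) {
      path[nrow(path), 1] <- min(max(p[1], 0), sz[1])
      path[nrow(path), 2] <- min(max(p[2], 0), sz[2])
      return(path)
    }
  }
  stop("streamline did not reach the mitral boundary within max_length_mm")
}

#' Lanes created by a streamlining lesion set
#'
#' A lane is a connected component of the non-lesion elements *beyond* the
#' seed isochrone (the sub-isochrone hub around the early-activation site
#' is excluded: it is the common entry all lanes share) that touches both
#' the isochrone and the mitral (outer) boundary. Also reports each lane's
#' width (twice the maximum distance of a lane element to the nearest
#' lesion element or boundary).
#'
#' @param mesh a `la_mesh`.
#' @param lesions list of `lesion_set`s (from [streamline_lines()]).
#' @param activation_map the sinus `activation_map`.
#' @param isochrone_offset_ms as in [streamline_lines()].
#' @return list with `n_lanes`, `max_width_mm`, `membership` (NA for
#'   lesion and hub elements).
#' @export
streamline_lanes <- function(mesh, lesions, activation_map,
                             isochrone_offset_ms = 10) {
  lat <- activation_map$lat
  lvl <- min(lat, na.rm = TRUE) + isochrone_offset_ms
  les_el <- unique(unlist(lapply(lesions, `[[`, "elements")))
  tri_lat <- (lat[mesh$triangles[, 1]] + lat[mesh$triangles[, 2]] +
              lat[mesh$triangles[, 3]]) / 3
  hub <- which(!is.na(tri_lat) & tri_lat <= lvl)
  keep <- setdiff(seq_len(nrow(mesh$triangles)), union(les_el, hub))
  memb <- subset_components(mesh, keep)
  cent <- triangle_centroids(mesh$nodes, mesh$triangles)
  sz <- mesh$config$size_mm
  # touch the isochrone = share a node with a hub element
  hub_nodes <- unique(as.vector(mesh$triangles[hub, , drop = FALSE]))
  touches_hub <- keep[rowSums(matrix(mesh$triangles[keep, ] %in% hub_nodes,
                                     ncol = 3)) > 0]
  bdist <- pmin(cent[, 1], sz[1] - cent[, 1], cent[, 2], sz[2] - cent[, 2])
  near_bnd <- intersect(keep,
                        which(bdist <= 1.2 * mean(mesh$edge_length)))
  lanes <- intersect(unique(memb[touches_hub]), unique(memb[near_bnd]))
  lanes <- lanes[!is.na(lanes)]
  widths <- vapply(lanes, function(l) {
    el <- which(memb == l)
    if (length(les_el) == 0) return(2 * max(bdist[el]))
    dmin <- rep(Inf, length(el))
    for (chunkstart in seq(1, length(el), by = 4000)) {
      ch <- el[chunkstart:min(chunkstart + 3999, length(el))]
      dd <- outer(cent[ch, 1], cent[les_el, 1], "-")^2 +
            outer(cent[ch, 2], cent[les_el, 2], "-")^2
      dmin[chunkstart:(chunkstart + length(ch) - 1)] <-
        pmin(sqrt(apply(dd, 1, min)), bdist[ch])
    }
    2 * max(dmin)
  }, numeric(1))
  list(n_lanes = length(lanes),
       max_width_mm = if (length(widths)) max(widths) else NA_real_,
       membership = memb)
}
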