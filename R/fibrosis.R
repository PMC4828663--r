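# Stochastic interstitial fibrosis: mesh-element edges are selected as
# fibrotic with probability alpha * (4 cos^2 theta + sin^2 theta) * L, where
# theta is the acute angle between the edge and the local fiber direction
# and L the local enhancement likelihood. Selected edges are decoupled by
# node splitting; fully-selected triangles are removed.

#' Fiber-alignment selection weight
#'
#' Edges parallel to the local fiber direction are four times more likely to
#' be selected than edges perpendicular to it: weight
#' `4 cos^2(theta) + sin^2(theta)`.
#'
#' @param theta acute angle (radians) between an edge and the fiber
#'   direction, in `[0, pi/2]`.
#' @return dimensionless weight in `[1, 4]`.
#' @export
edge_selection_weight <- function(theta) {
  if (any(theta < -1e-12 | theta > pi / 2 + 1e-12))
    stop("theta must lie in [0, pi/2]")
  4 * cos(theta)^2 + sin(theta)^2
}

# acute angle between each edge and the (averaged) fiber of its adjacent
# triangles; fiber sign ambiguity resolved before averaging
edge_fiber_angle <- function(mesh) {
  f1 <- mesh$fiber[mesh$edge_tri[, 1], , drop = FALSE]
  t2 <- mesh$edge_tri[, 2]
  f2 <- f1
  has2 <- !is.na(t2)
  f2[has2, ] <- mesh$fiber[t2[has2], , drop = FALSE]
  flip <- rowSums(f1 * f2) < 0
  f2[flip, ] <- -f2[flip, ]
  fa <- f1 + f2
  fa <- fa / sqrt(rowSums(fa^2))
  ev <- mesh$nodes[mesh$edges[, 2], , drop = FALSE] -
    mesh$nodes[mesh$edges[, 1], , drop = FALSE]
  ev <- ev / sqrt(rowSums(ev^2))
  acos(pmin(1, abs(rowSums(fa * ev))))
}

# per-edge likelihood = mean of adjacent triangle LGE values
edge_lge_value <- function(mesh, lge_values) {
  v1 <- lge_values[mesh$edge_tri[, 1]]
  t2 <- mesh$edge_tri[, 2]
  v2 <- v1
  v2[!is.na(t2)] <- lge_values[t2[!is.na(t2)]]
  (v1 + v2) / 2
}

#' Select fibrotic edges
#'
#' Each edge is assigned `u ~ Uniform(0, 1)` (a single `runif` draw over
#' edges in index order) and selected iff
#' `alpha * (4 cos^2 theta + sin^2 theta) * L > u`. Triangles whose three
#' edges are all selected are marked for removal. Connected components of
#' the selected-edge graph (edges sharing a node) are computed with their
#' total lengths.
#'
#' @param mesh a `la_mesh`.
#' @param lge an `lge_map` or a numeric per-triangle likelihood vector.
#' @param alpha positive weighting constant.
#' @param seed integer RNG seed.
#' @return object of class `fibrosis_map`: list with `selected` (logical per
#'   edge), `alpha`, `seed`, `removed_elements` (triangle indices),
#'   `components` (list of edge-index vectors), `component_length_um`.
#' @export
select_fibrotic_edges <- function(mesh, lge, alpha, seed = 1L) {
  if (alpha <= 0) stop("alpha must be positive")
  lv <- if (inherits(lge, "lge_map")) lge$value else lge
  if (length(lv) != nrow(mesh$triangles))
    stop("LGE values must be per triangle")
  w <- edge_selection_weight(edge_fiber_angle(mesh))
  L <- edge_lge_value(mesh, lv)
  set.seed(seed)
  u <- runif(nrow(mesh$edges))
  sel <- (alpha * w * L) > u
  fibrosis_map_from_selection(mesh, sel, alpha, seed)
}

# build the fibrosis_map bookkeeping from a logical edge-selection vector
fibrosis_map_from_selection <- function(mesh, sel, alpha, seed) {
  E <- nrow(mesh$edges)
  tri_sel_count <- rep(0L, nrow(mesh$triangles))
  for (cc in 1:2) {
    tt <- mesh$edge_tri[sel, cc]
    tt <- tt[!is.na(tt)]
    tb <- tabulate(tt, nbins = nrow(mesh$triangles))
    tri_sel_count <- tri_sel_count + tb
  }
  removed <- which(tri_sel_count == 3L)

  comps <- list(); comp_len <- numeric(0)
  if (any(sel)) {
    se <- which(sel)
    ed <- mesh$edges[se, , drop = FALSE]
    verts <- sort(unique(as.vector(ed)))
    g <- igraph::make_graph(edges = as.vector(t(matrix(match(ed, verts),
                                                       ncol = 2))),
                            n = length(verts), directed = FALSE)
    memb <- igraph::components(g)$membership
    ecomp <- memb[match(ed[, 1], verts)]
    comp_len <- as.vector(rowsum(mesh$edge_length[se] * 1000, ecomp))
    comps <- unname(split(se, ecomp))
  }
  structure(list(selected = sel, alpha = alpha, seed = as.integer(seed),
                 removed_elements = removed, components = comps,
                 component_length_um = unname(comp_len)),
            class = "fibrosis_map")
}

#' Median connected fibrotic-component length (micrometres)
#' @param fibmap a `fibrosis_map`.
#' @return median total length over components (`NA` if none).
#' @export
median_cluster_length <- function(fibmap) {
  if (length(fibmap$component_length_um) == 0) return(NA_real_)
  median(fibmap$component_length_um)
}

#' Calibrate the fibrosis weighting constant
#'
#' Bisection over `alpha` targeting a median connected fibrotic-edge
#' component length (default 670 um, the interstitial-fibrosis scale in
#' aging fiber bundles). The objective at each `alpha` is the mean over
#' `n_seeds` independent selections of the per-realization median component
#' length. The same uniform draws are reused across `alpha` values, making
#' the objective deterministic and monotone in `alpha`.
#'
#' @param mesh a `la_mesh`.
#' @param lge an `lge_map` or per-triangle likelihood vector.
#' @param target_median_um target median component length (um).
#' @param n_seeds number of selection realizations averaged per evaluation.
#' @param seed base RNG seed; realization s uses `seed + s - 1`.
#' @param tol_um convergence tolerance on the achieved median (um).
#' @param max_iter bisection iteration cap.
#' @return list with `alpha`, `achieved_median_um`, `n_iter`, `converged`.
#' @export
calibrate_alpha <- function(mesh, lge, target_median_um = 670, n_seeds = 20,
                            seed = 1L, tol_um = 50, max_iter = 30) {
  lv <- if (inherits(lge, "lge_map")) lge$value else lge
  if (all(lv <= 0)) stop("LGE likelihood is zero everywhere")
  if (target_median_um <= min(mesh$edge_length) * 1000)
    stop("target below the smallest edge length")
  w <- edge_selection_weight(edge_fiber_angle(mesh))
  L <- edge_lge_value(mesh, lv)
  E <- nrow(mesh$edges)
  U <- matrix(0, E, n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(as.integer(seed) + s - 1L)
    U[, s] <- runif(E)
  }
  el_um <- mesh$edge_length * 1000
  edge_a <- mesh$edges[, 1]
  objective <- function(alpha) {
    p <- alpha * w * L
    meds <- vapply(seq_len(n_seeds), function(s) {
      se <- which(p > U[, s])
      if (length(se) == 0) return(0)
      ed <- mesh$edges[se, , drop = FALSE]
      verts <- sort(unique(as.vector(ed)))
      g <- igraph::make_graph(edges = as.vector(t(matrix(match(ed, verts),
                                                         ncol = 2))),
                              n = length(verts), directed = FALSE)
      memb <- igraph::components(g)$membership
      median(as.vector(rowsum(el_um[se], memb[match(ed[, 1], verts)])))
    }, numeric(1))
    mean(meds)
  }
  lo <- 1e-4; hi <- 0.05
  f_hi <- objective(hi)
  while (f_hi < target_median_um && hi < 64) {
    hi <- hi * 2
    f_hi <- objective(hi)
  }
  if (f_hi < target_median_um)
    stop(sprintf(paste0("target median %g um unreachable; achievable at ",
                        "most ~%.0f um on this mesh/LGE"),
                 target_median_um, f_hi))
  f_lo <- objective(lo)
  best <- if (abs(f_hi - target_median_um) < abs(f_lo - target_median_um))
    c(hi, f_hi) else c(lo, f_lo)
  it <- 0L
  while (it < max_iter && abs(best[2] - target_median_um) > tol_um / 2 &&
         (hi - lo) > 1e-3 * hi) {
    mid <- sqrt(lo * hi)  # bisect in log space: alpha spans decades
    f_mid <- objective(mid)
    if (abs(f_mid - target_median_um) < abs(best[2] - target_median_um))
      best <- c(mid, f_mid)
    if (f_mid < target_median_um) lo <- mid else hi <- mid
    it <- it + 1L
  }
  list(alpha = best[1], achieved_median_um = best[2], n_iter = it,
       converged = abs(best[2] - target_median_um) <= tol_um)
}

#' Decouple fibrotic edges by node splitting
#'
#' Imposes no-flux microstructural discontinuities along selected edges.
#' For every node incident to selected edges the surrounding triangle fan is
#' cut at each selected edge; the resulting wedges receive independent node
#' copies (coordinates unchanged), so triangles on opposite sides of a
#' fibrotic path no longer share degrees of freedom. At an interior crack
#' tip (a node with a single selected incident edge whose fan is a closed
#' cycle) the fan is additionally cut opposite the crack so the selected
#' edge itself is always decoupled. Triangles whose three edges are all
#' selected are removed first (when `remove_elements`). If a fibrotic loop
#' would disconnect a patch of tissue, one junction node is left shared and
#' a message is emitted.
#'
#' @param mesh a `la_mesh`.
#' @param fibmap a `fibrosis_map` computed on `mesh`.
#' @param remove_elements drop fully-selected triangles (default TRUE).
#' @return a new `la_mesh` with duplicated nodes along fibrotic paths;
#'   fields `region`, `subdivision`, `fiber` carried over per triangle;
#'   boundary loops are kept from the input mesh (slits are not ostia).
#' @export
split_edges <- function(mesh, fibmap, remove_elements = TRUE) {
  stopifnot(inherits(fibmap, "fibrosis_map"))
  if (length(fibmap$selected) != nrow(mesh$edges))
    stop("fibrosis map does not match mesh")
  if (!any(fibmap$selected)) return(mesh)

  tri <- mesh$triangles
  keep_tri <- rep(TRUE, nrow(tri))
  if (remove_elements && length(fibmap$removed_elements) > 0)
    keep_tri[fibmap$removed_elements] <- FALSE

  # selected edge lookup by sorted node pair
  sel_e <- mesh$edges[fibmap$selected, , drop = FALSE]
  nmax <- nrow(mesh$nodes) + 1
  selkey <- sort(sel_e[, 1] * nmax + sel_e[, 2])
  ekey <- function(a, b) pmin(a, b) * nmax + pmax(a, b)
  is_selected_edge <- function(keys) {  # binary search in sorted selkey
    pos <- findInterval(keys, selkey)
    pos >= 1 & selkey[pmax(1, pos)] == keys
  }

  tri2 <- tri[keep_tri, , drop = FALSE]
  tid <- which(keep_tri)
  n_tri_comp_before <- tri_components(tri2)

  nodes <- mesh$nodes
  new_tri <- tri2
  dup_pairs <- matrix(integer(0), ncol = 2)  # (original, copy)

  touched <- sort(unique(as.vector(sel_e)))
  # incidence: triangles (rows of tri2) around each node, indexed by node id
  inc_named <- split(rep(seq_len(nrow(tri2)), 3L), as.vector(tri2))
  inc <- vector("list", nrow(mesh$nodes))
  inc[as.integer(names(inc_named))] <- inc_named

  # pass 1: wedge partition per touched node, computed on the ORIGINAL
  # topology so node order cannot influence the result
  plan <- list()
  for (v in touched) {
    tv <- inc[[v]]
    if (is.null(tv) || length(tv) < 2) next
    # wedge graph: triangles adjacent through a non-selected edge at v
    k <- length(tv)
    other <- lapply(tv, function(tt) setdiff(tri2[tt, ], v))
    am <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      shared <- intersect(other[[a]], other[[b]])
      if (length(shared) >= 1) {
        # shared edge (v, shared[1]); adjacency unless that edge is selected
        if (!is_selected_edge(ekey(v, shared[1]))) am[a, b] <- am[b, a] <- TRUE
      }
    }
    g <- igraph::graph_from_adjacency_matrix(am, mode = "undirected")
    memb <- igraph::components(g)$membership
    if (max(memb) == 1) {
      # closed fan cut only once (interior crack tip): cut again opposite
      # the selected edge so the crack itself is decoupled
      selnb <- sel_e[sel_e[, 1] == v | sel_e[, 2] == v, , drop = FALSE]
      nb <- setdiff(as.vector(selnb), v)[1]
      a0 <- which(vapply(other, function(o) nb %in% o, logical(1)))
      if (length(a0) == 2) {
        # order the fan as a path starting at a0[1] with the selected edge cut
        ordv <- fan_order(am, a0[1], a0[2])
        half <- ordv[seq_len(ceiling(length(ordv) / 2))]
        memb <- rep(1L, k); memb[half] <- 2L
      } else next  # boundary tip or degenerate: leave attached
    }
    plan[[length(plan) + 1]] <- list(v = v, tv = tv, memb = memb)
  }

  # pass 2: apply the duplications (triangle row ids are stable)
  for (pl in plan) {
    for (wgt in 2:max(pl$memb)) {
      nodes <- rbind(nodes, mesh$nodes[pl$v, , drop = FALSE])
      nv <- nrow(nodes)
      for (tt in pl$tv[pl$memb == wgt])
        new_tri[tt, new_tri[tt, ] == pl$v] <- nv
      dup_pairs <- rbind(dup_pairs, c(pl$v, nv))
    }
  }

  # re-attach patches disconnected by fibrotic loops: union-find over the
  # components of the split mesh, re-merging duplicate pairs that bridge
  # distinct components until the pre-split component count is restored
  merged_back <- 0L
  if (nrow(dup_pairs) > 0) {
    cm <- tri_component_membership(new_tri)
    ncomp <- max(cm)
    if (ncomp > n_tri_comp_before) {
      # component of the (first) triangle containing each node
      node_comp <- rep(NA_integer_, nrow(nodes))
      node_comp[as.vector(new_tri)] <- cm[rep(seq_len(nrow(new_tri)), 3L)]
      parent <- seq_len(ncomp)
      findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      extra <- ncomp - n_tri_comp_before
      undo <- logical(nrow(dup_pairs))
      for (r in seq_len(nrow(dup_pairs))) {
        if (extra <= 0L) break
        cv <- node_comp[dup_pairs[r, 1]]; cnv <- node_comp[dup_pairs[r, 2]]
        if (is.na(cv) || is.na(cnv)) next
        cv <- findp(cv); cnv <- findp(cnv)
        if (cv != cnv) {
          parent[cnv] <- cv
          undo[r] <- TRUE
          extra <- extra - 1L
          merged_back <- merged_back + 1L
        }
      }
      if (merged_back > 0) {
        repl <- dup_pairs[undo, , drop = FALSE]
        map <- seq_len(nrow(nodes))
        map[repl[, 2]] <- repl[, 1]
        new_tri[] <- map[new_tri]
        dup_pairs <- dup_pairs[!undo, , drop = FALSE]
        message("split_edges: left ", merged_back,
                " junction node(s) shared to avoid disconnecting tissue")
      }
    }
  }

  # drop now-unused node rows (removed elements may orphan nodes)
  used <- sort(unique(as.vector(new_tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  out <- mesh
  out$nodes <- nodes[used, , drop = FALSE]
  out$triangles <- matrix(remap[new_tri], ncol = 3L)
  out$fiber <- mesh$fiber[keep_tri, , drop = FALSE]
  out$region <- mesh$region[keep_tri]
  out$subdivision <- mesh$subdivision[keep_tri]
  out <- rebuild_mesh_topology(out)
  out$boundary_loops <- lapply(mesh$boundary_loops, function(l) {
    l2 <- remap[l]; l2[l2 > 0]
  })
  out$split_info <- list(n_nodes_added = nrow(out$nodes) - nrow(mesh$nodes),
                         merged_back = merged_back)
  out
}

# order a cut fan (path graph) from endpoint `from`, other cut side `to`
fan_order <- function(am, from, to) {
  k <- nrow(am)
  ordv <- integer(0); cur <- from; prev <- 0L
  for (q in seq_len(k)) {
    ordv <- c(ordv, cur)
    nb <- setdiff(which(am[cur, ]), c(prev, ordv))
    if (length(nb) == 0) break
    prev <- cur; cur <- nb[1]
  }
  ordv
}

# Electrical connectivity of triangles: two triangles are coupled when they
# share at least one node (P1 finite elements exchange flux through shared
# degrees of freedom). Implemented via the bipartite triangle-node graph.
tri_components <- function(tri) {
  max(tri_component_membership(tri))
}
tri_component_membership <- function(tri) {
  m <- nrow(tri)
  n <- max(tri)
  el <- cbind(rep(seq_len(m), 3L), as.vector(tri) + m)
  g <- igraph::make_graph(edges = as.vector(t(el)), n = m + n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  as.integer(factor(memb[seq_len(m)]))
}

#' @export
print.fibrosis_map <- function(x, ...) {
  cat("fibrosis_map:", sum(x$selected), "of", length(x$selected),
      "edges selected (alpha =", signif(x$alpha, 4), ")\n")
  cat("  components:", length(x$components), " median length:",
      round(median_cluster_length(x)), "um\n")
  cat("  removed elements:", length(x$removed_elements), "\n")
  invisible(x)
}
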