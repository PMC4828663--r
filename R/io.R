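# Mesh serialization: ASCII VTK legacy PolyData with per-triangle data
# arrays (fiber vectors, region, subdivision, optional LGE likelihood and
# lesion overlays). Minimal reader/writer sufficient for round-tripping
# the package's own meshes and for inspection in standard viewers.

#' Write a mesh to an ASCII VTK legacy file
#'
#' Per-triangle fields are emitted as CELL_DATA arrays: `fiber` (3-vector),
#' `region` (integer code, legend in the header comment), `subdivision`,
#' and optionally `lge` and any extra numeric per-triangle arrays.
#'
#' @param mesh a `la_mesh`.
#' @param path output file path.
#' @param lge optional `lge_map` or numeric per triangle.
#' @param extra named list of numeric per-triangle vectors.
#' @return invisibly `path`.
#' @export
write_mesh_vtk <- function(mesh, path, lge = NULL, extra = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  regions <- sort(unique(mesh$region))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("atrialab mesh; regions: ",
                      paste(seq_along(regions), regions, sep = "=",
                            collapse = " ")),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", n, "double")), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(paste("POLYGONS", m, 4 * m), con)
  write(t(cbind(3L, mesh$triangles - 1L)), con, ncolumns = 4)
  writeLines(paste("CELL_DATA", m), con)
  writeLines("VECTORS fiber double", con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$fiber[, 1], mesh$fiber[, 2],
                     mesh$fiber[, 3]), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  write(match(mesh$region, regions), con, ncolumns = 9)
  writeLines(c("SCALARS subdivision int 1", "LOOKUP_TABLE default"), con)
  write(mesh$subdivision, con, ncolumns = 9)
  if (!is.null(lge)) {
    lv <- if (inherits(lge, "lge_map")) lge$value else lge
    writeLines(c("SCALARS lge double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.12g", lv), con)
  }
  for (nm in names(extra)) {
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.12g", extra[[nm]]), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' @param path VTK legacy ASCII file.
#' @return list with `nodes`, `triangles`, `fiber`, `region`,
#'   `subdivision`, and any scalar cell arrays (e.g. `lge`) by name.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  regions <- NULL
  hdr <- grep("regions:", ln, value = TRUE)
  if (length(hdr)) {
    spec <- sub(".*regions: ", "", hdr[1])
    kv <- strsplit(strsplit(spec, " ")[[1]], "=")
    regions <- vapply(kv, `[`, character(1), 2)
  }
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  num <- function(from, count) {
    v <- scan(text = paste(ln[from:length(ln)], collapse = "\n"),
              n = count, quiet = TRUE)
    v
  }
  nodes <- matrix(num(ip + 1, 3 * n), ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", ln)[1]
  m <- as.integer(strsplit(ln[it], " +")[[1]][2])
  poly <- matrix(num(it + 1, 4 * m), ncol = 4, byrow = TRUE)
  tri <- poly[, 2:4, drop = FALSE] + 1L
  out <- list(nodes = nodes, triangles = tri)
  iv <- grep("^VECTORS fiber", ln)
  if (length(iv))
    out$fiber <- matrix(num(iv[1] + 1, 3 * m), ncol = 3, byrow = TRUE)
  for (sc in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[sc], " +")[[1]][2]
    vals <- num(sc + 2, m)
    if (nm == "region" && !is.null(regions))
      out$region <- regions[as.integer(vals)]
    else if (nm == "subdivision") out$subdivision <- as.integer(vals)
    else out[[nm]] <- vals
  }
  out
}

#' Export PS trajectories as CSV
#' @param trajectories a `ps_trajectories`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  utils::write.csv(as.data.frame(trajectories)[,
    c("id", "t", "x", "y", "z", "chirality")], path, row.names = FALSE)
  invisible(path)
}
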