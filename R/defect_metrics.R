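#' Geometric characteristics of a focal defect model
#'
#' Measures the defect's articulating surface: its area, major axis (the
#' two articulating vertices with the greatest pairwise Euclidean distance),
#' minor axis (the maximum extent of the articulating vertices along
#' directions perpendicular to the major axis) and aspect ratio
#' (major length / minor length, always >= 1).
#'
#' The minor axis is computed by projecting the articulating vertices onto
#' the plane orthogonal to the major-axis direction and taking the diameter
#' (maximum pairwise distance) of the projected set; this equals the maximum
#' extent over all perpendicular directions and reduces to the in-plane
#' perpendicular extent for near-planar defects.
#'
#' @param mesh defect \code{surface_mesh}.
#' @param articulating_mask logical or integer face selection of the
#'   articulating (outer) faces; default: faces labelled
#'   \code{"articulating"}, or all faces when the mesh carries no labels.
#' @param all_points if TRUE measure over every vertex of the defect mesh
#'   instead of articulating vertices only.
#' @return object of class \code{defect_record}: list with \code{area_mm2},
#'   \code{major_mm}, \code{minor_mm}, \code{aspect}, \code{major_endpoints},
#'   \code{minor_endpoints} (vertex coordinates), \code{degenerate} flag.
#' @export
defect_axes <- function(mesh, articulating_mask = NULL, all_points = FALSE) {
  stopifnot(is.surface_mesh(mesh))
  if (is.null(articulating_mask)) {
    articulating_mask <- if (!is.null(mesh$face_labels))
      mesh$face_labels == "articulating" else rep(TRUE, nrow(mesh$faces))
  }
  if (!any(articulating_mask)) stop("empty articulating mask")
  area <- surface_area(mesh, articulating_mask)
  pts <- if (all_points) mesh$vertices else
    mesh$vertices[sort(unique(as.vector(
      mesh$faces[articulating_mask, , drop = FALSE]))), , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 articulating vertices")

  maj <- diameter_pair(pts)
  dir <- unitize(pts[maj$j, ] - pts[maj$i, ])
  ## orthonormal basis of the perpendicular plane
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3v(dir, ref))
  e2 <- cross3v(dir, e1)
  proj <- cbind(pts %*% e1, pts %*% e2)
  minr <- diameter_pair(proj)
  degenerate <- minr$d < 1e-9
  structure(list(
    area_mm2 = area,
    major_mm = maj$d,
    minor_mm = minr$d,
    aspect = if (degenerate) Inf else maj$d / minr$d,
    major_endpoints = pts[c(maj$i, maj$j), , drop = FALSE],
    minor_endpoints = pts[c(minr$i, minr$j), , drop = FALSE],
    degenerate = degenerate), class = "defect_record")
}

#' @export
print.defect_record <- function(x, ...) {
  cat(sprintf(
    "defect_record: area %.1f mm^2, major %.1f mm, minor %.1f mm, aspect %.2f%s\n",
    x$area_mm2, x$major_mm, x$minor_mm, x$aspect,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

## maximum pairwise distance; O(n^2) in chunks, n is a few hundred here
diameter_pair <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  p2 <- rowSums(pts^2)
  best <- -Inf; bi <- 1L; bj <- 1L
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(p2[s:e], p2, "+") - 2 * (pts[s:e, , drop = FALSE] %*% t(pts))
    wi <- max.col(d2, ties.method = "first")
    vals <- d2[cbind(seq_len(e - s + 1L), wi)]
    k <- which.max(vals)
    if (vals[k] > best) {
      best <- vals[k]; bi <- s + k - 1L; bj <- wi[k]
    }
  }
  list(d = sqrt(max(best, 0)), i = bi, j = bj)
}

#' Tabulate defect metrics for a cohort
#'
#' @param defects list of defect \code{surface_mesh} objects (articulating
#'   faces labelled) or of \code{defect_record}s.
#' @param model_ids optional character vector of ids.
#' @param regions optional character vector (e.g. "medial"/"lateral").
#' @return data.frame: model_id, region, area_mm2, major_mm, minor_mm, aspect.
#' @export
defect_metrics_table <- function(defects, model_ids = NULL, regions = NULL) {
  recs <- lapply(defects, function(d)
    if (inherits(d, "defect_record")) d else defect_axes(d))
  data.frame(
    model_id = model_ids %||% sprintf("model_%03d", seq_along(recs)),
    region = regions %||% NA_character_,
    area_mm2 = vapply(recs, `[[`, numeric(1), "area_mm2"),
    major_mm = vapply(recs, `[[`, numeric(1), "major_mm"),
    minor_mm = vapply(recs, `[[`, numeric(1), "minor_mm"),
    aspect = vapply(recs, `[[`, numeric(1), "aspect"),
    stringsAsFactors = FALSE)
}
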