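#' Full ellipse axes from area and aspect ratio
#'
#' Inverts area = pi * (a/2) * (b/2) and aspect = a/b: the full major axis
#' is a = 2 sqrt(area * aspect / pi), the full minor axis
#' b = 2 sqrt(area / (pi * aspect)). Used to size the elliptical region of
#' interest for local radius-of-curvature measurement from the median
#' defect area and aspect ratio.
#'
#' @param area ellipse area, mm^2 (> 0).
#' @param aspect major:minor axis ratio (>= 1).
#' @return named numeric vector c(major_mm, minor_mm) of full axis lengths.
#' @export
patch_dimensions <- function(area, aspect) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  if (!is.finite(aspect) || aspect < 1) stop("aspect must be >= 1")
  c(major_mm = 2 * sqrt(area * aspect / pi),
    minor_mm = 2 * sqrt(area / (pi * aspect)))
}

## ---- circle fitting ----------------------------------------------------

## Pratt algebraic circle fit + geometric Gauss-Newton refinement.
## Returns center, radius, RMS of (distance - r), and a flat flag for
## (near-)collinear input.
fit_circle_2d <- function(xy, gn_iter = 20L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 distinct points for a circle fit")
  ctr <- colMeans(xy)
  P <- sweep(xy, 2L, ctr)
  ev <- eigen(crossprod(P) / n, symmetric = TRUE)$values
  if (ev[1] < 1e-20 || ev[2] / ev[1] < 1e-12)
    return(list(center = ctr, radius = Inf, rms = 0, flat = TRUE))
  z <- rowSums(P^2)
  M <- crossprod(cbind(z, P, 1)) / n
  Nc <- rbind(c(0, 0, 0, -2), c(0, 1, 0, 0), c(0, 0, 1, 0), c(-2, 0, 0, 0))
  eg <- eigen(solve(Nc, M))
  vals <- Re(eg$values)
  vecs <- Re(eg$vectors)
  ok <- which(vals > -1e-12)
  if (!length(ok))
    return(list(center = ctr, radius = Inf, rms = 0, flat = TRUE))
  v <- vecs[, ok[which.min(vals[ok])]]
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]
  if (abs(A) < 1e-14 * sqrt(B^2 + C^2))
    return(list(center = ctr, radius = Inf, rms = 0, flat = TRUE))
  cen <- c(-B, -C) / (2 * A)
  r <- sqrt(max(B^2 + C^2 - 4 * A * D, 0)) / (2 * abs(A))
  ## geometric refinement
  for (it in seq_len(gn_iter)) {
    dx <- sweep(P, 2L, cen)
    di <- sqrt(rowSums(dx^2))
    if (any(di < 1e-12)) break
    res <- di - r
    J <- cbind(-dx[, 1] / di, -dx[, 2] / di, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cen <- cen - step[1:2]; r <- r - step[3]
    if (max(abs(step)) < 1e-12) break
  }
  dx <- sweep(P, 2L, cen)
  res <- sqrt(rowSums(dx^2)) - r
  list(center = cen + ctr, radius = r, rms = sqrt(mean(res^2)), flat = FALSE)
}

## least-squares (Kasa) sphere fit; used as a degeneracy diagnostic for the
## cylinder fit
fit_sphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cen <- sol[1:3]
  r2 <- sol[4] + sum(cen^2)
  if (r2 <= 0) return(NULL)
  r <- sqrt(r2)
  res <- sqrt(rowSums(sweep(pts, 2L, cen)^2)) - r
  list(center = cen, radius = r, rms = sqrt(mean(res^2)))
}

#' Least-squares cylinder fit
#'
#' Fits a circular cylinder to a point cloud by minimising the sum of
#' squared (distance-to-axis - radius) residuals: the axis direction is
#' optimised over the unit sphere (Nelder-Mead from the three principal
#' axes of the point covariance, so the result is deterministic), and for
#' each candidate direction the radius and axis position come from a Pratt
#' circle fit to the points projected along the direction, refined
#' geometrically.
#'
#' Near-spherical point sets (a least-squares sphere explains the points
#' essentially as well as the cylinder) and near-planar sets (projected
#' circle radius diverges) are flagged as ill-conditioned.
#'
#' @param points m x 3 matrix (m >= 6) or a \code{surface_mesh}.
#' @param flat_radius radius above which the fit is considered planar.
#' @return object of class \code{cylinder_fit}: \code{axis_point},
#'   \code{axis_direction} (unit), \code{radius} (mm), \code{rms} (mm),
#'   \code{ill_conditioned}, \code{degeneracy} (\code{"none"},
#'   \code{"spherical"} or \code{"planar"}).
#' @export
fit_cylinder <- function(points, flat_radius = 1e4) {
  pts <- if (is.surface_mesh(points)) points$vertices else as.matrix(points)
  if (nrow(pts) < 6L) stop("cylinder fit needs at least 6 points")
  c0 <- colMeans(pts)
  P <- sweep(pts, 2L, c0)
  eigv <- eigen(crossprod(P) / nrow(P), symmetric = TRUE)$vectors
  obj <- function(ang) cyl_profile(P, dir_from_angles(ang))$rms
  best <- NULL
  for (j in 1:3) {
    a0 <- angles_from_dir(eigv[, j])
    op <- stats::optim(a0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 1000L))
    op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 1000L))
    if (is.null(best) || op$value < best$value) best <- op
  }
  w <- dir_from_angles(best$par)
  prof <- cyl_profile(P, w)
  sph <- fit_sphere(pts)
  degeneracy <- "none"
  if (!is.null(prof$flat) && prof$flat || prof$radius > flat_radius)
    degeneracy <- "planar"
  else if (!is.null(sph) && sph$rms <= prof$rms * 1.05 + 1e-12)
    degeneracy <- "spherical"
  axis_point <- c0 + prof$center3
  structure(list(axis_point = axis_point, axis_direction = w,
                 radius = prof$radius, rms = prof$rms,
                 ill_conditioned = degeneracy != "none",
                 degeneracy = degeneracy),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "cylinder_fit: radius %.3f mm, axis (%.3f, %.3f, %.3f), rms %.4g mm%s\n",
    x$radius, x$axis_direction[1], x$axis_direction[2], x$axis_direction[3],
    x$rms, if (x$ill_conditioned) paste0(" [", x$degeneracy, "]") else ""))
  invisible(x)
}

dir_from_angles <- function(ang) {
  c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
}

angles_from_dir <- function(d) {
  d <- unitize(d)
  c(acos(pmin(pmax(d[3], -1), 1)), atan2(d[2], d[1]))
}

## radius/axis-offset profile for a fixed direction: circle fit of the
## projection onto the plane perpendicular to w
cyl_profile <- function(P, w) {
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3v(w, ref)); e2 <- cross3v(w, e1)
  xy <- cbind(P %*% e1, P %*% e2)
  cf <- fit_circle_2d(xy)
  if (cf$flat)
    return(list(radius = Inf, rms = sqrt(mean((xy %*% c(1, 0))^2)),
                center3 = c(0, 0, 0), flat = TRUE))
  list(radius = cf$radius, rms = cf$rms,
       center3 = cf$center[1] * e1 + cf$center[2] * e2, flat = FALSE)
}

## ---- planes and patches ------------------------------------------------

#' Measurement planes at a probe point from a cylinder fit
#'
#' The anteroposterior (AP) plane has the cylinder axis as its normal and
#' passes through the probe point; the mediolateral (ML) plane passes
#' through the probe point and contains the whole cylinder axis. The two
#' planes are orthogonal whenever the probe point does not lie on the axis
#' (probe on the axis is an error: the ML plane is then undefined).
#'
#' @param cyl a \code{cylinder_fit}.
#' @param probe length-3 point on the surface.
#' @return list with \code{ap} and \code{ml}, each a plane
#'   \code{list(normal, point)}.
#' @export
probe_planes <- function(cyl, probe) {
  w <- unitize(cyl$axis_direction)
  rel <- probe - cyl$axis_point
  foot <- cyl$axis_point + sum(rel * w) * w
  radial <- probe - foot
  if (sqrt(sum(radial^2)) < 1e-9)
    stop("probe point lies on the cylinder axis; ML plane undefined")
  list(ap = list(normal = w, point = probe),
       ml = list(normal = unitize(cross3v(w, radial)), point = probe))
}

#' Extract the elliptical region of interest around a probe point
#'
#' Selects the faces whose centroids fall inside the ellipse of the given
#' full axes in the probe's tangent frame: the major axis lies along the
#' anteroposterior tangent (the intersection of the AP measurement plane
#' with the tangent plane) and the minor axis along the mediolateral
#' tangent. The patch is the connected component containing the probe; a
#' patch touching the mesh boundary is flagged as boundary-clipped.
#'
#' @param mesh a \code{surface_mesh}.
#' @param probe length-3 point on (or near) the surface.
#' @param axes full (major, minor) axis lengths in mm, e.g. from
#'   [patch_dimensions()].
#' @param ap_normal unit normal of the AP plane (the cylinder axis
#'   direction).
#' @return \code{surface_mesh} patch with attributes \code{"frame"} (list
#'   t_ap, t_ml, normal, probe) and \code{"boundary_clipped"}.
#' @export
extract_elliptical_patch <- function(mesh, probe, axes, ap_normal) {
  vn <- vertex_normals(mesh)
  nnv <- nn_dist2(matrix(probe, 1L), mesh$vertices)
  nvert <- nnv$index[1]
  n <- unitize(vn[nvert, ])
  w <- unitize(ap_normal)
  d <- cross3v(w, n)
  if (sqrt(sum(d^2)) < 1e-8)
    stop("AP direction undefined: cylinder axis parallel to surface normal")
  t_ap <- unitize(d)
  t_ml <- cross3v(n, t_ap)
  cen <- face_centroids(mesh)
  rel <- sweep(cen, 2L, probe)
  la <- rel %*% t_ap; lm <- rel %*% t_ml
  inside <- (la / (axes[1] / 2))^2 + (lm / (axes[2] / 2))^2 <= 1
  if (!any(inside)) stop("elliptical patch selected no faces")
  patch <- submesh(mesh, inside)
  comp <- face_components(patch)
  if (max(comp) > 1L) {
    pc <- face_centroids(patch)
    nearest_face <- which.min(rowSums(sweep(pc, 2L, probe)^2))
    orig <- attr(patch, "orig_vertices")
    patch <- submesh(patch, comp == comp[nearest_face],
                     keep_vertex_ids = TRUE)
    attr(patch, "orig_vertices") <- orig[attr(patch, "orig_vertices")]
  }
  clipped <- length(intersect(attr(patch, "orig_vertices"),
                              boundary_vertices(mesh))) > 0L
  attr(patch, "frame") <- list(t_ap = t_ap, t_ml = t_ml, normal = n,
                               probe = probe)
  attr(patch, "boundary_clipped") <- clipped
  patch
}

#' Signed circle fit of patch points in a measurement plane
#'
#' Orthogonally projects the points into the plane (optionally only points
#' within \code{max_offplane} of it, to avoid the radius shrinkage that
#' off-plane points introduce on doubly curved surfaces), fits a circle
#' (Pratt initialisation, geometric Gauss-Newton refinement) and signs the
#' radius by the side of the surface the centre falls on: positive when the
#' centre lies on the anti-normal (bone) side at the probe (convex),
#' negative otherwise (concave). Radii above \code{flat_cap} and
#' (near-)collinear projections are reported flat.
#'
#' @param points m x 3 matrix of patch points.
#' @param plane list(normal, point).
#' @param surface_normal outward surface normal at the probe (for the
#'   sign); NULL returns an unsigned radius.
#' @param probe probe point (defaults to \code{plane$point}).
#' @param max_offplane maximum |distance| to the plane for a point to enter
#'   the fit (default Inf).
#' @param flat_cap radius magnitude above which the section is reported
#'   flat, mm (default 500).
#' @return list: \code{radius} (signed mm, Inf when flat), \code{center}
#'   (3D), \code{residual_rms} (mm), \code{flat}, \code{n_points}.
#' @export
fit_circle_in_plane <- function(points, plane, surface_normal = NULL,
                                probe = NULL, max_offplane = Inf,
                                flat_cap = 500) {
  points <- as.matrix(points)
  nrm <- unitize(plane$normal)
  probe <- probe %||n% plane$point
  d <- (points %*% nrm)[, 1] - sum(plane$point * nrm)
  if (is.finite(max_offplane)) {
    keep <- abs(d) <= max_offplane
    points <- points[keep, , drop = FALSE]
    d <- d[keep]
  }
  points <- unique(points)
  if (nrow(points) < 3L)
    stop("fewer than 3 distinct points near the measurement plane")
  d <- (points %*% nrm)[, 1] - sum(plane$point * nrm)
  proj <- points - outer(d, nrm)
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3v(nrm, ref)); e2 <- cross3v(nrm, e1)
  org <- plane$point
  xy <- cbind(sweep(proj, 2L, org) %*% e1, sweep(proj, 2L, org) %*% e2)
  cf <- fit_circle_2d(xy)
  if (cf$flat || cf$radius > flat_cap)
    return(list(radius = Inf, center = c(NA, NA, NA),
                residual_rms = if (cf$flat) cf$rms else cf$rms,
                flat = TRUE, n_points = nrow(points)))
  center3 <- org + cf$center[1] * e1 + cf$center[2] * e2
  sgn <- 1
  if (!is.null(surface_normal))
    sgn <- if (sum((center3 - probe) * surface_normal) < 0) 1 else -1
  list(radius = sgn * cf$radius, center = center3,
       residual_rms = cf$rms, flat = FALSE, n_points = nrow(points))
}

#' Local signed AP and ML radii of curvature at a probe point
#'
#' Composes the measurement pipeline at one probe point: builds the AP and
#' ML planes from the cylinder fit, isolates the elliptical region of
#' interest centred on the probe (major axis anteroposterior), intersects
#' the patch with each plane, and fits a signed circle to each section
#' curve. Section points lie exactly on both the surface and the plane, so
#' no projection bias enters the radii.
#'
#' @param mesh a \code{surface_mesh}.
#' @param probe length-3 point of interest on the surface.
#' @param cyl a \code{cylinder_fit} of the posterior articulating surface.
#' @param patch_area ellipse area, mm^2 (default 270, the median defect
#'   size).
#' @param patch_aspect ellipse aspect ratio (default 1.70, consistent with
#'   24.2 x 14.2 mm axes at 270 mm^2).
#' @param flat_cap flat-radius threshold, mm.
#' @return object of class \code{roc_probe_result}: \code{probe},
#'   \code{ap_radius_mm}, \code{ml_radius_mm} (signed; Inf = flat),
#'   \code{ap_residual_mm}, \code{ml_residual_mm}, \code{ap_flat},
#'   \code{ml_flat}, \code{patch_area_mm2} (measured), \code{patch_aspect}
#'   (requested), \code{boundary_clipped}.
#' @export
measure_roc <- function(mesh, probe, cyl, patch_area = 270,
                        patch_aspect = 1.70, flat_cap = 500) {
  axes <- patch_dimensions(patch_area, patch_aspect)
  planes <- probe_planes(cyl, probe)
  patch <- extract_elliptical_patch(mesh, probe, axes, cyl$axis_direction)
  frame <- attr(patch, "frame")
  fit1 <- function(plane) {
    pts <- mesh_plane_section(patch, plane)
    if (nrow(pts) < 3L)
      stop("measurement plane intersects fewer than 3 patch points")
    fit_circle_in_plane(pts, plane, surface_normal = frame$normal,
                        probe = probe, flat_cap = flat_cap)
  }
  ap <- fit1(planes$ap)
  ml <- fit1(planes$ml)
  structure(list(probe = probe,
                 ap_radius_mm = ap$radius, ml_radius_mm = ml$radius,
                 ap_residual_mm = ap$residual_rms,
                 ml_residual_mm = ml$residual_rms,
                 ap_flat = ap$flat, ml_flat = ml$flat,
                 patch_area_mm2 = surface_area(patch),
                 patch_aspect = patch_aspect,
                 boundary_clipped = attr(patch, "boundary_clipped")),
            class = "roc_probe_result")
}

#' @export
print.roc_probe_result <- function(x, ...) {
  fmt <- function(r, fl) if (fl) "flat" else sprintf("%+.1f mm", r)
  cat(sprintf("roc_probe_result: AP %s, ML %s (patch %.0f mm^2%s)\n",
              fmt(x$ap_radius_mm, x$ap_flat), fmt(x$ml_radius_mm, x$ml_flat),
              x$patch_area_mm2,
              if (x$boundary_clipped) ", boundary-clipped" else ""))
  invisible(x)
}

#' Select the posterior articulating surface
#'
#' Faces of the condylar lobes posterior of a frame plane: faces whose
#' label is in \code{labels} (all faces for unlabelled meshes) with
#' centroid y < \code{y_cut}.
#'
#' @param mesh a \code{surface_mesh} in the working frame (+y anterior).
#' @param y_cut anterior limit of the selection, mm (default 0).
#' @param labels face labels eligible for selection.
#' @return \code{surface_mesh} submesh (with \code{"orig_vertices"}).
#' @export
select_posterior_articulating_surface <- function(
    mesh, y_cut = 0, labels = c("medial_condyle", "lateral_condyle")) {
  cen <- face_centroids(mesh)
  mask <- cen[, 2] < y_cut
  if (!is.null(mesh$face_labels)) mask <- mask & mesh$face_labels %in% labels
  if (!any(mask)) stop("posterior articulating selection is empty")
  submesh(mesh, mask)
}

#' Place equally spaced probe points along the anteroposterior direction
#'
#' Intersects the surface with the AP plane through the anchor point (the
#' plane family defined by the cylinder axis), fits a circle to the
#' section arc, and returns \code{n} points equally spaced in arc length
#' along the section and centred on the anchor. In hotspot mode the anchor
#' is typically the heat-map argmax vertex; for the trochlea it is
#' user-specified.
#'
#' @param mesh a \code{surface_mesh} (optionally a region submesh).
#' @param cyl a \code{cylinder_fit} defining the AP plane family.
#' @param anchor length-3 anchor point on the surface.
#' @param n number of points (default 5).
#' @param spacing arc-length spacing between consecutive points, mm;
#'   default half the major axis of the 270 mm^2 / 1.70 reference ellipse.
#' @return n x 3 matrix of on-surface points (row \code{(n+1)/2} at the
#'   anchor for odd n).
#' @export
place_probe_points <- function(mesh, cyl, anchor, n = 5L, spacing = NULL) {
  spacing <- spacing %||n% (patch_dimensions(270, 1.70)[["major_mm"]] / 2)
  plane <- list(normal = unitize(cyl$axis_direction), point = anchor)
  sec <- mesh_plane_section(mesh, plane)
  if (nrow(sec) < 3L) stop("AP section through the anchor is too small")
  ## parameterise the section arc by angle about its fitted circle centre
  nrm <- plane$normal
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3v(nrm, ref)); e2 <- cross3v(nrm, e1)
  xy <- cbind(sweep(sec, 2L, anchor) %*% e1, sweep(sec, 2L, anchor) %*% e2)
  cf <- fit_circle_2d(xy)
  if (cf$flat) stop("AP section is straight; cannot space points by arc")
  th <- atan2(xy[, 2] - cf$center[2], xy[, 1] - cf$center[1])
  th0 <- atan2(-cf$center[2], -cf$center[1])   # anchor is at the origin
  dth <- wrap_angle(th - th0)
  ord <- order(dth)
  dth_s <- dth[ord]
  offs <- (seq_len(n) - (n + 1) / 2) * spacing / cf$radius
  if (min(offs) < min(dth_s) || max(offs) > max(dth_s))
    stop("region too small for ", n, " points at ", signif(spacing, 3),
         " mm spacing")
  out <- matrix(NA_real_, n, 3L)
  sec_s <- sec[ord, , drop = FALSE]
  for (i in seq_len(n)) {
    j <- findInterval(offs[i], dth_s, all.inside = TRUE)
    w <- if (dth_s[j + 1] == dth_s[j]) 0 else
      (offs[i] - dth_s[j]) / (dth_s[j + 1] - dth_s[j])
    out[i, ] <- (1 - w) * sec_s[j, ] + w * sec_s[j + 1, ]
  }
  out
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Long-format probe-result table for a sample population
#'
#' @param results list of lists of \code{roc_probe_result} (outer: model,
#'   inner: probe point), or a flat list.
#' @param point_ids optional probe-point ids.
#' @param region region name recorded in the table.
#' @return data.frame: model, point, region, ap_radius_mm, ml_radius_mm,
#'   ap_flat, ml_flat.
#' @export
roc_results_table <- function(results, point_ids = NULL, region = NA) {
  if (length(results) && inherits(results[[1]], "roc_probe_result"))
    results <- list(results)
  rows <- list()
  for (m in seq_along(results)) {
    rs <- results[[m]]
    for (p in seq_along(rs)) {
      r <- rs[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, point = point_ids[p] %||n% p, region = region,
        ap_radius_mm = r$ap_radius_mm, ml_radius_mm = r$ml_radius_mm,
        ap_flat = r$ap_flat, ml_flat = r$ml_flat,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
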