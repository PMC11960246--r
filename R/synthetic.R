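#' Configuration for the synthetic condyle cohort generator
#'
#' Describes a population of smooth bicondylar cartilage-like sheets used as
#' a statistical stand-in for segmented distal femoral cartilage surfaces.
#' The base surface is a parametric sweep of sagittal circles of radius
#' \code{condyle_radius} whose centres are lifted mediolaterally by a
#' Gaussian ridge of height \code{groove_depth}; this produces two convex
#' posterior-distal lobes separated by a central groove that is concave
#' mediolaterally and convex anteroposteriorly, with closed-form normal
#' section curvatures everywhere.
#'
#' Working frame: +x medial, +y anterior, +z proximal, left-knee convention;
#' the articulating side faces distally (-z).
#'
#' @param n_models number of models in the cohort (>= 3).
#' @param condyle_radius sagittal (anteroposterior) section radius, mm.
#' @param condyle_separation distance between the groove inflection lines
#'   (inner condyle edges), mm.
#' @param groove_depth height of the trochlear ridge, mm; must be smaller
#'   than \code{condyle_radius}.
#' @param ap_extent arc length of the sheet in the anteroposterior
#'   direction, mm.
#' @param ml_extent width of the sheet in the mediolateral direction, mm.
#' @param mode_amplitudes standard deviations (mm) of the smooth planted
#'   deformation modes; length gives the number of modes (up to 4).
#' @param vertex_noise_sd isotropic per-vertex Gaussian noise, mm.
#' @param defect_area_median median defect articulating area, mm^2.
#' @param defect_aspect_median median defect aspect ratio (>= 1).
#' @param defect_area_sdlog log-sd of the log-normal area distribution.
#' @param defect_aspect_sdlog log-sd of the log-normal (aspect - 1)
#'   distribution.
#' @param hotspot_center parametric surface coordinate c(u, v) of the
#'   planted defect hotspot (u in radians along AP, v in [-1, 1] along ML).
#' @param hotspot_spread standard deviation of defect centres around the
#'   hotspot, mm on the surface.
#' @param side_mix fraction of right-sided models (mirrored on export).
#' @param nu,nv mesh resolution along u and v.
#' @param seed integer seed fixing every random draw.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_models = 70L,
                          condyle_radius = 40,
                          condyle_separation = 19,
                          groove_depth = 6,
                          ap_extent = 65,
                          ml_extent = 60,
                          mode_amplitudes = c(2, 1, 0.5, 0.25),
                          vertex_noise_sd = 0.1,
                          defect_area_median = 270,
                          defect_aspect_median = 1.6,
                          defect_area_sdlog = 0.63,
                          defect_aspect_sdlog = 0.6,
                          hotspot_center = c(-0.25, 0.55),
                          hotspot_spread = 5,
                          side_mix = 0.5,
                          nu = 48L, nv = 36L,
                          seed = 1L) {
  cfg <- list(n_models = as.integer(n_models),
              condyle_radius = condyle_radius,
              condyle_separation = condyle_separation,
              groove_depth = groove_depth,
              ap_extent = ap_extent, ml_extent = ml_extent,
              mode_amplitudes = mode_amplitudes,
              vertex_noise_sd = vertex_noise_sd,
              defect_area_median = defect_area_median,
              defect_aspect_median = defect_aspect_median,
              defect_area_sdlog = defect_area_sdlog,
              defect_aspect_sdlog = defect_aspect_sdlog,
              hotspot_center = hotspot_center,
              hotspot_spread = hotspot_spread,
              side_mix = side_mix,
              nu = as.integer(nu), nv = as.integer(nv),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_models < 3L) stop("n_models must be >= 3")
  lens <- c(cfg$condyle_radius, cfg$condyle_separation, cfg$ap_extent,
            cfg$ml_extent)
  if (any(lens <= 0)) stop("all length scales must be positive")
  if (cfg$groove_depth < 0) stop("groove_depth must be >= 0")
  if (cfg$groove_depth >= cfg$condyle_radius)
    stop("degenerate geometry: groove_depth must be < condyle_radius")
  if (cfg$defect_aspect_median < 1) stop("defect_aspect_median must be >= 1")
  if (cfg$vertex_noise_sd < 0 || cfg$hotspot_spread < 0)
    stop("standard deviations must be >= 0")
  if (cfg$side_mix < 0 || cfg$side_mix > 1)
    stop("side_mix must be in [0, 1]")
  if (length(cfg$mode_amplitudes) > 4L)
    stop("at most 4 planted deformation modes are available")
  invisible(cfg)
}

## ---- parametric base surface ------------------------------------------
##
## F(u, v) = ( (W/2) v,  R sin u,  g(u, v) - R cos u ),
## g(u, v) = G exp(-(v / sg)^2) s(u): a mediolateral Gaussian ridge
## (trochlear groove walls) gated anteriorly by the logistic s(u), so the
## posterior condyles are exactly cylindrical (as assumed by the
## posterior-cylinder fit) while the anterior centre carries the groove.
## sg is set so the ridge inflection |v| = sg/sqrt(2) falls at
## condyle_separation/2 in mm.

groove_sigma <- function(cfg) {
  (cfg$condyle_separation / cfg$ml_extent) * sqrt(2)
}

u_range <- function(cfg) {
  span <- cfg$ap_extent / cfg$condyle_radius
  c(-0.55 * span, 0.45 * span)  # posterior wrap slightly larger
}

## anterior gate: quintic smoothstep in u, exactly 0 posterior of
## GROOVE_U_ON and exactly 1 anterior of GROOVE_U_FULL (with vanishing
## first and second derivatives at both ends), so the posterior condyles
## are exactly cylindrical and the anterior trochlea exactly separable
GROOVE_U_ON <- -0.55
GROOVE_U_FULL <- 0.05

groove_gate <- function(u) {
  w <- GROOVE_U_FULL - GROOVE_U_ON
  t <- pmin(pmax((u - GROOVE_U_ON) / w, 0), 1)
  s <- 6 * t^5 - 15 * t^4 + 10 * t^3
  sp <- (30 * t^4 - 60 * t^3 + 30 * t^2) / w
  spp <- (120 * t^3 - 180 * t^2 + 60 * t) / w^2
  list(s = s, sp = sp, spp = spp)
}

## value and partial derivatives of the ridge g(u, v)
g_ridge <- function(cfg, u, v) {
  sg <- groove_sigma(cfg); G <- cfg$groove_depth
  gate <- groove_gate(u)
  s <- gate$s; sp <- gate$sp; spp <- gate$spp
  e <- exp(-(v / sg)^2)
  ev <- e * (-2 * v / sg^2)
  evv <- e * (4 * v^2 / sg^4 - 2 / sg^2)
  list(g = G * e * s, gu = G * e * sp, gv = G * ev * s,
       guu = G * e * spp, guv = G * ev * sp, gvv = G * evv * s)
}

surface_point_uv <- function(cfg, u, v) {
  R <- cfg$condyle_radius; W2 <- cfg$ml_extent / 2
  cbind(W2 * v, R * sin(u), g_ridge(cfg, u, v)$g - R * cos(u))
}

#' Closed-form signed normal-section radii of the base surface
#'
#' Evaluates the first and second fundamental forms of the parametric base
#' surface at (u, v) and returns the signed radii of the normal sections in
#' the anteroposterior direction (along the u tangent) and the mediolateral
#' direction (the in-surface direction perpendicular to it). Sign
#' convention: positive = convex (centre of curvature on the bone side of
#' the outward articular normal), negative = concave; an infinite radius is
#' returned for flat sections.
#'
#' @param cfg a \code{cohort_config}.
#' @param u,v parametric coordinates.
#' @return list with \code{point}, \code{normal} (outward), \code{r_ap},
#'   \code{r_ml} (signed mm, possibly \code{Inf}).
#' @export
surface_truth_radii <- function(cfg, u, v) {
  R <- cfg$condyle_radius; W2 <- cfg$ml_extent / 2
  gr <- g_ridge(cfg, u, v)
  Fu <- c(0, R * cos(u), gr$gu + R * sin(u))
  Fv <- c(W2, 0, gr$gv)
  Fuu <- c(0, -R * sin(u), gr$guu + R * cos(u))
  Fuv <- c(0, 0, gr$guv)
  Fvv <- c(0, 0, gr$gvv)
  n_raw <- cross3v(Fu, Fv)
  ## orient outward: away from the local sagittal circle centre
  radial <- c(0, R * sin(u), -R * cos(u))
  n <- unitize(n_raw) * sign(sum(unitize(n_raw) * radial))
  E <- sum(Fu^2); Ff <- sum(Fu * Fv); G2 <- sum(Fv^2)
  L <- sum(Fuu * n); M <- sum(Fuv * n); N2 <- sum(Fvv * n)
  ## AP: t = Fu
  r_ap <- signed_radius_from_ii(E, L)
  ## ML: in-surface direction orthogonal to Fu: t = a Fu + Fv, a = -Ff/E
  a <- -Ff / E
  I_ml <- E * a^2 + 2 * Ff * a + G2
  II_ml <- L * a^2 + 2 * M * a + N2
  r_ml <- signed_radius_from_ii(I_ml, II_ml)
  list(point = drop(surface_point_uv(cfg, u, v)), normal = n,
       r_ap = r_ap, r_ml = r_ml)
}

signed_radius_from_ii <- function(I, II) {
  if (abs(II) < 1e-14 * max(I, 1)) return(Inf)
  -I / II
}

#' Generate the synthetic bicondylar base surface
#'
#' Builds the parametric sheet as a triangulated mesh with faces labelled
#' \code{medial_condyle} (v > 0.25), \code{lateral_condyle} (v < -0.25) and
#' \code{trochlea} (central band), and attaches per-vertex parametric
#' coordinates and a truth record with closed-form signed AP/ML radii at
#' three designated probe points (medial condyle apex, lateral condyle
#' apex, trochlear groove centre).
#'
#' @param cfg a \code{cohort_config}.
#' @return list with \code{mesh} (a \code{surface_mesh} with attribute
#'   \code{"uv"}), \code{probes} (data.frame of probe truth) and \code{cfg}.
#' @export
generate_base_surface <- function(cfg) {
  validate_cohort_config(cfg)
  ur <- u_range(cfg)
  us <- seq(ur[1], ur[2], length.out = cfg$nu)
  vs <- seq(-1, 1, length.out = cfg$nv)
  uv <- cbind(u = rep(us, times = cfg$nv), v = rep(vs, each = cfg$nu))
  verts <- surface_point_uv(cfg, uv[, 1], uv[, 2])
  ## centre the mesh so rigid components of planted modes stay small
  verts <- sweep(verts, 2L, colMeans(verts))
  idx <- function(i, j) (j - 1L) * cfg$nu + i
  i <- rep(seq_len(cfg$nu - 1L), times = cfg$nv - 1L)
  j <- rep(seq_len(cfg$nv - 1L), each = cfg$nu - 1L)
  ## winding chosen so outward (distal, -z at the apex) normals are CCW
  f1 <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
  f2 <- cbind(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
  faces <- rbind(f1, f2)
  vc <- (uv[faces[, 1], 2] + uv[faces[, 2], 2] + uv[faces[, 3], 2]) / 3
  labels <- ifelse(vc > 0.25, "medial_condyle",
                   ifelse(vc < -0.25, "lateral_condyle", "trochlea"))
  mesh <- surface_mesh(verts, faces, face_labels = labels)
  ## flip winding if normals ended up inward at the distal apex
  apex <- which.min(abs(uv[, 1]) + abs(uv[, 2] - 0.6))
  vn <- vertex_normals(mesh)
  tr <- surface_truth_radii(cfg, uv[apex, 1], uv[apex, 2])
  if (sum(vn[apex, ] * tr$normal) < 0) {
    mesh <- surface_mesh(verts, faces[, c(1L, 3L, 2L)], face_labels = labels)
  }
  attr(mesh, "uv") <- uv
  ## trochlea probe on the anterior plateau where the ridge gate is fully on
  probes_uv <- rbind(medial_condyle = c(0, 0.6),
                     lateral_condyle = c(0, -0.6),
                     trochlea = c(min(0.35, 0.85 * ur[2]), 0))
  offset <- colMeans(surface_point_uv(cfg, uv[, 1], uv[, 2]))
  probes <- do.call(rbind, lapply(rownames(probes_uv), function(r) {
    t <- surface_truth_radii(cfg, probes_uv[r, 1], probes_uv[r, 2])
    data.frame(region = r, u = probes_uv[r, 1], v = probes_uv[r, 2],
               x = t$point[1] - offset[1], y = t$point[2] - offset[2],
               z = t$point[3] - offset[3],
               r_ap = t$r_ap, r_ml = t$r_ml, stringsAsFactors = FALSE)
  }))
  list(mesh = mesh, probes = probes, cfg = cfg)
}

## ---- planted deformation modes ----------------------------------------

## Fixed smooth displacement fields, made orthonormal as 3m-vectors and
## orthogonal to the infinitesimal rigid motions so generalised Procrustes
## alignment leaves the planted PCA structure intact.
planted_mode_basis <- function(mesh, q) {
  V <- mesh$vertices
  uv <- attr(mesh, "uv")
  n <- nrow(V)
  raw <- cbind(
    as.vector(cbind(0 * V[, 1], V[, 2], 0 * V[, 3])),          # AP stretch
    as.vector(cbind(V[, 1], 0 * V[, 2], 0 * V[, 3])),          # ML widen
    as.vector(cbind(0 * V[, 1], 0 * V[, 2],
                    exp(-(uv[, 2] / 0.45)^2))),                # groove depth
    as.vector(cbind(0 * V[, 1], sin(pi * uv[, 2]) * cos(uv[, 1]),
                    0 * V[, 3])))                              # AP skew
  rigid <- cbind(
    rep(c(1, 0, 0), each = n), rep(c(0, 1, 0), each = n),
    rep(c(0, 0, 1), each = n),
    as.vector(cbind(0 * V[, 1], -V[, 3], V[, 2])),
    as.vector(cbind(V[, 3], 0 * V[, 2], -V[, 1])),
    as.vector(cbind(-V[, 2], V[, 1], 0 * V[, 3])))
  rq <- qr.Q(qr(rigid))
  raw <- raw - rq %*% (t(rq) %*% raw)
  Q <- qr.Q(qr(raw))
  Q[, seq_len(q), drop = FALSE]
}

## ---- cohort generation -------------------------------------------------

#' Generate a synthetic cohort of native and defect cartilage models
#'
#' Each native model is the base surface displaced along the planted
#' orthonormal deformation modes with Gaussian coefficients, plus isotropic
#' vertex noise, then rigidly transformed; right-sided models (drawn with
#' probability \code{side_mix}) are mirrored in the sagittal plane so the
#' stored model is "as-scanned". Each defect is an extruded elliptical patch
#' of the native articulating surface whose centre is drawn around the
#' planted hotspot and whose area and aspect ratio are drawn from log-normal
#' distributions around the configured medians. Every model carries a truth
#' record sufficient to score all downstream estimates.
#'
#' @param cfg a \code{cohort_config}.
#' @return object of class \code{synthetic_cohort}: list with \code{cfg},
#'   \code{base}, \code{modes} (3m x q orthonormal planted basis),
#'   \code{natives}, \code{defects} (lists of \code{surface_mesh}),
#'   \code{truth} (list of per-model records) and \code{manifest}
#'   (data.frame: model_id, side, defect_region).
#' @export
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  base <- generate_base_surface(cfg)
  mesh0 <- base$mesh
  uv <- attr(mesh0, "uv")
  n <- nrow(mesh0$vertices)
  sds <- cfg$mode_amplitudes
  q <- length(sds)
  Q <- if (q > 0L) planted_mode_basis(mesh0, q) else
    matrix(numeric(0), 3L * n, 0L)
  ## local metric at the hotspot for mm -> parametric conversion
  hs <- cfg$hotspot_center
  met <- uv_metric(cfg, hs[1], hs[2])

  natives <- vector("list", cfg$n_models)
  defects <- vector("list", cfg$n_models)
  truth <- vector("list", cfg$n_models)
  sides <- character(cfg$n_models)
  regions <- character(cfg$n_models)
  for (i in seq_len(cfg$n_models)) {
    b <- if (q > 0L) stats::rnorm(q, 0, sds) else numeric(0)
    disp <- if (q > 0L) matrix(Q %*% b, n, 3L) else matrix(0, n, 3L)
    noise <- if (cfg$vertex_noise_sd > 0)
      matrix(stats::rnorm(3L * n, 0, cfg$vertex_noise_sd), n, 3L)
    else matrix(0, n, 3L)
    nat0 <- surface_mesh(mesh0$vertices + disp + noise, mesh0$faces,
                         face_labels = mesh0$face_labels)
    attr(nat0, "uv") <- uv
    ## defect draw
    duv <- c(hs[1] + stats::rnorm(1, 0, cfg$hotspot_spread) / met$du,
             hs[2] + stats::rnorm(1, 0, cfg$hotspot_spread) / met$dv)
    area <- stats::rlnorm(1, log(cfg$defect_area_median),
                          cfg$defect_area_sdlog)
    aspect <- 1 + stats::rlnorm(1, log(max(cfg$defect_aspect_median - 1,
                                           1e-6)),
                                cfg$defect_aspect_sdlog)
    def0 <- build_defect_patch(nat0, cfg, duv, area, aspect)
    ## rigid placement ("as-scanned" pose)
    ang <- stats::runif(3, -15, 15) * pi / 180
    Rm <- rot_xyz(ang[1], ang[2], ang[3])
    tv <- stats::runif(3, -20, 20)
    nat <- transform_mesh(nat0, Rm, tv)
    def <- transform_mesh(def0, Rm, tv)
    side <- if (stats::runif(1) < cfg$side_mix) "right" else "left"
    if (side == "right") {
      nat <- mirror_sagittal(nat)
      def <- mirror_sagittal(def)
    }
    center3d <- drop(surface_point_uv(cfg, duv[1], duv[2])) -
      colMeans(surface_point_uv(cfg, uv[, 1], uv[, 2]))
    natives[[i]] <- nat
    defects[[i]] <- def
    sides[i] <- side
    regions[i] <- if (duv[2] > 0.25) "medial"
    else if (duv[2] < -0.25) "lateral" else "trochlea"
    truth[[i]] <- list(model_id = sprintf("model_%03d", i),
                       mode_coefficients = b,
                       rotation = Rm, translation = tv, side = side,
                       defect_center_uv = duv,
                       defect_center_canonical = center3d,
                       defect_area_mm2 = area,
                       defect_aspect = aspect,
                       probes = base$probes)
  }
  structure(list(cfg = cfg, base = base, modes = Q,
                 natives = natives, defects = defects, truth = truth,
                 manifest = data.frame(
                   model_id = vapply(truth, `[[`, character(1), "model_id"),
                   side = sides, defect_region = regions,
                   stringsAsFactors = FALSE)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d models (%d right-sided), %d planted modes, seed %d\n",
    length(x$natives), sum(x$manifest$side == "right"),
    ncol(x$modes), x$cfg$seed))
  invisible(x)
}

## metric scale (mm per unit u / unit v) at a parametric point
uv_metric <- function(cfg, u, v) {
  gr <- g_ridge(cfg, u, v)
  list(du = sqrt(cfg$condyle_radius^2 + gr$gu^2),
       dv = sqrt((cfg$ml_extent / 2)^2 + gr$gv^2))
}

## Elliptical patch of the native surface around parametric centre duv,
## extruded toward the bone side to a thin solid-like open shell.
build_defect_patch <- function(native, cfg, duv, area, aspect,
                               thickness = 1.5) {
  uv <- attr(native, "uv")
  ax <- patch_dimensions(area, aspect)
  met <- uv_metric(cfg, duv[1], duv[2])
  ## face-centroid membership in parametric mm coordinates: approximately
  ## area-preserving (rim faces balance in and out)
  fc_u <- (uv[native$faces[, 1], 1] + uv[native$faces[, 2], 1] +
             uv[native$faces[, 3], 1]) / 3
  fc_v <- (uv[native$faces[, 1], 2] + uv[native$faces[, 2], 2] +
             uv[native$faces[, 3], 2]) / 3
  du_mm <- (fc_u - duv[1]) * met$du
  dv_mm <- (fc_v - duv[2]) * met$dv
  ## major axis along AP (u direction)
  fin <- (du_mm / (ax[1] / 2))^2 + (dv_mm / (ax[2] / 2))^2 <= 1
  if (!any(fin)) stop("defect patch fell outside the meshed surface")
  patch <- submesh(native, fin)
  comp <- face_components(patch)
  if (max(comp) > 1L) {
    keep <- comp == which.max(tabulate(comp))
    patch <- submesh(patch, keep, keep_vertex_ids = FALSE)
  }
  extrude_patch(patch, thickness)
}

## articulating faces keep native coordinates; bottom shifted along the
## inward (bone-side) normal; walls close the rim
extrude_patch <- function(patch, thickness) {
  nv <- nrow(patch$vertices)
  vn <- vertex_normals(patch)
  bottom_v <- patch$vertices - thickness * vn  # outward points away from bone
  verts <- rbind(patch$vertices, bottom_v)
  top_f <- patch$faces
  bot_f <- patch$faces[, c(1L, 3L, 2L), drop = FALSE] + nv
  ## rim walls from boundary edges
  ef <- edge_face_table(patch)
  bkeys <- names(ef)[lengths(ef) == 1L]
  wall_f <- NULL
  if (length(bkeys)) {
    be <- do.call(rbind, lapply(strsplit(bkeys, " "), as.integer))
    wall_f <- rbind(cbind(be[, 1], be[, 2], be[, 2] + nv),
                    cbind(be[, 1], be[, 2] + nv, be[, 1] + nv))
  }
  faces <- rbind(top_f, bot_f, wall_f)
  labels <- c(rep("articulating", nrow(top_f)),
              rep("bottom", nrow(bot_f)),
              rep("wall", if (is.null(wall_f)) 0L else nrow(wall_f)))
  surface_mesh(verts, faces, face_labels = labels)
}

rot_xyz <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## ---- analytic fixtures -------------------------------------------------

#' Analytic surface fixtures with closed-form curvature truth
#'
#' Samples meshes or point sets from named closed forms, used as oracles for
#' the curvature and defect-metric operations.
#'
#' \describe{
#'   \item{sphere_cap}{params: \code{radius}, \code{cap_angle} (rad, default
#'     pi/2.5), \code{n} rings. Both principal radii equal \code{+radius}.}
#'   \item{cylinder_patch}{params: \code{radius}, \code{length},
#'     \code{arc} (rad, default 4pi/3), \code{n}. Circumferential radius
#'     \code{+radius}, axial section flat.}
#'   \item{saddle_patch}{params: signed \code{r_ap}, \code{r_ml},
#'     \code{extent} (mm half-width), \code{n}. Height field
#'     z = -x^2/(2 r_ap) - y^2/(2 r_ml), outward normal +z at the origin.}
#'   \item{planar_ellipse}{params: full axes \code{major}, \code{minor},
#'     \code{n}. Flat elliptical disc, truth area pi*major*minor/4.}
#'   \item{exact_circle_points}{params: \code{radius}, \code{n},
#'     \code{center} (3), \code{normal} (3). Returns a point matrix.}
#' }
#'
#' @param kind fixture name (see Details).
#' @param ... closed-form parameters.
#' @return list with \code{mesh} (or \code{points}) and \code{truth}.
#' @export
analytic_fixture <- function(kind = c("sphere_cap", "cylinder_patch",
                                      "saddle_patch", "planar_ellipse",
                                      "exact_circle_points"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  ## exact name lookup: `$` would partially match (e.g. n / normal)
  gp <- function(nm, default = NULL)
    if (nm %in% names(p)) p[[nm]] else default
  switch(kind,
         sphere_cap = fixture_sphere_cap(gp("radius"),
                                         gp("cap_angle", pi / 2.5),
                                         gp("n", 40L)),
         cylinder_patch = fixture_cylinder(gp("radius"), gp("length"),
                                           gp("arc", 4 * pi / 3),
                                           gp("n", 40L)),
         saddle_patch = fixture_saddle(gp("r_ap"), gp("r_ml"),
                                       gp("extent", 15), gp("n", 40L)),
         planar_ellipse = fixture_ellipse(gp("major"), gp("minor"),
                                          gp("n", 60L)),
         exact_circle_points = fixture_circle_points(
           gp("radius"), gp("n", 100L), gp("center", c(0, 0, 0)),
           gp("normal", c(0, 0, 1))))
}

`%||n%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("fixture dimension parameters must be positive")
}

fixture_sphere_cap <- function(radius, cap_angle, n) {
  check_positive(radius, cap_angle)
  phis <- seq(0, cap_angle, length.out = n)[-1]
  nth <- 2L * n
  ths <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  g <- expand.grid(th = ths, ph = phis)
  ring <- cbind(radius * sin(g$ph) * cos(g$th),
                radius * sin(g$ph) * sin(g$th),
                radius * cos(g$ph))
  verts <- rbind(c(0, 0, radius), ring)
  idx <- function(i, j) 1L + (j - 1L) * nth + i  # ring j, azimuth i
  faces <- NULL
  ## apex fan
  i <- seq_len(nth); ip <- c(seq_len(nth - 1L) + 1L, 1L)
  faces <- cbind(1L, idx(i, 1L), idx(ip, 1L))
  for (j in seq_len(length(phis) - 1L)) {
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i, j + 1L), idx(ip, j)),
                   cbind(idx(ip, j), idx(i, j + 1L), idx(ip, j + 1L)))
  }
  m <- surface_mesh(verts, faces)
  vn <- vertex_normals(m)
  if (sum(vn[1, ] * c(0, 0, 1)) < 0)
    m <- surface_mesh(verts, faces[, c(1L, 3L, 2L)])
  list(mesh = m,
       truth = list(r1 = radius, r2 = radius, radius = radius))
}

fixture_cylinder <- function(radius, length, arc, n) {
  check_positive(radius, length, arc)
  ths <- seq(-arc / 2, arc / 2, length.out = n)
  zs <- seq(-length / 2, length / 2, length.out = n)
  g <- expand.grid(th = ths, z = zs)
  verts <- cbind(radius * cos(g$th), radius * sin(g$th), g$z)
  faces <- grid_faces(n, n)
  m <- surface_mesh(verts, faces)
  ## orient outward (radially away from the axis)
  vn <- vertex_normals(m)
  if (sum(vn[1, ] * c(verts[1, 1:2], 0)) < 0)
    m <- surface_mesh(verts, faces[, c(1L, 3L, 2L)])
  list(mesh = m,
       truth = list(radius = radius, axis = c(0, 0, 1),
                    axis_point = c(0, 0, 0), r_circumferential = radius,
                    r_axial = Inf))
}

fixture_saddle <- function(r_ap, r_ml, extent, n) {
  if (is.null(r_ap) || is.null(r_ml) || r_ap == 0 || r_ml == 0)
    stop("saddle radii must be nonzero")
  check_positive(extent, abs(r_ap), abs(r_ml))
  xs <- seq(-extent, extent, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  z <- -g$x^2 / (2 * r_ap) - g$y^2 / (2 * r_ml)
  verts <- cbind(g$x, g$y, z)
  faces <- grid_faces(n, n)
  m <- surface_mesh(verts, faces)
  ## orient so outward normal is +z at the origin
  vn <- vertex_normals(m)
  c0 <- which.min(rowSums(verts[, 1:2]^2))
  if (vn[c0, 3] < 0) m <- surface_mesh(verts, faces[, c(1L, 3L, 2L)])
  list(mesh = m, truth = list(r_ap = r_ap, r_ml = r_ml,
                              signs = sign(c(r_ap, r_ml))))
}

fixture_ellipse <- function(major, minor, n) {
  check_positive(major, minor)
  a <- major / 2; b <- minor / 2
  rs <- seq(0, 1, length.out = max(8L, n %/% 4L))[-1]
  nth <- n
  ths <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  g <- expand.grid(th = ths, r = rs)
  verts <- rbind(c(0, 0, 0),
                 cbind(a * g$r * cos(g$th), b * g$r * sin(g$th), 0))
  idx <- function(i, j) 1L + (j - 1L) * nth + i
  i <- seq_len(nth); ip <- c(seq_len(nth - 1L) + 1L, 1L)
  faces <- cbind(1L, idx(i, 1L), idx(ip, 1L))
  for (j in seq_len(length(rs) - 1L)) {
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i, j + 1L), idx(ip, j)),
                   cbind(idx(ip, j), idx(i, j + 1L), idx(ip, j + 1L)))
  }
  list(mesh = surface_mesh(verts, faces),
       truth = list(major = major, minor = minor,
                    area = pi * a * b, aspect = major / minor))
}

fixture_circle_points <- function(radius, n, center, normal) {
  check_positive(radius)
  nrm <- unitize(normal)
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3v(nrm, ref)); e2 <- cross3v(nrm, e1)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- sweep(radius * (outer(cos(th), e1) + outer(sin(th), e2)),
               2L, center, "+")
  list(points = pts, truth = list(radius = radius, center = center))
}

grid_faces <- function(nu, nv) {
  idx <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
        cbind(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L)))
}

## ---- cohort serialisation ---------------------------------------------

#' Write a synthetic cohort to disk
#'
#' Writes one ASCII PLY per native and defect model, a truth JSON, and a
#' manifest CSV (model_id, side, defect_region, file paths). Output is
#' deterministic byte-for-byte for a fixed config and seed.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$native_path <- file.path(dir, paste0(man$model_id, "_native.ply"))
  man$defect_path <- file.path(dir, paste0(man$model_id, "_defect.ply"))
  for (i in seq_along(cohort$natives)) {
    write_mesh(cohort$natives[[i]], man$native_path[i])
    write_mesh(cohort$defects[[i]], man$defect_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- lapply(cohort$truth, function(t) {
    t$rotation <- as.vector(t$rotation)
    t$probes <- NULL
    t
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}
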