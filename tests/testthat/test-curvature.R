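test_that("patch_dimensions inverts area and aspect exactly", {
  ax <- patch_dimensions(270, 1.7)
  expect_equal(round(unname(ax), 1), c(24.2, 14.2))
  expect_equal(unname(patch_dimensions(pi, 1)), c(2, 2), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    area <- stats::runif(1, 10, 800); aspect <- stats::runif(1, 1, 4)
    ax <- patch_dimensions(area, aspect)
    expect_equal(pi * ax[[1]] * ax[[2]] / 4, area,
                 tolerance = 1e-10 * area)
    expect_equal(ax[[1]] / ax[[2]], aspect, tolerance = 1e-10)
  }
  expect_error(patch_dimensions(-1, 2), "positive")
  expect_error(patch_dimensions(10, 0.5), "aspect")
})

test_that("circle fits recover exact circles in any pose and flag collinear input", {
  set.seed(9)
  for (rep in 1:5) {
    nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    ctr <- stats::rnorm(3, 0, 20)
    fx <- analytic_fixture("exact_circle_points", radius = 5, n = 60L,
                           center = ctr, normal = nrm)
    cf <- fit_circle_in_plane(fx$points, list(normal = nrm, point = ctr))
    expect_equal(abs(cf$radius), 5, tolerance = 1e-6)
    expect_lt(cf$residual_rms, 1e-9)
  }
  line <- cbind(seq(0, 10, length.out = 20), 0, 0)
  cl <- fit_circle_in_plane(line, list(normal = c(0, 0, 1),
                                       point = c(0, 0, 0)))
  expect_true(cl$flat)
})

test_that("noisy circle fits stay within 0.5 mm of a 25.6 mm radius", {
  for (s in 1:20) {
    set.seed(200 + s)
    fx <- analytic_fixture("exact_circle_points", radius = 25.6, n = 80L)
    pts <- fx$points + matrix(stats::rnorm(240, 0, 0.05), ncol = 3L)
    cf <- fit_circle_in_plane(pts, list(normal = c(0, 0, 1),
                                        point = c(0, 0, 0)))
    expect_equal(abs(cf$radius), 25.6, tolerance = 0.5 / 25.6)
  }
})

test_that("cylinder fits recover exact cylinders and degrade gracefully with noise", {
  fx <- analytic_fixture("cylinder_patch", radius = 20, length = 40,
                         n = 23L)  # 529 points
  cf <- fit_cylinder(fx$mesh$vertices)
  expect_equal(cf$radius, 20, tolerance = 1e-6 / 20)
  expect_lt(acos(min(1, abs(sum(cf$axis_direction * c(0, 0, 1))))), 1e-6)
  expect_false(cf$ill_conditioned)
  for (s in 1:5) {
    set.seed(300 + s)
    noisy <- fx$mesh$vertices +
      matrix(stats::rnorm(length(fx$mesh$vertices), 0, 0.1), ncol = 3L)
    cfn <- fit_cylinder(noisy)
    expect_equal(cfn$radius, 20, tolerance = 0.1 / 20)
  }
})

test_that("spherical point sets are flagged as ill-conditioned cylinder fits", {
  sp <- analytic_fixture("sphere_cap", radius = 20, n = 18L)
  cf <- fit_cylinder(sp$mesh$vertices)
  expect_true(cf$ill_conditioned)
  expect_equal(cf$degeneracy, "spherical")
  expect_error(fit_cylinder(sp$mesh$vertices[1:4, ]), "at least 6")
})

test_that("probe planes follow the cylinder-axis construction", {
  cyl <- structure(list(axis_point = c(0, 0, 0),
                        axis_direction = c(0, 0, 1), radius = 20, rms = 0,
                        ill_conditioned = FALSE, degeneracy = "none"),
                   class = "cylinder_fit")
  pl <- probe_planes(cyl, c(20, 0, 5))
  expect_equal(pl$ap$normal, c(0, 0, 1))
  expect_equal(pl$ap$point, c(20, 0, 5))
  ## ML plane is y = 0: normal along y
  expect_equal(abs(pl$ml$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sum(pl$ap$normal * pl$ml$normal), 0, tolerance = 1e-12)
  expect_error(probe_planes(cyl, c(0, 0, 7)), "axis")
})

test_that("elliptical patches have the requested area on flat and gently curved surfaces", {
  ax <- patch_dimensions(270, 1.7)
  ## flat sheet: no projection distortion
  xs <- seq(-20, 20, length.out = 60L)
  g <- expand.grid(x = xs, y = xs)
  flat <- surface_mesh(cbind(g$x, g$y, 0), cartmorph:::grid_faces(60L, 60L))
  p <- extract_elliptical_patch(flat, c(0, 0, 0), ax, c(0, 1, 0))
  expect_equal(surface_area(p), 270, tolerance = 0.02)
  expect_false(attr(p, "boundary_clipped"))
  ## sphere radius 100: metric distortion O((size/R)^2)
  sp <- analytic_fixture("sphere_cap", radius = 100, cap_angle = 0.4,
                         n = 60L)$mesh
  ps <- extract_elliptical_patch(sp, c(0, 0, 100), ax, c(0, 1, 0))
  expect_equal(surface_area(ps), 270, tolerance = 0.03)
  ## the probe's nearest face lies in the patch
  cen <- cartmorph:::face_centroids(ps)
  expect_lt(min(sqrt(rowSums(sweep(cen, 2L, c(0, 0, 100))^2))),
            2 * mean_edge_length(sp))
})

test_that("sphere probes give AP = ML = R within 2 percent", {
  sp <- analytic_fixture("sphere_cap", radius = 20, n = 40L)
  cyl <- fit_cylinder(sp$mesh$vertices)   # flagged spherical, still usable
  r <- measure_roc(sp$mesh, c(0, 0, 20), cyl, patch_area = 270,
                   patch_aspect = 1.7)
  expect_equal(r$ap_radius_mm, 20, tolerance = 0.02)
  expect_equal(r$ml_radius_mm, 20, tolerance = 0.02)
  expect_false(r$ap_flat); expect_false(r$ml_flat)
})

test_that("sphere AP and ML radii agree across patch sizes 1-4 cm^2", {
  sp <- analytic_fixture("sphere_cap", radius = 20, n = 40L)
  cyl <- fit_cylinder(sp$mesh$vertices)
  for (area in c(100, 270, 400)) {
    r <- measure_roc(sp$mesh, c(0, 0, 20), cyl, patch_area = area,
                     patch_aspect = 1.7)
    expect_equal(r$ap_radius_mm, r$ml_radius_mm, tolerance = 0.02)
    expect_equal(r$ap_radius_mm, 20, tolerance = 0.02)
  }
})

test_that("a convex cylinder probe reads +R anteroposteriorly and flat mediolaterally", {
  fx <- analytic_fixture("cylinder_patch", radius = 20, length = 60,
                         n = 40L)
  cf <- fit_cylinder(fx$mesh$vertices)
  r <- measure_roc(fx$mesh, c(20, 0, 0), cf, 270, 1.7)
  expect_equal(r$ap_radius_mm, 20, tolerance = 0.02)
  expect_true(r$ml_flat)
})

test_that("saddle probes reproduce signed radii within 5 percent at moderate patch size", {
  sdl <- analytic_fixture("saddle_patch", r_ap = 25.6, r_ml = -15.7,
                          extent = 16, n = 50L)
  cyl <- structure(list(axis_point = c(0, 0, -25.6),
                        axis_direction = c(0, 1, 0), radius = 25.6,
                        rms = 0, ill_conditioned = FALSE,
                        degeneracy = "none"), class = "cylinder_fit")
  r <- measure_roc(sdl$mesh, c(0, 0, 0), cyl, patch_area = 100,
                   patch_aspect = 1.7)
  expect_equal(r$ap_radius_mm, 25.6, tolerance = 0.05)
  expect_equal(r$ml_radius_mm, -15.7, tolerance = 0.05)
})

test_that("trochlear measurements reproduce the saddle sign pattern and converge to closed-form truth as the patch shrinks", {
  cfg <- cohort_config(n_models = 3L, mode_amplitudes = numeric(0),
                       vertex_noise_sd = 0, seed = 2L)
  bs <- generate_base_surface(cfg)
  post <- select_posterior_articulating_surface(bs$mesh)
  cyl <- fit_cylinder(post$vertices)
  tro <- bs$probes[bs$probes$region == "trochlea", ]
  probe <- as.numeric(tro[c("x", "y", "z")])
  errs <- sapply(c(400, 270, 100, 50), function(area) {
    r <- measure_roc(bs$mesh, probe, cyl, patch_area = area,
                     patch_aspect = 1.7)
    expect_gt(r$ap_radius_mm, 0)          # convex anteroposterior
    expect_lt(r$ml_radius_mm, 0)          # concave mediolateral groove
    abs(r$ml_radius_mm - tro$r_ml)
  })
  expect_true(all(diff(errs) < 0))        # monotone small-patch limit
  r50 <- measure_roc(bs$mesh, probe, cyl, patch_area = 50,
                     patch_aspect = 1.7)
  expect_equal(r50$ml_radius_mm, tro$r_ml, tolerance = 0.05)
  expect_equal(r50$ap_radius_mm, tro$r_ap, tolerance = 0.02)
})

test_that("radii are invariant under rigid transforms of the whole measurement", {
  sdl <- analytic_fixture("saddle_patch", r_ap = 30, r_ml = -18,
                          extent = 16, n = 45L)
  cyl0 <- structure(list(axis_point = c(0, 0, -30),
                         axis_direction = c(0, 1, 0), radius = 30, rms = 0,
                         ill_conditioned = FALSE, degeneracy = "none"),
                    class = "cylinder_fit")
  r0 <- measure_roc(sdl$mesh, c(0, 0, 0), cyl0, 150, 1.7)
  set.seed(21)
  for (rep in 1:3) {
    R <- random_rotation(); tv <- stats::rnorm(3, 0, 25)
    m2 <- transform_mesh(sdl$mesh, R, tv)
    cyl2 <- cyl0
    cyl2$axis_point <- as.vector(R %*% cyl0$axis_point + tv)
    cyl2$axis_direction <- as.vector(R %*% cyl0$axis_direction)
    r2 <- measure_roc(m2, tv, cyl2, 150, 1.7)
    expect_equal(r2$ap_radius_mm, r0$ap_radius_mm,
                 tolerance = 0.001)
    expect_equal(r2$ml_radius_mm, r0$ml_radius_mm,
                 tolerance = 0.001)
  }
})

test_that("sign convention: convex always positive, concave always negative, across orientations", {
  set.seed(33)
  for (rep in 1:20) {
    R <- random_rotation(); tv <- stats::rnorm(3, 0, 10)
    convex <- analytic_fixture("saddle_patch", r_ap = 28, r_ml = 22,
                               extent = 14, n = 30L)$mesh
    concave <- analytic_fixture("saddle_patch", r_ap = -28, r_ml = -22,
                                extent = 14, n = 30L)$mesh
    cyl <- structure(list(axis_point = as.vector(R %*% c(0, 0, -28) + tv),
                          axis_direction = as.vector(R %*% c(0, 1, 0)),
                          radius = 28, rms = 0, ill_conditioned = FALSE,
                          degeneracy = "none"), class = "cylinder_fit")
    rc <- measure_roc(transform_mesh(convex, R, tv), tv, cyl, 120, 1.7)
    rn <- measure_roc(transform_mesh(concave, R, tv), tv, cyl, 120, 1.7)
    expect_gt(rc$ap_radius_mm, 0); expect_gt(rc$ml_radius_mm, 0)
    expect_lt(rn$ap_radius_mm, 0); expect_lt(rn$ml_radius_mm, 0)
  }
})

test_that("probe rows are symmetric about a symmetric anchor and equally spaced in arc length", {
  cfg <- cohort_config(n_models = 3L, mode_amplitudes = numeric(0),
                       vertex_noise_sd = 0, seed = 2L)
  bs <- generate_base_surface(cfg)
  post <- select_posterior_articulating_surface(bs$mesh)
  cyl <- fit_cylinder(post$vertices)
  apex <- as.numeric(bs$probes[1, c("x", "y", "z")])
  pts <- place_probe_points(bs$mesh, cyl, apex, n = 5L, spacing = 6)
  expect_equal(pts[3, ], apex, tolerance = 0.3)
  gaps <- sqrt(rowSums(diff(pts)^2))
  expect_lt(max(abs(gaps - gaps[1])) / gaps[1], 0.05)
  ## symmetric about the apex in the sagittal plane of the probe
  expect_equal(pts[1, 3], pts[5, 3], tolerance = 0.3)
  expect_error(place_probe_points(bs$mesh, cyl, apex, n = 5L,
                                  spacing = 60), "too small")
})

test_that("posterior articulating selection is a strict labelled subset", {
  cfg <- cohort_config(n_models = 3L, seed = 4L)
  bs <- generate_base_surface(cfg)
  post <- select_posterior_articulating_surface(bs$mesh)
  expect_lt(surface_area(post), surface_area(bs$mesh))
  expect_true(all(post$face_labels %in%
                    c("medial_condyle", "lateral_condyle")))
  expect_error(select_posterior_articulating_surface(bs$mesh,
                                                     y_cut = -1000),
               "empty")
})
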