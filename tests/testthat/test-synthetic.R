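test_that("cohort generation is deterministic byte-for-byte", {
  cfg <- small_cohort_config(n_models = 4L, seed = 21L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("model_001_native.ply", "model_003_defect.ply",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("degenerate parameter combinations are rejected", {
  expect_error(cohort_config(groove_depth = 25, condyle_radius = 20),
               "groove_depth")
  expect_error(cohort_config(n_models = 2), "n_models")
  expect_error(cohort_config(defect_aspect_median = 0.8), "aspect")
  expect_error(cohort_config(ml_extent = -1), "positive")
})

test_that("removing every variation source yields identical native meshes", {
  cfg <- small_cohort_config(n_models = 4L, mode_amplitudes = numeric(0),
                             vertex_noise_sd = 0, side_mix = 0, seed = 5L)
  co <- generate_cohort(cfg)
  ## undo the per-model rigid placement using the recorded truth
  canon <- lapply(seq_along(co$natives), function(i) {
    tr <- co$truth[[i]]
    sweep(co$natives[[i]]$vertices, 2L, tr$translation) %*% tr$rotation
  })
  for (i in 2:4)
    expect_equal(canon[[i]], canon[[1]], tolerance = 1e-9)
})

test_that("zero hotspot spread pins every defect centre", {
  cfg <- small_cohort_config(n_models = 5L, hotspot_spread = 0, seed = 6L)
  co <- generate_cohort(cfg)
  ctrs <- t(vapply(co$truth, `[[`, numeric(2), "defect_center_uv"))
  expect_true(all(abs(sweep(ctrs, 2L, cfg$hotspot_center)) < 1e-12))
})

test_that("defect areas and aspects sample around the configured medians", {
  cfg <- cohort_config(n_models = 70L, nu = 30L, nv = 22L, seed = 31L)
  co <- generate_cohort(cfg)
  areas <- vapply(co$truth, `[[`, numeric(1), "defect_area_mm2")
  aspects <- vapply(co$truth, `[[`, numeric(1), "defect_aspect")
  expect_equal(stats::median(areas), 270, tolerance = 0.15)
  expect_equal(stats::median(aspects), 1.6, tolerance = 0.15)
  expect_true(all(aspects >= 1))
  ## measured articulating areas track the drawn truth
  tab <- defect_metrics_table(co$defects)
  expect_equal(stats::median(tab$area_mm2), 270, tolerance = 0.15)
})

test_that("defect articulating vertices lie on the native surface", {
  cfg <- small_cohort_config(n_models = 3L, seed = 8L)
  co <- generate_cohort(cfg)
  for (i in 1:3) {
    d <- co$defects[[i]]
    av <- sort(unique(as.vector(
      d$faces[d$face_labels == "articulating", , drop = FALSE])))
    dist <- points_to_surface_distance(d$vertices[av, , drop = FALSE],
                                       co$natives[[i]])
    expect_lt(max(dist), mean_edge_length(co$natives[[i]]))
  }
})

test_that("closed-form truth radii match a finite-difference second-form oracle", {
  cfg <- cohort_config(seed = 1L)
  h <- 1e-5
  fd_curvatures <- function(u, v) {
    F0 <- function(uu, vv) drop(cartmorph:::surface_point_uv(cfg, uu, vv))
    Fu <- (F0(u + h, v) - F0(u - h, v)) / (2 * h)
    Fv <- (F0(u, v + h) - F0(u, v - h)) / (2 * h)
    Fuu <- (F0(u + h, v) - 2 * F0(u, v) + F0(u - h, v)) / h^2
    Fvv <- (F0(u, v + h) - 2 * F0(u, v) + F0(u, v - h)) / h^2
    Fuv <- (F0(u + h, v + h) - F0(u + h, v - h) -
              F0(u - h, v + h) + F0(u - h, v - h)) / (4 * h^2)
    nr <- c(Fu[2] * Fv[3] - Fu[3] * Fv[2],
            Fu[3] * Fv[1] - Fu[1] * Fv[3],
            Fu[1] * Fv[2] - Fu[2] * Fv[1])
    nr <- nr / sqrt(sum(nr^2))
    radial <- c(0, cfg$condyle_radius * sin(u), -cfg$condyle_radius * cos(u))
    n <- nr * sign(sum(nr * radial))
    E <- sum(Fu^2); Ff <- sum(Fu * Fv); G2 <- sum(Fv^2)
    L <- sum(Fuu * n); M <- sum(Fuv * n); N2 <- sum(Fvv * n)
    a <- -Ff / E
    list(r_ap = -E / L,
         r_ml = -(E * a^2 + 2 * Ff * a + G2) / (L * a^2 + 2 * M * a + N2))
  }
  for (uv in list(c(0, 0.6), c(0.35, 0), c(-0.3, 0.4), c(0.2, -0.15))) {
    tr <- surface_truth_radii(cfg, uv[1], uv[2])
    fd <- fd_curvatures(uv[1], uv[2])
    expect_equal(tr$r_ap, fd$r_ap, tolerance = 1e-4)
    expect_equal(tr$r_ml, fd$r_ml, tolerance = 1e-4)
  }
})

test_that("zero groove depth gives an exact cylinder: AP radius = condyle radius, ML flat", {
  cfg <- cohort_config(condyle_radius = 20, groove_depth = 0,
                       mode_amplitudes = numeric(0), ap_extent = 40,
                       seed = 2L)
  tr <- surface_truth_radii(cfg, 0, 0.6)
  expect_equal(tr$r_ap, 20, tolerance = 1e-12)
  expect_equal(tr$r_ml, Inf)
})

test_that("analytic fixtures carry correct closed-form truth", {
  sp <- analytic_fixture("sphere_cap", radius = 20)
  expect_equal(sp$truth$r1, 20)
  d <- sqrt(rowSums(sp$mesh$vertices^2))
  expect_lt(max(abs(d - 20)), 1e-9)
  el <- analytic_fixture("planar_ellipse", major = 24.2, minor = 14.2)
  expect_equal(el$truth$area, 270, tolerance = 1e-3)
  sdl <- analytic_fixture("saddle_patch", r_ap = 25.6, r_ml = -15.7)
  expect_identical(sdl$truth$signs, c(1, -1))
  cp <- analytic_fixture("exact_circle_points", radius = 7,
                         center = c(1, 2, 3), normal = c(1, 1, 0))
  rad <- sqrt(rowSums(sweep(cp$points, 2L, c(1, 2, 3))^2))
  expect_lt(max(abs(rad - 7)), 1e-12)
  expect_error(analytic_fixture("sphere_cap", radius = -1), "positive")
  expect_error(analytic_fixture("planar_ellipse", major = 0, minor = 1),
               "positive")
})

test_that("right-sided models are mirrored and flagged consistently", {
  cfg <- small_cohort_config(n_models = 20L, side_mix = 1, seed = 13L)
  co <- generate_cohort(cfg)
  expect_true(all(co$manifest$side == "right"))
  ## mirroring back must restore the canonical (pre-mirror) model
  i <- 1L
  tr <- co$truth[[i]]
  restored <- mirror_sagittal(co$natives[[i]])
  canon <- sweep(restored$vertices, 2L, tr$translation) %*% tr$rotation
  base_plus <- co$base$mesh$vertices +
    matrix(co$modes %*% tr$mode_coefficients,
           nrow(co$base$mesh$vertices), 3L)
  expect_lt(mean(abs(canon - base_plus)), 3 * cfg$vertex_noise_sd)
})
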