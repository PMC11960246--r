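cohort_shapes <- function(k = 10L, seed = 1L, amps = c(2, 1), noise = 0) {
  cfg <- cohort_config(n_models = k, nu = 30L, nv = 22L,
                       mode_amplitudes = amps, vertex_noise_sd = noise,
                       side_mix = 0, seed = seed)
  co <- generate_cohort(cfg)
  cs <- build_corresponded_set(co$natives, reference_index = 1L,
                               method = "shared_topology")
  list(cfg = cfg, cohort = co, set = cs)
}

test_that("GPA aligns a rotated copy exactly and preserves centroid size without scaling", {
  x <- cohort_shapes(k = 3L, amps = numeric(0))
  a <- x$set$shapes[, , 1]
  R <- cartmorph:::rot_xyz(0, 0, pi / 4)
  arr <- array(c(a, a %*% t(R)), c(nrow(a), 3L, 2L))
  al <- gpa(arr)
  expect_lt(max(abs(al$aligned[, , 1] - al$aligned[, , 2])), 1e-6)
  csize <- function(v) sqrt(sum(scale(v, scale = FALSE)^2))
  for (i in 1:2)
    expect_equal(csize(al$aligned[, , i]), csize(arr[, , i]),
                 tolerance = 1e-12)
})

test_that("the GPA mean is invariant to random rigid perturbations of the cohort", {
  x <- cohort_shapes(k = 8L, seed = 3L)
  al0 <- gpa(x$set)
  set.seed(99)
  for (rep in 1:5) {
    pert <- x$set$shapes
    for (i in seq_len(dim(pert)[3])) {
      R <- random_rotation()
      pert[, , i] <- sweep(pert[, , i] %*% t(R), 2L,
                           stats::runif(3, -30, 30), "+")
    }
    al1 <- gpa(pert)
    ## the mean is defined up to a global rigid transform; compare after
    ## aligning the two means
    fit <- kabsch(al1$mean_shape, al0$mean_shape)
    m1 <- sweep(al1$mean_shape %*% t(fit$rotation), 2L, fit$translation,
                "+")
    expect_lt(max(sqrt(rowSums((m1 - al0$mean_shape)^2))), 1e-4)
  }
})

test_that("identical training shapes give a zero-mode model equal to the shape", {
  x <- cohort_shapes(k = 3L, amps = numeric(0))
  a <- x$set$shapes[, , 1]
  arr <- array(rep(a, 10L), c(nrow(a), 3L, 10L))
  md <- build_ssm(arr)
  expect_length(md$variances, 0)
  expect_equal(md$mean_shape, a, tolerance = 1e-9)
  expect_error(synthesize_shape(md, 1), "longer")
  expect_equal(synthesize_shape(md)$vertices, a, tolerance = 1e-9)
})

test_that("PCA reconstructs training shapes exactly with all modes", {
  x <- cohort_shapes(k = 8L, seed = 5L, noise = 0.1)
  al <- gpa(x$set)
  md <- build_ssm(al)
  for (i in c(1L, 4L)) {
    b <- project_shape(md, al$aligned[, , i])
    rec <- synthesize_shape(md, b)
    rms <- sqrt(mean(rowSums((rec$vertices - al$aligned[, , i])^2)))
    expect_lt(rms, 1e-6)
  }
})

test_that("synthesis is linear and symmetric about the mean", {
  x <- cohort_shapes(k = 6L, seed = 6L)
  md <- build_ssm(gpa(x$set))
  s_plus <- synthesize_shape(md, 2)$vertices
  s_minus <- synthesize_shape(md, -2)$vertices
  s_bar <- md$mean_shape
  expect_equal(s_bar - s_minus, s_plus - s_bar, tolerance = 1e-10)
  expect_equal(synthesize_shape(md)$vertices, s_bar)
})

test_that("projection and synthesis round-trip mode coefficients", {
  x <- cohort_shapes(k = 8L, seed = 7L)
  md <- build_ssm(gpa(x$set))
  set.seed(8)
  for (rep in 1:5) {
    b <- stats::rnorm(length(md$variances)) *
      pmin(3, abs(stats::rnorm(length(md$variances)))) *
      sqrt(md$variances)
    b2 <- project_shape(md, synthesize_shape(md, b))
    expect_lt(max(abs(b2 - b)), 1e-8)
  }
})

test_that("mode variances conserve the total variance of the training set", {
  x <- cohort_shapes(k = 10L, seed = 9L, noise = 0.1)
  al <- gpa(x$set)
  md <- build_ssm(al)
  X <- t(apply(al$aligned, 3L, as.vector))
  total <- sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1L)
  expect_equal(sum(md$variances), total, tolerance = 1e-6)
  expect_true(all(diff(md$variances) <= 1e-12))
  G <- crossprod(md$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("population sampling respects truncation and per-mode variances", {
  x <- cohort_shapes(k = 20L, seed = 10L, amps = c(2, 1, 0.5))
  md <- build_ssm(gpa(x$set))
  pop <- sample_population(md, n = 200L, seed = 4L)
  B <- pop$coefficients
  sdv <- sqrt(md$variances)
  for (j in 1:3) {
    expect_lte(max(abs(B[, j])), 3 * sdv[j] + 1e-12)
    ## 3 standard errors around zero mean
    expect_lt(abs(mean(B[, j])), 3 * sdv[j] / sqrt(200))
    ## chi-square-style bounds on the sample variance
    expect_equal(stats::var(B[, j]), md$variances[j], tolerance = 0.25)
  }
  p0 <- sample_population(md, n = 5L, seed = 4L, truncation_sd = 0)
  for (m in p0$meshes)
    expect_equal(m$vertices, md$mean_shape, tolerance = 1e-12)
  ## determinism
  pop2 <- sample_population(md, n = 200L, seed = 4L)
  expect_identical(pop$coefficients, pop2$coefficients)
})

test_that("SSM evaluation curves behave as nested projections require", {
  x <- cohort_shapes(k = 10L, seed = 12L, amps = c(2, 1), noise = 0)
  al <- gpa(x$set)
  md <- build_ssm(al)
  ev <- evaluate_ssm(al, md)
  cv <- ev$curves
  expect_equal(cv$compactness[nrow(cv)], 1.0, tolerance = 1e-12)
  expect_true(all(diff(cv$compactness) >= -1e-12))
  expect_true(all(diff(cv$accuracy_rms_mm) <= 1e-9))
  expect_gte(cv$compactness[2], 0.99)   # planted 2-mode structure
  gen <- cv$generalisation_rms_mm
  expect_true(all(gen[!is.na(gen)] >= 0))
})

test_that("AP/ML dimensions match the generator geometry and re-aligned copies", {
  cfg <- cohort_config(n_models = 3L, nu = 60L, nv = 44L,
                       mode_amplitudes = numeric(0), vertex_noise_sd = 0,
                       seed = 2L)
  bs <- generate_base_surface(cfg)
  dims <- ap_ml_dimensions(bs$mesh)
  ## dense closed-form truth from the parametric surface
  ur <- cartmorph:::u_range(cfg)
  us <- seq(ur[1], ur[2], length.out = 4000L)
  ys <- cfg$condyle_radius * sin(us)
  ap_truth <- max(ys) - min(ys)    # posterior line is parallel to x
  expect_equal(unname(dims["ap_mm"]), ap_truth,
               tolerance = 0.01)
  ## condyle-labelled vertices reach the sheet edges |v| = 1, x = +-W/2
  expect_equal(unname(dims["ml_mm"]), cfg$ml_extent, tolerance = 0.01)
  ## rigid transform + re-alignment leaves dimensions unchanged
  R <- cartmorph:::rot_xyz(0.2, -0.1, 0.3)
  m2 <- transform_mesh(bs$mesh, R, c(4, -7, 2))
  back <- kabsch(m2$vertices, bs$mesh$vertices)
  m3 <- transform_mesh(m2, back$rotation, back$translation)
  expect_equal(unname(ap_ml_dimensions(m3)), unname(dims),
               tolerance = 1e-3)
})

test_that("sampled populations overlap the input AP/ML distribution", {
  x <- cohort_shapes(k = 70L, seed = 14L, amps = c(2, 1), noise = 0.05)
  al <- gpa(x$set)
  md <- build_ssm(al)
  pop <- sample_population(md, n = 200L, seed = 2L)
  lab <- x$set$face_labels
  inp <- t(vapply(seq_len(70L), function(i)
    ap_ml_dimensions(surface_mesh(al$aligned[, , i], x$set$faces,
                                  face_labels = lab)), numeric(2)))
  smp <- t(vapply(pop$meshes, function(m)
    ap_ml_dimensions(surface_mesh(m$vertices, x$set$faces,
                                  face_labels = lab)), numeric(2)))
  expect_gte(ap_ml_overlap(inp, smp), 0.8)
})
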