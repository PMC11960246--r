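mean_and_defect <- function(seed = 2L) {
  cfg <- cohort_config(n_models = 3L, nu = 30L, nv = 22L,
                       mode_amplitudes = numeric(0), vertex_noise_sd = 0,
                       side_mix = 0, hotspot_spread = 0, seed = seed)
  co <- generate_cohort(cfg)
  tr <- co$truth[[1]]
  canon_def <- transform_mesh(co$defects[[1]], t(tr$rotation),
                              -as.vector(t(tr$rotation) %*% tr$translation))
  list(cfg = cfg, base = co$base$mesh, defect = canon_def, cohort = co)
}

test_that("similarity alignment to the mean recovers exact scale and pose", {
  x <- mean_and_defect()
  mean_shape <- x$base$vertices
  tr <- align_to_mean(list(mean_shape * 1.1), mean_shape)[[1]]
  expect_equal(tr$scale, 1 / 1.1, tolerance = 1e-6)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
  tr0 <- align_to_mean(list(mean_shape), mean_shape)[[1]]
  expect_equal(tr0$scale, 1, tolerance = 1e-12)
  expect_lt(max(abs(tr0$translation)), 1e-9)
  ## round trip under random similarity perturbations
  set.seed(5)
  for (rep in 1:5) {
    R <- random_rotation(); s <- stats::runif(1, 0.8, 1.2)
    tv <- stats::runif(3, -20, 20)
    pert <- sweep(s * mean_shape %*% t(R), 2L, tv, "+")
    fit <- align_to_mean(list(pert), mean_shape)[[1]]
    back <- sweep(fit$scale * pert %*% t(fit$rotation), 2L,
                  fit$translation, "+")
    expect_lt(max(abs(back - mean_shape)), 1e-4)
  }
})

test_that("the native transform transfers verbatim to the defect, preserving congruence", {
  x <- mean_and_defect()
  def <- x$defect
  id <- list(rotation = diag(3), translation = c(0, 0, 0), scale = 1)
  expect_equal(transfer_to_defect(def, id)$vertices, def$vertices)
  tr <- list(rotation = random_rotation(), translation = c(1, -2, 3),
             scale = 1.15)
  def2 <- transfer_to_defect(def, tr)
  d0 <- as.matrix(stats::dist(def$vertices[1:20, ]))
  d2 <- as.matrix(stats::dist(def2$vertices[1:20, ]))
  expect_equal(d2, 1.15 * d0, tolerance = 1e-9)
})

test_that("defect counting is exact, additive and order-invariant", {
  x <- mean_and_defect()
  mean_mesh <- x$base
  def <- x$defect
  hm1 <- defect_frequency(mean_mesh, list(def), tau = 0.2)
  ## articulating vertices of the defect coincide with mean-mesh vertices
  av <- sort(unique(as.vector(
    def$faces[def$face_labels == "articulating", , drop = FALSE])))
  nn <- cartmorph:::nn_dist2(def$vertices[av, , drop = FALSE],
                             mean_mesh$vertices)
  covered <- unique(nn$index)
  expect_true(all(hm1$counts[covered] == 1L))
  expect_equal(sum(hm1$counts > 0), length(covered),
               tolerance = 0.2 * length(covered))
  ## additivity and order invariance
  hm3 <- defect_frequency(mean_mesh, list(def, def, def), tau = 0.2)
  expect_true(all(hm3$counts == 3L * hm1$counts))
  def_shift <- transform_mesh(def, diag(3), c(5, 5, 0))
  hA <- defect_frequency(mean_mesh, list(def, def_shift), tau = 0.5)
  hB <- defect_frequency(mean_mesh, list(def_shift, def), tau = 0.5)
  expect_identical(hA$counts, hB$counts)
  expect_true(all(hA$counts <= hA$n_defects))
})

test_that("counts are monotone in the coverage tolerance", {
  x <- mean_and_defect()
  taus <- c(0.25, 0.5, 1, 2)
  cts <- sapply(taus, function(t)
    defect_frequency(x$base, list(x$defect), tau = t)$counts)
  for (j in seq_len(length(taus) - 1L))
    expect_true(all(cts[, j + 1L] >= cts[, j]))
})

test_that("regional masking flags out-of-region vertices without dropping counts", {
  x <- mean_and_defect()
  hm <- defect_frequency(x$base, list(x$defect), tau = 1,
                         region_label = "medial_condyle")
  hm_all <- defect_frequency(x$base, list(x$defect), tau = 1)
  expect_identical(hm$counts, hm_all$counts)
  expect_true(any(!hm$in_region))
  expect_true(hm$in_region[hm$argmax_vertex])
})

test_that("heat-map export round-trips counts and normalises colours", {
  x <- mean_and_defect()
  hm <- defect_frequency(x$base, list(x$defect), tau = 1)
  pre <- file.path(tempdir(), "hm_test")
  paths <- export_heatmap(hm, pre)
  csv <- utils::read.csv(paths[["csv"]])
  expect_identical(as.integer(csv$count), hm$counts)
  ply <- readLines(paths[["ply"]])
  body <- ply[-(1:grep("end_header", ply))]
  vert_rows <- body[seq_len(nrow(x$base$vertices))]
  cols <- t(vapply(strsplit(vert_rows, " "), function(f)
    as.integer(utils::tail(f, 3L)), integer(3)))
  ## max-count vertex at the top of the colour map, zero-count at the bottom
  expect_identical(cols[hm$argmax_vertex, ],
                   cols[which.max(hm$counts), ])
  zero_cols <- unique(cols[hm$counts == 0L, , drop = FALSE])
  expect_equal(nrow(zero_cols), 1L)
  ## all-zero map: uniform colour
  hm0 <- hm; hm0$counts <- rep(0L, length(hm$counts))
  hm0$mesh$vertex_scalar <- rep(0, length(hm$counts))
  p0 <- export_heatmap(hm0, file.path(tempdir(), "hm_zero"))
  ply0 <- readLines(p0[["ply"]])
  body0 <- ply0[-(1:grep("end_header", ply0))]
  v0 <- body0[seq_len(nrow(x$base$vertices))]
  c0 <- unique(t(vapply(strsplit(v0, " "), function(f)
    as.integer(utils::tail(f, 3L)), integer(3))))
  expect_equal(nrow(c0), 1L)
})

test_that("empty defect lists are rejected", {
  x <- mean_and_defect()
  expect_error(defect_frequency(x$base, list(), tau = 1), "empty")
})
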