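#' Generalised Procrustes alignment
#'
#' Iteratively removes position and orientation differences (optionally
#' size) across a corresponded shape set: centroids are translated to the
#' origin, each shape is rotated onto the current mean by the orthogonal
#' Procrustes solution, and the mean is recomputed, until the mean changes
#' by less than \code{tol} (mean per-vertex distance) or \code{max_iter}
#' iterations. With \code{with_scaling = FALSE} (the default, appropriate
#' when size differences are themselves of interest) each shape's centroid
#' size is preserved exactly.
#'
#' @param set a \code{corresponded_set}, or an n x 3 x k array.
#' @param with_scaling also remove isotropic size differences.
#' @param tol convergence tolerance on the mean shape, mm.
#' @param max_iter maximum iterations.
#' @return object of class \code{gpa_alignment}: list with \code{aligned}
#'   (n x 3 x k array), \code{mean_shape} (n x 3), \code{transforms}
#'   (per-shape rotation/translation/scale actually applied),
#'   \code{converged}, \code{iterations}, \code{delta}, plus \code{faces}
#'   and \code{face_labels} carried from the input.
#' @export
gpa <- function(set, with_scaling = FALSE, tol = 1e-6, max_iter = 100L) {
  shapes <- if (inherits(set, "corresponded_set")) set$shapes else set
  k <- dim(shapes)[3]
  if (is.na(k) || k < 2L) stop("GPA needs at least 2 corresponded shapes")
  n <- dim(shapes)[1]
  aligned <- shapes
  trans <- vector("list", k)
  for (i in seq_len(k)) {
    cc <- colMeans(shapes[, , i])
    aligned[, , i] <- sweep(shapes[, , i], 2L, cc)
    trans[[i]] <- list(rotation = diag(3), translation = -cc, scale = 1)
  }
  mean_shape <- aligned[, , 1]
  converged <- FALSE; delta <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    for (i in seq_len(k)) {
      fit <- kabsch(aligned[, , i], mean_shape, scale = with_scaling)
      aligned[, , i] <- fit$scale * aligned[, , i] %*% t(fit$rotation)
      trans[[i]]$rotation <- fit$rotation %*% trans[[i]]$rotation
      trans[[i]]$translation <- fit$scale *
        as.vector(fit$rotation %*% trans[[i]]$translation)
      trans[[i]]$scale <- fit$scale * trans[[i]]$scale
    }
    new_mean <- apply(aligned, c(1, 2), mean)
    delta <- mean(sqrt(rowSums((new_mean - mean_shape)^2)))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GPA did not converge: final mean delta %.3g mm", delta))
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 transforms = trans, converged = converged,
                 iterations = it, delta = delta,
                 faces = if (inherits(set, "corresponded_set")) set$faces,
                 face_labels = if (inherits(set, "corresponded_set"))
                   set$face_labels),
            class = "gpa_alignment")
}

#' PCA statistical shape model
#'
#' Principal component analysis of the aligned, corresponded training
#' shapes: the mean shape is the arithmetic mean, and the modes and their
#' variances come from the eigendecomposition of the sample covariance of
#' the vertex coordinates, computed via thin SVD of the centred k x 3m data
#' matrix. A new instance is synthesised as S = mean + P b.
#'
#' @param alignment a \code{gpa_alignment} (or n x 3 x k array of aligned
#'   shapes).
#' @param faces optional face list when an array is supplied.
#' @param var_tol modes with variance below \code{var_tol} times the total
#'   are dropped (default 1e-10); all-identical training sets yield a valid
#'   model with zero modes.
#' @return object of class \code{shape_model}: \code{mean_shape} (n x 3),
#'   \code{modes} (3m x q, orthonormal columns), \code{variances}
#'   (descending, mm^2), \code{n_train}, \code{faces}, \code{face_labels}.
#' @export
build_ssm <- function(alignment, faces = NULL, var_tol = 1e-10) {
  if (inherits(alignment, "gpa_alignment")) {
    shapes <- alignment$aligned
    faces <- faces %||n% alignment$faces
    labels <- alignment$face_labels
  } else {
    shapes <- alignment
    labels <- NULL
  }
  k <- dim(shapes)[3]
  if (k < 3L) stop("need at least 3 training shapes")
  n <- dim(shapes)[1]
  X <- t(apply(shapes, 3L, as.vector))        # k x 3m (vertex-major per axis)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(k - 1L, ncol(Xc)))
  lambda <- (sv$d[seq_len(ncol(sv$v))]^2) / (k - 1L)
  keep <- lambda > var_tol * max(sum(lambda), .Machine$double.eps)
  structure(list(mean_shape = matrix(mu, n, 3L),
                 modes = sv$v[, keep, drop = FALSE],
                 variances = lambda[keep],
                 n_train = k, faces = faces, face_labels = labels),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: %d vertices, %d modes from %d training shapes\n",
    nrow(x$mean_shape), length(x$variances), x$n_train))
  if (length(x$variances))
    cat(sprintf("  leading sd(mm): %s\n",
                paste(sprintf("%.3f", sqrt(utils::head(x$variances, 5L))),
                      collapse = ", ")))
  invisible(x)
}

#' Synthesise a cartilage instance from mode coefficients
#'
#' Evaluates S = mean + P b on the model topology. \code{b} may be shorter
#' than the number of modes (remaining coefficients are zero) but not
#' longer.
#'
#' @param model a \code{shape_model}.
#' @param b numeric coefficient vector (mm).
#' @return a \code{surface_mesh}.
#' @export
synthesize_shape <- function(model, b = numeric(0)) {
  q <- length(model$variances)
  if (length(b) > q)
    stop("coefficient vector longer than the number of modes (", q, ")")
  v <- as.vector(model$mean_shape)
  if (length(b) > 0L)
    v <- v + as.vector(model$modes[, seq_along(b), drop = FALSE] %*% b)
  surface_mesh(matrix(v, ncol = 3L),
               model$faces %||n% matrix(integer(0), 0L, 3L),
               face_labels = model$face_labels)
}

#' Project a shape onto the model's modes
#'
#' Returns the coefficient vector b = P' (s - mean); the inverse of
#' [synthesize_shape()] on the model's span.
#'
#' @param model a \code{shape_model}.
#' @param shape n x 3 matrix or \code{surface_mesh} with model topology.
#' @param n_modes number of leading modes (default all).
#' @return numeric coefficient vector.
#' @export
project_shape <- function(model, shape, n_modes = NULL) {
  v <- if (is.surface_mesh(shape)) shape$vertices else as.matrix(shape)
  d <- as.vector(v) - as.vector(model$mean_shape)
  q <- n_modes %||n% length(model$variances)
  as.vector(crossprod(model$modes[, seq_len(q), drop = FALSE], d))
}

#' Sample an artificial population from the shape model
#'
#' Draws coefficients b_i ~ Normal(0, lambda_i) independently per mode
#' (all modes by default), truncated at \code{truncation_sd} standard
#' deviations by resampling, and synthesises one mesh per draw.
#' Deterministic under \code{seed}.
#'
#' @param model a \code{shape_model} with at least one mode.
#' @param n number of samples.
#' @param seed integer seed.
#' @param truncation_sd truncation bound in per-mode standard deviations
#'   (default 3); 0 yields the mean shape for every sample.
#' @return list with \code{meshes} (length n) and \code{coefficients}
#'   (n x q matrix).
#' @export
sample_population <- function(model, n = 200L, seed = 1L,
                              truncation_sd = 3) {
  q <- length(model$variances)
  if (q < 1L) stop("model has no modes of variation")
  set.seed(seed)
  sdv <- sqrt(model$variances)
  B <- matrix(0, n, q)
  if (truncation_sd > 0) {
    for (j in seq_len(q)) {
      x <- stats::rnorm(n, 0, sdv[j])
      bad <- abs(x) > truncation_sd * sdv[j]
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), 0, sdv[j])
        bad <- abs(x) > truncation_sd * sdv[j]
      }
      B[, j] <- x
    }
  }
  meshes <- lapply(seq_len(n), function(i) synthesize_shape(model, B[i, ]))
  list(meshes = meshes, coefficients = B)
}

#' Evaluate shape-model quality: compactness, accuracy, generalisation
#'
#' Compactness is the cumulative variance fraction per retained mode count;
#' accuracy is the RMS vertex distance between each training shape and its
#' reconstruction with the leading modes (averaged over shapes);
#' generalisation is the same RMS for shapes left out of training
#' (leave-one-out retraining, the held-out shape re-aligned to the reduced
#' mean before projection).
#'
#' @param alignment the \code{gpa_alignment} used for training.
#' @param model the \code{shape_model} built from it.
#' @return object of class \code{ssm_evaluation}: data.frame \code{curves}
#'   with columns n_modes, compactness, accuracy_rms_mm,
#'   generalisation_rms_mm (generalisation NA beyond the leave-one-out mode
#'   count).
#' @export
evaluate_ssm <- function(alignment, model) {
  shapes <- alignment$aligned
  k <- dim(shapes)[3]; n <- dim(shapes)[1]
  q <- length(model$variances)
  compact <- cumsum(model$variances) / sum(model$variances)
  X <- t(apply(shapes, 3L, as.vector))
  mu <- as.vector(model$mean_shape)
  Xc <- sweep(X, 2L, mu)
  Bfull <- Xc %*% model$modes                 # k x q coefficients
  acc <- vapply(seq_len(q), function(m) {
    Rec <- Bfull[, seq_len(m), drop = FALSE] %*%
      t(model$modes[, seq_len(m), drop = FALSE])
    E <- Xc - Rec
    mean(vapply(seq_len(k), function(i)
      sqrt(mean(rowSums(matrix(E[i, ], n, 3L)^2))), numeric(1)))
  }, numeric(1))
  ## leave-one-out generalisation
  gen <- rep(NA_real_, q)
  if (k >= 4L) {
    qs_loo <- min(q, k - 2L)
    gen_acc <- matrix(NA_real_, k, qs_loo)
    for (i in seq_len(k)) {
      sub <- build_ssm(shapes[, , -i, drop = FALSE])
      held <- shapes[, , i]
      ## align held-out shape to the reduced-model mean (no scaling)
      fit <- kabsch(sweep(held, 2L, colMeans(held)), sub$mean_shape)
      hal <- sweep(sweep(held, 2L, colMeans(held)) %*% t(fit$rotation),
                   2L, fit$translation, "+")
      d <- as.vector(hal) - as.vector(sub$mean_shape)
      bq <- as.vector(crossprod(sub$modes, d))
      for (m in seq_len(min(qs_loo, length(bq)))) {
        rec <- as.vector(sub$mean_shape) +
          as.vector(sub$modes[, seq_len(m), drop = FALSE] %*% bq[seq_len(m)])
        err <- matrix(as.vector(hal) - rec, n, 3L)
        gen_acc[i, m] <- sqrt(mean(rowSums(err^2)))
      }
    }
    gm <- colMeans(gen_acc, na.rm = TRUE)
    gen[seq_along(gm)] <- gm
  }
  structure(list(curves = data.frame(
    n_modes = seq_len(q), compactness = compact,
    accuracy_rms_mm = acc, generalisation_rms_mm = gen)),
    class = "ssm_evaluation")
}

#' @export
print.ssm_evaluation <- function(x, ...) {
  cv <- x$curves
  cat(sprintf(
    "ssm_evaluation: %d modes; compactness .95 at %s modes; accuracy %.3f mm at full rank\n",
    nrow(cv),
    if (any(cv$compactness >= 0.95)) min(which(cv$compactness >= 0.95))
    else "NA",
    cv$accuracy_rms_mm[nrow(cv)]))
  invisible(x)
}

#' Anteroposterior length and mediolateral width of a cartilage model
#'
#' AP length: distance from the most anterior point to the line connecting
#' the most posterior point of the medial condyle and the most posterior
#' point of the lateral condyle. ML width: distance between the most
#' lateral point of the lateral condyle and the most medial point of the
#' medial condyle. The mesh must be in the working anatomical frame
#' (+x medial, +y anterior) and carry condyle face labels.
#'
#' @param mesh a labelled \code{surface_mesh}.
#' @return named numeric vector c(ap_mm, ml_mm).
#' @export
ap_ml_dimensions <- function(mesh) {
  if (is.null(mesh$face_labels))
    stop("ap_ml_dimensions requires condyle face labels")
  vid <- function(lbl) sort(unique(as.vector(
    mesh$faces[mesh$face_labels == lbl, , drop = FALSE])))
  med <- vid("medial_condyle"); lat <- vid("lateral_condyle")
  if (!length(med) || !length(lat))
    stop("missing medial_condyle / lateral_condyle labels")
  V <- mesh$vertices
  ant <- V[which.max(V[, 2]), ]
  pm <- V[med[which.min(V[med, 2])], ]
  pl <- V[lat[which.min(V[lat, 2])], ]
  dirv <- pl - pm
  ap <- if (sqrt(sum(dirv^2)) < 1e-9) sqrt(sum((ant - pm)^2)) else {
    u <- unitize(dirv)
    w <- ant - pm
    sqrt(sum((w - sum(w * u) * u)^2))
  }
  ml <- max(V[med, 1]) - min(V[lat, 1])
  c(ap_mm = ap, ml_mm = ml)
}

#' AP/ML population overlap between samples and input cohort
#'
#' Operationalises the visual comparison of sampled vs input (AP, ML)
#' scatter: the fraction of sampled points lying inside the convex hull of
#' the input points inflated by \code{inflate} about its centroid.
#'
#' @param input_dims,sample_dims two-column matrices of (AP, ML) in mm.
#' @param inflate hull inflation factor (default 1.05).
#' @return fraction in [0, 1].
#' @export
ap_ml_overlap <- function(input_dims, sample_dims, inflate = 1.05) {
  input_dims <- as.matrix(input_dims); sample_dims <- as.matrix(sample_dims)
  ctr <- colMeans(input_dims)
  hull <- sweep(sweep(input_dims, 2L, ctr) * inflate, 2L, ctr, "+")
  hidx <- grDevices::chull(hull)
  poly <- hull[hidx, , drop = FALSE]
  mean(vapply(seq_len(nrow(sample_dims)), function(i)
    point_in_polygon(sample_dims[i, ], poly), logical(1)))
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2]) &&
        p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}
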