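#' Rigid iterative closest point registration
#'
#' Aligns \code{source} to \code{target} with a rotation and translation by
#' alternating nearest-vertex matching and the orthogonal (Kabsch)
#' Procrustes solution. The mean closest-point residual is non-increasing
#' over iterations; iteration stops when its improvement falls below
#' \code{tol} or after \code{max_iter} iterations. If convergence from the
#' identity start stalls at a poor optimum, principal-axis initialisations
#' (all four proper sign combinations) are tried and the best kept, so the
#' procedure is deterministic.
#'
#' @param source,target \code{surface_mesh} objects (non-empty).
#' @param max_iter maximum iterations (default 50).
#' @param tol residual-improvement stopping tolerance, mm (default 1e-6).
#' @return list with \code{rotation}, \code{translation}, \code{residual}
#'   (mean closest-point distance, mm), \code{iterations} and
#'   \code{residual_trace}.
#' @export
rigid_icp <- function(source, target, max_iter = 50L, tol = 1e-6) {
  S <- source$vertices; Tg <- target$vertices
  if (nrow(S) < 3L || nrow(Tg) < 3L)
    stop("rigid_icp needs at least 3 vertices in each mesh")
  run <- function(R0, t0) icp_core(S, Tg, R0, t0, max_iter, tol)
  best <- run(diag(3), c(0, 0, 0))
  if (best$residual > 0.05 * mean_edge_length(target)) {
    ## principal-axis restarts for large initial misalignment
    cs <- scale(S, scale = FALSE); ct <- scale(Tg, scale = FALSE)
    es <- eigen(crossprod(cs) / nrow(cs), symmetric = TRUE)$vectors
    et <- eigen(crossprod(ct) / nrow(ct), symmetric = TRUE)$vectors
    for (sx in c(1, -1)) for (sy in c(1, -1)) {
      D <- diag(c(sx, sy, sx * sy))  # proper rotations only
      R0 <- et %*% D %*% t(es)
      t0 <- colMeans(Tg) - R0 %*% colMeans(S)
      cand <- run(R0, as.vector(t0))
      if (cand$residual < best$residual) best <- cand
    }
  }
  best
}

icp_core <- function(S, Tg, R, tv, max_iter, tol) {
  res_trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    Sc <- sweep(S %*% t(R), 2L, tv, "+")
    nn <- nn_dist2(Sc, Tg)
    res <- mean(sqrt(nn$dist2))
    res_trace <- c(res_trace, res)
    if (prev - res < tol) break
    prev <- res
    fit <- kabsch(S, Tg[nn$index, , drop = FALSE])
    R <- fit$rotation; tv <- fit$translation
  }
  Sc <- sweep(S %*% t(R), 2L, tv, "+")
  nn <- nn_dist2(Sc, Tg)
  list(rotation = R, translation = tv,
       residual = mean(sqrt(nn$dist2)), iterations = it,
       residual_trace = res_trace)
}

#' Orthogonal / similarity Procrustes solution
#'
#' Least-squares rotation (+ optional scale) and translation mapping X onto
#' Y, via SVD of the cross-covariance with reflection guarding.
#'
#' @param X,Y n x 3 matrices of paired points.
#' @param scale if TRUE estimate a similarity (with isotropic scale).
#' @return list with \code{rotation}, \code{translation}, \code{scale}.
#' @export
kabsch <- function(X, Y, scale = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  H <- crossprod(X0, Y0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) sum(sv$d * c(1, 1, d)) / sum(X0^2) else 1
  tv <- cy - s * as.vector(R %*% cx)
  list(rotation = R, translation = tv, scale = s)
}

#' Non-rigid ICP correspondence (locally affine, stiffness-relaxed)
#'
#' Deforms the reference mesh onto the target with a per-vertex affine
#' transform field regularised by a graph-Laplacian stiffness term, in the
#' style of stiffness-relaxed non-rigid ICP. The stiffness weight is
#' decreased over \code{stiffness} levels; at each level, nearest-vertex
#' correspondences are recomputed and the sparse normal equations solved
#' until the deformation stabilises. Correspondences whose normals disagree
#' by more than \code{normal_gate} degrees, or whose closest target vertex
#' lies on the target boundary (missing data), are down-weighted to zero
#' and flagged rather than extrapolated silently.
#'
#' @param reference \code{surface_mesh} providing the output topology.
#' @param target \code{surface_mesh}, roughly pre-aligned to the reference.
#' @param stiffness decreasing positive stiffness schedule (default 8
#'   levels from 50 to 0.5, log-spaced).
#' @param inner_iter inner iterations per stiffness level (default 10).
#' @param tol mean vertex-movement convergence tolerance, mm (default 1e-4).
#' @param normal_gate maximum normal disagreement, degrees (default 60).
#' @param gamma weighting of the affine translation block in the stiffness
#'   term (default 1).
#' @return list with \code{vertices} (reference topology deformed onto the
#'   target), \code{mesh}, \code{residual} (mean distance of output to
#'   target over used vertices, mm), \code{flagged} (vertex indices matched
#'   to missing/incompatible data) and \code{converged}.
#' @export
nonrigid_correspond <- function(reference, target,
                                stiffness = exp(seq(log(50), log(0.5),
                                                    length.out = 8L)),
                                inner_iter = 10L, tol = 1e-4,
                                normal_gate = 60, gamma = 1) {
  n <- nrow(reference$vertices)
  edges <- mesh_edges(reference)
  ne <- nrow(edges)
  tverts <- target$vertices
  tnorm <- vertex_normals(target)
  tbound <- boundary_vertices(target)
  is_bound <- logical(nrow(tverts)); is_bound[tbound] <- TRUE
  cosgate <- cos(normal_gate * pi / 180)

  ## stiffness incidence: rows (edge x 4 coords), M kron G
  G <- c(1, 1, 1, gamma)
  ii <- rep(seq_len(4L * ne), 2L)
  jj <- c(rep((edges[, 1] - 1L) * 4L, each = 4L) + rep(1:4, ne),
          rep((edges[, 2] - 1L) * 4L, each = 4L) + rep(1:4, ne))
  xx <- c(rep(G, ne), -rep(G, ne))
  Mkg <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(4L * ne, 4L * n))
  MtM <- Matrix::crossprod(Mkg)

  ## unknowns X: 4n x 3 (per-vertex 4x3 affine, row [v 1] %*% Xi)
  X <- matrix(0, 4L * n, 3L)
  X[seq(1L, 4L * n, by = 4L), 1L] <- 1
  X[seq(2L, 4L * n, by = 4L), 2L] <- 1
  X[seq(3L, 4L * n, by = 4L), 3L] <- 1
  V0 <- reference$vertices
  Dj <- rep((seq_len(n) - 1L) * 4L, each = 4L) + rep(1:4, n)
  Di <- rep(seq_len(n), each = 4L)
  Dx <- as.vector(t(cbind(V0, 1)))
  D <- Matrix::sparseMatrix(i = Di, j = Dj, x = Dx, dims = c(n, 4L * n))

  cur <- as.matrix(D %*% X)
  flagged <- integer(0)
  converged <- TRUE
  for (alpha in stiffness) {
    for (k in seq_len(inner_iter)) {
      rn <- vertex_normals(surface_mesh(cur, reference$faces))
      nn <- nn_dist2(cur, tverts)
      U <- tverts[nn$index, , drop = FALSE]
      w <- rep(1, n)
      ncomp <- rowSums(rn * tnorm[nn$index, , drop = FALSE])
      w[ncomp < cosgate] <- 0
      w[is_bound[nn$index]] <- 0
      if (all(w == 0)) stop("no usable closest-point pairs")
      Dw <- D * w
      A <- alpha^2 * MtM + Matrix::crossprod(Dw, Dw)
      rhs <- Matrix::crossprod(Dw, U * w)
      Xn <- as.matrix(Matrix::solve(A, rhs))
      new <- as.matrix(D %*% Xn)
      moved <- mean(sqrt(rowSums((new - cur)^2)))
      X <- Xn; cur <- new
      if (moved < tol) break
    }
    if (k == inner_iter && moved >= tol) converged <- FALSE
    flagged <- which(w == 0)
  }
  nn <- nn_dist2(cur, tverts)
  used <- setdiff(seq_len(n), flagged)
  res <- mean(sqrt(nn$dist2[used]))
  out <- surface_mesh(cur, reference$faces,
                      face_labels = reference$face_labels)
  list(vertices = cur, mesh = out, residual = res,
       flagged = flagged, converged = converged)
}

#' Build a corresponded shape set from unregistered meshes
#'
#' Registers every mesh to a reference (chosen by index, or seeded at
#' random, mirroring reference choice by random selection) with rigid ICP
#' followed by non-rigid correspondence, yielding k shapes that share the
#' reference topology. When all meshes already share the reference's
#' vertex count and face list (e.g. a synthetic cohort), set
#' \code{method = "shared_topology"} to take vertices as-is after rigid
#' alignment.
#'
#' @param meshes list of >= 3 \code{surface_mesh} objects.
#' @param reference_index index of the reference mesh, or NULL to draw one
#'   using \code{seed}.
#' @param seed integer seed for the random reference choice.
#' @param method \code{"nonrigid"} (default) or \code{"shared_topology"}.
#' @param residual_tol residual (mm) above which a member is listed in the
#'   exclusion report (default 1.0).
#' @param ... passed to [nonrigid_correspond()].
#' @return object of class \code{corresponded_set}: list with \code{shapes}
#'   (n x 3 x k array), \code{faces}, \code{face_labels},
#'   \code{reference_index}, \code{residuals}, \code{excluded}.
#' @export
build_corresponded_set <- function(meshes, reference_index = NULL,
                                   seed = 1L, method = c("nonrigid",
                                                         "shared_topology"),
                                   residual_tol = 1.0, ...) {
  method <- match.arg(method)
  k <- length(meshes)
  if (k < 3L) stop("need at least 3 meshes")
  if (is.null(reference_index)) {
    set.seed(seed)
    reference_index <- sample.int(k, 1L)
  }
  ref <- meshes[[reference_index]]
  n <- nrow(ref$vertices)
  shapes <- array(NA_real_, c(n, 3L, k))
  residuals <- numeric(k)
  for (i in seq_len(k)) {
    m <- meshes[[i]]
    if (i == reference_index) {
      shapes[, , i] <- ref$vertices
      residuals[i] <- 0
      next
    }
    if (method == "shared_topology") {
      ## correspondence is given by the shared vertex ordering; pose is
      ## removed later by GPA, so no ICP is needed
      if (nrow(m$vertices) != n || !identical(dim(m$faces), dim(ref$faces)))
        stop("shared_topology requires identical topology; mesh ", i,
             " differs")
      shapes[, , i] <- m$vertices
      residuals[i] <- 0
    } else {
      ## bring target into the reference frame
      tr <- rigid_icp(m, ref)
      aligned <- transform_mesh(m, tr$rotation, tr$translation)
      nr <- nonrigid_correspond(ref, aligned, ...)
      shapes[, , i] <- nr$vertices
      residuals[i] <- nr$residual
    }
  }
  structure(list(shapes = shapes, faces = ref$faces,
                 face_labels = ref$face_labels,
                 reference_index = reference_index,
                 residuals = residuals,
                 excluded = which(residuals > residual_tol)),
            class = "corresponded_set")
}

#' @export
print.corresponded_set <- function(x, ...) {
  cat(sprintf(
    "corresponded_set: %d shapes x %d vertices (reference %d), mean residual %.4f mm\n",
    dim(x$shapes)[3], dim(x$shapes)[1], x$reference_index,
    mean(x$residuals)))
  if (length(x$excluded))
    cat("  flagged members:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
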