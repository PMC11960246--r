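#' Triangulated surface mesh
#'
#' The universal currency of the pipeline: an open or closed triangulated
#' surface with coordinates in millimetres, optional per-face region labels
#' (e.g. \code{"medial_condyle"}) and an optional per-vertex scalar channel
#' (used for heat-map counts).
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, f x 3, 1-based vertex indices with
#'   counter-clockwise winding seen from outside the surface.
#' @param face_labels optional character vector of length f.
#' @param vertex_scalar optional numeric vector of length n.
#'
#' @return An object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL,
                         vertex_scalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 3L) stop("a surface mesh needs at least 3 vertices")
  if (ncol(faces) != 3L) stop("faces must be an f x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(face_labels)) {
    face_labels <- as.character(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("face_labels must have one entry per face")
  }
  if (!is.null(vertex_scalar)) {
    vertex_scalar <- as.numeric(vertex_scalar)
    if (length(vertex_scalar) != nrow(vertices))
      stop("vertex_scalar must have one entry per vertex")
  }
  structure(list(vertices = vertices, faces = faces,
                 face_labels = face_labels, vertex_scalar = vertex_scalar),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$face_labels))
                sprintf(", labels {%s}",
                        paste(unique(x$face_labels), collapse = ", "))
              else "",
              if (!is.null(x$vertex_scalar)) ", vertex scalar" else ""))
  invisible(x)
}

#' @export
is.surface_mesh <- function(x) inherits(x, "surface_mesh")

## ---- elementary per-face geometry -------------------------------------

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Per-face unit normals and areas
#'
#' @param mesh a \code{surface_mesh}.
#' @return list with \code{normals} (f x 3, unit) and \code{areas} (mm^2).
#' @keywords internal
face_geometry <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L)
  cc <- face_corner(mesh, 3L)
  cr <- cross3(b - a, cc - a)
  nrm2 <- sqrt(rowSums(cr^2))
  areas <- nrm2 / 2
  normals <- cr / ifelse(nrm2 > 0, nrm2, 1)
  list(normals = normals, areas = areas)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

cross3v <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' Area-weighted outward vertex normals
#'
#' @param mesh a \code{surface_mesh}.
#' @return n x 3 matrix of unit normals (zero rows for unreferenced vertices).
#' @export
vertex_normals <- function(mesh) {
  fg <- face_geometry(mesh)
  wn <- fg$normals * fg$areas
  out <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    s <- rowsum(wn, mesh$faces[, k])
    ids <- as.integer(rownames(s))
    out[ids, ] <- out[ids, ] + s
  }
  nn <- sqrt(rowSums(out^2))
  out / ifelse(nn > 0, nn, 1)
}

face_centroids <- function(mesh) {
  (face_corner(mesh, 1L) + face_corner(mesh, 2L) + face_corner(mesh, 3L)) / 3
}

#' Mean edge length of a mesh (mm)
#' @param mesh a \code{surface_mesh}.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Unique undirected edges (pairs of vertex indices)
#' @keywords internal
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

## edge -> incident face count; boundary edges have exactly one face
edge_face_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(f)), 3L)
  split(fid, key)
}

#' Boundary vertices of an open mesh
#'
#' Vertices incident to an edge shared by exactly one face.
#' @param mesh a \code{surface_mesh}.
#' @return integer vector of vertex indices.
#' @export
boundary_vertices <- function(mesh) {
  ef <- edge_face_table(mesh)
  bkeys <- names(ef)[lengths(ef) == 1L]
  if (length(bkeys) == 0L) return(integer(0))
  idx <- do.call(rbind, strsplit(bkeys, " "))
  sort(unique(as.integer(idx)))
}

#' Drop degenerate (zero-area) faces and unreferenced vertices
#' @param mesh a \code{surface_mesh}.
#' @param tol area below which a face counts as degenerate (mm^2).
#' @return cleaned \code{surface_mesh}.
#' @export
clean_mesh <- function(mesh, tol = 1e-12) {
  fg <- face_geometry(mesh)
  keep <- fg$areas > tol
  faces <- mesh$faces[keep, , drop = FALSE]
  labels <- if (!is.null(mesh$face_labels)) mesh$face_labels[keep] else NULL
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[faces], ncol = 3L),
               face_labels = labels,
               vertex_scalar = if (!is.null(mesh$vertex_scalar))
                 mesh$vertex_scalar[used] else NULL)
}

#' Extract a submesh from a face mask
#'
#' @param mesh a \code{surface_mesh}.
#' @param face_mask logical or integer vector selecting faces.
#' @param keep_vertex_ids if TRUE, attach the original vertex indices as
#'   attribute \code{"orig_vertices"}.
#' @return \code{surface_mesh} containing only the selected faces.
#' @export
submesh <- function(mesh, face_mask, keep_vertex_ids = TRUE) {
  faces <- mesh$faces[face_mask, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty face selection")
  labels <- if (!is.null(mesh$face_labels)) mesh$face_labels[face_mask]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  out <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                      matrix(remap[faces], ncol = 3L), face_labels = labels,
                      vertex_scalar = if (!is.null(mesh$vertex_scalar))
                        mesh$vertex_scalar[used] else NULL)
  if (keep_vertex_ids) attr(out, "orig_vertices") <- used
  out
}

#' Connected components of a face set (edge adjacency)
#'
#' @param mesh a \code{surface_mesh}.
#' @return integer vector of component ids, one per face.
#' @export
face_components <- function(mesh) {
  ef <- edge_face_table(mesh)
  nf <- nrow(mesh$faces)
  adj <- vector("list", nf)
  for (fs in ef) {
    if (length(fs) < 2L) next
    for (i in fs) adj[[i]] <- c(adj[[i]], setdiff(fs, i))
  }
  comp <- integer(nf); cur <- 0L
  for (s in seq_len(nf)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      f <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[f] != 0L) next
      comp[f] <- cur
      nb <- adj[[f]]
      if (length(nb)) stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

## ---- distances ---------------------------------------------------------

#' Squared distances from points to the nearest of a set of points
#' @keywords internal
nn_dist2 <- function(query, ref) {
  ## chunked brute force; fine for the mesh sizes used here
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  n <- nrow(query)
  out_d <- numeric(n); out_i <- integer(n)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(ref))))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    g <- query[s:e, , drop = FALSE] %*% t(ref)
    d2 <- outer(q2[s:e], r2, "+") - 2 * g
    wi <- max.col(-d2, ties.method = "first")
    out_i[s:e] <- wi
    out_d[s:e] <- d2[cbind(seq_len(e - s + 1L), wi)]
  }
  list(index = out_i, dist2 = pmax(out_d, 0))
}

#' Unsigned distance from points to a triangulated surface
#'
#' Exact point-to-triangle distances (Eberly's region decomposition),
#' minimised over the selected faces.
#'
#' @param points m x 3 matrix of query points.
#' @param mesh a \code{surface_mesh}.
#' @param face_mask optional logical/integer face selection.
#' @return numeric vector of m distances (mm).
#' @export
points_to_surface_distance <- function(points, mesh, face_mask = NULL) {
  points <- as.matrix(points)
  faces <- if (is.null(face_mask)) mesh$faces else
    mesh$faces[face_mask, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty face selection")
  V <- mesh$vertices
  best <- rep(Inf, nrow(points))
  A <- V[faces[, 1], , drop = FALSE]
  E0 <- V[faces[, 2], , drop = FALSE] - A
  E1 <- V[faces[, 3], , drop = FALSE] - A
  a <- rowSums(E0^2); b <- rowSums(E0 * E1); c <- rowSums(E1^2)
  for (t in seq_len(nrow(faces))) {
    D <- sweep(points, 2, A[t, ])
    d <- -(D %*% E0[t, ])[, 1]; e <- -(D %*% E1[t, ])[, 1]
    f <- rowSums(D^2)
    det <- a[t] * c[t] - b[t]^2
    s <- b[t] * e - c[t] * d
    tt <- b[t] * d - a[t] * e
    ## clamp barycentric solution to the triangle
    s1 <- s / det; t1 <- tt / det
    inside <- s >= 0 & tt >= 0 & (s + tt) <= det
    out <- which(!inside)
    if (length(out)) {
      ## candidate closest points on the three edges
      cand <- matrix(Inf, length(out), 3L)
      ## edge t=0: q(s) = A + s E0
      s_e <- pmin(pmax(-d[out] / a[t], 0), 1)
      cand[, 1] <- a[t] * s_e^2 + 2 * d[out] * s_e + f[out]
      ## edge s=0: q(t) = A + t E1
      t_e <- pmin(pmax(-e[out] / c[t], 0), 1)
      cand[, 2] <- c[t] * t_e^2 + 2 * e[out] * t_e + f[out]
      ## edge s+t=1
      num <- (c[t] + e[out]) - (b[t] + d[out])
      s_h <- pmin(pmax(num / (a[t] - 2 * b[t] + c[t]), 0), 1)
      t_h <- 1 - s_h
      cand[, 3] <- a[t] * s_h^2 + 2 * b[t] * s_h * t_h + c[t] * t_h^2 +
        2 * d[out] * s_h + 2 * e[out] * t_h + f[out]
      dmin_out <- pmin(cand[, 1], cand[, 2], cand[, 3])
    }
    d2 <- numeric(nrow(points))
    if (any(inside)) {
      si <- s1[inside]; ti <- t1[inside]
      d2[inside] <- a[t] * si^2 + 2 * b[t] * si * ti + c[t] * ti^2 +
        2 * d[inside] * si + 2 * e[inside] * ti + f[inside]
    }
    if (length(out)) d2[out] <- dmin_out
    best <- pmin(best, pmax(d2, 0))
  }
  sqrt(best)
}

#' Intersection curve of a mesh with a plane
#'
#' Computes the exact intersection segments of mesh triangles with the plane
#' \code{dot(x - point, normal) = 0} and returns the crossing points on the
#' mesh edges. Points lie exactly in the plane and on the surface.
#'
#' @param mesh a \code{surface_mesh}.
#' @param plane list with unit \code{normal} and \code{point}.
#' @return matrix of 3D points (possibly 0 rows).
#' @export
mesh_plane_section <- function(mesh, plane) {
  n <- unitize(plane$normal)
  sd <- (mesh$vertices %*% n)[, 1] - sum(plane$point * n)
  f <- mesh$faces
  segs <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  s1 <- sd[segs[, 1]]; s2 <- sd[segs[, 2]]
  crossing <- (s1 > 0 & s2 < 0) | (s1 < 0 & s2 > 0)
  on_plane <- abs(sd) < 1e-12
  out <- NULL
  if (any(crossing)) {
    w <- s1[crossing] / (s1[crossing] - s2[crossing])
    p1 <- mesh$vertices[segs[crossing, 1], , drop = FALSE]
    p2 <- mesh$vertices[segs[crossing, 2], , drop = FALSE]
    out <- p1 + (p2 - p1) * w
  }
  if (any(on_plane))
    out <- rbind(out, mesh$vertices[which(on_plane), , drop = FALSE])
  if (is.null(out)) return(matrix(numeric(0), 0L, 3L))
  unique(round(out, 10))
}
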