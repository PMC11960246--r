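#' Mirror a mesh in the sagittal plane
#'
#' Negates x (the working frame's mediolateral axis; the sagittal plane is
#' x = 0) and flips face winding so outward normals remain outward. Applying
#' the operation twice restores the original mesh exactly. Used to bring
#' right-sided ("as-scanned") knee models into the left-knee working frame.
#'
#' @param mesh a \code{surface_mesh}.
#' @return mirrored \code{surface_mesh}.
#' @export
mirror_sagittal <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  surface_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE],
               face_labels = mesh$face_labels,
               vertex_scalar = mesh$vertex_scalar)
}

#' Surface area of a mesh or face subset
#'
#' Sum of triangle areas over the selected faces, in mm^2. With a mask this
#' gives e.g. the articulating surface area of a defect model.
#'
#' @param mesh a \code{surface_mesh}.
#' @param face_mask optional logical or integer face selection.
#' @return area in mm^2.
#' @export
surface_area <- function(mesh, face_mask = NULL) {
  fg <- face_geometry(mesh)
  areas <- fg$areas
  if (!is.null(face_mask)) {
    areas <- areas[face_mask]
    if (length(areas) == 0L) stop("empty face mask")
  }
  sum(areas)
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for
#' outward-oriented closed surfaces.
#'
#' @param mesh a closed \code{surface_mesh}.
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L)
  cc <- face_corner(mesh, 3L)
  sum(rowSums(a * cross3(b, cc))) / 6
}

#' Apply a similarity transform to a mesh
#'
#' @param mesh a \code{surface_mesh}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @param scale scalar scale factor.
#' @return transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2L, translation, "+")
  surface_mesh(v, mesh$faces, face_labels = mesh$face_labels,
               vertex_scalar = mesh$vertex_scalar)
}
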