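#' Similarity alignment of native models to the mean shape
#'
#' For each corresponded native model, computes the similarity transform
#' (rotation, translation and scale — scaling is applied here, unlike
#' during shape-model construction) minimising the Procrustes distance to
#' the mean shape.
#'
#' @param natives n x 3 x k array or list of n x 3 vertex matrices
#'   corresponded to the mean topology.
#' @param mean_shape n x 3 matrix.
#' @return list of per-model transforms (rotation, translation, scale).
#' @export
align_to_mean <- function(natives, mean_shape) {
  shapes <- natives_as_list(natives)
  lapply(shapes, function(v) {
    if (!all(dim(v) == dim(mean_shape)))
      stop("native model does not share the mean-shape topology")
    kabsch(v, mean_shape, scale = TRUE)
  })
}

natives_as_list <- function(natives) {
  if (is.array(natives) && length(dim(natives)) == 3L)
    lapply(seq_len(dim(natives)[3]), function(i) natives[, , i])
  else if (is.list(natives))
    lapply(natives, function(m) if (is.surface_mesh(m)) m$vertices else
      as.matrix(m))
  else stop("natives must be an array, or a list of meshes/matrices")
}

#' Transfer a native model's alignment transform to its defect model
#'
#' Applies the similarity transform obtained from [align_to_mean()] for the
#' paired native model verbatim, so the defect stays congruent with its
#' native model (up to the common scale) in the mean-shape frame.
#'
#' @param defect defect \code{surface_mesh}.
#' @param transform list with rotation, translation, scale.
#' @return transformed \code{surface_mesh}.
#' @export
transfer_to_defect <- function(defect, transform) {
  transform_mesh(defect, transform$rotation, transform$translation,
                 transform$scale)
}

#' Defect-location frequency heat map on the mean shape
#'
#' For each vertex of the mean shape, counts the defect models whose
#' articulating surface passes within distance \code{tau} (unsigned
#' closest-point distance) of the vertex. Counts are order-invariant and
#' bounded by the number of defects, and non-decreasing in \code{tau}.
#'
#' @param mean_mesh \code{surface_mesh} of the mean shape.
#' @param defects list of defect \code{surface_mesh} objects already in the
#'   mean-shape frame; articulating faces are the faces labelled
#'   \code{"articulating"} (all faces when unlabelled).
#' @param tau coverage tolerance, mm (default 1.0, the largest voxel
#'   dimension of typical knee MRI).
#' @param region_label optional face label of \code{mean_mesh} restricting
#'   the reported region; counts on masked-out vertices are still computed
#'   but flagged in \code{in_region}.
#' @return object of class \code{defect_heatmap}: list with \code{counts}
#'   (integer per vertex), \code{n_defects}, \code{tau}, \code{mesh}
#'   (mean mesh with counts as vertex scalar), \code{in_region},
#'   \code{argmax_vertex}, \code{max_count}.
#' @export
defect_frequency <- function(mean_mesh, defects, tau = 1.0,
                             region_label = NULL) {
  if (length(defects) == 0L) stop("empty defect list")
  nv <- nrow(mean_mesh$vertices)
  counts <- integer(nv)
  for (d in defects) {
    mask <- if (!is.null(d$face_labels)) d$face_labels == "articulating"
    else rep(TRUE, nrow(d$faces))
    ## bounding-box prefilter before exact point-to-triangle distances
    av <- sort(unique(as.vector(d$faces[mask, , drop = FALSE])))
    lo <- apply(d$vertices[av, , drop = FALSE], 2L, min) - tau
    hi <- apply(d$vertices[av, , drop = FALSE], 2L, max) + tau
    near <- which(mean_mesh$vertices[, 1] >= lo[1] &
                    mean_mesh$vertices[, 1] <= hi[1] &
                    mean_mesh$vertices[, 2] >= lo[2] &
                    mean_mesh$vertices[, 2] <= hi[2] &
                    mean_mesh$vertices[, 3] >= lo[3] &
                    mean_mesh$vertices[, 3] <= hi[3])
    if (!length(near)) next
    dd <- points_to_surface_distance(
      mean_mesh$vertices[near, , drop = FALSE], d, mask)
    counts[near[dd <= tau]] <- counts[near[dd <= tau]] + 1L
  }
  in_region <- rep(TRUE, nv)
  if (!is.null(region_label)) {
    if (is.null(mean_mesh$face_labels))
      stop("mean mesh carries no face labels")
    rv <- sort(unique(as.vector(
      mean_mesh$faces[mean_mesh$face_labels %in% region_label, ,
                      drop = FALSE])))
    in_region <- seq_len(nv) %in% rv
  }
  cr <- counts; cr[!in_region] <- -1L
  argmax <- which.max(cr)
  out_mesh <- surface_mesh(mean_mesh$vertices, mean_mesh$faces,
                           face_labels = mean_mesh$face_labels,
                           vertex_scalar = as.numeric(counts))
  structure(list(counts = counts, n_defects = length(defects), tau = tau,
                 mesh = out_mesh, in_region = in_region,
                 argmax_vertex = argmax, max_count = counts[argmax]),
            class = "defect_heatmap")
}

#' @export
print.defect_heatmap <- function(x, ...) {
  cat(sprintf(
    "defect_heatmap: %d defects, tau %.2f mm, max count %d at vertex %d\n",
    x$n_defects, x$tau, x$max_count, x$argmax_vertex))
  invisible(x)
}

#' Export a heat map as coloured PLY, CSV counts and JSON summary
#'
#' The PLY carries the count as a per-vertex quality scalar plus an 8-bit
#' colour from \code{palette}, normalised so the maximum count maps to the
#' colour-map maximum (uniform minimum colour when all counts are zero).
#'
#' @param heatmap a \code{defect_heatmap}.
#' @param path_prefix output prefix; writes \code{<prefix>.ply},
#'   \code{<prefix>_counts.csv} and \code{<prefix>_summary.json}.
#' @param palette a colour-map function (n -> colours), default
#'   \code{grDevices::hcl.colors} with the viridis palette.
#' @return named character vector of the written paths, invisibly.
#' @export
export_heatmap <- function(heatmap, path_prefix,
                           palette = function(n)
                             grDevices::hcl.colors(n, "viridis")) {
  counts <- heatmap$counts
  ncol_map <- 256L
  cols <- grDevices::col2rgb(palette(ncol_map))
  idx <- if (max(counts) == 0L) rep(1L, length(counts)) else
    1L + as.integer(round((counts / max(counts)) * (ncol_map - 1L)))
  rgb <- t(cols[, idx, drop = FALSE])
  ply <- paste0(path_prefix, ".ply")
  csv <- paste0(path_prefix, "_counts.csv")
  json <- paste0(path_prefix, "_summary.json")
  write_mesh(heatmap$mesh, ply, colors = rgb)
  utils::write.csv(
    data.frame(vertex = seq_along(counts), count = counts,
               in_region = heatmap$in_region),
    csv, row.names = FALSE)
  jsonlite::write_json(
    list(n_defects = heatmap$n_defects, tau_mm = heatmap$tau,
         argmax_vertex = heatmap$argmax_vertex,
         max_count = heatmap$max_count),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(ply = ply, csv = csv, json = json))
}
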