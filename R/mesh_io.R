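#' Read a triangulated surface mesh
#'
#' Supports ASCII PLY, OBJ and STL. STL stores triangle soup, so on load
#' duplicated vertices are welded on a 1e-6 mm grid; PLY and OBJ round-trip
#' coordinates and topology exactly (to the printed precision). Binary files
#' are rejected with an explicit error.
#'
#' @param path file path.
#' @param format one of \code{"ply"}, \code{"obj"}, \code{"stl"}; default
#'   guessed from the file extension.
#' @return a \code{surface_mesh}.
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangulated surface mesh
#'
#' Writes ASCII PLY (with optional per-vertex scalar and colour), OBJ or
#' STL. Output is deterministic: fixed numeric formatting, no timestamps.
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @param format one of \code{"ply"}, \code{"obj"}, \code{"stl"}; default
#'   guessed from the file extension.
#' @param digits decimal digits for coordinates (default 6, i.e. 1e-6 mm).
#' @param colors optional f x 3 or n x 3 integer matrix (0-255) of vertex
#'   colours (PLY only).
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, digits = 6L,
                       colors = NULL) {
  stopifnot(is.surface_mesh(mesh))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = write_ply(mesh, path, digits, colors),
         obj = write_obj(mesh, path, digits),
         stl = write_stl(mesh, path, digits),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a

fmt_num <- function(x, digits) {
  out <- formatC(x, format = "f", digits = digits)
  ## avoid "-0.000000"
  gsub("^-(0\\.?0*)$", "\\1", out)
}

## ---- PLY ---------------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1] != "ply")
    stop("not a PLY file: ", path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("corrupt PLY: no end_header in ", path)
  header <- lines[seq_len(hend)]
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop("only ASCII PLY is supported (binary PLY header found): ", path)
  el <- grep("^element ", header)
  counts <- list()
  props <- list()
  for (i in el) {
    tok <- strsplit(header[i], "\\s+")[[1]]
    nm <- tok[2]
    counts[[nm]] <- as.integer(tok[3])
    j <- i + 1L
    pr <- character(0)
    while (j <= hend && grepl("^property ", header[j])) {
      pr <- c(pr, header[j]); j <- j + 1L
    }
    props[[nm]] <- pr
  }
  nv <- counts[["vertex"]] %||% stop("PLY without vertex element")
  nf <- counts[["face"]] %||% 0L
  body <- lines[(hend + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("corrupt or truncated PLY: expected ", nv + nf,
         " data rows, found ", length(body), " in ", path)
  vlines <- body[seq_len(nv)]
  vfields <- strsplit(trimws(vlines), "\\s+")
  nfield <- lengths(vfields)
  if (any(nfield < 3L)) stop("corrupt PLY vertex row in ", path)
  vm <- matrix(as.numeric(unlist(vfields)), nrow = nv, byrow = TRUE)
  if (any(!is.finite(vm[, 1:3]))) stop("non-numeric PLY vertex data in ", path)
  vnames <- sub("^property\\s+\\S+\\s+", "", props[["vertex"]])
  scalar <- NULL
  qcol <- match("quality", vnames)
  if (!is.na(qcol) && qcol <= ncol(vm)) scalar <- vm[, qcol]
  faces <- NULL
  if (nf > 0L) {
    flines <- body[nv + seq_len(nf)]
    ffields <- strsplit(trimws(flines), "\\s+")
    fm <- lapply(ffields, function(x) as.integer(x))
    if (any(vapply(fm, function(x) x[1] != 3L, logical(1))))
      stop("only triangulated PLY faces are supported: ", path)
    faces <- do.call(rbind, lapply(fm, function(x) x[2:4] + 1L))
  } else faces <- matrix(integer(0), 0L, 3L)
  surface_mesh(vm[, 1:3, drop = FALSE], faces, vertex_scalar = scalar)
}

write_ply <- function(mesh, path, digits, colors) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  vprops <- c("property float x", "property float y", "property float z")
  cols <- NULL
  if (!is.null(mesh$vertex_scalar)) vprops <- c(vprops, "property float quality")
  if (!is.null(colors)) {
    stopifnot(nrow(colors) == nv, ncol(colors) == 3L)
    vprops <- c(vprops, "property uchar red", "property uchar green",
                "property uchar blue")
    cols <- matrix(as.integer(pmin(pmax(colors, 0), 255)), ncol = 3L)
  }
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv), vprops,
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices", "end_header")
  vtxt <- apply(fmt_num(mesh$vertices, digits), 1L, paste, collapse = " ")
  if (!is.null(mesh$vertex_scalar))
    vtxt <- paste(vtxt, fmt_num(mesh$vertex_scalar, digits))
  if (!is.null(cols))
    vtxt <- paste(vtxt, cols[, 1], cols[, 2], cols[, 3])
  ftxt <- paste("3", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(header, vtxt, ftxt), path)
}

## ---- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines)) stop("corrupt OBJ (no vertices): ", path)
  vf <- strsplit(trimws(sub("^v", "", vlines)), "\\s+")
  vm <- t(vapply(vf, function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  if (any(!is.finite(vm))) stop("non-numeric OBJ vertex data in ", path)
  ff <- strsplit(trimws(sub("^f", "", flines)), "\\s+")
  fm <- t(vapply(ff, function(x) {
    x <- x[x != ""]
    if (length(x) != 3L) stop("only triangulated OBJ faces are supported")
    as.integer(sub("/.*$", "", x))
  }, integer(3)))
  surface_mesh(vm, fm)
}

write_obj <- function(mesh, path, digits) {
  vtxt <- paste("v", apply(fmt_num(mesh$vertices, digits), 1L, paste,
                           collapse = " "))
  ftxt <- paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(vtxt, ftxt), path)
}

## ---- STL (ASCII, welded on load) --------------------------------------

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5L)
  if (!identical(head, charToRaw("solid")))
    stop("only ASCII STL is supported (binary STL header found): ", path)
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("corrupt or truncated STL: vertex count ", length(vlines),
         " is not a positive multiple of 3 in ", path)
  vf <- strsplit(trimws(sub("^\\s*vertex", "", vlines)), "\\s+")
  vm <- t(vapply(vf, function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  if (any(!is.finite(vm))) stop("non-numeric STL vertex data in ", path)
  ## weld duplicated triangle-soup vertices on a 1e-6 mm grid
  key <- apply(round(vm, 6L), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  uverts <- vm[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  surface_mesh(uverts, faces)
}

write_stl <- function(mesh, path, digits) {
  fg <- face_geometry(mesh)
  n <- fmt_num(fg$normals, digits)
  v1 <- fmt_num(face_corner(mesh, 1L), digits)
  v2 <- fmt_num(face_corner(mesh, 2L), digits)
  v3 <- fmt_num(face_corner(mesh, 3L), digits)
  rows <- vapply(seq_len(nrow(mesh$faces)), function(i) {
    paste(c(sprintf("  facet normal %s %s %s", n[i, 1], n[i, 2], n[i, 3]),
            "    outer loop",
            sprintf("      vertex %s %s %s", v1[i, 1], v1[i, 2], v1[i, 3]),
            sprintf("      vertex %s %s %s", v2[i, 1], v2[i, 2], v2[i, 3]),
            sprintf("      vertex %s %s %s", v3[i, 1], v3[i, 2], v3[i, 3]),
            "    endloop", "  endfacet"), collapse = "\n")
  }, character(1))
  writeLines(c("solid cartmorph", rows, "endsolid cartmorph"), path)
}
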