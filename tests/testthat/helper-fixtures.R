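# Shared fixtures built in code at test time.

# closed lat-long sphere (for signed-volume checks)
make_closed_sphere <- function(radius = 10, n = 16L) {
  phis <- seq(0, pi, length.out = n + 2L)[-c(1L, n + 2L)]
  nth <- 2L * n
  ths <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  g <- expand.grid(th = ths, ph = phis)
  ring <- cbind(radius * sin(g$ph) * cos(g$th),
                radius * sin(g$ph) * sin(g$th),
                radius * cos(g$ph))
  verts <- rbind(c(0, 0, radius), ring, c(0, 0, -radius))
  np <- nrow(verts)
  idx <- function(i, j) 1L + (j - 1L) * nth + i
  i <- seq_len(nth); ip <- c(seq_len(nth - 1L) + 1L, 1L)
  faces <- cbind(1L, idx(i, 1L), idx(ip, 1L))
  for (j in seq_len(n - 1L)) {
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i, j + 1L), idx(ip, j)),
                   cbind(idx(ip, j), idx(i, j + 1L), idx(ip, j + 1L)))
  }
  faces <- rbind(faces, cbind(np, idx(ip, n), idx(i, n)))
  m <- surface_mesh(verts, faces)
  if (signed_volume(m) < 0) m <- surface_mesh(verts, faces[, c(1L, 3L, 2L)])
  m
}

# unit square as two triangles
make_unit_square <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# brute-force minor axis: 1-degree angular scan of extents perpendicular
# to the major direction (independent oracle for defect_axes)
minor_axis_scan <- function(pts, major_dir) {
  major_dir <- major_dir / sqrt(sum(major_dir^2))
  ref <- if (abs(major_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * major_dir) * major_dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(major_dir[2] * e1[3] - major_dir[3] * e1[2],
          major_dir[3] * e1[1] - major_dir[1] * e1[3],
          major_dir[1] * e1[2] - major_dir[2] * e1[1])
  best <- 0
  for (deg in seq(0, 179)) {
    u <- cos(deg * pi / 180) * e1 + sin(deg * pi / 180) * e2
    ext <- diff(range(pts %*% u))
    best <- max(best, ext)
  }
  best
}

# small fast synthetic config for cohort-level tests
small_cohort_config <- function(...) {
  cohort_config(nu = 30L, nv = 22L, ...)
}
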