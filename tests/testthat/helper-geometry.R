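# Brute-force convex-hull oracle for small grids: a pixel center is in the
# hull of a point set iff it coincides with a point, lies on a segment
# between two points, or lies inside a non-degenerate triangle of points.

hull_oracle <- function(pts, nr = 8, nc = 8) {
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, nc)
  k <- nrow(pts)
  inh <- logical(nr * nc)
  on_seg <- function(a, b) {
    cr <- (px - a[1]) * (b[2] - a[2]) - (py - a[2]) * (b[1] - a[1])
    cr == 0 & px >= min(a[1], b[1]) & px <= max(a[1], b[1]) &
      py >= min(a[2], b[2]) & py <= max(a[2], b[2])
  }
  for (i in 1:k) for (j in i:k) inh <- inh | on_seg(pts[i, ], pts[j, ])
  if (k >= 3) {
    for (tri in utils::combn(k, 3, simplify = FALSE)) {
      a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
      area2 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (area2 == 0) next
      d1 <- (px - a[1]) * (b[2] - a[2]) - (py - a[2]) * (b[1] - a[1])
      d2 <- (px - b[1]) * (c[2] - b[2]) - (py - b[2]) * (c[1] - b[1])
      d3 <- (px - c[1]) * (a[2] - c[2]) - (py - c[2]) * (a[1] - c[1])
      inh <- inh | (d1 >= 0 & d2 >= 0 & d3 >= 0) |
        (d1 <= 0 & d2 <= 0 & d3 <= 0)
    }
  }
  matrix(inh, nr, nc)
}

mask_from_points <- function(idx, nr = 8, nc = 8) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  m
}

pts_of_mask <- function(m) {
  rc <- which(m, arr.ind = TRUE)
  cbind(rc[, 2] - 0.5, rc[, 1] - 0.5)
}
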