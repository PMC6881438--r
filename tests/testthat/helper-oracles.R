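# Independent oracles used across the suite. These re-derive quantities by
# a different route than the implementation (matrix propagation instead of
# the closed form, plain-R exhaustive loops instead of the compiled search).

# Paraxial ABCD propagation through a GRIN duct: reduced angles (u = n
# theta), translation through distance d in medium n is [[1, d/n], [0, 1]],
# the duct matrix over length z is [[cos(g), sin(g)/(n0 sa)],
# [-n0 sa sin(g), cos(g)]] with g = z*sa. The back working distance is
# where a ray from the axial object point re-crosses the axis in medium n2.
abcd_back_wd <- function(n0, sa, z, l1, n1, n2) {
  g <- z * sa
  duct <- matrix(c(cos(g), -n0 * sa * sin(g),
                   sin(g) / (n0 * sa), cos(g)), 2, 2)
  t1 <- matrix(c(1, 0, l1 / n1, 1), 2, 2)
  ray <- duct %*% t1 %*% c(0, 1)   # y = 0, unit reduced angle
  -n2 * ray[1] / ray[2]
}

# lateral magnification of the lens by tracing a ray parallel to the axis
# from an off-axis object point to the conjugate plane
abcd_lateral_mag <- function(n0, sa, z, l1, n1, n2) {
  g <- z * sa
  duct <- matrix(c(cos(g), -n0 * sa * sin(g),
                   sin(g) / (n0 * sa), cos(g)), 2, 2)
  t1 <- matrix(c(1, 0, l1 / n1, 1), 2, 2)
  l2 <- abcd_back_wd(n0, sa, z, l1, n1, n2)
  t2 <- matrix(c(1, 0, l2 / n2, 1), 2, 2)
  sys <- t2 %*% duct %*% t1
  abs(sys[1, 1])
}

# plain-R edge-replicated shift (independent of the compiled kernel)
shift_rep_r <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- pmin(pmax(seq_len(ny) - dy, 1), ny)
  xs <- pmin(pmax(seq_len(nx) - dx, 1), nx)
  img[ys, xs, drop = FALSE]
}

# brute-force SSD minimizer with the same tie-break contract
brute_best_shift <- function(frame, templ, radius) {
  best <- Inf; best_s <- c(0L, 0L)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    s <- sum((templ - shift_rep_r(frame, dy, dx))^2)
    better <- s < best - 1e-12
    tie <- abs(s - best) <= 1e-12 &&
      (dy^2 + dx^2 < sum(best_s^2) ||
         (dy^2 + dx^2 == sum(best_s^2) &&
            (dy < best_s[1] || (dy == best_s[1] && dx < best_s[2]))))
    if (better || tie) { best <- min(best, s); best_s <- c(dy, dx) }
  }
  best_s
}
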