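# Independent oracles: deliberately naive implementations used to verify the
# package's fast paths. They never share code with the implementation.

# Exhaustive all-pairs minimum distance (double loop).
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

# Brute-force euclidean row-distance matrix (double loop).
brute_row_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  d
}

euler_rotation <- function(a, b, c) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# RMSD for a fixed rotation with the optimal (centroid-matching) translation.
rot_rmsd <- function(A, B, R) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

# Fine rotation-angle search: coarse Euler-angle grid refined around the
# best cell. Independent of the SVD route.
brute_rotation_rmsd <- function(A, B, levels = 4) {
  step <- pi / 18
  center <- c(0, 0, 0)
  best <- Inf
  best_ang <- center
  for (lev in seq_len(levels)) {
    if (lev == 1) {
      a_seq <- seq(-pi, pi, by = step)
      b_seq <- seq(0, pi, by = step)
      c_seq <- seq(-pi, pi, by = step)
    } else {
      a_seq <- seq(center[1] - step, center[1] + step, length.out = 9)
      b_seq <- seq(center[2] - step, center[2] + step, length.out = 9)
      c_seq <- seq(center[3] - step, center[3] + step, length.out = 9)
      step <- 2 * step / 8
    }
    for (a in a_seq) for (b in b_seq) for (cc in c_seq) {
      r <- rot_rmsd(A, B, euler_rotation(a, b, cc))
      if (r < best) {
        best <- r
        best_ang <- c(a, b, cc)
      }
    }
    center <- best_ang
  }
  best
}
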