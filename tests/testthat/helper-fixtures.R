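# Shared fixtures, built in code at test time.

# minimal hand-built monomer from a coordinate matrix
toy_monomer <- function(xyz, resno = seq_len(nrow(xyz)), elety = "CA",
                        aa = "A", b = 20, o = 1, model_id = "1",
                        chain_id = "A") {
  monomer_model(model_id, chain_id,
                data.frame(resno = resno, aa = aa, elety = elety,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           b = b, o = o, stringsAsFactors = FALSE))
}

# small non-degenerate 3D point cloud
toy_cloud <- function(n = 8, seed = 42) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 5), ncol = 3)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
         byrow = TRUE)
}

random_proper_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent brute-force oracle: best RMSD over SO(3) by nested grid
# search over Euler angles (translation handled by centroid matching)
grid_search_rmsd <- function(P, Q, levels = 6, n_grid = 13) {
  euler_rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_at <- function(a, b, c) {
    R <- euler_rot(a, b, c)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  # coarse global scan, keeping several candidate basins, then nested
  # refinement of each candidate
  coarse <- expand.grid(
    a = seq(0, 2 * pi, length.out = n_grid),
    b = seq(0, pi, length.out = n_grid),
    c = seq(0, 2 * pi, length.out = n_grid))
  coarse$r <- mapply(rmsd_at, coarse$a, coarse$b, coarse$c)
  cand <- coarse[order(coarse$r)[1:8], c("a", "b", "c")]
  best <- min(coarse$r)
  for (k in seq_len(nrow(cand))) {
    ctr <- as.numeric(cand[k, ])
    span <- rep(pi / (n_grid - 1) * 1.5, 3)
    for (lev in seq_len(levels)) {
      gr <- expand.grid(
        a = seq(ctr[1] - span[1], ctr[1] + span[1], length.out = 7),
        b = seq(ctr[2] - span[2], ctr[2] + span[2], length.out = 7),
        c = seq(ctr[3] - span[3], ctr[3] + span[3], length.out = 7))
      gr$r <- mapply(rmsd_at, gr$a, gr$b, gr$c)
      i <- which.min(gr$r)
      ctr <- as.numeric(gr[i, c("a", "b", "c")])
      best <- min(best, gr$r[i])
      span <- span * 0.4
    }
  }
  best
}

# analytic SASA of two intersecting probe-expanded spheres
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}
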