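# SAXS analysis: Guinier fitting, residue-bead Debye curves from
# coordinates, chi goodness-of-fit with free scale, and an exhaustive
# minimal ensemble search over candidate model curves.

#' Build a scattering curve
#' @param q momentum transfer, Angstrom^-1, strictly increasing, >= 0.
#' @param i intensities (arbitrary units).
#' @param sigma positive point errors; defaults to 1 for theoretical
#'   curves.
#' @export
scattering_curve <- function(q, i, sigma = rep(1, length(q))) {
  stopifnot(length(q) == length(i), length(sigma) == length(q),
            all(q >= 0), !is.unsorted(q, strictly = TRUE),
            all(sigma > 0))
  structure(list(q = q, i = i, sigma = sigma), class = "scattering_curve")
}

#' Guinier analysis of the low-angle regime
#'
#' Iterative weighted linear fit of ln I against q^2 over the window
#' where q * R_g <= `qrg_max` (1.3 by default): the window starts at the
#' lowest measured q, the fit is repeated with the window implied by the
#' current R_g until R_g changes by less than 0.5%.
#'
#' @param curve a `scattering_curve`.
#' @param qrg_max Guinier validity bound on q * R_g.
#' @param min_points minimum window size.
#' @return list `rg` (Angstrom), `i0`, `q_window`, `qrg_end`,
#'   `n_points`.
#' @export
guinier <- function(curve, qrg_max = 1.3, min_points = 5) {
  q <- curve$q; I <- curve$i; s <- curve$sigma
  ok <- I > 0
  q <- q[ok]; I <- I[ok]; s <- s[ok]
  if (length(q) < min_points) stop("too few positive-intensity points")
  fit_window <- function(idx) {
    w <- (I[idx] / s[idx])^2  # ln I errors are sigma/I
    f <- stats::lm(log(I[idx]) ~ I(q[idx]^2), weights = w)
    slope <- stats::coef(f)[2]
    if (slope >= 0) stop("no Guinier regime (non-negative slope)")
    list(rg = sqrt(-3 * slope), i0 = exp(stats::coef(f)[1]))
  }
  idx <- seq_len(max(min_points, min(10, length(q))))
  f <- fit_window(idx)
  for (iter in 1:30) {
    idx_new <- which(q * f$rg <= qrg_max)
    if (length(idx_new) < min_points)
      idx_new <- seq_len(min_points)
    f_new <- fit_window(idx_new)
    done <- abs(f_new$rg - f$rg) < 0.005 * f$rg
    f <- f_new; idx <- idx_new
    if (done) break
  }
  list(rg = unname(f$rg), i0 = unname(f$i0),
       q_window = range(q[idx]), qrg_end = max(q[idx]) * f$rg,
       n_points = length(idx))
}

#' Theoretical scattering curve by the Debye formula (residue beads)
#'
#' One bead per residue at the CA position with a uniform form factor:
#' I(q) = f^2 * sum_ij sinc(q * r_ij), so I(0) = (n f)^2. A deliberately
#' simple stand-in for hydrated all-atom predictors; adequate for
#' relative comparisons between models of the same protein.
#'
#' @param models a `monomer_model` or list of them (multi-chain
#'   assemblies are concatenated).
#' @param q momentum transfer grid, Angstrom^-1.
#' @param f uniform bead form factor.
#' @return a `scattering_curve` (sigma = 1).
#' @export
debye_curve <- function(models, q, f = 1) {
  if (inherits(models, "monomer_model")) models <- list(models)
  xyz <- do.call(rbind, lapply(models, function(m) {
    a <- m$atoms[m$atoms$elety == "CA", c("x", "y", "z")]
    as.matrix(a)
  }))
  n <- nrow(xyz)
  if (n < 1) stop("no CA beads found")
  d <- as.vector(stats::dist(xyz))
  I <- vapply(q, function(qk) {
    if (qk == 0) return((n * f)^2)
    x <- qk * d
    f^2 * (n + 2 * sum(sin(x) / x))
  }, numeric(1))
  scattering_curve(q, I)
}

#' Radius of gyration of residue beads (coordinate definition)
#' @inheritParams debye_curve
#' @return R_g in Angstrom.
#' @export
coordinate_rg <- function(models) {
  if (inherits(models, "monomer_model")) models <- list(models)
  xyz <- do.call(rbind, lapply(models, function(m)
    as.matrix(m$atoms[m$atoms$elety == "CA", c("x", "y", "z")])))
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Chi goodness-of-fit between experimental and theoretical curves
#'
#' Finds the scale c minimizing sum(((I_e - c I_t) / sigma)^2) in closed
#' form and reports chi = sqrt(min / N). The theoretical curve is
#' interpolated onto the experimental grid.
#'
#' @param exp experimental `scattering_curve` (with errors).
#' @param theo theoretical `scattering_curve`.
#' @return list `scale`, `chi`.
#' @export
chi_fit <- function(exp, theo) {
  if (min(exp$q) < min(theo$q) - 1e-12 ||
      max(exp$q) > max(theo$q) + 1e-12)
    stop("experimental q range outside theoretical grid")
  It <- stats::approx(theo$q, theo$i, xout = exp$q)$y
  w <- 1 / exp$sigma^2
  scale <- sum(w * exp$i * It) / sum(w * It^2)
  chi <- sqrt(mean(((exp$i - scale * It) / exp$sigma)^2))
  list(scale = scale, chi = chi)
}

# chi for a non-negative weighted combination of pool curves
nnls_chi <- function(A, b, n) {
  fit <- pracma::lsqnonneg(A, b)
  chi <- sqrt(sum(fit$resid.norm) / n)
  list(coef = fit$x, chi = chi)
}

#' Minimal ensemble search over a pool of theoretical curves
#'
#' Exhaustively evaluates all subsets of the pool up to `max_size`
#' members; for each subset, non-negative least squares fits the
#' (scale-absorbing) weights against the experimental curve. Returns the
#' smallest subset whose chi is within `tol_factor` of the global best.
#'
#' @param exp experimental `scattering_curve`.
#' @param pool list of theoretical `scattering_curve`s (<= 40).
#' @param max_size largest subset considered (default 5).
#' @param tol_factor acceptance factor on the global best chi
#'   (default 1.05).
#' @return list `selected` (pool indices), `weights` (sum to 1),
#'   `scale`, `chi`, `chi_by_size`.
#' @export
minimal_ensemble_search <- function(exp, pool, max_size = 5,
                                    tol_factor = 1.05) {
  if (!length(pool)) stop("empty pool")
  if (length(pool) > 40) stop("pool too large for exhaustive search")
  max_size <- min(max_size, length(pool))
  A_full <- vapply(pool, function(th)
    stats::approx(th$q, th$i, xout = exp$q)$y / exp$sigma,
    numeric(length(exp$q)))
  b <- exp$i / exp$sigma
  n <- length(b)
  best_by_size <- vector("list", max_size)
  for (k in seq_len(max_size)) {
    subsets <- utils::combn(length(pool), k)
    best <- NULL
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      r <- nnls_chi(A_full[, idx, drop = FALSE], b, n)
      if (is.null(best) || r$chi < best$chi)
        best <- list(idx = idx, coef = r$coef, chi = r$chi)
    }
    best_by_size[[k]] <- best
  }
  chis <- vapply(best_by_size, `[[`, numeric(1), "chi")
  chi_star <- min(chis)
  k_sel <- which(chis <= tol_factor * chi_star + 1e-12)[1]
  sel <- best_by_size[[k_sel]]
  keep <- sel$coef > 0
  coef <- sel$coef[keep]; idx <- sel$idx[keep]
  list(selected = idx, weights = coef / sum(coef), scale = sum(coef),
       chi = sel$chi, chi_by_size = chis)
}

#' Read a 3-column SAXS .dat file (q, I, sigma)
#' @param path whitespace- or comma-separated text file; `#` comments
#'   allowed.
#' @export
read_scattering_dat <- function(path) {
  df <- utils::read.table(path, comment.char = "#", sep = "",
                          col.names = c("q", "i", "sigma"))
  scattering_curve(df$q, df$i, df$sigma)
}

#' Write a scattering curve as a .dat file
#' @param curve a `scattering_curve`.
#' @param path output path.
#' @export
write_scattering_dat <- function(curve, path) {
  utils::write.table(
    data.frame(q = curve$q, i = curve$i, sigma = curve$sigma),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
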