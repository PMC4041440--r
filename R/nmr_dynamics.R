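# 15N relaxation and chemical-shift-perturbation analysis.
#
# R1 and R2 are obtained per residue by monoexponential fits of peak
# intensity against relaxation delay; the heteronuclear NOE is the
# saturated/unsaturated intensity ratio with a duplicate-based error.
# The overall rotational correlation time tau_c follows from the trimmed
# mean R2/R1 ratio of the most ordered residues via the isotropic
# large-molecule closed form
#   tau_c = sqrt(6 <R2/R1> - 7) / (4 pi nu_N),
# valid when J(omega) is dominated by the overall tumbling term.

GAMMA_RATIO_15N <- 0.101329  # |gamma(15N)| / gamma(1H)

#' 15N Larmor frequency from the spectrometer proton frequency
#' @param proton_mhz 1H frequency in MHz (e.g. 599.78).
#' @return nu_N in Hz.
#' @export
nitrogen_frequency <- function(proton_mhz) {
  GAMMA_RATIO_15N * proton_mhz * 1e6
}

#' Fit a monoexponential relaxation decay
#'
#' Nonlinear least-squares fit of I(t) = I0 * exp(-R * t). Start values
#' come from a log-linear fit; parameter errors from the fit covariance.
#' When repeated delays are present, their scatter provides the noise
#' estimate used to scale the parameter errors.
#'
#' @param delays delay times in seconds (>= 4 distinct values).
#' @param intensities peak intensities (arbitrary units).
#' @return list with `rate` (s^-1), `rate_err`, `i0`, `flagged` (TRUE for
#'   non-convergence or non-positive rate, excluded downstream).
#' @export
fit_exponential_rate <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  if (length(unique(delays)) < 4)
    stop("need at least 4 distinct delays")
  if (!all(is.finite(intensities))) stop("non-finite intensities")
  df <- data.frame(t = delays, I = intensities)
  pos <- df$I > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(I) ~ t, data = df[pos, ])
    r0 <- max(-unname(stats::coef(lf)[2]), 1e-3)
    i00 <- exp(unname(stats::coef(lf)[1]))
  } else {
    r0 <- 1; i00 <- max(df$I)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t), data = df,
                      start = list(I0 = i00, R = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(rate = NA_real_, rate_err = NA_real_, i0 = NA_real_,
                flagged = TRUE))
  co <- summary(fit)$coefficients
  rate <- co["R", "Estimate"]; err <- co["R", "Std. Error"]
  # duplicate-delay scatter as noise estimate, when available
  dup <- split(df$I, df$t)
  dup <- dup[vapply(dup, length, integer(1)) > 1]
  if (length(dup)) {
    s_dup <- sqrt(mean(unlist(lapply(dup, function(v) stats::var(v)))))
    s_fit <- summary(fit)$sigma
    if (is.finite(s_dup) && s_fit > 0) err <- err * s_dup / s_fit
  }
  list(rate = rate, rate_err = err,
       i0 = co["I0", "Estimate"],
       flagged = !is.finite(rate) || rate <= 1e-3)
}

#' Fit a table of relaxation series
#'
#' @param table data frame with columns `residue`, `delay_s`, `intensity`
#'   (and optionally `replicate`).
#' @return data frame `residue`, `rate`, `rate_err`, `i0`, `flagged`.
#' @export
fit_relaxation_table <- function(table) {
  stopifnot(all(c("residue", "delay_s", "intensity") %in% names(table)))
  res <- sort(unique(table$residue))
  rows <- lapply(res, function(r) {
    d <- table[table$residue == r, ]
    f <- tryCatch(fit_exponential_rate(d$delay_s, d$intensity),
                  error = function(e) list(rate = NA_real_,
                                           rate_err = NA_real_,
                                           i0 = NA_real_, flagged = TRUE))
    data.frame(residue = r, rate = f$rate, rate_err = f$rate_err,
               i0 = f$i0, flagged = f$flagged)
  })
  do.call(rbind, rows)
}

#' Steady-state heteronuclear NOE from intensity ratios
#'
#' NOE = I_on / I_off (with / without proton saturation). With a
#' duplicate pair of experiments the value is the mean of the two ratios
#' and the error half their absolute difference.
#'
#' @param i_on,i_off intensities; vectors of length 1 (single set) or 2
#'   (duplicate sets).
#' @return list `noe`, `noe_err`, `flagged` (TRUE when `i_off` is ~0 or
#'   the NOE exceeds the physical ceiling ~1.2).
#' @export
het_noe <- function(i_on, i_off) {
  stopifnot(length(i_on) == length(i_off))
  if (any(abs(i_off) < 1e-12 * max(abs(i_on), 1)))
    return(list(noe = NA_real_, noe_err = NA_real_, flagged = TRUE))
  ratios <- i_on / i_off
  noe <- mean(ratios)
  err <- if (length(ratios) == 2) abs(diff(ratios)) / 2 else NA_real_
  list(noe = noe, noe_err = err, flagged = noe > 1.2)
}

#' Select the most ordered residues for tumbling analysis
#'
#' Excludes residues with hetNOE below `noe_min` and residues whose
#' R2/R1 deviates more than `k_sd` standard deviations from the trimmed
#' mean, iterating the deviation filter once.
#'
#' @param rates data frame with columns `residue`, `r1`, `r2`, `noe`.
#' @param noe_min hetNOE floor (default 0.65).
#' @param k_sd deviation cut in SD units (default 1).
#' @param trim trimming fraction for the trimmed mean (default 0.1).
#' @return integer vector of selected residue numbers.
#' @export
select_ordered_residues <- function(rates, noe_min = 0.65, k_sd = 1,
                                    trim = 0.1) {
  ok <- is.finite(rates$r1) & is.finite(rates$r2) & rates$r1 > 0 &
    rates$r2 > 0
  if ("noe" %in% names(rates))
    ok <- ok & is.finite(rates$noe) & rates$noe >= noe_min
  sel <- rates[ok, ]
  ratio <- sel$r2 / sel$r1
  for (pass in 1:2) {
    m <- mean(ratio, trim = trim)
    s <- stats::sd(ratio)
    keep <- abs(ratio - m) <= k_sd * s
    if (all(keep)) break
    sel <- sel[keep, ]; ratio <- ratio[keep]
  }
  sort(sel$residue)
}

#' Rotational correlation time from the mean R2/R1 ratio
#'
#' Isotropic large-molecule closed form:
#' tau_c = sqrt(6 * <R2/R1> - 7) / (4 * pi * nu_N).
#'
#' @param rates data frame `residue`, `r1`, `r2` (and optionally `noe`);
#'   alternatively pass `mean_ratio` directly.
#' @param nu_n 15N Larmor frequency in Hz (see [nitrogen_frequency()]).
#' @param residues residues to use; default [select_ordered_residues()].
#' @param mean_ratio optional pre-computed mean R2/R1 (overrides `rates`).
#' @return list `tau_c` (seconds), `mean_ratio`, `residues_used`.
#' @export
tau_c_from_r2_r1 <- function(rates = NULL, nu_n, residues = NULL,
                             mean_ratio = NULL) {
  if (is.null(mean_ratio)) {
    if (is.null(residues)) residues <- select_ordered_residues(rates)
    if (length(residues) < 5) stop("need >= 5 selected residues")
    sel <- rates[rates$residue %in% residues, ]
    mean_ratio <- mean(sel$r2 / sel$r1)
  } else residues <- integer(0)
  if (mean_ratio <= 7 / 6)
    stop("mean R2/R1 <= 7/6: outside the validity of the closed form")
  tau_c <- sqrt(6 * mean_ratio - 7) / (4 * pi * nu_n)
  list(tau_c = tau_c, mean_ratio = mean_ratio, residues_used = residues)
}

# ---- chemical shift perturbation ---------------------------------------

#' Combined chemical shift perturbation profile of a titration point
#'
#' Matches peaks of the free and bound spectra by residue number and
#' computes the combined perturbation
#' Delta delta = sqrt(ddH^2 + (ddN / n_weight)^2), the intensity ratio
#' I_bound / I_free, and a centered sliding-window mean of the ratio
#' (edge windows truncated). Residues present in only one spectrum get
#' `NA` (never 0) for both quantities.
#'
#' @param free,bound data frames with columns `residue`, `h_ppm`,
#'   `n_ppm`, `intensity`.
#' @param n_weight 15N scaling divisor in the combined shift (default
#'   6.51, the convention of the source data).
#' @param window sliding-window width in residues (odd; default 5).
#' @return data frame `residue`, `dd_h`, `dd_n`, `dd_combined`,
#'   `intensity_ratio`, `ratio_windowed`.
#' @export
csp <- function(free, bound, n_weight = 6.51, window = 5) {
  need <- c("residue", "h_ppm", "n_ppm", "intensity")
  stopifnot(all(need %in% names(free)), all(need %in% names(bound)),
            window %% 2 == 1)
  res <- sort(unique(c(free$residue, bound$residue)))
  fi <- match(res, free$residue); bi <- match(res, bound$residue)
  dd_h <- abs(bound$h_ppm[bi] - free$h_ppm[fi])
  dd_n <- abs(bound$n_ppm[bi] - free$n_ppm[fi])
  dd <- sqrt(dd_h^2 + (dd_n / n_weight)^2)
  ratio <- bound$intensity[bi] / free$intensity[fi]
  half <- (window - 1) / 2
  win <- vapply(seq_along(res), function(i) {
    in_win <- which(abs(res - res[i]) <= half)
    v <- ratio[in_win]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(residue = res, dd_h = dd_h, dd_n = dd_n, dd_combined = dd,
             intensity_ratio = ratio, ratio_windowed = win)
}

#' Call perturbation hotspots
#'
#' Flags residues whose combined shift perturbation (or, with
#' `metric = "intensity"`, whose windowed intensity *drop*) exceeds the
#' profile mean by `k` standard deviations.
#'
#' @param profile output of [csp()].
#' @param k threshold in SD units (default 1).
#' @param metric `"csp"` or `"intensity"`.
#' @return integer vector of called residues (possibly empty).
#' @export
hotspot_call <- function(profile, k = 1, metric = c("csp", "intensity")) {
  metric <- match.arg(metric)
  v <- switch(metric, csp = profile$dd_combined,
              intensity = 1 - profile$ratio_windowed)
  if (all(is.na(v))) stop("profile contains no usable values")
  thr <- mean(v, na.rm = TRUE) + k * stats::sd(v, na.rm = TRUE)
  sort(profile$residue[!is.na(v) & v > thr])
}
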