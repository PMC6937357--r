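# Model fits on the measured metrics: the noise-versus-counts power law
# (Poisson statistics predict COV ~ N^(-1/2)), the micro-to-NEMA
# cross-calibration, and the exponential lesion-ratio-versus-size fit.

#' Fit the noise-versus-counts power law
#'
#' Least-squares fit of `log COV = log a + b log N` on (counts-per-voxel,
#' COV) points. Pure Poisson statistics give b = -1/2; the reported
#' `deviation_from_half` is `b - (-0.5)`.
#'
#' @param counts vector of detected counts per voxel, > 0.
#' @param cov vector of matching COV values, > 0.
#' @return list(a, b, se_b, r_squared, deviation_from_half, n).
#' @export
fit_noise_vs_counts <- function(counts, cov) {
  ok <- is.finite(counts) & is.finite(cov) & counts > 0 & cov > 0
  counts <- counts[ok]; cov <- cov[ok]
  if (length(counts) < 3)
    stop("need at least 3 valid (counts, COV) points", call. = FALSE)
  if (length(unique(signif(counts, 12))) < 2)
    stop("degenerate fit: all counts equal", call. = FALSE)
  fit <- lm(log(cov) ~ log(counts))
  s <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  b <- unname(coef(fit)[2])
  list(a = exp(unname(coef(fit)[1])), b = b,
       se_b = unname(s$coefficients[2, 2]),
       r_squared = s$r.squared, deviation_from_half = b + 0.5,
       n = length(counts))
}

#' Cross-calibrate micro-phantom recovery coefficients to the NEMA scale
#'
#' The two phantoms share a 10 mm sphere; each micro RC is rescaled by
#' `rc_nema_10mm / rc_micro_10mm` so the two RC-versus-size curves join
#' (correcting for the different attenuation environments).
#'
#' @param rc_micro numeric vector of micro-phantom RCs.
#' @param rc_micro_10mm,rc_nema_10mm the 10 mm sphere RCs in each phantom,
#'   both > 0.
#' @return rescaled RCs (same order as `rc_micro`).
#' @export
cross_calibrate_micro <- function(rc_micro, rc_micro_10mm, rc_nema_10mm) {
  if (!is.finite(rc_micro_10mm) || rc_micro_10mm <= 0)
    stop("micro 10 mm RC must be > 0", call. = FALSE)
  if (!is.finite(rc_nema_10mm) || rc_nema_10mm <= 0)
    stop("NEMA 10 mm RC must be > 0", call. = FALSE)
  rc_micro * (rc_nema_10mm / rc_micro_10mm)
}

#' Exponential fit of a ratio-versus-size curve
#'
#' Nonlinear least squares for `y(d) = y_inf + A * exp(-d / tau)` with
#' `y_inf >= 0` and `tau > 0`, for BPL/OSEM ratio versus lesion diameter.
#'
#' @param diameter vector of diameters, mm (>= 4 points).
#' @param ratio matching ratio values.
#' @return list(y_inf, A, tau, r_squared, degenerate, fitted).
#' @export
fit_ratio_vs_size <- function(diameter, ratio) {
  ok <- is.finite(diameter) & is.finite(ratio)
  d <- diameter[ok]; y <- ratio[ok]
  if (length(d) < 4) stop("need at least 4 points", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-20 * max(1, mean(y)^2)) {
    # constant input: amplitude ~ 0, R^2 undefined
    return(list(y_inf = mean(y), A = 0, tau = NA_real_,
                r_squared = NA_real_, degenerate = TRUE,
                fitted = rep(mean(y), length(d))))
  }
  start <- list(y_inf = max(min(y), 1e-6), A = max(y) - min(y) + 1e-6,
                tau = diff(range(d)) / 2)
  fit <- tryCatch(
    nls(y ~ y_inf + A * exp(-d / tau), start = start, algorithm = "port",
        lower = c(y_inf = 0, A = -Inf, tau = 1e-6),
        control = list(maxiter = 500, warnOnly = FALSE)),
    error = function(e)
      stop("ratio-vs-size fit did not converge (starts: y_inf=",
           signif(start$y_inf, 4), ", A=", signif(start$A, 4), ", tau=",
           signif(start$tau, 4), "): ", conditionMessage(e), call. = FALSE))
  p <- coef(fit)
  res <- y - fitted(fit)
  list(y_inf = unname(p["y_inf"]), A = unname(p["A"]),
       tau = unname(p["tau"]), r_squared = 1 - sum(res^2) / ss_tot,
       degenerate = FALSE, fitted = as.numeric(fitted(fit)))
}
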