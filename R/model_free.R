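#' Guinier fit of the low-Q region
#'
#' Weighted linear regression of `ln I` against `Q^2` over a user-chosen
#' window, giving the radius of gyration `Rg = sqrt(-3 * slope)` and the
#' forward intensity `I(0) = exp(intercept)`. Points with non-positive
#' intensity are masked before taking logarithms. The default window,
#' 0.001 < Q^2 < 0.002 Angstrom^-2, is the usual choice for a compactly
#' folded ~30 kDa scatterer; it is a parameter, not a constant.
#'
#' The conventional validity guideline Q*Rg <= 1.3 is reported and, when
#' `enforce_qrg` is set and exceeded, flagged with a warning -- never an
#' error, because unfolded states are routinely fit beyond it.
#'
#' @param curve a [scattering_curve()].
#' @param q2_min,q2_max Guinier window in Q^2 (Angstrom^-2).
#' @param enforce_qrg if `TRUE`, attach a warning flag when Q*Rg at the
#'   window edge exceeds 1.3.
#' @return `guinier_result`: list with `rg`, `rg_err` (Angstrom), `i0`,
#'   `i0_err`, `q2_range`, `qrg_max`, `r_squared`, `n_points`,
#'   `qrg_warning`.
#' @export
guinier_fit <- function(curve, q2_min = 0.001, q2_max = 0.002,
                        enforce_qrg = FALSE) {
  stopifnot(inherits(curve, "scattering_curve"))
  q2 <- curve$q^2
  sel <- q2 >= q2_min & q2 <= q2_max & curve$intensity > 0
  if (sum(sel) < 3) {
    stop("fewer than 3 positive-intensity points in the Guinier window")
  }
  x <- q2[sel]
  y <- log(curve$intensity[sel])
  # var(ln I) = (sigma/I)^2
  w <- if (is.null(curve$sigma)) rep(1, length(x)) else {
    s <- curve$sigma[sel]
    ifelse(is.finite(s) & s > 0, (curve$intensity[sel] / s)^2, NA_real_)
  }
  if (anyNA(w)) w[is.na(w)] <- stats::median(w, na.rm = TRUE)
  fit <- stats::lm(y ~ x, weights = w)
  slope <- stats::coef(fit)[["x"]]
  if (slope >= 0) stop("no Guinier decay in window (non-negative slope)")
  rg <- sqrt(-3 * slope)
  i0 <- exp(stats::coef(fit)[["(Intercept)"]])
  # noiseless synthetic curves fit exactly; summary.lm's "essentially
  # perfect fit" warning is meaningless here
  smry <- suppressWarnings(summary(fit))
  vc <- suppressWarnings(stats::vcov(fit))
  rg_err <- 3 * sqrt(vc["x", "x"]) / (2 * rg)
  i0_err <- i0 * sqrt(vc["(Intercept)", "(Intercept)"])
  qrg_max <- sqrt(max(x)) * rg
  warn <- isTRUE(enforce_qrg) && qrg_max > 1.3
  if (warn) {
    warning(sprintf("Q*Rg = %.2f at window edge exceeds the 1.3 guideline", qrg_max))
  }
  structure(list(
    rg = rg, rg_err = rg_err, i0 = i0, i0_err = i0_err,
    q2_range = c(min(x), max(x)), qrg_max = qrg_max,
    r_squared = smry$r.squared, n_points = length(x),
    qrg_warning = warn
  ), class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f +/- %.2f A, I(0) = %.4g +/- %.2g (%d pts, QRg_max %.2f)\n",
              x$rg, x$rg_err, x$i0, x$i0_err, x$n_points, x$qrg_max))
  invisible(x)
}

#' Debye function of an ideal Gaussian chain
#'
#' `D(u) = 2 (exp(-u) + u - 1) / u^2` with `u = (Q * Rg)^2`; the closed-form
#' normalized intensity of a random-walk polymer. For `u < 1e-4` the series
#' `1 - u/3 + u^2/12` is used to avoid cancellation.
#'
#' @param q momentum transfer, Angstrom^-1.
#' @param rg radius of gyration, Angstrom.
#' @return numeric vector `D((q * rg)^2)`.
#' @export
debye_function <- function(q, rg) {
  u <- (q * rg)^2
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- 1 - u[small] / 3 + u[small]^2 / 12
  ub <- u[!small]
  out[!small] <- 2 * (exp(-ub) + ub - 1) / ub^2
  out
}

#' Fit the Debye random-coil function to a curve
#'
#' Weighted nonlinear least squares of `I(Q) = I(0) * D((Q*Rg)^2)` over
#' `(I(0), Rg)`. The starting Rg comes from a Guinier pass over the fit range
#' (falling back to 20 Angstrom); on non-convergence a restart grid
#' Rg in {5, 10, 20, 40, 80} Angstrom is tried before giving up.
#'
#' @param curve a [scattering_curve()].
#' @param q_range fit window in Q (Angstrom^-1); default spans the data.
#' @param init_rg starting Rg in Angstrom, or `"auto"`.
#' @return `debye_result`: list with `rg`, `rg_err`, `i0`, `i0_err`,
#'   `chi2_reduced`, `q_range`.
#' @export
debye_fit <- function(curve, q_range = NULL, init_rg = "auto") {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(q_range)) q_range <- range(curve$q)
  win <- curve_window(curve, q_range[1], q_range[2])
  if (length(win$q) < 10) stop("fewer than 10 points in the Debye fit range")
  w <- curve_weights(win)
  df <- data.frame(q = win$q, i = win$intensity)

  rg0 <- if (identical(init_rg, "auto")) {
    g <- tryCatch(
      guinier_fit(win, q2_min = min(win$q)^2, q2_max = stats::quantile(win$q^2, 0.25)),
      error = function(e) NULL)
    if (is.null(g)) 20 else g$rg
  } else as.numeric(init_rg)

  try_one <- function(rg_start) {
    i0_start <- max(win$intensity[1], 1e-12)
    tryCatch(
      minpack.lm::nlsLM(i ~ i0 * debye_function(q, rg), data = df,
                        start = list(i0 = i0_start, rg = rg_start),
                        weights = w, lower = c(1e-12, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_one(rg0)
  best_resid <- Inf
  if (is.null(fit)) {
    for (rg_start in c(5, 10, 20, 40, 80)) {
      fit <- try_one(rg_start)
      if (!is.null(fit)) break
      best_resid <- min(best_resid, Inf)
    }
  }
  if (is.null(fit)) {
    stop(sprintf("Debye fit did not converge from the restart grid (best residual: %g)",
                 best_resid))
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  dof <- max(length(win$q) - 2L, 1L)
  chi2 <- sum(w * stats::residuals(fit)^2) / dof
  structure(list(
    rg = unname(est["rg"]), rg_err = unname(se[2]),
    i0 = unname(est["i0"]), i0_err = unname(se[1]),
    chi2_reduced = chi2, q_range = range(win$q)
  ), class = "debye_result")
}

#' @export
print.debye_result <- function(x, ...) {
  cat(sprintf("Debye fit: Rg = %.2f +/- %.2f A, I(0) = %.4g, chi2_red = %.3g\n",
              x$rg, x$rg_err, x$i0, x$chi2_reduced))
  invisible(x)
}

# Centered moving-average smoother used by the Kratky feature extraction;
# window is in points, forced odd.
smooth_ma <- function(y, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(y)
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(y[lo:hi])
  }
  out
}

#' Kratky transform and fold-state classification
#'
#' Computes `y = Q^2 * I(Q)` pointwise and classifies the curve shape:
#' a compactly folded particle shows a low-Q bell, a random coil a flat
#' high-Q plateau without a bell, and a partially flexible structure both.
#' Feature definitions (all tunable): the bell is a local maximum of the
#' smoothed transform below `bell_q_max` exceeding the high-Q median by at
#' least `bell_prominence`; the plateau requires the relative drift of the
#' smoothed transform above `plateau_q_min` to stay within
#' `plateau_flatness` of flat.
#'
#' @param curve a [scattering_curve()].
#' @param bell_q_max upper Q bound for the bell search (Angstrom^-1).
#' @param plateau_q_min lower Q bound for the plateau check (Angstrom^-1).
#' @param bell_prominence required fractional excess of the bell peak over
#'   the high-Q median.
#' @param plateau_flatness allowed fractional drift across the plateau.
#' @return `kratky_profile`: list with `q`, `y`, `classification` (one of
#'   `"folded"`, `"random_coil"`, `"partially_flexible"`) and `features`
#'   (`bell_peak_q`, possibly `NA`; `plateau_level`, possibly `NA`).
#' @export
kratky_transform <- function(curve, bell_q_max = 0.15, plateau_q_min = 0.2,
                             bell_prominence = 0.25, plateau_flatness = 0.2) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q
  y <- q^2 * curve$intensity
  ys <- smooth_ma(y, max(5L, length(y) %/% 20L))

  hi <- q >= plateau_q_min
  hi_median <- if (any(hi)) stats::median(ys[hi]) else stats::median(ys)

  # bell: interior local maximum of the smoothed transform below bell_q_max
  bell_peak_q <- NA_real_
  low_idx <- which(q < bell_q_max)
  if (length(low_idx) >= 3) {
    interior <- low_idx[low_idx > 1 & low_idx < length(q)]
    is_max <- vapply(interior, function(i) ys[i] >= ys[i - 1] && ys[i] >= ys[i + 1],
                     logical(1))
    cand <- interior[is_max]
    cand <- cand[ys[cand] >= (1 + bell_prominence) * hi_median]
    if (length(cand)) bell_peak_q <- q[cand[which.max(ys[cand])]]
  }
  has_bell <- !is.na(bell_peak_q)

  # plateau: relative drift of the smoothed transform across the high-Q range
  plateau_level <- NA_real_
  has_plateau <- FALSE
  if (sum(hi) >= 5) {
    yh <- ys[hi]; qh <- q[hi]
    mean_y <- mean(yh)
    if (mean_y > 0) {
      sl <- stats::coef(stats::lm(yh ~ qh))[["qh"]]
      drift <- sl * (max(qh) - min(qh)) / mean_y
      has_plateau <- abs(drift) <= plateau_flatness
      if (has_plateau) plateau_level <- mean_y
    }
  }

  classification <- if (has_bell && !has_plateau) "folded"
    else if (!has_bell && has_plateau) "random_coil"
    else "partially_flexible"

  structure(list(
    q = q, y = y, classification = classification,
    features = list(bell_peak_q = bell_peak_q, plateau_level = plateau_level)
  ), class = "kratky_profile")
}

#' @export
print.kratky_profile <- function(x, ...) {
  cat(sprintf("Kratky profile: %s (bell at Q = %s, plateau level = %s)\n",
              x$classification,
              if (is.na(x$features$bell_peak_q)) "none" else
                sprintf("%.3f A^-1", x$features$bell_peak_q),
              if (is.na(x$features$plateau_level)) "none" else
                sprintf("%.3g", x$features$plateau_level)))
  invisible(x)
}

# Half-up rounding (printed-table convention); R's round() is half-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Molecular-weight ratio from forward intensities
#'
#' For dilute particles at fixed contrast, `I(0)` is proportional to
#' molecular weight times weight concentration, so
#' `MW / MW_st = (I(0)/C) / (I(0)_st/C_st)` against a standard sample of
#' known (or unit) relative molecular weight. Reported at full precision
#' together with half-up rounding to 1 decimal, the convention of printed
#' tables.
#'
#' @param i0,c forward intensity and concentration (mg/mL) of the sample.
#' @param i0_st,c_st the same for the standard sample.
#' @param mw_st_ratio relative molecular weight of the standard (default 1).
#' @return `mw_ratio_result`: list with `i0`, `c`, `i0_st`, `c_st`, `ratio`,
#'   `ratio_rounded`.
#' @export
mw_ratio <- function(i0, c, i0_st, c_st, mw_st_ratio = 1) {
  vals <- c(i0 = i0, c = c, i0_st = i0_st, c_st = c_st,
            mw_st_ratio = mw_st_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs to mw_ratio must be positive and finite")
  }
  ratio <- (i0 / c) / (i0_st / c_st) * mw_st_ratio
  structure(list(i0 = i0, c = c, i0_st = i0_st, c_st = c_st,
                 ratio = ratio, ratio_rounded = round_half_up(ratio, 1)),
            class = "mw_ratio_result")
}

#' @export
print.mw_ratio_result <- function(x, ...) {
  cat(sprintf("MW ratio: %.4f (rounded: %.1f)\n", x$ratio, x$ratio_rounded))
  invisible(x)
}

#' Aggregated-particle fraction from low-Q excess
#'
#' Two-population decomposition of the low-Q region: the curve is modeled as
#' a monomer Guinier term (held near a previously fitted `monomer_fit`) plus
#' a large-particle Guinier term of fixed `aggregate_rg`. The per-particle
#' forward intensity scales as molecular weight squared (volume squared), so
#' the number fraction of aggregates follows from the fitted I(0) ratio
#' scaled by the inverse square of the volume ratio, with the volume ratio
#' taken as the cube of the size ratio.
#'
#' @param curve a [scattering_curve()].
#' @param monomer_fit a `guinier_result` for the monomer population.
#' @param aggregate_rg assumed aggregate radius of gyration, Angstrom.
#' @param q_max upper Q bound of the decomposition window (Angstrom^-1).
#' @return `aggregate_estimate`: list with `fraction` (number fraction in
#'   0..1), `monomer_i0`, `aggregate_i0`, `size_ratio`, `note`.
#' @export
aggregate_fraction <- function(curve, monomer_fit, aggregate_rg = 100,
                               q_max = 0.05) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(monomer_fit, "guinier_result"))
  win <- curve_window(curve, q_max = q_max)
  if (length(win$q) < 5) stop("too few low-Q points for the decomposition")
  w <- curve_weights(win)
  rg_m <- monomer_fit$rg
  i0_m0 <- monomer_fit$i0

  monomer_pred <- i0_m0 * exp(-win$q^2 * rg_m^2 / 3)
  excess <- win$intensity - monomer_pred
  if (!any(excess > 0)) {
    return(structure(list(fraction = 0, monomer_i0 = i0_m0, aggregate_i0 = 0,
                          size_ratio = aggregate_rg / rg_m,
                          note = "no low-Q excess above the monomer extrapolation"),
                     class = "aggregate_estimate"))
  }

  df <- data.frame(q = win$q, i = win$intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      i ~ i0m * exp(-q^2 * rg_m^2 / 3) + i0a * exp(-q^2 * aggregate_rg^2 / 3),
      data = df, weights = w,
      start = list(i0m = i0_m0, i0a = max(mean(pmax(excess, 0)), 1e-12)),
      lower = c(0.8 * i0_m0, 0), upper = c(1.2 * i0_m0, Inf)),
    error = function(e) NULL)
  if (is.null(fit)) stop("two-population decomposition did not converge")
  est <- stats::coef(fit)
  size_ratio <- aggregate_rg / rg_m
  # I(0) per particle ~ V^2; number fraction = (i0a/i0m) / (V_a/V_m)^2 with
  # V_a/V_m = size_ratio^3
  n_ratio <- (est[["i0a"]] / est[["i0m"]]) / size_ratio^6
  frac <- n_ratio / (1 + n_ratio)
  structure(list(fraction = unname(frac), monomer_i0 = est[["i0m"]],
                 aggregate_i0 = est[["i0a"]], size_ratio = size_ratio,
                 note = sprintf("assumes I(0) per particle ~ V^2 and V ratio = (Rg ratio)^3 = %.3g",
                                size_ratio^3)),
            class = "aggregate_estimate")
}

#' @export
print.aggregate_estimate <- function(x, ...) {
  cat(sprintf("Aggregate fraction: %.3g%% (%s)\n", 100 * x$fraction, x$note))
  invisible(x)
}
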