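#' Construct a 1D scattering curve
#'
#' The central in-memory container for a reduced small-angle scattering
#' dataset: a strictly increasing momentum-transfer grid `q` (in inverse
#' Angstrom), intensities `I(Q)` (typically cm^-1 after absolute calibration,
#' but any consistent scale is accepted -- every analysis in this package is
#' scale-covariant), and optional 1-sigma uncertainties.
#'
#' Negative intensities are legal: background-subtracted data carry
#' information below zero and are kept; operations that take logarithms mask
#' them instead of failing.
#'
#' @param q numeric vector of momentum transfer values, Angstrom^-1, strictly
#'   increasing and positive.
#' @param intensity numeric vector, same length as `q`.
#' @param sigma optional numeric vector of 1-sigma uncertainties (same units
#'   as `intensity`); `NULL` means unknown, treated downstream as unit
#'   weights.
#' @param label free-text label (for example a pD condition).
#' @param concentration protein concentration in mg/mL, or `NA`.
#' @param pd_value pD of the sample, or `NA`.
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = "",
                             concentration = NA_real_, pd_value = NA_real_) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("q and intensity must have the same length")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be finite and strictly positive")
  }
  dq <- diff(q)
  if (any(dq <= 0)) {
    first_bad <- which(dq <= 0)[1] + 1L
    stop(sprintf("q must be strictly increasing; first offending row: %d (q = %g)",
                 first_bad, q[first_bad]))
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma must match q in length")
    if (any(is.finite(sigma) & sigma < 0)) stop("sigma must be non-negative")
  }
  if (max(q) > 5) {
    warning("max(q) > 5 Angstrom^-1; the data may be in nm^-1 (no conversion applied)")
  }
  structure(
    list(q = q, intensity = intensity, sigma = sigma, label = as.character(label),
         concentration = as.numeric(concentration), pd_value = as.numeric(pd_value)),
    class = "scattering_curve"
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %s\n", if (nzchar(x$label)) x$label else "(unlabeled)"))
  cat(sprintf("  %d points, q = %.4g .. %.4g A^-1, sigma %s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "absent" else "present"))
  if (!is.na(x$concentration)) cat(sprintf("  concentration: %g mg/mL\n", x$concentration))
  if (!is.na(x$pd_value)) cat(sprintf("  pD: %g\n", x$pd_value))
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

# Effective least-squares weights: 1/sigma^2 where sigma is present and
# positive, unit weights otherwise.
curve_weights <- function(curve) {
  if (is.null(curve$sigma)) return(rep(1, length(curve$q)))
  w <- ifelse(is.finite(curve$sigma) & curve$sigma > 0, 1 / curve$sigma^2, NA_real_)
  pos <- w[is.finite(w)]
  w[!is.finite(w)] <- if (length(pos)) stats::median(pos) else 1
  w
}

# Restrict a curve to a q-window, preserving metadata.
curve_window <- function(curve, q_min = -Inf, q_max = Inf) {
  keep <- curve$q >= q_min & curve$q <= q_max
  scattering_curve(curve$q[keep], curve$intensity[keep],
                   if (is.null(curve$sigma)) NULL else curve$sigma[keep],
                   label = curve$label, concentration = curve$concentration,
                   pd_value = curve$pd_value)
}
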