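# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the joint-clubs model
#'
#' The open-bundle scattering model: `n_clubs` identical rigid cylinders
#' ("clubs", the alpha-helices) of length `club_length` joined end-to-end by
#' short flexible loops of length `loop_gap`, with the joint orientations
#' averaged over an ensemble of conformations.
#'
#' `club_diameter` is a DIAMETER: the cylinder radius used internally is
#' `club_diameter / 2`. This convention matches the structural comparison
#' the model is built for (helix diameters of ~10 Angstrom).
#'
#' @param club_length club (cylinder) length L, Angstrom.
#' @param club_diameter club diameter R, Angstrom.
#' @param n_clubs number of clubs (default 4, a four-helix bundle).
#' @param loop_gap end-to-end spacing bridged by each loop, Angstrom
#'   (default 5, a short inter-helix loop; fixed, not fitted).
#' @param scale forward-intensity scale (model tends to `scale + background`
#'   as Q tends to 0).
#' @param background flat incoherent background.
#' @return A `joint_clubs_params` object.
#' @export
joint_clubs_params <- function(club_length, club_diameter, n_clubs = 4,
                               loop_gap = 5, scale = 1, background = 0) {
  stopifnot(n_clubs >= 1, club_length > 0, club_diameter > 0,
            loop_gap >= 0, scale > 0, background >= 0)
  structure(list(n_clubs = as.integer(n_clubs), club_length = club_length,
                 club_diameter = club_diameter, loop_gap = loop_gap,
                 scale = scale, background = background),
            class = "joint_clubs_params")
}

# Sample unit axis vectors for every club of every conformation, uniformly
# on the sphere with a fold-back rejection: the angle between consecutive
# club axes must stay below max_angle (degrees), preventing a club from
# doubling back through its predecessor.
sample_club_axes <- function(n_conformations, n_clubs, max_angle = 150,
                             max_tries = 1000) {
  cos_min <- cos(max_angle * pi / 180)
  axes <- matrix(0, nrow = n_conformations * n_clubs, ncol = 3)
  rand_unit <- function() {
    z <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    c(r * cos(phi), r * sin(phi), z)
  }
  for (c_i in seq_len(n_conformations)) {
    prev <- NULL
    for (k in seq_len(n_clubs)) {
      tries <- 0L
      repeat {
        a <- rand_unit()
        if (is.null(prev) || sum(a * prev) > cos_min) break
        tries <- tries + 1L
        if (tries >= max_tries) {
          stop("joint rejection loop exceeded 1000 tries; try a larger loop_gap")
        }
      }
      axes[(c_i - 1L) * n_clubs + k, ] <- a
      prev <- a
    }
  }
  axes
}

#' Joint-clubs model intensity
#'
#' Monte-Carlo conformational average of the jointed-cylinder chain. Each
#' conformation places the clubs end-to-end with independent uniformly
#' random joint orientations (rejecting fold-back angles of 150 degrees or
#' more); the scattering of each rigid conformation is orientationally
#' averaged by spherical quadrature of the analytic cylinder amplitudes and
#' their inter-club phase factors. The result is
#' `scale * <F^2> + background` with `<F^2>` normalized to 1 at Q = 0.
#' A fixed seed makes the curve bit-reproducible.
#'
#' @param params a [joint_clubs_params()].
#' @param q_grid momentum-transfer grid, Angstrom^-1.
#' @param n_conformations Monte-Carlo ensemble size (default 20000 for
#'   final curves; fits use fewer).
#' @param seed RNG seed for the conformational ensemble.
#' @param n_orient orientational quadrature directions per conformation.
#' @return `theoretical_curve` with fields `q`, `intensity`, `source`,
#'   plus `seed` and `n_conformations`.
#' @export
joint_clubs_intensity <- function(params, q_grid, n_conformations = 20000,
                                  seed = 1, n_orient = 128) {
  stopifnot(inherits(params, "joint_clubs_params"), n_conformations >= 100)
  q_grid <- as.numeric(q_grid)
  axes <- with_seed(seed, sample_club_axes(n_conformations, params$n_clubs))
  m <- cpp_joint_clubs(axes, params$n_clubs, params$club_length,
                       params$club_diameter / 2, params$loop_gap,
                       q_grid, as.integer(n_orient))
  structure(list(q = q_grid, intensity = params$scale * m + params$background,
                 source = sprintf("joint_clubs(n=%d, L=%.3g, R=%.3g)",
                                  params$n_clubs, params$club_length,
                                  params$club_diameter),
                 contrast = NULL, seed = seed,
                 n_conformations = n_conformations),
            class = "theoretical_curve")
}

#' Orientationally averaged cylinder form factor (closed quadrature)
#'
#' The classical normalized form factor of a right circular cylinder,
#' `P(Q) = integral_0^1 [sinc(QLt/2) * 2 J1(Q r sqrt(1-t^2)) / (Q r
#' sqrt(1-t^2))]^2 dt`, evaluated by adaptive quadrature. Serves as the
#' independent single-cylinder reference for the joint-clubs model and as
#' the exact generator for synthetic cylinder data.
#'
#' @param q momentum-transfer values, Angstrom^-1.
#' @param length cylinder length, Angstrom.
#' @param diameter cylinder diameter, Angstrom.
#' @return numeric vector of `P(Q)`, equal to 1 at Q = 0.
#' @export
cylinder_form_factor <- function(q, length, diameter) {
  rad <- diameter / 2
  j1norm <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 8,
                               2 * besselJ(x, 1) / x)
  sincv <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  vapply(q, function(qv) {
    stats::integrate(function(t) {
      (sincv(qv * length * t / 2) * j1norm(qv * rad * sqrt(1 - t^2)))^2
    }, 0, 1, rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
}

#' Fit the joint-clubs model to a scattering curve
#'
#' Weighted least squares over club length L, club diameter R, scale and
#' background, with `n_clubs` and `loop_gap` held fixed. The Monte-Carlo
#' conformational ensemble is drawn once per fit (common random numbers),
#' so the objective is deterministic and smooth in (L, R); scale and
#' background are profiled out linearly at every step. Parameter
#' uncertainties come from the Jacobian at the optimum, inflated by
#' `sqrt(chi2_reduced)`.
#'
#' @param curve a [scattering_curve()].
#' @param init a [joint_clubs_params()] giving starting values and the
#'   fixed `n_clubs` / `loop_gap`.
#' @param q_range fit window in Q (Angstrom^-1); default spans the data.
#' @param n_conformations ensemble size per objective evaluation.
#' @param seed RNG seed (the ensemble is shared across evaluations).
#' @param n_orient orientational quadrature directions.
#' @return `joint_clubs_fit`: list with `params` (fitted), `param_errors`
#'   (named: club_length, club_diameter, scale, background),
#'   `chi2_reduced`, `q_range`, `n_conformations`, `seed`.
#' @export
joint_clubs_fit <- function(curve, init, q_range = NULL,
                            n_conformations = 2000, seed = 1,
                            n_orient = 128) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(init, "joint_clubs_params"))
  if (is.null(q_range)) q_range <- range(curve$q)
  win <- curve_window(curve, q_range[1], q_range[2])
  if (length(win$q) < 20) stop("fewer than 20 points in the fit range")
  w <- curve_weights(win)
  y <- win$intensity
  axes <- with_seed(seed, sample_club_axes(n_conformations, init$n_clubs))

  model_curve <- function(L, R) {
    cpp_joint_clubs(axes, init$n_clubs, L, R / 2, init$loop_gap,
                    win$q, as.integer(n_orient))
  }
  profile_linear <- function(m) {
    # solve min_w || y - (scale m + bg) ||^2 with scale > 0, bg >= 0
    sw <- sum(w); swm <- sum(w * m); swm2 <- sum(w * m^2)
    swy <- sum(w * y); swmy <- sum(w * m * y)
    det <- swm2 * sw - swm^2
    scale <- (swmy * sw - swm * swy) / det
    bg <- (swm2 * swy - swm * swmy) / det
    if (bg < 0 || !is.finite(bg)) { bg <- 0; scale <- swmy / swm2 }
    if (scale <= 0 || !is.finite(scale)) return(NULL)
    list(scale = scale, bg = bg)
  }
  objective <- function(par) {
    L <- par[1]; R <- par[2]
    m <- model_curve(L, R)
    lin <- profile_linear(m)
    if (is.null(lin)) return(1e30)
    sum(w * (y - lin$scale * m - lin$bg)^2)
  }

  starts <- rbind(c(init$club_length, init$club_diameter),
                  as.matrix(expand.grid(L = c(20, 30, 40), R = c(8, 10, 14))))
  best <- NULL
  tried <- data.frame(L = numeric(0), R = numeric(0), objective = numeric(0))
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = c(5, 2), upper = c(300, 80),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      tried <- rbind(tried, data.frame(L = opt$par[1], R = opt$par[2],
                                       objective = opt$value))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!is.null(best) && s == 1 && best$convergence == 0) break
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e30) {
    stop(paste0("joint-clubs fit did not converge; residuals tried:\n",
                paste(utils::capture.output(print(tried)), collapse = "\n")))
  }

  L_hat <- unname(best$par[1]); R_hat <- unname(best$par[2])
  m <- model_curve(L_hat, R_hat)
  lin <- profile_linear(m)
  resid <- y - lin$scale * m - lin$bg
  dof <- max(length(y) - 4L, 1L)
  chi2 <- sum(w * resid^2) / dof

  # numeric Jacobian in (L, R, scale, background)
  hL <- max(1e-3 * L_hat, 1e-3); hR <- max(1e-3 * R_hat, 1e-3)
  dm_dL <- (model_curve(L_hat + hL, R_hat) - model_curve(L_hat - hL, R_hat)) / (2 * hL)
  dm_dR <- (model_curve(L_hat, R_hat + hR) - model_curve(L_hat, R_hat - hR)) / (2 * hR)
  J <- cbind(lin$scale * dm_dL, lin$scale * dm_dR, m, rep(1, length(m)))
  JtWJ <- t(J) %*% (w * J)
  cov <- tryCatch(solve(JtWJ) * chi2, error = function(e)
    matrix(NA_real_, 4, 4))
  errs <- sqrt(pmax(diag(cov), 0))
  names(errs) <- c("club_length", "club_diameter", "scale", "background")

  fitted_params <- joint_clubs_params(
    club_length = L_hat, club_diameter = R_hat, n_clubs = init$n_clubs,
    loop_gap = init$loop_gap, scale = lin$scale,
    background = max(lin$bg, 0))
  structure(list(params = fitted_params, param_errors = errs,
                 chi2_reduced = chi2, q_range = range(win$q),
                 n_conformations = n_conformations, seed = seed),
            class = "joint_clubs_fit")
}

#' @export
print.joint_clubs_fit <- function(x, ...) {
  cat(sprintf("Joint-clubs fit (n_clubs = %d): L = %.1f +/- %.1f A, R = %.1f +/- %.1f A\n",
              x$params$n_clubs, x$params$club_length,
              x$param_errors[["club_length"]], x$params$club_diameter,
              x$param_errors[["club_diameter"]]))
  cat(sprintf("  scale = %.4g, background = %.4g, chi2_red = %.3g, seed = %d, %d conformations\n",
              x$params$scale, x$params$background, x$chi2_reduced, x$seed,
              x$n_conformations))
  invisible(x)
}
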