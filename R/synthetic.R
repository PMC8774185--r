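#' Normalized sphere form factor
#'
#' `P(Q) = [3 (sin(QR) - QR cos(QR)) / (QR)^3]^2` for a homogeneous sphere
#' of radius `radius`; equals 1 at Q = 0. The sphere's radius of gyration is
#' `sqrt(3/5) * radius`.
#'
#' @param q momentum transfer, Angstrom^-1.
#' @param radius sphere radius, Angstrom.
#' @return numeric vector.
#' @export
sphere_form_factor <- function(q, radius) {
  x <- q * radius
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 5
  xb <- x[!small]
  out[!small] <- (3 * (sin(xb) - xb * cos(xb)) / xb^3)^2
  out
}

#' Specify a synthetic scattering dataset
#'
#' Defines a ground-truth model, a q grid, and a counting-statistics noise
#' recipe. Supported models and their `params`:
#' \describe{
#'   \item{sphere}{`radius` (A), `i0`; optional `floor_intensity` for a flat
#'     incoherent floor.}
#'   \item{gaussian_coil}{`rg` (A), `i0` (Debye function).}
#'   \item{cylinder}{`length`, `diameter` (A), `i0`.}
#'   \item{joint_clubs}{`club_length`, `club_diameter` (A), `i0`; optional
#'     `n_clubs` (4), `loop_gap` (5), `n_conformations` (5000).}
#'   \item{two_population}{`rg_m`, `i0_m`, `rg_a`, `i0_a`: a sum of two
#'     Guinier terms (monomer plus trace aggregate).}
#'   \item{mixture}{`components`: list of specs (model/params) plus
#'     `weights`; intensities are summed with the given weights.}
#' }
#' The noise model is `sigma(Q) = I(Q) * (floor + counting /
#' sqrt(max(I(Q), 1e-12) * t_eff))`: a fractional floor plus a counting term
#' that grows as the intensity falls, mirroring how statistical error bars
#' behave on a reduced SANS curve at a few mg/mL.
#'
#' @param model model tag (see above).
#' @param params named list of model parameters.
#' @param q_grid list with `qmin`, `qmax` (Angstrom^-1), `n`, and `spacing`
#'   (`"linear"` or `"log"`). The default grid, 0.01--0.45, covers a
#'   low-Q Guinier region plus the working window of a typical SANS
#'   experiment on a small protein.
#' @param noise list with `floor` (fractional), `counting`, `t_eff`;
#'   `floor = 0, counting = 0` gives a noiseless curve (sigma absent).
#' @param seed RNG seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(model, params,
                           q_grid = list(qmin = 0.01, qmax = 0.45, n = 120,
                                         spacing = "linear"),
                           noise = list(floor = 0.01, counting = 8e-4,
                                        t_eff = 1),
                           seed = 1) {
  stopifnot(q_grid$qmin > 0, q_grid$n >= 20)
  noise$floor <- if (is.null(noise$floor)) 0 else noise$floor
  noise$counting <- if (is.null(noise$counting)) 0 else noise$counting
  noise$t_eff <- if (is.null(noise$t_eff)) 1 else noise$t_eff
  stopifnot(noise$floor >= 0, noise$counting >= 0, noise$t_eff > 0)
  structure(list(model = model, params = params, q_grid = q_grid,
                 noise = noise, seed = seed),
            class = "synthetic_spec")
}

eval_model_intensity <- function(model, params, q) {
  switch(model,
    sphere = {
      i <- params$i0 * sphere_form_factor(q, params$radius)
      if (!is.null(params$floor_intensity)) i <- i + params$floor_intensity
      i
    },
    gaussian_coil = params$i0 * debye_function(q, params$rg),
    cylinder = params$i0 * cylinder_form_factor(q, params$length, params$diameter),
    joint_clubs = {
      p <- joint_clubs_params(
        club_length = params$club_length, club_diameter = params$club_diameter,
        n_clubs = if (is.null(params$n_clubs)) 4 else params$n_clubs,
        loop_gap = if (is.null(params$loop_gap)) 5 else params$loop_gap,
        scale = params$i0,
        background = if (is.null(params$background)) 0 else params$background)
      nc <- if (is.null(params$n_conformations)) 5000 else params$n_conformations
      sd_ <- if (is.null(params$mc_seed)) 1 else params$mc_seed
      joint_clubs_intensity(p, q, n_conformations = nc, seed = sd_)$intensity
    },
    two_population = {
      params$i0_m * exp(-q^2 * params$rg_m^2 / 3) +
        params$i0_a * exp(-q^2 * params$rg_a^2 / 3)
    },
    mixture = {
      stopifnot(length(params$components) == length(params$weights))
      Reduce(`+`, Map(function(comp, wt) {
        wt * eval_model_intensity(comp$model, comp$params, q)
      }, params$components, params$weights))
    },
    stop(sprintf("unknown model tag: %s", model))
  )
}

#' Generate a synthetic scattering curve with ground truth
#'
#' Evaluates the exact intensity of the requested model on the grid,
#' perturbs it with
#' Gaussian noise of the specified sigma(Q), and returns both the noisy
#' curve (with its true sigma attached) and a ground-truth record. Fully
#' reproducible from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param label,concentration,pd_value metadata for the curve.
#' @return list with `curve` (a [scattering_curve()]) and `truth` (list:
#'   `model`, `params`, `ideal_intensity`, plus `rg`/`i0` where the model
#'   defines them).
#' @export
generate_curve <- function(spec, label = spec$model,
                           concentration = NA_real_, pd_value = NA_real_) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$q_grid
  q <- if (identical(g$spacing, "log")) {
    exp(seq(log(g$qmin), log(g$qmax), length.out = g$n))
  } else {
    seq(g$qmin, g$qmax, length.out = g$n)
  }
  ideal <- eval_model_intensity(spec$model, spec$params, q)
  nz <- spec$noise
  noiseless <- nz$floor == 0 && nz$counting == 0
  sigma <- ideal * (nz$floor + nz$counting / sqrt(pmax(ideal, 1e-12) * nz$t_eff))
  intensity <- if (noiseless) ideal else
    with_seed(spec$seed, ideal + stats::rnorm(length(q), 0, sigma))

  truth <- list(model = spec$model, params = spec$params,
                ideal_intensity = ideal, seed = spec$seed)
  truth$i0 <- switch(spec$model,
    sphere = spec$params$i0, gaussian_coil = spec$params$i0,
    cylinder = spec$params$i0, joint_clubs = spec$params$i0,
    two_population = spec$params$i0_m + spec$params$i0_a, NULL)
  truth$rg <- switch(spec$model,
    sphere = sqrt(3 / 5) * spec$params$radius,
    gaussian_coil = spec$params$rg, NULL)

  curve <- scattering_curve(q, intensity,
                            if (noiseless) NULL else sigma,
                            label = label, concentration = concentration,
                            pd_value = pd_value)
  list(curve = curve, truth = truth)
}

#' Write a generated curve plus its ground-truth sidecar
#'
#' Writes the `.dat` file via [write_curve()] and a `<path>.truth.json`
#' sidecar holding the generating model and parameters, so downstream
#' checks never need to parse truth out of filenames.
#'
#' @param generated output of [generate_curve()].
#' @param path output `.dat` path.
#' @return invisibly, the sidecar path.
#' @export
write_generated <- function(generated, path) {
  write_curve(generated$curve, path)
  truth <- generated$truth
  truth$ideal_intensity <- NULL
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Four reference unfolding-scenario curves
#'
#' Emits labeled synthetic curves for the four solution states the analysis
#' pipeline distinguishes: (i) an unfolded random coil (Debye function,
#' Rg = 25 A), (ii) a compactly folded dimer (globule with Rg = 18 A),
#' (iii) a 9:1 dimer:monomer mixture (incipient dissociation), and (iv) an
#' open-bundle monomer (joint-clubs chain, L = 31.5 A, R = 10.6 A, four
#' clubs). Forward intensities are scaled so that I(0)/C of the dimer is
#' exactly twice that of the monomeric states, the signature the
#' molecular-weight ratio analysis keys on.
#'
#' @param seed RNG seed (noise and Monte-Carlo ensembles derive from it).
#' @param noise noise recipe passed to [synthetic_spec()].
#' @return named list (`coil`, `folded_dimer`, `dissociating`,
#'   `open_bundle`) of [generate_curve()] outputs.
#' @export
generate_bundle_scenarios <- function(seed = 1,
                                      noise = list(floor = 0.01,
                                                   counting = 8e-4,
                                                   t_eff = 1)) {
  k0 <- 0.078 / 5.5   # monomer I(0) per (mg/mL)
  rg_dimer <- 18; rg_monomer <- 14
  r_dimer <- rg_dimer / sqrt(3 / 5)
  r_monomer <- rg_monomer / sqrt(3 / 5)

  coil <- generate_curve(
    synthetic_spec("gaussian_coil", list(rg = 25, i0 = k0 * 5.5),
                   noise = noise, seed = seed),
    label = "coil", concentration = 5.5, pd_value = 1.7)

  folded <- generate_curve(
    synthetic_spec("sphere", list(radius = r_dimer, i0 = 2 * k0 * 5.5),
                   noise = noise, seed = seed + 1),
    label = "folded_dimer", concentration = 5.5, pd_value = 6.4)

  dissociating <- generate_curve(
    synthetic_spec("mixture", list(
      components = list(
        list(model = "sphere", params = list(radius = r_dimer, i0 = 2 * k0 * 5.3)),
        list(model = "sphere", params = list(radius = r_monomer, i0 = k0 * 5.3))),
      weights = c(0.9, 0.1)),
      noise = noise, seed = seed + 2),
    label = "dissociating", concentration = 5.3, pd_value = 9.6)

  open_bundle <- generate_curve(
    synthetic_spec("joint_clubs",
                   list(club_length = 31.5, club_diameter = 10.6,
                        n_clubs = 4, loop_gap = 5, i0 = k0 * 5.3,
                        n_conformations = 5000, mc_seed = seed + 3),
                   noise = noise, seed = seed + 3),
    label = "open_bundle", concentration = 5.3, pd_value = 13)

  list(coil = coil, folded_dimer = folded, dissociating = dissociating,
       open_bundle = open_bundle)
}
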