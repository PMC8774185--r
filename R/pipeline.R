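#' Describe one measurement condition for the pipeline
#'
#' @param curve a [scattering_curve()] or a path readable by [read_curve()].
#' @param label condition label (e.g. `"pD 6.4"`).
#' @param concentration protein concentration, mg/mL.
#' @param standard `TRUE` for the (single) standard condition the
#'   molecular-weight ratios are taken against.
#' @param model shape model to fit: `"debye"`, `"joint_clubs"`, `"none"`.
#' @param dmax maximum dimension for the P(r) inversion, Angstrom.
#' @param guinier_q2 Guinier window in Q^2 (Angstrom^-2).
#' @param pr_q P(r) window in Q (Angstrom^-1).
#' @param jc_init starting [joint_clubs_params()] for a joint-clubs fit.
#' @return A `condition_config`.
#' @export
condition_config <- function(curve, label, concentration,
                             standard = FALSE,
                             model = c("debye", "joint_clubs", "none"),
                             dmax = 60,
                             guinier_q2 = c(0.001, 0.002),
                             pr_q = c(0.05, 0.25),
                             jc_init = joint_clubs_params(30, 10)) {
  model <- match.arg(model)
  structure(list(curve = curve, label = label,
                 concentration = concentration, standard = standard,
                 model = model, dmax = dmax, guinier_q2 = guinier_q2,
                 pr_q = pr_q, jc_init = jc_init),
            class = "condition_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds a `conditions` list (fields as in [condition_config()];
#' `curve` is a path relative to the YAML file) and optional `thresholds`
#' (`dimer_min`, `monomer_max`) and `seed` entries.
#'
#' @param path YAML file path.
#' @return list with `conditions` (list of `condition_config`),
#'   `thresholds`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  conds <- lapply(cfg$conditions, function(cc) {
    curve_path <- cc$curve
    if (!file.exists(curve_path)) curve_path <- file.path(base, cc$curve)
    jc <- if (is.null(cc$jc_init)) joint_clubs_params(30, 10) else
      joint_clubs_params(cc$jc_init$club_length, cc$jc_init$club_diameter,
                         n_clubs = if (is.null(cc$jc_init$n_clubs)) 4 else cc$jc_init$n_clubs,
                         loop_gap = if (is.null(cc$jc_init$loop_gap)) 5 else cc$jc_init$loop_gap)
    condition_config(
      curve = curve_path, label = cc$label,
      concentration = cc$concentration,
      standard = isTRUE(cc$standard),
      model = if (is.null(cc$model)) "debye" else cc$model,
      dmax = if (is.null(cc$dmax)) 60 else cc$dmax,
      guinier_q2 = if (is.null(cc$guinier_q2)) c(0.001, 0.002) else as.numeric(cc$guinier_q2),
      pr_q = if (is.null(cc$pr_q)) c(0.05, 0.25) else as.numeric(cc$pr_q),
      jc_init = jc)
  })
  list(conditions = conds,
       thresholds = if (is.null(cfg$thresholds)) list() else cfg$thresholds,
       seed = if (is.null(cfg$seed)) 1 else cfg$seed)
}

run_stage <- function(stages, name, expr) {
  res <- tryCatch(
    withCallingHandlers(expr,
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) {
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
  stages[[name]] <- res
  stages
}

stage_ok <- function(x) !inherits(x, "stage_error") && !is.null(x)

#' Run the full per-condition analysis and assign solution states
#'
#' For every condition: Guinier fit, Kratky transform, P(r) inversion, a
#' Debye random-coil fit, optionally a joint-clubs fit, and the
#' molecular-weight ratio against the standard condition. Each condition is
#' then assigned a state from the combined evidence:
#' \itemize{
#'   \item MW ratio >= `dimer_min` and Kratky folded: `folded_dimer`
#'   \item MW ratio <= `monomer_max` and Kratky random coil: `random_coil`
#'   \item MW ratio <= `monomer_max`, Kratky partially flexible, and the
#'     joint-clubs fit beating the Debye fit in reduced chi^2:
#'     `open_bundle_monomer`
#'   \item otherwise `folded_mixed`
#' }
#' Stage failures are recorded per condition and the pipeline continues.
#' Re-running with the same configuration and seed reproduces the report
#' byte for byte.
#'
#' @param config list of [condition_config()]s, or a YAML path for
#'   [read_pipeline_config()].
#' @param dimer_min,monomer_max MW-ratio bands for dimer/monomer calls.
#' @param seed seed for the joint-clubs ensembles.
#' @param n_conformations ensemble size for joint-clubs fits.
#' @param verbose emit per-stage log messages.
#' @return `state_report`: list with `conditions` (per-condition results,
#'   state and evidence), `thresholds`, `seed`.
#' @export
run_pipeline <- function(config, dimer_min = 1.7, monomer_max = 1.3,
                         seed = 1, n_conformations = 1000, verbose = FALSE) {
  if (is.character(config)) {
    cfg <- read_pipeline_config(config)
    config <- cfg$conditions
    if (!is.null(cfg$thresholds$dimer_min)) dimer_min <- cfg$thresholds$dimer_min
    if (!is.null(cfg$thresholds$monomer_max)) monomer_max <- cfg$thresholds$monomer_max
    seed <- cfg$seed
  }
  stopifnot(length(config) >= 1)
  std_idx <- which(vapply(config, function(cc) isTRUE(cc$standard), logical(1)))
  if (length(std_idx) != 1) {
    stop("exactly one condition must be marked as the standard")
  }
  say <- function(...) if (verbose) message(sprintf(...))

  per <- lapply(config, function(cc) {
    curve <- if (inherits(cc$curve, "scattering_curve")) cc$curve else
      read_curve(cc$curve)
    say("[%s] %d points", cc$label, length(curve$q))
    st <- list()
    st <- run_stage(st, "guinier",
                    guinier_fit(curve, cc$guinier_q2[1], cc$guinier_q2[2]))
    st <- run_stage(st, "kratky", kratky_transform(curve))
    st <- run_stage(st, "pr",
                    ift(curve, dmax = cc$dmax, q_range = cc$pr_q))
    st <- run_stage(st, "debye", debye_fit(curve))
    if (cc$model == "joint_clubs") {
      say("[%s] joint-clubs fit: seed %d, %d conformations", cc$label,
          seed, n_conformations)
      st <- run_stage(st, "joint_clubs",
                      joint_clubs_fit(curve, cc$jc_init,
                                      n_conformations = n_conformations,
                                      seed = seed))
    }
    list(config = cc, curve = curve, stages = st)
  })

  std <- per[[std_idx]]
  std_ok <- stage_ok(std$stages$guinier)
  results <- lapply(per, function(p) {
    cc <- p$config; st <- p$stages
    mw <- NULL
    if (std_ok && stage_ok(st$guinier)) {
      mw <- mw_ratio(st$guinier$i0, cc$concentration,
                     std$stages$guinier$i0, std$config$concentration)
    }
    evidence <- character(0)
    kr_class <- if (stage_ok(st$kratky)) st$kratky$classification else NA_character_
    ratio <- if (!is.null(mw)) mw$ratio else NA_real_
    if (!is.na(ratio)) {
      band <- if (ratio >= dimer_min) "dimer band" else
        if (ratio <= monomer_max) "monomer band" else "intermediate band"
      evidence <- c(evidence, sprintf("MW ratio %.2f (%s)", ratio, band))
    }
    if (!is.na(kr_class)) {
      evidence <- c(evidence, sprintf("Kratky classification: %s", kr_class))
    }
    jc_better <- stage_ok(st$joint_clubs) && stage_ok(st$debye) &&
      st$joint_clubs$chi2_reduced < st$debye$chi2_reduced
    if (stage_ok(st$joint_clubs) && stage_ok(st$debye)) {
      evidence <- c(evidence,
                    sprintf("joint-clubs chi2_red %.3g vs Debye %.3g",
                            st$joint_clubs$chi2_reduced, st$debye$chi2_reduced))
    }
    state <- if (!is.na(ratio) && ratio >= dimer_min &&
                 identical(kr_class, "folded")) "folded_dimer"
      else if (!is.na(ratio) && ratio <= monomer_max &&
               identical(kr_class, "random_coil")) "random_coil"
      else if (!is.na(ratio) && ratio <= monomer_max &&
               identical(kr_class, "partially_flexible") && jc_better)
        "open_bundle_monomer"
      else "folded_mixed"
    list(label = cc$label, stages = st, mw = mw, state = state,
         evidence = evidence)
  })

  structure(list(conditions = results,
                 thresholds = list(dimer_min = dimer_min,
                                   monomer_max = monomer_max),
                 seed = seed),
            class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat("State report\n")
  for (r in x$conditions) {
    cat(sprintf("  %-14s -> %s\n", r$label, r$state))
    for (e in r$evidence) cat(sprintf("      - %s\n", e))
  }
  invisible(x)
}

report_numbers <- function(report) {
  lapply(report$conditions, function(r) {
    st <- r$stages
    num <- function(stage, field) {
      if (stage_ok(st[[stage]])) st[[stage]][[field]] else NULL
    }
    out <- list(
      label = r$label, state = r$state, evidence = r$evidence,
      guinier = if (stage_ok(st$guinier))
        list(rg = st$guinier$rg, rg_err = st$guinier$rg_err,
             i0 = st$guinier$i0, i0_err = st$guinier$i0_err) else
        list(error = st$guinier$message),
      kratky = if (stage_ok(st$kratky))
        list(classification = st$kratky$classification,
             bell_peak_q = st$kratky$features$bell_peak_q,
             plateau_level = st$kratky$features$plateau_level) else
        list(error = st$kratky$message),
      pr = if (stage_ok(st$pr))
        list(rg = st$pr$rg, rg_err = st$pr$rg_err, i0 = st$pr$i0,
             dmax = st$pr$dmax, chi2_reduced = st$pr$chi2_reduced) else
        list(error = st$pr$message),
      debye = if (stage_ok(st$debye))
        list(rg = st$debye$rg, rg_err = st$debye$rg_err, i0 = st$debye$i0,
             chi2_reduced = st$debye$chi2_reduced) else
        list(error = st$debye$message)
    )
    if (!is.null(st$joint_clubs)) {
      out$joint_clubs <- if (stage_ok(st$joint_clubs))
        list(club_length = st$joint_clubs$params$club_length,
             club_diameter = st$joint_clubs$params$club_diameter,
             club_length_err = unname(st$joint_clubs$param_errors[["club_length"]]),
             club_diameter_err = unname(st$joint_clubs$param_errors[["club_diameter"]]),
             chi2_reduced = st$joint_clubs$chi2_reduced,
             seed = st$joint_clubs$seed,
             n_conformations = st$joint_clubs$n_conformations) else
        list(error = st$joint_clubs$message)
    }
    if (!is.null(r$mw)) {
      out$mw_ratio <- list(ratio = r$mw$ratio,
                           ratio_rounded = r$mw$ratio_rounded)
    }
    out
  })
}

#' Write a state report to disk
#'
#' Writes `report.json` (machine-readable; every number is copied from a
#' stage result, nothing is recomputed) and `report.txt` (human-readable)
#' into `dir`. Given identical inputs and seeds the JSON is byte-identical
#' across runs.
#'
#' @param report a `state_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  payload <- list(conditions = report_numbers(report),
                  thresholds = report$thresholds, seed = report$seed)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(json_path)
}
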