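test_that("two equal scatterers give the closed-form interference curve", {
  d <- 12
  xyz <- rbind(c(0, 0, 0), c(0, 0, d))
  mod <- raw_atomic_model(xyz)
  # equal residues => equal effective f; normalized curve is (1 + sinc(qd))/2
  q <- seq(0.01, 0.4, length.out = 60)
  theo <- debye_sum_curve(mod, q_grid = q)
  i0 <- debye_sum_curve(mod, q_grid = c(1e-6, 1e-5))$intensity[1]
  expect_equal(theo$intensity / i0, (1 + sin(q * d) / (q * d)) / 2,
               tolerance = 1e-9)
})

test_that("histogram acceleration matches the direct double sum", {
  set.seed(3)
  mod <- raw_atomic_model(matrix(runif(150, 0, 40), ncol = 3))
  q <- seq(0.01, 0.4, length.out = 50)
  direct <- debye_sum_curve(mod, q_grid = q, method = "direct")
  hist <- debye_sum_curve(mod, q_grid = q, method = "histogram")
  expect_lt(max(abs(hist$intensity / direct$intensity - 1)), 1e-3)
})

test_that("the Debye sum is invariant under rigid motion", {
  mod <- read_atomic_model(write_helix_pdb(15), "asis")
  q <- seq(0.01, 0.4, length.out = 40)
  base <- debye_sum_curve(mod, q_grid = q)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- mod
  xyz <- as.matrix(mod$atoms[, c("x", "y", "z")]) %*% rot
  moved$atoms$x <- xyz[, 1] + 5
  moved$atoms$y <- xyz[, 2] - 3
  moved$atoms$z <- xyz[, 3] + 100
  shifted <- debye_sum_curve(moved, q_grid = q)
  expect_lt(max(abs(shifted$intensity / base$intensity - 1)), 1e-9)
})

test_that("a dimer of identical monomers scatters 4x at zero angle", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(make_helix_pdb_lines(20, chain = "A"),
               make_helix_pdb_lines(20, chain = "B", z0 = 60, serial0 = 80),
               "END"), tf)
  dimer <- read_atomic_model(tf, "dimer")
  mono <- read_atomic_model(tf, "monomer")
  q0 <- c(1e-6, 1e-5)
  ratio <- debye_sum_curve(dimer, q_grid = q0)$intensity[1] /
    debye_sum_curve(mono, q_grid = q0)$intensity[1]
  expect_equal(ratio, 4, tolerance = 1e-6)
})

test_that("coordinate Rg: unit cube closed form and weighting identity", {
  cube <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  mod <- raw_atomic_model(cube)
  expect_equal(coordinate_rg(mod, "uniform"), sqrt(3) / 2, tolerance = 1e-12)
  # equal residues => equal contrast weights => identical Rg
  expect_equal(coordinate_rg(mod, "contrast"), coordinate_rg(mod, "uniform"),
               tolerance = 1e-12)
})

test_that("coordinate Rg agrees with the Guinier Rg of the computed curve", {
  mod <- read_atomic_model(write_helix_pdb(25), "asis")
  rg_c <- coordinate_rg(mod, "contrast")
  qmax <- 0.9 / rg_c
  q <- seq(qmax / 10, qmax, length.out = 50)
  g <- suppressWarnings(guinier_fit(as_scattering_curve(debye_sum_curve(mod, q_grid = q)),
                                    q2_min = 0, q2_max = qmax^2))
  expect_lt(abs(g$rg - rg_c), 1)
})

test_that("helix axis length and diameter recover the generating geometry", {
  n_res <- 20; rise <- 1.5; radius <- 2.3
  mod <- read_atomic_model(write_helix_pdb(n_res, radius = radius,
                                           rise = rise), "asis")
  hd <- helix_definition("H1", 1, n_res)
  expect_equal(helix_axis_length(mod, hd), (n_res - 1) * rise,
               tolerance = 0.5 / 28.5)
  m <- average_helix_metrics(mod, list(hd))
  expect_equal(m$mean_length, helix_axis_length(mod, hd))
  expect_equal(m$mean_diameter, 2 * radius, tolerance = 0.15)
})

test_that("degenerate helix ranges are rejected", {
  mod <- read_atomic_model(write_helix_pdb(20), "asis")
  expect_error(helix_axis_length(mod, helix_definition("X", 1, 3)),
               "at least 4")
  expect_error(helix_axis_length(mod, helix_definition("Y", 15, 30)),
               "missing CA")
})

test_that("contrast model controls the solvent term", {
  expect_error(contrast_model(solvent_d2o = 2), "solvent_d2o")
  cm_d <- contrast_model(1, 0.9)
  cm_h <- contrast_model(0, 0)
  expect_gt(cm_d$solvent_sld, 0.6)   # D2O, fm/A^3
  expect_lt(cm_h$solvent_sld, 0)     # H2O is slightly negative
  # more exchange in D2O raises the particle scattering length
  mod <- read_atomic_model(write_helix_pdb(10), "asis")
  f_hi <- sum(bundlesans:::atom_contrast_f(mod, contrast_model(1, 1)))
  f_lo <- sum(bundlesans:::atom_contrast_f(mod, contrast_model(1, 0)))
  expect_gt(f_hi, f_lo)
})
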