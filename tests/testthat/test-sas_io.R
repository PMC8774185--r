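test_that("curve write/read round trip preserves data and metadata", {
  q <- seq(0.01, 0.4, length.out = 100)
  set.seed(1)
  cur <- scattering_curve(q, exp(-q^2 * 100) + rnorm(100, 0, 1e-4),
                          sigma = abs(rnorm(100, 0.01, 0.001)),
                          label = "pD 6.4 sample", concentration = 5.5,
                          pd_value = 6.4)
  tf <- tempfile(fileext = ".dat")
  write_curve(cur, tf)
  back <- read_curve(tf)
  expect_equal(back$q, cur$q, tolerance = 1e-9)
  expect_equal(back$intensity, cur$intensity, tolerance = 1e-9)
  expect_equal(back$sigma, cur$sigma, tolerance = 1e-9)
  expect_identical(back$label, "pD 6.4 sample")
  expect_equal(back$concentration, 5.5)
  expect_equal(back$pd_value, 6.4)
})

test_that("2-column input yields sigma-absent curves; headers are skipped", {
  tf <- tempfile(fileext = ".dat")
  writeLines(c("# Q I err", "some stray header", sprintf("%g %g", 1:10 / 100,
                                                         10:1)), tf)
  cur <- read_curve(tf)
  expect_null(cur$sigma)
  expect_length(cur$q, 10)
  # sigma absent => unit weights downstream
  expect_equal(bundlesans:::curve_weights(cur), rep(1, 10))
})

test_that("comma-separated and mixed dialects parse identically", {
  q <- 1:20 / 50
  i <- exp(-q)
  s <- rep(0.01, 20)
  tf1 <- tempfile(); tf2 <- tempfile()
  writeLines(sprintf("%.8g %.8g %.8g", q, i, s), tf1)
  writeLines(c("Q,I,err", sprintf("%.8g,%.8g,%.8g", q, i, s)), tf2)
  c1 <- read_curve(tf1)
  c2 <- read_curve(tf2)
  expect_equal(c1$q, c2$q)
  expect_equal(c1$intensity, c2$intensity)
  expect_equal(c1$sigma, c2$sigma)
})

test_that("malformed curves are rejected with informative errors", {
  tf <- tempfile()
  writeLines(sprintf("%g %g", c(0.01, 0.02, 0.02, 0.03, 0.04, 0.05), 6:1), tf)
  expect_error(read_curve(tf), "strictly increasing.*row")
  writeLines(sprintf("%g %g", c(0.01, 0.02, 0.03), 3:1), tf)
  expect_error(read_curve(tf), "at least 5")
  expect_error(read_curve(tempfile()), "not found")
  expect_error(scattering_curve(c(-0.01, 0.02), c(1, 1)), "positive")
})

test_that("a q scale that looks like nm^-1 triggers a warning", {
  expect_warning(scattering_curve(seq(0.1, 6, length.out = 30),
                                  rep(1, 30)), "nm")
})

test_that("negative intensities survive I/O and the container", {
  q <- seq(0.01, 0.3, length.out = 30)
  i <- c(rep(1, 25), -1e-4, 2e-4, -3e-4, 1e-4, -2e-5)
  tf <- tempfile()
  write_curve(scattering_curve(q, i), tf)
  expect_equal(read_curve(tf)$intensity, i, tolerance = 1e-9)
})

test_that("PDB parsing: atoms, waters, heme, assemblies", {
  lines <- c(
    make_helix_pdb_lines(6, chain = "A"),
    make_helix_pdb_lines(6, chain = "B", z0 = 30, serial0 = 24),
    pdb_line(49, "FE", "HEM", "A", 200, 0, 0, -5, "FE", het = TRUE),
    pdb_line(50, "O", "HOH", "A", 300, 9, 9, 9, "O", het = TRUE),
    pdb_line(51, "O", "DOD", "B", 301, 9, 9, 40, "O", het = TRUE),
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)

  asis <- read_atomic_model(tf, "asis")
  # asis count equals ATOM+HETATM non-water records
  expect_equal(nrow(asis$atoms), 48 + 1)
  expect_false(any(asis$atoms$residue %in% c("HOH", "DOD")))
  expect_true("HEM" %in% asis$atoms$residue)

  mono <- read_atomic_model(tf, "monomer")
  expect_setequal(unique(mono$atoms$chain), "A")
  expect_true("HEM" %in% mono$atoms$residue)  # heme rides with its chain
  expect_equal(nrow(mono$atoms), 25)

  dimer <- read_atomic_model(tf, "dimer")
  expect_equal(nrow(dimer$atoms), 49)

  # determinism
  again <- read_atomic_model(tf, "asis")
  expect_identical(asis$atoms, again$atoms)
})

test_that("3-atom synthetic PDB parses coordinates exactly", {
  lines <- c(pdb_line(1, "C", "ALA", "A", 1, 1.25, -2.5, 3.75, "C"),
             pdb_line(2, "N", "ALA", "A", 1, 0, 0, 0, "N"),
             pdb_line(3, "O", "ALA", "A", 1, -1, 1, -1, "O"), "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  mod <- read_atomic_model(tf, "asis")
  expect_equal(nrow(mod$atoms), 3)
  expect_equal(mod$atoms$x[1], 1.25)
  expect_equal(mod$atoms$z[1], 3.75)
  expect_setequal(mod$atoms$element, c("C", "N", "O"))
})
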