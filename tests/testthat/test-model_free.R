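test_that("Guinier fit inverts the Guinier law exactly", {
  for (rg in c(12, 20, 28)) {
    for (i0 in c(0.08, 7)) {
      qmax <- 1 / rg
      q <- seq(0.2 / rg, qmax, length.out = 40)
      cur <- scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3))
      g <- suppressWarnings(guinier_fit(cur, q2_min = 0, q2_max = qmax^2))
      expect_equal(g$rg, rg, tolerance = 1e-6)
      expect_equal(g$i0, i0, tolerance = 1e-6)
    }
  }
})

test_that("Guinier Rg of a hard sphere is sqrt(3/5) of its radius", {
  R <- 25.82
  rg_true <- sqrt(3 / 5) * R     # closed-form second moment of a ball
  qmax <- 0.9 / rg_true          # window respecting Q*Rg <= 1.0
  q <- seq(0.002, qmax, length.out = 60)
  cur <- scattering_curve(q, 5 * sphere_form_factor(q, R))
  g <- suppressWarnings(guinier_fit(cur, q2_min = 0, q2_max = qmax^2))
  expect_equal(g$rg / R, sqrt(3 / 5), tolerance = 0.01)
  expect_equal(g$rg, 20.0, tolerance = 0.01 * 20)
})

test_that("Guinier errors on non-decaying data and tiny windows", {
  q <- seq(0.01, 0.05, length.out = 20)
  expect_error(guinier_fit(scattering_curve(q, exp(+q^2 * 100)),
                           0, 0.0025), "no Guinier decay")
  expect_error(guinier_fit(scattering_curve(q, exp(-q^2 * 100)),
                           0.0024, 0.0025), "fewer than 3")
})

test_that("Q*Rg guideline produces a warning, not an error", {
  rg <- 25
  q <- seq(0.01, 0.1, length.out = 50)
  cur <- scattering_curve(q, exp(-q^2 * rg^2 / 3))
  expect_warning(g <- guinier_fit(cur, 0, 0.01, enforce_qrg = TRUE),
                 "1.3 guideline")
  expect_true(g$qrg_warning)
  expect_equal(g$rg, rg, tolerance = 1e-6)
})

test_that("Debye fit is self-inverse and scale-equivariant", {
  q <- seq(0.01, 0.3, length.out = 80)
  cur <- scattering_curve(q, debye_function(q, 25))
  d <- debye_fit(cur)
  expect_equal(d$rg, 25, tolerance = 1e-6)
  expect_equal(d$i0, 1, tolerance = 1e-6)

  k <- 137.5
  cur_k <- scattering_curve(q, k * cur$intensity)
  dk <- debye_fit(cur_k)
  expect_equal(dk$rg, d$rg, tolerance = 1e-9)
  expect_equal(dk$i0, k * d$i0, tolerance = 1e-9)
})

test_that("Debye fit recovers the Rg of a discrete Gaussian chain", {
  # oracle: brute-force pairwise sinc sum over bead coordinates, ensemble-
  # averaged over chain realizations (a single realization's scattering is
  # not the Debye function; the ensemble's is)
  set.seed(17)
  n_chains <- 50; n <- 300; b <- 4
  rg_nominal <- sqrt(n * b^2 / 6)
  q <- seq(0.05 / rg_nominal, 1.5 / rg_nominal, length.out = 40)
  acc <- numeric(length(q))
  rg2 <- numeric(n_chains)
  for (m in seq_len(n_chains)) {
    steps <- matrix(rnorm(3 * n, 0, b / sqrt(3)), ncol = 3)
    xyz <- apply(steps, 2, cumsum)
    rg2[m] <- mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
    dmat <- as.matrix(dist(xyz))
    acc <- acc + vapply(q, function(qv) {
      x <- qv * dmat
      s <- sin(x) / x
      s[!is.finite(s)] <- 1
      mean(s)
    }, numeric(1))
  }
  fit <- debye_fit(scattering_curve(q, acc / n_chains))
  expect_equal(fit$rg, sqrt(mean(rg2)), tolerance = 0.02)
})

test_that("Kratky transform classifies coil, globule, and mixtures", {
  q <- seq(0.01, 0.45, length.out = 120)
  coil <- kratky_transform(scattering_curve(q, 0.08 * debye_function(q, 25)))
  expect_identical(coil$classification, "random_coil")
  expect_true(is.na(coil$features$bell_peak_q))

  R <- 18 / sqrt(3 / 5)
  glob <- kratky_transform(
    scattering_curve(q, 0.16 * sphere_form_factor(q, R) + 5e-5))
  expect_identical(glob$classification, "folded")
  expect_lt(glob$features$bell_peak_q, 0.15)
})

test_that("Kratky plateau of a Gaussian coil reaches 2 i0 / rg^2", {
  rg <- 25; i0 <- 3
  q_at <- 10 / rg    # Q * Rg = 10
  y <- q_at^2 * i0 * debye_function(q_at, rg)
  expect_equal(y, 2 * i0 / rg^2, tolerance = 0.01)
})

test_that("mw_ratio reproduces printed-table arithmetic and identities", {
  expect_equal(mw_ratio(0.165, 5.5, 0.078, 5.5)$ratio_rounded, 2.1)
  expect_equal(mw_ratio(0.141, 5.3, 0.078, 5.5)$ratio_rounded, 1.9)
  expect_equal(mw_ratio(0.088, 5.3, 0.078, 5.5)$ratio_rounded, 1.2)
  for (a in c(0.01, 0.08, 3)) {
    for (b in c(0.5, 5.5)) {
      expect_identical(mw_ratio(a, b, a, b)$ratio, 1)
    }
  }
  expect_error(mw_ratio(0, 1, 1, 1), "positive")
  expect_error(mw_ratio(1, 1, -2, 1), "positive")
})

test_that("half-up rounding matches table conventions", {
  expect_equal(bundlesans:::round_half_up(1.85, 1), 1.9)
  expect_equal(bundlesans:::round_half_up(2.1154, 1), 2.1)
})

test_that("aggregate fraction recovers a known trace-aggregate admixture", {
  rg_m <- 25; i0_m <- 0.08; f_num <- 0.002; rg_a <- 100
  i0_a <- i0_m * f_num / (1 - f_num) * (rg_a / rg_m)^6
  q <- seq(0.008, 0.25, length.out = 150)
  ideal <- i0_m * exp(-q^2 * rg_m^2 / 3) + i0_a * exp(-q^2 * rg_a^2 / 3)
  cur <- noisy_curve(q, ideal, 0.01, seed = 5)
  # monomer reference from a window where the aggregate term has died off
  gm <- suppressWarnings(guinier_fit(cur, q2_min = 0.002, q2_max = 0.004))
  est <- aggregate_fraction(cur, gm, aggregate_rg = rg_a)
  expect_gt(est$fraction, f_num / 2)
  expect_lt(est$fraction, f_num * 2)

  pure <- scattering_curve(q, i0_m * exp(-q^2 * rg_m^2 / 3))
  gp <- suppressWarnings(guinier_fit(pure, 0.001, 0.002))
  est0 <- aggregate_fraction(pure, gp, aggregate_rg = rg_a)
  expect_identical(est0$fraction, 0)
  expect_match(est0$note, "no low-Q excess")
})
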