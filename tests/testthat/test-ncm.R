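test_that("predicted_frequency obeys limits, symmetry and monotonicity", {
  # d -> 0+: everything is detectable
  expect_equal(predicted_frequency(0.3, Nm = 50, d = 1e-12), 1, tolerance = 1e-6)
  # Beta(a, a) is symmetric about 1/2
  expect_equal(predicted_frequency(0.5, Nm = 80, d = 0.5), 0.5, tolerance = 1e-12)
  # monotone in p, checked against direct numerical integration of the density
  Nm <- 100; d <- 1e-4
  f1 <- predicted_frequency(1e-3, Nm, d)
  f2 <- predicted_frequency(1e-2, Nm, d)
  expect_lt(f1, f2)
  int <- integrate(function(x) dbeta(x, Nm * 1e-3, Nm * (1 - 1e-3)),
                   lower = d, upper = 1, rel.tol = 1e-10)
  expect_equal(f1, int$value, tolerance = 1e-6)
  grid_p <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 0.9)
  expect_true(all(diff(predicted_frequency(grid_p, 200, 1e-4)) >= 0))
  # monotone in Nm for p > d
  expect_true(all(diff(sapply(c(10, 100, 1000),
                              function(nm) predicted_frequency(0.01, nm, 1e-4))) > 0))
  expect_error(predicted_frequency(0, 10, 0.1), "strictly inside")
  expect_error(predicted_frequency(1, 10, 0.1), "strictly inside")
})

test_that("finite-read detection curve matches brute-force beta-binomial", {
  # P(detect) = 1 - E[(1-x)^N] under x ~ Beta(a, b), by quadrature
  Nm <- 150; N <- 5000
  for (p in c(1e-4, 1e-3, 0.01)) {
    a <- Nm * p; b <- Nm * (1 - p)
    ref <- 1 - integrate(function(x) (1 - x)^N * dbeta(x, a, b),
                         0, 1, rel.tol = 1e-10)$value
    expect_equal(predicted_frequency_reads(p, Nm, N), ref, tolerance = 1e-6)
  }
})

test_that("fit is self-consistent when observations sit on the model curve", {
  p <- sort(runif(80, 1e-4, 0.2))
  N <- 5000; Nm_true <- 350
  # default detection model
  freq <- predicted_frequency_reads(p, Nm_true, N)
  fit <- lakeassembly:::fit_Nm(p, freq, d = 1 / N, N = N, detection = "reads")
  expect_equal(fit$Nm, Nm_true, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-12)
  # classic threshold model
  freq_t <- predicted_frequency(p, Nm_true, d = 1 / N)
  fit_t <- lakeassembly:::fit_Nm(p, freq_t, d = 1 / N, N = N,
                                 detection = "threshold")
  expect_equal(fit_t$Nm, Nm_true, tolerance = 1e-4)
})

test_that("R^2 is non-positive when frequency carries no abundance signal", {
  set.seed(8)
  p <- sort(runif(60, 1e-4, 0.2))
  N <- 5000
  for (freq in list(rep(0.5, 60), 0.5 + rnorm(60, 0, 0.01))) {
    fit <- lakeassembly:::fit_Nm(p, freq, d = 1 / N, N = N, detection = "reads")
    sst <- sum((freq - mean(freq))^2)
    r2 <- 1 - fit$sse / sst
    expect_lte(r2, 0)
  }
})

test_that("fit_ncm recovers m from neutral simulations and is scale-consistent", {
  m_true <- 0.05
  mm <- simulate_neutral(n_samples = 150, N = 8000, m = m_true, n_taxa = 200,
                         seed = 31)
  fit <- fit_ncm(mm, n_bootstrap = 100, seed = 32)
  expect_lt(abs(fit$m - m_true) / m_true, 0.2)
  expect_true(fit$ci_m[1] < fit$ci_m[2])
  expect_true(fit$r_squared > 0.5 && fit$r_squared <= 1)

  # bootstrap reproducibility, bit for bit
  fit2 <- fit_ncm(mm, n_bootstrap = 100, seed = 32)
  expect_identical(fit$ci_m, fit2$ci_m)
  expect_identical(fit$ci_r_squared, fit2$ci_r_squared)

  # multiplying all counts by a constant leaves the occupancy-abundance cloud
  # unchanged, so the fitted Nm moves only mildly (through the detection
  # limit) while N multiplies; m-hat = Nm/N consequently scales ~ 1/k
  fit_t <- fit_ncm(mm, n_bootstrap = 2, seed = 1, detection = "threshold")
  scaled <- abundance_matrix(unclass(mm) * 5L)
  fit_s <- fit_ncm(scaled, n_bootstrap = 2, seed = 1, detection = "threshold")
  expect_equal(fit_s$N, 5 * fit_t$N)
  expect_lt(abs(log(fit_s$Nm / fit_t$Nm)), log(2))   # Nm pinned by the cloud
  expect_lt(fit_s$m / fit_t$m, 0.5)                  # m absorbs the 1/k factor
})

test_that("taxon partition brackets the fitted curve correctly", {
  mm <- simulate_neutral(n_samples = 100, N = 5000, m = 0.1, n_taxa = 150,
                         seed = 41)
  fit <- fit_ncm(mm, n_bootstrap = 2, seed = 1)
  part <- partition_taxa(fit, level = 0.95)
  expect_equal(nrow(part), nrow(fit$taxa))
  expect_true(all(part$band_lo <= part$band_hi))
  expect_true(all(part$partition[part$frequency > part$band_hi] == "above"))
  expect_true(all(part$partition[part$frequency < part$band_lo] == "below"))
  within <- part$frequency >= part$band_lo & part$frequency <= part$band_hi
  expect_true(all(part$partition[within] == "neutral"))
  # a taxon exactly on its prediction is neutral (prediction inside the band)
  on_curve <- which.min(abs(part$frequency - part$predicted))
  if (abs(part$frequency[on_curve] - part$predicted[on_curve]) < 1e-9) {
    expect_equal(as.character(part$partition[on_curve]), "neutral")
  }
  # most neutral-simulation taxa should be labelled neutral
  expect_gt(mean(part$partition == "neutral"), 0.5)
})

test_that("fit_ncm rejects degenerate inputs and writes its outputs", {
  mm <- simulate_neutral(n_samples = 40, N = 2000, m = 0.1, n_taxa = 60, seed = 51)
  flat <- abundance_matrix(matrix(5L, 12, 10,
                                  dimnames = list(sprintf("s%d", 1:12),
                                                  sprintf("t%d", 1:10))))
  expect_error(suppressWarnings(fit_ncm(flat)), "distinct")
  prefix <- file.path(withr::local_tempdir(), "ncm")
  fit <- fit_ncm(mm, n_bootstrap = 10, seed = 1)
  paths <- write_ncm(fit, prefix, seed = 1)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$m, fit$m, tolerance = 1e-12)
})
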