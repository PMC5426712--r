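test_that("ensemble_profiles computes one exact Debye profile per conformer", {
  q <- default_q_grid(n = 21)
  s <- make_toy_structure("random-cloud", 8, 10, seed = 4, element = "C")
  e1 <- ensemble_profiles(list(s), q)
  expect_equal(nrow(e1$intensities), 1L)
  expect_equal(e1$intensities[1, ], debye_intensity(s, q)$intensity)

  copies <- ensemble_profiles(rep(list(s), 4), q)
  expect_true(all(apply(copies$intensities, 2, function(col) all(col == col[1]))))
  expect_error(ensemble_profiles(list(), q), "empty")

  # the sampled-ensemble row mean approaches the analytic thermal mean
  sv <- assign_tau(s, "uniform", value = 0.3)
  ens <- mc_sample_ensemble(sv, 400, seed = 8)
  e <- ensemble_profiles(ens, q, ff_model())
  mu_hat <- colMeans(e$intensities)
  se <- apply(e$intensities, 2, sd) / sqrt(400)
  mu <- mean_intensity_uniform(sv, 0.3, q, ff_model())$intensity
  expect_true(all(abs(mu_hat - mu) <= 4 * se + 1e-9))
})

test_that("sample_mean_cov matches closed forms and is positive-semidefinite", {
  q <- c(0.1, 0.2, 0.3)
  a <- c(1, 2, 3); b <- c(2, 1, 5)
  e <- sas_ensemble(q, rbind(a, b))
  mc <- sample_mean_cov(e)
  expect_equal(mc$mean$intensity, (a + b) / 2)
  expect_equal(diag(mc$cov$cov), (a - b)^2 / 2)

  same <- sas_ensemble(q, rbind(a, a, a))
  expect_equal(sample_mean_cov(same)$cov$cov, matrix(0, 3, 3))
  expect_error(sample_mean_cov(sas_ensemble(q, rbind(a))), "at least 2")

  set.seed(5)
  big <- sas_ensemble(seq(0.01, 0.2, 0.01),
                      matrix(rexp(50 * 20), 50, 20))
  V <- sample_mean_cov(big)$cov$cov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))

  # weighted estimator agrees with the unweighted one for uniform weights
  wt <- sas_ensemble(big$q, big$intensities,
                     weights = rep(2, 50))     # non-unit but uniform
  expect_equal(sample_mean_cov(wt)$cov$cov, V, tolerance = 1e-12)
})

test_that("relative SD reports the SD as a fraction of the mean", {
  q <- c(0.1, 0.2)
  mean_p <- sas_profile(q, c(4, 8))
  zero <- sas_cov(q, matrix(0, 2, 2))
  expect_equal(relative_sd(mean_p, zero)$intensity, c(0, 0))
  unit <- sas_cov(q, diag(c(16, 64)))
  expect_equal(relative_sd(mean_p, unit)$intensity, c(1, 1))

  set.seed(3)
  e <- sas_ensemble(q, matrix(rexp(40, rate = 0.2), 20, 2))
  mc <- sample_mean_cov(e)
  rel <- relative_sd(mc$mean, mc$cov)
  expect_equal(rel$intensity,
               apply(e$intensities, 2, sd) / colMeans(e$intensities))
  expect_equal(attr(rel, "argmax_q"), q[which.max(rel$intensity)])
})

test_that("confidence bands collapse correctly and cover a Gaussian ensemble", {
  q <- seq(0.05, 0.5, 0.05)
  mu <- 100 * exp(-10 * q^2)
  sdv <- 0.05 * mu
  V <- diag(sdv^2)
  mean_p <- sas_profile(q, mu)
  cv <- sas_cov(q, V)
  b0 <- confidence_band(mean_p, cv, level_sd = 0)
  expect_equal(b0$lower, mu)
  expect_equal(b0$upper, mu)
  bz <- confidence_band(mean_p, sas_cov(q, matrix(0, 10, 10)), level_sd = 1)
  expect_equal(bz$lower, mu)

  # 1-sigma band contains ~68% of Gaussian conformer intensities per q
  set.seed(11)
  M <- 10000
  I <- sweep(matrix(rnorm(M * 10), M, 10), 2, sdv, "*")
  I <- sweep(I, 2, mu, "+")
  b1 <- confidence_band(mean_p, cv, level_sd = 1)
  cover <- colMeans(sweep(I, 2, b1$lower, ">=") & sweep(I, 2, b1$upper, "<="))
  expect_true(all(abs(cover - 0.6827) < 0.03))
})

test_that("comparison to experiment flags q where ensemble SD beats noise", {
  q <- seq(0.05, 0.5, 0.05)
  mu <- 100 * exp(-10 * q^2)
  mean_p <- sas_profile(q, mu)
  zero_band <- confidence_band(mean_p, sas_cov(q, matrix(0, 10, 10)))
  expt <- sas_profile(q, mu, error = rep(0.5, 10))
  expect_false(any(compare_to_experiment(zero_band, expt)$flagged))

  sdv <- 0.04 * mu
  band <- confidence_band(mean_p, sas_cov(q, diag(sdv^2)))
  expt0 <- sas_profile(q, mu, error = rep(0, 10))
  expect_true(all(compare_to_experiment(band, expt0)$flagged))
  expect_error(compare_to_experiment(band, sas_profile(q, mu)), "no error")

  # floppy ensemble vs 1%-noise experiment: mid/high q flagged, low q not
  s <- make_toy_structure("globule", 80, 12, seed = 6, element = "X")
  sv <- assign_tau(s, "uniform", value = 3)
  qf <- default_q_grid(n = 51)
  mu2 <- mean_intensity(sv, qf, ff_point())
  cv2 <- covariance_matrix(sv, qf, ff_point())
  band2 <- confidence_band(mu2, cv2)
  expt2 <- sas_profile(qf, mu2$intensity, error = 0.01 * mu2$intensity)
  cmp <- compare_to_experiment(band2, expt2)
  expect_false(cmp$flagged[1])                       # I(0) has no ensemble SD
  expect_true(any(cmp$flagged[cmp$q >= 0.1]))
  # flags stable under refining the model grid (interpolation invariance)
  qf2 <- default_q_grid(n = 101)
  band2b <- confidence_band(mean_intensity(sv, qf2, ff_point()),
                            covariance_matrix(sv, qf2, ff_point()))
  cmp2 <- compare_to_experiment(band2b, expt2)
  expect_lte(mean(cmp2$flagged != cmp$flagged), 0.005)
})

test_that("ensemble binary container round-trips bit-exactly", {
  set.seed(2)
  e <- sas_ensemble(seq(0.01, 0.1, 0.01), matrix(runif(50), 5, 10),
                    weights = runif(5) + 0.5)
  path <- tempfile(fileext = ".bin")
  write_ensemble_bin(e, path)
  back <- read_ensemble_bin(path)
  expect_identical(back$intensities, e$intensities)
  expect_identical(back$q, e$q)
  expect_identical(back$weights, e$weights)
  expect_identical(back$labels, e$labels)
})
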