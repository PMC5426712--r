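# samples n distances between two atoms displaced with SDs tau_k, tau_l
sample_distances <- function(n, d0, tau_k, tau_l, seed) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n, sd = sqrt(tau_k^2 + tau_l^2)), ncol = 3)
  v[, 1] <- v[, 1] + d0
  sqrt(rowSums(v^2))
}

test_that("thermal distance density is a proper density matching simulation", {
  for (case in list(c(5, 0.4, 0.3), c(12, 1.5, 0), c(3, 0.2, 0.2))) {
    d0 <- case[1]; tk <- case[2]; tl <- case[3]
    total <- integrate(noncentral_chi_pdf, 0, Inf, d0 = d0,
                       tau_k = tk, tau_l = tl, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_equal(noncentral_chi_pdf(0, 5, 0.3, 0.4), 0)
  expect_error(noncentral_chi_pdf(1, 5, 0, 0), "both be zero")

  # Kolmogorov-Smirnov against sampled inter-atom distances
  d0 <- 8; tk <- 0.7; tl <- 0.4
  d <- sample_distances(1e5, d0, tk, tl, seed = 42)
  cdf <- function(x) vapply(x, function(u)
    integrate(noncentral_chi_pdf, 0, u, d0 = d0, tau_k = tk, tau_l = tl,
              rel.tol = 1e-9)$value, numeric(1))
  ks <- suppressWarnings(ks.test(d, cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("thermal sinc expectation is exact (Monte-Carlo cross-check)", {
  expect_equal(sinc_expectation(0, 10, 0.5, 0.5), 1)
  q <- seq(0, 0.5, 0.1)
  expect_equal(sinc_expectation(q, 10, 0, 0), sinc(q * 10))

  set.seed(7)
  for (i in 1:3) {
    qv <- runif(1, 0.05, 0.5); d0 <- runif(1, 3, 30)
    tk <- runif(1, 0.1, 1.5); tl <- runif(1, 0.1, 1.5)
    d <- sample_distances(2e5, d0, tk, tl, seed = 100 + i)
    x <- sinc(qv * d)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(sinc_expectation(qv, d0, tk, tl) - mean(x)), 3 * se + 1e-12)
  }
})

test_that("per-atom thermal mean reduces correctly and matches sampling", {
  s <- make_toy_structure("random-cloud", 5, 10, seed = 7, element = "X")
  q <- default_q_grid(n = 26)
  ffp <- ff_point()

  s0 <- assign_tau(s, "uniform", value = 0)
  expect_equal(mean_intensity(s0, q, ffp)$intensity,
               debye_intensity(s0, q, ffp)$intensity, tolerance = 1e-14)

  su <- assign_tau(s, "uniform", value = 0.5)
  expect_equal(mean_intensity(su, q, ffp)$intensity,
               mean_intensity_uniform(su, 0.5, q, ffp)$intensity,
               tolerance = 1e-12)

  # non-uniform taus against the Monte-Carlo ensemble mean
  sv <- s; sv$tau <- c(0.2, 0.5, 0.3, 0.8, 0.4)
  mc <- mc_mean_cov(sv, q, ffp, n_samples = 20000, seed = 3)
  mu <- mean_intensity(sv, q, ffp)$intensity
  dev <- abs(mu - mc$mean$intensity)
  expect_true(all(dev <= 3 * mc$se_mean + 1e-9))
})

test_that("uniform-tau mean is a convex combination with the right limits", {
  s <- make_toy_structure("globule", 40, 10, seed = 5, element = "C")
  q <- default_q_grid(n = 51)
  ff <- ff_model(c1 = 1)
  m <- mean_intensity_uniform(s, 0.8, q, ff)$intensity
  I0 <- debye_intensity(s, q, ff)$intensity
  F <- sapply(s$element, function(e) effective_form_factor(e, q, ff))
  fl <- rowSums(F^2)
  expect_true(all(m >= pmin(I0, fl) - 1e-9 & m <= pmax(I0, fl) + 1e-9))
  # large q*tau limit: only the self-term floor survives
  expect_equal(mean_intensity_uniform(s, 50, 0.5, ff)$intensity,
               sum(sapply(s$element, function(e)
                 effective_form_factor(e, 0.5, ff))^2),
               tolerance = 1e-6)
})

test_that("mixture mean is a weighted sum with fast-decaying floppy part", {
  s <- make_toy_structure("globule", 30, 8, seed = 2, element = "X")
  q <- default_q_grid(n = 41)
  ffp <- ff_point()
  one <- mixture_mean_intensity(list(list(structure = s, tau = 0.4, weight = 1)),
                                q, ffp)
  expect_equal(one$intensity, mean_intensity_uniform(s, 0.4, q, ffp)$intensity)

  both <- mixture_mean_intensity(
    list(list(structure = s, tau = 0.4, weight = 0.5),
         list(structure = s, tau = 0.4, weight = 0.5)), q, ffp)
  expect_equal(both$intensity, one$intensity, tolerance = 1e-12)

  expect_error(mixture_mean_intensity(
    list(list(structure = s, tau = 0.4, weight = 0.6),
         list(structure = s, tau = 0.4, weight = 0.6)), q, ffp),
    "sum to 1")

  # the floppy component's coherent (non-floor) term decays faster with q:
  # its high-q/low-q ratio is smaller than the stiff component's
  nonfloor <- function(tau, qv) {
    exp(-qv^2 * tau^2) *
      (debye_intensity(s, qv, ffp)$intensity - n_atoms(s))
  }
  rA <- nonfloor(0.3, 0.4) / nonfloor(0.3, 0.05)
  rB <- nonfloor(3.0, 0.4) / nonfloor(3.0, 0.05)
  expect_lt(abs(rB), abs(rA))
})

test_that("geometric factor nu is the cosine at the shared atom", {
  s <- point_structure(rbind(c(0, 0, 0), c(-2, 0, 0), c(5, 0, 0), c(0, 3, 0)))
  expect_equal(geometric_nu(s, 1, 2, 3), -1)   # collinear, opposite sides
  expect_equal(geometric_nu(s, 1, 3, 4), 0)    # right angle at atom 1
  set.seed(1)
  r <- point_structure(matrix(rnorm(9, sd = 5), 3))
  v1 <- r$xyz[2, ] - r$xyz[1, ]; v2 <- r$xyz[3, ] - r$xyz[1, ]
  expect_equal(geometric_nu(r, 1, 2, 3),
               sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  dup <- point_structure(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(geometric_nu(dup, 1, 2, 3), "coincident")
})

test_that("bivariate normal approximation has the stated moments", {
  b <- bivariate_normal_approx(10, 12, 0.3, 0, 0.5, 0.6)
  expect_equal(b$cov[1, 2], 0)                  # rigid shared atom decorrelates
  b2 <- bivariate_normal_approx(10, 12, 1, 0.5, 0, 0)
  expect_equal(det(b2$cov), 0)                  # perfectly correlated: rank 1
  expect_warning(bivariate_normal_approx(1, 1, 0, 0.5, 0.5, 0.5), "unreliable")

  # moments against direct simulation at small tau/d
  set.seed(9)
  p1 <- c(0, 0, 0); p2 <- c(10, 0, 0); p3 <- c(3, 9, 0)
  tk <- 0.2; tl <- 0.15; tn <- 0.25
  n <- 2e5
  Dk <- matrix(rnorm(3 * n, sd = tk), ncol = 3)
  Dl <- matrix(rnorm(3 * n, sd = tl), ncol = 3)
  Dn <- matrix(rnorm(3 * n, sd = tn), ncol = 3)
  dkl <- sqrt(rowSums((rep(p2 - p1, each = n) + Dl - Dk)^2))
  dkn <- sqrt(rowSums((rep(p3 - p1, each = n) + Dn - Dk)^2))
  nu <- sum((p2 - p1) * (p3 - p1)) / sqrt(sum((p2 - p1)^2) * sum((p3 - p1)^2))
  b3 <- bivariate_normal_approx(sqrt(sum((p2 - p1)^2)), sqrt(sum((p3 - p1)^2)),
                                nu, tk, tl, tn)
  expect_equal(mean(dkl), b3$mean[1], tolerance = 1e-3)
  expect_equal(mean(dkn), b3$mean[2], tolerance = 1e-3)
  expect_equal(cov(dkl, dkn), b3$cov[1, 2], tolerance = 0.02)
  expect_equal(var(dkl), b3$cov[1, 1], tolerance = 0.02)
})

test_that("analytic covariance has the required structure and limits", {
  s <- make_toy_structure("random-cloud", 6, 12, seed = 13, element = "X")
  s <- assign_tau(s, "uniform", value = 0.2)
  q <- default_q_grid(n = 21)
  cv <- covariance_matrix(s, q, ff_point())

  expect_equal(cv$cov, t(cv$cov))
  expect_equal(cv$cov, cv$auto + cv$cross, tolerance = 1e-12)
  expect_true(all(diag(cv$auto) >= 0))
  # q = 0 row/column vanish exactly
  expect_identical(unname(cv$cov[1, ]), rep(0, 21))
  expect_identical(unname(cv$cov[, 1]), rep(0, 21))
  # two atoms: no shared-atom triples, cross term identically zero
  two <- assign_tau(point_structure(rbind(c(0, 0, 0), c(6, 0, 0))),
                    "uniform", value = 0.3)
  cv2 <- covariance_matrix(two, q, ff_point())
  expect_identical(cv2$cross, matrix(0, 21, 21))
  # vanishes with tau
  s0 <- assign_tau(s, "uniform", value = 0)
  expect_identical(covariance_matrix(s0, q, ff_point())$cov, matrix(0, 21, 21))
})

test_that("covariance scales as tau^2 and matches the quadrature oracle", {
  s <- make_toy_structure("random-cloud", 5, 10, seed = 7, element = "X")
  dmin <- min(distance_matrix(s)[distance_matrix(s) > 0])
  q <- seq(0, 0.5, 0.05)
  ffp <- ff_point()
  tau1 <- 0.02 * dmin
  c1 <- covariance_matrix(assign_tau(s, "uniform", value = tau1), q, ffp)
  c2 <- covariance_matrix(assign_tau(s, "uniform", value = 2 * tau1), q, ffp)
  expect_equal(c2$cov, 4 * c1$cov, tolerance = 1e-10)   # exactly linear in tau^2

  # exact-covariance quadrature oracle agrees to the second-order truncation
  qd <- quadrature_mean_cov(assign_tau(s, "uniform", value = tau1), q, ffp)
  reldev <- max(abs(c1$cov - qd$cov$cov)) / max(abs(qd$cov$cov))
  expect_lt(reldev, 5 * (0.02)^2)
})

test_that("analytic covariance matches the Monte-Carlo oracle elementwise", {
  s <- make_toy_structure("random-cloud", 5, 10, seed = 7, element = "X")
  D <- distance_matrix(s)
  tau <- 0.04 * min(D[D > 0])
  sv <- assign_tau(s, "uniform", value = tau)
  q <- seq(0, 0.5, 0.05)
  mc <- mc_mean_cov(sv, q, ff_point(), n_samples = 40000, seed = 21)
  cv <- covariance_matrix(sv, q, ff_point())
  tol <- 3 * mc$se_cov + 5 * 0.04^2 * max(abs(cv$cov)) + 1e-12
  expect_true(all(abs(cv$cov - mc$cov$cov) <= tol))
})

test_that("correlation matrix is unit-diagonal, clamped and guards q = 0", {
  s <- make_toy_structure("globule", 30, 10, seed = 3, element = "X")
  s <- assign_tau(s, "uniform", value = 0.5)
  q <- default_q_grid(n = 26)
  rho <- correlation_matrix(covariance_matrix(s, q, ff_point()))
  expect_true(all(is.nan(rho$rho[1, ])))        # q = 0 left undefined
  def <- rho$rho[-1, -1]
  expect_equal(diag(def), rep(1, 25))
  expect_true(all(abs(def) <= 1))

  # rank-1 covariance gives |rho| == 1 everywhere
  v <- c(0.5, 1, 2, 3)
  r1 <- correlation_matrix(sas_cov(c(0.1, 0.2, 0.3, 0.4), v %o% v))
  expect_equal(abs(r1$rho), matrix(1, 4, 4))

  neg <- diag(c(1, -0.5, 1))
  expect_error(correlation_matrix(sas_cov(c(0.1, 0.2, 0.3), neg)),
               class = "sascov_numerical")
})

test_that("covariance writers round-trip (text approximately, binary exactly)", {
  s <- assign_tau(make_toy_structure("random-cloud", 4, 8, seed = 1, element = "X"),
                  "uniform", value = 0.3)
  cv <- covariance_matrix(s, seq(0.01, 0.2, 0.01), ff_point())
  tpath <- tempfile(fileext = ".txt")
  write_cov_text(cv, tpath)
  back <- read_cov_text(tpath)
  expect_equal(back$q, cv$q, tolerance = 1e-8)
  expect_equal(back$cov, cv$cov, tolerance = 1e-8)

  bpath <- tempfile(fileext = ".bin")
  write_cov_bin(cv, bpath)
  bin <- read_cov_bin(bpath)
  expect_identical(bin$cov, cv$cov)            # bit-exact
  expect_identical(bin$auto, cv$auto)
  expect_identical(bin$cross, cv$cross)
  expect_identical(bin$q, cv$q)
})
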