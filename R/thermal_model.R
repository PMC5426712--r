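#' Density of the distance between two thermally displaced atoms
#'
#' When atoms `k` and `l` are displaced independently around mean positions a
#' distance `d0` apart, with isotropic Gaussian displacements of per-coordinate
#' SD `tau_k` and `tau_l`, their instantaneous distance follows a noncentral
#' chi distribution with three degrees of freedom and per-coordinate variance
#' `s2 = tau_k^2 + tau_l^2`:
#' \deqn{p(d) = \frac{1}{\sqrt{2\pi s^2}} \frac{d}{d_0}
#'   \left[e^{-(d-d_0)^2/2s^2} - e^{-(d+d_0)^2/2s^2}\right]}
#'
#' @param d distance at which to evaluate the density, Angstrom (vectorized).
#' @param d0 mean-position distance, Angstrom (> 0).
#' @param tau_k,tau_l per-coordinate thermal SDs, Angstrom (not both zero).
#' @return Density values, 1/Angstrom.
#' @export
noncentral_chi_pdf <- function(d, d0, tau_k, tau_l) {
  if (any(d < 0)) stopf("d must be non-negative")
  if (d0 <= 0) stopf("d0 must be positive")
  s2 <- tau_k^2 + tau_l^2
  if (s2 <= 0) stopf("tau_k and tau_l cannot both be zero (rigid pair)")
  (d / d0) / sqrt(2 * pi * s2) *
    (exp(-(d - d0)^2 / (2 * s2)) - exp(-(d + d0)^2 / (2 * s2)))
}

#' Exact thermal expectation of the sinc kernel
#'
#' For a pair of independently displaced atoms the expectation of
#' `sinc(q d)` over the thermal distance distribution has the exact closed
#' form
#' \deqn{E\,\mathrm{sinc}(qd) = \mathrm{sinc}(q d_0)\,
#'   e^{-q^2 (\tau_k^2+\tau_l^2)/2}.}
#' No approximation is involved; this is the building block of the exact
#' ensemble-average intensity.
#'
#' @param q momentum transfer, 1/Angstrom (vectorized).
#' @param d0 mean-position distance, Angstrom (> 0).
#' @param tau_k,tau_l per-coordinate thermal SDs, Angstrom.
#' @return Numeric vector, length of `q`.
#' @export
sinc_expectation <- function(q, d0, tau_k, tau_l) {
  if (any(q < 0)) stopf("q must be non-negative")
  if (d0 <= 0) stopf("d0 must be positive")
  sinc(q * d0) * exp(-q^2 * (tau_k^2 + tau_l^2) / 2)
}

#' Exact ensemble-average intensity under per-atom thermal motion
#'
#' Mean Debye intensity over the thermal ensemble in which every atom `k` is
#' displaced independently with per-coordinate SD `tau_k`:
#' \deqn{E I(q) = \sum_k \sum_l f_k f_l e^{-q^2\tau_k^2/2} e^{-q^2\tau_l^2/2}
#'   \mathrm{sinc}(q d^\circ_{kl}) + \sum_k (1 - e^{-q^2\tau_k^2}) f_k^2.}
#' This is exact (not a small-`tau` approximation). With all `tau = 0` it
#' equals [debye_intensity()]; at high `q tau` it tends to the incoherent
#' floor `sum_k f_k^2`.
#'
#' @param s a `sas_structure` with `tau` assigned (see [assign_tau()]).
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param chunk pairs per processing block.
#' @return A `sas_profile`.
#' @export
mean_intensity <- function(s, q = default_q_grid(), ff = ff_model(),
                           chunk = 200000L) {
  if (is.null(s$tau)) stopf("tau is not assigned; see assign_tau()")
  q <- check_q_grid(q)
  F <- ff_eval(ff, s, q)
  damp <- exp(-outer(q^2, s$tau^2) / 2)         # |q| x N
  A <- F * damp
  I <- rowSums(A^2) + rowSums((1 - damp^2) * F^2)
  n <- n_atoms(s)
  if (n >= 2L) {
    px <- pair_index(s)
    P <- nrow(px$pairs)
    for (lo in seq(1L, P, by = chunk)) {
      hi <- min(lo + chunk - 1L, P)
      idx <- lo:hi
      S <- sinc(outer(q, px$d[idx]))
      W <- A[, px$pairs[idx, "k"], drop = FALSE] *
           A[, px$pairs[idx, "l"], drop = FALSE]
      I <- I + 2 * rowSums(W * S)
    }
  }
  sas_profile(q, I, label = s$label)
}

#' Ensemble-average intensity for uniform thermal motion
#'
#' With a single `tau` for every atom the exact thermal mean collapses to a
#' convex combination of the rigid profile and the incoherent floor:
#' \deqn{E I(q) = e^{-q^2\tau^2} I_{x^\circ}(q) +
#'   (1 - e^{-q^2\tau^2}) \sum_k f_k(q)^2.}
#'
#' @param s a `sas_structure` (its stored `tau`, if any, is ignored).
#' @param tau uniform per-coordinate thermal SD, Angstrom.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @return A `sas_profile`.
#' @export
mean_intensity_uniform <- function(s, tau, q = default_q_grid(),
                                   ff = ff_model()) {
  if (!is_scalar_number(tau) || tau < 0) stopf("tau must be a non-negative scalar")
  q <- check_q_grid(q)
  I0 <- debye_intensity(s, q, ff)$intensity
  F <- ff_eval(ff, s, q)
  floor_ <- rowSums(F^2)
  w <- exp(-q^2 * tau^2)
  sas_profile(q, w * I0 + (1 - w) * floor_, label = s$label)
}

#' Ensemble-average intensity of a mixture of thermal ensembles
#'
#' For a system populating several conformations, each with its own uniform
#' thermal deviation and population weight, the average intensity is the
#' weighted sum of the per-component thermal means. Because each component's
#' coherent term is damped by `exp(-q^2 tau^2)`, components with small `tau`
#' dominate the structured part of the profile at high `q`.
#'
#' @param components list of `list(structure =, tau =, weight =)` entries.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @return A `sas_profile`. Weights must be non-negative and sum to 1 (no
#'   silent renormalization).
#' @export
mixture_mean_intensity <- function(components, q = default_q_grid(),
                                   ff = ff_model()) {
  w <- vapply(components, function(cc) as.numeric(cc$weight), numeric(1))
  if (any(w < 0)) stopf("mixture weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8)
    stopf("mixture weights must sum to 1 (got %.6g); renormalize explicitly", sum(w))
  q <- check_q_grid(q)
  I <- numeric(length(q))
  for (i in seq_along(components)) {
    cc <- components[[i]]
    I <- I + w[i] * mean_intensity_uniform(cc$structure, cc$tau, q, ff)$intensity
  }
  sas_profile(q, I, label = "mixture")
}

#' Geometric correlation factor of two distances sharing an atom
#'
#' Cosine of the angle at atom `k` between the direction to atom `l` and the
#' direction to atom `n`; it scales the covariance of the two shared-atom
#' distances. Values are clipped to `[-1, 1]` against rounding.
#'
#' @param s a `sas_structure`.
#' @param k,l,n distinct atom indices; `k` is the shared atom.
#' @return Scalar in `[-1, 1]`.
#' @export
geometric_nu <- function(s, k, l, n) {
  if (length(unique(c(k, l, n))) != 3L) stopf("k, l, n must be distinct")
  v1 <- s$xyz[l, ] - s$xyz[k, ]
  v2 <- s$xyz[n, ] - s$xyz[k, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stopf("coincident atoms: zero distance in triple")
  min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
}

#' Bivariate normal approximation to two shared-atom distances
#'
#' Small-`tau` approximation of the joint distribution of `d_kl` and `d_kn`
#' when atom `k` is shared: a bivariate normal with mean
#' `(d0_kl + (tau_k^2+tau_l^2)/d0_kl, d0_kn + (tau_k^2+tau_n^2)/d0_kn)`,
#' variances `tau_k^2+tau_l^2` and `tau_k^2+tau_n^2`, and covariance
#' `nu * tau_k^2` where `nu` is the cosine of the angle at the shared atom.
#'
#' @param d0_kl,d0_kn mean-position distances, Angstrom (> 0).
#' @param nu geometric factor from [geometric_nu()].
#' @param tau_k,tau_l,tau_n per-coordinate thermal SDs, Angstrom.
#' @return `list(mean = <2-vector>, cov = <2x2 matrix>)`. Warns (but does not
#'   fail) when `tau/d0 > 0.2`, where the expansion degrades.
#' @export
bivariate_normal_approx <- function(d0_kl, d0_kn, nu, tau_k, tau_l, tau_n) {
  if (d0_kl <= 0 || d0_kn <= 0) stopf("distances must be positive")
  taus <- max(tau_k, tau_l, tau_n)
  if (taus / min(d0_kl, d0_kn) > 0.2)
    warning("tau/d0 > 0.2: the small-displacement expansion is unreliable here")
  m <- c(d0_kl + (tau_k^2 + tau_l^2) / d0_kl,
         d0_kn + (tau_k^2 + tau_n^2) / d0_kn)
  S <- matrix(c(tau_k^2 + tau_l^2, nu * tau_k^2,
                nu * tau_k^2, tau_k^2 + tau_n^2), 2, 2)
  list(mean = m, cov = S)
}

#' Profile covariance container
#'
#' Holds the symmetric covariance matrix `V(I(q_i), I(q_j))` of a scattering
#' profile over a q grid, optionally with its autocovariance / cross-covariance
#' decomposition (analytic path only).
#'
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param cov symmetric covariance matrix, intensity^2 units.
#' @param auto,cross optional decomposition components (same shape).
#' @param label free text.
#' @return An object of class `sas_cov`.
#' @export
sas_cov <- function(q, cov, auto = NULL, cross = NULL, label = "") {
  q <- check_q_grid(q)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == length(q))) stopf("cov must be |q| x |q|")
  asym <- suppressWarnings(max(abs(cov - t(cov)), na.rm = TRUE))
  if (is.finite(asym) && asym > 1e-10 * suppressWarnings(max(abs(cov), 1e-300, na.rm = TRUE)))
    stopf("covariance matrix is not symmetric (max asymmetry %.3g)", asym)
  cov <- (cov + t(cov)) / 2
  structure(list(q = q, cov = cov, auto = auto, cross = cross,
                 label = as.character(label)[1]),
            class = "sas_cov")
}

#' @export
print.sas_cov <- function(x, ...) {
  cat(sprintf("<sas_cov> %s: %d x %d, max |V| = %.4g%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), length(x$q), max(abs(x$cov), na.rm = TRUE),
              if (!is.null(x$auto)) " (with auto/cross decomposition)" else ""))
  invisible(x)
}

#' Analytic covariance of a thermal-ensemble scattering profile
#'
#' Second-order (in `tau/d`) covariance between the intensities at `q_i` and
#' `q_j` for independent isotropic Gaussian atomic motion. Two term classes
#' survive: the *autocovariance* (a pair distance with itself) and the
#' *cross-covariance* (two distances sharing one atom),
#' \deqn{V^\circ_{ij}(d) = (\tau_k^2+\tau_l^2)\, q_i q_j\,
#'   \sigma(q_i d)\sigma(q_j d), \qquad
#'   V_{ij}(d, d') = \nu\, \tau_k^2\, q_i q_j\, \sigma(q_i d)\sigma(q_j d'),}
#' summed with multiplicities 2 (ordered pairs) and 4 (ordered shared-atom
#' triples) respectively; the multiplicities were fixed by requiring agreement
#' with a brute-force Monte-Carlo covariance on toy systems. The row and
#' column at `q = 0` vanish identically (`q_i q_j` prefactor): `I(0)` counts
#' electrons and carries no conformational variance.
#'
#' The cross term costs `O(N^2 |q|^2)` after factorization over the shared
#' atom; structures beyond `max_atoms` atoms are refused unless
#' `force = TRUE`.
#'
#' @param s a `sas_structure` with `tau` assigned.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param max_atoms guard for the `O(N^2 |q|^2)` cost (default 2000).
#' @param force bypass the `max_atoms` guard.
#' @param chunk pairs per block in the auto term.
#' @return A `sas_cov` with the total matrix and its `auto`/`cross` parts.
#' @export
covariance_matrix <- function(s, q = default_q_grid(), ff = ff_model(),
                              max_atoms = 2000L, force = FALSE,
                              chunk = 100000L) {
  if (is.null(s$tau)) stopf("tau is not assigned; see assign_tau()")
  n <- n_atoms(s)
  if (n < 2L) stopf("covariance needs at least 2 atoms")
  if (n > max_atoms && !force)
    stopf("structure has %d atoms (> %d); the cross term is O(N^2 |q|^2) - pass force = TRUE to proceed", n, max_atoms)
  q <- check_q_grid(q)
  nq <- length(q)
  F <- ff_eval(ff, s, q)
  tau2 <- s$tau^2

  # autocovariance: 4 x sum over unordered pairs (== 2 x ordered-pair sum)
  Vauto <- matrix(0, nq, nq)
  px <- pair_index(s)
  P <- nrow(px$pairs)
  for (lo in seq(1L, P, by = chunk)) {
    hi <- min(lo + chunk - 1L, P)
    idx <- lo:hi
    kk <- px$pairs[idx, "k"]; ll <- px$pairs[idx, "l"]
    B <- q * F[, kk, drop = FALSE] * F[, ll, drop = FALSE] *
      sigma_kernel(outer(q, px$d[idx]))
    t2p <- tau2[kk] + tau2[ll]
    Vauto <- Vauto + 4 * tcrossprod(B * rep(t2p, each = nq), B)
  }

  # cross-covariance, factorized over the shared atom a:
  #   sum_{b != c} nu f_b s_i(ab) f_c s_j(ac) = g_a(q_i).g_a(q_j) - h_a(q_i,q_j)
  Vcross <- matrix(0, nq, nq)
  if (n >= 3L) {
    D <- distance_matrix(s)
    for (a in seq_len(n)) {
      if (tau2[a] == 0) next
      others <- setdiff(seq_len(n), a)
      da <- D[a, others]
      if (any(da == 0)) stopf("coincident atoms (zero distance) at atom %d", a)
      U <- sweep(s$xyz[others, , drop = FALSE], 2, s$xyz[a, ]) / da
      S <- sigma_kernel(outer(q, da)) * F[, others, drop = FALSE]  # nq x (n-1)
      G <- S %*% U                                                 # nq x 3
      M <- tcrossprod(G) - tcrossprod(S)
      w <- q * F[, a]
      Vcross <- Vcross + 4 * tau2[a] * (w %o% w) * M
    }
  }
  V <- Vauto + Vcross
  sas_cov(q, (V + t(V)) / 2, auto = (Vauto + t(Vauto)) / 2,
          cross = (Vcross + t(Vcross)) / 2, label = s$label)
}

#' Correlation matrix container
#'
#' @param q momentum-transfer grid.
#' @param rho symmetric matrix of correlations in `[-1, 1]`; entries involving
#'   a zero-variance point (`q = 0`) are `NaN` (undefined, not imputed).
#' @param n_clamped number of entries clipped into `[-1, 1]`.
#' @param label free text.
#' @return An object of class `sas_corr`.
#' @export
sas_corr <- function(q, rho, n_clamped = 0L, label = "") {
  q <- check_q_grid(q)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == length(q))) stopf("rho must be |q| x |q|")
  structure(list(q = q, rho = rho, n_clamped = as.integer(n_clamped),
                 label = as.character(label)[1]),
            class = "sas_corr")
}

#' @export
print.sas_corr <- function(x, ...) {
  def <- x$rho[!is.na(x$rho)]
  cat(sprintf("<sas_corr> %s: %d x %d, range [%.3f, %.3f], %d clamped\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), length(x$q),
              if (length(def)) min(def) else NA, if (length(def)) max(def) else NA,
              x$n_clamped))
  invisible(x)
}

#' @export
plot.sas_corr <- function(x, nlevels = 21, ...) {
  ok <- which(!is.na(diag(x$rho)))
  graphics::filled.contour(x$q[ok], x$q[ok], x$rho[ok, ok],
                           levels = seq(-1, 1, length.out = nlevels),
                           xlab = "q_i (1/A)", ylab = "q_j (1/A)", ...)
  invisible(x)
}

#' Correlation matrix of a profile covariance
#'
#' `rho(q_i, q_j) = V(q_i, q_j) / sqrt(V(q_i, q_i) V(q_j, q_j))`. Rows and
#' columns with zero variance (the `q = 0` boundary) are left `NaN`; entries
#' are clamped to `[-1, 1]` (the second-order covariance is not guaranteed
#' positive-semidefinite) and the number of clamping events is recorded.
#' A strictly negative diagonal entry signals that the second-order
#' approximation broke down and raises an error.
#'
#' @param cv a `sas_cov`.
#' @return A `sas_corr`.
#' @export
correlation_matrix <- function(cv) {
  d <- diag(cv$cov)
  tol <- -1e-12 * max(abs(d), 1e-300)
  if (any(d < tol))
    numerical_error("negative variance on the diagonal (min %.3g): the second-order covariance approximation broke down for this structure/tau", min(d))
  defined <- d > 0
  rho <- matrix(NaN, length(d), length(d))
  if (any(defined)) {
    sd_ <- sqrt(d[defined])
    sub <- cv$cov[defined, defined, drop = FALSE] / (sd_ %o% sd_)
    nc <- sum(abs(sub) > 1)
    sub[sub > 1] <- 1
    sub[sub < -1] <- -1
    diag(sub) <- 1
    rho[defined, defined] <- sub
  } else nc <- 0L
  sas_corr(cv$q, rho, n_clamped = nc, label = cv$label)
}

#' Write a covariance (or correlation) matrix as plain text
#'
#' Dense whitespace-separated matrix preceded by a one-line `# q:` header
#' carrying the grid.
#'
#' @param cv a `sas_cov` or `sas_corr`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cov_text <- function(cv, path) {
  M <- if (inherits(cv, "sas_corr")) cv$rho else cv$cov
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# q:", paste(sprintf("%.8e", cv$q), collapse = " ")), con)
  utils::write.table(format(M, digits = 10, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plain-text matrix written by [write_cov_text()]
#'
#' @param path file path.
#' @return A `sas_cov` (correlation matrices read back as plain `sas_cov`;
#'   wrap with [sas_corr()] if needed).
#' @export
read_cov_text <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# q:")]
  if (length(hdr) != 1L) stopf("missing '# q:' header in %s", path)
  q <- as.numeric(strsplit(sub("^# q:\\s*", "", hdr), "\\s+")[[1]])
  M <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  dimnames(M) <- NULL
  sas_cov(q, M, label = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a covariance to the binary container
#'
#' Self-describing compressed container (R serialization) with arrays `q`,
#' `cov`, `auto`, `cross`; round-trips bit-exactly via [read_cov_bin()].
#'
#' @param cv a `sas_cov`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cov_bin <- function(cv, path) {
  saveRDS(list(container = "sascov-cov", version = 1L, q = cv$q,
               cov = cv$cov, auto = cv$auto, cross = cv$cross,
               label = cv$label),
          path, compress = "gzip")
  invisible(path)
}

#' Read a covariance from the binary container
#' @param path file written by [write_cov_bin()].
#' @return A `sas_cov`.
#' @export
read_cov_bin <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "sascov-cov")) stopf("%s is not a covariance container", path)
  sas_cov(x$q, x$cov, auto = x$auto, cross = x$cross, label = x$label %||% "")
}
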