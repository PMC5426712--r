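#' Generate a synthetic toy structure
#'
#' Deterministic (per seed) generators for the structure shapes used by the
#' oracle tests and diagnostics:
#' * `"random-cloud"` - atoms uniform in a ball of the given radius;
#' * `"globule"` - same, but intended for globular-scale diagnostics
#'   (uniform density, so `R_G = sqrt(3/5) * scale`);
#' * `"linear-chain"` - `n` atoms equally spaced `scale` apart on a line;
#' * `"two-domain"` - two globules (radius `0.35 * scale`) with centres
#'   `scale` apart joined by a sparse linker (~10% of the atoms).
#'
#' @param kind one of `"random-cloud"`, `"globule"`, `"linear-chain"`,
#'   `"two-domain"`.
#' @param n_atoms number of atoms (>= 1).
#' @param scale length scale in Angstrom (> 0): ball radius, chain spacing, or
#'   domain separation.
#' @param tau optional thermal SD (scalar or per atom), Angstrom.
#' @param seed integer seed fixing all randomness.
#' @param element element symbol for every atom (`"X"` is the point atom with
#'   `f == 1` under the default table).
#' @return A `sas_structure`.
#' @export
make_toy_structure <- function(kind = c("random-cloud", "two-domain",
                                        "linear-chain", "globule"),
                               n_atoms, scale, tau = NULL, seed = 1L,
                               element = "C") {
  kind <- match.arg(kind)
  if (n_atoms < 1L) stopf("n_atoms must be >= 1")
  if (scale <= 0) stopf("scale must be positive")
  ball <- function(n, radius, centre = c(0, 0, 0)) {
    # uniform in a ball: isotropic direction, radius ~ R * U^(1/3)
    z <- matrix(stats::rnorm(3 * n), ncol = 3)
    z <- z / sqrt(rowSums(z^2))
    r <- radius * stats::runif(n)^(1 / 3)
    sweep(z * r, 2, centre, "+")
  }
  xyz <- with_seed(seed, switch(kind,
    "random-cloud" = ,
    "globule" = ball(n_atoms, scale),
    "linear-chain" = cbind((seq_len(n_atoms) - 1) * scale, 0, 0),
    "two-domain" = {
      n_link <- max(0L, round(0.1 * n_atoms))
      n1 <- ceiling((n_atoms - n_link) / 2)
      n2 <- n_atoms - n_link - n1
      if (n2 < 1L) { n2 <- 1L; n1 <- max(1L, n1 - 1L) }
      c1 <- c(-scale / 2, 0, 0); c2 <- c(scale / 2, 0, 0)
      lnk <- if (n_link > 0)
        cbind(seq(-scale / 2, scale / 2, length.out = n_link + 2)[-c(1, n_link + 2)],
              0, 0)
      else NULL
      rbind(ball(n1, 0.35 * scale, c1), lnk, ball(n2, 0.35 * scale, c2))
    }))
  sas_structure(xyz, rep(element, n_atoms), tau = tau,
                label = sprintf("%s n=%d scale=%g seed=%d", kind, n_atoms,
                                scale, seed))
}

#' Sample a Monte-Carlo thermal ensemble of conformers
#'
#' Draws conformers by displacing every atom of the mean structure
#' independently with an isotropic Gaussian of per-coordinate SD `tau_k` -
#' exactly the generative model behind the analytic theory. Bit-reproducible
#' given the seed.
#'
#' @param s a `sas_structure` with `tau` assigned.
#' @param n_samples number of conformers (>= 1).
#' @param seed integer seed.
#' @return List of `sas_structure` conformers.
#' @export
mc_sample_ensemble <- function(s, n_samples, seed = 1L) {
  if (is.null(s$tau)) stopf("tau is not assigned; see assign_tau()")
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  n <- n_atoms(s)
  with_seed(seed, lapply(seq_len(n_samples), function(m) {
    out <- s
    out$xyz <- s$xyz + matrix(stats::rnorm(3 * n), ncol = 3) * s$tau
    out$label <- sprintf("%s mc#%d", s$label, m)
    out
  }))
}

# brute-force per-conformer intensities of the thermal ensemble, computed by
# direct pair-distance resampling (shares only the sinc kernel with the
# analytic code paths). Returns an n_samples x |q| matrix.
mc_intensities <- function(s, q, ff, n_samples, seed, chunk = 20000L) {
  n <- n_atoms(s)
  F <- ff_eval(ff, s, q)
  self_term <- rowSums(F^2)
  px <- pair_index(s)
  P <- nrow(px$pairs)
  I <- matrix(rep(self_term, each = n_samples), n_samples, length(q))
  if (P == 0L) return(I)
  with_seed(seed, {
    done <- 0L
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      rows <- done + seq_len(m)
      disp <- array(stats::rnorm(m * n * 3), dim = c(m, n, 3)) *
        rep(s$tau, each = m)
      Dm <- matrix(0, m, P)
      for (p in seq_len(P)) {
        k <- px$pairs[p, "k"]; l <- px$pairs[p, "l"]
        dx <- disp[, l, ] - disp[, k, ]
        dx <- sweep(dx, 2, s$xyz[l, ] - s$xyz[k, ], "+")
        Dm[, p] <- sqrt(rowSums(dx^2))
      }
      for (iq in seq_along(q)) {
        w <- F[iq, px$pairs[, "k"]] * F[iq, px$pairs[, "l"]]
        I[rows, iq] <- I[rows, iq] + 2 * drop(sinc(q[iq] * Dm) %*% w)
      }
      done <- done + m
    }
  })
  I
}

#' Monte-Carlo estimate of the thermal mean and covariance
#'
#' Brute-force oracle for the analytic theory: samples the thermal ensemble,
#' computes every conformer's Debye intensity by direct pair resampling, and
#' returns the sample mean and (unbiased) covariance together with jackknife
#' standard errors over `blocks` conformer blocks, enabling "within 3 SE"
#' assertions against the analytic formulas.
#'
#' @param s a `sas_structure` with `tau` assigned.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param n_samples number of conformers (>= 2).
#' @param seed integer seed.
#' @param blocks jackknife block count (default 10).
#' @return List with `mean` (`sas_profile`), `cov` (`sas_cov`), `se_mean`
#'   (per-q SE of the mean), `se_cov` (elementwise SE of the covariance) and
#'   `n_samples`.
#' @export
mc_mean_cov <- function(s, q = default_q_grid(), ff = ff_model(),
                        n_samples = 10000L, seed = 1L, blocks = 10L) {
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  q <- check_q_grid(q)
  I <- mc_intensities(s, q, ff, n_samples, seed)
  mu <- colMeans(I)
  V <- stats::cov(I)
  blk <- rep(seq_len(blocks), length.out = n_samples)
  mu_jk <- array(0, c(blocks, length(q)))
  V_jk <- array(0, c(blocks, length(q), length(q)))
  for (b in seq_len(blocks)) {
    keep <- blk != b
    mu_jk[b, ] <- colMeans(I[keep, , drop = FALSE])
    V_jk[b, , ] <- stats::cov(I[keep, , drop = FALSE])
  }
  fac <- (blocks - 1) / blocks
  se_mean <- sqrt(fac * colSums(sweep(mu_jk, 2, colMeans(mu_jk))^2))
  V_bar <- apply(V_jk, c(2, 3), mean)
  se_cov <- sqrt(fac * apply(sweep(V_jk, c(2, 3), V_bar)^2, c(2, 3), sum))
  list(mean = sas_profile(q, mu, error = se_mean, label = "MC mean"),
       cov = sas_cov(q, (V + t(V)) / 2, label = "MC covariance"),
       se_mean = se_mean, se_cov = se_cov, n_samples = n_samples)
}

#' Quadrature evaluation of the exact thermal mean and covariance
#'
#' Deterministic high-accuracy oracle for small structures. Only two classes
#' of terms contribute to the exact covariance (distances that are identical,
#' and distances sharing one atom; disjoint pairs are independent):
#' * pair terms `E[sinc(q_i d) sinc(q_j d)]` are integrated by Gauss-Legendre
#'   quadrature against the noncentral-chi distance density;
#' * shared-atom terms are reduced by conditioning on the shared atom's
#'   displacement (3-D Gauss-Hermite grid), the two distances being
#'   conditionally independent with exactly known conditional sinc means.
#'
#' Unlike the analytic [covariance_matrix()], this evaluation is exact up to
#' quadrature error at any `tau/d`, so it resolves the second-order truncation
#' error of the analytic formulas - which Monte-Carlo sampling cannot do at
#' realistic sample counts when `tau/d` is small.
#'
#' @param s a `sas_structure` with `tau` assigned (intended for N <= ~20).
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param nodes_radial Gauss-Legendre node count for pair integrals.
#' @param nodes_gh Gauss-Hermite nodes per dimension for shared-atom terms.
#' @return List with `mean` (`sas_profile`) and `cov` (`sas_cov`, with
#'   auto/cross decomposition).
#' @export
quadrature_mean_cov <- function(s, q = default_q_grid(), ff = ff_model(),
                                nodes_radial = 96L, nodes_gh = 12L) {
  if (is.null(s$tau)) stopf("tau is not assigned; see assign_tau()")
  n <- n_atoms(s)
  if (n < 2L) stopf("needs at least 2 atoms")
  q <- check_q_grid(q)
  nq <- length(q)
  F <- ff_eval(ff, s, q)
  tau <- s$tau

  # pair integrals: E[sinc(q_i d)] and E[sinc(q_i d) sinc(q_j d)] per pair
  px <- pair_index(s)
  P <- nrow(px$pairs)
  Em <- matrix(0, nq, P)        # E[sinc(q_i d_p)]
  auto <- matrix(0, nq, nq)
  mean_I <- rowSums(F^2)        # diagonal d_kk = 0 terms are exactly f^2
  for (p in seq_len(P)) {
    k <- px$pairs[p, "k"]; l <- px$pairs[p, "l"]
    d0 <- px$d[p]
    s2 <- tau[k]^2 + tau[l]^2
    if (s2 == 0) {
      sc <- sinc(q * d0)
      Em[, p] <- sc
      mean_I <- mean_I + 2 * F[, k] * F[, l] * sc
      next                       # rigid pair: no variance contribution
    }
    gl <- pracma::gaussLegendre(nodes_radial,
                                max(0, d0 - 10 * sqrt(s2)),
                                d0 + 10 * sqrt(s2))
    pd <- noncentral_chi_pdf(gl$x, d0, tau[k], tau[l]) * gl$w
    pd <- pd / sum(pd)   # renormalize the truncated density so that the
                         # q = 0 covariance row is exactly zero
    Sq <- sinc(outer(q, gl$x))                 # nq x nodes
    Em[, p] <- drop(Sq %*% pd)
    Eprod <- Sq %*% (t(Sq) * pd)               # E[s_i s_j]
    Cpair <- Eprod - Em[, p] %o% Em[, p]
    coef <- (F[, k] * F[, l]) %o% (F[, k] * F[, l])
    auto <- auto + 4 * coef * Cpair
    mean_I <- mean_I + 2 * F[, k] * F[, l] * Em[, p]
  }

  # shared-atom (cross) terms via 3-D Gauss-Hermite over the shared atom
  cross <- matrix(0, nq, nq)
  if (n >= 3L) {
    gh <- pracma::gaussHermite(nodes_gh)
    g3 <- expand.grid(gh$x, gh$x, gh$x)
    w3 <- apply(expand.grid(gh$w, gh$w, gh$w), 1, prod) / pi^(3 / 2)
    w3 <- w3 / sum(w3)
    Z <- as.matrix(g3)                         # nodes^3 x 3
    for (a in seq_len(n)) {
      if (tau[a] == 0) next                    # rigid shared atom: exact 0
      Delta <- sqrt(2) * tau[a] * Z
      others <- setdiff(seq_len(n), a)
      # conditional means m_b[i, t] = E[sinc(q_i d_ab) | Delta_a(t)]
      Mcond <- lapply(others, function(b) {
        v <- sweep(-Delta, 2, s$xyz[b, ] - s$xyz[a, ], "+")
        e <- sqrt(rowSums(v^2))
        sinc(outer(q, e)) * exp(-q^2 * tau[b]^2 / 2)
      })
      names(Mcond) <- as.character(others)
      Econd <- vapply(Mcond, function(M) drop(M %*% w3), numeric(nq))
      for (bi in seq_along(others)) for (ci in seq_along(others)) {
        if (bi == ci) next
        b <- others[bi]; cc <- others[ci]
        Eij <- Mcond[[bi]] %*% (t(Mcond[[ci]]) * w3)
        Cterm <- Eij - Econd[, bi] %o% Econd[, ci]
        coef <- (F[, a] * F[, b]) %o% (F[, a] * F[, cc])
        cross <- cross + 4 * coef * Cterm
      }
    }
  }
  V <- auto + cross
  list(mean = sas_profile(q, mean_I, label = "quadrature mean"),
       cov = sas_cov(q, (V + t(V)) / 2, auto = (auto + t(auto)) / 2,
                     cross = (cross + t(cross)) / 2,
                     label = "quadrature covariance"))
}
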