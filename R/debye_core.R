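#' Numerically stable sinc kernel
#'
#' `sin(x)/x` with the series `1 - x^2/6 + x^4/120` below `x = 1e-4`, so that
#' `sinc(0) == 1` exactly and there is never a division by zero.
#'
#' @param x non-negative numeric vector.
#' @return `sin(x)/x`, elementwise.
#' @export
sinc <- function(x) {
  small <- x < 1e-4
  out <- x
  out[small] <- 1 - x[small]^2 / 6 + x[small]^4 / 120
  xb <- x[!small]
  out[!small] <- sin(xb) / xb
  out
}

#' Derivative kernel of sinc
#'
#' `sigma(x) = d/dx sin(x)/x = (cos(x) - sin(x)/x)/x`, evaluated through the
#' series `-x/3 + x^3/30` below `x = 1e-4`; `sigma(0) == 0` exactly. This is
#' the kernel of the analytic profile covariance.
#'
#' @param x non-negative numeric vector.
#' @return Numeric vector, elementwise.
#' @export
sigma_kernel <- function(x) {
  small <- x < 1e-4
  out <- x
  out[small] <- -x[small] / 3 + x[small]^3 / 30
  xb <- x[!small]
  out[!small] <- (cos(xb) - sin(xb) / xb) / xb
  out
}

#' Pairwise distance matrix of a structure
#'
#' @param s a `sas_structure`.
#' @return Symmetric `N x N` matrix of Euclidean distances in Angstrom with a
#'   zero diagonal.
#' @export
distance_matrix <- function(s) {
  m <- as.matrix(stats::dist(s$xyz))
  dimnames(m) <- NULL
  m
}

#' Default momentum-transfer grid
#'
#' 101 equally spaced points on `[0, 0.5]` 1/Angstrom, covering `q R_G` well
#' past the informative mid-q band for protein-sized radii of gyration.
#'
#' @param qmin,qmax grid limits, 1/Angstrom.
#' @param n number of points.
#' @return Numeric vector.
#' @export
default_q_grid <- function(qmin = 0, qmax = 0.5, n = 101L) {
  seq(qmin, qmax, length.out = n)
}

#' Scattering profile container
#'
#' @param q strictly increasing grid of momentum-transfer values, 1/Angstrom,
#'   with `q[1] >= 0`.
#' @param intensity per-q intensities (arbitrary units).
#' @param error optional per-q standard deviations, same units.
#' @param label free text.
#' @return An object of class `sas_profile`.
#' @export
sas_profile <- function(q, intensity, error = NULL, label = "") {
  q <- check_q_grid(q)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(q)) stopf("intensity length must match q")
  if (!all(is.finite(intensity))) stopf("intensities must be finite")
  if (!is.null(error)) {
    error <- as.numeric(error)
    if (length(error) != length(q)) stopf("error length must match q")
    if (any(error < 0)) stopf("errors must be non-negative")
  }
  structure(list(q = q, intensity = intensity, error = error,
                 label = as.character(label)[1]),
            class = "sas_profile")
}

#' @export
print.sas_profile <- function(x, ...) {
  cat(sprintf("<sas_profile> %s: %d points, q in [%.4g, %.4g] 1/A, I(qmin) = %.6g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q), x$intensity[1]))
  invisible(x)
}

#' @export
plot.sas_profile <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$intensity, type = "l", log = log,
                 xlab = "q (1/A)", ylab = "I(q) (a.u.)", ...)
  invisible(x)
}

# unordered atom pair index (k < l) in stats::dist order, plus flat distances
pair_index <- function(s) {
  n <- n_atoms(s)
  if (n < 2L)
    return(list(pairs = matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("k", "l"))),
                d = numeric()))
  k <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  l <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  pairs <- cbind(k = k, l = l)
  list(pairs = pairs, d = as.numeric(stats::dist(s$xyz)))
}

#' Exact Debye intensity of a rigid structure
#'
#' Orientationally averaged scattering intensity
#' \deqn{I(q) = \sum_k \sum_l f_k(q) f_l(q) \,\mathrm{sinc}(q d_{kl})}
#' over all ordered atom pairs (the `k = l` self terms contribute
#' `sinc(0) = 1`). Computed over unordered pairs with a factor 2 plus the
#' diagonal; `I(0) = (sum_k f_k(0))^2`.
#'
#' @param s a `sas_structure`.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param chunk number of atom pairs processed per block (memory control).
#' @return A `sas_profile`.
#' @export
debye_intensity <- function(s, q = default_q_grid(), ff = ff_model(),
                            chunk = 200000L) {
  q <- check_q_grid(q)
  F <- ff_eval(ff, s, q)
  I <- rowSums(F^2)
  n <- n_atoms(s)
  if (n >= 2L) {
    px <- pair_index(s)
    P <- nrow(px$pairs)
    for (lo in seq(1L, P, by = chunk)) {
      hi <- min(lo + chunk - 1L, P)
      idx <- lo:hi
      S <- sinc(outer(q, px$d[idx]))
      W <- F[, px$pairs[idx, "k"], drop = FALSE] *
           F[, px$pairs[idx, "l"], drop = FALSE]
      I <- I + 2 * rowSums(W * S)
    }
  }
  sas_profile(q, I, label = s$label)
}

#' Read a scattering profile from a 3-column text file
#'
#' The common SAXS `.dat` dialect: whitespace-separated columns `q I [err]`,
#' `#` starts a comment.
#'
#' @param path file path.
#' @return A `sas_profile` (with errors if a third column is present).
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stopf("profile file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stopf("profile file needs at least 2 columns (q, I)")
  err <- if (ncol(tab) >= 3L) tab[[3]] else NULL
  sas_profile(tab[[1]], tab[[2]], error = err,
              label = sub("\\.dat$", "", basename(path)))
}

#' Write a scattering profile to a 3-column text file
#'
#' @param p a `sas_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q(1/A) I(a.u.)%s", if (!is.null(p$error)) " err" else ""), con)
  if (is.null(p$error)) {
    writeLines(sprintf("%.8e %.8e", p$q, p$intensity), con)
  } else {
    writeLines(sprintf("%.8e %.8e %.8e", p$q, p$intensity, p$error), con)
  }
  invisible(path)
}
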