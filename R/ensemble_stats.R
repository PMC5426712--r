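#' Per-conformer profile set
#'
#' Holds the scattering profiles of an explicit conformer ensemble on a shared
#' q grid, with optional per-conformer weights.
#'
#' @param q shared momentum-transfer grid, 1/Angstrom.
#' @param intensities matrix with one row per conformer, one column per q.
#' @param labels optional per-conformer labels.
#' @param weights optional non-negative per-conformer weights (default
#'   uniform); stored unnormalized, normalized where used.
#' @return An object of class `sas_ensemble`.
#' @export
sas_ensemble <- function(q, intensities, labels = NULL, weights = NULL) {
  q <- check_q_grid(q)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(q)) stopf("intensity columns must match q grid")
  m <- nrow(intensities)
  if (m < 1L) stopf("at least one conformer is required")
  labels <- labels %||% sprintf("conformer_%d", seq_len(m))
  if (length(labels) != m) stopf("labels length must match conformer count")
  weights <- weights %||% rep(1, m)
  if (length(weights) != m || any(weights < 0) || sum(weights) == 0)
    stopf("weights must be non-negative, one per conformer, not all zero")
  structure(list(q = q, intensities = unname(intensities),
                 labels = as.character(labels), weights = as.numeric(weights)),
            class = "sas_ensemble")
}

#' @export
print.sas_ensemble <- function(x, ...) {
  cat(sprintf("<sas_ensemble> %d conformers x %d q points, q in [%.4g, %.4g] 1/A\n",
              nrow(x$intensities), length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Compute per-conformer Debye profiles for an ensemble
#'
#' One exact [debye_intensity()] profile per conformer, in input order, on a
#' shared grid. Conformers may have different atom/element compositions
#' (disordered-protein ensembles sometimes do).
#'
#' @param structures non-empty list of `sas_structure`s.
#' @param q shared momentum-transfer grid, 1/Angstrom.
#' @param ff an [ff_model()].
#' @param weights optional per-conformer weights.
#' @return A `sas_ensemble`.
#' @export
ensemble_profiles <- function(structures, q = default_q_grid(),
                              ff = ff_model(), weights = NULL) {
  if (inherits(structures, "sas_structure")) structures <- list(structures)
  if (length(structures) == 0L) stopf("empty conformer list")
  q <- check_q_grid(q)
  I <- t(vapply(structures,
                function(s) debye_intensity(s, q, ff)$intensity,
                numeric(length(q))))
  labs <- vapply(structures, function(s) s$label, character(1))
  labs[!nzchar(labs)] <- sprintf("conformer_%d", which(!nzchar(labs)))
  sas_ensemble(q, I, labels = labs, weights = weights)
}

#' Sample mean and covariance of an ensemble of profiles
#'
#' Weighted mean and unbiased sample covariance of the per-conformer
#' intensities. For uniform weights the usual `M - 1` denominator is used;
#' for general weights the effective-sample-size correction
#' `1 - sum(w_m^2)` (weights normalized to 1) replaces it.
#'
#' @param e a `sas_ensemble` with at least 2 conformers.
#' @return `list(mean = <sas_profile>, cov = <sas_cov>)`.
#' @export
sample_mean_cov <- function(e) {
  M <- nrow(e$intensities)
  if (M < 2L) stopf("covariance needs at least 2 conformers")
  w <- e$weights / sum(e$weights)
  mu <- colSums(e$intensities * w)
  X <- sweep(e$intensities, 2, mu)
  V <- crossprod(X * w, X) / (1 - sum(w^2))
  list(mean = sas_profile(e$q, mu, label = "ensemble mean"),
       cov = sas_cov(e$q, (V + t(V)) / 2, label = "ensemble covariance"))
}

#' Relative standard deviation of an ensemble profile
#'
#' `sqrt(diag(cov)) / mean`, pointwise: the SD as a fraction of the mean
#' intensity. The returned profile carries the grid mean and the location of
#' the maximum as attributes `mean_rel_sd` and `argmax_q`.
#'
#' @param mean a `sas_profile` of mean intensities (must be positive).
#' @param cov the matching `sas_cov`.
#' @return A dimensionless `sas_profile`.
#' @export
relative_sd <- function(mean, cov) {
  if (!isTRUE(all.equal(mean$q, cov$q))) stopf("mean and covariance grids differ")
  if (any(mean$intensity <= 0)) stopf("mean intensity must be positive at every q")
  d <- diag(cov$cov)
  if (any(d < -1e-12 * max(abs(d), 1e-300)))
    numerical_error("negative variance on the covariance diagonal")
  r <- sqrt(pmax(d, 0)) / mean$intensity
  out <- sas_profile(mean$q, r, label = "relative SD")
  attr(out, "mean_rel_sd") <- mean(r)
  attr(out, "argmax_q") <- mean$q[which.max(r)]
  out
}

#' Pointwise confidence band of an ensemble profile
#'
#' `mean +/- level_sd * sqrt(diag(cov))` at every q, e.g. `level_sd = 1` for
#' the 68% band of a Gaussian ensemble.
#'
#' @param mean a `sas_profile`.
#' @param cov the matching `sas_cov`.
#' @param level_sd non-negative SD multiplier.
#' @return An object of class `sas_band`: list with `q`, `mean`, `sd`,
#'   `lower`, `upper`, `level_sd`.
#' @export
confidence_band <- function(mean, cov, level_sd = 1) {
  if (!isTRUE(all.equal(mean$q, cov$q))) stopf("mean and covariance grids differ")
  if (!is_scalar_number(level_sd) || level_sd < 0)
    stopf("level_sd must be a non-negative scalar")
  d <- diag(cov$cov)
  if (any(d < -1e-12 * max(abs(d), 1e-300)))
    numerical_error("negative variance on the covariance diagonal")
  sd_ <- sqrt(pmax(d, 0))
  structure(list(q = mean$q, mean = mean$intensity, sd = sd_,
                 lower = mean$intensity - level_sd * sd_,
                 upper = mean$intensity + level_sd * sd_,
                 level_sd = level_sd),
            class = "sas_band")
}

#' @export
print.sas_band <- function(x, ...) {
  cat(sprintf("<sas_band> %d points, +/- %g SD, max rel. width %.3g\n",
              length(x$q), x$level_sd,
              max((x$upper - x$lower) / pmax(abs(x$mean), 1e-300))))
  invisible(x)
}

#' Compare an ensemble band with an experimental profile
#'
#' Interpolates the model ensemble SD (linearly in intensity vs q) onto the
#' experimental grid, restricted to the overlapping q range, and flags every
#' experimental point where the ensemble SD exceeds the experimental error -
#' i.e. where ensemble averaging is in principle detectable above the noise.
#'
#' @param band a `sas_band` from [confidence_band()].
#' @param experimental a `sas_profile` with per-point errors.
#' @return A data frame with columns `q`, `model_sd`, `exp_err`, `flagged`;
#'   attribute `flagged_ranges` gives the contiguous flagged q intervals.
#' @export
compare_to_experiment <- function(band, experimental) {
  if (is.null(experimental$error))
    stopf("experimental profile has no error column")
  qe <- experimental$q
  keep <- qe >= min(band$q) & qe <= max(band$q)
  if (!any(keep)) stopf("no overlap between model and experimental q ranges")
  qe <- qe[keep]
  sd_m <- stats::approx(band$q, band$sd, xout = qe)$y
  err <- experimental$error[keep]
  flagged <- sd_m > err
  out <- data.frame(q = qe, model_sd = sd_m, exp_err = err, flagged = flagged)
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rngs <- cbind(q_lo = qe[starts[runs$values]], q_hi = qe[ends[runs$values]])
  attr(out, "flagged_ranges") <- rngs
  out
}

#' Write an ensemble to the binary container
#'
#' Compressed self-describing container with arrays `q`, `intensities`,
#' `weights`, `labels`; bit-exact round-trip via [read_ensemble_bin()].
#'
#' @param e a `sas_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_bin <- function(e, path) {
  saveRDS(list(container = "sascov-ensemble", version = 1L, q = e$q,
               intensities = e$intensities, weights = e$weights,
               labels = e$labels),
          path, compress = "gzip")
  invisible(path)
}

#' Read an ensemble from the binary container
#' @param path file written by [write_ensemble_bin()].
#' @return A `sas_ensemble`.
#' @export
read_ensemble_bin <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "sascov-ensemble"))
    stopf("%s is not an ensemble container", path)
  sas_ensemble(x$q, x$intensities, labels = x$labels, weights = x$weights)
}
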