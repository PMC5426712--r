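#' Mutual information of two correlated profile points
#'
#' For jointly Gaussian intensities with correlation `rho`, the mutual
#' information is `-0.5 * log(1 - rho^2)` in nats (natural log; any other base
#' rescales all values by a constant). High mutual information between
#' neighbouring points means the profile is redundant there, i.e. its local
#' information content is low.
#'
#' @param rho correlation value(s) in `(-1, 1)` (vectorized). `NaN` passes
#'   through as `NaN`.
#' @return Mutual information in nats. `|rho| >= 1` returns the largest
#'   representable double and sets the attribute `saturated` (with a warning).
#' @export
mutual_information <- function(rho) {
  out <- rep(NaN, length(rho))
  sat <- !is.na(rho) & abs(rho) >= 1
  ok <- !is.na(rho) & !sat
  out[ok] <- -0.5 * log1p(-rho[ok]^2)
  if (any(sat)) {
    out[sat] <- .Machine$double.xmax
    attr(out, "saturated") <- sat
    warning("|rho| >= 1: mutual information saturated to .Machine$double.xmax")
  }
  out
}

#' Mutual information along an off-diagonal of the correlation matrix
#'
#' Applies [mutual_information()] to `rho(q_i, q_{i+offset})` for every valid
#' `i`, profiling the redundancy between neighbouring profile points along q.
#'
#' @param c a `sas_corr`.
#' @param offset off-diagonal in grid steps (>= 1).
#' @return Data frame with columns `q` (the lower point `q_i`) and `mi`
#'   (nats); rows where the correlation is undefined carry `NaN`.
#' @export
neighbor_mi_profile <- function(c, offset = 1L) {
  n <- length(c$q)
  offset <- as.integer(offset)
  if (offset < 1L) stopf("offset must be >= 1")
  if (offset >= n) stopf("offset (%d) must be smaller than the grid length (%d)", offset, n)
  i <- seq_len(n - offset)
  r <- c$rho[cbind(i, i + offset)]
  data.frame(q = c$q[i], mi = suppressWarnings(as.numeric(mutual_information(r))))
}

#' Correlation bandwidth along the diagonal
#'
#' For each grid point `q_i`, the q-width of the maximal contiguous run of
#' points around the diagonal whose correlation with `q_i` stays at or above
#' the threshold. A wide band means neighbouring points are redundant (low
#' information density); the band is narrowest where the profile is most
#' informative. The width of the identity matrix is 0 (only the diagonal
#' passes); an all-ones matrix gives the full grid span.
#'
#' @param c a `sas_corr`.
#' @param threshold correlation threshold in `(0, 1)` (default 0.5; the
#'   location of the bandwidth minimum is insensitive to this choice).
#' @return Data frame of class `sas_bandwidth` with columns `q`, `width`
#'   (1/Angstrom) and attribute `threshold`. Undefined diagonal entries
#'   (`q = 0`) carry `NA` width.
#' @export
bandwidth_profile <- function(c, threshold = 0.5) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly between 0 and 1")
  n <- length(c$q)
  width <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(c$rho[i, i])) next
    lo <- i
    while (lo > 1L && !is.na(c$rho[i, lo - 1L]) && c$rho[i, lo - 1L] >= threshold)
      lo <- lo - 1L
    hi <- i
    while (hi < n && !is.na(c$rho[i, hi + 1L]) && c$rho[i, hi + 1L] >= threshold)
      hi <- hi + 1L
    width[i] <- c$q[hi] - c$q[lo]
  }
  out <- data.frame(q = c$q, width = width)
  attr(out, "threshold") <- threshold
  class(out) <- c("sas_bandwidth", "data.frame")
  out
}

#' Global minimum of the correlation matrix
#'
#' Smallest defined correlation entry, with ties broken by the smallest
#' `(q_i, q_j)` pair lexicographically.
#'
#' @param c a `sas_corr`.
#' @return `list(q_i =, q_j =, rho_min =)` with `q_i <= q_j`.
#' @export
min_correlation <- function(c) {
  ok <- which(!is.na(c$rho), arr.ind = TRUE)
  if (nrow(ok) == 0L) stopf("correlation matrix has no defined entries")
  vals <- c$rho[ok]
  m <- min(vals)
  cand <- ok[vals == m, , drop = FALSE]
  ij <- t(apply(cand, 1, sort))
  ord <- order(ij[, 1], ij[, 2])
  best <- ij[ord[1], ]
  list(q_i = c$q[best[1]], q_j = c$q[best[2]], rho_min = m)
}

#' Write per-q information diagnostics as a TSV table
#'
#' Tab-separated table with header: q, bandwidth at the given threshold, and
#' first-off-diagonal mutual information.
#'
#' @param c a `sas_corr`.
#' @param path output path.
#' @param threshold bandwidth threshold.
#' @return `path`, invisibly.
#' @export
write_info_table <- function(c, path, threshold = 0.5) {
  bw <- bandwidth_profile(c, threshold)
  mi <- neighbor_mi_profile(c, 1L)
  tab <- data.frame(q = bw$q,
                    bandwidth = bw$width,
                    neighbor_mi = c(mi$mi, NA_real_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# correlation bandwidth threshold: %g", threshold), con)
  suppressWarnings(utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                                      quote = FALSE))
  invisible(path)
}
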