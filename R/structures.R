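#' Atomic structure container
#'
#' A `sas_structure` holds an ordered set of atoms: element symbols, Cartesian
#' coordinates in Angstrom, optional per-atom thermal deviations `tau`
#' (the standard deviation of the isotropic Gaussian displacement of each
#' coordinate, in Angstrom) and occupancy-like weights. Atom order is
#' preserved everywhere; pair indices `(k, l)` always refer to this order.
#'
#' @param xyz numeric matrix with one row per atom and 3 columns (Angstrom).
#' @param element character vector of element symbols, one per atom.
#' @param tau optional non-negative numeric vector (or scalar, recycled) of
#'   per-coordinate thermal standard deviations in Angstrom. `NULL` means
#'   "not assigned"; the thermal-ensemble functions require it.
#' @param weight occupancy-like weight in `[0, 1]`, recycled to all atoms.
#' @param nhyd integer count of hydrogens folded into each atom's effective
#'   form factor (see [read_pdb()]'s `hydrogens = "fold"`).
#' @param bfactor optional numeric vector of crystallographic B-factors
#'   (Angstrom^2), kept so [assign_tau()] can convert them.
#' @param label free-text label.
#' @return An object of class `sas_structure`.
#' @export
sas_structure <- function(xyz, element, tau = NULL, weight = 1, nhyd = 0L,
                          bfactor = NULL, label = "") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1L) stopf("a structure needs at least 1 atom")
  if (!all(is.finite(xyz))) stopf("atom coordinates must be finite")
  element <- as.character(element)
  if (length(element) != n) stopf("element must have one entry per atom")
  if (!is.null(tau)) {
    tau <- rep_len(as.numeric(tau), n)
    if (anyNA(tau) || any(tau < 0)) stopf("tau must be non-negative")
  }
  weight <- rep_len(as.numeric(weight), n)
  if (any(weight < 0 | weight > 1)) stopf("weights must lie in [0, 1]")
  nhyd <- rep_len(as.integer(nhyd), n)
  if (!is.null(bfactor)) bfactor <- rep_len(as.numeric(bfactor), n)
  structure(
    list(xyz = unname(xyz), element = element, tau = tau, weight = weight,
         nhyd = nhyd, bfactor = bfactor, label = as.character(label)[1]),
    class = "sas_structure"
  )
}

#' @export
print.sas_structure <- function(x, ...) {
  cat(sprintf("<sas_structure> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d atoms (%s)\n", n_atoms(x),
              paste(names(sort(table(x$element), decreasing = TRUE)), collapse = ", ")))
  if (is.null(x$tau)) cat("  tau: not assigned\n")
  else cat(sprintf("  tau: [%.3g, %.3g] A\n", min(x$tau), max(x$tau)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `sas_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$xyz)

# residue names treated as water when filtering PDB records
.water_resids <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3", "TIP4")

#' Read atomic structures from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), optionally splitting multi-model
#' files (MODEL/ENDMDL blocks) into one structure per model. Coordinates are
#' in Angstrom. The element is taken from the element column when present,
#' falling back to atom-name heuristics. Waters and other heteroatoms are
#' excluded by default: solvation is handled through form-factor corrections,
#' not explicit solvent.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` returns a single `sas_structure` from the
#'   first model; `"all"` returns a list with one structure per model.
#' @param keep_het keep non-water HETATM records? Default `FALSE`.
#' @param keep_waters keep water records? Default `FALSE`.
#' @param hydrogens `"keep"` retains hydrogens as explicit atoms; `"fold"`
#'   removes them and adds their scattering to the nearest heavy atom
#'   (incrementing its `nhyd` count); `"drop"` discards them.
#' @return A `sas_structure`, or a list of them when `model_policy = "all"`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all"),
                     keep_het = FALSE, keep_waters = FALSE,
                     hydrogens = c("keep", "fold", "drop")) {
  model_policy <- match.arg(model_policy)
  hydrogens <- match.arg(hydrogens)
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stopf("could not parse PDB file %s: %s", path,
                              conditionMessage(e)))
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  is_water <- toupper(at$resid) %in% .water_resids
  keep[is_water & !keep_waters] <- FALSE
  keep[!is_water & at$type == "HETATM" & !keep_het] <- FALSE
  if (!any(keep)) stopf("zero atoms after filtering records of %s", path)

  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) {
    guessed <- suppressWarnings(bio3d::atom2ele(at$elety[miss]))
    bad <- is.na(guessed) | !nzchar(guessed)
    if (any(bad)) {
      i <- which(miss)[which(bad)[1]]
      stopf("unknown element for record %d (atom name '%s')", i, at$elety[i])
    }
    elem[miss] <- guessed
  }
  elem <- trimws(elem)
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, nchar(elem))))

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  base <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)

  one <- function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    s <- sas_structure(co, elem[keep], bfactor = at$b[keep],
                       label = if (n_models > 1L) sprintf("%s#%d", base, m) else base)
    switch(hydrogens,
           keep = s,
           drop = drop_hydrogens(s, fold = FALSE),
           fold = drop_hydrogens(s, fold = TRUE))
  }
  if (model_policy == "first") one(1L) else lapply(seq_len(n_models), one)
}

# remove hydrogens, optionally crediting each to its nearest heavy atom
drop_hydrogens <- function(s, fold = TRUE) {
  h <- s$element == "H"
  if (!any(h)) return(s)
  if (all(h)) stopf("structure contains only hydrogens")
  heavy <- which(!h)
  nh <- s$nhyd[heavy]
  if (fold) {
    for (i in which(h)) {
      d2 <- rowSums(sweep(s$xyz[heavy, , drop = FALSE], 2, s$xyz[i, ])^2)
      j <- which.min(d2)
      nh[j] <- nh[j] + 1L + s$nhyd[i]
    }
  }
  sas_structure(s$xyz[heavy, , drop = FALSE], s$element[heavy],
                tau = s$tau[heavy], weight = s$weight[heavy], nhyd = nh,
                bfactor = s$bfactor[heavy], label = s$label)
}

#' Assign per-atom thermal deviations
#'
#' Sets the thermal standard deviation `tau` (Angstrom, per coordinate) of
#' every atom, either to a uniform value or from crystallographic B-factors
#' through the Debye-Waller relation `B = 8 pi^2 tau^2`.
#'
#' @param s a `sas_structure`.
#' @param mode `"uniform"` or `"from-bfactor"`.
#' @param value uniform tau in Angstrom (required for `mode = "uniform"`).
#' @return A copy of `s` with `tau` assigned; the input is not modified.
#' @export
assign_tau <- function(s, mode = c("uniform", "from-bfactor"), value = NULL) {
  mode <- match.arg(mode)
  out <- s
  if (mode == "uniform") {
    if (!is_scalar_number(value) || value < 0)
      stopf("uniform mode needs a single non-negative tau value")
    out$tau <- rep(as.numeric(value), n_atoms(s))
  } else {
    if (is.null(s$bfactor) || anyNA(s$bfactor))
      stopf("from-bfactor mode requires B-factors on every atom")
    if (any(s$bfactor < 0)) stopf("negative B-factor encountered")
    out$tau <- sqrt(s$bfactor / (8 * pi^2))
  }
  out
}

# electron counts for R_G weighting and form-factor sanity checks
.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, X = 1)

#' Radius of gyration
#'
#' Root-mean-square distance of the atoms from their (weighted) centroid.
#'
#' @param s a `sas_structure`.
#' @param weighting `"uniform"` weights every atom equally;
#'   `"electron-count"` weights by the element's electron count (hydrogens
#'   folded via `nhyd` are included).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(s, weighting = c("uniform", "electron-count")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "uniform") rep(1, n_atoms(s)) else {
    z <- .element_z[s$element]
    if (anyNA(z)) stopf("no electron count for element(s): %s",
                        paste(unique(s$element[is.na(z)]), collapse = ", "))
    unname(z) + s$nhyd * .element_z[["H"]]
  }
  w <- w * s$weight
  ctr <- colSums(s$xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(s$xyz, 2, ctr)^2)) / sum(w))
}

#' Root-mean-square deviation between two structures
#'
#' Plain coordinate RMSD over atoms in file order, without superposition.
#'
#' @param a,b `sas_structure`s with equal atom counts.
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) stopf("atom counts differ (%d vs %d)",
                                      n_atoms(a), n_atoms(b))
  sqrt(mean(rowSums((a$xyz - b$xyz)^2)))
}

# optimal rotation (Kabsch, via SVD) mapping centred P onto centred Q
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition of an ensemble onto a reference
#'
#' Least-squares (Kabsch) superposition of each structure onto the reference.
#' Note that Debye intensities are invariant under rigid motion, so alignment
#' only matters for real-space diagnostics, never for scattering profiles.
#'
#' @param ensemble list of `sas_structure`s, all with the same atom count as
#'   `reference`.
#' @param reference a `sas_structure`.
#' @return List of aligned structures (copies; inputs untouched).
#' @export
kabsch_align <- function(ensemble, reference) {
  if (inherits(ensemble, "sas_structure")) ensemble <- list(ensemble)
  nref <- n_atoms(reference)
  cref <- colMeans(reference$xyz)
  Q <- sweep(reference$xyz, 2, cref)
  lapply(ensemble, function(s) {
    if (n_atoms(s) != nref)
      stopf("atom count mismatch: %d vs reference %d", n_atoms(s), nref)
    cs <- colMeans(s$xyz)
    P <- sweep(s$xyz, 2, cs)
    R <- kabsch_rotation(P, Q)
    out <- s
    out$xyz <- sweep(P %*% R, 2, cref, "+")
    out
  })
}

#' Write structures to a (multi-model) PDB file
#'
#' Writes one ATOM record per atom; a list of structures is written as a
#' multi-model file with MODEL/ENDMDL blocks. Assigned thermal deviations are
#' stored in the B-factor column as `8 pi^2 tau^2` (capped at 999.99, the
#' column width limit), so [read_pdb()] + [assign_tau()]`("from-bfactor")`
#' round-trips tau for values below ~3.6 Angstrom.
#'
#' @param s a `sas_structure` or a list of them (equal atom counts).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  models <- if (inherits(s, "sas_structure")) list(s) else s
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    st <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    b <- if (!is.null(st$tau)) pmin(8 * pi^2 * st$tau^2, 999.99)
         else if (!is.null(st$bfactor)) pmin(st$bfactor, 999.99)
         else rep(0, n_atoms(st))
    el <- toupper(st$element)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n_atoms(st)) %% 100000L,
      sprintf(" %-3s", substr(el, 1, 3)), "GLY", "A",
      seq_len(n_atoms(st)) %% 10000L,
      st$xyz[, 1], st$xyz[, 2], st$xyz[, 3], st$weight, b, el)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
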