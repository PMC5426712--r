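# Four-Gaussian vacuum form-factor coefficients (Cromer-Mann parametrization,
# International Tables vol. C) for the elements dominating biomolecules, plus
# a point-atom pseudo-element "X" with f == 1 used throughout the test suite.
# The constant term is re-centred so that f(0) equals the electron count
# exactly (published sums deviate from Z by < 2e-3 e).
# V is the excluded solvent volume per atom in A^3 (Fraser et al. dummy-atom
# volumes); X has V = 0 so solvent corrections never touch it.
.ff_table_default <- local({
  tb <- rbind(
    H = c(0.489918, 0.262003, 0.196767, 0.049879,
          20.6593, 7.74039, 49.5519, 2.20159, 1, 5.15),
    C = c(2.31000, 1.02000, 1.58860, 0.865000,
          20.8439, 10.2075, 0.568700, 51.6512, 6, 16.44),
    N = c(12.2126, 3.13220, 2.01250, 1.16630,
          0.005700, 9.89330, 28.9975, 0.582600, 7, 2.49),
    O = c(3.04850, 2.28680, 1.54630, 0.867000,
          13.2771, 5.70110, 0.323900, 32.9089, 8, 9.13),
    P = c(6.43450, 4.17910, 1.78000, 1.49080,
          1.90670, 27.1570, 0.526000, 68.1645, 15, 5.73),
    S = c(6.90530, 5.20340, 1.43790, 1.58630,
          1.46790, 22.2151, 0.253600, 56.1720, 16, 19.86),
    X = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0)
  )
  colnames(tb) <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "Z", "V")
  df <- as.data.frame(tb)
  df$c <- df$Z - (df$a1 + df$a2 + df$a3 + df$a4)   # enforce f(0) = Z
  df$element <- rownames(tb)
  rownames(df) <- df$element
  df
})

#' Form-factor model
#'
#' Bundles a multi-Gaussian vacuum form-factor table with a simplified solvent
#' correction. The effective factor of an atom is
#' \deqn{f(q) = f_{vac}(q) - c_1 \rho_s V \exp(-q^2 V^{2/3} / 4\pi) + c_2 h}
#' where `V` is the element's dummy-atom excluded volume (A^3), `rho_s` the
#' bulk solvent electron density (e/A^3) and `h = rho_s * 30 A^3` a crude,
#' q-independent hydration addend per atom that treats solvent accessibility
#' as uniform (experimental; default off). This is a deliberately simple
#' excluded-volume model exposing `c1`/`c2`-style knobs; it is not a
#' hydration-layer model.
#'
#' @param parametrization name of the coefficient set (`"cromer-mann"`).
#' @param c1 excluded-volume scale (dimensionless; 0 disables).
#' @param c2 hydration-addend scale (dimensionless; 0 disables; experimental).
#' @param rho_s bulk solvent electron density, e/A^3 (water: 0.334).
#' @param table optional coefficient table, e.g. from [read_ff_table()].
#' @return An object of class `sas_ff`.
#' @export
ff_model <- function(parametrization = "cromer-mann", c1 = 0, c2 = 0,
                     rho_s = 0.334, table = NULL) {
  tab <- table %||% .ff_table_default
  needed <- c("element", "a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "c", "Z", "V")
  if (!all(needed %in% names(tab)))
    stopf("form-factor table lacks columns: %s",
          paste(setdiff(needed, names(tab)), collapse = ", "))
  rownames(tab) <- tab$element
  structure(list(parametrization = parametrization, table = tab,
                 c1 = as.numeric(c1), c2 = as.numeric(c2),
                 rho_s = as.numeric(rho_s)),
            class = "sas_ff")
}

#' Point-atom form-factor model
#'
#' Every supported element scatters with `f == 1` and no solvent correction.
#' Analytic results in the thermal model are form-factor-agnostic, so the
#' test suite uses this model to decouple correctness from the solvation
#' stand-in.
#'
#' @return An `sas_ff` whose factors are identically 1.
#' @export
ff_point <- function() {
  tab <- .ff_table_default
  tab[, c("a1", "a2", "a3", "a4", "V")] <- 0
  tab$c <- 1
  tab$Z <- 1
  ff_model("point", c1 = 0, c2 = 0, table = tab)
}

#' @export
print.sas_ff <- function(x, ...) {
  cat(sprintf("<sas_ff> %s (c1=%g, c2=%g, rho_s=%g e/A^3; elements: %s)\n",
              x$parametrization, x$c1, x$c2, x$rho_s,
              paste(x$table$element, collapse = " ")))
  invisible(x)
}

ff_row <- function(model, element) {
  i <- match(element, model$table$element)
  if (anyNA(i)) stopf("unknown element(s) in form-factor table: %s",
                      paste(unique(element[is.na(i)]), collapse = ", "))
  model$table[i, , drop = FALSE]
}

#' Vacuum form factor of an element
#'
#' Multi-Gaussian fit `f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c`; at `q = 0`
#' it equals the element's electron count.
#'
#' @param element element symbol present in the model's table.
#' @param q momentum transfer, 1/Angstrom (vectorized).
#' @param model an [ff_model()].
#' @return Numeric vector of form-factor values, length of `q`.
#' @export
vacuum_form_factor <- function(element, q, model = ff_model()) {
  if (any(q < 0)) stopf("q must be non-negative")
  r <- ff_row(model, element[1])
  s2 <- (q / (4 * pi))^2
  r$a1 * exp(-r$b1 * s2) + r$a2 * exp(-r$b2 * s2) +
    r$a3 * exp(-r$b3 * s2) + r$a4 * exp(-r$b4 * s2) + r$c
}

#' Effective (solvent-corrected) form factor
#'
#' Vacuum factor minus the scaled dummy-atom excluded-volume term, plus the
#' optional uniform hydration addend (see [ff_model()]). With `c1 = c2 = 0`
#' it reduces to [vacuum_form_factor()] at every `q`.
#'
#' @inheritParams vacuum_form_factor
#' @return Numeric vector, length of `q`.
#' @export
effective_form_factor <- function(element, q, model = ff_model()) {
  r <- ff_row(model, element[1])
  f <- vacuum_form_factor(element, q, model)
  if (model$c1 != 0 && r$V > 0)
    f <- f - model$c1 * model$rho_s * r$V * exp(-q^2 * r$V^(2 / 3) / (4 * pi))
  if (model$c2 != 0)
    f <- f + model$c2 * model$rho_s * 30
  f
}

# effective form factors for all atoms of a structure: |q| x N matrix.
# Folded hydrogens (nhyd) contribute additively.
ff_eval <- function(model, s, q) {
  els <- unique(s$element)
  per_el <- vapply(els, function(e) effective_form_factor(e, q, model),
                   numeric(length(q)))
  per_el <- matrix(per_el, nrow = length(q))
  colnames(per_el) <- els
  F <- per_el[, match(s$element, els), drop = FALSE]
  if (any(s$nhyd > 0)) {
    fh <- effective_form_factor("H", q, model)
    F <- F + outer(fh, as.numeric(s$nhyd))
  }
  F * rep(s$weight, each = length(q))
}

#' Read a form-factor coefficient table from a text file
#'
#' Whitespace-separated table with a header line naming the columns
#' `element a1 a2 a3 a4 b1 b2 b3 b4 c Z V`; `#` starts a comment. Allows
#' alternative parametrizations to be plugged into [ff_model()].
#'
#' @param path file path.
#' @return A data frame usable as the `table` argument of [ff_model()].
#' @export
read_ff_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$element <- as.character(tab$element)
  tab
}
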