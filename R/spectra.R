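# Post-processing of electronic transition tables: Gaussian broadening in
# the wavelength domain, normalisation, peak location, shift and
# intensity-change metrics, and HOMO-LUMO gap bookkeeping.

#' Build or read an electronic transition table
#'
#' A transition table is a tibble with one row per excited state and
#' columns `state`, `lambda_nm` (> 0), `f` (oscillator strength, >= 0),
#' `mu_tr_D` (transition dipole, debye), plus optional `assignment`,
#' `character` and `percent` annotations and an optional logical
#' `predominant` flag.
#'
#' @param state State labels (e.g. `"S1"`).
#' @param lambda_nm Transition wavelengths in nm.
#' @param f Oscillator strengths.
#' @param mu_tr_D Transition dipole moments in debye.
#' @param assignment,character,percent Optional annotations (orbital
#'   assignment, LE/ICT/ECT character, contribution percentage).
#' @param predominant Optional logical flag marking the predominant row.
#' @return A transition tibble.
#' @export
transition_table <- function(state, lambda_nm, f, mu_tr_D = NA_real_,
                             assignment = NA_character_,
                             character = NA_character_,
                             percent = NA_real_, predominant = NULL) {
  if (any(lambda_nm <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(f < 0)) stop("oscillator strengths must be >= 0", call. = FALSE)
  out <- tibble::tibble(state = as.character(state),
                        lambda_nm = as.numeric(lambda_nm),
                        f = as.numeric(f), mu_tr_D = as.numeric(mu_tr_D),
                        assignment = assignment, character = character,
                        percent = percent)
  if (!is.null(predominant)) out$predominant <- predominant
  out
}

#' @rdname transition_table
#' @param path Path to a TSV file with the transition-table columns.
#' @export
read_transitions <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("state", "lambda_nm", "f")
  if (!all(need %in% names(df))) {
    stop("transition table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname transition_table
#' @param transitions A transition tibble to write.
#' @export
write_transitions <- function(transitions, path) {
  readr::write_tsv(transitions, path)
  invisible(path)
}

#' Gaussian broadening of stick transitions
#'
#' Each transition contributes a Gaussian in the wavelength domain with
#' amplitude proportional to its oscillator strength:
#' `I(lambda) = sum_k f_k exp(-4 ln2 (lambda - lambda_k)^2 / fwhm^2)`.
#' The integrated intensity equals `sum_k f_k * fwhm * sqrt(pi / (4 ln2))`
#' (up to grid-edge truncation).
#'
#' @param transitions A transition tibble (see [transition_table()]).
#' @param fwhm Full width at half maximum in nm (default 20).
#' @param from,to,by Wavelength grid in nm (default 120-400 nm at 0.1 nm).
#' @return A `uv_spectrum` tibble with columns `wavelength`, `intensity`
#'   and attributes `fwhm` and `normalized`.
#' @export
broaden <- function(transitions, fwhm = 20, from = 120, to = 400, by = 0.1) {
  if (nrow(transitions) == 0) stop("empty transition list", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  grid <- seq(from, to, by = by)
  k <- 4 * log(2) / fwhm^2
  intensity <- rep(0, length(grid))
  for (i in seq_len(nrow(transitions))) {
    if (transitions$f[i] == 0) next
    intensity <- intensity +
      transitions$f[i] * exp(-k * (grid - transitions$lambda_nm[i])^2)
  }
  out <- tibble::tibble(wavelength = grid, intensity = intensity)
  attr(out, "fwhm") <- fwhm
  attr(out, "normalized") <- FALSE
  class(out) <- c("uv_spectrum", class(tibble::tibble()))
  out
}

#' Normalise a spectrum to unit maximum
#'
#' @param spectrum A `uv_spectrum` tibble.
#' @return The spectrum scaled so its maximum intensity is exactly 1.
#' @export
normalize_spectrum <- function(spectrum) {
  mx <- max(spectrum$intensity)
  if (!is.finite(mx) || mx <= 0) {
    stop("cannot normalise an all-zero spectrum", call. = FALSE)
  }
  spectrum$intensity <- spectrum$intensity / mx
  attr(spectrum, "normalized") <- TRUE
  spectrum
}

#' Wavelength of maximum absorption
#'
#' Returns the wavelength of the global intensity maximum; exact ties are
#' resolved towards the longest wavelength.
#'
#' @param spectrum A `uv_spectrum` tibble (raw or normalised).
#' @return lambda max in nm.
#' @export
lambda_max <- function(spectrum) {
  if (nrow(spectrum) == 0) stop("empty spectrum grid", call. = FALSE)
  mx <- max(spectrum$intensity)
  max(spectrum$wavelength[spectrum$intensity == mx])
}

# the designated predominant row: explicit flag if present, else highest f
.predominant_row <- function(transitions) {
  if ("predominant" %in% names(transitions) &&
      any(transitions$predominant %in% TRUE)) {
    transitions[which(transitions$predominant)[1], , drop = FALSE]
  } else if (nrow(transitions) > 0) {
    transitions[which.max(transitions$f), , drop = FALSE]
  } else {
    stop("transition table has no predominant row", call. = FALSE)
  }
}

#' Predominant-transition wavelength shift
#'
#' Signed shift `lambda(b) - lambda(a)` between the predominant transition
#' of each table (the flagged row, or the highest oscillator strength).
#' Positive shifts are bathochromic (towards red), negative hypsochromic
#' (towards blue); the label is attached as an attribute.
#'
#' @param transitions_a,transitions_b Transition tibbles.
#' @param mode Shift definition; only `"predominant"` is implemented.
#' @return Shift in nm with attribute `label`.
#' @export
transition_shift <- function(transitions_a, transitions_b,
                             mode = "predominant") {
  mode <- match.arg(mode, "predominant")
  la <- .predominant_row(transitions_a)$lambda_nm
  lb <- .predominant_row(transitions_b)$lambda_nm
  shift <- lb - la
  attr(shift, "label") <- if (shift > 0) "bathochromic" else
    if (shift < 0) "hypsochromic" else "none"
  shift
}

#' Relative change between two values
#'
#' `100 * (b - a) / a`, used for oscillator-strength and transition-dipole
#' changes on complexation.
#'
#' @param value_a Baseline value (non-zero).
#' @param value_b New value.
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(0.5465, 0.4545) # about -17 percent
percent_change <- function(value_a, value_b) {
  if (any(value_a == 0)) stop("zero baseline in percent change",
                              call. = FALSE)
  100 * (value_b - value_a) / value_a
}

#' HOMO-LUMO gap from an orbital energy table
#'
#' The gap is `E(LUMO) - E(HOMO)`, taking the highest-energy occupied
#' entry and the lowest-energy unoccupied entry when degenerate labels are
#' present. A non-positive gap (occupied above unoccupied) is rejected.
#'
#' @param orbital_table Tibble with columns `label` (e.g. `"HOMO"`,
#'   `"HOMO-1"`, `"LUMO"`, `"LUMO+2"`) and `energy_ev`.
#' @return Gap in eV.
#' @export
#' @examples
#' homo_lumo_gap(tibble::tibble(label = c("HOMO", "LUMO"),
#'                              energy_ev = c(-9.0, 0.76)))
homo_lumo_gap <- function(orbital_table) {
  stopifnot(all(c("label", "energy_ev") %in% names(orbital_table)))
  occ <- grepl("^HOMO(-[0-9]+)?$", orbital_table$label)
  vir <- grepl("^LUMO(\\+[0-9]+)?$", orbital_table$label)
  if (!any(occ) || !any(vir)) {
    stop("orbital table must contain HOMO and LUMO entries", call. = FALSE)
  }
  gap <- min(orbital_table$energy_ev[vir]) -
    max(orbital_table$energy_ev[occ])
  if (gap <= 0) stop("HOMO lies above LUMO; not a closed-shell gap",
                     call. = FALSE)
  gap
}
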