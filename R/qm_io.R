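#' Molecular-orbital spectrum
#'
#' An ordered set of molecular-orbital energies with per-orbital occupation
#' numbers, the source of the frontier (HOMO/LUMO) energies.  Energies are
#' stored in eV, ascending; occupations are 0, 1 or 2 electrons.
#'
#' @param energies numeric vector of orbital energies in eV.
#' @param occupations integer-like vector of the same length with values in
#'   \{0, 1, 2\}.
#' @return An object of class `orbital_spectrum` with fields `energies`,
#'   `occupations` and `n_electrons`.
#' @examples
#' sp <- orbital_spectrum(c(-10, -6.24, -1.733, 0.5), c(2, 2, 0, 0))
#' sp$n_electrons
#' @export
orbital_spectrum <- function(energies, occupations) {
  energies <- as.numeric(energies)
  occupations <- as.numeric(occupations)
  if (length(energies) == 0L)
    stop("orbital spectrum needs at least one orbital", call. = FALSE)
  if (length(energies) != length(occupations))
    stop("energies and occupations differ in length", call. = FALSE)
  if (any(!is.finite(energies)))
    stop("non-finite orbital energy", call. = FALSE)
  if (!all(occupations %in% c(0, 1, 2)))
    stop("occupations must be 0, 1 or 2 electrons", call. = FALSE)
  if (is.unsorted(energies)) {
    ord <- order(energies)
    energies <- energies[ord]
    occupations <- occupations[ord]
  }
  if (sum(occupations) < 1)
    stop("spectrum has no occupied orbital", call. = FALSE)
  structure(
    list(energies = energies, occupations = occupations,
         n_electrons = as.integer(round(sum(occupations)))),
    class = "orbital_spectrum")
}

#' @export
print.orbital_spectrum <- function(x, ...) {
  cat(sprintf("<orbital_spectrum: %d orbitals, %d electrons>\n",
              length(x$energies), x$n_electrons))
  occ <- x$energies[x$occupations > 0]
  vir <- x$energies[x$occupations == 0]
  if (length(occ)) cat(sprintf("  HOMO %10.4f eV\n", max(occ)))
  if (length(vir)) cat(sprintf("  LUMO %10.4f eV\n", min(vir)))
  invisible(x)
}

#' Parse an orbital-energy listing
#'
#' Reads an orbital-energy block in the package's plain-text fixture dialect
#' (`"qcf"`).  The dialect is line-oriented: `#` starts a comment,
#' `unit eV|hartree` sets the energy unit (default eV), and each orbital is
#' one `orbital <energy> <occupation>` line.  Energies given in hartree are
#' converted to eV.
#'
#' @param text a file path, or a character vector of lines (or one string
#'   with embedded newlines).
#' @param dialect input dialect; only `"qcf"` is built in.
#' @return An [orbital_spectrum].
#' @examples
#' txt <- c("unit eV", "orbital -10.0 2", "orbital -6.240 2",
#'          "orbital -1.733 0", "orbital 0.5 0")
#' parse_orbital_energies(txt)
#' @seealso [format_orbital_energies()] for the inverse.
#' @export
parse_orbital_energies <- function(text, dialect = "qcf") {
  if (!identical(dialect, "qcf"))
    stop("unrecognized orbital dialect: ", dialect, call. = FALSE)
  lines <- .as_lines(text)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unit <- "ev"
  energies <- numeric(0)
  occupations <- numeric(0)
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tolower(tok[1])
    if (key == "unit") {
      unit <- tolower(tok[2])
      if (!unit %in% c("ev", "hartree"))
        stop("unknown energy unit: ", tok[2], call. = FALSE)
    } else if (key == "orbital") {
      if (length(tok) < 3L)
        stop("malformed orbital line: ", ln, call. = FALSE)
      energies <- c(energies, as.numeric(tok[2]))
      occupations <- c(occupations, as.numeric(tok[3]))
    }
    # other keys are tolerated so spectra can live inside larger qcf files
  }
  if (length(energies) == 0L)
    stop("no orbital block found", call. = FALSE)
  if (unit == "hartree") energies <- hartree_to_ev(energies)
  orbital_spectrum(energies, occupations)
}

#' Serialize an orbital spectrum to the qcf fixture dialect
#'
#' @param spectrum an [orbital_spectrum].
#' @return Character vector of qcf lines; `parse_orbital_energies()` on the
#'   result reproduces the spectrum.
#' @export
format_orbital_energies <- function(spectrum) {
  stopifnot(inherits(spectrum, "orbital_spectrum"))
  c("unit eV",
    sprintf("orbital %.10g %g", spectrum$energies, spectrum$occupations))
}

#' Per-atom partial charges of one electronic state
#'
#' @param scheme charge-partition scheme name (e.g. `"mulliken"`,
#'   `"hirshfeld"`); kept explicit because condensed Fukui values depend on
#'   it.
#' @param atom_labels element symbols, 1-based order of the atom list.
#' @param q per-atom partial charges in elementary charge units.
#' @param net_charge total molecular charge the set must sum to.
#' @param tol validation tolerance on `|sum(q) - net_charge|`.
#' @return An object of class `charge_set`.
#' @examples
#' charge_set("mulliken", c("O", "H", "H"), c(-0.8, 0.4, 0.4), 0)
#' @export
charge_set <- function(scheme, atom_labels, q, net_charge = 0, tol = 1e-3) {
  q <- as.numeric(q)
  if (length(q) == 0L) stop("empty charge set", call. = FALSE)
  if (length(atom_labels) != length(q))
    stop("atom_labels and q differ in length", call. = FALSE)
  if (abs(sum(q) - net_charge) > tol)
    stop(sprintf("charges sum to %.6f, expected net charge %g", sum(q),
                 net_charge), call. = FALSE)
  structure(
    list(scheme = tolower(scheme), atom_labels = as.character(atom_labels),
         q = q, net_charge = net_charge),
    class = "charge_set")
}

#' A single quantum-chemistry result record
#'
#' Bundles what one electronic-structure calculation yields for one species
#' or conformer: the total electronic energy (hartree), and optionally the
#' orbital spectrum, vibrational frequencies (cm^-1, imaginary modes
#' negative) and per-atom charge sets.
#'
#' @param label species/conformer identifier.
#' @param total_energy total electronic energy in hartree.
#' @param net_charge integer molecular charge.
#' @param multiplicity spin multiplicity (>= 1).
#' @param spectrum optional [orbital_spectrum].
#' @param frequencies optional numeric vector of cm^-1 values.
#' @param charges optional [charge_set] or list of charge sets.
#' @return An object of class `qm_result`.
#' @export
qm_result <- function(label, total_energy, net_charge = 0, multiplicity = 1,
                      spectrum = NULL, frequencies = NULL, charges = NULL) {
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  if (!is.numeric(total_energy) || length(total_energy) != 1L ||
      !is.finite(total_energy))
    stop("total_energy must be one finite number (hartree)", call. = FALSE)
  if (!is.null(spectrum)) stopifnot(inherits(spectrum, "orbital_spectrum"))
  if (inherits(charges, "charge_set")) charges <- list(charges)
  structure(
    list(label = as.character(label), total_energy = total_energy,
         net_charge = as.integer(net_charge),
         multiplicity = as.integer(multiplicity),
         spectrum = spectrum, frequencies = frequencies, charges = charges),
    class = "qm_result")
}

#' Certify a stationary point as a real minimum
#'
#' A structure is a true minimum of the potential-energy surface when its
#' vibrational analysis yields no imaginary mode.  Imaginary frequencies are
#' encoded, as in most electronic-structure logs, as negative cm^-1 values.
#'
#' @param frequencies numeric vector of vibrational frequencies in cm^-1.
#' @return `TRUE` iff every frequency is strictly positive.
#' @examples
#' check_minimum(c(12.3, 85.0, 1650.2))  # TRUE
#' check_minimum(c(-15.4, 85.0))         # FALSE: one imaginary mode
#' @export
check_minimum <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0L)
    stop("empty frequency list: cannot certify a minimum", call. = FALSE)
  if (any(!is.finite(frequencies)))
    stop("non-finite frequency", call. = FALSE)
  all(frequencies > 0)
}

#' Select the lowest-energy conformer
#'
#' @param results a list of [qm_result] records sharing net charge and
#'   multiplicity.
#' @return The element with the minimum `total_energy`; exact ties go to the
#'   earliest list position.
#' @examples
#' a <- qm_result("c1", -1517.422)
#' b <- qm_result("c2", -1517.410)
#' select_lowest_conformer(list(b, a))$label  # "c1"
#' @export
select_lowest_conformer <- function(results) {
  if (length(results) == 0L) stop("empty conformer list", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "qm_result")))
  qs <- vapply(results, function(r) r$net_charge, integer(1))
  ms <- vapply(results, function(r) r$multiplicity, integer(1))
  if (length(unique(qs)) > 1L || length(unique(ms)) > 1L)
    stop("conformers mix net charge or multiplicity", call. = FALSE)
  es <- vapply(results, function(r) r$total_energy, numeric(1))
  results[[which.min(es)]]   # which.min takes the first position on ties
}

# Accept a path, a single string with newlines, or a vector of lines.
.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}
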