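#' Frontier-orbital energies
#'
#' @param e_homo energy of the highest occupied molecular orbital (eV).
#' @param e_lumo energy of the lowest unoccupied molecular orbital (eV);
#'   must lie strictly above `e_homo`.
#' @return An object of class `cdft_frontier`.
#' @examples
#' frontier_energies(-6.240, -1.733)
#' @export
frontier_energies <- function(e_homo, e_lumo) {
  stopifnot(is.finite(e_homo), is.finite(e_lumo))
  if (e_lumo <= e_homo)
    stop("degenerate frontier: LUMO must lie strictly above HOMO",
         call. = FALSE)
  structure(list(e_homo = as.numeric(e_homo), e_lumo = as.numeric(e_lumo)),
            class = "cdft_frontier")
}

#' @export
print.cdft_frontier <- function(x, ...) {
  cat(sprintf("<frontier: HOMO %.3f eV, LUMO %.3f eV, gap %.3f eV>\n",
              x$e_homo, x$e_lumo, x$e_lumo - x$e_homo))
  invisible(x)
}

#' Extract frontier energies from an orbital spectrum
#'
#' HOMO is the highest-energy orbital holding any electrons; LUMO the
#' lowest-energy empty orbital.
#'
#' @param spectrum an [orbital_spectrum].
#' @return A [frontier_energies] object.
#' @export
frontier_from_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "orbital_spectrum"))
  occ <- spectrum$energies[spectrum$occupations > 0]
  vir <- spectrum$energies[spectrum$occupations == 0]
  if (length(occ) == 0L) stop("no occupied orbital", call. = FALSE)
  if (length(vir) == 0L)
    stop("fully occupied spectrum: no unoccupied orbital", call. = FALSE)
  frontier_energies(max(occ), min(vir))
}

#' Vertical ionization potential and electron affinity (Koopmans)
#'
#' Within the Koopmans-in-DFT approximation, I = -e_HOMO and A = -e_LUMO.
#' A negative A (unbound anion, e_LUMO > 0) is allowed and passed through.
#'
#' @param f a [frontier_energies] object.
#' @return Named numeric `c(I = , A = )` in eV.
#' @examples
#' vertical_ia(frontier_energies(-6.240, -1.733))  # I = 6.240, A = 1.733
#' @export
vertical_ia <- function(f) {
  stopifnot(inherits(f, "cdft_frontier"))
  c(I = -f$e_homo, A = -f$e_lumo)
}

#' Ionization potential and electron affinity by total-energy differences
#'
#' The Delta-SCF route: I = E(N-1) - E(N), A = E(N) - E(N+1), from the total
#' electronic energies of the neutral, cation and anion at one geometry.
#'
#' @param e_n,e_nm1,e_np1 total energies of the N, N-1 and N+1 electron
#'   states.
#' @param unit `"hartree"` (default) or `"ev"`.
#' @return Named numeric `c(I = , A = )` in eV.
#' @export
finite_difference_ia <- function(e_n, e_nm1, e_np1, unit = c("hartree", "ev")) {
  unit <- match.arg(unit)
  for (e in list(e_n, e_nm1, e_np1))
    if (!is.numeric(e) || length(e) != 1L || !is.finite(e))
      stop("all three total energies are required", call. = FALSE)
  ia <- c(I = e_nm1 - e_n, A = e_n - e_np1)
  if (unit == "hartree") ia <- hartree_to_ev(ia)
  ia
}

#' Global CDFT reactivity descriptors
#'
#' From the vertical ionization potential I and electron affinity A:
#' electronegativity chi = (I+A)/2, chemical potential mu = -chi, global
#' hardness eta = I - A (the full HOMO-LUMO gap convention, no 1/2 factor),
#' softness S = 1/eta, electrophilicity omega = chi^2/(2 eta),
#' electrodonating power omega^- = (3I+A)^2 / (16 eta), electroaccepting
#' power omega^+ = (I+3A)^2 / (16 eta), net electrophilicity
#' Delta-omega = omega^- + omega^+, and the gap-based absorption-wavelength
#' estimate lambda_max.  Values are kept unrounded; rounding is a
#' reporting-layer concern.
#'
#' @param x a [frontier_energies] object (vertical/Koopmans mode), or a
#'   named numeric `c(I = , A = )` in eV as returned by
#'   [finite_difference_ia()] (Delta-SCF mode).
#' @param tol gaps at or below this (eV) are rejected as degenerate.
#' @return An object of class `cdft_global`, a list with fields
#'   `i_vertical`, `a_vertical`, `chi`, `mu`, `eta`, `softness`, `omega`,
#'   `omega_minus`, `omega_plus`, `net_electrophilicity`, `lambda_max`.
#' @examples
#' d <- global_descriptors(frontier_energies(-6.240, -1.733))
#' round(d$chi, 3)    # 3.986 eV
#' round(d$eta, 3)    # 4.507 eV
#' @export
global_descriptors <- function(x, tol = 1e-9) {
  if (inherits(x, "cdft_frontier")) {
    ia <- vertical_ia(x)
  } else if (is.numeric(x) && length(x) == 2L) {
    if (!all(c("I", "A") %in% names(x)))
      stop("numeric input must be named c(I = , A = )", call. = FALSE)
    ia <- x[c("I", "A")]
  } else {
    stop("x must be frontier energies or a named (I, A) pair", call. = FALSE)
  }
  i <- unname(ia["I"]); a <- unname(ia["A"])
  eta <- i - a
  if (!is.finite(eta) || eta <= tol)
    stop("degenerate frontier: hardness I - A must be positive",
         call. = FALSE)
  chi <- (i + a) / 2
  omega_minus <- (3 * i + a)^2 / (16 * eta)
  omega_plus <- (i + 3 * a)^2 / (16 * eta)
  structure(
    list(i_vertical = i, a_vertical = a,
         chi = chi, mu = -chi, eta = eta, softness = 1 / eta,
         omega = chi^2 / (2 * eta),
         omega_minus = omega_minus, omega_plus = omega_plus,
         net_electrophilicity = omega_minus + omega_plus,
         lambda_max = .hc_ev_nm / eta),
    class = "cdft_global")
}

#' @export
print.cdft_global <- function(x, ...) {
  cat("Global CDFT reactivity descriptors (eV):\n")
  sym <- c(chi = "electronegativity  chi", eta = "hardness           eta",
           omega = "electrophilicity   omega",
           omega_minus = "electrodonating    omega-",
           omega_plus = "electroaccepting   omega+",
           net_electrophilicity = "net electrophilicity")
  for (k in names(sym))
    cat(sprintf("  %-22s %8.3f\n", sym[[k]], x[[k]]))
  cat(sprintf("  %-22s %8.0f nm\n", "lambda_max", x$lambda_max))
  invisible(x)
}

#' Absorption-wavelength estimate from the HOMO-LUMO gap
#'
#' The Kohn-Sham HOMO-LUMO gap approximates the lowest excitation energy;
#' lambda_max = hc / gap with hc = 1239.841984 eV nm.
#'
#' @param f a [frontier_energies] object, or a positive numeric gap in eV.
#' @return Wavelength in nm (unrounded; report as nearest integer).
#' @examples
#' lambda_max(frontier_energies(-6.240, -1.733))  # 275.09 nm
#' @export
lambda_max <- function(f) {
  gap <- if (inherits(f, "cdft_frontier")) f$e_lumo - f$e_homo
         else as.numeric(f)
  if (!is.finite(gap) || gap <= 0)
    stop("non-positive HOMO-LUMO gap", call. = FALSE)
  .hc_ev_nm / gap
}

#' Koopmans-compliance (KID) diagnostics
#'
#' Measures how well the frontier orbital energies of the chosen density
#' functional reproduce the Delta-SCF ionization energies:
#' J_I = |e_HOMO + E(N-1) - E(N)|, J_A = |e_LUMO + E(N) - E(N+1)|,
#' J_HL = sqrt(J_I^2 + J_A^2).  Values of a few tenths of an eV or less
#' indicate that using orbital energies in place of energy differences
#' (the KID procedure) is justified.
#'
#' @param e_n,e_nm1,e_np1 total energies of the N, N-1, N+1 electron states.
#' @param f a [frontier_energies] object (eV).
#' @param unit unit of the total energies: `"hartree"` (default) or `"ev"`.
#' @return An object of class `kid_diagnostics`: list with `j_i`, `j_a`,
#'   `j_hl` in eV.
#' @export
kid_diagnostics <- function(e_n, e_nm1, e_np1, f, unit = c("hartree", "ev")) {
  unit <- match.arg(unit)
  stopifnot(inherits(f, "cdft_frontier"))
  ia <- finite_difference_ia(e_n, e_nm1, e_np1, unit = unit)
  j_i <- abs(f$e_homo + ia[["I"]])
  j_a <- abs(f$e_lumo + ia[["A"]])
  structure(list(j_i = j_i, j_a = j_a, j_hl = sqrt(j_i^2 + j_a^2)),
            class = "kid_diagnostics")
}

#' @export
print.kid_diagnostics <- function(x, ...) {
  cat(sprintf("<KID diagnostics: J_I %.4f, J_A %.4f, J_HL %.4f eV>\n",
              x$j_i, x$j_a, x$j_hl))
  invisible(x)
}
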