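#' Condensed (per-atom) Fukui functions and dual descriptor
#'
#' Condensed from partial-charge differences between the N, N-1 and N+1
#' electron states at fixed geometry:
#' f^-_k = q_k(N-1) - q_k(N)   (susceptibility to electrophilic attack),
#' f^+_k = q_k(N) - q_k(N+1)   (susceptibility to nucleophilic attack),
#' dual_k = f^+_k - f^-_k.
#' The charge-based sign convention makes f^- positive at electron-donating
#' sites; e.g. q(N) = (0, 0), q(N-1) = (0.6, 0.4) gives f^- = (0.6, 0.4):
#' the first atom loses more electron density on ionization.  When each
#' charge set conserves its own net charge exactly, sum(f^-) = sum(f^+) = 1
#' and sum(dual) = 0.
#'
#' @param q_n,q_nm1,q_np1 [charge_set] records of the neutral, cation
#'   (net charge +1 relative to neutral) and anion (-1), with identical
#'   scheme, atom count and labels.
#' @return An object of class `condensed_fukui` with fields `scheme`,
#'   `atom_labels`, `f_minus`, `f_plus`, `dual`.
#' @examples
#' qn  <- charge_set("mulliken", c("C", "O"), c(0, 0), 0)
#' qc  <- charge_set("mulliken", c("C", "O"), c(0.6, 0.4), 1)
#' qa  <- charge_set("mulliken", c("C", "O"), c(-0.7, -0.3), -1)
#' condensed_fukui(qn, qc, qa)$f_minus   # 0.6 0.4
#' @export
condensed_fukui <- function(q_n, q_nm1, q_np1) {
  for (q in list(q_n, q_nm1, q_np1))
    stopifnot(inherits(q, "charge_set"))
  if (!identical(q_n$scheme, q_nm1$scheme) ||
      !identical(q_n$scheme, q_np1$scheme))
    stop("charge-partition scheme mismatch across states", call. = FALSE)
  n <- length(q_n$q)
  if (length(q_nm1$q) != n || length(q_np1$q) != n)
    stop("atom-count mismatch across states", call. = FALSE)
  if (!identical(q_n$atom_labels, q_nm1$atom_labels) ||
      !identical(q_n$atom_labels, q_np1$atom_labels))
    stop("atom-label mismatch across states", call. = FALSE)
  if (q_nm1$net_charge - q_n$net_charge != 1)
    stop("cation set must carry net charge +1 relative to neutral",
         call. = FALSE)
  if (q_np1$net_charge - q_n$net_charge != -1)
    stop("anion set must carry net charge -1 relative to neutral",
         call. = FALSE)
  f_minus <- q_nm1$q - q_n$q
  f_plus <- q_n$q - q_np1$q
  structure(
    list(scheme = q_n$scheme, atom_labels = q_n$atom_labels,
         f_minus = f_minus, f_plus = f_plus, dual = f_plus - f_minus),
    class = "condensed_fukui")
}

#' @export
print.condensed_fukui <- function(x, ...) {
  cat(sprintf("<condensed_fukui (%s), %d atoms>\n", x$scheme,
              length(x$f_minus)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$f_minus) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.condensed_fukui <- function(x, ...) {
  data.frame(atom = seq_along(x$f_minus), element = x$atom_labels,
             f_minus = x$f_minus, f_plus = x$f_plus, dual = x$dual)
}

#' Write condensed Fukui values as CSV
#'
#' Columns: atom (1-based index), element, f_minus, f_plus, dual.
#'
#' @param cf a [condensed_fukui].
#' @param path output file.
#' @export
write_fukui_csv <- function(cf, path) {
  stopifnot(inherits(cf, "condensed_fukui"))
  utils::write.csv(as.data.frame(cf), path, row.names = FALSE)
  invisible(path)
}

#' Grid-based Fukui fields and dual descriptor
#'
#' Voxelwise finite differences of electron densities at fixed geometry:
#' f^-(r) = rho_N(r) - rho_(N-1)(r), f^+(r) = rho_(N+1)(r) - rho_N(r),
#' dual(r) = f^+(r) - f^-(r).  The three input grids must be congruent
#' (same origin, axes and counts).
#'
#' @param rho_n,rho_nm1,rho_np1 congruent [volumetric_grid] densities of
#'   the N, N-1 and N+1 electron states.
#' @param tol congruence tolerance (bohr) on origin and axes.
#' @return A list of three [volumetric_grid]s: `f_minus`, `f_plus`, `dual`,
#'   sharing the input geometry.
#' @export
grid_fukui <- function(rho_n, rho_nm1, rho_np1, tol = 1e-8) {
  grids <- list(rho_n, rho_nm1, rho_np1)
  for (g in grids) stopifnot(inherits(g, "volumetric_grid"))
  for (g in grids[-1]) {
    if (!identical(g$counts, rho_n$counts))
      stop("non-congruent grids: counts differ", call. = FALSE)
    if (max(abs(g$origin - rho_n$origin)) > tol ||
        max(abs(g$axes - rho_n$axes)) > tol)
      stop("non-congruent grids: origin/axes differ", call. = FALSE)
  }
  remake <- function(v) volumetric_grid(rho_n$origin, rho_n$axes,
                                        rho_n$counts, rho_n$atoms, v)
  f_minus <- rho_n$values - rho_nm1$values
  f_plus <- rho_np1$values - rho_n$values
  list(f_minus = remake(f_minus), f_plus = remake(f_plus),
       dual = remake(f_plus - f_minus))
}

#' Rank reactive sites by a condensed Fukui descriptor
#'
#' @param cf a [condensed_fukui].
#' @param which one of `"f_minus"` (electrophilic attack), `"f_plus"`
#'   (nucleophilic attack), `"dual"`.
#' @param k how many top sites to return (0 to the atom count).
#' @return data.frame with columns `atom` (1-based index), `element`,
#'   `value`, sorted by descending value; ties broken by ascending atom
#'   index.
#' @examples
#' qn <- charge_set("m", c("C", "N", "O"), c(0, 0, 0), 0)
#' qc <- charge_set("m", c("C", "N", "O"), c(0.1, 0.5, 0.4), 1)
#' qa <- charge_set("m", c("C", "N", "O"), c(-0.4, -0.3, -0.3), -1)
#' rank_sites(condensed_fukui(qn, qc, qa), "f_minus", 2)
#' @export
rank_sites <- function(cf, which = c("f_minus", "f_plus", "dual"), k) {
  stopifnot(inherits(cf, "condensed_fukui"))
  which <- match.arg(which)
  n <- length(cf$f_minus)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n)
    stop("k must lie in 0..", n, call. = FALSE)
  v <- cf[[which]]
  ord <- order(-v, seq_len(n))
  top <- ord[seq_len(k)]
  data.frame(atom = top, element = cf$atom_labels[top], value = v[top],
             row.names = NULL)
}
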