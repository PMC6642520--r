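# Seeded generators for every input the pipeline consumes.  Ground truths
# recorded in the 'expected' fields are computed analytically at generation
# time, never by the descriptor code, so tests against them are
# non-circular.

# Run expr under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate an orbital spectrum with a prescribed frontier
#'
#' Occupied levels lie strictly below `e_homo` with the top level at exactly
#' `e_homo`; the lowest virtual sits at exactly `e_homo + gap`.  All
#' occupied orbitals hold 2 electrons.  Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_occ,n_virt occupied/virtual orbital counts (>= 1).
#' @param e_homo target HOMO energy (eV).
#' @param gap target HOMO-LUMO gap (eV, > 0).
#' @return An [orbital_spectrum] whose frontier is `(e_homo, e_homo + gap)`.
#' @examples
#' sp <- make_spectrum(1, 5, 5, -6.240, 4.507)
#' frontier_from_spectrum(sp)
#' @export
make_spectrum <- function(seed, n_occ, n_virt, e_homo, gap) {
  if (n_occ < 1 || n_virt < 1)
    stop("need at least one occupied and one virtual orbital", call. = FALSE)
  if (!is.finite(gap) || gap <= 0) stop("gap must be > 0", call. = FALSE)
  .with_seed(seed, {
    occ <- e_homo - c(rev(cumsum(stats::runif(n_occ - 1, 0.2, 2))), 0)
    vir <- e_homo + gap + c(0, cumsum(stats::runif(n_virt - 1, 0.2, 2)))
    orbital_spectrum(c(occ, vir), c(rep(2, n_occ), rep(0, n_virt)))
  })
}

#' Generate a charge triplet for the N, N-1 and N+1 electron states
#'
#' The neutral set sums to exactly 0, the cation to +1 and the anion to -1
#' (up to floating point), so the condensed Fukui functions built from the
#' triplet sum to exactly (1, 1, 0).  A nonzero `noise` breaks charge
#' conservation on purpose, by adding `noise` to one cation charge and
#' subtracting it from one anion charge, to exercise validation machinery.
#'
#' @param seed integer seed.
#' @param n_atoms number of atoms (>= 1).
#' @param labels optional element labels (recycled); random C/N/O/S
#'   otherwise.
#' @param noise conservation-breaking offset in e (default 0).
#' @return List of three [charge_set]s: `q_n`, `q_nm1`, `q_np1`.
#' @export
make_charge_triplet <- function(seed, n_atoms, labels = NULL, noise = 0) {
  if (n_atoms < 1) stop("n_atoms must be >= 1", call. = FALSE)
  .with_seed(seed, {
    if (is.null(labels))
      labels <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
    labels <- rep_len(labels, n_atoms)
    q0 <- stats::rnorm(n_atoms, sd = 0.3)
    q0 <- q0 - sum(q0) / n_atoms          # neutral: sum ~ 0
    q0[n_atoms] <- -sum(q0[-n_atoms])     # last atom absorbs rounding
    share <- function() {
      d <- stats::runif(n_atoms)
      d / sum(d)                          # one full electron, split
    }
    d_cat <- share(); d_an <- share()
    q_cat <- q0 + d_cat; q_cat[1] <- q_cat[1] + noise
    q_an <- q0 - d_an;  q_an[1] <- q_an[1] - noise
    tol <- max(1e-3, abs(noise) * (1 + 1e-9) + 1e-9)
    list(q_n = charge_set("synthetic", labels, q0, 0),
         q_nm1 = charge_set("synthetic", labels, q_cat, 1, tol = tol),
         q_np1 = charge_set("synthetic", labels, q_an, -1, tol = tol))
  })
}

#' Generate a density-grid triplet with known Fukui fields
#'
#' Emulates the electron densities of the N, N-1 and N+1 states on a cubic
#' box of 16 bohr: `rho_n` is a smooth positive background, and
#' `rho_nm1 = rho_n - g1`, `rho_np1 = rho_n + g2`, where `g1` and `g2` are
#' sums of isotropic Gaussian blobs analytically normalized to integrate to
#' one electron.  Blob centers keep a 4-sigma margin from every face, so
#' the discrete integrals of the resulting Fukui fields equal 1 to well
#' within 1e-3.  The analytic ground truths are attached as the `expected`
#' attribute.
#'
#' @param seed integer seed.
#' @param counts grid counts, each >= 16 (integration accuracy floor).
#' @param n_blobs Gaussians per one-electron field.
#' @return List of three congruent [volumetric_grid]s `rho_n`, `rho_nm1`,
#'   `rho_np1`, with attribute `expected` (list: `int_f_minus`,
#'   `int_f_plus`, `int_dual`, `blob_centers_minus`, `blob_centers_plus`).
#' @export
make_grid_triplet <- function(seed, counts = c(32L, 32L, 32L), n_blobs = 2L) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 16L))
    stop("grid too coarse: all counts must be >= 16", call. = FALSE)
  if (n_blobs < 1L) stop("n_blobs must be >= 1", call. = FALSE)
  box <- 16
  h <- box / counts
  axes <- diag(h)
  origin <- c(0, 0, 0)
  # voxel-center coordinates along each axis
  xs <- lapply(1:3, function(i) origin[i] + (seq_len(counts[i]) - 0.5) * h[i])
  .with_seed(seed, {
    field <- function(centers, sigmas, amps) {
      v <- array(0, counts)
      for (k in seq_along(sigmas)) {
        gx <- exp(-(xs[[1]] - centers[k, 1])^2 / (2 * sigmas[k]^2))
        gy <- exp(-(xs[[2]] - centers[k, 2])^2 / (2 * sigmas[k]^2))
        gz <- exp(-(xs[[3]] - centers[k, 3])^2 / (2 * sigmas[k]^2))
        v <- v + amps[k] * outer(gx, outer(gy, gz))
      }
      aperm(v, c(3, 2, 1))  # z fastest in the flattened cube layout
    }
    blob_set <- function() {
      sigmas <- stats::runif(n_blobs, 1.0, 1.6)
      if (any(8 * sigmas >= box))
        stop("blob exceeds the box margin", call. = FALSE)
      centers <- t(vapply(sigmas, function(s)
        stats::runif(3, 4 * s, box - 4 * s), numeric(3)))
      amps <- (1 / n_blobs) / ((2 * pi)^1.5 * sigmas^3)
      list(centers = centers, sigmas = sigmas, amps = amps)
    }
    b1 <- blob_set(); b2 <- blob_set()
    bg <- 0.2 + field(matrix(box / 2, 1, 3), box / 6, 0.5)
    g1 <- field(b1$centers, b1$sigmas, b1$amps)
    g2 <- field(b2$centers, b2$sigmas, b2$amps)
    mk <- function(v) volumetric_grid(origin, axes, counts,
                                      values = as.numeric(v))
    out <- list(rho_n = mk(bg), rho_nm1 = mk(bg - g1), rho_np1 = mk(bg + g2))
    attr(out, "expected") <- list(
      int_f_minus = 1, int_f_plus = 1, int_dual = 0,
      blob_centers_minus = b1$centers, blob_centers_plus = b2$centers,
      blob_sigmas_minus = b1$sigmas, blob_sigmas_plus = b2$sigmas)
    out
  })
}

#' The Taltobulin fixture bundle
#'
#' Packages every input the full analysis needs for the Taltobulin
#' (HTI-286) peptide: the structure as SMILES, an orbital spectrum whose
#' frontier matches the reference frontier energies (-6.240 / -1.733 eV),
#' total electronic energies of the N and N+-1 states constructed to be
#' Koopmans-consistent with that frontier (synthetic: the reference reports
#' only E(N) = -1517.422 au), a five-conformer energy list, a seeded charge
#' triplet over the molecule's 34 atoms, a density-grid triplet, the six
#' externally supplied bioactivity scores, and the supplied miLogP and
#' molecular-volume values.  The `expected` field holds the reference
#' values the pipeline should reproduce.  The SMILES is self-validated
#' against MW 473.66 and 34 heavy atoms at load time.
#'
#' @param seed seed for the synthetic (charge/grid) components.
#' @return A list of class `fixture_bundle`.
#' @export
taltobulin_fixture <- function(seed = 286L) {
  smiles <- paste0("CNC(C(C)(C)c1ccccc1)C(=O)N(C)C(C(C)(C)C)",
                   "C(=O)NC(/C=C(\\C)C(O)=O)C(C)C")
  mol <- parse_smiles(smiles)
  if (nrow(mol$atoms) != 34L || round(molecular_weight(mol), 2) != 473.66)
    stop("fixture self-validation failure: Taltobulin SMILES does not ",
         "reproduce MW 473.66 / 34 heavy atoms", call. = FALSE)
  e_homo <- -6.240; e_lumo <- -1.733
  e_n <- -1517.422
  e_nm1 <- e_n + ev_to_hartree(-e_homo)   # Koopmans-consistent cation
  e_np1 <- e_n - ev_to_hartree(-e_lumo)   # Koopmans-consistent anion
  spectrum <- make_spectrum(seed, n_occ = 30, n_virt = 10,
                            e_homo = e_homo, gap = e_lumo - e_homo)
  conformers <- .with_seed(seed, {
    es <- c(e_n, sort(e_n + stats::runif(4, 0.005, 0.05)))
    lapply(seq_along(es), function(i)
      qm_result(sprintf("conformer_%d", i), es[i],
                frequencies = stats::runif(3 * 34 - 6, 10, 3200)))
  })
  structure(list(
    smiles = smiles,
    spectrum = spectrum,
    conformers = conformers,
    energies = list(e_n = e_n, e_nm1 = e_nm1, e_np1 = e_np1),
    charge_triplet = make_charge_triplet(seed, 34,
                                         labels = mol$atoms$element),
    grid_triplet = make_grid_triplet(seed, c(32L, 32L, 32L), 2L),
    bioactivity = list(gpcr = 0.43, ion_channel = 0.15, kinase = -0.12,
                       nuclear_receptor = 0.19, protease = 0.68,
                       enzyme = 0.42),
    milogp_input = 4.43,
    volume_input = 479.94,
    seed = as.integer(seed),
    expected = list(
      e_total_au = -1517.422, e_homo_ev = -6.240, e_lumo_ev = -1.733,
      lambda_max_nm = 275,
      chi_ev = 3.986, eta_ev = 4.507, omega_ev = 1.763,
      omega_minus_ev = 5.800, omega_plus_ev = 1.814,
      net_electrophilicity_ev = 7.614,
      milogp = 4.43, tpsa = 98.73, n_atoms = 34, n_on = 7, n_ohnh = 3,
      nviol = 0, n_rotb = 11, volume = 479.94, mw = 473.66,
      categories = c(gpcr = "active", ion_channel = "active",
                     kinase = "moderately active",
                     nuclear_receptor = "active", protease = "active",
                     enzyme = "active"))),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle: %d-atom molecule, seed %d>\n",
              x$expected$n_atoms, x$seed))
  invisible(x)
}
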