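#' Molecular weight
#'
#' Average-isotope molecular weight from standard atomic weights, including
#' implicit hydrogens.
#'
#' @param m a [mol_structure].
#' @return MW in Da (unrounded; report to 2 decimals).
#' @export
molecular_weight <- function(m) {
  stopifnot(inherits(m, "mol_structure"))
  sum(.atomic_weights[m$atoms$element]) +
    sum(m$atoms$n_h) * .atomic_weights[["H"]]
}

#' Hydrogen-bond acceptor count (nON)
#'
#' The Molinspiration convention: the number of nitrogen plus oxygen atoms.
#'
#' @param m a [mol_structure].
#' @export
count_hba <- function(m) {
  stopifnot(inherits(m, "mol_structure"))
  sum(m$atoms$element %in% c("N", "O"))
}

#' Hydrogen-bond donor count (nOHNH)
#'
#' The Molinspiration convention: the number of hydrogen atoms bonded to
#' nitrogen or oxygen (not the number of heteroatoms carrying them).
#'
#' @param m a [mol_structure].
#' @export
count_hbd <- function(m) {
  stopifnot(inherits(m, "mol_structure"))
  sum(m$atoms$n_h[m$atoms$element %in% c("N", "O")])
}

#' Rotatable-bond count (nrotb)
#'
#' A bond is rotatable when it is a single, acyclic bond between two
#' non-terminal heavy atoms (heavy-atom degree >= 2 on both ends), and is
#' not an amide C-N bond (the C bearing a double-bonded O).
#'
#' @param m a [mol_structure].
#' @export
rotatable_bonds <- function(m) {
  stopifnot(inherits(m, "mol_structure"))
  b <- m$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(m$atoms))
  el <- m$atoms$element
  carbonyl_c <- vapply(seq_len(nrow(m$atoms)), function(i)
    el[i] == "C" && any(b$order == 2L &
                        ((b$a1 == i & el[b$a2] == "O") |
                         (b$a2 == i & el[b$a1] == "O"))), logical(1))
  n_rot <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || b$in_ring[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (el[i] == "C" && carbonyl_c[i] && el[j] == "N") ||
             (el[j] == "C" && carbonyl_c[j] && el[i] == "N")
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

# Environment key of one atom for the Ertl TPSA table; see tables.R.
.tpsa_key <- function(m, i) {
  a <- m$atoms[i, ]
  b <- m$bonds
  mine <- which(b$a1 == i | b$a2 == i)
  if (a$aromatic) {
    pat <- vapply(mine, function(k) {
      if (b$aromatic[k]) "a" else c("s", "d", "t")[b$order[k]]
    }, character(1))
    el <- tolower(a$element)
  } else {
    pat <- c("s", "d", "t")[b$order[mine]]
    el <- a$element
  }
  pat <- paste(pat[order(match(pat, c("a", "s", "d", "t")))], collapse = "")
  key <- paste(el, a$charge, a$n_h, pat, sep = "|")
  if (a$in_ring3 && paste0(key, "|r3") %in% names(.tpsa_contrib))
    key <- paste0(key, "|r3")
  key
}

#' Topological polar surface area (Ertl)
#'
#' Sum of published fragment contributions over the molecule's nitrogen and
#' oxygen environments (optionally also S and P with `include_sp = TRUE`,
#' the extended convention; the default matches the common N/O-only TPSA).
#'
#' @param m a [mol_structure].
#' @param include_sp also sum sulfur/phosphorus contributions.
#' @return TPSA in Angstrom^2 (unrounded; report to 2 decimals).
#' @examples
#' \donttest{
#' tpsa(parse_smiles("c1ccccc1C(O)=O"))  # benzoic acid: 17.07 + 20.23
#' }
#' @export
tpsa <- function(m, include_sp = FALSE) {
  stopifnot(inherits(m, "mol_structure"))
  el_set <- c("N", "O", if (include_sp) c("S", "P"))
  idx <- which(m$atoms$element %in% el_set)
  total <- 0
  for (i in idx) {
    key <- .tpsa_key(m, i)
    if (!key %in% names(.tpsa_contrib))
      stop(sprintf("no TPSA contribution for atom %d (%s, environment %s)",
                   i, m$atoms$element[i], key), call. = FALSE)
    total <- total + .tpsa_contrib[[key]]
  }
  total
}

# Reduced Wildman-Crippen type of one heavy atom; see tables.R.
.crippen_type <- function(m, i) {
  a <- m$atoms[i, ]
  el <- a$element
  b <- m$bonds
  mine <- which(b$a1 == i | b$a2 == i)
  partner <- ifelse(b$a1[mine] == i, b$a2[mine], b$a1[mine])
  p_el <- m$atoms$element[partner]
  multi <- b$order[mine] >= 2L
  if (el == "C") {
    if (a$aromatic) return(if (a$n_h > 0) "C_ar_h" else "C_ar_sub")
    if (any(multi & p_el %in% c("N", "O", "S"))) return("C_carbonyl")
    if (any(multi)) return("C_sp2")
    if (any(p_el != "C")) return("C_sp3_het")
    return("C_sp3")
  }
  if (el == "N") {
    if (a$aromatic) return("N_aromatic")
    if (a$charge > 0) return(if (a$n_h > 0) "N_pos_h" else "N_pos")
    if (any(multi)) return("N_sp2")
    if (a$n_h >= 2) return("N_amine_h2")
    if (a$n_h == 1) return("N_amine_h1")
    return("N_tertiary")
  }
  if (el == "O") {
    if (a$aromatic) return("O_aromatic")
    if (a$charge < 0) {
      carboxylate <- any(p_el == "C" & vapply(partner, function(p) {
        pb <- which(b$a1 == p | b$a2 == p)
        any(b$order[pb] == 2L &
              m$atoms$element[ifelse(b$a1[pb] == p, b$a2[pb],
                                     b$a1[pb])] == "O")
      }, logical(1)))
      return(if (carboxylate) "O_carboxylate" else "O_anion")
    }
    if (a$n_h > 0) return("O_hydroxyl")
    if (any(multi)) return(if (any(p_el[multi] %in% c("N", "O")))
      "O_n_oxide" else "O_carbonyl")
    return(if (any(m$atoms$aromatic[partner])) "O_ar_ether" else "O_ether")
  }
  if (el == "S") return(if (a$aromatic) "S_aromatic" else "S_any")
  if (el == "P") return("P_any")
  paste0(el, "_any")
}

#' Per-atom logP contribution types
#'
#' Assigns every heavy atom (and, as pseudo-entries, every hydrogen class)
#' its reduced Wildman-Crippen type, so the additive [logp()] value can be
#' re-summed independently against [crippen_table()].
#'
#' @param m a [mol_structure].
#' @return data.frame with columns `atom` (heavy-atom index, `NA` for
#'   hydrogen pseudo-entries), `type` and `count`.
#' @export
logp_atom_types <- function(m) {
  stopifnot(inherits(m, "mol_structure"))
  n <- nrow(m$atoms)
  types <- vapply(seq_len(n), function(i) .crippen_type(m, i), character(1))
  h_type <- function(i) {
    el <- m$atoms$element[i]
    if (el == "N") return("H_on_n")
    if (el == "O") {
      # acidic OH: the O's carbon neighbor carries a carbonyl O
      b <- m$bonds
      mine <- which(b$a1 == i | b$a2 == i)
      partner <- ifelse(b$a1[mine] == i, b$a2[mine], b$a1[mine])
      acid <- any(m$atoms$element[partner] == "C" &
                    vapply(partner, function(p) {
                      pb <- which(b$a1 == p | b$a2 == p)
                      any(b$order[pb] == 2L &
                            m$atoms$element[ifelse(b$a1[pb] == p, b$a2[pb],
                                                   b$a1[pb])] == "O")
                    }, logical(1)))
      return(if (acid) "H_on_o_acid" else "H_polar")
    }
    if (el == "C") return("H_on_c")
    "H_polar"
  }
  out <- data.frame(atom = seq_len(n), type = types, count = 1L)
  hs <- which(m$atoms$n_h > 0)
  if (length(hs)) {
    out <- rbind(out, data.frame(
      atom = NA_integer_,
      type = vapply(hs, h_type, character(1)),
      count = m$atoms$n_h[hs]))
  }
  out
}

#' Atom-contribution logP stand-in
#'
#' An open, additive octanol/water partition-coefficient estimate using the
#' reduced Wildman-Crippen scheme of [crippen_table()].  It is a documented
#' stand-in for the proprietary miLogP model: expect agreement within about
#' one log unit, and prefer an externally supplied miLogP value for
#' Rule-of-Five decisions when one is available.
#'
#' @param m a [mol_structure].
#' @return Estimated logP (dimensionless).
#' @export
logp <- function(m) {
  types <- logp_atom_types(m)
  unknown <- setdiff(types$type, names(.crippen_contrib))
  if (length(unknown))
    stop("uncovered logP atom type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(.crippen_contrib[types$type] * types$count)
}

#' Lipinski Rule-of-Five violation count
#'
#' One violation for each of MW > 500 Da, logP > 5, H-bond donors > 5,
#' H-bond acceptors > 10.  Boundaries are compliant (a value exactly at the
#' limit is not a violation), per the rule's original phrasing.
#'
#' @param p a [drug_profile], or a named list/vector with `mw`, `n_ohnh`,
#'   `n_on` (and optionally `milogp_input` / `logp`).
#' @param logp_value the logP to judge; defaults to the profile's supplied
#'   miLogP when present, else its computed logP.
#' @return Integer violation count in 0..4.
#' @examples
#' ro5_violations(list(mw = 473.66, n_ohnh = 3, n_on = 7), logp_value = 4.43)
#' @export
ro5_violations <- function(p, logp_value = NULL) {
  p <- as.list(p)
  need <- c("mw", "n_ohnh", "n_on")
  if (!all(need %in% names(p)))
    stop("profile must provide mw, n_ohnh and n_on", call. = FALSE)
  if (is.null(logp_value))
    logp_value <- if (!is.null(p$milogp_input)) p$milogp_input else p$logp
  if (is.null(logp_value) || !is.finite(logp_value))
    stop("no logP value available for the Rule-of-Five check", call. = FALSE)
  sum(p$mw > 500, logp_value > 5, p$n_ohnh > 5, p$n_on > 10)
}

#' Classify a bioactivity score
#'
#' Molinspiration-style activity bands: a score above 0 is `active`, from
#' -5.0 to 0.0 inclusive `moderately active`, and below -5.0 `inactive`.
#'
#' @param score numeric vector of bioactivity scores.
#' @return Character vector of categories.
#' @examples
#' classify_bioactivity(c(0.68, -0.12, -6))
#' @export
classify_bioactivity <- function(score) {
  if (any(!is.finite(score))) stop("non-finite score", call. = FALSE)
  ifelse(score > 0, "active",
         ifelse(score >= -5.0, "moderately active", "inactive"))
}

#' Bioactivity score set with categories
#'
#' Bioactivity scores are externally supplied inputs (the predictive models
#' behind them are proprietary); this wraps the six standard target-class
#' scores with their [classify_bioactivity()] categories.
#'
#' @param gpcr,ion_channel,kinase,nuclear_receptor,protease,enzyme scores.
#' @return data.frame with columns `target`, `score`, `category`.
#' @export
bioactivity_scores <- function(gpcr, ion_channel, kinase, nuclear_receptor,
                               protease, enzyme) {
  score <- c(gpcr = gpcr, ion_channel = ion_channel, kinase = kinase,
             nuclear_receptor = nuclear_receptor, protease = protease,
             enzyme = enzyme)
  data.frame(target = names(score), score = unname(score),
             category = classify_bioactivity(unname(score)),
             row.names = NULL)
}

#' Full drug-likeness profile of a molecule
#'
#' Computes the Molinspiration-style property block (MW, nAtoms, nON,
#' nOHNH, nrotb, TPSA, logP) from a structure, carries optional externally
#' supplied miLogP and molecular-volume values, and counts Rule-of-Five
#' violations (using the supplied miLogP when present, else the computed
#' logP stand-in).
#'
#' @param m a [mol_structure] or a SMILES string.
#' @param milogp_input optional externally supplied miLogP.
#' @param volume_input optional externally supplied molecular volume
#'   (Angstrom^3); not computable here (the model is proprietary).
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(m, milogp_input = NULL, volume_input = NULL) {
  if (is.character(m)) m <- parse_smiles(m)
  stopifnot(inherits(m, "mol_structure"))
  p <- list(mw = molecular_weight(m), n_atoms = nrow(m$atoms),
            n_on = count_hba(m), n_ohnh = count_hbd(m),
            n_rotb = rotatable_bonds(m), tpsa = tpsa(m), logp = logp(m),
            milogp_input = milogp_input, volume_input = volume_input)
  p$nviol <- ro5_violations(p)
  structure(p, class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("Drug-likeness profile:\n")
  cat(sprintf("  MW      %8.2f Da\n", x$mw))
  cat(sprintf("  nAtoms  %8d\n", x$n_atoms))
  cat(sprintf("  nON     %8d\n", x$n_on))
  cat(sprintf("  nOHNH   %8d\n", x$n_ohnh))
  cat(sprintf("  nrotb   %8d\n", x$n_rotb))
  cat(sprintf("  TPSA    %8.2f A^2\n", x$tpsa))
  cat(sprintf("  logP    %8.2f (stand-in)\n", x$logp))
  if (!is.null(x$milogp_input))
    cat(sprintf("  miLogP  %8.2f (supplied)\n", x$milogp_input))
  if (!is.null(x$volume_input))
    cat(sprintf("  volume  %8.2f A^3 (supplied)\n", x$volume_input))
  cat(sprintf("  nviol   %8d\n", x$nviol))
  invisible(x)
}
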