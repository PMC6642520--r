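# Descriptor contribution tables, shipped in source form.
#
# TPSA: Ertl fragment contributions (Ertl, Rohde & Selzer, J. Med. Chem.
# 2000) for N/O environments, plus the S/P extension.  Keys encode the atom
# environment as element | aromatic | charge | n_h | bond pattern, where the
# bond pattern counts heavy-atom bonds by order: s = single, d = double,
# t = triple (sorted), with "r3" appended for three-membered-ring atoms.

.tpsa_contrib <- c(
  # nitrogen, neutral
  "N|0|0|sss"    = 3.24,
  "N|0|0|sd"     = 12.36,
  "N|0|0|t"      = 23.79,
  "N|0|0|sdd"    = 11.68,
  "N|0|0|dt"     = 13.60,
  "N|0|0|sss|r3" = 3.01,
  "N|0|1|ss"     = 12.03,
  "N|0|1|ss|r3"  = 21.94,
  "N|0|1|d"      = 23.85,
  "N|0|2|s"      = 26.02,
  # nitrogen, cationic
  "N|1|0|ssss"   = 0.00,
  "N|1|0|ssd"    = 3.01,
  "N|1|0|st"     = 4.36,
  "N|1|1|sss"    = 4.44,
  "N|1|1|sd"     = 13.97,
  "N|1|2|ss"     = 16.61,
  "N|1|2|d"      = 25.59,
  "N|1|3|s"      = 27.64,
  # aromatic nitrogen (a = in-ring aromatic bond, s/d = exocyclic)
  "n|0|0|aa"     = 12.89,
  "n|0|0|aaa"    = 4.41,
  "n|0|0|aas"    = 4.93,
  "n|0|0|aad"    = 8.39,
  "n|0|1|aa"     = 15.79,
  "n|1|0|aaa"    = 4.10,
  "n|1|0|aas"    = 3.88,
  "n|1|1|aa"     = 14.14,
  # oxygen
  "O|0|0|ss"     = 9.23,
  "O|0|0|ss|r3"  = 12.53,
  "O|0|0|d"      = 17.07,
  "O|0|1|s"      = 20.23,
  "O|-1|0|s"     = 23.06,
  "o|0|0|aa"     = 13.14,
  # sulfur / phosphorus (Ertl extension; excluded from the default TPSA)
  "S|0|0|ss"     = 25.30,
  "S|0|0|d"      = 32.09,
  "S|0|0|ssd"    = 19.21,
  "S|0|0|ssdd"   = 8.38,
  "S|0|1|s"      = 38.80,
  "s|0|0|aa"     = 28.24,
  "s|0|0|aad"    = 21.70,
  "P|0|0|sss"    = 13.59,
  "P|0|0|sd"     = 34.14,
  "P|0|0|sssd"   = 9.81,
  "P|0|1|ssd"    = 23.47)

# logP: reduced Wildman-Crippen atom-contribution scheme (Wildman &
# Crippen, J. Chem. Inf. Comput. Sci. 1999).  Atom types are coarser than
# the original 68-type SMARTS scheme but use the published contribution
# constants; hydrogens contribute individually.  Documented accuracy target:
# within about one log unit of fragment-based reference values for druglike
# organics.

.crippen_contrib <- c(
  C_sp3          = 0.1441,   # sp3 C bonded only to C/H
  C_sp3_het      = -0.2035,  # sp3 C with a heteroatom neighbor
  C_sp2          = 0.1551,   # vinylic/acetylenic C (multiple bond to C)
  C_carbonyl     = -0.2783,  # C multiply bonded to a heteroatom
  C_ar_h         = 0.1581,   # aromatic CH
  C_ar_sub       = 0.1360,   # substituted aromatic C
  N_amine_h2     = -1.0190,
  N_amine_h1     = -0.7096,
  N_tertiary     = -0.3187,
  N_sp2          = 0.1836,   # N with a multiple bond
  N_aromatic     = -0.3239,
  N_pos_h        = -1.9500,  # protonated N
  N_pos          = -0.3396,  # quaternary N+
  O_hydroxyl     = -0.2893,
  O_ether        = -0.0684,
  O_ar_ether     = -0.4195,  # ether O on an aromatic ring
  O_carbonyl     = -0.1526,  # O=C
  O_n_oxide      = 0.0335,   # O=N / O=O
  O_carboxylate  = -1.3260,  # O- of a carboxylate
  O_anion        = -1.1890,
  O_aromatic     = 0.1552,
  S_any          = 0.6482,
  S_aromatic     = 0.6237,
  P_any          = 0.8612,
  F_any          = 0.4202,
  Cl_any         = 0.6895,
  Br_any         = 0.8456,
  I_any          = 0.8857,
  H_on_c         = 0.1230,
  H_on_n         = 0.2142,
  H_on_o_acid    = 0.2980,   # acidic OH (O-H with a carbonyl on the O's C)
  H_polar        = -0.2677)  # other O-H / S-H

# Standard atomic weights (IUPAC 2021 abridged), g/mol.
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998403, P = 30.973762, S = 32.06,
                     Cl = 35.45, Br = 79.904, I = 126.90447)

#' Shipped descriptor contribution tables
#'
#' `tpsa_table()` returns the Ertl fragment contributions keyed by atom
#' environment; `crippen_table()` the reduced Wildman-Crippen logP atom
#' contributions keyed by atom type.  Exposed so the additive descriptors
#' can be audited and re-summed independently.
#'
#' @return A named numeric vector of contributions (Angstrom^2 for TPSA,
#'   log units for logP).
#' @export
tpsa_table <- function() .tpsa_contrib

#' @rdname tpsa_table
#' @export
crippen_table <- function() .crippen_contrib
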