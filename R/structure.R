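#' Parse a SMILES string into a molecular graph
#'
#' Chemical interpretation of the SMILES (including kekulization of
#' aromatic rings) is delegated to OpenBabel through
#' `ChemmineOB::convertFormat()`; the resulting V2000 connection table is
#' turned into an explicit molecular graph with implicit-hydrogen counts,
#' formal charges, ring membership and aromaticity flags, which is what the
#' drug-likeness descriptors operate on.  A syntax pre-check (balanced
#' parentheses and brackets, paired ring-closure digits, allowed tokens)
#' rejects malformed strings that OpenBabel would silently truncate.
#'
#' Supported elements: C, H, N, O, S, P, F, Cl, Br, I.  Aromaticity is
#' perceived on 5- and 6-membered rings by a Hueckel-style rule: every ring
#' atom must be sp2 (in-ring or exocyclic double bond) or a lone-pair donor
#' (N, O, S with only single bonds), and the in-ring pi-electron count must
#' satisfy 4n+2.  This covers benzenoid and the common heteroaromatic rings;
#' fused borderline systems are outside the supported subset.
#'
#' @param s a SMILES string, or the path of a file whose first line is one.
#' @return An object of class `mol_structure`: list with `atoms`
#'   (data.frame: `element`, `charge`, `n_h`, `aromatic`, `in_ring`,
#'   `in_ring3`), `bonds` (data.frame: `a1`, `a2`, `order`, `in_ring`,
#'   `aromatic`), `rings` (list of atom-index vectors) and `smiles`.
#'   Atom indices are 1-based.
#' @examples
#' \donttest{
#' m <- parse_smiles("CCO")
#' nrow(m$atoms)       # 3 heavy atoms
#' m$atoms$n_h         # 3 2 1
#' }
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("s must be one SMILES string", call. = FALSE)
  if (file.exists(s)) s <- trimws(readLines(s, warn = FALSE)[1])
  .smiles_syntax_check(s)
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(s, "\n")),
    error = function(e) stop("SMILES parse failure: ", conditionMessage(e),
                             call. = FALSE))
  ctab <- .parse_ctab(sdf)
  if (length(ctab$element) == 0L)
    stop("SMILES parse failure: ", s, call. = FALSE)
  if (nrow(ctab$bonds) && any(ctab$bonds$order == 4L))
    stop("aromatic bond orders in connection table are not supported; ",
         "expected a kekulized structure", call. = FALSE)
  .build_structure(ctab$element, ctab$charge, ctab$bonds, s)
}

# Reject SMILES strings OpenBabel would silently truncate: unbalanced
# parentheses/brackets, unpaired ring-closure labels, stray characters.
.smiles_syntax_check <- function(s) {
  fail <- function(why) stop("SMILES parse failure (", why, "): ", s,
                             call. = FALSE)
  if (!grepl("[A-Za-z*]", s)) fail("no atoms")
  bare <- gsub("\\[[^][]+\\]", "A", s)     # collapse bracket atoms
  if (grepl("[][]", bare)) fail("unbalanced brackets")
  if (!grepl("^[A-Za-z0-9()=#$/\\\\%.+*:-]*$", bare)) fail("bad character")
  depth <- 0L
  for (ch in strsplit(bare, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) fail("unbalanced parentheses")
  }
  if (depth != 0L) fail("unbalanced parentheses")
  # ring-closure labels: single digits and %nn pairs must each occur twice
  toks <- gregexpr("%[0-9]{2}|[0-9]", gsub("[A-Za-z]", "", bare))[[1]]
  if (toks[1] != -1) {
    lab <- regmatches(gsub("[A-Za-z]", "", bare), list(toks))[[1]]
    if (any(table(lab) %% 2 != 0)) fail("unpaired ring closure")
  }
  invisible(TRUE)
}

# Minimal V2000 ctab reader for OpenBabel-written SDF text.
.parse_ctab <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (length(lines) < 4L) return(list(element = character(0)))
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    return(list(element = character(0)))
  atom_lines <- lines[4 + seq_len(natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  code[is.na(code)] <- 0L
  # legacy ctab charge codes: 1..3 are +3..+1, 5..7 are -1..-3
  charge <- integer(natoms)
  charge[code %in% 1:3] <- 4L - code[code %in% 1:3]
  charge[code %in% 5:7] <- -(code[code %in% 5:7] - 4L)
  bond_lines <- lines[4 + natoms + seq_len(nbonds)]
  bonds <- data.frame(
    a1 = as.integer(substr(bond_lines, 1, 3)),
    a2 = as.integer(substr(bond_lines, 4, 6)),
    order = as.integer(substr(bond_lines, 7, 9)))
  # property block: M CHG lines override the legacy charge column
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    charge <- integer(natoms)
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                               "[[:space:]]+")[[1]])
      n <- f[1]
      for (k in seq_len(n))
        charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(element = element, charge = charge, bonds = bonds)
}

# Assemble a mol_structure from elements, formal charges and a bond table;
# explicit hydrogens are folded into the n_h count of their heavy neighbor.
.build_structure <- function(element, charge, bonds, smiles) {
  supported <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  bad <- setdiff(unique(element), supported)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- length(element)
  explicit_h <- integer(n)
  is_h <- element == "H"
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (is_h[a1] && !is_h[a2]) explicit_h[a2] <- explicit_h[a2] + 1L
      if (is_h[a2] && !is_h[a1]) explicit_h[a1] <- explicit_h[a1] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    element <- element[keep]; charge <- charge[keep]
    explicit_h <- explicit_h[keep]
    n <- length(element)
  }
  bond_sum <- numeric(n)
  degree <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    for (a in c(bonds$a1[b], bonds$a2[b])) {
      bond_sum[a] <- bond_sum[a] + bonds$order[b]
      degree[a] <- degree[a] + 1L
    }
  }
  n_h <- explicit_h + vapply(seq_len(n), function(i)
    .implicit_h(element[i], charge[i], bond_sum[i] + explicit_h[i]),
    integer(1))
  rings <- .find_rings(n, bonds)
  in_ring_bond <- .ring_bonds(n, bonds)
  in_ring <- rep(FALSE, n)
  for (r in rings) in_ring[r] <- TRUE
  for (b in which(in_ring_bond)) {
    in_ring[bonds$a1[b]] <- TRUE; in_ring[bonds$a2[b]] <- TRUE
  }
  in_ring3 <- rep(FALSE, n)
  for (r in rings) if (length(r) == 3L) in_ring3[r] <- TRUE
  aromatic <- .perceive_aromatic(element, charge, n_h, bonds, rings)
  bond_arom <- rep(FALSE, nrow(bonds))
  for (r in attr(aromatic, "aromatic_rings")) {
    hit <- (bonds$a1 %in% r) & (bonds$a2 %in% r) & in_ring_bond
    bond_arom[hit] <- TRUE
  }
  structure(
    list(atoms = data.frame(element = element, charge = charge, n_h = n_h,
                            aromatic = as.logical(aromatic),
                            in_ring = in_ring, in_ring3 = in_ring3),
         bonds = cbind(bonds, in_ring = in_ring_bond, aromatic = bond_arom),
         rings = rings, smiles = smiles),
    class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  comp <- table(factor(x$atoms$element,
                       c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")))
  comp <- comp[comp > 0]
  cat(sprintf("<mol_structure: %d heavy atoms (%s), %d bonds, %d ring(s)>\n",
              nrow(x$atoms),
              paste0(names(comp), comp, collapse = " "),
              nrow(x$bonds), length(x$rings)))
  invisible(x)
}

# Implicit hydrogen count from the standard valence model.
.implicit_h <- function(element, charge, bond_sum) {
  val <- switch(element,
    C = 4 - abs(charge),
    N = 3 + charge,
    P = if (bond_sum > 3 + charge) 5 + charge else 3 + charge,
    O = 2 + charge,
    S = if (bond_sum > 4) 6 else if (bond_sum > 2) 4 else 2,
    F = , Cl = , Br = , I = max(0, 1 - abs(charge)),
    0)
  as.integer(max(0, round(val - bond_sum)))
}

# Which bonds lie in a ring: bond endpoints stay connected without the bond.
.ring_bonds <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  adj <- vector("list", n)
  for (b in seq_len(nb)) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], b)
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], b)
  }
  vapply(seq_len(nb), function(b) {
    src <- bonds$a1[b]; dst <- bonds$a2[b]
    seen <- rep(FALSE, n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (eb in adj[[v]]) {
        if (eb == b) next
        w <- if (bonds$a1[eb] == v) bonds$a2[eb] else bonds$a1[eb]
        if (w == dst) return(TRUE)
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    FALSE
  }, logical(1))
}

# Small rings (size <= 8): shortest cycle through each ring bond, dedup by
# atom set.  Adequate for aromaticity and small-ring typing of druglike
# molecules; not a full SSSR.
.find_rings <- function(n, bonds) {
  ring_b <- .ring_bonds(n, bonds)
  if (!any(ring_b)) return(list())
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], b)
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], b)
  }
  rings <- list()
  for (b in which(ring_b)) {
    src <- bonds$a1[b]; dst <- bonds$a2[b]
    # BFS shortest path src -> dst avoiding bond b
    prev <- rep(NA_integer_, n)
    seen <- rep(FALSE, n); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (eb in adj[[v]]) {
        if (eb == b) next
        w <- if (bonds$a1[eb] == v) bonds$a2[eb] else bonds$a1[eb]
        if (!seen[w]) {
          seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
          if (w == dst) { found <- TRUE; break }
        }
      }
    }
    if (!found) next
    path <- dst
    while (path[1] != src) path <- c(prev[path[1]], path)
    if (length(path) <= 8L) rings[[length(rings) + 1L]] <- sort(path)
  }
  unique(rings)
}

# Hueckel-style aromaticity on 5/6-membered rings (see parse_smiles docs).
.perceive_aromatic <- function(element, charge, n_h, bonds, rings) {
  n <- length(element)
  aromatic <- rep(FALSE, n)
  arings <- list()
  has_double <- rep(FALSE, n)
  for (b in seq_len(nrow(bonds))) if (bonds$order[b] == 2L) {
    has_double[bonds$a1[b]] <- TRUE; has_double[bonds$a2[b]] <- TRUE
  }
  for (r in rings) {
    if (!length(r) %in% c(5L, 6L)) next
    if (!all(element[r] %in% c("C", "N", "O", "S"))) next
    inring_double <- 0L
    lp <- 0L
    ok <- TRUE
    for (b in seq_len(nrow(bonds))) {
      if (bonds$order[b] == 2L && bonds$a1[b] %in% r && bonds$a2[b] %in% r)
        inring_double <- inring_double + 1L
    }
    for (a in r) {
      in_ring_db <- any(bonds$order == 2L &
                        ((bonds$a1 == a & bonds$a2 %in% r) |
                         (bonds$a2 == a & bonds$a1 %in% r)))
      if (in_ring_db) next                      # part of an in-ring double bond
      if (has_double[a]) next                   # exocyclic sp2: contributes 0
      if (element[a] %in% c("N", "O", "S") && charge[a] <= 0) {
        lp <- lp + 1L                           # lone-pair donor
      } else {
        ok <- FALSE; break                      # saturated carbon: not aromatic
      }
    }
    if (!ok) next
    pi_e <- 2L * inring_double + 2L * lp
    if (pi_e %% 4L == 2L) {
      aromatic[r] <- TRUE
      arings[[length(arings) + 1L]] <- r
    }
  }
  attr(aromatic, "aromatic_rings") <- arings
  aromatic
}
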