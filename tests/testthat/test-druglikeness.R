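# The fixture SMILES for Taltobulin (HTI-286), validated elsewhere against
# the published MW / heavy-atom count.
talt <- paste0("CNC(C(C)(C)c1ccccc1)C(=O)N(C)C(C(C)(C)C)",
               "C(=O)NC(/C=C(\\C)C(O)=O)C(C)C")

test_that("SMILES parsing resolves heavy atoms and implicit hydrogens", {
  m <- parse_smiles("CCO")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$element, c("C", "C", "O"))
  expect_equal(m$atoms$n_h, c(3, 2, 1))
  w <- parse_smiles("O")
  expect_equal(w$atoms$n_h, 2)
  expect_equal(parse_smiles("C")$atoms$n_h, 4)
  # charged species
  ac <- parse_smiles("CC(=O)[O-]")
  expect_equal(ac$atoms$charge, c(0, 0, 0, -1))
  expect_equal(sum(ac$atoms$n_h), 3)
})

test_that("malformed and unsupported SMILES are rejected", {
  expect_error(parse_smiles("C(("), "parse failure")
  expect_error(parse_smiles("C1CC"), "ring closure")
  expect_error(parse_smiles("[Se]C"), "unsupported element")
  expect_error(parse_smiles(""), "SMILES")
})

test_that("aromatic perception covers benzenoid and heteroaromatic rings", {
  expect_true(all(parse_smiles("c1ccccc1")$atoms$aromatic))
  pyr <- parse_smiles("c1ccncc1")
  expect_true(all(pyr$atoms$aromatic))
  # cyclohexane is saturated: in a ring, not aromatic
  ch <- parse_smiles("C1CCCCC1")
  expect_true(all(ch$atoms$in_ring))
  expect_false(any(ch$atoms$aromatic))
  # exocyclic double bonds do not break ring aromaticity perception
  tol <- parse_smiles("Cc1ccccc1")
  expect_equal(sum(tol$atoms$aromatic), 6)
})

test_that("molecular weight uses standard atomic weights", {
  expect_equal(round(molecular_weight(parse_smiles("O")), 2), 18.02)
  expect_equal(round(molecular_weight(parse_smiles("C")), 2), 16.04)
  expect_equal(round(molecular_weight(parse_smiles(talt)), 2), 473.66)
})

test_that("donor/acceptor counts follow the N+O / H-on-N,O conventions", {
  expect_equal(count_hba(parse_smiles("c1ccccc1")), 0)
  expect_equal(count_hba(parse_smiles("O")), 1)
  expect_equal(count_hbd(parse_smiles("O")), 2)
  expect_equal(count_hbd(parse_smiles("CCO")), 1)
  m <- parse_smiles(talt)
  expect_equal(count_hba(m), 7)
  expect_equal(count_hbd(m), 3)
})

test_that("rotatable bonds exclude terminal, ring and amide bonds", {
  expect_equal(rotatable_bonds(parse_smiles("CC")), 0)
  expect_equal(rotatable_bonds(parse_smiles("CCCC")), 1)
  expect_equal(rotatable_bonds(parse_smiles("c1ccccc1")), 0)
  # N-methylacetamide: the only candidate C-N bond is an amide
  expect_equal(rotatable_bonds(parse_smiles("CC(=O)NC")), 0)
  expect_equal(rotatable_bonds(parse_smiles(talt)), 11)
})

test_that("Ertl TPSA reproduces fragment sums", {
  expect_equal(tpsa(parse_smiles("c1ccccc1")), 0)
  expect_equal(tpsa(parse_smiles("c1ccccc1C(O)=O")), 37.30)  # 17.07 + 20.23
  expect_equal(tpsa(parse_smiles("c1ccncc1")), 12.89)
  expect_equal(tpsa(parse_smiles(talt)), 98.73, tolerance = 0.1 / 98.73)
  # thioether contributes only under the S/P extension
  expect_equal(tpsa(parse_smiles("CSC")), 0)
  expect_equal(tpsa(parse_smiles("CSC"), include_sp = TRUE), 25.30)
})

test_that("logP stand-in is additive over its atom types", {
  m <- parse_smiles("CCO")
  types <- logp_atom_types(m)
  tab <- crippen_table()
  # independent re-summation from the exposed table
  expect_equal(logp(m), sum(tab[types$type] * types$count), tolerance = 1e-12)
  # methane: one sp3 carbon plus four hydrocarbon hydrogens
  expect_equal(logp(parse_smiles("C")),
               tab[["C_sp3"]] + 4 * tab[["H_on_c"]], tolerance = 1e-12)
})

test_that("logP stand-in lands near the supplied miLogP for the fixture", {
  expect_equal(logp(parse_smiles(talt)), 4.43, tolerance = 1.0 / 4.43)
})

test_that("descriptors are invariant under SMILES rewriting", {
  same <- list(
    c("CCO", "OCC", "C(O)C"),
    c("c1ccccc1C(O)=O", "OC(=O)c1ccccc1", "C(=O)(O)c1ccccc1"),
    c("CC(=O)NC", "CNC(C)=O", "O=C(C)NC"))
  for (group in same) {
    profs <- lapply(group, function(s) {
      m <- parse_smiles(s)
      c(molecular_weight(m), count_hba(m), count_hbd(m),
        rotatable_bonds(m), tpsa(m), logp(m))
    })
    for (p in profs[-1]) expect_equal(p, profs[[1]], tolerance = 1e-9)
  }
})

test_that("structure descriptors agree with the OpenBabel oracle", {
  for (smi in c("CCO", "c1ccccc1C(O)=O", talt)) {
    ob <- ChemmineR::propOB(ChemmineR::smiles2sdf(smi))
    m <- parse_smiles(smi)
    expect_equal(count_hbd(m), ob$HBD)
    expect_equal(tpsa(m), ob$TPSA, tolerance = 0.02)
    expect_equal(molecular_weight(m), ob$MW, tolerance = 1e-3)
  }
})

test_that("Rule-of-Five counting is boundary-inclusive and monotone", {
  expect_equal(ro5_violations(list(mw = 473.66, n_ohnh = 3, n_on = 7),
                              logp_value = 4.43), 0)
  expect_equal(ro5_violations(list(mw = 600, n_ohnh = 6, n_on = 11),
                              logp_value = 6.0), 4)
  # exactly at the limits: compliant
  expect_equal(ro5_violations(list(mw = 500, n_ohnh = 5, n_on = 10),
                              logp_value = 5.0), 0)
  expect_error(ro5_violations(list(mw = 400), logp_value = 2), "n_ohnh")
  expect_error(ro5_violations(list(mw = 400, n_ohnh = 1, n_on = 2)),
               "no logP")
  # monotonicity: raising any property never lowers the count
  set.seed(9)
  for (i in 1:50) {
    base <- list(mw = stats::runif(1, 100, 900),
                 n_ohnh = sample(0:8, 1), n_on = sample(0:14, 1))
    lp <- stats::runif(1, -2, 8)
    v0 <- ro5_violations(base, logp_value = lp)
    bumped <- base
    bumped$mw <- base$mw + 200
    expect_gte(ro5_violations(bumped, logp_value = lp + 3), v0)
  }
})

test_that("bioactivity categories partition the real line", {
  expect_equal(classify_bioactivity(0.68), "active")
  expect_equal(classify_bioactivity(-0.12), "moderately active")
  expect_equal(classify_bioactivity(-6.0), "inactive")
  # boundaries: 0 and -5 are moderately active
  expect_equal(classify_bioactivity(c(0, -5)),
               rep("moderately active", 2))
  expect_error(classify_bioactivity(NaN), "non-finite")
  set.seed(2)
  x <- stats::runif(200, -10, 5)
  cats <- classify_bioactivity(x)
  expect_true(all(cats %in% c("active", "moderately active", "inactive")))
  expect_equal(cats == "active", x > 0)
  expect_equal(cats == "inactive", x < -5)
})

test_that("drug profile assembles the Molinspiration-style block", {
  p <- drug_profile(talt, milogp_input = 4.43, volume_input = 479.94)
  expect_s3_class(p, "drug_profile")
  expect_equal(round(p$mw, 2), 473.66)
  expect_equal(p$n_atoms, 34)
  expect_equal(p$n_on, 7)
  expect_equal(p$n_ohnh, 3)
  expect_equal(p$n_rotb, 11)
  expect_equal(p$tpsa, 98.73, tolerance = 0.1 / 98.73)
  expect_equal(p$nviol, 0)
  b <- bioactivity_scores(gpcr = 0.43, ion_channel = 0.15, kinase = -0.12,
                          nuclear_receptor = 0.19, protease = 0.68,
                          enzyme = 0.42)
  expect_equal(b$category,
               c("active", "active", "moderately active", "active",
                 "active", "active"))
})
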