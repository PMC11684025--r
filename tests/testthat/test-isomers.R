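test_that("unassigned stereocentres and geometries are enumerated and deduplicated", {
  # one unassigned tetrahedral centre -> two enantiomers
  e <- enumerateIsomers("CC(F)Cl")
  expect_length(e, 2L)
  expect_true(all(grepl("@", e)))
  # fixed geometry preserved, nothing enumerated
  expect_length(enumerateIsomers("C/C=C/C"), 1L)
  # unassigned double bond -> E and Z
  z <- enumerateIsomers("CC=CC")
  expect_length(z, 2L)
  # assigned centre preserved, not re-enumerated
  a <- enumerateIsomers("C[C@H](F)Cl")
  expect_length(a, 1L)
  expect_equal(a, canonicalSmiles("C[C@H](F)Cl"))
})

test_that("false stereocentres collapse during canonical deduplication", {
  # isopropyl carbon has two identical substituents: no stereocentre
  expect_length(enumerateIsomers("CC(C)C"), 1L)
  # terminal alkene has no geometry
  expect_length(enumerateIsomers("CC(C)=C"), 1L)
})

test_that("combined centres multiply and enumeration is capped with a warning", {
  both <- enumerateIsomers("CC(F)C=CC")  # 1 centre x 1 geometry
  expect_length(both, 4L)
  expect_warning(capped <- enumerateIsomers("CC(F)C=CC", maxIsomers = 2L),
                 "truncated")
  expect_lte(length(capped), 2L)
})

test_that("unparsable SMILES fails with the offending string named", {
  expect_error(enumerateIsomers("not_a_smiles"), "not_a_smiles")
})

test_that("every toy library compound enumerates to valid, parseable isomers", {
  for (smi in toyLigandLibrary()) {
    iso <- enumerateIsomers(smi)
    expect_gte(length(iso), 1L)
    for (s in iso) {
      g <- molGraphFromSmiles(s)
      expect_s4_class(g, "MolGraph")
      expect_gte(nrow(atoms(g)), 4L)
    }
  }
})
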