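test_that("SMILES parsing adds explicit hydrogens and formal charges", {
  m <- parse_molecule("C", "smiles")
  expect_s3_class(m, "qeq_mol")
  expect_equal(sort(table(m$elements), decreasing = TRUE),
               sort(c(C = 1L, H = 4L), decreasing = TRUE), ignore_attr = TRUE)
  expect_length(m$elements, 5L)
  expect_equal(nrow(m$bonds), 4L)
  expect_identical(total_formal_charge(m), 0L)

  ac <- parse_molecule("CC(=O)[O-]", "smiles")
  expect_identical(total_formal_charge(ac), -1L)

  diamine <- parse_molecule("[NH3+]CC[NH3+]", "smiles")
  expect_identical(total_formal_charge(diamine), 2L)
  expect_equal(sum(diamine$formal_charges == 1L), 2L)
})

test_that("malformed records give typed parse errors with no partial result", {
  expect_error(parse_molecule("C(", "smiles"), class = "qeqnet_parse_error")
  expect_error(parse_molecule("C1CC", "smiles"), class = "qeqnet_parse_error")
  expect_error(parse_molecule("C)(C", "smiles"), class = "qeqnet_parse_error")
  expect_error(parse_molecule("not an sdf", "sdf"), class = "qeqnet_parse_error")
})

test_that("out-of-vocabulary elements are refused", {
  expect_error(parse_molecule("C[Si](C)C", "smiles"), class = "qeqnet_vocab_error")
  # but an extended vocabulary accepts them
  m <- parse_molecule("C[Si](C)C", "smiles", vocabulary = c(QEQ_ELEMENTS, "Si"))
  expect_true("Si" %in% m$elements)
})

test_that("multi-fragment records are rejected", {
  expect_error(parse_molecule("O.O", "smiles"), class = "qeqnet_fragment_error")
  expect_error(
    molecule(c("O", "H", "H", "O"), rbind(c(1L, 2L), c(1L, 3L))),
    class = "qeqnet_fragment_error"
  )
})

test_that("molecule construction validates bonds", {
  expect_error(molecule("C", rbind(c(1L, 2L))), class = "qeqnet_mol_error")
  expect_error(molecule(c("C", "C"), rbind(c(1L, 1L))), class = "qeqnet_mol_error")
  expect_error(
    molecule(c("C", "C"), rbind(c(1L, 2L), c(2L, 1L))),
    class = "qeqnet_mol_error"  # duplicate bond under canonical ordering
  )
})

test_that("SDF and MOL2 records parse to the same molecule as their SMILES", {
  sdf_txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", "CC(=O)[O-]", options = data.frame(names = "h", args = ""))
  mol2_txt <- ChemmineOB::convertFormat(
    "SMI", "MOL2", "CC(=O)[O-]", options = data.frame(names = "h", args = ""))
  from_smiles <- parse_molecule("CC(=O)[O-]", "smiles")
  from_sdf <- parse_molecule(sdf_txt, "sdf")
  from_mol2 <- parse_molecule(mol2_txt, "mol2")
  for (m in list(from_sdf, from_mol2)) {
    expect_identical(sort(m$elements), sort(from_smiles$elements))
    expect_identical(total_formal_charge(m), -1L)
    expect_identical(nrow(m$bonds), nrow(from_smiles$bonds))
  }
})

test_that("aromaticity and ring membership are perceived from topology", {
  benz <- parse_molecule("c1ccccc1", "smiles")
  expect_identical(sum(benz$aromatic), 6L)          # the six carbons
  expect_identical(sum(benz$in_ring), 6L)
  hexane <- parse_molecule("C1CCCCC1", "smiles")
  expect_identical(sum(hexane$aromatic), 0L)
  expect_identical(sum(hexane$in_ring), 6L)
})
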