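test_that("parsing counts heavy atoms and rejects malformed SMILES", {
  expect_equal(heavy_atom_count(parse_molecule("CCO")), 3L)
  expect_equal(heavy_atom_count(parse_molecule("NCC(=O)O", "gly")), 5L)
  expect_error(parse_molecule("C1CC", id = "badring"), "badring")
  expect_error(parse_molecule("", id = "empty"), "non-empty")
  expect_error(parse_molecule(c("C", "CC")), "single")
})

test_that("batch parsing reports failures without dropping them silently", {
  recs <- data.frame(id = c("ok1", "broken", "ok2"),
                     smiles = c("CCO", "C1CC", "c1ccccc1"))
  ms <- parse_molecules(recs)
  expect_equal(ms$ids, c("ok1", "ok2"))
  expect_equal(ms$failures$id, "broken")
  expect_error(parse_molecules(data.frame(id = c("a", "a"),
                                          smiles = c("C", "CC"))),
               "duplicate")
})

test_that("descriptors follow the nOH/nNH and nO/nN counting definitions", {
  d_eth <- compute_descriptors(parse_molecule("CCO", "ethanol"))
  expect_equal(d_eth[["hbd"]], 1)
  expect_equal(d_eth[["hba"]], 1)
  expect_equal(d_eth[["n_carbon"]], 2)
  expect_equal(d_eth[["n_hetero"]], 1)
  expect_equal(d_eth[["n_rings"]], 0)
  expect_equal(d_eth[["n_rotb"]], 0)

  # glycine: two N-H plus one O-H; one N plus two O
  d_gly <- compute_descriptors(parse_molecule("NCC(=O)O", "glycine"))
  expect_equal(d_gly[["hbd"]], 3)
  expect_equal(d_gly[["hba"]], 3)
  expect_equal(d_gly[["mw"]], 75.07, tolerance = 1e-3)
  expect_equal(d_gly[["tpsa"]], 63.32, tolerance = 1e-6)
  expect_equal(d_gly[["n_rotb"]], 1)

  # benzene: no polar fragments, one ring
  d_benz <- compute_descriptors(parse_molecule("c1ccccc1", "benzene"))
  expect_identical(d_benz[["tpsa"]], 0)
  expect_equal(d_benz[["n_rings"]], 1)
  expect_equal(d_benz[["n_hetero"]], 0)
})

test_that("descriptor values agree with independently computed references", {
  # reference values computed with RDKit 2024.09 (Wildman-Crippen logP,
  # Ertl TPSA, strict rotatable bonds); MW tolerance covers atomic-weight
  # table revisions
  d_asp <- compute_descriptors(
    parse_molecule("CC(=O)Oc1ccccc1C(=O)O", "aspirin"))
  expect_equal(d_asp[["mw"]], 180.159, tolerance = 1e-4)
  expect_equal(d_asp[["logp"]], 1.3101, tolerance = 0.02)
  expect_equal(d_asp[["tpsa"]], 63.60, tolerance = 1e-6)
  # 3 under the amide-only exclusion: phenyl-O, O-C(=O) and phenyl-C(=O)
  # all rotate (RDKit's strict pattern additionally drops the ester bond)
  expect_equal(d_asp[["n_rotb"]], 3)
  expect_equal(d_asp[["n_rings"]], 1)
  expect_equal(d_asp[["hbd"]], 1)
  expect_equal(d_asp[["hba"]], 4)

  # tetrapeptide GGFL: amide C-N bonds are not rotatable
  d_pep <- compute_descriptors(parse_molecule(
    "NCC(=O)NCC(=O)NC(Cc1ccccc1)C(=O)NC(CC(C)C)C(=O)O", "ggfl"))
  expect_equal(d_pep[["hbd"]], 6)
  expect_equal(d_pep[["hba"]], 9)
  expect_equal(d_pep[["tpsa"]], 150.62, tolerance = 1e-6)
  expect_equal(d_pep[["n_rotb"]], 11)
  expect_equal(d_pep[["mw"]], 392.45, tolerance = 0.02)
})

test_that("descriptors are idempotent and invariant to SMILES rewriting", {
  forms <- list(ethanol = c("CCO", "OCC"),
                glycine = c("NCC(=O)O", "OC(=O)CN", "C(N)C(O)=O"),
                benzene = c("c1ccccc1", "C1=CC=CC=C1"),
                toluene = c("Cc1ccccc1", "c1ccccc1C"))
  for (nm in names(forms)) {
    ref <- compute_descriptors(parse_molecule(forms[[nm]][1], nm))
    for (alt in forms[[nm]][-1]) {
      expect_equal(compute_descriptors(parse_molecule(alt, nm)), ref,
                   info = paste(nm, alt))
    }
    # recomputing on the canonical SMILES reproduces the vector exactly
    mol <- parse_molecule(forms[[nm]][1], nm)
    expect_identical(compute_descriptors(parse_molecule(mol$cansmi, nm)),
                     ref)
  }
})

test_that("pure hydrocarbons carry zero polar descriptors", {
  for (smi in c("CCCCCC", "C1CCCCC1", "Cc1ccccc1", "c1ccc2ccccc2c1",
                "CC(C)(C)C")) {
    d <- compute_descriptors(parse_molecule(smi, smi))
    expect_identical(d[["n_hetero"]], 0)
    expect_identical(d[["hba"]], 0)
    expect_identical(d[["hbd"]], 0)
    expect_identical(d[["tpsa"]], 0)
  }
})

test_that("salts reduce to the largest organic fragment", {
  m <- parse_molecule("CC(=O)O.CCN", "pair")
  expect_equal(heavy_atom_count(m), 4L)      # acetic acid beats ethylamine
  expect_equal(m$dropped_fragments, 1L)
  m2 <- parse_molecule("c1ccccc1.O", "benzene_hydrate")
  expect_equal(heavy_atom_count(m2), 6L)
  m3 <- parse_molecule("[Na+].CC(=O)[O-]", "sodium_acetate")
  expect_equal(compute_descriptors(m3)[["n_carbon"]], 2)
})

test_that("fingerprints honour their length, invariance and radius contracts", {
  eth <- parse_molecule("CCO", "eth")
  fp <- morgan_fingerprint(eth, radius = 2L, n_bits = 2048L)
  expect_length(fp, 2048L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, morgan_fingerprint(parse_molecule("OCC", "eth2"),
                                          2L, 2048L))
  expect_gte(sum(morgan_fingerprint(parse_molecule("C", "methane"),
                                    2L, 2048L)), 1L)
  # bit count is non-decreasing in radius (unfolded width)
  for (smi in c("CCO", "NCC(=O)O", "CC(=O)Oc1ccccc1C(=O)O")) {
    mol <- parse_molecule(smi, smi)
    nset <- vapply(0:3, function(r) {
      sum(morgan_fingerprint(mol, radius = r, n_bits = 4096L))
    }, 0L)
    expect_true(all(diff(nset) >= 0L), info = smi)
  }
  expect_error(morgan_fingerprint(eth, 2L, 1000L), "power of two")
  expect_error(morgan_fingerprint(eth, 2L, 8192L), "native")
  expect_error(morgan_fingerprint(eth, 9L, 2048L), "radius")
})

test_that("molecule readers and the descriptor writer round-trip", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "NCC(=O)O gly", "c1ccccc1"), smi)
  recs <- read_smi(smi)
  expect_equal(recs$id, c("eth", "gly", "mol3"))

  csv <- system.file("extdata", "example_molecules.csv",
                     package = "drugrules")
  recs2 <- read_molecule_csv(csv)
  expect_true(all(c("id", "smiles", "name") %in% names(recs2)))
  tab <- descriptor_table(parse_molecules(recs2))
  expect_equal(nrow(tab), nrow(recs2))
  out <- tempfile(fileext = ".csv")
  write_descriptor_csv(tab, out)
  back <- utils::read.csv(out)
  expect_equal(back$mw, tab$mw, tolerance = 1e-9)

  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_molecule_csv(bad), "smiles")
})
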