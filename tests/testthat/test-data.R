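test_that("the sampler is deterministic, range-respecting and typed", {
  cfg <- sampler_config(500, seed = 11)
  t1 <- sample_descriptor_vectors(cfg)
  t2 <- sample_descriptor_vectors(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 500L)

  ranges <- default_descriptor_ranges()
  for (k in names(ranges)) {
    expect_gte(min(t1[[k]]), ranges[[k]][1])
    expect_lte(max(t1[[k]]), ranges[[k]][2])
  }
  for (k in c("hbd", "hba", "n_rotb", "n_carbon", "n_hetero", "n_rings")) {
    expect_true(all(t1[[k]] == round(t1[[k]])), info = k)
  }
  # byte-identical CSV under a fixed config
  f1 <- tempfile(); f2 <- tempfile()
  utils::write.csv(sample_descriptor_vectors(cfg), f1, row.names = FALSE)
  utils::write.csv(sample_descriptor_vectors(cfg), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(sample_descriptor_vectors(sampler_config(0))), 0L)
  expect_error(sampler_config(-5), "non-negative")
})

test_that("stratified sampling meets the minimum class-count contract", {
  cfg <- sampler_config(5000, seed = 7, stratify_rule = "ro5")
  tab <- sample_descriptor_vectors(cfg)
  expect_equal(nrow(tab), 5000L)
  y <- count_violations_table(tab, builtin_ruleset("ro5"))
  counts <- tabulate(y + 1L, 5L)
  expect_true(all(counts >= 500L))   # floor(5000 / (2 * 5))

  # a rule whose compliant class is unreachable under the ranges
  ranges <- default_descriptor_ranges()
  ranges$mw <- c(700, 2000)          # Muegge needs mw <= 600 for class 0
  expect_error(
    sample_descriptor_vectors(
      sampler_config(200, seed = 1, ranges = ranges,
                     stratify_rule = "muegge", max_batches = 3L)),
    "under-represented")
})

test_that("descriptor tables are labelled by the counters", {
  tab <- data.frame(mw = c(300, 400, 500), logp = c(1, 2, 3),
                    hbd = c(1, 2, 3), hba = c(2, 4, 6),
                    tpsa = c(50, 80, 100), n_rotb = c(3, 5, 7),
                    n_carbon = c(10, 20, 30), n_hetero = c(2, 4, 6),
                    n_rings = c(1, 2, 3))
  ds <- build_dataset_from_descriptor_table(tab, builtin_ruleset("ro5"))
  expect_equal(ds$targets$ro5, c(0L, 0L, 0L))

  bad <- data.frame(mw = 1200, logp = 11, hbd = 7, hba = 16, tpsa = 260,
                    n_rotb = 21, n_carbon = 5, n_hetero = 3, n_rings = 1)
  ds2 <- build_dataset_from_descriptor_table(bad, builtin_ruleset("bro5"))
  expect_equal(ds2$targets$bro5, 6L)

  expect_error(build_dataset_from_descriptor_table(tab[0, ],
                                                   builtin_ruleset("ro5")),
               "empty")
  expect_error(
    build_dataset_from_descriptor_table(tab[setdiff(names(tab), "hba")],
                                        builtin_ruleset("ro5")),
    "hba")
})

test_that("molecule datasets label both representations identically", {
  rules <- list(builtin_ruleset("ro5"), builtin_ruleset("bro5"),
                builtin_ruleset("muegge"))

  gly <- data.frame(id = "gly", smiles = "NCC(=O)O")
  ds <- build_labelled_dataset(gly, rules)
  expect_equal(dim(ds$features), c(1L, 9L))
  # glycine logP is negative, so the default Ro5 (lower logP bound on)
  # counts one violation; the platform convention without it counts none
  expect_equal(ds$targets$ro5, 1L)
  ds_off <- build_labelled_dataset(gly,
                                   builtin_ruleset("ro5",
                                                   ro5_logp_lower = FALSE))
  expect_equal(ds_off$targets$ro5, 0L)
  expect_equal(ds$targets$bro5, 0L)
  expect_equal(ds$targets$muegge, 1L)   # mw 75.07 < 200

  peps <- generate_peptide_set(10, c(2, 8), seed = 5)
  dsd <- build_labelled_dataset(peps, rules)
  dsf <- build_labelled_dataset(peps, rules, representation = "fingerprints",
                                fp_params = list(radius = 2L,
                                                 n_bits = 512L))
  expect_identical(dsd$targets, dsf$targets)
  expect_equal(length(dsf$feature_names), 512L)

  mixed <- rbind(peps[1:3, ], data.frame(id = "bad", smiles = "C1CC",
                                         name = NA))
  expect_warning(dsm <- build_labelled_dataset(mixed, rules), "failed")
  expect_equal(dataset_nrow(dsm), 3L)
  expect_equal(attr(dsm, "failures")$id, "bad")
})

test_that("splits are reproducible partitions of the expected size", {
  ds <- build_dataset_from_descriptor_table(
    sample_descriptor_vectors(sampler_config(10, seed = 2)),
    builtin_ruleset("ro5"))
  parts <- split_dataset(ds, split_spec(0.2, 42L))
  expect_equal(dataset_nrow(parts$train), 8L)
  expect_equal(dataset_nrow(parts$test), 2L)
  expect_length(intersect(parts$train$ids, parts$test$ids), 0L)
  expect_setequal(c(parts$train$ids, parts$test$ids), ds$ids)

  parts2 <- split_dataset(ds, split_spec(0.2, 42L))
  expect_identical(parts$test$ids, parts2$test$ids)
  parts3 <- split_dataset(ds, split_spec(0.2, 43L))
  expect_false(identical(parts$test$ids, parts3$test$ids))

  one <- build_dataset_from_descriptor_table(
    sample_descriptor_vectors(sampler_config(1, seed = 2)),
    builtin_ruleset("ro5"))
  expect_error(split_dataset(one), "non-empty")
  expect_error(split_spec(0), "\\(0, 1\\)")
  expect_error(split_spec(1.2), "\\(0, 1\\)")
})

test_that("dataset CSVs round-trip through the sidecar", {
  rules <- list(builtin_ruleset("ro5"), builtin_ruleset("bro5"))
  ds <- build_dataset_from_descriptor_table(
    sample_descriptor_vectors(sampler_config(50, seed = 4)), rules)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_identical(back$targets, ds$targets)
  expect_identical(back$ids, ds$ids)
  expect_equal(back$features, ds$features, tolerance = 1e-9)
  expect_equal(back$representation, "descriptors")

  peps <- generate_peptide_set(6, c(2, 5), seed = 9)
  dsf <- build_labelled_dataset(peps, builtin_ruleset("ro5"),
                                representation = "fingerprints",
                                fp_params = list(radius = 2L,
                                                 n_bits = 256L))
  pf <- tempfile(fileext = ".csv")
  write_dataset_csv(dsf, pf)
  backf <- read_dataset_csv(pf)
  expect_identical(as.matrix(backf$features), as.matrix(dsf$features))
  expect_identical(backf$targets, dsf$targets)

  expect_error(read_dataset_csv(tempfile()), "sidecar")
})

test_that("the peptide assembler emits valid backbone SMILES", {
  expect_equal(generate_peptide_smiles(residues = "G")$smiles, "NCC(=O)O")
  expect_equal(generate_peptide_smiles(residues = c("G", "G"))$smiles,
               "NCC(=O)NCC(=O)O")
  expect_equal(generate_peptide_smiles(residues = "GG")$smiles,
               "NCC(=O)NCC(=O)O")
  expect_error(generate_peptide_smiles(residues = "GXZ"), "unknown residue")

  # any 12-mer parses and exceeds the Ro5 weight threshold
  for (seed in c(1L, 2L, 3L)) {
    rec <- generate_peptide_smiles(length = 12L, seed = seed, id = "p12")
    mol <- parse_molecule(rec$smiles, rec$id)
    expect_gt(compute_descriptors(mol)[["mw"]], 500)
  }

  set1 <- generate_peptide_set(5, c(2, 6), seed = 31)
  set2 <- generate_peptide_set(5, c(2, 6), seed = 31)
  expect_identical(set1, set2)
  expect_equal(nrow(set1), 5L)
  # every assembled SMILES is parseable
  expect_equal(nrow(parse_molecules(set1)$failures), 0L)
})
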