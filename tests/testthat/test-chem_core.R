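test_that("canonicalization maps equivalent SMILES to one form and is idempotent", {
  expect_identical(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  corpus <- fixture_corpus(30)
  canon <- canonicalize(corpus)
  expect_identical(canonicalize(canon), canon)
})

test_that("unparseable SMILES raise errors naming the offending input", {
  expect_error(canonicalize("C1CC"), "C1CC")
  expect_error(canonicalize("not_a_molecule"), "invalid SMILES")
  p <- parse_smiles(c("CCO", "C1CC", ""))
  expect_identical(p$valid, c(TRUE, FALSE, FALSE))
  expect_true(all(p$mw[p$valid] > 0))
})

test_that("molecule records carry canonical SMILES and positive descriptors", {
  rec <- molecule_record(c("CCO", "c1ccccc1"), id = c("a", "b"))
  expect_identical(rec$smiles_canonical, c("CCO", "c1ccccc1"))
  expect_true(all(rec$mw > 0))
  expect_error(molecule_record(c("CCO", "C1CC"), id = c("a", "b")), "b")
})

test_that("file readers round-trip ids and SMILES", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# header", "CCO\tethanol", "c1ccccc1"), tmp)
  sm <- read_smiles_file(tmp)
  expect_identical(sm$smiles, c("CCO", "c1ccccc1"))
  expect_identical(sm$id[1], "ethanol")

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "x", smiles = "CCO"), csv, row.names = FALSE)
  expect_identical(read_molecules_csv(csv)$smiles, "CCO")

  out <- withr::local_tempfile(fileext = ".csv")
  write_molecules_csv(molecule_record("CCO", id = "e"), out)
  expect_identical(read.csv(out)$smiles_canonical, "CCO")
})

test_that("SDF records are read via the backend", {
  sdf <- c("ethanol",
           "  molforge",
           "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    1.3000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0",
           "  2  3  1  0",
           "M  END",
           "$$$$")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, tmp)
  mols <- read_sdf(tmp)
  expect_identical(mols$id, "ethanol")
  expect_identical(canonicalize(mols$smiles), "CCO")
})

test_that("fingerprints are deterministic, correctly sized, non-empty for heavy atoms", {
  f1 <- fingerprints("c1ccccc1O")[[1]]
  f2 <- fingerprints("Oc1ccccc1")[[1]]  # same molecule, different input order
  for (k in FP_KINDS) expect_identical(unclass(f1[[k]]), unclass(f2[[k]]))
  expect_identical(attr(f1$MACCS166, "nbits"), 166L)
  expect_identical(attr(f1$PATH, "nbits"), 2048L)
  expect_gt(length(f1$PATH), 0)
  expect_gt(length(f1$CIRCULAR), 0)
  expect_error(fingerprint("CCO", "NOT_A_KIND"))
  expect_error(fingerprints("CCO", nbits = 1000), "power of two")
})

test_that("similarity measures match their closed forms on a hand-evaluated pair", {
  A <- fp_from_bits(c(1, 2, 3))
  B <- fp_from_bits(c(2, 3, 4))
  expect_equal(similarity(A, B, "TANIMOTO"), 0.5)
  expect_equal(similarity(A, B, "DICE"), 2 / 3, tolerance = 1e-12)
  expect_equal(similarity(A, B, "COSINE"), 2 / 3, tolerance = 1e-12)
  expect_equal(similarity(A, B, "SOKAL"), 1 / 3, tolerance = 1e-12)
  expect_equal(similarity(A, B, "KULCZYNSKI"), 2 / 3, tolerance = 1e-12)
  expect_equal(similarity(A, B, "MCCONNAUGHEY"), 1 / 3, tolerance = 1e-12)
})

test_that("self-similarity is maximal and disjoint sets score zero", {
  A <- fp_from_bits(c(5, 9, 100))
  for (m in setdiff(SIM_MEASURES, "MCCONNAUGHEY")) {
    expect_equal(similarity(A, A, m), 1)
  }
  expect_equal(similarity(A, A, "MCCONNAUGHEY"), 1)
  B <- fp_from_bits(c(7, 8))
  expect_equal(similarity(A, B, "TANIMOTO"), 0)
  expect_equal(similarity(A, B, "MCCONNAUGHEY"), -1)
})

test_that("degenerate vectors follow the documented conventions", {
  Z <- fp_from_bits(integer(0))
  A <- fp_from_bits(1:3)
  for (m in setdiff(SIM_MEASURES, "MCCONNAUGHEY")) {
    expect_equal(similarity(Z, Z, m), 0)
    expect_equal(similarity(Z, A, m), 0)
  }
  expect_error(similarity(Z, Z, "MCCONNAUGHEY"), "undefined")
  expect_error(similarity(Z, A, "MCCONNAUGHEY"), "undefined")
  expect_error(similarity(A, fp_from_bits(1, nbits = 166), "TANIMOTO"),
               "mismatch")
})

test_that("all six measures agree with a brute-force set-arithmetic oracle", {
  set.seed(99)
  nbits <- 64L
  for (i in 1:300) {
    bitsA <- sample(0:(nbits - 1), sample(1:40, 1))
    bitsB <- sample(0:(nbits - 1), sample(1:40, 1))
    A <- fp_from_bits(bitsA, nbits)
    B <- fp_from_bits(bitsB, nbits)
    for (m in SIM_MEASURES) {
      expect_equal(similarity(A, B, m), oracle_similarity(bitsA, bitsB, nbits, m),
                   tolerance = 1e-12)
    }
    expect_lte(similarity(A, B, "TANIMOTO"), similarity(A, B, "DICE"))
    expect_equal(similarity(A, B, "TANIMOTO"), similarity(B, A, "TANIMOTO"))
  }
})
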