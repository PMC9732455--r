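test_that("BRICS fragmentation handles uncleavable and amide-containing molecules", {
  fr <- fragment_molecules(c("CC", "CC(=O)Nc1ccccc1"))
  expect_identical(fr[[1]]$fragments, "CC")
  expect_identical(fr[[1]]$bonds, character(0))
  # reference BRICS decomposition: acyl, linker nitrogen, aryl
  expect_identical(sort(fr[[2]]$fragments), c("*C(C)=O", "*N*", "*c1ccccc1"))
  expect_identical(sort(fr[[2]]$bonds), c("L1-L5", "L16-L5"))
  # invariant to input atom ordering
  fr2 <- fragment_molecules("c1ccccc1NC(C)=O")
  expect_identical(sort(fr2[[1]]$fragments), sort(fr[[2]]$fragments))
})

test_that("fragment space counts aggregate occurrences and add over corpora", {
  one <- build_fragment_space(rep("CC(=O)Nc1ccccc1", 10))
  expect_true(all(one$fragments == 10))
  expect_true(all(one$bonds == 10))

  a <- build_fragment_space(c("CC(=O)Nc1ccccc1"), corpus_id = "a")
  b <- build_fragment_space(c("CC(=O)Nc1ccccc1", "CCOC(=O)c1ccccc1"),
                            corpus_id = "b")
  m <- merge_fragment_spaces(a, b)
  for (f in names(m$fragments)) {
    expect_identical(m$fragments[[f]],
                     sum(a$fragments[f], b$fragments[f], na.rm = TRUE))
  }
  expect_identical(m$corpus_size, 3L)

  # brute-force recount over a fixture corpus
  corpus <- fixture_corpus(30)
  space <- build_fragment_space(corpus)
  per_mol <- fragment_molecules(corpus)
  expect_identical(sum(space$fragments),
                   length(unlist(lapply(per_mol, `[[`, "fragments"))))
  expect_identical(sum(space$bonds),
                   length(unlist(lapply(per_mol, `[[`, "bonds"))))
})

test_that("RAFSF spans 1 (all pieces at the space maximum) to 10 (absent piece)", {
  # all of this molecule's pieces are distinct, so each count equals Cmax = 1
  space <- build_fragment_space("CC(=O)Nc1ccccc1")
  expect_equal(rafsf_score("CC(=O)Nc1ccccc1", space)$score, 1)
  # a molecule introducing unseen fragments scores exactly 10
  out <- rafsf_score("CCCCNC(=O)C1CCCN1", space)
  expect_equal(out$score, 10)
  expect_true(is.na(out$rarest_count))
})

test_that("the log-frequency penalty hits the documented midpoint", {
  space <- build_fragment_space("CC(=O)Nc1ccccc1")
  # engineer counts: rare fragment at 9, others at Cmax = 99
  # log10(1+9)/log10(1+99) = 1/2 -> penalty 0.5 -> score 5.5
  space$fragments[] <- 99L
  space$fragments["*c1ccccc1"] <- 9L
  space$bonds[] <- 99L
  res <- rafsf_score("CC(=O)Nc1ccccc1", space)
  expect_equal(res$score, 5.5, tolerance = 1e-12)
  expect_identical(res$rarest_piece, "*c1ccccc1")
})

test_that("RAFSF is bounded, monotone in counts, and deterministic", {
  corpus <- fixture_corpus(60)
  space <- build_fragment_space(corpus)
  scores <- rafsf_score(corpus, space)
  expect_true(all(scores$score >= 1 & scores$score <= 10))
  expect_equal(scores$score, rafsf_score(corpus, space)$score)

  # decrementing a fragment count never decreases a score (for fragments not
  # defining the space maximum; lowering Cmax itself rescales all penalties)
  mol <- corpus[1]
  base <- rafsf_score(mol, space)$score
  cmax <- max(space$fragments)
  for (f in rafsf_score(mol, space)$detail[[1]]$piece) {
    sp2 <- space
    if (f %in% names(sp2$fragments) && sp2$fragments[[f]] > 1 &&
        sp2$fragments[[f]] < cmax) {
      sp2$fragments[[f]] <- sp2$fragments[[f]] - 1L
      expect_gte(rafsf_score(mol, sp2)$score, base)
    }
  }
})

test_that("space files are self-describing and round-trip losslessly", {
  space <- build_fragment_space(fixture_corpus(30), corpus_id = "fix30")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_space(space, tmp)
  back <- read_fragment_space(tmp)
  expect_identical(back$fragments[order(names(back$fragments))],
                   space$fragments[order(names(space$fragments))])
  expect_identical(back$bonds[order(names(back$bonds))],
                   space$bonds[order(names(space$bonds))])
  expect_identical(back$rules, space$rules)
  expect_identical(back$corpus_id, "fix30")
  expect_error(read_fragment_space(system.file("extdata",
                                               "kinase_panel_SYNTHETIC.csv",
                                               package = "molforge")),
               "not a RAFSF space file")
})

test_that("empty corpora and empty spaces are rejected", {
  expect_error(build_fragment_space(character(0)))
  space <- build_fragment_space("CC")
  space$fragments <- stats::setNames(integer(0), character(0))
  expect_error(rafsf_score("CC", space), "empty")
})
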