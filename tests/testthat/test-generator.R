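test_that("tokenisation keeps multi-character tokens intact and round-trips", {
  expect_identical(tokenize_smiles("CCl")[[1]], c("C", "Cl"))
  expect_identical(tokenize_smiles("BrCC[nH]")[[1]], c("Br", "C", "C", "[nH]"))
  expect_identical(tokenize_smiles("C%12CC%12")[[1]], c("C", "%12", "C", "C", "%12"))
  corpus <- fixture_corpus(40, seed = 5)
  rebuilt <- vapply(tokenize_smiles(corpus), paste, character(1), collapse = "")
  expect_identical(rebuilt, corpus)
})

test_that("vocabularies enumerate corpus tokens deterministically", {
  v <- build_vocabulary("CCO")
  expect_identical(v$tokens, c("<PAD>", "<BEGIN>", "<END>", "C", "O"))
  v2 <- build_vocabulary(c("CCl", "CC"))
  expect_true("Cl" %in% v2$tokens)
  expect_false("l" %in% v2$tokens)
  # encode/decode round-trip through specials
  ids <- encode_smiles(v, "CCO")[[1]]
  expect_identical(ids[1], v$begin)
  expect_identical(ids[length(ids)], v$end)
  expect_identical(decode_smiles(v, ids), "CCO")
  expect_error(encode_smiles(v, "CN"), "'N'")
})

test_that("sampling is reproducible and respects the length cap", {
  m <- tiny_model()
  s1 <- sample_smiles(m, 30, seed = 42)
  s2 <- sample_smiles(m, 30, seed = 42)
  expect_identical(s1, s2)
  expect_identical(length(s1), 30L)
  short <- sample_smiles(m, 20, seed = 1, max_length = 5)
  expect_true(all(lengths(tokenize_smiles(short)) <= 5))
  expect_error(sample_smiles(m, 5, temperature = 0))
})

test_that("checkpoints round-trip with identical sampling behaviour", {
  m <- tiny_model()
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_generator(m, tmp)
  back <- load_generator(tmp)
  expect_identical(sample_smiles(back, 25, seed = 7),
                   sample_smiles(m, 25, seed = 7))
  # corruption is detected
  broken <- readRDS(tmp)
  broken$params$by[1] <- broken$params$by[1] + 1
  tmp2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(broken, tmp2)
  expect_error(load_generator(tmp2), "hash")
})

test_that("training reduces the loss and records a history", {
  m <- tiny_model()
  expect_identical(nrow(m$history), 2L)
  expect_lt(m$history$train_loss[2], m$history$train_loss[1])
  expect_true(all(is.finite(m$history$val_loss)))
  expect_error(pretrain(c("CCO", "CC"), epochs = 1), "10")
})

test_that("an overfit single-molecule model regenerates its training molecule", {
  target <- "CCOC(=O)c1ccccc1"
  m <- pretrain(rep(target, 10), epochs = 120, seed = 2,
                config = generator_config(layers = 1L, hidden = 24L,
                                          batch_size = 4L, lr = 5e-3))
  # low-temperature sampling approaches argmax decoding
  s <- sample_smiles(m, 20, temperature = 0.05, seed = 3)
  expect_identical(unique(s), target)
  # the training molecule is the modal sample at moderate temperature
  s2 <- sample_smiles(m, 60, temperature = 0.5, seed = 4)
  expect_identical(names(sort(table(s2), decreasing = TRUE))[1], target)
})

test_that("fine-tuning raises the focused-set likelihood; zero epochs is identity", {
  corpus <- fixture_corpus(60, seed = 11)
  m <- memo("ft_base", pretrain(corpus, epochs = 4, seed = 6,
                                config = generator_config(layers = 1L,
                                                          hidden = 48L,
                                                          batch_size = 16L,
                                                          lr = 5e-3)))
  focused <- generate_analog_series(FIXTURE_SCAFFOLDS[1], "C1CCNCC1",
                                    "C(C)(C)C", n = 12, seed = 13)
  ft <- fine_tune(m, focused, epochs = 6, seed = 7)
  expect_gt(ft$focused_ll_after, ft$focused_ll_before)
  expect_equal(ft$focused_ll_before, log_likelihood(m, focused),
               tolerance = 1e-10)

  same <- fine_tune(m, focused, epochs = 0)
  expect_identical(sample_smiles(same, 10, seed = 9),
                   sample_smiles(m, 10, seed = 9))

  # fine-tuning on a subset of the pretraining corpus is also non-decreasing
  ft2 <- fine_tune(m, corpus[1:10], epochs = 3, seed = 8)
  expect_gte(ft2$focused_ll_after, ft2$focused_ll_before)
})

test_that("generation metrics match hand counts on a constructed sample", {
  rep_ <- evaluate_generation(c("CCO", "CCO", "C1CC", "c1ccccc1"),
                              training = "CCO")
  expect_equal(rep_$validity, 0.75)
  expect_equal(rep_$uniqueness, 2 / 3, tolerance = 1e-12)
  expect_equal(rep_$novelty, 0.5)

  allbad <- evaluate_generation(c("C1CC", "xx"), training = "CCO")
  expect_equal(allbad$validity, 0)
  expect_true(is.na(allbad$uniqueness))
  expect_true(is.na(allbad$novelty))

  memorised <- evaluate_generation(c("CCO", "OCC"), training = "CCO")
  expect_equal(memorised$novelty, 0)
})

test_that("diversity and scaffold overlap are computed on unique valid molecules", {
  rep_ <- evaluate_generation(c("CCO", "CCO"), training = "CC")
  expect_true(is.na(rep_$internal_diversity))  # a single unique molecule
  rep2 <- evaluate_generation(c("c1ccccc1CC", "c1ccccc1CCC", "CCNCC"),
                              training = "CC",
                              reference = "c1ccccc1C")
  expect_gt(rep2$internal_diversity, 0)
  expect_lt(rep2$internal_diversity, 1)
  # two of three unique valid molecules share the benzene framework
  expect_equal(rep2$scaffold_overlap, 2 / 3, tolerance = 1e-12)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep2, tmp)
  expect_equal(jsonlite::read_json(tmp)$n_sampled, 3)
})
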