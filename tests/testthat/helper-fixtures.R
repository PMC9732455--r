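# Shared fixtures, built once per test run.  Fingerprint/fragmentation
# results are additionally memoised inside the package, so repeated use
# across test files costs one backend round-trip.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

fixture_corpus <- function(n = 60, seed = 11) {
  memo(paste0("corpus_", n, "_", seed), generate_corpus(n, seed = seed))
}

# hand-built fingerprints for similarity arithmetic
fp_from_bits <- function(bits, nbits = 2048L, kind = "PATH") {
  structure(sort(as.integer(bits)), nbits = as.integer(nbits), kind = kind,
            class = "molforge_fp")
}

# independent dense-logical-vector similarity oracle (set arithmetic done a
# different way than the implementation's sorted-integer intersections)
oracle_similarity <- function(bitsA, bitsB, nbits, measure) {
  va <- rep(FALSE, nbits); va[bitsA + 1] <- TRUE
  vb <- rep(FALSE, nbits); vb[bitsB + 1] <- TRUE
  a <- sum(va); b <- sum(vb); cc <- sum(va & vb)
  switch(measure,
    TANIMOTO = if (a + b - cc == 0) 0 else cc / (a + b - cc),
    DICE = if (a + b == 0) 0 else 2 * cc / (a + b),
    COSINE = if (a * b == 0) 0 else cc / sqrt(a * b),
    SOKAL = if (2 * a + 2 * b - 3 * cc == 0) 0 else cc / (2 * a + 2 * b - 3 * cc),
    KULCZYNSKI = if (a * b == 0) 0 else cc * (a + b) / (2 * a * b),
    MCCONNAUGHEY = (cc * (a + b) - a * b) / (a * b))
}

# a tiny pre-trained generator shared across generator tests
tiny_model <- function() {
  memo("tiny_model", {
    corpus <- fixture_corpus(40, seed = 5)
    pretrain(corpus, epochs = 2, seed = 3,
             config = generator_config(layers = 1L, hidden = 24L,
                                       batch_size = 8L, lr = 5e-3))
  })
}
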