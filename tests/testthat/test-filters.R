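test_that("property windows are closed intervals with named violations", {
  mol <- "CC(=O)Nc1ccccc1"
  mw <- parse_smiles(mol)$mw
  lp <- parse_smiles(mol)$logp
  expect_true(property_filter(mol, c(100, 600), c(-1, 6))$pass)
  # a bound exactly at the computed value still passes
  expect_true(property_filter(mol, c(mw, mw), c(lp, lp))$pass)
  res <- property_filter(mol, c(mw + 1, 600), c(-1, 6))
  expect_false(res$pass)
  expect_identical(res$violations, "mw")
  res2 <- property_filter(mol, c(mw + 1, 600), c(lp + 1, 6))
  expect_identical(res2$violations, "mw,logp")
})

test_that("the PAINS catalog flags a catechol and passes ethanol", {
  res <- alert_filter(c("CCO", "Oc1ccccc1O"))
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  expect_match(res$alerts[2], "catechol_A")
})

test_that("custom alert files work and uncompilable SMARTS are named", {
  f <- withr::local_tempfile(fileext = ".smarts")
  writeLines(c("# comment", "nitro\t[N+](=O)[O-]"), f)
  res <- alert_filter(c("CCO", "O=[N+]([O-])c1ccccc1"), alert_file = f)
  expect_identical(res$pass, c(TRUE, FALSE))
  expect_identical(res$alerts[2], "nitro")

  empty <- withr::local_tempfile(fileext = ".smarts")
  writeLines("# nothing", empty)
  expect_true(all(alert_filter(c("CCO", "Oc1ccccc1O"), alert_file = empty)$pass))

  bad <- withr::local_tempfile(fileext = ".smarts")
  writeLines("broken\t[C~~", bad)
  expect_error(alert_filter("CCO", alert_file = bad), "broken")
})

test_that("novelty is exact canonical set-difference", {
  expect_identical(novelty_filter(c("CCO", "c1ccccc1"), "OCC")$pass,
                   c(FALSE, TRUE))
  expect_true(all(novelty_filter(c("CCO", "CC"), character(0))$pass))
})

test_that("the funnel conjunction, reasons and survivor count are exact", {
  space <- build_fragment_space(fixture_corpus(200))
  ref <- "CCCCNC(=O)c1ccc(C(C)(C)C)cc1"
  hits <- c(
    canonicalize(ref),                  # fails novelty only
    "Oc1ccccc1O",                       # fails PAINS + property + feasibility
    "CCO",                              # fails property (mw) + feasibility
    "CCCCNC(=O)c1ccc(C(C)C)cc1",        # in-family: passes everything
    "CCCCNC(=O)c1ccc(CC)cc1"            # in-family: passes everything
  )
  v <- apply_funnel(hits, space = space, reference = ref)
  expect_identical(v$pass, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_false(v$novelty[1])
  expect_false(v$alerts[2])
  expect_false(v$property[3])
  expect_match(v$reasons[3], "property:mw")
  expect_identical(funnel_survivors(v), hits[4:5])
  # the overall verdict is exactly the conjunction of the per-filter columns
  expect_identical(v$pass, v$property & v$alerts & v$novelty &
                             v$feasibility & v$toxicity)
  # toxicity plug-in contract: a failing plug-in removes everything
  v2 <- apply_funnel(hits, space = space, reference = ref,
                     toxicity_plugins = list(
                       block = function(s) tibble::tibble(pass = rep(FALSE, length(s)),
                                                          score = rep(1, length(s)))))
  expect_identical(sum(v2$pass), 0L)
})

test_that("disabled filters are recorded as not-evaluated, not as passes", {
  v <- apply_funnel(c("CCO", "Oc1ccccc1O"), filters = "alerts")
  expect_true(all(is.na(v$property)))
  expect_true(all(is.na(v$novelty)))
  expect_identical(v$pass, c(TRUE, FALSE))
  v0 <- apply_funnel(c("CCO", "Oc1ccccc1O"), filters = character(0))
  expect_true(all(v0$pass))
})

test_that("the funnel is monotone in enabled filters and idempotent", {
  space <- build_fragment_space(fixture_corpus(200))
  hits <- c("CCO", "Oc1ccccc1O", "CCCCNC(=O)c1ccc(C(C)C)cc1",
            "CCCCNC(=O)c1ccc(CC)cc1")
  sets <- list("property", c("property", "alerts"),
               c("property", "alerts", "feasibility"),
               c("property", "alerts", "feasibility", "novelty", "toxicity"))
  prev <- Inf
  for (fs in sets) {
    n <- sum(apply_funnel(hits, filters = fs, space = space,
                          reference = "CC")$pass)
    expect_lte(n, prev)
    prev <- n
  }
  v <- apply_funnel(hits, space = space, reference = "CC")
  surv <- funnel_survivors(v)
  v2 <- apply_funnel(surv, space = space, reference = "CC")
  expect_identical(funnel_survivors(v2), surv)
})

test_that("funnel verdicts serialise to CSV", {
  v <- apply_funnel("CCO", filters = "property")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_verdicts(v, tmp)
  expect_true("pass" %in% names(read.csv(tmp)))
})
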