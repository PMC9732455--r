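#' Pipeline run configuration
#'
#' All knobs of the generate -> evaluate -> filter -> feasibility-rank funnel
#' in one serialisable object.  The full configuration is echoed into the
#' run summary so every output is traceable to its settings, and two runs
#' with equal configurations produce identical outputs.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param corpus_size Pretraining corpus size.
#' @param pretrain_epochs,finetune_epochs LSTM training epochs.
#' @param n_focused Size of the fine-tuning analog series.
#' @param n_samples Number of SMILES sampled from the fine-tuned model.
#' @param temperature Sampling temperature.
#' @param hidden,layers LSTM size (see [generator_config()]).
#' @param rafsf_threshold Feasibility cutoff used by the funnel.
#' @param mw_range,logp_range Property windows.
#' @param filters Funnel stages to enable (see [apply_funnel()]).
#' @param query_scaffold,query_r1,query_r2 Template of the design query used
#'   for the focused set.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, corpus_size = 500L,
                            pretrain_epochs = 20L, finetune_epochs = 10L,
                            n_focused = 20L, n_samples = 1000L,
                            temperature = 1.0, hidden = 256L, layers = 2L,
                            rafsf_threshold = 6.0,
                            mw_range = c(200, 600), logp_range = c(-1, 6),
                            filters = c("property", "alerts", "novelty",
                                        "feasibility", "toxicity"),
                            query_scaffold = FIXTURE_SCAFFOLDS[1],
                            query_r1 = "C1CCNCC1", query_r2 = "C(C)(C)C") {
  cfg <- list(seed = as.integer(seed), corpus_size = as.integer(corpus_size),
              pretrain_epochs = as.integer(pretrain_epochs),
              finetune_epochs = as.integer(finetune_epochs),
              n_focused = as.integer(n_focused),
              n_samples = as.integer(n_samples), temperature = temperature,
              hidden = as.integer(hidden), layers = as.integer(layers),
              rafsf_threshold = rafsf_threshold, mw_range = mw_range,
              logp_range = logp_range, filters = filters,
              query_scaffold = query_scaffold, query_r1 = query_r1,
              query_r2 = query_r2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; omitted keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage_done <- function(dir, name, hash) {
  marker <- file.path(dir, paste0(".", name, ".hash"))
  file.exists(marker) && identical(readLines(marker, warn = FALSE), hash)
}

stage_mark <- function(dir, name, hash) {
  writeLines(hash, file.path(dir, paste0(".", name, ".hash")))
}

#' Run the full de novo design funnel
#'
#' Orchestrates: fixture corpus -> LSTM pretraining -> focused-set
#' fine-tuning -> sampling -> generation metrics -> lead-like funnel
#' (property, alerts, novelty vs the focused actives, RAFSF feasibility
#' against a corpus-derived fragment space, toxicity plug-ins) -> survivor
#' ranking by feasibility.  Every stage writes its output under `out_dir`
#' and records a hash of the configuration; a rerun with the same
#' configuration reuses completed stages (`resume = TRUE`), and any stage
#' failure leaves earlier outputs in place.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse stage outputs whose configuration hash matches.
#' @return The run summary (also written to `summary.json`): funnel counts
#'   (`n_sampled` >= `n_valid_unique` >= `n_survivors`), generation metrics
#'   and the full configuration.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n", sep = "",
        file = log_path, append = TRUE)
  }
  run_stage <- function(name, files, fn) {
    paths <- file.path(out_dir, files)
    if (resume && stage_done(out_dir, name, hash) && all(file.exists(paths))) {
      logmsg("stage ", name, ": reused")
      return(invisible(NULL))
    }
    logmsg("stage ", name, ": start")
    ok <- tryCatch({fn(paths); TRUE},
                   error = function(e) {
                     logmsg("stage ", name, ": FAILED: ", conditionMessage(e))
                     stop("pipeline stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    stage_mark(out_dir, name, hash)
    logmsg("stage ", name, ": done")
    invisible(NULL)
  }

  run_stage("corpus", "corpus.smi", function(p) {
    corpus <- generate_corpus(config$corpus_size, seed = config$seed)
    writeLines(corpus, p[1])
  })
  corpus <- readLines(file.path(out_dir, "corpus.smi"))

  run_stage("pretrain", "pretrained.rds", function(p) {
    model <- pretrain(corpus, epochs = config$pretrain_epochs,
                      seed = config$seed,
                      config = generator_config(layers = config$layers,
                                                hidden = config$hidden))
    save_generator(model, p[1])
  })

  run_stage("focused", "focused.smi", function(p) {
    focused <- generate_analog_series(config$query_scaffold, config$query_r1,
                                      config$query_r2, n = config$n_focused,
                                      seed = config$seed + 1L)
    writeLines(focused, p[1])
  })
  focused <- readLines(file.path(out_dir, "focused.smi"))

  run_stage("finetune", "finetuned.rds", function(p) {
    model <- load_generator(file.path(out_dir, "pretrained.rds"))
    model <- fine_tune(model, focused, epochs = config$finetune_epochs,
                       seed = config$seed + 2L)
    save_generator(model, p[1])
  })

  run_stage("sample", "samples.smi", function(p) {
    model <- load_generator(file.path(out_dir, "finetuned.rds"))
    samples <- sample_smiles(model, config$n_samples,
                             temperature = config$temperature,
                             seed = config$seed + 3L)
    writeLines(samples, p[1])
  })
  samples <- readLines(file.path(out_dir, "samples.smi"))

  run_stage("evaluate", "generation_report.json", function(p) {
    report <- evaluate_generation(samples, training = corpus,
                                  reference = focused,
                                  seed = config$seed + 4L)
    write_report(report, p[1])
  })
  report <- jsonlite::read_json(file.path(out_dir, "generation_report.json"))

  run_stage("space", "fragment_space.tsv", function(p) {
    write_fragment_space(build_fragment_space(corpus, corpus_id = "fixture"),
                         p[1])
  })

  run_stage("funnel", c("verdicts.csv", "survivors.csv"), function(p) {
    space <- read_fragment_space(file.path(out_dir, "fragment_space.tsv"))
    parsed <- parse_smiles(samples)
    hits <- unique(parsed$canonical[parsed$valid])
    verdicts <- apply_funnel(hits, filters = config$filters, space = space,
                             reference = focused,
                             rafsf_threshold = config$rafsf_threshold,
                             mw_range = config$mw_range,
                             logp_range = config$logp_range)
    write_verdicts(verdicts, p[1])
    survivors <- funnel_survivors(verdicts)
    ranked <- if (length(survivors)) {
      rs <- rafsf_score(survivors,
                        read_fragment_space(file.path(out_dir,
                                                      "fragment_space.tsv")))
      rs[order(rs$score, rs$smiles), c("smiles", "score")]
    } else tibble::tibble(smiles = character(), score = numeric())
    utils::write.csv(as.data.frame(ranked), p[2], row.names = FALSE)
  })

  verdicts <- utils::read.csv(file.path(out_dir, "verdicts.csv"))
  parsed <- parse_smiles(samples)
  summary <- list(
    config = unclass(config), config_hash = unname(hash),
    funnel = list(n_sampled = length(samples),
                  n_valid = sum(parsed$valid),
                  n_valid_unique = nrow(verdicts),
                  n_survivors = sum(verdicts$pass)),
    generation = report)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
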