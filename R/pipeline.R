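# End-to-end pipeline: generate-params -> calibrate -> scan -> call -> score.
# Configuration is a plain named list (or a YAML file of one); every stage
# logs to stderr and all randomness flows from explicit seeds.

pipeline_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))
  }
}

#' Default pipeline configuration
#'
#' A small, fast demonstration setup; override any entry via the `config`
#' argument of [run_pipeline()] or a YAML file.
#'
#' @return Named list of configuration entries: alphabet kind, orbital
#'   count, seeds, electrode label and gamma, bias voltage, calibration
#'   sizes, model order, test-set size and optional output directory.
#' @export
default_pipeline_config <- function() {
  list(
    alphabet_kind = "DNA",
    m = 5L,
    param_seed = 1L,
    electrode = "Al",
    gamma = 1e-3,
    bias_voltage = 0.1,
    calibration = list(n_sequences = 4L, sequence_length = 50L,
                       n_polyx_sequences = 1L, polyx_length_range = c(3L, 10L),
                       seed = 11L),
    pdf_grid = list(),
    order = 2L,
    test = list(n_sequences = 1L, sequence_length = 50L, seed = 101L),
    out_dir = NULL,
    verbose = TRUE
  )
}

scan_sequences <- function(seqs, params, electrode, bias, stage, verbose) {
  lapply(seq_along(seqs), function(i) {
    pipeline_log(stage, "scanning sequence %d/%d (%d nt)", i, length(seqs),
                 length(seqs[[i]]), verbose = verbose)
    scan_chain(build_chain(seqs[[i]], params), electrode, bias)
  })
}

#' Run the full simulation and base-calling pipeline
#'
#' Stages: (1) synthesize a fragment parameter set; (2) generate training
#' sequences, compute their current traces and build the P1/P2/P3 library;
#' (3) generate held-out test sequences and their traces; (4) call bases at
#' order 1 and refine to the configured order; (5) score fidelity against
#' the known truth.  Identical configuration and seeds give identical
#' artifacts.  If `out_dir` is set, the parameter set (JSON), traces (TSV),
#' called sequences (FASTA), PDF library (RDS) and a provenance block
#' (YAML) are written there.
#'
#' @param config Named list (see [default_pipeline_config()]) or path to a
#'   YAML file with the same structure; partial lists are merged over the
#'   defaults.
#' @return List with `params`, `pdfs`, `test_sequences`, `test_traces`,
#'   `calls`, `reports` (per test sequence, orders 1 and `order`), and
#'   `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  v <- cfg$verbose

  stage <- "generate-params"
  params <- tryCatch(
    generate_parameter_set(cfg$alphabet_kind, m = cfg$m, seed = cfg$param_seed),
    error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  pipeline_log(stage, "%s alphabet, m = %d, seed = %d", cfg$alphabet_kind,
               cfg$m, cfg$param_seed, verbose = v)

  stage <- "configure"
  electrode <- tryCatch({
    if (inherits(cfg$electrode, "electrode_pair")) cfg$electrode
    else electrode_pair(cfg$electrode, gamma = cfg$gamma)
  }, error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  bias <- bias_spec(cfg$bias_voltage)

  stage <- "calibrate"
  result <- tryCatch({
    cal_cfg <- do.call(calibration_config, c(
      cfg$calibration, list(alphabet_kind = cfg$alphabet_kind,
                            electrode = electrode, bias = bias)))
    train <- generate_training_sequences(cal_cfg)
    traces <- scan_sequences(train, params, electrode, bias, stage, v)
    store <- collect_observations(train, traces)
    pipeline_log(stage, "%d observations (%d singles)", store$counts$singles,
                 store$counts$singles, verbose = v)
    pdfs <- build_pdfs(store, cfg$pdf_grid)
    list(train = train, store = store, pdfs = pdfs)
  }, error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))

  stage <- "scan"
  test <- tryCatch({
    set.seed(cfg$test$seed)
    seqs <- lapply(seq_len(cfg$test$n_sequences), function(i) {
      nucleotide_sequence(sample(tb_alphabet(cfg$alphabet_kind),
                                 cfg$test$sequence_length, replace = TRUE),
                          cfg$alphabet_kind, id = sprintf("test_%03d", i))
    })
    traces <- scan_sequences(seqs, params, electrode, bias, stage, v)
    list(sequences = seqs, traces = traces)
  }, error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))

  stage <- "call"
  calls <- tryCatch(lapply(test$traces, function(tr) {
    p1 <- call_p1(tr, result$pdfs)
    refined <- if (cfg$order >= 2) refine(tr, result$pdfs, p1, order = cfg$order)
      else p1
    list(p1 = p1, refined = refined)
  }), error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))

  stage <- "score"
  reports <- tryCatch(lapply(seq_along(calls), function(i) {
    list(p1 = fidelity(calls[[i]]$p1, test$sequences[[i]]),
         refined = fidelity(calls[[i]]$refined, test$sequences[[i]]))
  }), error = function(e) stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  for (i in seq_along(reports)) {
    pipeline_log(stage, "sequence %d: P1 fidelity %.3f, order-%d fidelity %.3f",
                 i, reports[[i]]$p1$fidelity, cfg$order,
                 reports[[i]]$refined$fidelity, verbose = v)
  }

  out <- list(params = params, pdfs = result$pdfs,
              train_sequences = result$train,
              test_sequences = test$sequences, test_traces = test$traces,
              calls = calls, reports = reports, config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameter_set(params, file.path(cfg$out_dir, "params.json"))
    saveRDS(result$pdfs, file.path(cfg$out_dir, "pdfs.rds"))
    for (i in seq_along(test$traces)) {
      write_trace(test$traces[[i]],
                  file.path(cfg$out_dir, sprintf("trace_%03d.tsv", i)))
    }
    write_fasta(lapply(calls, function(cl) cl$refined$called),
                file.path(cfg$out_dir, "called.fasta"))
    write_fasta(test$sequences, file.path(cfg$out_dir, "truth.fasta"))
    prov <- list(
      package_version = as.character(utils::packageVersion("transverseq")),
      config = cfg_serializable(cfg),
      config_hash = config_hash(cfg),
      fidelity = lapply(reports, function(r) list(p1 = r$p1$fidelity,
                                                  refined = r$refined$fidelity)))
    yaml::write_yaml(prov, file.path(cfg$out_dir, "provenance.yaml"))
  }
  invisible(out)
}

cfg_serializable <- function(cfg) {
  cfg$electrode <- if (inherits(cfg$electrode, "electrode_pair"))
    cfg$electrode$label else cfg$electrode
  cfg
}

config_hash <- function(cfg) {
  # dependency-free stable hash of the deparsed config (provenance only)
  s <- paste(deparse(cfg_serializable(cfg)), collapse = "")
  x <- utf8ToInt(s)
  h <- 5381
  for (c in x) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", h)
}
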