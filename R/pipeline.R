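#' End-to-end pipeline steps
#'
#' `run_simulate()`, `run_train()`, `run_predict()` and `run_evaluate()`
#' orchestrate the full workflow (simulate -> train -> predict -> evaluate)
#' over the package's building blocks. Each step is reproducible from its
#' resolved configuration plus master seed, and when given an output
#' directory writes its resolved configuration (`run_config.json`) next to
#' its outputs. The thin command-line wrapper in
#' `system.file("scripts", "editnet", package = "editnet")` exposes the
#' same four steps as shell subcommands.
#'
#' @param out_dir Output directory; `NULL` (where allowed) skips writing.
#' @param config An [sim_config()].
#' @param motif An [motif_model()].
#' @param n_gold_sets Partition candidates into this many gold sets.
#' @return `run_simulate()`: the file paths written, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, config = sim_config(),
                         motif = motif_model(), n_gold_sets = 1L) {
  dataset <- generate_dataset(config, motif, n_gold_sets)
  paths <- write_dataset(dataset, out_dir)
  write_run_config(out_dir, list(step = "simulate", config = unclass(config),
                                 motif = unclass(motif),
                                 n_gold_sets = n_gold_sets))
  invisible(paths)
}

#' @rdname pipeline
#' @param genome An `editnet_genome`, or a FASTA path.
#' @param labels Labeled candidate tibble (columns `contig`, `pos`, `ref`,
#'   `alt`, `label`, optional `gold_set`), or a labels TSV path.
#' @param level Hierarchy level to train: `"net"`, `"ensemble"`,
#'   `"module"`, `"component"` or `"full"`. `"full"` trains a separate and
#'   a pooled component (the gold sets are split between them) and
#'   averages the two.
#' @param spec Level spec: an [net_spec()] for `"net"`, an
#'   [ensemble_spec()] for `"ensemble"`, a [module_spec()] otherwise.
#' @param train_cfg A [train_config()].
#' @param seed Master seed for all training randomness.
#' @param model_path Optional path; the trained model is archived there.
#' @return `run_train()`: the trained object (invisibly if `model_path`
#'   is given, with the file written).
#' @export
run_train <- function(genome, labels, level = c("module", "net", "ensemble",
                                                "component", "full"),
                      spec = NULL, train_cfg = train_config(), seed = 1L,
                      flank = NULL, model_path = NULL) {
  level <- match.arg(level)
  if (!inherits(genome, "editnet_genome")) genome <- read_reference(genome)
  if (is.character(labels)) labels <- read_labels(labels)
  if (!"label" %in% names(labels)) stop_("labels must carry a 'label' column")
  spec <- spec %||% switch(level,
    net = net_spec(), ensemble = ensemble_spec(), module_spec())
  flank <- flank %||% switch(level,
    net = spec$input_flank,
    ensemble = spec$member_spec$input_flank,
    max(spec$scales))
  examples <- extract_windows(genome, labels, flank)
  trained <- switch(level,
    net = train_individual_net(examples, spec, train_cfg, seed),
    ensemble = train_ensemble(examples, spec, train_cfg, seed),
    module = train_module(examples, spec, train_cfg, seed),
    component = train_component(split_gold_sets(examples), spec, train_cfg, seed),
    full = {
      sets <- split_gold_sets(examples)
      if (length(sets) == 1) sets <- c(sets, sets)
      half <- seq_len(ceiling(length(sets) / 2))
      separate <- train_component(sets[half], spec, train_cfg,
                                  derive_seed(seed, 30L, 1L))
      pooled <- train_component(sets[-half], spec, train_cfg,
                                derive_seed(seed, 30L, 2L))
      assemble_model(separate, pooled)
    })
  if (!is.null(model_path)) {
    save_model(trained, model_path)
    write_run_config(dirname(model_path),
                     list(step = "train", level = level, seed = seed,
                          flank = flank, n_examples = nrow(examples)))
    return(invisible(trained))
  }
  trained
}

split_gold_sets <- function(examples) {
  if ("gold_set" %in% names(examples)) {
    unname(split(examples, examples$gold_set))
  } else {
    list(examples)
  }
}

#' @rdname pipeline
#' @param model A trained editnet object, or a model archive path.
#' @param candidates Candidate tibble or VCF/TSV path.
#' @param cutoff Calling cutoff (strict `>`).
#' @param flank Window flank for extraction; defaults to the model's widest
#'   scale.
#' @return `run_predict()`: `list(scores = <tibble>, called = <tibble>)`;
#'   when `out_dir` is given, also writes `scores.tsv` and a BED-like
#'   `called_sites.bed` (contig, pos-1, pos, ref>alt, score).
#' @export
run_predict <- function(model, genome, candidates, cutoff = 0.5,
                        flank = NULL, out_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (!inherits(genome, "editnet_genome")) genome <- read_reference(genome)
  if (is.character(candidates)) candidates <- read_candidates(candidates)
  flank <- flank %||% max(model_scales(model))
  unknown <- setdiff(unique(candidates$contig), names(genome))
  if (length(unknown) > 0) {
    stop_("candidate contig(s) absent from reference: ",
          paste(unknown, collapse = ", "))
  }
  windows <- extract_windows(genome, candidates, flank)
  scored <- score_candidates(model, windows)
  scored$seq <- NULL
  called <- call_editing_sites(scored, cutoff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scored, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bed <- tibble::tibble(
      contig = called$contig, start = called$pos - 1L, end = called$pos,
      name = paste0(called$ref, ">", called$alt),
      score = called$p_editing
    )
    utils::write.table(bed, file.path(out_dir, "called_sites.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_run_config(out_dir, list(step = "predict", cutoff = cutoff,
                                   flank = flank,
                                   n_candidates = nrow(candidates),
                                   n_called = nrow(called)))
  }
  list(scores = scored, called = called)
}

model_scales <- function(model) {
  switch(class(model)[1],
    editnet_net = model$spec$input_flank,
    editnet_ensemble = model$input_flank,
    model$scales)
}

#' @rdname pipeline
#' @param predicted Predicted site tibble (or scores TSV path).
#' @param verified_true,verified_false Verified site tibbles.
#' @param scores,labels Optional score vector and binary truth for
#'   AUC/AUCPR.
#' @return `run_evaluate()`: the one-row [eval_report()] tibble; when
#'   `out_dir` is given, also written as `eval_report.json` and
#'   `eval_report.tsv`.
#' @export
run_evaluate <- function(predicted, verified_true, verified_false,
                         scores = NULL, labels = NULL, out_dir = NULL) {
  if (nrow(verified_true) + nrow(verified_false) == 0) {
    stop_("empty truth: no verified sites supplied")
  }
  report <- eval_report(predicted, verified_true, verified_false,
                        scores, labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(report), file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(report, file.path(out_dir, "eval_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_config(out_dir, list(step = "evaluate",
                                   n_predicted = nrow(predicted)))
  }
  report
}

write_run_config <- function(dir, resolved) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  resolved$package_version <- as.character(utils::packageVersion("editnet"))
  jsonlite::write_json(resolved, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
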