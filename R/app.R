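# Pipeline surface tying the modules together:
#   simulate -> featurize -> train -> evaluate -> attend
# Each stage is a plain function taking a configuration list (typically
# parsed from a YAML file by the command-line wrapper in inst/cli/mutmil).
# No stage mutates its inputs; all artifacts land under the run directory,
# together with a manifest recording the configuration and seed.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "mutmil_run",
    task = list(n_bags = 200L, bag_size = c(20L, 40L), witness_rate = 0.1),
    model = list(n_heads = 2L, aggregation = "mean",
                 encoder_widths = 32L, attention_l1 = 0.05,
                 epochs = 60L, batch_size = 32L, lr = 0.02,
                 instance_dropout = 0.2),
    folds = list(k = 5L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML key/value file and merges it over the built-in defaults;
#' `overrides` (e.g. from command-line flags) take final precedence.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional named list of overrides.
#' @return Configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

write_manifest <- function(cfg, dir) {
  manifest <- list(
    config = cfg,
    package_version = as.character(utils::packageVersion("mutmil")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_paths <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("required input path(s) missing: ", paste(missing, collapse = ", "))
  }
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` writes a self-contained synthetic task directory
#' (FASTA + MAF + labels); `featurize` reads those files and writes an
#' SBS96-encoded instance table; `train` fits a stratified k-fold of
#' attention MIL models and writes per-fold metrics and checkpoints;
#' `evaluate` writes per-sample class probabilities; `attend` writes
#' per-instance, per-head attention.
#'
#' @param subcommand One of simulate, featurize, train, evaluate, attend.
#' @param cfg Configuration list from [load_run_config()].
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(subcommand = c("simulate", "featurize", "train",
                                        "evaluate", "attend"),
                         cfg = load_run_config()) {
  subcommand <- match.arg(subcommand)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cfg, cfg$out_dir)
  switch(subcommand,
    simulate = stage_simulate(cfg),
    featurize = stage_featurize(cfg),
    train = stage_train(cfg),
    evaluate = stage_evaluate(cfg),
    attend = stage_attend(cfg)
  )
  invisible(cfg$out_dir)
}

stage_simulate <- function(cfg) {
  spec <- task_spec(
    "presence", n_bags = cfg$task$n_bags,
    bag_size = as.integer(cfg$task$bag_size),
    witness_rate = cfg$task$witness_rate, seed = cfg$seed
  )
  write_presence_maf_task(spec, cfg$out_dir)
}

task_paths <- function(cfg) {
  list(genome = file.path(cfg$out_dir, "genome.fa"),
       maf = file.path(cfg$out_dir, "variants.maf"),
       labels = file.path(cfg$out_dir, "labels.tsv"),
       features = file.path(cfg$out_dir, "instances.tsv"))
}

stage_featurize <- function(cfg) {
  p <- task_paths(cfg)
  require_paths(p$genome, p$maf, p$labels)
  rec <- read_maf(p$maf, dialect = maf_dialect("minimal"))
  rec <- filter_by_flags(rec, verbose = TRUE)
  rec <- merge_consecutive_snvs(rec)
  genome <- read_genome(p$genome)
  idx <- sbs96_index(rec, genome)
  out <- data.frame(sample_id = rec$sample_id, sbs96 = idx)
  data.table::fwrite(out, p$features, sep = "\t")
}

load_task_bags <- function(cfg) {
  p <- task_paths(cfg)
  require_paths(p$features, p$labels)
  feat <- data.table::fread(p$features, data.table = FALSE)
  lab <- data.table::fread(p$labels, data.table = FALSE)
  sample_ids <- lab$sample_id
  bag <- match(feat$sample_id, sample_ids)
  mil_bags(encode_sbs96(feat$sbs96), bag,
           labels = factor(lab$label), sample_ids = sample_ids,
           n_bags = length(sample_ids))
}

model_config_from <- function(cfg, n_classes) {
  m <- cfg$model
  mil_config(
    n_classes = n_classes,
    n_heads = m$n_heads %||% n_classes,
    aggregation = m$aggregation %||% "mean",
    encoder_widths = as.integer(m$encoder_widths %||% 32L),
    attention_l1 = m$attention_l1 %||% 0.05,
    instance_dropout = m$instance_dropout %||% 0,
    epochs = as.integer(m$epochs %||% 60L),
    batch_size = as.integer(m$batch_size %||% 32L),
    lr = m$lr %||% 0.02,
    seed = cfg$seed
  )
}

stage_train <- function(cfg) {
  bags <- load_task_bags(cfg)
  plan <- stratified_kfold(bags$labels, cfg$folds$k, seed = cfg$seed)
  mcfg <- model_config_from(cfg, nlevels(bags$labels))
  cv <- mil_crossval(bags, mcfg, plan)
  data.table::fwrite(cv$metrics, file.path(cfg$out_dir, "metrics.tsv"),
                     sep = "\t")
  for (f in seq_along(cv$models)) {
    saveRDS(cv$models[[f]],
            file.path(cfg$out_dir, sprintf("fold%02d.rds", f)))
  }
  saveRDS(plan, file.path(cfg$out_dir, "fold_plan.rds"))
}

stage_evaluate <- function(cfg) {
  bags <- load_task_bags(cfg)
  plan <- readRDS(file.path(cfg$out_dir, "fold_plan.rds"))
  probs <- matrix(NA_real_, bags$n_bags, nlevels(bags$labels))
  for (f in seq_len(plan$k)) {
    model <- readRDS(file.path(cfg$out_dir, sprintf("fold%02d.rds", f)))
    test_ix <- which(plan$assignments == f)
    probs[test_ix, ] <- predict(model, subset_bags(bags, test_ix))
  }
  out <- data.frame(sample_id = bags$sample_ids, label = bags$labels,
                    probs)
  names(out)[-(1:2)] <- paste0("p_", levels(bags$labels))
  data.table::fwrite(out, file.path(cfg$out_dir, "predictions.tsv"),
                     sep = "\t")
}

stage_attend <- function(cfg) {
  bags <- load_task_bags(cfg)
  plan <- readRDS(file.path(cfg$out_dir, "fold_plan.rds"))
  rows <- list()
  for (f in seq_len(plan$k)) {
    model <- readRDS(file.path(cfg$out_dir, sprintf("fold%02d.rds", f)))
    test_ix <- which(plan$assignments == f)
    sub <- subset_bags(bags, test_ix)
    attn <- attention_weights(model, sub)
    rows[[f]] <- data.frame(
      fold = f, sample_id = sub$sample_ids[sub$bag],
      instance = seq_len(nrow(attn)), attn
    )
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- paste0("head", seq_len(ncol(out) - 3L))
  data.table::fwrite(out, file.path(cfg$out_dir, "attention.tsv"),
                     sep = "\t")
}
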