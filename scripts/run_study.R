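#!/usr/bin/env Rscript
# Thin command-line entry over the package's study runner: generates the
# synthetic dataset, runs the classifier-by-filter cross-validated grid and
# writes all result artifacts to the output directory.
#
# Usage: Rscript scripts/run_study.R --out <dir> [--seed N] [--smoke]
#                                    [--config cfg.yaml]
# The optional YAML config may override generator/training fields, e.g.:
#   generator: {n_models_per_class: 2, class_separation: 1.5}
#   train:     {max_epochs: 50}
#   classifiers: [rf, nn]
#   filters: [raw, lowpass]

suppressMessages(library(stiffsense))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[[i + 1]]
}
out_dir <- arg_val("--out", "study_out")
seed <- as.integer(arg_val("--seed", "1"))
smoke <- "--smoke" %in% args
cfg_path <- arg_val("--config", NA)

`%||%` <- function(a, b) if (is.null(a)) b else a

gen_args <- list(); train_args <- list()
classifiers <- c("rf", "nn", "cnn")
filters <- c("raw", "lowpass", "bandstop")
if (!is.na(cfg_path)) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("--config requires the 'yaml' package")
  y <- yaml::read_yaml(cfg_path)
  gen_args <- y$generator %||% list()
  train_args <- y$train %||% list()
  if (!is.null(y$classifiers)) classifiers <- y$classifiers
  if (!is.null(y$filters)) filters <- y$filters
}

cfg <- study_config(
  generator = do.call(generator_config, gen_args),
  train = do.call(train_config, train_args),
  classifiers = classifiers, filters = filters,
  seed = seed, smoke = smoke)

res <- run_full_study(cfg, out_dir, verbose = TRUE)
print(res$grid)
message("artifacts written to ", out_dir)
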