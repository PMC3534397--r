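## Experiment orchestration: plain-text config, subcommands, TSV reports.
##
## The config file is DCF ("Key: value" records, as in R's DESCRIPTION
## files); CLI flags of the form key=value override config keys. All reports
## are TSV so runs can be diffed.

.default_config <- function() list(
  dataset_index = NULL,       # index.tsv path
  structure_dir = NULL,       # directory of .pdb files
  alignment_dir = NULL,       # directory of <q>__<t>.fasta files
  alignment_format = "aligned-fasta",
  bases = "CA,CB,HEAVY",
  cutoffs = "4.5,5,5.5,6,6.5,7,7.5,8,10,12,15,20,30,50,100",
  min_separation = 3,
  relax = 0,
  separation_bin = NULL,      # "lo,hi" or "lo,Inf"
  class_filter = NULL,
  level = "fold_id",
  out_dir = "fc_out",
  seed = 1,
  n_folds = 5,
  members_per_fold = 4,
  noise_sigma = 0.5,
  indel_prob = 0,
  corruption_shift_prob = 0,  # > 0 enables alignment corruption
  corruption_max_shift = 2,
  corruption_block_length = 5,
  corruption_unaligned_prob = 0.05)

#' Read an experiment configuration
#'
#' @param path Optional DCF config file (`Key: value` lines); missing keys
#'   take defaults.
#' @param overrides Named list or `key=value` character vector overriding
#'   config keys (as from CLI arguments).
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    got <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
    names(got) <- tolower(names(got))
    for (k in names(got)) cfg[[k]] <- got[[k]]
  }
  if (is.character(overrides)) {
    kv <- strsplit(overrides[grepl("=", overrides)], "=", fixed = TRUE)
    overrides <- stats::setNames(lapply(kv, function(x)
      paste(x[-1L], collapse = "=")), vapply(kv, `[`, "", 1L))
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

.cfg_num <- function(x) as.numeric(x)
.cfg_nums <- function(x) as.numeric(strsplit(as.character(x), ",")[[1L]])
.cfg_strs <- function(x) trimws(strsplit(as.character(x), ",")[[1L]])

.cfg_definitions <- function(cfg)
  definition_grid(bases = .cfg_strs(cfg$bases),
                  cutoffs = .cfg_nums(cfg$cutoffs),
                  min_separation = as.integer(.cfg_num(cfg$min_separation)))

# alignment files are named <query>__<template>.fasta
.read_alignment_dir <- function(dir, format) {
  files <- list.files(dir, pattern = "\\.(fasta|fa|aln|txt)$",
                      full.names = TRUE)
  out <- list()
  for (f in files) {
    ids <- strsplit(sub("\\.[^.]*$", "", basename(f)), "__", fixed = TRUE)[[1L]]
    a <- read_alignment(f, format = format,
                        query_id = ids[1L],
                        template_id = if (length(ids) > 1L) ids[2L] else NULL)
    out[[paste(a$query_id, a$template_id, sep = "|")]] <- a
  }
  out
}

.read_structure_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  if (length(files) == 0L) stop("no PDB files in ", dir)
  out <- list()
  failed <- character(0)
  for (f in files) {
    s <- tryCatch(suppressWarnings(
      read_structure(f, "A", id = sub("\\.(pdb|ent)$", "", basename(f)))),
                  error = function(e) {
                    failed <<- c(failed, paste0(basename(f), ": ",
                                                conditionMessage(e)))
                    NULL
                  })
    if (!is.null(s)) out[[s$id]] <- s
  }
  if (length(failed))
    warning("unreadable structures skipped:\n  ",
            paste(failed, collapse = "\n  "))
  out
}

#' Generate a synthetic benchmark on disk
#'
#' Writes PDB structures, aligned-FASTA alignments (files named
#' `<query>__<template>.fasta`) and the dataset index TSV under
#' `out_dir`, in the layout that [cmd_build_maps()] and [cmd_evaluate()]
#' consume unmodified.
#'
#' @param cfg Configuration list from [read_config()].
#' @return The output directory, invisibly.
#' @export
cmd_synth <- function(cfg) {
  n_folds <- as.integer(.cfg_num(cfg$n_folds))
  if (n_folds < 2L) stop("n_folds must be at least 2")
  corr <- NULL
  if (.cfg_num(cfg$corruption_shift_prob) > 0)
    corr <- corruption_model(
      shift_prob = .cfg_num(cfg$corruption_shift_prob),
      max_shift = as.integer(.cfg_num(cfg$corruption_max_shift)),
      block_length = .cfg_num(cfg$corruption_block_length),
      unaligned_prob = .cfg_num(cfg$corruption_unaligned_prob))
  bm <- make_benchmark(n_folds = n_folds,
                       members_per_fold =
                         as.integer(.cfg_num(cfg$members_per_fold)),
                       noise_sigma = .cfg_num(cfg$noise_sigma),
                       indel_prob = .cfg_num(cfg$indel_prob),
                       corruption = corr,
                       seed = as.integer(.cfg_num(cfg$seed)))
  out <- cfg$out_dir
  sdir <- file.path(out, "structures"); adir <- file.path(out, "alignments")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  for (s in bm$structures)
    write_structure_pdb(s, file.path(sdir, paste0(s$id, ".pdb")))
  for (key in names(bm$alignments)) {
    a <- bm$alignments[[key]]
    write_alignment_fasta(a, file.path(
      adir, paste0(a$query_id, "__", a$template_id, ".fasta")))
  }
  write_dataset_index(bm$index, file.path(out, "index.tsv"))
  message("synthetic benchmark written to ", out,
          " (seed ", cfg$seed, ", ", length(bm$structures), " structures, ",
          length(bm$alignments), " alignments)")
  invisible(out)
}

#' Build contact maps for every structure and definition
#'
#' Writes one TSV map per (structure, definition) under
#' `out_dir/maps/<definition>/`, plus an occupancy summary. Unreadable
#' structures are recorded and skipped; the run continues.
#'
#' @param cfg Configuration list; `structure_dir` must be set.
#' @return Data frame summarizing per-definition mean occupancy, invisibly.
#' @export
cmd_build_maps <- function(cfg) {
  if (is.null(cfg$structure_dir)) stop("structure_dir not configured")
  structures <- .read_structure_dir(cfg$structure_dir)
  if (length(structures) == 0L) stop("no readable structures")
  defs <- .cfg_definitions(cfg)
  rows <- list()
  for (d in defs) {
    dlab <- format(d)
    ddir <- file.path(cfg$out_dir, "maps", dlab)
    dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
    occ <- numeric(0)
    for (s in structures) {
      m <- suppressWarnings(build_contact_map(s, d))
      write_contact_map(m, file.path(ddir, paste0(s$id, ".tsv")))
      occ <- c(occ, occupancy(m))
    }
    rows[[dlab]] <- data.frame(definition = dlab, base = d$base,
                               cutoff = d$cutoff,
                               n_structures = length(structures),
                               mean_occupancy = mean(occ))
  }
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(cfg$out_dir, "map_occupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("built ", length(structures) * length(defs), " contact maps (",
          length(structures), " structures x ", length(defs),
          " definitions)")
  invisible(summary)
}

#' Score a pair list by FCC
#'
#' Reads structures and alignments per the configuration, scores every pair
#' in the given TSV pair list (columns `query_id`, `template_id`, optional
#' `label`) under the first configured definition, and writes
#' `out_dir/fcc.tsv`.
#'
#' @param cfg Configuration list.
#' @param pair_list Path to the TSV pair list.
#' @return The score data frame, invisibly.
#' @export
cmd_fcc <- function(cfg, pair_list) {
  structures <- .read_structure_dir(cfg$structure_dir)
  alignments <- .read_alignment_dir(cfg$alignment_dir, cfg$alignment_format)
  pairs <- utils::read.table(pair_list, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  d <- .cfg_definitions(cfg)[[1L]]
  maps <- lapply(structures, build_contact_map, d = d)
  sc <- score_pairs(pairs, maps, alignments,
                    relax = as.integer(.cfg_num(cfg$relax)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sc, file.path(cfg$out_dir, "fcc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sc)
}

#' Run the retrieval evaluation and write reports
#'
#' Reads the dataset index, structures and alignments per the configuration,
#' runs [run_retrieval()] over the configured definition grid, and writes:
#' `auc_table.tsv` (per fold x definition), `summary.tsv` (per definition),
#' `roc_<definition>.tsv` (averaged curves), `best_definitions.tsv` and
#' `occupancy_auc.tsv`.
#'
#' @param cfg Configuration list; `dataset_index`, `structure_dir` and
#'   `alignment_dir` must be set.
#' @return The [run_retrieval()] result, invisibly.
#' @export
cmd_evaluate <- function(cfg) {
  for (k in c("dataset_index", "structure_dir", "alignment_dir"))
    if (is.null(cfg[[k]])) stop(k, " not configured")
  idx <- read_dataset_index(cfg$dataset_index)
  structures <- .read_structure_dir(cfg$structure_dir)
  alignments <- .read_alignment_dir(cfg$alignment_dir, cfg$alignment_format)
  bin <- if (!is.null(cfg$separation_bin)) .cfg_nums(cfg$separation_bin)
  res <- run_retrieval(
    idx, structures, alignments, .cfg_definitions(cfg),
    level = cfg$level,
    class_filter = cfg$class_filter,
    separation_bin = bin,
    relax = as.integer(.cfg_num(cfg$relax)))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$auc_table, file.path(out, "auc_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$summary, file.path(out, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (dlab in names(res$averaged))
    write_roc_tsv(res$averaged[[dlab]],
                  file.path(out, paste0("roc_", dlab, ".tsv")))
  best <- best_definition_per_fold(res$auc_table)
  utils::write.table(
    data.frame(definition = names(best), n_folds_best = as.integer(best)),
    file.path(out, "best_definitions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(occupancy_auc_profile(res$summary),
                     file.path(out, "occupancy_auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("evaluation reports written to ", out)
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth`, `build-maps`, `fcc` and `evaluate`.
#' Flags: `--config <file>` (DCF), `--seed <int>`, `--out <dir>`,
#' `--pairs <tsv>` (for `fcc`), plus free-form `key=value` overrides.
#'
#' @param args Character vector, defaults to `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return Invisibly, the subcommand's return value.
#' @export
foldcontacts_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: foldcontacts <synth|build-maps|fcc|evaluate> [options]")
  cmd <- args[1L]; args <- args[-1L]
  flag <- function(name) {
    i <- which(args == name)
    if (length(i)) args[i[1L] + 1L] else NULL
  }
  cfg_path <- flag("--config")
  overrides <- args[grepl("=", args) & !startsWith(args, "--")]
  cfg <- read_config(cfg_path, overrides)
  if (!is.null(flag("--seed"))) cfg$seed <- as.integer(flag("--seed"))
  if (!is.null(flag("--out"))) cfg$out_dir <- flag("--out")
  switch(cmd,
    "synth" = cmd_synth(cfg),
    "build-maps" = cmd_build_maps(cfg),
    "fcc" = cmd_fcc(cfg, flag("--pairs")),
    "evaluate" = cmd_evaluate(cfg),
    stop("unknown subcommand: ", cmd))
}
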