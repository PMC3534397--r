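synth_dir <- function(seed = 3L, ...) {
  out <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- read_config(overrides = list(
    out_dir = out, seed = seed, n_folds = 2, members_per_fold = 2, ...))
  suppressMessages(cmd_synth(cfg))
  out
}

test_that("cmd_synth writes a self-consistent benchmark layout", {
  out <- synth_dir()
  expect_true(file.exists(file.path(out, "index.tsv")))
  idx <- read_dataset_index(file.path(out, "index.tsv"))
  expect_equal(nrow(idx$entries), 4L)
  pdbs <- list.files(file.path(out, "structures"), pattern = "\\.pdb$")
  expect_length(pdbs, 4L)
  alns <- list.files(file.path(out, "alignments"), pattern = "\\.fasta$")
  expect_gt(length(alns), 0L)
  # deterministic: same seed twice gives identical files
  out2 <- synth_dir()
  for (f in c("index.tsv", file.path("structures", pdbs[1L])))
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
  expect_error(suppressMessages(cmd_synth(read_config(
    overrides = list(n_folds = 1)))), "n_folds")
})

test_that("cmd_build_maps writes one map per structure and definition", {
  out <- synth_dir()
  cfg <- read_config(overrides = list(
    structure_dir = file.path(out, "structures"),
    out_dir = out, bases = "CA,CB", cutoffs = "6.5"))
  summ <- suppressMessages(cmd_build_maps(cfg))
  expect_equal(nrow(summ), 2L)
  maps <- list.files(file.path(out, "maps"), recursive = TRUE)
  expect_length(maps, 4L * 2L)
  expect_true(file.exists(file.path(out, "map_occupancy.tsv")))
  # idempotent: a re-run overwrites identically
  one <- file.path(out, "maps", "CB_6.5", maps[grepl("^CB", maps)][1L])
  before <- readLines(file.path(out, "maps", maps[1L]))
  suppressMessages(cmd_build_maps(cfg))
  expect_identical(readLines(file.path(out, "maps", maps[1L])), before)
  expect_error(suppressMessages(cmd_build_maps(
    read_config(overrides = list(structure_dir = withr::local_tempdir())))),
    "no PDB files")
})

test_that("cmd_evaluate reproduces a direct run_retrieval invocation", {
  out <- synth_dir(seed = 11L, n_folds = 3, members_per_fold = 3)
  cfg <- read_config(overrides = list(
    dataset_index = file.path(out, "index.tsv"),
    structure_dir = file.path(out, "structures"),
    alignment_dir = file.path(out, "alignments"),
    out_dir = file.path(out, "eval"), bases = "CB", cutoffs = "6.5,100"))
  res <- suppressMessages(suppressWarnings(cmd_evaluate(cfg)))
  for (f in c("auc_table.tsv", "summary.tsv", "roc_CB_6.5.tsv",
              "best_definitions.tsv", "occupancy_auc.tsv"))
    expect_true(file.exists(file.path(out, "eval", f)))

  # the report must equal direct invocation on the same inputs
  idx <- read_dataset_index(file.path(out, "index.tsv"))
  structures <- foldcontacts:::.read_structure_dir(
    file.path(out, "structures"))
  alignments <- foldcontacts:::.read_alignment_dir(
    file.path(out, "alignments"), "aligned-fasta")
  direct <- run_retrieval(idx, structures, alignments,
                          definition_grid(bases = "CB",
                                          cutoffs = c(6.5, 100)))
  expect_equal(res$summary, direct$summary)
  got <- utils::read.table(file.path(out, "eval", "summary.tsv"),
                           sep = "\t", header = TRUE)
  expect_equal(got$avg_auc, direct$summary$avg_auc, tolerance = 1e-12)
})

test_that("relaxed matching never lowers a reported FCC", {
  out <- synth_dir(seed = 29L, n_folds = 2, members_per_fold = 3)
  base_cfg <- list(
    dataset_index = file.path(out, "index.tsv"),
    structure_dir = file.path(out, "structures"),
    alignment_dir = file.path(out, "alignments"),
    bases = "CB", cutoffs = "6.5")
  r0 <- suppressMessages(cmd_evaluate(read_config(overrides = c(
    base_cfg, out_dir = file.path(out, "e0"), relax = 0))))
  r1 <- suppressMessages(cmd_evaluate(read_config(overrides = c(
    base_cfg, out_dir = file.path(out, "e1"), relax = 1))))
  key0 <- paste(r0$scores$query_id, r0$scores$template_id)
  key1 <- paste(r1$scores$query_id, r1$scores$template_id)
  expect_equal(key0, key1)
  expect_true(all(r1$scores$fcc >= r0$scores$fcc))
})

test_that("cmd_fcc scores an explicit pair list", {
  out <- synth_dir(seed = 31L)
  idx <- read_dataset_index(file.path(out, "index.tsv"))
  ids <- idx$entries$structure_id
  pairs <- data.frame(query_id = ids[1L], template_id = ids[2L],
                      label = "pos")
  pl <- file.path(out, "pairs.tsv")
  utils::write.table(pairs, pl, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- read_config(overrides = list(
    structure_dir = file.path(out, "structures"),
    alignment_dir = file.path(out, "alignments"),
    out_dir = out, bases = "CB", cutoffs = "6.5"))
  sc <- cmd_fcc(cfg, pl)
  expect_equal(nrow(sc), 1L)
  expect_true(sc$fcc >= 0 && sc$fcc <= 1)
  expect_true(file.exists(file.path(out, "fcc.tsv")))
})

test_that("CLI dispatch, config files and overrides", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "config.dcf")
  writeLines(c("n_folds: 2", "members_per_fold: 2", "noise_sigma: 0.4"), cfgfile)
  suppressMessages(foldcontacts_cli(c(
    "synth", "--config", cfgfile, "--seed", "9", "--out",
    file.path(out, "bench"))))
  expect_true(file.exists(file.path(out, "bench", "index.tsv")))
  expect_error(foldcontacts_cli(character(0)), "usage")
  expect_error(foldcontacts_cli("frobnicate"), "unknown subcommand")
  # key=value override wins over the config file
  cfg <- read_config(cfgfile, c("noise_sigma=0.9"))
  expect_equal(as.numeric(cfg$noise_sigma), 0.9)
})
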