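#' Dataset index of classified structures
#'
#' Maps each structure to its fold, superfamily and structural class, the way
#' a SCOP-style classification does. Read/written as four-column TSV.
#'
#' @param entries Data frame with columns `structure_id`, `fold_id`,
#'   `superfamily_id`, `class_id` (class is one of `a`, `b`, `a/b`, `a+b`,
#'   `other`).
#' @return A `DatasetIndex`.
#' @export
dataset_index <- function(entries) {
  req <- c("structure_id", "fold_id", "superfamily_id", "class_id")
  stopifnot(all(req %in% names(entries)))
  if (anyDuplicated(entries$structure_id))
    stop("duplicate structure_id in dataset index")
  idx <- list(entries = as.data.frame(entries)[, req])
  class(idx) <- "DatasetIndex"
  idx
}

#' @export
print.DatasetIndex <- function(x, ...) {
  cat(sprintf("DatasetIndex: %d structures, %d folds, %d superfamilies\n",
              nrow(x$entries), length(unique(x$entries$fold_id)),
              length(unique(x$entries$superfamily_id))))
  invisible(x)
}

#' @rdname dataset_index
#' @param path TSV file path.
#' @export
read_dataset_index <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  dataset_index(df)
}

#' @rdname dataset_index
#' @param idx A `DatasetIndex`.
#' @export
write_dataset_index <- function(idx, path) {
  utils::write.table(idx$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# deterministic representative: lexicographically smallest structure_id
.fold_representative <- function(idx, group_id, level) {
  members <- idx$entries$structure_id[idx$entries[[level]] == group_id]
  sort(members)[1L]
}

#' Positive and negative pair sets for one fold
#'
#' Positives are all unordered within-group pairs; negatives pair the group's
#' representative (by default the lexicographically smallest structure id)
#' with every structure of a different group.
#'
#' @param idx A `DatasetIndex`.
#' @param fold_id Group to evaluate.
#' @param level `"fold_id"` or `"superfamily_id"`: which hierarchy level
#'   defines a group.
#' @param representative Optional structure id to use as the negative-side
#'   representative.
#' @return List with data frames `positives` and `negatives`, each with
#'   columns `query_id`, `template_id`, `label`.
#' @export
build_pair_sets <- function(idx, fold_id, level = c("fold_id",
                                                    "superfamily_id"),
                            representative = NULL) {
  level <- match.arg(level)
  ent <- idx$entries
  members <- sort(ent$structure_id[ent[[level]] == fold_id])
  if (length(members) < 2L)
    stop("group '", fold_id, "' has fewer than 2 members")
  others <- ent$structure_id[ent[[level]] != fold_id]
  if (length(others) == 0L)
    stop("no structures outside group '", fold_id, "': negatives undefined")
  cmb <- utils::combn(members, 2L)
  positives <- data.frame(query_id = cmb[1L, ], template_id = cmb[2L, ],
                          label = "pos")
  rep_id <- if (is.null(representative))
    members[1L] else representative
  negatives <- data.frame(query_id = rep_id, template_id = others,
                          label = "neg")
  list(positives = positives, negatives = negatives)
}

#' ROC curve from positive and negative scores
#'
#' Threshold sweep over descending score with tied scores processed as one
#' block (a simultaneous diagonal step). The trapezoidal area equals the
#' normalized Mann-Whitney U statistic with ties weighted one half.
#'
#' @param pos_scores,neg_scores Numeric score vectors (higher = more
#'   positive-like); both non-empty.
#' @return A `ROCCurve`: list with matrix `points` (columns `fpr`, `tpr`,
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  if (n_pos == 0L || n_neg == 0L)
    stop("both positive and negative scores are required")
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tp <- vapply(thr, function(s) sum(pos_scores >= s), 1L)
  fp <- vapply(thr, function(s) sum(neg_scores >= s), 1L)
  pts <- cbind(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts[, "fpr"]) *
             (utils::head(pts[, "tpr"], -1L) +
              utils::tail(pts[, "tpr"], -1L)) / 2)
  out <- list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg)
  class(out) <- "ROCCurve"
  out
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve: AUC %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

# grid used for pointwise curve averaging
.fpr_grid <- function(n = 1001L) seq(0, 1, length.out = n)

# interpolate a ROC polyline onto a common FPR grid. Vertical segments
# (duplicated fpr) are discontinuities: at a breakpoint the upper tpr is
# taken; between breakpoints the polyline segment runs from the upper tpr of
# the left breakpoint to the lower tpr of the right one. This preserves the
# trapezoidal area up to the grid resolution.
.interp_roc <- function(curve, grid) {
  fpr <- curve$points[, "fpr"]; tpr <- curve$points[, "tpr"]
  bp <- unique(fpr)
  hi <- vapply(bp, function(x) max(tpr[fpr == x]), numeric(1L))
  lo <- vapply(bp, function(x) min(tpr[fpr == x]), numeric(1L))
  out <- numeric(length(grid))
  k <- findInterval(grid, bp)
  at_bp <- grid %in% bp
  out[at_bp] <- hi[match(grid[at_bp], bp)]
  mid <- which(!at_bp)
  if (length(mid)) {
    x1 <- bp[k[mid]]; x2 <- bp[k[mid] + 1L]
    y1 <- hi[k[mid]]; y2 <- lo[k[mid] + 1L]
    out[mid] <- y1 + (grid[mid] - x1) / (x2 - x1) * (y2 - y1)
  }
  out
}

#' Fold-averaged ROC curve
#'
#' Interpolates each per-fold curve onto a common grid of 1001 evenly spaced
#' false-positive rates and averages the true-positive rates pointwise; the
#' AUC is the trapezoidal area of the mean curve.
#'
#' @param curves Non-empty list of `ROCCurve` objects.
#' @param grid_points Number of grid points.
#' @return A `ROCCurve` on the common grid (with `n_pos`, `n_neg` summed).
#' @export
average_roc <- function(curves, grid_points = 1001L) {
  stopifnot(length(curves) >= 1L)
  grid <- .fpr_grid(grid_points)
  tprs <- vapply(curves, .interp_roc, numeric(length(grid)), grid = grid)
  mean_tpr <- rowMeans(as.matrix(tprs))
  pts <- cbind(fpr = grid, tpr = mean_tpr)
  auc <- sum(diff(grid) * (utils::head(mean_tpr, -1L) +
                           utils::tail(mean_tpr, -1L)) / 2)
  out <- list(points = pts, auc = auc,
              n_pos = sum(vapply(curves, `[[`, 1L, "n_pos")),
              n_neg = sum(vapply(curves, `[[`, 1L, "n_neg")))
  class(out) <- "ROCCurve"
  out
}

#' Run the fold-retrieval experiment
#'
#' For each contact definition: builds per-fold positive/negative pair sets,
#' scores every pair by FCC, computes a per-fold ROC curve, and averages the
#' curves over folds. Optional restrictions: a single structural class, a
#' sequence-separation bin, relaxed contact matching.
#'
#' @param idx A `DatasetIndex`.
#' @param structures Named list of `Structure` objects (names = ids).
#' @param alignments Named list of `PairwiseAlignment`, keyed
#'   `"<query>|<template>"` (either orientation).
#' @param definitions List of `ContactDefinition` objects.
#' @param level `"fold_id"` or `"superfamily_id"`.
#' @param class_filter Optional class id (`a`, `b`, `a/b`, `a+b`, `other`):
#'   only folds of that class are evaluated.
#' @param separation_bin Optional `c(lo, hi)` separation bin applied to every
#'   map.
#' @param relax 0 or 1 contact-matching relaxation.
#' @param maps Optional pre-built maps: a list (one element per definition) of
#'   named `ContactMap` lists; built from `structures` when `NULL`.
#' @return List with `auc_table` (data frame: fold_id, definition, base,
#'   cutoff, auc, mean_occupancy), `averaged` (named list of averaged
#'   `ROCCurve` per definition), `summary` (data frame: definition, base,
#'   cutoff, mean_occupancy, avg_auc), and `scores` (per-pair FCC table).
#' @export
run_retrieval <- function(idx, structures, alignments, definitions,
                          level = c("fold_id", "superfamily_id"),
                          class_filter = NULL, separation_bin = NULL,
                          relax = 0L, maps = NULL) {
  level <- match.arg(level)
  ent <- idx$entries
  groups <- unique(ent[[level]])
  if (!is.null(class_filter)) {
    keep <- vapply(groups, function(g)
      all(ent$class_id[ent[[level]] == g] == class_filter), TRUE)
    groups <- groups[keep]
    if (length(groups) == 0L) stop("no groups of class '", class_filter, "'")
  }
  sizes <- table(ent[[level]])
  groups <- groups[sizes[as.character(groups)] >= 2L]
  if (length(groups) == 0L)
    stop("no groups with at least 2 members at level ", level)

  auc_rows <- list(); avg_curves <- list(); summary_rows <- list()
  score_rows <- list()
  for (d in definitions) {
    dlab <- format(d)
    if (is.null(maps)) {
      dmaps <- lapply(structures, build_contact_map, d = d)
    } else {
      dmaps <- maps[[dlab]]
      if (is.null(dmaps)) stop("no prebuilt maps for definition ", dlab)
    }
    if (!is.null(separation_bin))
      dmaps <- lapply(dmaps, filter_by_separation,
                      lo = separation_bin[1L], hi = separation_bin[2L])
    occ <- mean(vapply(dmaps, occupancy, numeric(1L)))
    curves <- list()
    for (g in groups) {
      ps <- build_pair_sets(idx, g, level = level)
      sc_pos <- score_pairs(ps$positives, dmaps, alignments, relax)
      sc_neg <- score_pairs(ps$negatives, dmaps, alignments, relax)
      curve <- roc_curve(sc_pos$fcc, sc_neg$fcc)
      curves[[as.character(g)]] <- curve
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        fold_id = g, definition = dlab, base = d$base, cutoff = d$cutoff,
        auc = curve$auc, mean_occupancy = occ)
      score_rows[[length(score_rows) + 1L]] <-
        cbind(definition = dlab, fold_id = g, rbind(sc_pos, sc_neg))
    }
    avg <- average_roc(curves)
    avg_curves[[dlab]] <- avg
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      definition = dlab, base = d$base, cutoff = d$cutoff,
      mean_occupancy = occ, avg_auc = avg$auc)
  }
  list(auc_table = do.call(rbind, auc_rows),
       averaged = avg_curves,
       summary = do.call(rbind, summary_rows),
       scores = do.call(rbind, score_rows))
}

#' Best contact definition per fold
#'
#' For each fold, every definition attaining the fold's maximal AUC is
#' counted (ties all count); folds whose maximum AUC falls below `min_auc`
#' contribute nothing.
#'
#' @param auc_table Data frame with columns `fold_id`, `definition`, `auc`
#'   (as produced by [run_retrieval()]).
#' @param min_auc Minimum acceptable best AUC (default 0.7).
#' @return Named integer vector: definition -> number of folds for which it
#'   is (one of) the best.
#' @export
best_definition_per_fold <- function(auc_table, min_auc = 0.7) {
  counts <- integer(0)
  for (g in unique(auc_table$fold_id)) {
    sub <- auc_table[auc_table$fold_id == g, ]
    best <- max(sub$auc)
    if (best < min_auc) next
    winners <- sub$definition[sub$auc == best]
    for (w in winners)
      counts[w] <- (if (is.na(counts[w])) 0L else counts[w]) + 1L
  }
  counts
}

#' Occupancy versus AUC profile
#'
#' One point per contact definition: x = dataset-mean occupancy, y =
#' fold-averaged AUC, sorted by occupancy. Reveals the band of map occupancy
#' in which retrieval works best.
#'
#' @param summary Data frame with columns `definition`, `base`, `cutoff`,
#'   `mean_occupancy`, `avg_auc` (from [run_retrieval()]).
#' @return The same data frame sorted by `mean_occupancy`.
#' @export
occupancy_auc_profile <- function(summary) {
  summary[order(summary$mean_occupancy), , drop = FALSE]
}

#' Best TM-score among the top-ranked pairs
#'
#' Pairs are sorted by descending FCC; pairs with equal FCC collapse to a
#' single rank carrying their mean TM-score; the curve value at rank k is the
#' best (maximum) TM-score seen among the first k rank entries. TM-scores are
#' externally supplied scalars.
#'
#' @param fcc Numeric FCC per pair.
#' @param tm_score Numeric TM-score per pair (same length).
#' @return Data frame: `rank`, `fcc`, `mean_tm`, `best_tm` (running maximum).
#' @export
best_tmscore_by_rank <- function(fcc, tm_score) {
  stopifnot(length(fcc) == length(tm_score), length(fcc) >= 1L)
  agg <- stats::aggregate(tm_score, by = list(fcc = fcc), FUN = mean)
  agg <- agg[order(agg$fcc, decreasing = TRUE), ]
  data.frame(rank = seq_len(nrow(agg)), fcc = agg$fcc, mean_tm = agg$x,
             best_tm = cummax(agg$x))
}

#' Write a ROC curve as TSV
#' @param curve A `ROCCurve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve$points), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
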