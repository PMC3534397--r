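## Synthetic structures, fold families and corrupted alignments.
##
## The generator emulates the statistical shape of a fold-retrieval dataset:
## groups of structures sharing a topology (same fold) with per-member
## coordinate noise, gold residue correspondences inherited from the shared
## template, and threading-like corrupted alignments with controlled
## residue-shift error. Only Calpha and Cbeta pseudo-atoms are produced, so
## the HEAVY contact base degenerates to min(CA, CB) distances -- enough to
## exercise all three code paths with analytic geometry.

# run expr with a locally seeded RNG, leaving the caller's stream untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.helix_coords <- function(n, rise = 1.5, twist_deg = 100, radius = 2.3,
                          cb_len = 1.53) {
  th <- (seq_len(n) - 1L) * twist_deg * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1L) * rise)
  # Cbeta points radially outward from the helix axis
  cb <- ca + cb_len * cbind(cos(th), sin(th), 0)
  list(ca = ca, cb = cb)
}

#' Ideal alpha-helix structure
#'
#' Calpha trace with 1.5 Angstrom rise and 100 degrees of twist per residue
#' on a 2.3 Angstrom helix radius; Cbeta placed 1.53 Angstrom from Calpha,
#' directed outward from the helix axis. Heavy atoms are the Calpha and Cbeta
#' pseudo-atoms.
#'
#' @param n Number of residues, at least 4.
#' @param id Structure identifier.
#' @return A `Structure` (all residues tagged element 1).
#' @export
make_helix <- function(n, id = "helix") {
  if (n < 4L) stop("a helix needs at least 4 residues")
  g <- .helix_coords(n)
  heavy <- lapply(seq_len(n), function(k) rbind(g$ca[k, ], g$cb[k, ]))
  new_structure(id, rep("ALA", n), g$ca, g$cb, heavy,
                element = rep(1L, n))
}

#' Antiparallel beta-sheet structure
#'
#' Extended strands (Calpha step 3.4 Angstrom along the strand axis) laid
#' antiparallel at the given inter-strand spacing. Cbeta alternates sides of
#' the sheet plane along each strand (displaced 1.53 Angstrom perpendicular
#' to the plane), so cross-strand Cbeta pairs alternate near/far relative to
#' the corresponding Calpha pairs -- the geometry that makes a Calpha-based
#' contact map catch cross-strand contacts that a Cbeta-based map misses.
#' With an odd `strand_len` the antiparallel register places every
#' offset-by-one cross-strand pair on opposite sides of the sheet.
#'
#' @param n_strands Number of strands, at least 2.
#' @param strand_len Residues per strand, at least 3 (odd lengths produce the
#'   full Calpha-versus-Cbeta sheet effect).
#' @param strand_spacing Inter-strand spacing in Angstrom (default 4.8).
#' @param id Structure identifier.
#' @return A `Structure`; residues carry their strand index as element tag.
#' @export
make_sheet <- function(n_strands, strand_len, strand_spacing = 4.8,
                       id = "sheet") {
  if (n_strands < 2L) stop("a sheet needs at least 2 strands")
  if (strand_len < 3L) stop("strands need at least 3 residues")
  step <- 3.4; cb_len <- 1.53
  ca <- NULL; cb <- NULL; element <- integer(0)
  for (s in seq_len(n_strands)) {
    x <- seq_len(strand_len) * step
    if (s %% 2L == 0L) x <- rev(x)            # antiparallel
    y <- rep((s - 1L) * strand_spacing, strand_len)
    z <- rep(0, strand_len)
    sca <- cbind(x, y, z)
    # side-chain direction alternates along the strand (local index parity)
    zdir <- cb_len * (-1)^(seq_len(strand_len))
    scb <- sca + cbind(0, 0, zdir)
    ca <- rbind(ca, sca); cb <- rbind(cb, scb)
    element <- c(element, rep(s, strand_len))
  }
  n <- nrow(ca)
  heavy <- lapply(seq_len(n), function(k) rbind(ca[k, ], cb[k, ]))
  new_structure(id, rep("VAL", n), ca, cb, heavy, element = element)
}

#' Count contacts that bridge distinct secondary-structure elements
#'
#' Uses the `element` tag the synthetic generators attach to residues (strand
#' or helix index; 0 = loop). Contacts within one element, or touching a
#' loop, are not counted.
#'
#' @param m A `ContactMap` built on `s`.
#' @param s The generating `Structure` (must carry `element`).
#' @return Integer count of cross-element contacts.
#' @export
cross_element_contacts <- function(m, s) {
  stopifnot(!is.null(s$element), m$length == structure_length(s))
  el <- s$element
  sum(el[m$i] != el[m$j] & el[m$i] > 0L & el[m$j] > 0L)
}

#' Fold specification
#'
#' An ordered list of secondary-structure elements, each with a rigid
#' placement, connected by loops of fixed length. Realized into coordinates
#' by [realize_fold()].
#'
#' @param fold_id Fold identifier.
#' @param elements List of elements, each a list with `kind` (`"helix"` or
#'   `"strand"`), `length` (residues), `shift` (3-vector, Angstrom) and
#'   optional `flip` (logical: reverse the element's axis direction).
#' @param loop_length Loop residues between consecutive elements (default 4).
#' @return A `FoldSpec`.
#' @export
fold_spec <- function(fold_id, elements, loop_length = 4L) {
  stopifnot(length(elements) >= 1L)
  for (e in elements)
    stopifnot(e$kind %in% c("helix", "strand"), e$length >= 3L,
              length(e$shift) == 3L)
  fs <- list(fold_id = fold_id, elements = elements,
             loop_length = as.integer(loop_length))
  class(fs) <- "FoldSpec"
  fs
}

#' Structural class implied by a fold specification
#'
#' All-helix folds are class `a`, all-strand folds class `b`, mixed folds
#' class `a/b`.
#'
#' @param spec A `FoldSpec`.
#' @return One of `"a"`, `"b"`, `"a/b"`.
#' @export
fold_class <- function(spec) {
  kinds <- unique(vapply(spec$elements, `[[`, "", "kind"))
  if (identical(kinds, "helix")) "a"
  else if (identical(kinds, "strand")) "b"
  else "a/b"
}

#' Realize a fold specification into coordinates
#'
#' Helices follow the ideal helix geometry of [make_helix()]; strands are
#' extended chains (3.4 Angstrom Calpha step) with alternating Cbeta. Each
#' element is translated by its `shift` (and optionally flipped); loops are
#' glycine stretches interpolated linearly between consecutive element
#' termini. Emits a warning if two non-adjacent Calpha come closer than 3.5
#' Angstrom (steric clash in the specification).
#'
#' @param spec A `FoldSpec`.
#' @param id Structure identifier (defaults to the fold id).
#' @return A `Structure`; element tags number the elements, loops are 0.
#' @export
realize_fold <- function(spec, id = spec$fold_id) {
  ca <- NULL; cb <- NULL; element <- integer(0); res <- character(0)
  piece <- function(e) {
    if (e$kind == "helix") {
      g <- .helix_coords(e$length)
      if (isTRUE(e$flip)) {        # reverse axis: rotate 180 deg about x
        g$ca[, 2:3] <- -g$ca[, 2:3]; g$cb[, 2:3] <- -g$cb[, 2:3]
      }
    } else {
      x <- seq_len(e$length) * 3.4
      if (isTRUE(e$flip)) x <- rev(x)   # antiparallel strand
      sca <- cbind(x, 0, 0)
      g <- list(ca = sca,
                cb = sca + cbind(0, 0, 1.53 * (-1)^(seq_len(e$length))))
    }
    g$ca <- sweep(g$ca, 2L, e$shift, "+")
    g$cb <- sweep(g$cb, 2L, e$shift, "+")
    g
  }
  for (k in seq_along(spec$elements)) {
    g <- piece(spec$elements[[k]])
    if (k > 1L && spec$loop_length > 0L) {
      from <- ca[nrow(ca), ]; to <- g$ca[1L, ]
      # route the loop on a quadratic Bezier arc bulging away from the fold
      # body, so loops do not thread through the elements
      centroid <- colMeans(rbind(ca, g$ca))
      mid <- (from + to) / 2
      u <- mid - centroid
      if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 0, 1)
      u <- u / sqrt(sum(u^2))
      h <- max(6, sqrt(sum((to - from)^2)) / 2)
      ctrl <- mid + h * u
      fr <- seq_len(spec$loop_length) / (spec$loop_length + 1L)
      bez <- function(p0, p1, p2, s)
        outer((1 - s)^2, p0) + outer(2 * s * (1 - s), p1) + outer(s^2, p2)
      lca <- bez(from, ctrl, to, fr)
      ca <- rbind(ca, lca); cb <- rbind(cb, lca + NA)
      element <- c(element, rep(0L, spec$loop_length))
      res <- c(res, rep("GLY", spec$loop_length))
    }
    ca <- rbind(ca, g$ca); cb <- rbind(cb, g$cb)
    element <- c(element, rep(k, nrow(g$ca)))
    res <- c(res, rep(if (spec$elements[[k]]$kind == "helix") "ALA" else "VAL",
                      nrow(g$ca)))
  }
  n <- nrow(ca)
  # relax loop residues out of steric clashes (elements stay rigid): push any
  # loop Calpha closer than 3.6 A to a non-adjacent residue along the
  # separation vector until the spec's 3.5 A clash limit is respected
  loops <- which(element == 0L)
  if (length(loops)) {
    for (iter in 1:100) {
      D <- as.matrix(stats::dist(ca))
      cl <- which(D < 3.6 & upper.tri(D), arr.ind = TRUE)
      cl <- cl[cl[, 2L] - cl[, 1L] > 1L, , drop = FALSE]
      cl <- cl[element[cl[, 1L]] == 0L | element[cl[, 2L]] == 0L, ,
               drop = FALSE]
      if (nrow(cl) == 0L) break
      for (r in seq_len(nrow(cl))) {
        i <- cl[r, 1L]; j <- cl[r, 2L]
        v <- ca[j, ] - ca[i, ]
        d <- sqrt(sum(v^2))
        v <- if (d < 1e-6) c(0, 0, 1) else v / d
        push <- (3.7 - d)
        if (element[i] == 0L && element[j] == 0L) {
          ca[i, ] <- ca[i, ] - v * push / 2
          ca[j, ] <- ca[j, ] + v * push / 2
        } else if (element[i] == 0L) {
          ca[i, ] <- ca[i, ] - v * push
        } else {
          ca[j, ] <- ca[j, ] + v * push
        }
      }
    }
  }
  heavy <- lapply(seq_len(n), function(k) {
    if (is.na(cb[k, 1])) ca[k, , drop = FALSE] else rbind(ca[k, ], cb[k, ])
  })
  D <- as.matrix(stats::dist(ca))
  close <- which(D < 3.5 & upper.tri(D), arr.ind = TRUE)
  close <- close[close[, 2L] - close[, 1L] > 1L, , drop = FALSE]
  if (nrow(close))
    warning("fold spec '", spec$fold_id, "' has ", nrow(close),
            " non-adjacent Calpha pairs closer than 3.5 A")
  new_structure(id, res, ca, cb, heavy, element = element)
}

# jitter every pseudo-atom of a structure with isotropic Gaussian noise
.jitter_structure <- function(s, sigma, id) {
  L <- structure_length(s)
  ca <- s$ca + matrix(stats::rnorm(3L * L, 0, sigma), L, 3L)
  cb <- s$cb
  has_cb <- !is.na(cb[, 1L])
  cb[has_cb, ] <- cb[has_cb, , drop = FALSE] +
    matrix(stats::rnorm(3L * sum(has_cb), 0, sigma), sum(has_cb), 3L)
  heavy <- lapply(seq_len(L), function(k) {
    if (has_cb[k]) rbind(ca[k, ], cb[k, ]) else ca[k, , drop = FALSE]
  })
  new_structure(id, s$res_name, ca, cb, heavy, element = s$element)
}

#' Generate a family of same-fold structures with gold alignments
#'
#' Members share the fold template's backbone, perturbed by isotropic
#' per-atom Gaussian noise; loop residues may be deleted (short indels). The
#' gold alignment between any two members is the residue correspondence
#' inherited from the template, restricted to positions present in both.
#'
#' @param spec A `FoldSpec`.
#' @param n_members At least 2.
#' @param noise_sigma Coordinate noise standard deviation in Angstrom.
#' @param indel_prob Per-loop-residue deletion probability.
#' @param seed Integer seed (optional; RNG state is restored on exit).
#' @param member_ids Optional character vector of member identifiers.
#' @return List with `structures` (named list of `Structure`), `alignments`
#'   (named list of gold `PairwiseAlignment`, keyed `"<id1>|<id2>"` for every
#'   unordered member pair), and `positions` (list: surviving template
#'   positions per member).
#' @export
make_fold_family <- function(spec, n_members, noise_sigma = 0.5,
                             indel_prob = 0, seed = NULL,
                             member_ids = NULL) {
  stopifnot(n_members >= 2L, noise_sigma >= 0)
  template <- realize_fold(spec)
  L <- structure_length(template)
  if (is.null(member_ids))
    member_ids <- sprintf("%s_m%d", spec$fold_id, seq_len(n_members))
  .with_seed(seed, {
    structures <- list(); positions <- list()
    for (m in seq_len(n_members)) {
      keep <- rep(TRUE, L)
      if (indel_prob > 0) {
        loops <- which(template$element == 0L)
        keep[loops] <- stats::runif(length(loops)) >= indel_prob
      }
      sub <- new_structure(member_ids[m],
                           template$res_name[keep],
                           template$ca[keep, , drop = FALSE],
                           template$cb[keep, , drop = FALSE],
                           template$heavy[keep],
                           element = template$element[keep])
      structures[[member_ids[m]]] <-
        .jitter_structure(sub, noise_sigma, member_ids[m])
      positions[[member_ids[m]]] <- which(keep)
    }
    alignments <- list()
    if (n_members >= 2L) {
      cmb <- utils::combn(member_ids, 2L)
      for (k in seq_len(ncol(cmb))) {
        id1 <- cmb[1L, k]; id2 <- cmb[2L, k]
        common <- intersect(positions[[id1]], positions[[id2]])
        q <- match(common, positions[[id1]])
        t <- match(common, positions[[id2]])
        alignments[[paste(id1, id2, sep = "|")]] <-
          pairwise_alignment(id1, id2, q, t, source = "gold",
                             query_length = length(positions[[id1]]),
                             template_length = length(positions[[id2]]))
      }
    }
    list(structures = structures, alignments = alignments,
         positions = positions)
  })
}

#' Threading-error model for alignment corruption
#'
#' @param shift_prob Probability that a contiguous residue block is shifted.
#' @param max_shift Maximum absolute residue shift per block.
#' @param block_length Mean block length (geometric).
#' @param unaligned_prob Probability that an aligned residue is dropped.
#' @param seed Optional integer seed.
#' @return A `CorruptionModel`.
#' @export
corruption_model <- function(shift_prob = 0.3, max_shift = 2L,
                             block_length = 5, unaligned_prob = 0.05,
                             seed = NULL) {
  stopifnot(shift_prob >= 0, shift_prob <= 1, unaligned_prob >= 0,
            unaligned_prob <= 1, max_shift >= 1L, block_length >= 1)
  m <- list(shift_prob = shift_prob, max_shift = as.integer(max_shift),
            block_length = block_length, unaligned_prob = unaligned_prob,
            seed = seed)
  class(m) <- "CorruptionModel"
  m
}

#' Corrupt a gold alignment with threading-like errors
#'
#' Partitions the aligned pairs into contiguous blocks (geometric lengths),
#' shifts each block's template indices by a random amount up to
#' `max_shift` with probability `shift_prob`, and drops residues with
#' probability `unaligned_prob`. Pairs shifted out of the template range, or
#' breaking monotonicity, are dropped, so the output is always a valid
#' monotone one-to-one alignment.
#'
#' @param gold A non-empty `PairwiseAlignment`.
#' @param model A `CorruptionModel`.
#' @return A `PairwiseAlignment` with source `"corrupted"`.
#' @export
corrupt_alignment <- function(gold, model) {
  n <- n_aligned(gold)
  stopifnot(n >= 1L)
  .with_seed(model$seed, {
    # block boundaries
    lens <- integer(0)
    while (sum(lens) < n)
      lens <- c(lens, 1L + stats::rgeom(1L, 1 / model$block_length))
    block <- rep(seq_along(lens), lens)[seq_len(n)]
    tt <- gold$t
    for (b in unique(block)) {
      if (stats::runif(1L) < model$shift_prob) {
        k <- sample.int(model$max_shift, 1L)
        s <- sample(c(-1L, 1L), 1L)
        tt[block == b] <- tt[block == b] + s * k
      }
    }
    keep <- stats::runif(n) >= model$unaligned_prob
    keep <- keep & tt >= 1L
    if (!is.na(gold$template_length))
      keep <- keep & tt <= gold$template_length
    q <- gold$q[keep]; tt <- tt[keep]
    # left-to-right pass enforcing strict template monotonicity
    ok <- rep(TRUE, length(tt))
    last <- 0L
    for (k in seq_along(tt)) {
      if (tt[k] > last) last <- tt[k] else ok[k] <- FALSE
    }
    pairwise_alignment(gold$query_id, gold$template_id, q[ok], tt[ok],
                       source = "corrupted",
                       query_length = gold$query_length,
                       template_length = gold$template_length)
  })
}

# distinct fold specifications cycled by the benchmark generator
.default_fold_specs <- function(n_folds) {
  ring <- function(k, n, r) {
    th <- 2 * pi * (k - 1L) / n
    c(r * cos(th), r * sin(th), 0)
  }
  mk <- list(
    function(fid) fold_spec(fid, lapply(1:3, function(k)
      list(kind = "helix", length = 10L, shift = ring(k, 3L, 5.5),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, lapply(1:4, function(k)
      list(kind = "helix", length = 9L, shift = ring(k, 4L, 7),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, lapply(1:4, function(k)
      list(kind = "strand", length = 7L, shift = c(0, (k - 1L) * 4.8, 0),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, lapply(1:3, function(k)
      list(kind = "strand", length = 9L, shift = c(0, (k - 1L) * 4.8, 0),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, c(
      lapply(1:2, function(k)
        list(kind = "strand", length = 7L, shift = c(0, (k - 1L) * 4.8, 9),
             flip = k %% 2L == 0L)),
      list(list(kind = "helix", length = 12L,
                shift = c(12, 2.4, 0), flip = TRUE)))),
    function(fid) fold_spec(fid, lapply(1:5, function(k)
      list(kind = "helix", length = 8L, shift = ring(k, 5L, 8.5),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, lapply(1:5, function(k)
      list(kind = "strand", length = 7L, shift = c(0, (k - 1L) * 4.8, 0),
           flip = k %% 2L == 0L))),
    function(fid) fold_spec(fid, c(
      list(list(kind = "helix", length = 10L, shift = c(-9, 0, 0))),
      lapply(1:3, function(k)
        list(kind = "strand", length = 5L, shift = c(2, (k - 1L) * 4.8, 7),
             flip = k %% 2L == 0L))))
  )
  lapply(seq_len(n_folds), function(f)
    mk[[((f - 1L) %% length(mk)) + 1L]](sprintf("F%02d", f)))
}

#' Generate a desk-scale fold-retrieval benchmark
#'
#' Builds `n_folds` distinct fold topologies (helix bundles, beta sheets,
#' mixed folds), a noisy family of structures for each, gold alignments for
#' every within-fold pair, index-wise alignments between the fold
#' representatives and all foreign structures (the negative pairs of the
#' retrieval experiment), and -- when a corruption model is supplied --
#' threading-like corrupted counterparts of every alignment. Fully
#' reproducible from `seed`.
#'
#' @param n_folds Number of folds, at least 2.
#' @param members_per_fold Structures per fold, at least 2.
#' @param noise_sigma Per-atom coordinate noise (Angstrom, default 0.5).
#' @param indel_prob Per-loop-residue deletion probability (default 0).
#' @param corruption Optional `CorruptionModel` applied to every alignment.
#' @param seed Integer seed.
#' @return List with `index` (a `DatasetIndex`), `structures` (named list),
#'   `alignments` (named list keyed `"<query>|<template>"`; corrupted when a
#'   corruption model was given), and `gold_alignments` (always the
#'   uncorrupted set).
#' @export
make_benchmark <- function(n_folds = 5L, members_per_fold = 4L,
                           noise_sigma = 0.5, indel_prob = 0,
                           corruption = NULL, seed = 1L) {
  stopifnot(n_folds >= 2L, members_per_fold >= 2L)
  specs <- .default_fold_specs(n_folds)
  .with_seed(seed, {
    structures <- list(); gold <- list(); entries <- NULL
    for (f in seq_len(n_folds)) {
      fam <- make_fold_family(specs[[f]], members_per_fold,
                              noise_sigma = noise_sigma,
                              indel_prob = indel_prob, seed = NULL)
      structures <- c(structures, fam$structures)
      gold <- c(gold, fam$alignments)
      entries <- rbind(entries, data.frame(
        structure_id = names(fam$structures),
        fold_id = specs[[f]]$fold_id,
        superfamily_id = paste0(specs[[f]]$fold_id, ".",
                                seq_along(fam$structures)),
        class_id = fold_class(specs[[f]])))
    }
    idx <- dataset_index(entries)
    # negative pairs: each fold's representative vs every foreign structure
    for (f in seq_len(n_folds)) {
      fid <- specs[[f]]$fold_id
      rep_id <- sort(entries$structure_id[entries$fold_id == fid])[1L]
      foreign <- entries$structure_id[entries$fold_id != fid]
      for (tid in foreign) {
        key <- paste(rep_id, tid, sep = "|")
        if (!is.null(gold[[key]]) ||
            !is.null(gold[[paste(tid, rep_id, sep = "|")]])) next
        lq <- structure_length(structures[[rep_id]])
        lt <- structure_length(structures[[tid]])
        m <- min(lq, lt)
        gold[[key]] <- pairwise_alignment(rep_id, tid, seq_len(m),
                                          seq_len(m), source = "index",
                                          query_length = lq,
                                          template_length = lt)
      }
    }
    alignments <- gold
    if (!is.null(corruption))
      alignments <- lapply(gold, corrupt_alignment, model = corruption)
    list(index = idx, structures = structures, alignments = alignments,
         gold_alignments = gold)
  })
}
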