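#' Common contacts between two contact maps through an alignment
#'
#' A query contact (a_i, a_j) is a common contact when both endpoints are
#' aligned, to template residues (b_m, b_n), and the template also has that
#' contact. With `relax = 1`, a template contact within one residue at each
#' endpoint (after ordering the endpoints) is accepted instead of an exact
#' match; a single template contact may serve several query contacts.
#'
#' @param mq Query `ContactMap`.
#' @param mt Template `ContactMap`.
#' @param a `PairwiseAlignment` from the query to the template.
#' @param relax 0 (exact matching) or 1 (plus/minus one residue matching).
#' @return Integer matrix with columns `i`, `j`: the query contacts that are
#'   common (possibly zero rows).
#' @export
common_contacts <- function(mq, mt, a, relax = 0L) {
  if (mq$structure_id != a$query_id)
    stop("query map is for '", mq$structure_id, "' but alignment queries '",
         a$query_id, "'")
  if (mt$structure_id != a$template_id)
    stop("template map is for '", mt$structure_id,
         "' but alignment targets '", a$template_id, "'")
  stopifnot(relax %in% c(0L, 1L))
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  if (length(mq$i) == 0L || length(mt$i) == 0L || n_aligned(a) == 0L)
    return(empty)
  # query index -> template index lookup
  map <- rep(NA_integer_, mq$length)
  map[a$q] <- a$t
  bm <- map[mq$i]; bn <- map[mq$j]
  cand <- !is.na(bm) & !is.na(bn)
  if (!any(cand)) return(empty)
  lo <- pmin(bm[cand], bn[cand]); hi <- pmax(bm[cand], bn[cand])
  tkey <- mt$i * (mt$length + 3L) + mt$j
  if (relax == 0L) {
    hit <- (lo * (mt$length + 3L) + hi) %in% tkey
  } else {
    hit <- rep(FALSE, length(lo))
    for (di in -1L:1L) for (dj in -1L:1L) {
      ii <- lo + di; jj <- hi + dj
      sw <- ii > jj
      if (any(sw)) { tmp <- ii[sw]; ii[sw] <- jj[sw]; jj[sw] <- tmp }
      hit <- hit | ((ii * (mt$length + 3L) + jj) %in% tkey)
    }
  }
  cbind(i = mq$i[cand][hit], j = mq$j[cand][hit])
}

#' Fraction of common contacts (FCC)
#'
#' FCC is the number of query residues involved in at least one common contact
#' divided by the number of aligned residues; it ranges from 0 to 1 and is the
#' pair-similarity score used for fold retrieval. FCC is directional
#' (query-denominated); `symmetric = TRUE` returns the mean of both
#' directions.
#'
#' @inheritParams common_contacts
#' @param symmetric Average FCC over both orientations of the pair.
#' @return An `FCCResult`: list with `query_id`, `template_id`, `fcc`,
#'   `n_common_contacts`, `n_query_residues_in_common`, `n_aligned`, `relax`.
#' @export
fraction_common_contacts <- function(mq, mt, a, relax = 0L,
                                     symmetric = FALSE) {
  if (n_aligned(a) == 0L)
    stop("FCC undefined for an empty alignment (",
         a$query_id, " -> ", a$template_id, ")")
  cc <- common_contacts(mq, mt, a, relax)
  res_in <- unique(c(cc[, "i"], cc[, "j"]))
  fcc <- length(res_in) / n_aligned(a)
  if (symmetric) {
    rev_a <- pairwise_alignment(a$template_id, a$query_id, a$t, a$q,
                                source = a$source,
                                query_length = a$template_length,
                                template_length = a$query_length)
    cc2 <- common_contacts(mt, mq, rev_a, relax)
    fcc <- (fcc + length(unique(c(cc2[, "i"], cc2[, "j"]))) /
              n_aligned(rev_a)) / 2
  }
  out <- list(query_id = mq$structure_id, template_id = mt$structure_id,
              fcc = fcc, n_common_contacts = nrow(cc),
              n_query_residues_in_common = length(res_in),
              n_aligned = n_aligned(a), relax = as.integer(relax))
  class(out) <- "FCCResult"
  out
}

#' @export
print.FCCResult <- function(x, ...) {
  cat(sprintf(
    "FCC %s -> %s: %.3f (%d residues in %d common contacts / %d aligned%s)\n",
    x$query_id, x$template_id, x$fcc, x$n_query_residues_in_common,
    x$n_common_contacts, x$n_aligned,
    if (x$relax) ", relaxed" else ""))
  invisible(x)
}

#' Batch FCC scoring over a pair list
#'
#' Scores each (query, template) pair using pre-built contact maps and
#' alignments, returning a data frame suitable for writing as TSV.
#'
#' @param pairs Data frame with columns `query_id`, `template_id` and
#'   optionally `label`.
#' @param maps Named list of `ContactMap` objects (names = structure ids).
#' @param alignments Named list of `PairwiseAlignment` objects, keyed
#'   `"<query_id>|<template_id>"`; the reversed key is used (and the alignment
#'   flipped) when only the opposite orientation is stored.
#' @param relax 0 or 1.
#' @return Data frame: `query_id`, `template_id`, `label`, `n_aligned`,
#'   `n_common`, `fcc`.
#' @export
score_pairs <- function(pairs, maps, alignments, relax = 0L) {
  n <- nrow(pairs)
  out <- data.frame(query_id = pairs$query_id,
                    template_id = pairs$template_id,
                    label = if ("label" %in% names(pairs)) pairs$label else NA,
                    n_aligned = integer(n), n_common = integer(n),
                    fcc = numeric(n))
  for (k in seq_len(n)) {
    qid <- pairs$query_id[k]; tid <- pairs$template_id[k]
    a <- alignments[[paste(qid, tid, sep = "|")]]
    if (is.null(a)) {
      rev <- alignments[[paste(tid, qid, sep = "|")]]
      if (is.null(rev))
        stop("no alignment for pair ", qid, " | ", tid)
      a <- pairwise_alignment(qid, tid, rev$t, rev$q, source = rev$source,
                              query_length = rev$template_length,
                              template_length = rev$query_length)
    }
    mq <- maps[[qid]]; mt <- maps[[tid]]
    if (is.null(mq) || is.null(mt))
      stop("missing contact map for pair ", qid, " | ", tid)
    r <- fraction_common_contacts(mq, mt, a, relax)
    out$n_aligned[k] <- r$n_aligned
    out$n_common[k] <- r$n_common_contacts
    out$fcc[k] <- r$fcc
  }
  out
}
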