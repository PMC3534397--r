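#' Pairwise residue alignment
#'
#' A set of one-to-one, strictly monotone correspondences between query and
#' template residue indices (1-based, counted over non-gap positions).
#'
#' @param query_id,template_id Structure identifiers.
#' @param q,t Integer vectors of equal length: aligned query and template
#'   residue indices. Must be strictly increasing in both coordinates.
#' @param source Free-text label, e.g. `"structural"`, `"threading"`,
#'   `"synthetic"`.
#' @param query_length,template_length Optional chain lengths; when supplied,
#'   indices are checked against them.
#' @return An object of class `PairwiseAlignment`.
#' @export
pairwise_alignment <- function(query_id, template_id, q, t,
                               source = "unknown",
                               query_length = NA_integer_,
                               template_length = NA_integer_) {
  q <- as.integer(q); t <- as.integer(t)
  stopifnot(length(q) == length(t))
  if (length(q)) {
    stopifnot(all(diff(q) > 0L), all(diff(t) > 0L), q[1L] >= 1L, t[1L] >= 1L)
    if (!is.na(query_length)) stopifnot(q[length(q)] <= query_length)
    if (!is.na(template_length)) stopifnot(t[length(t)] <= template_length)
  }
  a <- list(query_id = query_id, template_id = template_id, q = q, t = t,
            source = source, query_length = as.integer(query_length),
            template_length = as.integer(template_length))
  class(a) <- "PairwiseAlignment"
  a
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("PairwiseAlignment %s -> %s: %d aligned pairs (%s)\n",
              x$query_id, x$template_id, length(x$q), x$source))
  invisible(x)
}

#' Number of aligned residue pairs
#' @param a A `PairwiseAlignment`.
#' @return Integer.
#' @export
n_aligned <- function(a) length(a$q)

# two gapped sequences -> (q, t) index pairs over gap-free columns
.columns_to_pairs <- function(qseq, tseq) {
  qc <- strsplit(qseq, "")[[1L]]
  tc <- strsplit(tseq, "")[[1L]]
  if (length(qc) != length(tc))
    stop("gapped sequences have unequal length (", length(qc), " vs ",
         length(tc), ")")
  qgap <- qc == "-"; tgap <- tc == "-"
  qidx <- cumsum(!qgap); tidx <- cumsum(!tgap)
  sel <- !qgap & !tgap
  if (!any(sel)) stop("alignment has zero aligned columns")
  list(q = qidx[sel], t = tidx[sel],
       qlen = sum(!qgap), tlen = sum(!tgap))
}

# locate the sequence/connector/sequence block of TM-align plain-text output
.parse_tmalign_block <- function(lines) {
  anchor <- grep("denotes", lines)
  cand <- if (length(anchor)) (anchor[length(anchor)] + 1L) else NA_integer_
  if (!is.na(cand) && cand + 2L <= length(lines)) {
    blk <- lines[cand:(cand + 2L)]
    if (nchar(blk[1L]) == nchar(blk[3L])) return(blk)
  }
  # fallback: last triple of equal-width lines whose middle row is only
  # connector characters
  nz <- which(nzchar(lines))
  for (k in rev(seq_along(nz))) {
    if (k < 3L) break
    blk <- lines[nz[(k - 2L):k]]
    if (nchar(blk[1L]) == nchar(blk[3L]) &&
        grepl("^[:. ]*$", blk[2L]) && nchar(blk[2L]) > 0L)
      return(blk)
  }
  stop("no TM-align alignment block found")
}

#' Read a pairwise alignment
#'
#' Supports two dialects: aligned FASTA (two records of equal gapped length,
#' gaps as `-`; the first record is the query) and the three-line plain-text
#' alignment block of TM-align output (query sequence, connector line,
#' template sequence). Gap-free columns become aligned pairs with indices
#' counted over non-gap characters.
#'
#' @param path Input file.
#' @param format `"aligned-fasta"` or `"tmalign-text"`.
#' @param query_id,template_id Optional identifier overrides; for aligned
#'   FASTA the record names are used by default.
#' @return A `PairwiseAlignment`.
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "tmalign-text"),
                           query_id = NULL, template_id = NULL) {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) != 2L)
      stop("aligned FASTA must contain exactly two records, found ",
           length(recs))
    ids <- sub("\\s.*$", "", names(recs))
    qseq <- as.character(recs[[1L]]); tseq <- as.character(recs[[2L]])
    src <- "aligned-fasta"
  } else {
    lines <- readLines(path, warn = FALSE)
    blk <- .parse_tmalign_block(lines)
    qseq <- blk[1L]; tseq <- blk[3L]
    ids <- c("query", "template")
    src <- "tmalign"
  }
  p <- .columns_to_pairs(qseq, tseq)
  pairwise_alignment(
    query_id = if (is.null(query_id)) ids[1L] else query_id,
    template_id = if (is.null(template_id)) ids[2L] else template_id,
    q = p$q, t = p$t, source = src,
    query_length = p$qlen, template_length = p$tlen)
}

#' Write an alignment as aligned FASTA
#'
#' Reconstructs the two gapped rows from the index pairs, using `X` for
#' residue characters (sequence content is not tracked by the alignment
#' object).
#'
#' @param a A `PairwiseAlignment` with known `query_length` and
#'   `template_length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path) {
  ql <- a$query_length; tl <- a$template_length
  stopifnot(!is.na(ql), !is.na(tl))
  qrow <- character(0); trow <- character(0)
  qpos <- 1L; tpos <- 1L
  # unaligned stretches occupy disjoint columns so no spurious pairs arise
  emit <- function(nq, nt) {
    c(paste0(strrep("X", nq), strrep("-", nt)),
      paste0(strrep("-", nq), strrep("X", nt)))
  }
  pairs_q <- c(a$q, ql + 1L); pairs_t <- c(a$t, tl + 1L)
  for (k in seq_along(pairs_q)) {
    nq <- pairs_q[k] - qpos; nt <- pairs_t[k] - tpos
    if (nq > 0L || nt > 0L) {
      seg <- emit(nq, nt); qrow <- c(qrow, seg[1L]); trow <- c(trow, seg[2L])
    }
    if (k <= length(a$q)) {
      qrow <- c(qrow, "X"); trow <- c(trow, "X")
      qpos <- a$q[k] + 1L; tpos <- a$t[k] + 1L
    }
  }
  recs <- Biostrings::BStringSet(c(paste(qrow, collapse = ""),
                                   paste(trow, collapse = "")))
  names(recs) <- c(a$query_id, a$template_id)
  Biostrings::writeXStringSet(recs, path)
  invisible(path)
}

#' Alignment sensitivity against a gold standard
#'
#' The fraction of gold-standard pairs (q, t) for which the test alignment
#' aligns q to some template residue t' with `|t' - t| <= tolerance`.
#' Tolerance 0 is exact agreement; tolerance 2 is the common "within two
#' residues of the correct position" relaxation. The shift is applied on the
#' template index.
#'
#' @param test,gold `PairwiseAlignment` objects for the same ordered
#'   (query, template) pair; `gold` must be non-empty.
#' @param tolerance Non-negative integer residue-shift tolerance.
#' @param denominator `"gold"` (default; the number of gold pairs) or
#'   `"query"` (the query length, when known) -- the latter reproduces the
#'   fraction-of-query-residues variant of the accuracy.
#' @return Fraction in `[0, 1]`.
#' @export
alignment_sensitivity <- function(test, gold, tolerance = 0L,
                                  denominator = c("gold", "query")) {
  denominator <- match.arg(denominator)
  if (test$query_id != gold$query_id || test$template_id != gold$template_id)
    stop("alignments concern different protein pairs: ",
         test$query_id, "->", test$template_id, " vs ",
         gold$query_id, "->", gold$template_id)
  if (n_aligned(gold) == 0L) stop("gold alignment is empty")
  stopifnot(tolerance >= 0L)
  test_t <- stats::setNames(test$t, test$q)
  tt <- test_t[as.character(gold$q)]           # NA where q unaligned in test
  hits <- !is.na(tt) & abs(tt - gold$t) <= tolerance
  den <- if (denominator == "gold") n_aligned(gold) else {
    if (is.na(gold$query_length)) stop("query length unknown")
    gold$query_length
  }
  sum(hits) / den
}
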