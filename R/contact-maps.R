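#' Contact definition
#'
#' A contact definition is the triple (base, distance cutoff, minimum sequence
#' separation). Two residues i < j are in contact when `j - i >=
#' min_separation` and their base distance is at most `cutoff` (the boundary is
#' closed). The base distance is the Calpha-Calpha distance (`CA`), the
#' Cbeta-Cbeta distance with the glycine Calpha substitution (`CB`), or the
#' minimum over all heavy-atom pairs of the two residues (`HEAVY`).
#'
#' @param base One of `"CA"`, `"CB"`, `"HEAVY"`.
#' @param cutoff Distance cutoff in Angstrom, > 0.
#' @param min_separation Minimum sequence separation `j - i` (default 3, i.e.
#'   residues at least three positions apart).
#' @return An object of class `ContactDefinition`.
#' @export
contact_definition <- function(base = c("CA", "CB", "HEAVY"), cutoff,
                               min_separation = 3L) {
  base <- match.arg(base)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0,
            min_separation >= 1L)
  d <- list(base = base, cutoff = as.numeric(cutoff),
            min_separation = as.integer(min_separation))
  class(d) <- "ContactDefinition"
  d
}

#' @export
format.ContactDefinition <- function(x, ...)
  sprintf("%s_%g", x$base, x$cutoff)

#' @export
print.ContactDefinition <- function(x, ...) {
  cat(sprintf("ContactDefinition: base %s, cutoff %g A, separation >= %d\n",
              x$base, x$cutoff, x$min_separation))
  invisible(x)
}

#' The canonical grid of contact definitions
#'
#' All combinations of the three contact bases with the fifteen distance
#' cutoffs 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0, 10.0, 12.0, 15.0, 20.0,
#' 30.0, 50.0 and 100.0 Angstrom, at minimum sequence separation 3.
#'
#' @param bases Subset of `c("CA", "CB", "HEAVY")`.
#' @param cutoffs Subset of the canonical cutoffs (any positive values are
#'   accepted).
#' @param min_separation Minimum sequence separation.
#' @return List of `ContactDefinition` objects.
#' @export
definition_grid <- function(bases = c("CA", "CB", "HEAVY"),
                            cutoffs = c(4.5, 5, 5.5, 6, 6.5, 7, 7.5, 8,
                                        10, 12, 15, 20, 30, 50, 100),
                            min_separation = 3L) {
  out <- list()
  for (b in bases) for (cf in cutoffs)
    out[[length(out) + 1L]] <- contact_definition(b, cf, min_separation)
  out
}

new_contact_map <- function(structure_id, length, definition, i, j) {
  stopifnot(length(i) == length(j))
  if (length(i)) {
    stopifnot(all(i < j), all(i >= 1L), all(j <= length),
              all(j - i >= definition$min_separation))
    o <- order(i, j)
    i <- as.integer(i[o]); j <- as.integer(j[o])
    stopifnot(!anyDuplicated(cbind(i, j)))
  }
  m <- list(structure_id = structure_id, length = as.integer(length),
            definition = definition, i = as.integer(i), j = as.integer(j))
  class(m) <- "ContactMap"
  m
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap '%s' (%d residues, %s, cutoff %g A): %d contacts\n",
              x$structure_id, x$length, x$definition$base,
              x$definition$cutoff, length(x$i)))
  invisible(x)
}

#' Number of contacts in a map
#' @param m A `ContactMap`.
#' @return Integer.
#' @export
n_contacts <- function(m) length(m$i)

# minimum inter-residue heavy-atom distance matrix; L x L, symmetric
.min_heavy_dist <- function(heavy) {
  L <- length(heavy)
  atoms <- do.call(rbind, heavy)
  ridx <- rep(seq_len(L), vapply(heavy, nrow, 1L))
  D <- as.matrix(stats::dist(atoms))
  out <- matrix(Inf, L, L)
  # aggregate the atom-level matrix to residue-level minima
  for (a in seq_len(L)) {
    rows <- which(ridx == a)
    sub <- D[rows, , drop = FALSE]
    out[a, ] <- vapply(seq_len(L), function(b)
      min(sub[, ridx == b]), numeric(1L))
  }
  out
}

#' Build a contact map for a structure
#'
#' Marks every residue pair (i, j) with `j - i >= min_separation` whose base
#' distance is within the cutoff (closed boundary: a distance exactly equal to
#' the cutoff is a contact).
#'
#' @param s A `Structure`.
#' @param d A `ContactDefinition`.
#' @return A `ContactMap`.
#' @export
build_contact_map <- function(s, d) {
  stopifnot(inherits(s, "Structure"), inherits(d, "ContactDefinition"))
  L <- structure_length(s)
  if (L < d$min_separation + 1L) {
    warning("structure ", s$id, " shorter than min_separation + 1; empty map")
    return(new_contact_map(s$id, L, d, integer(0), integer(0)))
  }
  D <- if (d$base == "HEAVY") {
    .min_heavy_dist(base_coordinates(s, "HEAVY"))
  } else {
    as.matrix(stats::dist(base_coordinates(s, d$base)))
  }
  idx <- which(upper.tri(D), arr.ind = TRUE)
  sep_ok <- (idx[, 2L] - idx[, 1L]) >= d$min_separation
  hit <- sep_ok & (D[idx] <= d$cutoff)
  new_contact_map(s$id, L, d, idx[hit, 1L], idx[hit, 2L])
}

#' Number of separation-eligible residue pairs
#'
#' Pairs (i, j) with i < j and `j - i >= min_separation` in a chain of the
#' given length.
#'
#' @param length Residue count.
#' @param min_separation Minimum separation.
#' @return Integer pair count.
#' @export
n_eligible_pairs <- function(length, min_separation = 3L) {
  k <- length - min_separation
  if (k <= 0L) return(0L)
  as.integer(k * (k + 1) / 2)
}

#' Contact-map occupancy
#'
#' The fraction of residue pairs marked as contacts. By default the
#' denominator counts only separation-eligible pairs, so occupancy reaches 1
#' at a saturating cutoff; `denominator = "all"` uses all L(L-1)/2 pairs
#' instead, for sensitivity checks.
#'
#' @param m A `ContactMap`.
#' @param denominator `"eligible"` (default) or `"all"`.
#' @return Fraction in `[0, 1]`.
#' @export
occupancy <- function(m, denominator = c("eligible", "all")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "eligible")
    n_eligible_pairs(m$length, m$definition$min_separation)
  else m$length * (m$length - 1) / 2
  if (den == 0L) stop("no eligible residue pairs (length ", m$length, ")")
  length(m$i) / den
}

#' Restrict a contact map to a sequence-separation bin
#'
#' Retains contacts with `lo <= j - i <= hi`; both bounds inclusive, `hi =
#' Inf` for an open-ended bin such as "> 23" (pass `lo = 24`).
#'
#' @param m A `ContactMap`.
#' @param lo Lower separation bound, `>= min_separation`.
#' @param hi Upper separation bound or `Inf`.
#' @return A `ContactMap` whose definition is annotated with the bin.
#' @export
filter_by_separation <- function(m, lo, hi = Inf) {
  stopifnot(lo >= m$definition$min_separation)
  if (lo > hi) stop("lo > hi in separation bin")
  sep <- m$j - m$i
  keep <- sep >= lo & sep <= hi
  out <- new_contact_map(m$structure_id, m$length, m$definition,
                         m$i[keep], m$j[keep])
  out$definition$separation_bin <- c(lo, hi)
  out
}

#' Write a contact map as TSV
#'
#' Header comment lines carry the identifier, length and definition; body rows
#' are 1-based `i<TAB>j` contact pairs.
#'
#' @param m A `ContactMap`.
#' @param path Output path.
#' @param format `"tsv"` (native) or `"casp-rr"` (CASP RR-like rows
#'   `i j 0 cutoff 1.0`).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(m, path, format = c("tsv", "casp-rr")) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "tsv") {
    writeLines(c(
      paste0("# id\t", m$structure_id),
      paste0("# length\t", m$length),
      paste0("# base\t", m$definition$base),
      paste0("# cutoff\t", m$definition$cutoff),
      paste0("# min_separation\t", m$definition$min_separation)), con)
    if (length(m$i))
      writeLines(paste(m$i, m$j, sep = "\t"), con)
  } else {
    if (length(m$i))
      writeLines(sprintf("%d %d 0 %g 1.0", m$i, m$j, m$definition$cutoff), con)
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path TSV contact map path.
#' @return A `ContactMap`.
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  d <- contact_definition(vals[["base"]], as.numeric(vals[["cutoff"]]),
                          as.integer(vals[["min_separation"]]))
  if (length(body)) {
    ij <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
  } else i <- j <- integer(0)
  new_contact_map(vals[["id"]], as.integer(vals[["length"]]), d, i, j)
}
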