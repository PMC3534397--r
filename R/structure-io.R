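#' @keywords internal
"_PACKAGE"

## Internal representation of a protein structure
##
## A Structure is a list with components:
##   id        - character scalar (e.g. "1abcA")
##   res_name  - character vector of three-letter residue codes, length L
##   ca        - L x 3 numeric matrix of Calpha coordinates (NA row if absent)
##   cb        - L x 3 numeric matrix of Cbeta coordinates (NA row if absent)
##   heavy     - list of length L; each element a (n_atoms x 3) matrix of all
##               non-hydrogen atom coordinates of that residue
##   orig_num  - integer vector, the author/PDB residue numbering (metadata)
##   element   - optional integer vector tagging which secondary-structure
##               element a residue belongs to (0 = loop); used by the
##               synthetic generator
## Residues are renumbered 1..L internally; all sequence-separation math uses
## these internal indices.

new_structure <- function(id, res_name, ca, cb, heavy,
                          orig_num = seq_along(res_name),
                          element = NULL) {
  L <- length(res_name)
  stopifnot(L >= 1, nrow(ca) == L, nrow(cb) == L, length(heavy) == L)
  s <- list(id = id, res_name = res_name, ca = ca, cb = cb, heavy = heavy,
            orig_num = as.integer(orig_num), element = element)
  class(s) <- "Structure"
  s
}

#' Number of residues in a structure
#' @param s A `Structure`.
#' @return Integer residue count.
#' @export
structure_length <- function(s) length(s$res_name)

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d residues", x$id, structure_length(x)))
  n_ca <- sum(!is.na(x$ca[, 1]))
  n_cb <- sum(!is.na(x$cb[, 1]))
  cat(sprintf(" (CA: %d, CB: %d, heavy atoms: %d)\n",
              n_ca, n_cb, sum(vapply(x$heavy, nrow, 1L))))
  invisible(x)
}

#' Does a structure carry only Calpha atoms?
#'
#' Structures deposited as Calpha traces carry no side-chain information; the
#' heavy-atom and Cbeta contact bases degenerate on them, so callers typically
#' discard such entries from retrieval datasets.
#'
#' @param s A `Structure`.
#' @return Logical scalar.
#' @export
is_ca_only <- function(s) {
  all(vapply(s$heavy, nrow, 1L) == 1L) && all(is.na(s$cb[, 1]))
}

# fixed-column fields of a PDB ATOM record
.pdb_field <- function(lines, from, to) substr(lines, from, to)

.is_hydrogen <- function(name, elem) {
  elem <- toupper(trimws(elem))
  has_elem <- nzchar(elem)
  byelem <- has_elem & (elem == "H" | elem == "D")
  # fall back on the atom-name convention: strip leading digits, then H/D
  nm <- toupper(sub("^[0-9 ]*", "", trimws(name)))
  byname <- !has_elem & grepl("^[HD]", nm)
  byelem | byname
}

#' Read one chain of a PDB file as a Structure
#'
#' Parses ATOM records of the requested chain, resolves alternate locations by
#' keeping the first conformer, drops hydrogens and HETATM records, and
#' renumbers residues 1..L in chain order (the original numbering is retained
#' as metadata). An optional residue range, given in the original PDB
#' numbering, carves out a domain before renumbering.
#'
#' @param path Path to a PDB-format file.
#' @param chain_id Single chain identifier; `" "` selects the blank chain.
#' @param residue_range Optional `c(lo, hi)` inclusive span in original PDB
#'   numbering.
#' @param id Identifier stored on the returned object; defaults to file base
#'   name plus chain.
#' @return A `Structure`. If the chain is a Calpha-only trace a warning is
#'   emitted and the attribute `ca_only` is set to `TRUE`; the caller decides
#'   whether to discard it.
#' @export
read_structure <- function(path, chain_id, residue_range = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(lines) == 0L) stop("no ATOM records in ", path)
  chains <- .pdb_field(lines, 22, 22)
  lines <- lines[chains == chain_id]
  if (length(lines) == 0L)
    stop("chain '", chain_id, "' not found in ", path)

  name   <- .pdb_field(lines, 13, 16)
  altloc <- .pdb_field(lines, 17, 17)
  resnm  <- trimws(.pdb_field(lines, 18, 20))
  resseq <- as.integer(.pdb_field(lines, 23, 26))
  icode  <- .pdb_field(lines, 27, 27)
  x <- as.numeric(.pdb_field(lines, 31, 38))
  y <- as.numeric(.pdb_field(lines, 39, 46))
  z <- as.numeric(.pdb_field(lines, 47, 54))
  elem <- if (max(nchar(lines)) >= 78) trimws(.pdb_field(lines, 77, 78)) else
    rep("", length(lines))

  keep <- !.is_hydrogen(name, elem)
  # altloc: keep the blank conformer, else the first altloc letter seen
  alts <- setdiff(unique(altloc), " ")
  if (length(alts))
    keep <- keep & (altloc == " " | altloc == alts[1L])
  resid_key <- paste(resseq, icode)

  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    keep <- keep & resseq >= residue_range[1L] & resseq <= residue_range[2L]
  }
  if (!any(keep)) stop("zero residues after filtering in ", path)
  name <- trimws(name[keep]); resnm <- resnm[keep]
  resseq <- resseq[keep]; resid_key <- resid_key[keep]
  xyz <- cbind(x[keep], y[keep], z[keep])

  ukeys <- unique(resid_key)          # chain order = file order
  L <- length(ukeys)
  ca <- matrix(NA_real_, L, 3); cb <- matrix(NA_real_, L, 3)
  heavy <- vector("list", L); rnames <- character(L); onum <- integer(L)
  for (k in seq_len(L)) {
    sel <- which(resid_key == ukeys[k])
    # duplicate atom names within a residue (altloc leftovers): keep first
    sel <- sel[!duplicated(name[sel])]
    heavy[[k]] <- xyz[sel, , drop = FALSE]
    rnames[k] <- resnm[sel[1L]]; onum[k] <- resseq[sel[1L]]
    i_ca <- sel[name[sel] == "CA"][1L]
    i_cb <- sel[name[sel] == "CB"][1L]
    if (!is.na(i_ca)) ca[k, ] <- xyz[i_ca, ]
    if (!is.na(i_cb)) cb[k, ] <- xyz[i_cb, ]
  }
  if (any(diff(onum) != 1L))
    warning("non-contiguous original numbering in ", path,
            "; residues renumbered 1..", L)
  if (is.null(id))
    id <- paste0(sub("\\.(pdb|ent)$", "", basename(path)),
                 if (chain_id != " ") chain_id else "")
  s <- new_structure(id, rnames, ca, cb, heavy, orig_num = onum)
  if (is_ca_only(s)) {
    warning("structure ", id, " is a Calpha-only trace")
    attr(s, "ca_only") <- TRUE
  }
  s
}

#' Write a Structure to a minimal PDB file
#'
#' Emits ATOM records for every heavy atom. Atoms named CA and CB are written
#' with those names; remaining heavy atoms get generic names. Coordinates are
#' written at PDB precision (3 decimals).
#'
#' @param s A `Structure`.
#' @param path Output file path.
#' @param chain_id Chain identifier to write (default "A").
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path, chain_id = "A") {
  con <- file(path, "w"); on.exit(close(con))
  serial <- 0L
  generic <- c("N", "C", "O", "CG", "CD", "CE", "CZ", "OG", "SD", "NZ")
  for (k in seq_len(structure_length(s))) {
    atoms <- s$heavy[[k]]
    # label CA/CB rows by matching coordinates
    labels <- rep(NA_character_, nrow(atoms))
    if (!is.na(s$ca[k, 1])) {
      i <- which(apply(atoms, 1L, function(r) all(r == s$ca[k, ])))[1L]
      if (!is.na(i)) labels[i] <- "CA"
    }
    if (!is.na(s$cb[k, 1])) {
      i <- which(is.na(labels) &
                 apply(atoms, 1L, function(r) all(r == s$cb[k, ])))[1L]
      if (!is.na(i)) labels[i] <- "CB"
    }
    gi <- 0L
    for (a in seq_len(nrow(atoms))) {
      serial <- serial + 1L
      nm <- labels[a]
      if (is.na(nm)) { gi <- gi + 1L; nm <- generic[min(gi, length(generic))] }
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, paste0(" ", formatC(nm, width = 3, flag = "-")),
        s$res_name[k], chain_id, s$orig_num[k],
        atoms[a, 1], atoms[a, 2], atoms[a, 3],
        substr(nm, 1, 1)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Per-residue coordinates under a contact base
#'
#' The three contact bases are `CA` (one Calpha coordinate per residue), `CB`
#' (the Cbeta coordinate, substituting Calpha for glycine or when the side
#' chain is truncated), and `HEAVY` (every non-hydrogen atom of the residue).
#'
#' @param s A `Structure`.
#' @param base One of `"CA"`, `"CB"`, `"HEAVY"`.
#' @return For `CA`/`CB`, an L x 3 matrix; for `HEAVY`, a list of matrices.
#' @export
base_coordinates <- function(s, base = c("CA", "CB", "HEAVY")) {
  base <- match.arg(base)
  L <- structure_length(s)
  switch(base,
    CA = {
      miss <- which(is.na(s$ca[, 1]))
      if (length(miss))
        stop("CA base requested but CA missing for residues: ",
             paste(miss, collapse = ", "))
      s$ca
    },
    CB = {
      out <- s$cb
      miss <- which(is.na(out[, 1]))
      if (length(miss)) {
        nongly <- miss[s$res_name[miss] != "GLY"]
        if (length(nongly))
          warning("CB missing for non-glycine residues ",
                  paste(nongly, collapse = ", "), "; using CA")
        if (any(is.na(s$ca[miss, 1])))
          stop("residues with neither CB nor CA: ",
               paste(miss[is.na(s$ca[miss, 1])], collapse = ", "))
        out[miss, ] <- s$ca[miss, , drop = FALSE]
      }
      out
    },
    HEAVY = s$heavy
  )
}
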