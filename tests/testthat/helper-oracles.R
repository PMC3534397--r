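# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own vectorized code paths: everything is a plain double
# loop over residue/atom pairs.

# O(L^2 * A^2) minimum base distance per eligible pair: explicit loops, no
# dist() reuse; computed once per (structure, base), reused across cutoffs
brute_base_dists <- function(s, base, min_sep = 3L) {
  L <- structure_length(s)
  coord <- function(k) {
    if (base == "CA") return(s$ca[k, , drop = FALSE])
    if (base == "CB") {
      if (!is.na(s$cb[k, 1])) return(s$cb[k, , drop = FALSE])
      return(s$ca[k, , drop = FALSE])
    }
    s$heavy[[k]]
  }
  rows <- list()
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j - i < min_sep) next
    A <- coord(i); B <- coord(j)
    dmin <- Inf
    for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
      d <- sqrt(sum((A[a, ] - B[b, ])^2))
      if (d < dmin) dmin <- d
    }
    rows[[length(rows) + 1L]] <- c(i, j, dmin)
  }
  do.call(rbind, rows)
}

brute_contact_pairs <- function(s, base, cutoff, min_sep = 3L,
                                dists = NULL) {
  if (is.null(dists)) dists <- brute_base_dists(s, base, min_sep)
  if (is.null(dists)) return(matrix(integer(0), 0L, 2L))
  hit <- dists[, 3L] <= cutoff
  if (!any(hit)) return(matrix(integer(0), 0L, 2L))
  unname(cbind(as.integer(dists[hit, 1L]), as.integer(dists[hit, 2L])))
}

map_pairs <- function(m) {
  if (length(m$i) == 0L) return(matrix(integer(0), 0L, 2L))
  unname(cbind(m$i, m$j))
}

# Mann-Whitney AUC with ties counted one half, by full enumeration
brute_mw_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# random point-cloud structure: CA trace of ~3.8 A steps, CB on a random
# direction, heavy = {CA, CB}; occasional glycine with no CB
random_structure <- function(n, id = "rnd", gly_prob = 0.1) {
  steps <- matrix(stats::rnorm(3L * n), n, 3L)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  ca <- apply(steps, 2L, cumsum)
  if (n == 1L) ca <- matrix(ca, 1L, 3L)
  dir <- matrix(stats::rnorm(3L * n), n, 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  cb <- ca + 1.53 * dir
  is_gly <- stats::runif(n) < gly_prob
  cb[is_gly, ] <- NA_real_
  heavy <- lapply(seq_len(n), function(k)
    if (is_gly[k]) ca[k, , drop = FALSE] else rbind(ca[k, ], cb[k, ]))
  foldcontacts:::new_structure(
    id, ifelse(is_gly, "GLY", "ALA"), ca, cb, heavy)
}

# hand-built contact map without going through build_contact_map
manual_map <- function(id, length, i, j, base = "CB", cutoff = 6.5,
                       min_sep = 3L) {
  foldcontacts:::new_contact_map(
    id, length, contact_definition(base, cutoff, min_sep), i, j)
}

# random monotone one-to-one alignment between chains of length lq and lt
random_alignment <- function(qid, tid, lq, lt, n_pairs) {
  n <- min(n_pairs, lq, lt)
  pairwise_alignment(qid, tid, sort(sample.int(lq, n)),
                     sort(sample.int(lt, n)),
                     query_length = lq, template_length = lt)
}

# random contact map: each eligible pair is a contact with probability p
random_map <- function(id, length, p = 0.25, min_sep = 3L) {
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(length)) for (j in seq_len(length)) {
    if (j - i >= min_sep && stats::runif(1L) < p) {
      ii <- c(ii, i); jj <- c(jj, j)
    }
  }
  manual_map(id, length, ii, jj, min_sep = min_sep)
}

# minimal hand-written PDB fixture: full-backbone ALA/GLY chain
write_fixture_pdb <- function(path, resnums = c(1L, 2L, 3L),
                              resnames = rep("ALA", length(resnums)),
                              chain = "A") {
  lines <- character(0)
  serial <- 0L
  # backbone template offsets per residue (arbitrary but fixed)
  atoms <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0),
                O = c(1.5, 2.5, 0), CB = c(2.0, -0.8, 1.2))
  for (k in seq_along(resnums)) {
    base <- c(4.0 * k, 0, 0)
    use <- if (resnames[k] == "GLY") atoms[1:4] else atoms
    for (nm in names(use)) {
      serial <- serial + 1L
      p <- base + use[[nm]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, paste0(" ", formatC(nm, width = 3, flag = "-")),
        resnames[k], chain, resnums[k], p[1], p[2], p[3],
        substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
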