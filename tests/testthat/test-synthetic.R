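test_that("ideal helix geometry matches its closed form", {
  h <- make_helix(10)
  ca <- h$ca
  # constant consecutive CA-CA distance by construction
  step <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  expect_equal(diff(range(step)), 0, tolerance = 1e-9)
  # closed-form check: i,i+4 pairs are nearer than i,i+3 on a 100 deg helix
  d3 <- sqrt(sum((ca[1, ] - ca[4, ])^2))
  d4 <- sqrt(sum((ca[1, ] - ca[5, ])^2))
  th <- (0:9) * 100 * pi / 180
  ref <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (0:9))
  expect_equal(ca, ref, ignore_attr = TRUE)
  expect_lt(d4, d3 + 1.5)   # helical periodicity brings i+4 close
  # CB is 1.53 A from CA, radially outward
  expect_equal(sqrt(rowSums((h$cb - h$ca)^2)), rep(1.53, 10))
  expect_error(make_helix(3), "at least 4")
})

test_that("sheet geometry: cross-strand CA near, alternating CB far", {
  sh <- make_sheet(2, 7)
  ca <- sh$ca; cb <- sh$cb
  # every residue of strand 1 has a facing partner within 6.5 A
  for (i in 1:7) {
    d <- sqrt(rowSums((ca[8:14, , drop = FALSE] -
                       matrix(ca[i, ], 7, 3, byrow = TRUE))^2))
    expect_lte(min(d), 6.5)
  }
  # offset-by-one cross-strand pairs sit on opposite sheet faces: CB pairs
  # are farther apart than the corresponding CA pairs
  far <- 0L
  for (i in 1:7) for (j in 8:14) {
    dca <- sqrt(sum((ca[i, ] - ca[j, ])^2))
    dcb <- sqrt(sum((cb[i, ] - cb[j, ])^2))
    if (abs(cb[i, 3] - cb[j, 3]) > 1) {
      expect_gt(dcb, dca)
      far <- far + 1L
    }
  }
  expect_gt(far, 0L)
  expect_error(make_sheet(1, 7), "at least 2")
  expect_error(make_sheet(2, 2), "at least 3")
})

test_that("realized folds respect the clash limit and tag elements", {
  for (sp in foldcontacts:::.default_fold_specs(8)) {
    expect_no_warning(s <- realize_fold(sp))
    D <- as.matrix(dist(s$ca))
    diag(D) <- Inf
    nonadj <- abs(row(D) - col(D)) > 1
    expect_gte(min(D[nonadj]), 3.5)
    expect_true(any(s$element > 0))
  }
  expect_equal(fold_class(foldcontacts:::.default_fold_specs(3)[[1]]), "a")
  expect_equal(fold_class(foldcontacts:::.default_fold_specs(3)[[3]]), "b")
})

test_that("fold families: determinism, degenerate case, gold alignments", {
  sp <- foldcontacts:::.default_fold_specs(1)[[1]]
  f1 <- make_fold_family(sp, 3, noise_sigma = 0.5, seed = 7L)
  f2 <- make_fold_family(sp, 3, noise_sigma = 0.5, seed = 7L)
  expect_equal(f1$structures[[1]]$ca, f2$structures[[1]]$ca)
  f3 <- make_fold_family(sp, 3, noise_sigma = 0.5, seed = 8L)
  expect_false(isTRUE(all.equal(f1$structures[[1]]$ca, f3$structures[[1]]$ca)))

  # noise 0, no indels: members identical; self-FCC = fraction of residues
  # with at least one eligible contact
  f0 <- make_fold_family(sp, 2, noise_sigma = 0, indel_prob = 0, seed = 1L)
  s1 <- f0$structures[[1]]; s2 <- f0$structures[[2]]
  expect_equal(s1$ca, s2$ca)
  d <- contact_definition("CB", 6.5)
  m1 <- build_contact_map(s1, d); m2 <- build_contact_map(s2, d)
  a <- f0$alignments[[1]]
  r <- fraction_common_contacts(m1, m2, a)
  expect_equal(r$fcc,
               length(unique(c(m1$i, m1$j))) / structure_length(s1))
})

test_that("indels shorten members and gold alignments stay consistent", {
  sp <- foldcontacts:::.default_fold_specs(1)[[1]]
  fam <- make_fold_family(sp, 3, noise_sigma = 0.3, indel_prob = 0.5,
                          seed = 99L)
  lens <- vapply(fam$structures, structure_length, 1L)
  template_len <- structure_length(realize_fold(sp))
  expect_true(any(lens < template_len))
  for (a in fam$alignments) {
    expect_lte(a$q[n_aligned(a)], a$query_length)
    expect_lte(a$t[n_aligned(a)], a$template_length)
  }
})

test_that("within-fold FCC exceeds between-fold FCC", {
  specs <- foldcontacts:::.default_fold_specs(2)
  famA <- make_fold_family(specs[[1]], 4, noise_sigma = 0.5, seed = 41L)
  famB <- make_fold_family(specs[[2]], 4, noise_sigma = 0.5, seed = 42L)
  d <- contact_definition("CB", 6.5)
  mapsA <- lapply(famA$structures, build_contact_map, d = d)
  mapsB <- lapply(famB$structures, build_contact_map, d = d)
  within <- vapply(famA$alignments, function(a)
    fraction_common_contacts(mapsA[[a$query_id]], mapsA[[a$template_id]],
                             a)$fcc, numeric(1))
  between <- numeric(0)
  for (ia in names(mapsA)) for (ib in names(mapsB)) {
    la <- mapsA[[ia]]$length; lb <- mapsB[[ib]]$length
    m <- min(la, lb)
    a <- pairwise_alignment(ia, ib, 1:m, 1:m, query_length = la,
                            template_length = lb)
    between <- c(between, fraction_common_contacts(mapsA[[ia]],
                                                   mapsB[[ib]], a)$fcc)
  }
  expect_gt(mean(within), mean(between))
})

test_that("corrupt_alignment: identity, uniform shift, monotonicity", {
  gold <- pairwise_alignment("q", "t", 1:20, 4:23, query_length = 20L,
                             template_length = 30L)
  noop <- corruption_model(shift_prob = 0, unaligned_prob = 0, seed = 1L)
  expect_equal(corrupt_alignment(gold, noop)[c("q", "t")],
               gold[c("q", "t")])

  allshift <- corruption_model(shift_prob = 1, max_shift = 1L,
                               block_length = 1000, unaligned_prob = 0,
                               seed = 5L)
  shifted <- corrupt_alignment(gold, allshift)
  expect_equal(alignment_sensitivity(shifted, gold, 0L), 0.0)
  expect_equal(alignment_sensitivity(shifted, gold, 2L), 1.0)

  set.seed(123)
  for (rep in 1:200) {
    model <- corruption_model(shift_prob = runif(1), max_shift = 3L,
                              block_length = 4, unaligned_prob = runif(1, 0, 0.5))
    out <- corrupt_alignment(gold, model)
    if (n_aligned(out) > 1L) {
      expect_true(all(diff(out$q) > 0))
      expect_true(all(diff(out$t) > 0))
    }
    expect_true(all(out$t >= 1 & out$t <= 30))
  }
})

test_that("expected sensitivity decreases with the shift rate", {
  gold <- pairwise_alignment("q", "t", 1:50, 11:60, query_length = 50L,
                             template_length = 80L)
  mean_sens <- vapply(c(0.1, 0.5, 0.9), function(p) {
    mean(vapply(1:40, function(s) {
      model <- corruption_model(shift_prob = p, max_shift = 2L,
                                unaligned_prob = 0, seed = 1000L + s)
      alignment_sensitivity(corrupt_alignment(gold, model), gold, 0L)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sens) < 0))
})

test_that("make_benchmark is reproducible and covers all needed pairs", {
  bm1 <- make_benchmark(n_folds = 3L, members_per_fold = 2L, seed = 5L)
  bm2 <- make_benchmark(n_folds = 3L, members_per_fold = 2L, seed = 5L)
  expect_equal(bm1$structures[[4]]$ca, bm2$structures[[4]]$ca)
  expect_equal(names(bm1$alignments), names(bm2$alignments))
  expect_error(make_benchmark(n_folds = 1L), "n_folds")

  # every retrieval pair must have an alignment in some orientation
  keys <- names(bm1$alignments)
  for (g in unique(bm1$index$entries$fold_id)) {
    ps <- build_pair_sets(bm1$index, g)
    for (df in ps) for (k in seq_len(nrow(df))) {
      fwd <- paste(df$query_id[k], df$template_id[k], sep = "|")
      rev <- paste(df$template_id[k], df$query_id[k], sep = "|")
      expect_true(fwd %in% keys || rev %in% keys)
    }
  }
  # corruption leaves the gold set available
  bmc <- make_benchmark(n_folds = 2L, members_per_fold = 2L, seed = 5L,
                        corruption = corruption_model(seed = NULL))
  expect_equal(vapply(bmc$gold_alignments, function(a) a$source, ""),
               vapply(bm1$gold_alignments[names(bmc$gold_alignments)],
                      function(a) a$source, ""))
})
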