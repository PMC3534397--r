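# foldcontacts

Machinery for asking a concrete question in template-based protein structure
prediction: **which definition of a residue–residue contact best
distinguishes proteins of the same fold from proteins of different folds?**

A contact definition is a triple (contact *base*, distance *cutoff*, minimum
sequence separation). The base is the atom set used to measure inter-residue
distance — Cα, Cβ (Cα substituted for glycine), or the minimum over all
heavy (non-hydrogen) atoms — combined with cutoffs from 4.5 to 100 Å and a
minimum separation of 3 residues (|j − i| ≥ 3). The package:

1. builds **contact maps** of protein structures under any such definition
   (`read_structure()`, `build_contact_map()`, `occupancy()`,
   `filter_by_separation()`);
2. scores a pair of structures by the **fraction of common contacts (FCC)**
   through a residue-level alignment (`read_alignment()`,
   `fraction_common_contacts()`): a query contact (a_i, a_j) is *common*
   when its alignment partners (b_m, b_n) are also in contact in the
   template, and

   FCC = (# query residues involved in ≥ 1 common contact) / (# aligned residues) ∈ [0, 1];

3. evaluates each contact definition by **fold retrieval**: same-fold pairs
   are positives, the fold representative paired with foreign structures are
   negatives, pairs are ranked by FCC, and per-fold ROC curves are averaged
   pointwise over folds (`build_pair_sets()`, `roc_curve()`,
   `average_roc()`, `run_retrieval()`, `best_definition_per_fold()`); the
   AUC equals the Mann–Whitney statistic with ties weighted ½;
4. ships a **synthetic benchmark generator** (`make_helix()`,
   `make_sheet()`, `make_fold_family()`, `corrupt_alignment()`,
   `make_benchmark()`): fold families with per-member coordinate noise,
   gold residue correspondences, and threading-like corrupted alignments
   with controlled residue-shift error — so the entire pipeline is testable
   without downloading any structure database.

Intended users: structural bioinformaticians benchmarking contact
definitions, threading scoring terms, or contact-map-based similarity
scores.

## Worked example

```r
library(foldcontacts)

bm   <- make_benchmark(n_folds = 5, members_per_fold = 4, seed = 1)
defs <- definition_grid(bases = "CB", cutoffs = c(4.5, 6.5, 8, 12, 100))
res  <- run_retrieval(bm$index, bm$structures, bm$alignments, defs)
res$summary
#>  definition base cutoff mean_occupancy   avg_auc
#>      CB_4.5   CB    4.5     0.01280073 0.9374998
#>      CB_6.5   CB    6.5     0.07688508 1.0000000
#>        CB_8   CB    8.0     0.13833790 1.0000000
#>       CB_12   CB   12.0     0.35393746 0.5687499
#>      CB_100   CB  100.0     1.00000000 0.5000000
```

(The last row is exactly `0.5`: with every eligible pair a contact, all
FCC values tie at 1 and retrieval is random.) The profile shows the
characteristic shape: very sparse maps (4.5 Å, 1.3 % occupancy) and
saturated maps (100 Å) discriminate folds worse than intermediate cutoffs.
With threading-like alignment errors the same definition loses accuracy:

```r
corr <- corruption_model(shift_prob = 0.5, max_shift = 2)
bmc  <- make_benchmark(n_folds = 5, members_per_fold = 4, seed = 1,
                       corruption = corr)
run_retrieval(bmc$index, bmc$structures, bmc$alignments,
              list(contact_definition("CB", 6.5)))$summary$avg_auc
#> [1] 0.9031249
```

Scoring one pair directly:

```r
d  <- contact_definition("CB", 6.5)
m1 <- build_contact_map(bm$structures[[1]], d)
m1
#> ContactMap 'F01_m1' (38 residues, CB, cutoff 6.5 A): 56 contacts
m2 <- build_contact_map(bm$structures[[2]], d)
fraction_common_contacts(m1, m2, bm$alignments[[1]])
#> FCC F01_m1 -> F01_m2: 0.895 (34 residues in 46 common contacts / 38 aligned)
```

## Command line

```sh
Rscript -e 'foldcontacts::foldcontacts_cli()' synth     --seed 1 --out bench
Rscript -e 'foldcontacts::foldcontacts_cli()' build-maps \
    structure_dir=bench/structures --out bench
Rscript -e 'foldcontacts::foldcontacts_cli()' evaluate \
    dataset_index=bench/index.tsv structure_dir=bench/structures \
    alignment_dir=bench/alignments --out bench/eval
```

Subcommands: `synth`, `build-maps`, `fcc`, `evaluate`; `--config <dcf>`
reads a `Key: value` config file, bare `key=value` arguments override it.
All reports are TSV.

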