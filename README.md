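# genprops

Presence/absence inference of higher-order genome functions — pathways,
macromolecular complexes, transport systems, guilds, metapaths and the
organizational categories that arrange them into a browsable hierarchy —
from protein-family annotation of a proteome.

A *genome property* models one functional attribute as an ordered series
of **steps** (e.g. the enzymes of a pathway), each satisfied by any of
its **evidence** lines: an InterPro entry, or another property (in
metapaths and categories). Given the InterProScan matches of a proteome,
each property is asserted as

- **YES** — proteins match the evidence for *all* required steps;
- **PARTIAL** — the number of matched required steps exceeds the
  property's curated threshold *t* but not all are matched;
- **NO** — the matched count falls at or below *t*.

Optional steps are reported but never change the call. The resulting
YES/PARTIAL/NO vector over all properties is a functional *fingerprint*
of the proteome; encoded numerically (NO = 0, PARTIAL = 1, YES = 2),
fingerprints support phylogenetic profiling: Gower distances
`d(x, y) = mean_i |x_i − y_i| / range_i`, ordination, and a permutation
ANOSIM test of group separation
`R = (mean between-group rank − mean within-group rank) / (n(n−1)/4)`.

The package covers the full data life cycle:

- **DESC flatfiles** (`parse_desc`, `write_desc`, `parse_flatfile`,
  `write_flatfile`) — the two-letter line-code dialect in the style of
  the Pfam/TIGRFAMs DESC files, plus the concatenated release file,
  status sidecars and FASTA example sidecars;
- **match input** (`parse_interproscan_tsv`,
  `apply_promiscuity_filter`) — InterProScan TSV to a per-proteome match
  table, with optional exclusion of step evidence matching more than 3
  distinct proteins (used for fair cross-resource coverage comparison);
- **assignment** (`evaluate_all`, `summary_report`, `long_report`,
  `protein_report`) — topologically ordered evaluation of the property
  dependency graph and the three report forms;
- **profiling** (`build_matrix`, `encode_matrix`, `gower_dist`,
  `anosim_test`, `overlap_partition`, `export_profiles`);
- **release QC** (`qc_report` and the individual checks;
  `select_evidence` implements the curation heuristic preferring
  family-type InterPro entries, then the most specific in hierarchy);
- **synthetic fixtures** (`make_registry`, `make_matches`,
  `make_sidecars`, `make_grouped_profiles`) — deterministic generators
  with planted ground truth, so everything is testable offline.

A command-line front end with `assign`, `validate`, `profile` and
`fixtures` subcommands ships at
`system.file("scripts", "gprop.R", package = "genprops")`.

## Worked example

```r
library(genprops)

reg <- make_registry(n_leaves = 4, n_metapath = 1, n_category = 1, seed = 3)
mm  <- make_matches(reg, seed = 5)          # planted ground truth inside
tab <- parse_interproscan_tsv(mm$tsv, "demo")
res <- evaluate_all(reg, tab)
summary_report(res, reg)
#>     accession                              name   state
#> 1 GenProp9001                Lysine degradation PARTIAL
#> 2 GenProp9002        Chorismate salvage pathway     YES
#> 3 GenProp9003          Menaquinone biosynthesis      NO
#> 4 GenProp9004             Cobalamin degradation     YES
#> 5 GenProp9501 Metapath: Lysine transport system      NO
```

Each row is one property with its assigned state; `PARTIAL` means more
required steps matched than the threshold allows for `NO`, but not all
of them (here: the planted state, recovered exactly —
`identical(vapply(res, function(x) x$state, character(1)), mm$truth)` is
`TRUE`). Profiling several proteomes:

```r
prof <- make_grouped_profiles(n_groups = 3, n_per_group = 6,
                              separation = 1, seed = 11)
m <- build_matrix(prof$results_by_proteome)
anosim_test(gower_dist(encode_matrix(m)), prof$groups,
            n_permutations = 999, seed = 11)
#> ANOSIM R = 1.0000, p = 0.001 (999 permutations)
```

`R = 1` means every between-group distance exceeds every within-group
distance — the groups' property blocks separate them perfectly.

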