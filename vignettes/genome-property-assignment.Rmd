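---
title: "Asserting genome properties and profiling proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asserting genome properties and profiling proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genprops)
```

## The model

A genome property describes a higher-order functional attribute — a
biosynthetic pathway, a macromolecular complex, a transport system, a
guild of alternative enzymes, a metapath composed of other properties,
or a purely organizational category — as an ordered series of *steps*.
A step is one functional component (one enzyme of the pathway, one
subunit of the complex) and carries one or more *evidence* lines, each
either an InterPro entry or another property. A step is satisfied when
any one of its evidence lines is: for InterPro evidence, when at least
one protein of the proteome matches the entry; for property evidence,
when the cited property is itself asserted YES (a flag relaxes this to
YES-or-PARTIAL; the strict default is the conservative choice, since a
partially present sub-system does not demonstrate the function the
citing step needs).

Steps are *required* or *optional*. Required steps model components
necessary for the function; optional steps capture accessory components
worth reporting. Only required steps decide the call. Each property
carries a curated non-negative integer threshold $t$: with $R$ required
steps of which $m$ matched,

$$\textrm{state} = \begin{cases}
\textrm{YES} & m = R,\ R > 0\\
\textrm{PARTIAL} & t < m < R\\
\textrm{NO} & m \le t.
\end{cases}$$

The threshold absorbs real-world failure modes — steps with no suitable
family model, unknown enzymes for a step, and evidence shared between
properties that should not count without supporting steps. Counting
only required steps toward $t$ is deliberate: YES is defined on
required steps, and letting optional matches push a property to PARTIAL
would allow optional-rich properties to score with zero required
evidence. A property with no required steps (or no steps) is NO and is
flagged by the QC report rather than guessed at.

Assignment of a whole registry is a topological sweep of the
property-dependency graph (one directed edge per property evidence), so
metapaths and categories always see their children's results; a cycle
aborts evaluation with its path. There is no randomness anywhere in
assignment. Categories are evaluated like metapaths but excluded from
summary reports by default — they organize the hierarchy and assert no
biology of their own.

## File formats

Properties live in DESC records: two-letter line codes in the style of
the Pfam and TIGRFAMs DESC files, with the header half (`AC`, `DE`,
`TP`, `AU`, `TH`, reference blocks, `CC` description, `DR` cross
references) followed by step blocks (`SN`, `ID`, `DN`, `RQ`, `EV`,
`TG`), terminated by `//`. Design choices where the convention leaves
room: code and value are separated by exactly two spaces; `TH` defaults
to 0 when absent; `EV` values are semicolon-separated with the first
InterPro/GenProp token the evidence accession and the rest retained as
informational member-database signatures; unknown codes are preserved
verbatim so newer files survive a round trip; `CC` text reflows at
column 74 and round-trips up to whitespace normalization; files are
UTF-8 with line endings normalized on read. The concatenated release
file is parsed leniently by default (per-record errors are collected,
suiting files of unknown provenance) and strictly for curation. FASTA
sidecars link example sequences to steps through a `step=N` header
token — the format itself prescribes no linkage, so the token is this
package's convention. Status sidecars are
`accession<TAB>checked,public`; only checked-and-public records are
releasable, and the release parse excludes the rest.

InterProScan TSV input uses the standard column layout (protein in
column 1, signature in column 5, integrated InterPro accession in
column 12 when present). The promiscuous-evidence filter — drop all
matches of any step evidence hitting more than 3 distinct proteins —
exists for fair cross-resource coverage comparison and is **off** in
the default assignment path; the count is taken within the input table
as given. Signature-level fallback matching is available behind a flag,
default off.

## Profiling statistics

Fingerprints are encoded NO = 0, PARTIAL = 1, YES = 2 — a strict
monotone bijection, so distances respect the state ordering. The Gower
distance between fingerprints is the mean of range-normalized absolute
differences; properties with zero observed range carry no information
and are dropped from the mean (a matrix that is constant everywhere has
distance 0 by convention). ANOSIM ranks all $n(n-1)/2$ pairwise
distances with mid-ranks for ties and contrasts mean between- and
within-group ranks, normalized by $n(n-1)/4$ so $R \in [-1, 1]$;
significance uses label permutations with the standard $+1$ correction,
$p = (1 + \#\{R^\ast \ge R\}) / (1 + N)$. The permutation stream is
seeded explicitly and restores the caller's RNG state. Group sizes
below 2 are rejected. These choices (mid-ranks, $+1$ correction) are
the field-standard ones; the implementation is cross-checked against an
independent brute-force ranking and against `vegan::anosim` in the test
suite.

The three-source overlap partition splits a proteome into the 7
disjoint regions of three annotation sets plus the unannotated
remainder; the 8 counts sum to the proteome size by construction, and
the test suite verifies the partition against reference coverage counts
for six microbial proteomes.

## The synthetic generator

`make_registry` emulates a small release: leaf properties of the
functional types with 2–4 steps each, metapaths citing *disjoint*
subsets of the leaves, and categories wiring everything to a root so
the connectivity check passes. Disjointness is what makes planted
states independently realizable. Every leaf has at least two required
steps and a threshold at most `required - 2`, so YES, PARTIAL and NO
are all feasible; `make_matches` then plants an exact state per leaf by
drawing the matched required count from the state's defining interval
(for PARTIAL, uniformly from the open interval $(t, R)$), with optional
steps matched at random precisely because they must not matter. States
of metapaths and categories are derived from the planted leaves by the
threshold formula directly, giving a ground truth that is independent
of the evaluator's graph machinery. Synthetic InterPro accessions come
from a reserved `IPR9xxxxx` range and proteins are `label_P000N`, so
fixtures cannot collide with real accessions; evidence accessions are
unique per step, so no cross-talk between properties. Everything is
deterministic under a seed, to the byte, and every generated artifact
parses in strict mode.

`make_grouped_profiles` emulates the group structure seen when
profiling genomes by phylum: each group has its own block of properties
(YES with probability `separation` inside the group, NO outside) over a
background of properties with a shared base state flipped with
probability `0.3 (1 - separation)`. At `separation = 1` within-group
distances are exactly 0 and ANOSIM R is exactly 1; at `separation = 0`
there is no group signal and R fluctuates around 0. What the generator
does *not* emulate: real domain architectures, correlated evidence
between related properties, taxonomically structured backgrounds, or
annotation noise that varies by genome quality — so passing tests
demonstrate the correctness of the machinery, not field performance on
real proteomes. Large-cohort effect sizes (profiling thousands of
genomes) are likewise outside what desk-scale synthetic data can
reproduce; the package's claims there are the property-level ones (R =
1 under perfect separation, null behaviour under shuffling), computed
in the test suite at 18 proteomes and 999 permutations.

## Curation heuristics and QC

`select_evidence` encodes the selection rule used when an example
protein matches several InterPro entries: prefer entries of type
family (they tend to be more specific than domains or homologous
superfamilies), then the most specific entry — the deepest in its
InterPro hierarchy. "Broad taxonomic coverage" is operationalized as a
tie-break on recorded taxonomic breadth only (candidates without a
recorded breadth rank last), with a final lexicographic tie-break so
the choice is deterministic and order-invariant. Thresholds of
semi-automatically generated properties default to 0.

The release QC report aggregates: hierarchy connectivity (every
non-category property cited by a category or metapath; categories cited
by a category or designated as roots — roots are configuration, not
hard-coded), evidence validity against the InterProScan release's
accession universe (property evidence is resolved internally and never
checked against it), FASTA sidecar presence for every
InterPro-evidenced step of non-category properties, graph problems, and
curation warnings (no required step; threshold making PARTIAL
unreachable). A registry is release-ready iff the report is empty.

## Worked example

```{r example}
reg <- make_registry(n_leaves = 4, n_metapath = 1, n_category = 1,
                     seed = 3)
mm <- make_matches(reg, seed = 5)
res <- evaluate_all(reg, parse_interproscan_tsv(mm$tsv, "demo"))
summary_report(res, reg)
identical(vapply(res, function(x) x$state, character(1)), mm$truth)
```

```{r profiling}
prof <- make_grouped_profiles(n_groups = 3, n_per_group = 6,
                              separation = 1, seed = 11)
m <- build_matrix(prof$results_by_proteome)
anosim_test(gower_dist(encode_matrix(m)), prof$groups,
            n_permutations = 999, seed = 11)
```

## Known limitations

Genomic-context validation (operon adjacency) is out of scope — the
evidence here is proteome-level only. GC-content or
manually-assigned-species properties of the original property corpus
are not representable. The FASTA presence check verifies coverage, not
that the example sequences would actually match their evidence (that
needs a sequence search). The evaluator treats the registry as a DAG;
properties appearing under several categories are fine, cycles are not.
Open design points were resolved as follows: the released flatfile
excludes non-public properties; the promiscuity threshold counts
proteins in the table as given; a property with zero required steps
reports NO and is flagged in QC rather than promoted by optional
matches.
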