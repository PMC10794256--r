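---
title: "Comparing biosynthetic gene clusters by domain architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing biosynthetic gene clusters by domain architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdalign)
```

## The problem

Biosynthetic gene clusters (BGCs) encode the enzymatic assembly lines that
build natural products. In phylogenetically distant organisms — say, algae
versus the bacteria that dominate the curated reference databases — protein
sequences of homologous clusters diverge far past the reach of
sequence-level comparison, while the *architecture* of the assembly line
(which biosynthetic domains occur, in which order) is conserved much
longer. `bdalign` therefore compares clusters at the domain level: each
cluster is reduced to its **biosynthetic domain architecture (BDA)**, the
ordered sequence of domain labels carried by its proteins, and BDAs are
aligned and clustered like sequences over a small custom alphabet.

The intended workflow is: detect candidate clusters with a rule-based
genome miner and read its annotated GenBank regions; read experimentally
characterized reference clusters from curated JSON metadata; score
domain-domain homology from the detector's own profile HMMs; align all
candidate and reference BDAs pairwise; cluster at a similarity threshold;
and flag candidates whose architecture matches a characterized reference.
A companion scan profiles transporter genes in and around clusters, since
export machinery is often co-located with the pathway it serves.

## From annotation to BDA

`parse_antismash_genbank()` reads regions and their CDS features, taking
domain calls from two qualifier vocabularies: `NRPS_PKS` (modular-domain
calls with protein coordinates, converted to genomic coordinates) and
`sec_met_domain` (detection-rule hits, assigned their CDS's coordinates).
Where a CDS carries both kinds, `resolve_feature_precedence()` keeps
`NRPS_PKS` for the modular classes (NRPS, modular PKS) and
`sec_met_domain` for the non-modular classes (type III PKS, terpene
synthase), because the modular vocabulary is the finer-grained one exactly
where modularity matters.

Post-processing applies three rules with the defaults exposed in
`filter_config()`:

* **Short contigs** (`min_contig_length = 10000` bp): regions on contigs
  shorter than 10 kb are removed outright — strictly, so a 10 000 bp contig
  survives.
* **Trimming**: region bounds shrink to the extent of CDSs that carry at
  least one biosynthetic domain; domain-free records are left untrimmed and
  flagged rather than silently dropped.
* **Contig edge** (`edge_margin = 20000` bp): a region overlapping the
  first or last 20 kb of its contig is flagged as potentially incomplete.
  The interval test is closed at the contig ends and half-open toward the
  interior.

Product labels map to classes (`map_product_to_class()`): NRPS and
NRPS-like products to NRPS; type I/II PKS to modular PKS; type III PKS and
terpene to their own classes. Mixed products resolve by the priority
NRPS > modular PKS > type III PKS > TPS, with one documented override: the
presence of an iterative-ketosynthase domain forces a hybrid into the
modular PKS class, because single-module iterative PKSs behave as PKSs
regardless of accompanying NRPS domains. Reference metadata maps
non-exclusively (`classify_reference()`): an entry annotated both NRP and
Polyketide carries both classes; a Polyketide entry whose only synthase
subclass is type III is type III PKS, never modular. A Polyketide entry
listing no synthase subclass at all is treated as the generic modular
case — the metadata schema only distinguishes "includes a non-type-III
subclass" from "only type III", and an empty list satisfies neither.

**Token order.** Within `build_bda()` CDSs are sorted by genomic start and
domains within a CDS follow translation order — genomic order on the plus
strand, reverse genomic order on the minus strand. The assembly line runs
in translation order, so this is the order in which modules act; source
annotations do not state a convention, and this choice makes the BDA of a
cluster invariant under reverse-complementing its contig. Labels are
normalized (whitespace/hyphens to underscores, subtype parentheses
flattened) and passed through a small alias table so that both qualifier
vocabularies land on one canonical token per domain.

## The scoring matrix

Domain-domain homology is scored from the detector's profile HMMs. For two
match-state emission distributions $e_1, e_2$ over the amino-acid alphabet
with background $b$, the column score is the log-odds co-emission

$$ s(e_1, e_2) = \log \sum_a \frac{e_1(a)\, e_2(a)}{b(a)}, $$

which is positive for columns that co-emit more than chance, zero for
uninformative columns, and $-\infty$ for columns that cannot co-emit any
letter. `raw_coemission()` maximizes the summed column score over monotone
column alignments (a deterministic dynamic program with a configurable
per-column gap cost, default 0) and floors the result at zero.
`normalized_coemission()` self-normalizes by the geometric mean of the two
self-scores, giving a similarity in $[0,1]$ that is exactly 1 for
identical profiles and 0 for unrelated ones; a `norm = "max"` alternative
divides by the larger self-score instead. The full transition structure of
the profiles (insert/delete states) is parsed but ignored: the scoring
contract needs only the two properties the downstream method relies on —
self-similarity 1 and zero co-emission mapping to the penalty value — and a
match-column score keeps the computation deterministic and testable
against brute-force enumeration.

`build_scoring_matrix()` assembles the label-by-label matrix: diagonal
exactly 1, off-diagonal entries equal to the normalized co-emission when
positive and **−1 otherwise**. The −1 floor is the load-bearing choice: it
makes pairing two non-homologous domains strictly worse than gapping them
both, so misalignment is suppressed by construction (see below). An
epsilon option allows raising the "zero co-emission" cutoff above 0.
Because the normalization applied by external profile-comparison tools is
not always reproducible, a matrix TSV import path (`read_matrix()`)
bypasses the internal scorer entirely.

## BDA alignment, similarity, and misalignment

`align_pair()` is an exact Needleman–Wunsch on domain tokens with **linear
gap cost 0** (end gaps free by construction), mirroring a text aligner run
with all gap penalties zero and shifts allowed — but exact rather than
heuristic. From the single reported traceback:

* $N$ — total alignment columns,
* $M$ — columns with a domain on both sides,
* **BDA similarity** $= M/N$ (equivalently, uncorrected $p$-distance
  $= 1 - M/N$),
* *misaligned* — columns pairing two domains whose matrix entry is −1.

With gap cost 0 the DP never gains by accepting a −1 pair: leaving both
tokens unaligned costs nothing and scores higher. Under the default
tie-break — prefer the diagonal only when the pair score is positive,
otherwise gap — no optimal traceback contains a misaligned column, and the
suite verifies this property over random instances. Heuristic text
aligners do produce a small percentage of such columns; this package
reports the audit (`count_misaligned()`) but, by design, its own pairwise
alignments audit at zero.

Degenerate optima are unavoidable at gap cost 0 (many tracebacks share the
optimal score, and they can differ in $N$). The deterministic tie-break
makes the reported $M/N$ reproducible; it also maximizes $M$ along the
chosen path, which is the variant most favourable to recognizing shared
architecture. Unknown tokens are a hard error by default
(`unknown = "mismatch"` treats them as −1 against everything instead).

`align_cluster()` re-aligns a cluster's members for display: sequences
join a growing profile in order of decreasing pairwise similarity, each
addition using the same zero-gap DP with column scores taken as the
maximum over the profile column's tokens. Gap-stripping any row recovers
the input BDA exactly.

## Clustering and candidate status

`cluster_greedy()` groups BGCs whenever one member reaches the threshold
similarity (default 0.8, ties inclusive) with any current member — single
linkage, equal to connected components of the threshold graph, hence
order-independent; the suite checks equality against an independent
union-find and igraph's components.

Candidate status is assigned by `assign_status()`:

* **hit** — a *direct* similarity ≥ 0.8 to at least one reference;
* **clustered** — no such reference edge, but ≥ 0.8 to another candidate;
* **orphan** — neither.

The definitional sentence for "hit" demands a direct edge; a candidate
connected to a reference only transitively through other candidates is
*clustered*, with an `in_reference_cluster` flag for transparency. The two
readings differ only when references join clusters transitively, and the
direct-edge reading is the one stated as a definition.

## Domain composition and the transporter scan

`domain_frequencies()` reports, per class and role, the mean count of each
domain per BGC; `top_domains()` ranks the top ten per group (ties broken
lexicographically). Contig-edge records are included by default — the
frequency summaries describe the detected set as a whole — with
`complete_only = TRUE` as the alternative.

The transporter scan (`enrichment_scan()`) takes complete (non-edge)
candidates only, since flank content is meaningless when the flank runs
off the contig. Around each cluster three disjoint spans are formed — the
5′ 20 kb flank, the cluster region, the 3′ 20 kb flank, clipped at contig
bounds — and genes are assigned by overlap with in-cluster priority. Each
span is tiled into 1 kb windows; per-family window frequency is genes per
kb, counting a gene in the window holding its start coordinate (midpoint
or overlap-weighted assignment would shift counts by at most one window at
these scales); a partial terminal window keeps its actual width and is
width-weighted in means. For each class, the ten most abundant families
are tested per region: that family's window frequencies in the region
versus all other windows of the class, by Wilcoxon rank-sum.

`rank_sum_test()` uses midranks for ties, complete enumeration of group
assignments when the pooled sample has at most 10 observations, and the
tie-corrected normal approximation with continuity correction otherwise.
The *enriched* flag is raw two-sided $p < 0.05$ with no multiplicity
correction (a Benjamini–Hochberg option exists but is off by default,
matching the conventional presentation of such scans); the reported mean
frequencies per region show the direction. *Exclusive* marks families
whose genes fall in a single region. Under a uniform-placement null the
flag rate sits at the nominal 5% — the suite checks 1000 simulated
families land in $0.05 \pm 0.02$ — and a 5× in-cluster density is detected
with power above 0.9 at the default window counts.

## The synthetic generator

All tests run on generated data with known ground truth:

* `generate_phmm_family()` draws an ancestor of (near-)point-mass emission
  columns and derives members by redrawing each column with probability
  `divergence` (default 0.2 in the vocabulary set). Families on disjoint
  alphabet subsets have exactly zero cross co-emission, reproducing the
  −1 block structure. `vocabulary_hmms()` builds one profile per canonical
  token with the field's homology groups (condensation subtypes, carrier
  proteins, ketosynthase subtypes) as families.
* `generate_bda()` expands module grammars: the NRPS elongation module
  condensation–adenylation–carrier, the seven-domain iterative PKS module,
  the hybrid KS module, plus optional adenylation–carrier starter and
  terminal thioesterase. `perturb_bda()` substitutes within homology
  groups, deletes, and inserts at given per-token rates (the recovery
  experiments use substitution rate 0.1, the regime in which cluster
  recovery should be exact).
* `simulate_bgc_records()` lays tokens onto CDSs (up to three domains per
  CDS, random strand) so GenBank writing and parsing round-trip exactly.
* `generate_transporter_layout()` places genes by Poisson sampling at a
  per-kb density (default 0.1 genes/kb/family), uniformly or with a
  configurable in-cluster boost (default factor 5).

What the generator does **not** emulate: real nucleotide or protein
sequence content, intron structure, annotation error, correlated domain
losses, or the covariance between cluster length and domain count seen in
real assemblies. Passing tests therefore demonstrate correctness of the
algorithms under their stated contracts, not field performance on any
particular genome set.

## Numerical choices and problem sizes

Floating-point equality in DP tracebacks uses a 1e−9 tolerance; raw
co-emission scores below 1e−9 are treated as exactly zero so that
uninformative profiles fail loudly instead of propagating rounding noise.
Matrix TSVs round-trip at 12 significant digits. All generators take an
explicit integer seed and avoid unordered iteration, so fixtures are
identical across platforms.

The shipped suites use desk-scale sizes chosen to exercise every code
path while keeping the full run around half a minute: oracle equivalence
on 200 random BDA pairs (length ≤ 6) and 100 random similarity graphs
(≤ 14 nodes); misalignment audits over 250 random alignments; recovery of
3 grammar families × 20 members; enrichment calibration over 1000
simulated families on 10 clusters and power over 40 replicates.

## Limitations

* BDA similarity degrades for highly multi-modular clusters: repeated
  elongation modules make $M/N$ sensitive to copy-number differences, so
  two clusters sharing module chemistry but differing in module count can
  fall below threshold.
* Alignment is restricted to the modular classes; type III PKS and
  terpene clusters are compared by composition only, as their single-enzyme
  architecture gives BDAs too short to align meaningfully.
* The co-emission scorer uses match columns only; profiles whose
  similarity lives mainly in transition structure will be under-scored.
  The matrix import path exists for exactly this case.
* Reference metadata carries no domain calls; reference BDAs must come
  from annotated GenBank of the reference loci, processed through the same
  extraction path as candidates.
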