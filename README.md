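# bdalign

Compare biosynthetic gene clusters (BGCs) by their **biosynthetic domain
architecture (BDA)** — the ordered sequence of biosynthetic domain labels
carried by a cluster's proteins — instead of by protein sequence. The
package is aimed at genome-mining studies that detect candidate clusters in
non-model organisms (e.g. algae) and want to prioritize them against the
experimentally characterized references curated in MIBiG-style metadata,
where sequence-level homology is too diverged to be informative but the
assembly-line architecture is conserved.

## Method at its core

1. **Extraction.** antiSMASH-dialect GenBank regions are parsed into BGC
   records; regions on contigs < 10 kb are removed, regions are trimmed to
   their domain-bearing CDSs, and regions overlapping the terminal 20 kb of
   a contig are flagged as potential partial detections. Candidate products
   map to classes (NRPS, modular PKS, type III PKS, TPS); reference JSON
   entries are kept when complete and experimentally supported.
2. **Scoring matrix.** Domain–domain homology is scored from profile HMMs:
   per matched column, the log-odds co-emission
   `log Σ_a e1(a) e2(a) / b(a)`, maximized over monotone column alignments
   and self-normalized to `s(i,j) ∈ (0, 1]` with `s(i,i) = 1`. Pairs with
   zero co-emission get `s(i,j) = −1`, which makes pairing non-homologous
   domains strictly worse than gapping them.
3. **Alignment.** Exact global (Needleman–Wunsch) alignment of two BDAs
   under that matrix with all gap penalties zero. From the alignment,
   `M` = columns occupied on both sides, `N` = total columns, and
   **BDA similarity = M/N** (uncorrected p-distance `1 − M/N`). With the
   −1 floor and gap cost 0, optimal tracebacks contain no "misaligned"
   column (a −1 pair at one position).
4. **Clustering.** Single-linkage grouping at similarity ≥ 0.8, and
   candidate status against the reference panel: **hit** (direct edge
   ≥ 0.8 to a reference), **clustered** (≥ 0.8 only to other candidates),
   **orphan** (neither).
5. **Context.** Per-class domain-frequency composition, and a transporter
   scan that tiles each complete cluster and its 20 kb flanks into 1 kb
   windows and tests per-family gene frequencies (genes/kb) between regions
   with a Wilcoxon rank-sum test (enriched at raw p < 0.05).

A seeded synthetic generator (profile-HMM families with known homology
structure, module-grammar BDAs, GenBank/JSON writers, transporter layouts)
provides all test inputs; nothing is downloaded.

## Worked example

The package's running example is a candidate NRPS from an algal genome
whose architecture matches a characterized reference cluster:

```r
library(bdalign)

m <- homology_matrix(list(
  c("Cond_Starter", "Cond_DCL", "Cond_LCL", "Cond_Dual"),  # condensation
  "AMP_binding",                                           # adenylation
  c("PCP", "ACP", "PP_bind"),                              # carrier proteins
  "TE"))                                                   # thioesterase

candidate <- bda("MesVir_RPFO01000156.1_1",
                 c("Cond_LCL", "AMP_binding", "PP_bind",
                   "Cond_LCL", "AMP_binding", "PCP"))
reference <- bda("BGC0001873",
                 c("Cond_Starter", "AMP_binding", "PCP",
                   "Cond_DCL", "AMP_binding", "PP_bind", "TE"))

align_pair(candidate, reference, m)
#> <bda_alignment> MesVir_RPFO01000156.1_1 vs BGC0001873: M=6 N=7 similarity=0.857 score=6.000
#>   Cond_LCL AMP_binding PP_bind Cond_LCL AMP_binding PCP -
#>   Cond_Starter AMP_binding PCP Cond_DCL AMP_binding PP_bind TE
```

All six candidate domains align against homologous reference domains
(condensation subtypes match each other, carrier proteins match each
other), the reference's terminal thioesterase is gapped, and the similarity
6/7 ≈ 0.857 clears the 0.8 clustering threshold — so this candidate is a
**hit** for BGC0001873:

```r
tab <- all_pairs(list(candidate), m, refs = list(reference))
assign_status(tab, cluster_greedy(tab), "BGC0001873")$status
#>              candidate_id status best_reference best_similarity in_reference_cluster
#> 1 MesVir_RPFO01000156.1_1    hit     BGC0001873       0.8571429                FALSE
```

A shell pipeline over the same functions is available via
`inst/scripts/bda-tools.R` (subcommands `simulate`, `extract`, `refset`,
`matrix`, `align`, `cluster`, `compose`, `transporters`).

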