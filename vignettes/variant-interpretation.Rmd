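---
title: "Interpreting splice-affecting variants in USH2A-associated disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting splice-affecting variants in USH2A-associated disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedx)
```

## The problem

A large fraction of people with Usher syndrome type 2 or autosomal recessive
retinitis pigmentosa (arRP) carry one clearly pathogenic *USH2A* allele and
remain genetically unexplained because the second allele hides outside the
exons: deep in an intron, where it creates or strengthens splice sites and
pulls a pseudoexon (PE) into the mature mRNA, or as a structural variant (SV)
that exon-centric assays miss. `splicedx` implements the interpretation layer
of a whole-genome-sequencing workflow for such cohorts: triage of annotated
SNVs and SVs, selection of candidates for minigene splice assays, prediction
of the transcript- and protein-level consequence of an observed splice event,
assay-driven classification, and per-proband case resolution.

The package deliberately stops where annotation tools start: allele
frequencies, Grantham/CADD/PhyloP scores and SpliceAI delta scores are
consumed as annotations, never computed; CNV/SV calls are inputs. Wet-lab
steps (minigene construction, antisense oligonucleotide design and testing)
are outside its scope — their *outcomes* are the package's inputs.

## Triage rules and their parameters

All thresholds live in `triage_config()` and are inclusive comparisons:

* `af_max = 0.01` — a variant is kept only when its global allele frequency
  *and* the frequency in every subpopulation are at most 1%. A variant absent
  from the frequency database is treated as frequency 0.
* Category rule — stop gain, frameshift, in-frame insertion/deletion and
  canonical (±1/±2) splice-site variants are kept outright.
* Missense rule — Grantham ≥ 80 (scale 5–215) OR CADD_PHRED ≥ 15 (0–99) OR
  PhyloP ≥ 2.7. The clause is a disjunction; an absent score simply fails its
  own clause.
* SpliceAI rule (`meets_spliceai_rule()`) — two of the four delta scores
  (acceptor gain/loss, donor gain/loss, each in [0, 1]) ≥ 0.1, or any single
  score ≥ 0.15. Raw delta scores at the tool's default settings are used; no
  distance re-masking is applied here. Missing scores make the rule evaluate
  false with a warning rather than an error, so a sparsely annotated record
  survives triage through its other clauses.
* SVs (`prioritize_sv()`) — caller QC pass, quality ≥ 100 of 1,000, AF ≤ 1%,
  and overlap with at least one panel-gene exon. The caller's internal QC is
  consumed as a boolean because its procedure is defined elsewhere. The SV
  size convention is ≥ 50 nt, measured between the HGVS anchors including
  intronic offsets; inversions are structural at any size.

`select_for_minigene()` encodes the assay-selection bookkeeping: from the
SpliceAI-flagged candidates plus any manual additions, it removes stop-gain
and canonical splice-site variants (pathogenic without an assay), previously
characterized variants, sequencing artifacts, variants whose assay could not
complete a genotype (the proband would remain mono-allelic), and variants
predicted to create a canonical splice site.

## The consequence engine

`transcript_model()` holds exon intervals (1-based inclusive, always stored
`start <= end`) in transcript order; on the minus strand — the *USH2A*
situation — transcript order runs down the genome. `c_to_genomic()` /
`genomic_to_c()` implement HGVS c.-style coordinates including intronic
offsets and UTR anchors; intronic positions anchor to the nearer exon
boundary, with the donor side winning the exact-midpoint tie.

A minigene observation is encoded as `splice_event()` objects of six classes:
pseudoexon inclusion, full exon skip, 5'/3' exon extension, partial exon
skip, and internal exon deletion via a novel donor/acceptor pair.
`apply_event()` rebuilds the mutant mature transcript by exon surgery; a
pseudoexon is spliced between the flanking exons of the intron that contains
it (PE-adjacent exon extension is not modelled — observed PEs splice cleanly),
and an internal deletion yields two smaller exons, hence one extra exon–exon
junction.

`predict_protein_consequence()` translates the mutant CDS from the canonical
start with the standard nuclear codon table, stopping at the first in-frame
stop, and derives the HGVS p. description by comparison with the wild-type
protein:

* a stop codon lying wholly within inserted nucleotides gives
  `Xaa#_Yaa#ins*N` with N counting novel residues from the insertion point —
  this is how a frameshifting 118-nt pseudoexon can still read `ins*13` when
  its internal stop precedes any shifted native codon, and an in-frame 87-nt
  pseudoexon reads `ins*5`;
* an in-frame event whose translation reaches the normal terminal stop gives
  `del`, `ins` or `delins`, with the deletion block placed as 3'-most as the
  sequence allows (maximal common prefix);
* any other premature stop gives `fs*N` counting from the first changed
  residue, or the nonsense form `Xaa#*` when the first changed codon is
  itself the stop.

An in-frame deletion whose junction codon happens to spell a stop is treated
as a premature-termination outcome, not a deletion — the classifying fact is
where translation actually ends. Degenerate inputs are refused early:
pseudoexon intervals must lie inside one intron, extensions inside their
intron, partial skips inside their exon, and an event that removes the start
codon is an error. A mutant with no stop before the transcript end is
reported as an open-ended frameshift with a warning.

NMD is flagged by the canonical 50-nt rule (premature stop ending ≥ 50 nt
upstream of the last exon–exon junction of the *mutant* transcript). The
source procedure never states an NMD rule, so the flag is informational and
never feeds classification.

### The independent oracle

`bf_splice_consequence()` re-derives every consequence by a deliberately
different route: a per-base genomic lookup table built by walking exons, raw
character-vector slicing for the event surgery, its own complement map and
codon table, and naive-loop prefix/suffix comparison. The test suite and
`analysis/03_splice_consequences.R` require 100% agreement on 500 seeded
random (transcript, event) pairs spanning both strands and all six event
classes; the ins*/fs* boundary, the 3'-most deletion placement, and the NMD
flag must all match exactly.

## Classification and case resolution

`classify_from_assay()` encodes the assay-driven rules: a full effect (no
conventionally spliced transcript left) whose every product carries a
premature stop is pathogenic; a full in-frame deletion disrupting a predicted
functional protein domain is likely pathogenic, and a full-effect outcome
mixing PTC and in-frame products is treated the same way (the in-frame
product alone caps the certainty); any residual conventionally spliced
transcript caps the call at VUS. Domain disruption is an input (a domain
table judgement), not something the package infers. A variant with no splice
effect is not reclassified by this rule. Published labels for individual
variants can sit one notch below the rule's output where other ACMG evidence
intervened; cohort analyses therefore run on the table's printed labels, and
both pathogenic and likely pathogenic count as "(likely) pathogenic" for
resolution, so case status is unaffected.

`resolve_case()`: two (likely) pathogenic alleles → solved; exactly one plus
a VUS → possibly solved; anything else → unsolved. One refinement proved
necessary to reproduce the published table faithfully: its overview lists,
for unexplained probands, variants that were found but *not* deemed
potentially causative, including one proband with a pathogenic allele and a
VUS that the study still calls unsolved. The cohort fixture therefore
carries a per-allele `vus_causative` flag transcribed from the table's
section structure, and a VUS not deemed causative does not support a case.
The flag defaults to causative, so the plain rule is unchanged for ordinary
use, and `resolve_case_oracle_table()` — an independent enumeration over all
36 ordered classification pairs — pins the rule down in tests.
`cohort_summary()` rounds percentages half-up to integers.

## What the generators emulate — and what they do not

`make_transcript()` produces a multi-exon gene on a random strand: six exons
of 60–240 nt, introns of 250–2,000 nt, ~45% GC, a CDS with ATG start, no
internal stop, and an in-frame terminal stop, plus a 3' UTR that opens with a
cassette containing a stop in all three frames so frameshifted reads always
terminate. This is a compact stand-in for a disease-gene locus; it is *not*
USH2A-sized (72 exons, 800 kb), and annotation fields in
`make_variant_table()` are sampled independently per field, so nothing about
score correlation, mutational spectra or haplotype structure carries over to
real data. Passing tests therefore demonstrate the correctness of the
coordinate arithmetic, surgery, translation and decision rules — not
calibration against real variant databases. `make_cohort()` mirrors the
referral-cohort genotype mixture (37% two (likely) pathogenic alleles, 12%
one plus a causative VUS, 5% two VUS, 5% benign-containing pairs, 31%
mono-allelic, 10% none), chosen to echo the published cohort's composition.
All generators are deterministic under `sim_config(seed = )`.

## Problem sizes and reproducibility

The oracle-equivalence runs use 100 random transcripts × 5 events (500
pairs), the coordinate round-trips 200 positions per transcript over several
transcripts of each strand, and the SpliceAI truth table the full
6^4 grid over {0, 0.09, 0.1, 0.14, 0.15, 1}; these sizes exercise every
branch of the engine while keeping the whole suite around a minute. The
`analysis/` scripts re-run the same computations as a narrative workflow and
write their tables under `results/`.

## Known limitations

* The HGVS grammar covers the constructs that occur in this study
  (substitutions, del/dup/ins/delins including inverted-segment delins,
  inversions, intronic offsets, UTR anchors, compound alleles) — not the full
  nomenclature.
* Whole-genome `g.` descriptions of complex SVs whose breakends lie outside
  the gene are parsed and typed but not consequence-annotated.
* Overlapping calls from multiple SV callers are treated as independent
  records; no merging strategy is implied.
* The minigene outcome table encodes one tentative second pseudoexon (PE20a)
  as optional: its haplotype attribution is explicitly uncertain, and one
  published event description (the novel donor/acceptor offsets of the exon
  13 internal deletion) is encoded by its printed nucleotide offsets without
  resolving the donor/acceptor naming.
* Splice outcomes come from minigene assays in HEK293T cells; splicing can be
  cell-type specific, so partial effects in particular may differ in retina —
  one reason the partial-effect rule caps at VUS.
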