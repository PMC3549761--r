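---
title: "Diagnostic SNP discovery from reduced-representation reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic SNP discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rrsnp` implements a counts-based pipeline for discovering
lineage-diagnostic (autapomorphic) SNPs from genome-reduced, multiplexed
pyrosequencing data, together with a synthetic-data generator that makes the
whole pipeline testable against planted ground truth. This vignette explains
the models, the tunable parameters, what the simulator does and does not
emulate, and the design choices made where the underlying protocol left the
design open.

## The stated world the simulator emulates

The generator's defaults describe a discovery panel typical of salmonid
conservation genomics:

* **ten lineage groups** — nine cutthroat-trout-like lineages plus a
  rainbow-trout-like outgroup — with **2–4 sequenced individuals per
  lineage** and 6 outgroup individuals, 36 in all;
* a **2 Mb multi-contig reference** standing in for the genome-reduced
  fraction of a much larger genome, including one **mitochondrial-like
  contig** (~16.6 kb) and ~10% of bases flagged **repetitive** in the truth
  masks;
* three classes of planted substitutions: **autapomorphic** variants fixed on
  both haplotypes of every focal-group individual (0.2/kb per group),
  **shared** polymorphisms segregating at 50% per haplotype in 2–4 groups
  (1/kb), and **rare within-group** variants carried on a single haplotype of
  a single individual (0.5/kb). These rates put desk-scale totals in the
  thousands, enough to exercise every filter without hour-long runs;
* occasional **paralog-collapsed contigs** (4% of contigs): dense apparent
  heterozygosity (~10 variant sites/kb on one haplotype of *every*
  individual), mimicking two co-assembled gene copies — the failure mode the
  window filter and the one-per-contig rule exist to catch.

Genome reduction is an in-silico double digest with EcoRI (`G^AATTC`) and
BfaI (`C^TAG`) — standard REBASE cut sites; the protocol names the enzymes
only — followed by size selection. Only fragments with one EcoRI and one
BfaI end are retained (mirroring biotin–streptavidin selective adapter
capture; configurable off), with inclusive length bounds of 450–600 bp
applied to the insert without adapters. On random 2 Mb sequence this retains
~2% of the genome; the real protocol's "~90% discarded" is a qualitative
anchor, and the retained-minority property is what the tests assert.

Reads are 454-like: lengths approximately normal with mean 379 bp and SD
60 bp (truncated at the fragment), starting at either fragment end on one of
the individual's two haplotypes with equal probability. Per-individual yield
is negative-binomially over-dispersed (dispersion 0.5) to reproduce the
unequal per-barcode read totals seen on real multiplexed runs. The error
model is independent per-base substitutions (0.002) plus ±1 indels per
homopolymer run of length ≥ 2 (0.002/run) — the dominant 454 error mode.
Quality strings are a constant Q30 symbol because the downstream filters
never read qualities. Not emulated: flowgram (SFF) output, PCR duplicates,
adapter read-through, strand-specific artifacts, and real
alignment/assembly — truth alignments are emitted directly in SAM, so a
green test establishes the filters' behavior *given correct alignments*, not
the robustness of any aligner.

A single integer seed drives every stage through documented stream splits
(panel → digest → reads → genotypes), so identical configurations give
byte-identical FASTQ/SAM/TSV outputs.

## The filter cascade

Candidates are pileup columns with ≥ 2 called `A/C/G/T` alleles; the major
and minor alleles are the two most frequent, ties broken by the fixed base
order A < C < G < T (this tie-break, plus leftmost-coordinate rules, makes
all outputs deterministic). The criteria, with defaults:

| id | rule | default |
|----|------|---------|
| C1 | variant allele confined to one group | tolerance 0 reads elsewhere |
| C2 | pooled read depth at the column | ≥ 8 |
| C3 | reference flank each side; indel/ambiguity-free zone | 50 bp; 20 bp |
| C4 | minor-allele reads; minor fraction of called alleles | ≥ 3; ≥ 4% |
| C5 | focal-group reads carrying the variant | ≥ 95% |
| C6 | outside repeat masks and off the mtDNA contig | — |
| W  | position-weighted window score | reject at ≥ 6 |
| C7 | one locus per contig | max depth, leftmost on ties |

Design choices where the protocol is silent:

* **C2 depth scope** is pooled across all individuals ("all reads at the
  SNP locus" does not scope it); a per-group minimum can be imposed by
  raising `min_depth` relative to expected per-group coverage.
* **C4 denominator** counts only called `A/C/G/T` alleles; `N` calls count
  toward depth (C2) and toward ambiguity evidence (C3) but never toward an
  allele, so ambiguous base calls cannot create or dilute alleles.
* **C5 numerator** is the focal group's *variant* allele — the allele that
  drives the autapomorphy — not the pooled minor per se; the intent is
  "fixed or nearly fixed within the subspecies".
* **Indel conventions** (pileup): deletions add evidence at every deleted
  position but no base count; insertions add evidence at the flanking
  reference position on each side. C3 needs only a clean/not-clean signal.
  Note the consequence: at high depth and realistic 454 indel rates, a
  single erroneous read dirties a 41-bp window, so C3 is the dominant filter
  on noisy data. The planted-recovery guarantees are therefore stated — and
  tested — at zero sequencing error.
* **Window filter**: only the rejection threshold (≥ 6) is published. The
  radius (20 bp, matching the clean zone) and the banded weights
  (3 within 1–5 bp, 2 within 6–10 bp, 1 within 11–20 bp) are this package's
  defaults, fully exposed in `filter_params()`. A neighboring position
  counts as polymorphic only when ≥ 2 alleles each have ≥ 2 reads —
  unguarded singletons are sequencing noise at 454 error rates and would
  make the filter reject nearly everything.
* **Pairwise counts**: entry (A, B) counts candidates focal to A whose
  group-consensus base differs between A and B. The published pairwise table
  this emulates is asymmetric for reasons its source does not explain; the
  package defines one explicit ordered-pair semantics and does not claim to
  reproduce that table.

## Diversity summaries

Genotypes are coded 0/1/2 copies of the panel-wide minor allele; per-group
MAF is folded to ≤ 0.5 (the theoretical maximum for a biallelic marker).
Because published per-group "average MAF" tables rarely state whether zeros
are included, `summarize_polymorphism()` reports both conventions, labeled.
The distance is the allele-sharing distance, `d(i,j) = 1 − shared/(2L)` with
`shared = 2 − |g_i − g_j|` per jointly typed locus — the protocol being
emulated does not name its distance, so this documented, metric choice is
the package's own. PCoA is classical metric scaling: double-center
`−D²/2`, symmetric eigendecomposition, coordinates scaled by square roots
of positive eigenvalues, variance explained relative to the
positive-eigenvalue total; axis signs are fixed by making the first nonzero
loading positive. The admixture index is a deliberately lightweight,
counts-based stand-in for model-based clustering: per group, the normalized
fraction of that group's diagnostic alleles an individual carries, with a
hybrid flag at second-fraction ≥ 0.10. It is suitable for flagging F1-like
individuals in simulations, not a substitute for Bayesian ancestry
estimation on real data.

The pipeline's verification panel tops each lineage up to ~10 genotyped
individuals. Verification individuals carry their lineage's diagnostic
alleles at frequency 0.9 (near-fixation — consistent with what the
95%-identity criterion tolerates) and other lineages' diagnostic alleles at
frequency 0.02 (residual introgression, which real wild samples show).
Perfectly pure panels would fold every focal-group MAF to zero and make the
Table-3-style summary degenerate; these two frequencies are a realism
choice, not calibrated to reproduce any published number.

## Numerical and degenerate-input conventions

* All internal coordinates are 0-based half-open; SAM (1-based) and BED
  (0-based) convert at the boundary, and masks use half-open containment
  (a SNP at position 100 is inside `[100, 200)`, one at 99 is not).
* Thresholds are inclusive at their printed boundaries: a fragment of
  exactly 450 bp is retained; a minor fraction of exactly 4% and an
  identity of exactly 95% pass; a window score of exactly 6 rejects.
* Barcode matching is exact prefix match, no mismatch tolerance: the
  protocol does not describe the vendor's error handling, and exactness
  keeps truth-recovery tests crisp. Barcodes must be mutually prefix-free.
* Empty inputs return empty, well-typed tables; invalid configurations
  raise `rrsnp_config_error` naming the offending field; malformed or
  unknown-contig SAM records raise `rrsnp_format_error` naming the record.
* PCoA on a matrix with no positive eigenvalues errors as degenerate;
  eigenvalue positivity uses a relative `1e-12` tolerance.

## Known limitations

* The simulator plants substitutions only; haplotypes never differ from the
  reference by indels, so alignment-induced indel artifacts come solely
  from the read error model.
* Reads are represented on the forward strand; strand and reverse
  complementation are not modeled (the filters are strand-agnostic counts).
* The discovery-side guarantees are proven at zero sequencing error; with
  realistic error rates the C3 clean-zone rule dominates attrition, which
  is faithful to the rule as stated but means desk-scale noisy runs
  validate far fewer loci than planted.
* BAM/CRAM, paired-end data, genotype likelihoods, primer thermodynamics,
  Bayesian clustering, and network construction are out of scope.
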