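---
title: "Methods: from annotated somatic variants to filtered neoantigen candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from annotated somatic variants to filtered neoantigen candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoforge)
```

## Scope and assumptions

`neoforge` begins where the upstream tools of a proteogenomic neoantigen
screen end. It consumes their tabular outputs — ANNOVAR-style exonic
annotations, STAR-Fusion-style fusion coding effects, Kallisto-style
transcript abundances, a MaxQuant-style identified-peptide list, and
NetMHCpan/NetMHCIIpan-style affinity tables — and implements everything
downstream: mutant protein construction, mutation-anchored window
extraction, custom search-database assembly, binder classification and
the four-stage filter cascade. Read alignment, variant calling, HLA
typing, the MS search itself and the binding neural networks are out of
scope by design; where an affinity table is not available the package
substitutes a deterministic mock predictor so every stage remains
executable and testable offline.

Two standing assumptions: fusions arrive as already-translated junction
protein sequences (translating genomic breakpoints is upstream work), and
frameshift variants carry a cDNA-level edit (`c.6_7insC`) because their
protein product can only be obtained by re-translating the edited CDS.

## Coordinates

All coordinates are 1-based inclusive, end to end — the HGVS convention
of the input formats and the natural convention of R string functions.
Keeping one convention internally and externally removes an entire class
of off-by-one defects that a 0-based internal representation would buy
nothing for in a language whose `substr()` is 1-based.

## Mutant proteins and the altered region

Every constructed mutant carries an interval `[a, b]` in mutant
coordinates marking the residues considered novel:

* **missense** — the substituted residue, `[pos, pos]`;
* **in-frame insertion** — the inserted residues;
* **in-frame deletion** — the two residues flanking the deletion
  junction, clamped to `[1, L]` at the termini. A deletion changes no
  residue; its novelty is the new adjacency, and windows must span the
  junction to contain it;
* **frameshift** — from the first residue that differs from the
  reference translation through the end of the product. Translation
  proceeds codon by codon and truncates at the first stop codon;
  products that run off the CDS without a stop are kept and flagged
  (`stopFound = FALSE`) rather than silently discarded — discarding them
  would hide candidates the screen is supposed to count;
* **fusion** — the junction residue pair when in frame; junction to end
  when the 3' partner is out of frame.

Reference mismatches (the annotation's reference residue disagreeing
with the proteome) raise a typed condition and are collected per variant
set, never silently dropped: a mismatch usually means the annotation and
proteome releases disagree, which the analyst needs to see.

## Window extraction

For window length $k$ and altered region $[a, b]$ on a mutant of length
$L$, valid starts are $s \in [\max(1, a-k+1),\ \min(b, L-k+1)]$ — exactly
the length-$k$ substrings whose interval intersects the altered region,
with stride fixed at 1. Class I uses $k \in [8, 11]$, class II
$k \in [15, 30]$. For a single interior site this yields $k$ windows per
length: 38 class I and 360 class II windows in total; at sequence
boundaries the count is clipped. Windows containing non-standard residues
(X, U) are dropped and counted, because binding predictors reject them;
the underlying sequences are kept. Deduplication is per variant on
(sequence, $k$) keeping the leftmost start — cross-variant duplicates
survive until report-level deduplication because per-mutation-class
provenance matters for the output files. Candidate FASTA output is
emitted for external predictors (FASTA, not FASTQ: peptides have no
quality scores, whatever upstream docs may call the format).

## Binder classification

Strong/weak/non categories are a pure function of MHC class and
percentile rank: class I strong at `%Rank <= 0.5`, weak on `(0.5, 2]`;
class II strong at `%Rank <= 2`, weak on `(2, 10]`; all boundaries
inclusive exactly as published. Candidate selection uses the percentile
rank only; IC50 is carried through untouched because it is consumed later
by the strict screen, not by selection. Allele names are normalized to
one canonical notation (`HLA-A*03:01`, `DRB4*01:03`) since typing tools
and predictors mix `HLA-A03:01`, `HLA-A_03_01` and `DRB4_0103` freely;
unrecognized names (e.g. class II heterodimer pairs) pass through
verbatim.

The mock predictor derives rank and IC50 from a 31-bit polynomial hash of
(peptide, allele) and the seed: ranks approximately uniform on (0, 100],
IC50 log-uniform on (1, 50000] nM, byte-identical across platforms, no
RNG state consumed. It models no binding biology at all — that is the
point: it gives the cascade deterministic, seed-reproducible inputs whose
downstream consequences can be computed by arithmetic.

## The filter cascade

Stage order follows the published screen: binder selection, expression,
MS evidence, then two *parallel* terminal screens (database similarity
and strict thresholds) applied to the MS survivors — the two published
comparisons are separate, not sequential.

**Expression.** Candidates are kept when their source transcript's
abundance is strictly positive (`tpm_min_exclusive = 0`, configurable).
The published description of this filter ("remove ... TPM < 0") is
unsatisfiable as written since TPM is non-negative; removing
non-expressed transcripts (TPM = 0) is its stated intent and is what the
package does. Variants absent from the table are treated as unexpressed
but counted separately. Fusions use the maximum over the two partner
genes.

**MS evidence.** Tryptic peptides rarely coincide with MHC windows, so
exact equality would annihilate the cascade. A candidate is supported
when an identified peptide contains it, is contained in it, or overlaps
it by at least `ms_min_overlap = 7` residues (the search engine's
minimum peptide length) when both locate on the same mutant protein — and
in every case the shared residues must include at least one altered
position, otherwise the evidence only confirms wild-type sequence.

**Database similarity.** Each candidate is aligned locally (BLOSUM62,
gap open 11, extend 1 — protein-BLAST defaults) against a curated
database of validated neoantigen peptides carrying high/medium confidence
tiers; both tiers are searched and the best hit's tier is recorded. The
published screen reports "similarity scores" on a bounded scale without
defining them; the package defines

$$\mathrm{similarity} = 100 \times \frac{\text{positive-scoring aligned pairs}}{\text{query length}}$$

which is 100 for an identical peptide (every BLOSUM62 diagonal entry is
positive), 0 when no positive-scoring local alignment exists, and
bounded on [0, 100] — consistent with the published 20–100 match window
and 40–100 observed range. This definition is a reasoned reconstruction,
not a published fact. To make the value well defined when several local
alignments share the optimal score, the aligner maximizes (score,
positives) lexicographically, so the reported similarity never depends on
traceback tie-breaking. The kernel is a small C++ three-state affine
Smith–Waterman; tests check it against two independent oracles — an
R suffix-recursion formulation for (score, positives) and Biostrings'
local aligner for the score. A candidate matches when its best similarity
lies in `[sim_threshold_low, sim_threshold_high]` = [20, 100], and the
matching ratio is $100 \times \text{matched}/\text{compared}$ to two
decimals, reported as `NA` (not 0) for an empty comparison.

**Strict screen.** Class I candidates only, keeping
`IC50 <= 34` nM *and* `TPM >= 33`, both boundaries inclusive — published
immunogenicity-derived thresholds. Class II candidates are skipped with a
warning: the published screen defines no class II analogue, so the
package refuses to invent one. For the same reason the database and
strict screens run only on the class I arm of `runPipeline()`.

## Reporting

Counts are aggregated per stage, mutation class and MHC class, with
per-allele counts over unique peptides (one peptide can bind several
alleles; the per-class files keep every row, the per-allele counts
deduplicate). Sum identities — per-class counts adding up to stage
totals, strong + weak equalling selected binders — are asserted inside
`aggregateReport()`. Ratios are rounded to 2 decimals and percent
increases to 1, matching the precision of the published tables; result
files are written atomically (write-then-rename) per mutation class.
Where a published total disagrees across sections with the sum of its
published parts (289,142 vs 289,138 for the class II candidates), the
package sides with the per-class sum.

## The synthetic generator and what passing tests mean

`generateFixture()` emulates the *shape* of the real inputs at toy
scale: 50 proteins of 250–350 residues, 5 variants per mutation class,
the five published class I alleles and two class II alleles, 70% of
transcripts expressed (TPM log-uniform on [1, 1000]), half the mutant
proteins MS-detectable, and a 60-entry decoy database with up to 8
planted exact copies of candidate windows. Each variant sits on its own
protein so evidence for one variant cannot accidentally support another;
MS evidence for a detected variant is a mutant-protein fragment padded by
the widest window length around the altered region, so by construction it
supports every window of that variant and no window of any other. CDS
sequences are reverse-translated with uniformly sampled synonymous
codons, so they translate back exactly to their proteins. A single seed
drives every choice; identical spec and seed give byte-identical files,
and the caller's RNG stream is saved and restored.

The ground truth lists the `variant|peptide|allele` keys that must
survive each stage, derived by direct threshold arithmetic (not by
calling the filter code): mock rank against the class thresholds for the
binder stage, the generator's own expressed/detected coin flips for
expression and MS, and explicit IC50/TPM comparisons for the strict
stage. Candidate enumeration itself is shared with the package (the
window rule has its own brute-force oracle tests), and for the
similarity stage only the planted exact copies are knowable in advance —
the ground truth asserts they are matched whenever they reach that
stage, a superset check, since the similarity of random decoys cannot be
known without running an aligner.

Passing the end-to-end test therefore shows that the cascade's plumbing
is faithful to the stated rules under known inputs. It does not show
that the rules find true neoantigens: the fixture has no binding
biology, no real MS noise or missed cleavages, no expression structure,
and no homology between its random proteins — four features of real data
this generator deliberately does not model.

## Problem sizes and degenerate inputs

The test suite uses 100 randomized mutants for the window oracle, 200+
randomized CDS edits for the frameshift oracle, a 20×20 random peptide
panel (all 400 ordered pairs) for the alignment oracles, 300 random
pairs for the ratio arithmetic, and default-scale fixtures for the
end-to-end checks; the full suite runs in about two minutes on one core.
Degenerate inputs are contracts, not accidents: proteins shorter than
the minimum window length yield empty tables (logged, not errors),
empty candidate sets give `NA` matching ratios, an empty mutant set
still builds a valid (warned) search database, deleting an entire
sequence or editing past the CDS end raise typed `InvalidVariant`
conditions, and a zero-variant fixture runs the whole pipeline to an
all-zero report.

## Known limitations

* Multi-transcript annotations produce one record per transcript;
  selecting a canonical transcript is left to the analyst.
* Wild-type proteins coexist with their mutant counterparts in the
  search database (the MS engine needs wild-type context); decoy
  (reversed) entries are not generated because search engines build
  their own.
* The expression filter operates at transcript/gene resolution, not
  allele-specific expression.
* No proteasomal-cleavage, TAP-transport or TCR–pMHC modeling; these
  belong to other tools.
* `similaritySearch()` is the package's own aligner; delegating to an
  external `blastp` binary is not implemented — the in-package metric is
  the defined quantity, and an external tool's bit-scores would not be
  comparable on the 0–100 scale.
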