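---
title: "Methods: neoepitope prioritization, callable-territory TMB and DNA–RNA concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoepitope prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`neoforge` is the analysis layer of a neoantigen discovery workflow for
tumors whose immunogenicity is driven by structural chaos rather than SNV
load. This vignette documents the models it implements, the assumptions
behind them, the tunable parameters, the synthetic test cohort, and the
design decisions taken where the problem was genuinely open.

## Scope and assumptions

The engine starts *after* primary analysis: it consumes a filtered
tumor–normal somatic VCF plus effect annotation, an Arriba-style fusion
table, per-base depth tracks, transcript TPMs, and a class I HLA genotype.
It assumes:

* the caller's FILTER field is authoritative (`PASS` means all upstream
  tests passed; anything else disqualifies the record);
* effect annotation identifies, per variant, a consequence class and the
  transcript-level coordinates needed to rebuild the mutant protein;
* binding `%Rank` values come from a NetMHCpan-class predictor — the
  engine never re-implements one. Real predictions are imported from
  tabular output; a deterministic stub (stable digest of peptide+allele,
  with allele-specific anchor bonuses) stands in for tests.

## Callable territory and TMB

Uneven exome capture makes genome-wide TMB denominators misleading: a
sample whose coding target is only fractionally covered at usable depth
would have its burden diluted. The engine therefore defines a
**callable territory** — CDS positions with depth ≥ `min_depth`
(default 10×) — and reports

TMB = (PASS, depth-qualified nonsynonymous mutations inside the territory)
/ (callable megabases).

Nonsynonymous means missense, stop-gain, frameshift or in-frame indel.
Stop-gains are *counted here but excluded from the epitope path*: they
truncate the protein rather than produce a presentable substituted
context, and transcripts with premature stops are prone to
nonsense-mediated decay. Synonymous variants count nowhere.

Two open points were decided as follows (flagged because the convention
affects comparability):

* the TMB numerator is restricted to callable CDS only; no separate
  capture-target mask is applied;
* Ti/Tv is computed over PASS, depth-qualified *biallelic SNVs* within the
  same callable territory; indels and MNVs are excluded (standard
  practice), and a zero-transversion sample reports Ti/Tv as undefined
  (`NA`) rather than infinity, keeping downstream tables finite.

## Peptide generation

All candidate peptides are 8–11-mers, the lengths that account for most
MHC class I ligands.

* **Missense**: the annotated residue is substituted into the transcript
  protein (a mismatch between annotation and sequence is a hard error —
  it means the two resources are out of sync). Every window of length
  8–11 containing the substituted residue is emitted, truncated only by
  the protein termini, with the same-coordinate wild-type peptide
  attached.
* **Frameshift**: the indel is applied to the CDS and the mutant is
  re-translated from codon 1. The altered span runs from the first
  residue that differs from the reference translation through the new
  terminus (stop excluded). Re-translating from codon 1 rather than
  locally guarantees the novel tail is read in the exactly shifted frame;
  a frameshift whose shifted frame stops immediately yields no context.
* **In-frame indels**: insertions mark the inserted residues as the
  altered span. Pure deletions leave no altered residue, so windows are
  required to *straddle the deletion joint* (the newly adjacent residue
  pair) — the nearest consistent reading of "handled similarly" to
  substitutions. Protein-silent in-frame edits yield no context.
* **Fusions**: only high-confidence, in-frame fusions with ≥ 5 junction
  reads and/or discordant pairs survive filtering. The chimeric junction
  CDS is translated from its first codon — the sequence is assumed to be
  supplied in the fusion ORF's frame, with `junction_offset` locating the
  breakpoint within it (Arriba's `|`-marked transcript sequence provides
  exactly this; a sidecar FASTA covers callers that omit it). Only
  windows containing at least one residue from each partner are kept, so
  every fusion peptide is junction-spanning and strictly absent from the
  normal proteome. A stop codon upstream of the junction suppresses the
  whole record.

Peptides containing `X` (ambiguity) or a stop are suppressed. Duplicate
sequences from different windows of one variant collapse to the first
window; identical sequences arising from *different* variants remain
distinct records, because their expression/clonality evidence differs.
Nearby somatic variants are not phased into a joint context
(single-variant contexts; a known limitation).

## The priority score

Every component is bounded, and the composite is their product scaled to
0–100:

$$\mathrm{priority} = 100 \cdot L(r)\cdot \tanh(E/s)\cdot \mathrm{VAF}\cdot F$$

* **Binding**, $L(r) = 1/(1+e^{5(r-2)})$: the logistic transform of the
  `%Rank`, slope 5, inflection at 2%. $L(2)=\tfrac12$ analytically; ranks
  beyond 2% collapse smoothly toward 0 instead of being hard-excluded.
  Classification thresholds: strong < 0.5%, weak 0.5–2.0% (both
  boundary values are weak), non-binder above 2.0%.
* **Expression**, $\tanh(E/s)$: 0 at zero expression, saturating toward
  1. Scales (TPM/10, FFPM/2) were chosen so the component has gradient
  over the ranges where expressed candidates actually live (roughly
  1–50 TPM, 1–10 FFPM); both configurable. A separate hard gate excludes
  TPM < 1 (genes) and FFPM < 1 (fusions) as insufficient antigen supply —
  the gate is a veto, not a weight, so near-threshold expression does not
  silently scale scores.
* **Clonality**: VAF enters linearly, deprioritizing subclonal events.
  Fusions, whose VAF cannot be read from RNA evidence, are treated as
  clonal drivers (weight 1) and their FFPM serves as the expression
  proxy.
* **Foreignness / agretopicity**: the agretopicity index
  $r_{wt}/r_{mut}$ is reported raw; the composite uses the bounded factor
  $F = 1 - 0.5\,L(r_{wt})$, so a strongly binding wild-type counterpart
  (self-like presentation) at most halves priority while keeping the
  score bounded. Candidates without a counterpart (frameshift, indel,
  fusion) are fully foreign ($F=1$, index absent).
* **Self-similarity veto**: a peptide occurring verbatim anywhere in the
  reference proteome is assigned priority 0 outright.

The 0–100 product scale is a deliberate design choice: published
composite "priority scores" of this family are reported on scales whose
weights are not derivable from the available descriptions, so the package
reproduces the *structure* (which components, how bounded, which vetoes)
on a declared scale rather than guessing weights. Rankings, the quantity
that matters downstream, depend only on the structure.

Ranking is fully deterministic: descending priority, then ascending
`%Rank`, descending expression, and lexicographic peptide/allele/gene as
final tie-breaks; identical inputs yield byte-identical output tables
(floats rendered at fixed precision by the writers).

## DNA–RNA concordance

Isolated extreme exome depth is not evidence of amplification in legacy
capture data; spikes shared between tumor and matched normal are capture
bias. The classifier reduces each locus to three booleans:

* `dna_elevated`: tumor locus/background depth ratio ≥ `r_dna`
  (default 3) *and* tumor ratio ≥ `r_somatic` (default 2) × the normal's
  ratio — locus depth is always judged against the sample's own mean CDS
  depth, which absorbs library-size differences;
* `shared_with_normal`: both tumor and normal locus ratios ≥ `r_dna`;
* `rna_elevated`: TPM ≥ max(`t_abs` = 50, `f_rel` = 5 × per-gene cohort
  reference TPM, default the cohort median).

Label mapping (total over the boolean space): DNA + RNA and not shared →
`concordant_amplification`; DNA without RNA, or shared →
`capture_artifact`; RNA only → `transcriptional_only`; otherwise
`unremarkable`. The underlying logic is qualitative in its source domain;
the numeric defaults are package choices, declared once and configurable,
not values inferred from data.

## The synthetic cohort

`toy_cohort_spec()` / `simulate_cohort()` generate a coherent toy world:
20 genes × 600 bp on one contig, one transcript each (the first gene split
across two abundance rows to exercise TPM aggregation), three samples —
SNV-heavy without fusions, SNV-low with fusions (one passing, three
failing for support/confidence/frame), and an amplification-driven sample
carrying the three planted concordance events (depth ×12 + TPM ×100
amplification; ×10 tumor+normal shared spike; expression-only gene).
Capture unevenness is emulated by a block of genes at 5× baseline against
30× elsewhere (Gaussian per-base noise, σ = 3); decoy variants
(synonymous, stop-gain, non-PASS, sub-threshold depth) exercise every
filter. All randomness derives from one seed, sectioned into per-artifact
streams so regeneration is stable, and a ground-truth manifest (planted
counts, callable bases, expected TMB/Ti-Tv, per-variant truth table) is
written alongside.

What the generator does *not* emulate: read-level errors, alignment
artifacts, splice structure (toy CDS are intronless), realistic mutational
signatures, HLA diversity, or a real proteome's repeat structure. A green
test therefore establishes the *engine's arithmetic and contracts* — not
calling accuracy on real data, and not the biological validity of any
specific candidate.

## Numerical and degenerate-input choices

* VCF positions, protein and CDS coordinates are 1-based; BED is 0-based
  half-open and converted on read.
* Multi-allelic VCF records are split per ALT; VAF = ALT allelic depth /
  total allelic depth of the tumor sample; records with unparseable
  depth/VAF are dropped and counted in a warning rather than aborting the
  sample.
* Sparse depth tracks: absent positions are depth 0 everywhere.
* Empty CDS, zero callable territory, zero background depth, and
  zero-size RNA libraries are hard errors (they signal unusable inputs,
  not edge cases to smooth over).
* The stub predictor's ranks are exact in double arithmetic (polynomial
  rolling hash mod 10^6+3) and platform-independent.
* Binding predictions imported for the same (peptide, allele) pair with
  conflicting values are a hard error; exact duplicates collapse.

## Known limitations

Candidate lists are predictions: no proteasomal processing, TAP
transport, or T-cell recognition modeling; class II is out of scope.
Clonality is raw VAF, not a deconvolved cancer-cell fraction. The
self-similarity veto is exact-match only — near-self peptides pass it.
The fusion expression gate uses FFPM, whose comparability across
libraries is weaker than TPM. And the composite score's scale is a
package convention; cross-study comparisons should use ranks, not raw
scores.
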