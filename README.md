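# neoforge

Neoepitope discovery and prioritization for structurally complex ("cold")
tumors, from filtered somatic variants and expressed gene fusions.

Complex-karyotype sarcomas and similar malignancies carry few SNVs but
profound structural instability, so aggregate biomarkers such as raw tumor
mutational burden (TMB) understate their immunogenic potential — especially
in legacy exome data with uneven capture. `neoforge` implements the
analysis layer that turns already-called inputs (somatic VCF + effect
annotation, Arriba-style fusion tables, per-base coverage tracks,
transcript TPMs, class I HLA types) into:

* a ranked, component-scored list of candidate MHC class I neoepitopes
  (8–11-mers from missense SNVs, in-frame and frameshift indels, and
  junction-spanning fusion peptides);
* callable-territory-normalized TMB, Ti/Tv and breadth-of-coverage
  summaries;
* a DNA–RNA concordance report separating functional amplifications from
  capture artifacts and purely transcriptional elevation.

Upstream read processing (alignment, variant calling, VEP annotation,
fusion calling, HLA typing, the NetMHCpan neural network itself) is out of
scope; predictions are consumed through an import adapter, with a
deterministic stub predictor for fully offline testing.

## The score

Each candidate peptide–allele pair receives a bounded composite priority:

    priority = 100 · L(r) · tanh(E/s) · VAF · F

* `L(r) = 1 / (1 + exp(5·(r − 2)))` — logistic down-weighting of the
  NetMHCpan `%Rank` `r`, inflecting at 2% (strong binders < 0.5%, weak
  0.5–2%; above 2% the weight collapses rather than hard-excluding);
* `tanh(E/s)` — expression support (gene TPM, scale 10; fusion FFPM,
  scale 2), with a separate hard gate at TPM ≥ 1 (FFPM ≥ 1 for fusions);
* `VAF` — clonality weight (fusions are treated as clonal, VAF = 1);
* `F = 1 − 0.5·L(r_wt)` — foreignness: a strongly binding wild-type
  counterpart at most halves priority; the agretopicity index
  `r_wt / r_mut` is reported alongside. Frameshift, indel and junction
  peptides have no counterpart and are fully foreign.

Peptides occurring verbatim anywhere in the reference proteome are vetoed
to priority 0. TMB counts PASS, depth ≥ 10× nonsynonymous mutations
(missense, stop-gain, frameshift, in-frame indel) per megabase of CDS that
itself reaches ≥ 10× depth; stop-gains count for TMB but are excluded from
the epitope path.

## Worked example

Everything below runs offline on the seeded synthetic cohort (3 samples,
20 toy genes; see the methods vignette for what it does and does not
emulate):

```r
library(neoforge)
cohort <- simulate_cohort(toy_cohort_spec(seed = 7), "toy")
out <- run_pipeline(cohort$manifest_path, neo_config(), "toy_out")

out$tmb$S1
#> <neo_tmb> 14 nonsynonymous / 0.009761 Mb callable = 1434.279 mut/Mb; Ti/Tv 0.625

head(out$candidates[, .(sample, source_type, gene_label, peptide,
                        hla_allele, rank_percent, priority_score)], 3)
#>    sample source_type gene_label     peptide  hla_allele rank_percent priority_score
#> 1:     S1  frameshift        G05 RRSCSPPLRFP HLA-B*07:02   0.01481475       67.88923
#> 2:     S1  frameshift        G05 CSPPLRFPTPE HLA-B*07:02   0.18580316       67.88474
#> 3:     S1  frameshift        G05    RSCSPPLR HLA-A*02:01   0.32870559       67.87661

out$concordance[label != "unremarkable",
                .(sample, gene, tumor_ratio, normal_ratio, tpm, label)]
#>    sample   gene tumor_ratio normal_ratio    tpm                    label
#> 1:     S3    G17   6.5413798    0.7812371 410.00 concordant_amplification
#> 2:     S3    G18   5.4487216    7.7922010   6.98         capture_artifact
#> 3:     S3    G19   0.5484493    0.7701997 200.00     transcriptional_only
```

The TMB line reads: 14 PASS nonsynonymous mutations over 9,761 callable
coding bases. (The toy genome is ~12 kb, hence the inflated mut/Mb scale —
the arithmetic, not the magnitude, is the point.) The top candidates are
frameshift-derived peptides: fully foreign, well expressed, strong
predicted binders under the stub predictor. The concordance report
recovers the three planted events in sample S3: a true amplification
(depth ×12 with commensurate expression), a capture spike shared with the
matched normal (artifact), and an expression-only gene.

A subcommand CLI wraps the same stages
(`simulate`, `run`, `tmb`, `peptides`, `fusions`, `bind`, `concordance`):

```sh
Rscript inst/cli/neoforge.R simulate --out toy --seed 7
Rscript inst/cli/neoforge.R run --manifest toy/manifest.json --out toy_out
```

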