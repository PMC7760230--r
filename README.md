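# dspforge

Analysis workflow for **digital spatial profiling (DSP) protein counts**:
antibody-barcode counts collected per region of interest (ROI) from tissue
compartments — tumour, tumour microenvironment (TME) and normal adjacent
tissue (NAT). It is written for analysts who receive an ROI × probe count
matrix (targets, isotype-IgG background controls, and housekeeper probes)
plus ROI metadata, and need a reproducible path from raw counts to
compartment biology and survival associations.

## What it computes

For counts $y_{rp}$ (ROI $r$, probe $p$) with IgG-control set $G$ and
housekeepers $H$:

* **QC / probe filtering.** Per-ROI background
  $b_r = \mathrm{mean}_{g \in G}\, y_{rg}$; signal-to-noise
  $s_{rp} = y_{rp} / b_r$; a target is *robust* when
  $\mathrm{median}_r\, s_{rp} \ge 1$ (mean summary and other thresholds
  configurable). Low-median ROIs are flagged, never silently dropped.
* **Normalizer assessment.** Pairwise Pearson correlations among candidate
  factors (GAPDH, Histone H3, S6, Histone H3/S6 mean, IgG mean, ROI area,
  nuclei count); the recommended factor is the housekeeper-derived one
  with the best worst-case correlation to the non-biological references.
* **Normalization.** Housekeeper scaling
  $\tilde y_{rp} = y_{rp}\, \bar f / f_r$ with
  $f_r = \mathrm{mean}(y_{r,\mathrm{H3}}, y_{r,\mathrm{S6}})$ and $\bar f$
  the grand geometric mean (count scale preserved); or global scaling by
  TMM (doubly trimmed, precision-weighted mean of M-values) or RLE
  (median ratio to per-probe geometric means), factors normalized to
  multiply to 1.
* **Differential expression.** Paired t-tests between matched patient
  compartments and Mann-Whitney tests between unmatched groups, on log2
  normalized values, with Benjamini-Hochberg adjustment within each
  comparison; per-compartment probe-probe correlation matrices.
* **Clustering.** Per-probe z-scores, Ward.D2 linkage, k-means classes
  (default k = 3).
* **Survival screening.** Unadjusted univariate Cox proportional hazards
  (Efron ties) of per-patient mean log2 expression against overall
  survival, per compartment, ranked by hazard ratio.
* **Simulation.** A negative-binomial generator with per-ROI log-normal
  size factors, patient-level biological heterogeneity, compartment
  effects, NAT signal depression and linked survival — with a ground-truth
  ledger, so every stage above is testable against known answers.

## Worked example

Simulate the default 96-ROI cohort (45 tumour / 32 TME / 19 NAT from 64
patients, 18 tumour-TME pairs) with a known TME enrichment of CD3, CD4 and
CD68 and a protective survival effect on CD3, then run the full pipeline:

```r
library(dspforge)

design <- simulation_design(
  effect_table = data.frame(probe_id = c("CD3", "CD4", "CD68"),
                            compartment = "TME", log2fc = c(2, 1.5, 1)),
  survival_betas = c(CD3 = log(0.5)),
  seed = 2)
res <- run_pipeline(list(simulate = design))
#> [input] 0.03s 96 ROIs x 58 probes
#> [qc] 0.03s 36 robust targets, 0 ROIs flagged
#> [normalize] 0.04s method=hk_mean recommended=hk_mean
#> [de] 0.15s 4 comparisons
#> [cluster] 0.16s k=3
#> [survival] 1.27s 2 compartments screened
```

The normalizer assessment recommends the Histone H3/S6 mean — its
correlations with the non-biological references are strong
(IgG mean 0.91, area 0.73, nuclei 0.70) — and 36 of 52 targets pass the
IgG signal-to-noise filter. The paired TME vs tumour comparison recovers
the three planted enrichments at the top, with effects (mean paired log2
difference) close to the generating values 2 / 1.5 / 1, and nothing else
below the 0.05 FDR line:

```r
de <- res$de$TME_vs_Tumour_paired
head(de[order(de$p_adj), c("probe_id", "n", "effect", "statistic", "p_adj")], 5)
#>    probe_id  n effect statistic    p_adj
#> 6       CD3 18 2.0201     32.10 4.25e-15
#> 7       CD4 18 1.5472     25.93 7.43e-14
#> 1      CD68 18 0.9823     19.00 8.29e-12
#> 20    CD127 18 0.1105      1.80 6.50e-01
#> 25   CD45RO 18 0.0868      1.85 6.50e-01
```

The tumour-compartment Cox screen ranks probes by hazard ratio; the
planted protective marker sits near the top with its generating hazard
ratio (0.5) inside the confidence interval — at 45 patients a univariate
screen is noisy, which is exactly what the simulation makes visible:

```r
head(res$cox$Tumour[, c("probe_id", "n", "n_events", "hr",
                        "ci_low", "ci_high", "p")], 3)
#>   probe_id  n n_events    hr ci_low ci_high       p
#> 4    CD11c 45       38 0.366  0.159   0.846 0.01863
#> 6      CD3 45       38 0.426  0.227   0.799 0.00785
#> 1     CD68 45       38 0.493  0.263   0.923 0.02701
```

Setting `out_dir` in the config writes every stage artifact
(`snr_table.tsv`, `normalized.tsv`, `de_*.tsv`, `clusters.tsv`,
`cox_*.tsv`, ...) plus a `manifest.json` recording parameters, seeds and
warnings. The same pipeline runs from the shell:

```sh
exec/dspforge run --config run.yaml --out results/
exec/dspforge simulate --config sim.yaml --out sim_data/
```

See `vignettes/dsp-protein-workflow.Rmd` for the models, parameter
meanings and design choices.

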