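# tadfusion

Differential contact-enrichment analysis of TAD boundary deletions in
capture Hi-C data, plus allele-specific expression scoring for hybrid
crosses.

## The problem

Deleting a TAD boundary can fuse two neighbouring chromatin domains and
redirect enhancers to the wrong gene. Capture Hi-C shows this as a gain of
contacts across the former boundary — but a deletion also shortens genomic
distances, and contact frequency decays steeply with distance, so the
wild-type and mutant maps are never directly comparable. `tadfusion` is for
genomicists who have binned wild-type and deletion-mutant contact maps of a
locus and want a calibrated, per-position score of where the mutant's
folding actually changed, beyond what the distance change alone predicts.

## The method

From the wild-type map `V` (VC_SQRT-normalized) the package builds the
**distance-only null** `V*`: estimate the locus's distance-decay profile
`P(s)` (mean contact at bin separation `s`), lift `V` onto the deleted
genome under a *balanced* model that rescales every pair moved from
separation `s` to `s'` by `P(s')/P(s)`, then lift back to reference
coordinates under a coordinate-only *easy* model. `V*` is the mutant map
expected if the deletion acted purely through genomic distance.

Departures from the null are scored per bin `k`:

    D(k, f) = mean{ log(V_ij / V*_ij) : i in [k-f, k), j in (k, k+f],
                    V_ij > 0, V*_ij > 0 }

followed by a Z-score transform of `D` across positions. A fused boundary
appears as a positive Z peak; contiguous bins with `|Z|` above a threshold
are merged into BED calls. Subtraction maps (depth-matched, optionally
coarsened, signed differences) visualize the same changes. For hybrid-cross
RNA-seq, per-SNP allele ratios `(mus + 1)/(cast + 1)` are aggregated per
gene and compared between genotypes with a two-tailed Mann–Whitney U test
(exact for small samples without ties).

A synthetic generator simulates the whole study design — a 455-bin, 5-kb,
three-TAD capture locus with Poisson counting noise, a boundary deletion
with or without insulation loss, and hybrid SNP coverage tables — so every
claim above is tested end to end.

## Worked example

Simulate a boundary-fusing 30-kb deletion, score it, and test allelic
imbalance:

```r
library(tadfusion)

model <- kit_locus_model(depth = 5e6)           # 3 TADs, 455 x 5 kb bins
del   <- deletion_spec("chrS", 1430000, 1460000, "Kit_d30k")
sim   <- simulate_deletion_experiment(
           experiment_spec(model, del, fused = TRUE, seed = 7))

wt    <- vc_sqrt_normalize(sim$wt)
mut   <- vc_sqrt_normalize(sim$mutant_in_ref)
vstar <- simulate_wt_under_deletion(wt, del)    # distance-only null
track <- d_score(mut, vstar, f = 20)
summary(track, z_threshold = 2)
#> D(k,f) track, f = 20 bins (100 kb window each side)
#> scale factors: observed 0.9917, liftovered 1.008
#> 1 insulation-change call(s) at |Z| >= 2
#>   chrom   start     end   peak_z sign n_bins
#> 1  chrS 1390000 1500000 5.257022 gain     22
```

One gain call, peak Z = 5.26, spanning the deleted boundary (bin 290, at
1,445,000 bp): the mutant gained cross-boundary contacts far beyond the
distance-only expectation. With `fused = FALSE` (insulation retained) the
same pipeline returns no call — the statistic is calibrated, not merely
sensitive.

```r
tab <- rbind(
  simulate_snp_counts("Kdr", 21, 100, 0.99,  seed = 7, genotype = "Wt"),
  simulate_snp_counts("Kdr", 21, 100, 49.71, seed = 8, genotype = "Kit_d30k"))
compare_alleles(snp_coverage_table(as.data.frame(tab)[, 1:5]), "Kdr")
#> <allelic_result> Kdr: Wt 1.014 +/- 0.157 (n=21) vs Kit_d30k 42.633 +/- 22.259 (n=21)
#>   Mann-Whitney U = 0, two-tailed p = 2.454e-08 (normal-tie-corrected)
allele_fraction(42.633)   # 0.977 -> ~98% of transcripts from the musculus allele
```

A command-line wrapper covering the same stages (`simulate`, `normalize`,
`expected`, `liftover`, `simulate-null`, `subtract`, `dscore`, `allelic`)
is installed at `system.file("scripts", "tadfusion.R", package =
"tadfusion")`; every output is accompanied by a manifest recording
parameters, package version and input checksums.

See `vignettes/tad-boundary-deletion-analysis.Rmd` for the model's
assumptions, parameter choices and limitations.

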