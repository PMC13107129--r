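# repscan

Structure-based delineation of rolling-circle replication (RCR)
initiator families and detection of the bipartite origins they act on.

Plasmids and small viral genomes — including archaeal pleolipoviruses —
often replicate by a rolling-circle mechanism: an initiator endonuclease
binds a double-stranded inverted repeat (the *bind* site), nicks a nearby
hairpin (the *nick* site), and the freed 3'-OH primes synthesis. The
initiators themselves can be so sequence-divergent that their family
membership is only visible at the structure level. `repscan` provides
the computational toolkit for both sides of that analysis:

* **Protein side** — alignment-based sequence identity and greedy
  redundancy clustering (CD-HIT-style thresholds), a mean-pLDDT
  model-confidence gate, Kabsch superposition, TM-score structural
  alignment (from scratch, in compiled code), all-vs-all similarity
  matrices, silhouette-cut "similarity block" delineation with adjusted
  Rand index and purity, nearest-family ranking, a deterministic
  geometric structural alphabet with progressive alignment, and UPGMA
  dendrograms with column-bootstrap supports.
* **DNA side** — inverted-repeat detection, maximum-weight hairpin
  folding (nested-pairing dynamic program, weights GC=3 / AU=2 / GU=1,
  minimum loop 3), a scanner for the (IR, hairpin) origin architecture
  downstream of a rep ORF, and classification of substitution series as
  structure-preserving / loop / stem-disrupting / symmetry effects.
* **Synthetic data** — generators for protein families (rigid scaffolds
  plus noise and sequence divergence, with known ground truth) and
  replicons with planted origins, so the entire pipeline runs and is
  tested at desk scale.

The TM-score of an aligned pair set with distances `d_i` is
`TM = (1/L_norm) * sum_i 1/(1 + (d_i/d0)^2)` with
`d0 = 1.24 (L_norm - 15)^(1/3) - 1.8` Å (floored at 0.5 Å), maximized
over superpositions; sequence-logo columns use
`IC = log2(20) - H - 19/(2 n ln 2)` bits. The methods vignette
(`vignettes/repscan-methods.Rmd`) documents every model, parameter and
design choice.

## Worked example

Five synthetic families, four members each (the default generator), the
full family pipeline with 200 bootstrap replicates:

```r
library(repscan)
cfg <- pipeline_config(list(tree = list(n_bootstrap = 200L)), seed = 11)
res <- run_family_pipeline(cfg, out_dir = "results/family")
```

```
blocks: 5; adjusted Rand index: 1; purity: 1
mean TM within families:  0.832
mean TM between families: 0.193
```

The similarity matrix recovers the five families as five blocks with
perfect label agreement (ARI 1): within-family TM-scores sit in the
same-fold regime (> 0.8) while between-family scores stay at the
unrelated-fold level (~0.2). The origin side:

```r
cfg <- pipeline_config(list(
  simulate = list(n_replicons = 50L),
  ori = list(mutations = c("G188CC195G", "A191TA192T",
                           "T186GG187T", "C195AC196A"))), seed = 11)
ori <- run_ori_pipeline(cfg, out_dir = "results/ori")
```

```
planted-origin recovery: 50/50
                 spec                class
G188CC195G G188CC195G structure_preserving
A191TA192T A191TA192T        loop_mutation
T186GG187T T186GG187T         stem_disrupt
C195AC196A C195AC196A         stem_disrupt
```

All 50 planted origins are detected, and the four stem/loop substitution
series are classified exactly as their compensatory design predicts: the
G188C+C195G double swap keeps the stem paired (replication-compatible),
the loop and uncompensated stem changes disrupt the element.

The numbered scripts under `analysis/` run these analyses end to end
(`01_simulate_data.R`, `02_family_delineation.R`,
`03_motif_conservation.R`, `04_ori_scan.R`) and write their tables under
`results/`. The motif driver profiles a synthetic initiator alignment:
the catalytic-motif search reports `KHYYM` at position 281 and the
catalytic tyrosine column (283) at conservation 1.0.

## Layout

```
R/                  package code (one file per analysis stage)
src/                compiled kernels (Kabsch, TM-score, alignment search)
analysis/           numbered end-to-end drivers
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests (with oracles)
vignettes/          methods vignette
```
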