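# glocerna

Identification of functional lncRNA-mediated competing endogenous RNA
(ceRNA) pairs from normal/tumor (N/T) matched expression cohorts, for
transcriptomics researchers studying miRNA-sponge regulation in cancer.

A lncRNA acting as a ceRNA sponges miRNAs shared with a protein-coding
gene (PCG), so the two transcripts are expected to be positively coupled.
`glocerna` scores every candidate lncRNA-PCG pair (pairs sharing at least
one miRNA in a CLIP-seq-supported interaction table) with a two-stage
rule on the per-patient relative expression
*e<sub>g</sub><sup>i</sup> = log₂ y<sub>g</sub><sup>i</sup> − log₂ x<sub>g</sub><sup>i</sup>*
(tumor minus normal, per matched sample *i*):

* **Local criterion — DEC score.** Per sample,
  dec<sub>i</sub>(l, g) = +1 if both log₂FC > 1, −1 if both < −1, else 0;
  the DEC score is Σᵢ |dec<sub>i</sub>(l, g)|, the number of
  direction-consistent samples. It captures ceRNA signals present in only
  a subset of a heterogeneous cohort.
* **Global criterion.** Pearson correlation cor(l, g) of
  (e<sub>l</sub>, e<sub>g</sub>) across patients with its *t*-test
  p-value.

A pair is a **functional ceRNA** iff DEC score > 5, cor(l, g) > 0 and
*P* < 0.05 (all strict); its lncRNA is a functional ce-lncRNA. Around the
scorer, the package provides the traditional three-criterion baseline,
bipartite network topology (degree, betweenness, lncRNA similarity,
cross-cohort overlap), hypergeometric cancer-hallmark enrichment,
Kaplan-Meier/log-rank survival screening with mean-expression
dichotomization, super-enhancer/typical-enhancer (SE/TE) gene assignment,
THZ1-sensitivity classification, and a fully deterministic synthetic-data
generator with planted ground truth.

## Worked example

Simulate a 20-patient matched cohort with 100 planted ceRNA pairs among
900 miRNA-sharing decoys, then run the scorer:

```r
library(glocerna)

cfg    <- synthetic_config(seed = 1)
cohort <- generate_cohort(cfg)
pairs  <- build_candidate_pairs(cohort$interactions)
res    <- run_glocerna(cohort$matrix, pairs)
print(res, n = 3)
#> GloceRNA results: 1000 pairs scored over 20 patients; 100 functional; 0 skipped; 0 excluded (zero variance)
#>   lncrna_id  pcg_id shared_mirna_count dec_score        cor      p_value
#> 1   LNC0001 PCG0225                  1        19 0.96652118 4.443903e-12
#> 2   LNC0002 PCG0273                  1        16 0.93951796 8.249120e-10
#> 3   LNC0003 PCG0005                  1         0 0.05124808 8.301015e-01
#>   functional
#> 1       TRUE
#> 2       TRUE
#> 3      FALSE
#> ... and 997 more rows

build_network(res)
#> ceRNA network: 100 lncRNAs, 100 PCGs, 100 edges
```

The planted pair LNC0001-PCG0225 is direction-consistent in 19 of 20
matched samples (DEC = 19) with strongly positive correlation of relative
expression, so it passes all three criteria; the null pair LNC0003-PCG0005
fails both. Against the generator's truth this run recovers every planted
pair with no false positives:

```r
truth_key <- paste(cohort$truth$true_pairs$lncrna_id,
                   cohort$truth$true_pairs$pcg_id)
found_key <- paste(res$lncrna_id, res$pcg_id)[res$functional]
mean(truth_key %in% found_key)   # sensitivity
#> [1] 1
mean(!found_key %in% truth_key)  # false-discovery proportion
#> [1] 0
```

`run_pipeline(pipeline_config(outdir, seed))` chains every stage
(simulate → pairs → scoring → network → enrichment → survival →
enhancers → THZ1) and writes per-stage TSVs plus a manifest; a thin
command-line front end lives at `inst/cli/glocerna.R`
(`simulate`, `run`, `pipeline` subcommands).

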