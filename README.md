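# conformerCCS

Peptide ions can adopt more than one stable conformation in the gas phase.
In trapped ion mobility spectrometry (TIMS) data this shows up as a single
peptidoform–charge pair producing two or more distinct collisional cross
section (CCS, Å²) features. Models that predict one CCS per peptide are
systematically wrong for these ions — worse, naive dataset merging can
average two conformers into a value matching neither.

`conformerCCS` is an R package for people building CCS predictors or
rescoring pipelines from MaxQuant-evidence-style identification tables. It
provides the full workflow:

1. **Evidence I/O** — read multi-run evidence TSVs (MaxQuant dialect or
   ProForma-like), keep MS/MS-identified features with distinct MS1
   features.
2. **Between-run alignment** — charge-specific additive offsets
   *y = x + b* estimated by the median of pairwise differences, greedy
   run accretion in descending identification order, a 100-pair overlap
   gate for unalignable runs.
3. **Conformer curation** — within-run splitting and cross-run matching of
   CCS values at a 2% relative tolerance, recurrence filtering (≥2 runs),
   charge ≤ 4, yielding disjoint multi- and uniconformer datasets.
4. **Two-output CCS prediction** — atomic-composition encoding, a shared
   dense encoder with two branch heads predicting a (small, large)
   conformer CCS pair, an assignment-aware MAE loss, 81/9/10 splits, early
   stopping, and transfer learning from a single-output model. The network
   (backprop + Adam) is implemented in base R, so there are no framework
   dependencies.
5. **XIM analysis** — extracted-ion-mobilogram peak picking, multimodal
   fractions under relative-intensity thresholds, replicate order-reversal
   rates, Mason–Schamp conversion between 1/K₀ and CCS, and
   nearest-prediction annotation of observed peaks.
6. **Synthetic data** — a fully seeded generator planting per-run offsets,
   conformer structure, noise, dropout and Gaussian-mixture mobilograms,
   so every stage is testable without external data.

The conformer definition throughout is the field's 2% rule: CCS values
*a*, *b* of one ion are distinct conformers iff |a − b| / min(a, b) >
0.02. The two-output model trains on curated records with the loss
L = (|p₁ − t₍₁₎| + |p₂ − t₍₂₎|)/2, where t₍₁₎ ≤ t₍₂₎ are the sorted
conformer targets (an assignment-minimum variant is available); baselines
with two outputs and one target use |p₁ − t| + |p₂ − t|.

## Worked example

```r
library(conformerCCS)

## simulate a small multi-run cohort with planted conformer structure
cfg <- generator_config(n_peptides = 1000, seed = 42)
sim <- generate_cohort(cfg)

## identification filter -> charge-specific alignment -> conformer curation
runs <- filter_identified(sim$runs)
aligned <- align_all(runs)
cur <- curate(aligned)
cat(sprintf("curated: %d multiconformer, %d uniconformer ions\n",
            nrow(cur$multi), nrow(cur$uni)))

## pretrain a single-output model, fine-tune the two-output model
single <- train_ccs_model(cur$uni, model_spec(n_outputs = 1),
                          train_config("single", seed = 7))
multi2 <- cur$multi[vapply(cur$multi$ccs_values, length, integer(1)) == 2L]
tuned <- fine_tune(single, multi2, model_spec(n_outputs = 2),
                   train_config("multiconf", seed = 7))

test_rec <- multi2[tuned$splits$test]
print(evaluate_predictions(predict(tuned, test_rec), test_rec, "paired"))

## XIM stage: peak statistics on simulated replicate mobilograms
xim <- generate_mobilograms(mobilogram_config(n_ions = 100, seed = 9))
cat(sprintf("multimodal fraction at 10%% threshold: %.2f\n",
            multimodal_fraction(xim$rep_a, 0.10)))
rv <- order_reversal_rate(xim$rep_a, xim$rep_b, rel_threshold = 0.25)
cat(sprintf("order reversal: %d of %d bimodal ions (%.2f)\n",
            rv$n_reversed, rv$n_bimodal, rv$rate))
```

This prints (exact output of the code above):

```
curated: 61 multiconformer, 939 uniconformer ions
   output      mae median_rel_err pearson_r frac_below_median_gap
   <char>    <num>          <num>     <num>                 <num>
1:  small 13.32261     0.01130835 0.9938446                     1
2:  large 24.85592     0.02398664 0.9922629                     1
multimodal fraction at 10% threshold: 0.29
order reversal: 10 of 29 bimodal ions (0.34)
```

Reading it: the generator planted ~6% multiconformer ions and the curation
recovered 61 of them (the rest are uniconformer); the fine-tuned two-output
model, trained on only 55 multiconformer records at this toy scale,
predicts the small conformer with 1.1% and the large with 2.4% median
relative error on held-out ions, and every prediction errs by less than
the median gap between the two observed conformers; the mobilogram
generator planted 30% bimodal ions with a 35% intensity-swap rate, and the
peak picker measures 0.29 and 0.34. At the default scale
(`n_peptides = 5000`) both model medians drop well under 2% — run
`scripts/acceptance.R` for that number.

There is also a command-line entry point wiring the stages
(`simulate`, `curate`, `train`, `finetune`, `predict`, `evaluate`, `xim`),
each writing a JSON manifest beside its output:

```sh
Rscript -e 'conformerCCS::run_cli()' --help
Rscript -e 'conformerCCS::run_cli()' curate --evidence evidence.tsv \
    --out-multi multi.tsv --out-uni uni.tsv --report stats.json
```

## Documentation

`vignettes/methods.Rmd` describes the models, tunable parameters, the
synthetic world and its limits, numerical choices, and known limitations.
All exported functions carry roxygen documentation.
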