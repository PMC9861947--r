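# mnasar

Substructural MNA descriptors and Bayesian structure–activity prediction
for cell-line cytotoxicity and mechanisms of action.

## What this is for

Screening campaigns describe a compound's effect on a tumor cell line or a
protein target qualitatively: *active* or *inactive*. `mnasar` is for
computational chemists and chemical biologists who want to train, validate
and apply qualitative structure–activity (SAR) models of that kind on their
own activity tables — predicting, for a new structure, a ranked list of
cell lines it is likely to be cytotoxic against, or targets it is likely to
modulate.

The pipeline has four stages, each available as an R function and a CLI
subcommand:

1. **Structures → descriptors.** Molecules (SMILES or MDL Molfile/SDF) are
   standardized — salts stripped to the largest covalent fragment, every
   implicit hydrogen materialized as an explicit atom — and converted to
   **Multilevel Neighborhoods of Atoms (MNA)** descriptors: canonical
   strings for atom-centered fragments, where level 0 is the atom label
   (element plus formal-charge sign) and level *k* wraps the sorted
   level-(*k*−1) labels of the atom's neighbors, e.g. `C(HHHH)` for the
   carbon of methane. Bond orders and stereochemistry are deliberately
   ignored.
2. **Activity tables → labeled sets.** Curation rules turn raw IC50 / GI50
   / Ki / Kact / %-inhibition measurements into binary labels: potency
   strictly below 10,000 nM or inhibition strictly above 50% is active;
   NCI60-style −log10 GI50 screens are labeled at the 1/10/100 nM cuts
   (≥ 9 / 8 / 7) after failure-reason rows are deleted and replicates
   collapsed to their median. Conflicts resolve active-wins.
3. **Training.** A regularized naive-Bayes scorer over descriptor
   presence/absence. With `N` compounds, `n_d` carrying descriptor `d`,
   and activity `a` having `n_a` actives of which `n_da` carry `d`:

       p_da = (n_da + c·p_a) / (n_d + c),   p_a = n_a / N
       s(x, a) = mean over d in D(x)∩V of  arcsin(2·p_da − 1)

   Each compound's analytic leave-one-out (LOO) score — its own counts
   subtracted — is stored as the model's calibration distribution.
4. **Prediction and validation.** A query's score is ranked within the
   calibration distributions to give **Pa** (probability "to be active")
   and **Pi** ("to be inactive"); results are listed by Pa − Pi
   descending. Accuracy per activity is **IAP** (invariant accuracy of
   prediction, numerically the ROC AUC) under analytic LOO and stratified
   k-fold cross-validation; activities with LOO IAP strictly above 0.8 are
   selected as reliable.

Because Pa is a rank within the LOO score distribution of the training
actives, it is calibrated by construction: filtering predictions at
Pa > 0.7 loses about 70% of true activities, at Pa > 0.5 about half —
the designed trade-off between confidence and recall.

## Worked example

```r
library(mnasar)
# descriptor-level synthetic set with a planted structure-activity signal
ds  <- make_descriptor_dataset(synth_config(n_active = 50, n_inactive = 200, seed = 7))
fit <- sar_train(ds$labeled, ds$features)
summary(fit)
#> sar_model: 250 training compounds, 500 descriptors, 1 activities
#>   regularization c = 1, MNA max level = 2
#> per-activity leave-one-out accuracy (IAP = ROC AUC):
#>  activity_id n_active n_inactive iap_loo
#>    synthetic       50        200  0.9956

tl <- training_loo(fit, "synthetic")
mean(tl$Pa[tl$label == "active"] <= 0.5)   # 0.5: half lost at Pa > 0.5
mean(tl$Pa[tl$label == "active"] <= 0.7)   # 0.7: 70% lost at Pa > 0.7

predict(fit, ds$enriched[1:5])   # a query carrying planted descriptors
#>   compound_id activity_id     score Pa Pi
#> 1       query   synthetic 0.3835373  1  0
```

The LOO IAP of 0.9956 says a random training active outscores a random
inactive 99.6% of the time under leave-one-out; the query built from the
planted (enrichment-carrying) descriptors outscores every calibration
compound, hence Pa = 1, Pi = 0.

The same flow from a shell, end to end on generated structures:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "mnasar", package = "mnasar"))')
Rscript $cli simulate  --dir demo --n-active 30 --n-inactive 60 --seed 1
Rscript $cli curate    --activities demo/activity.csv --labels-out demo/labels.tsv
Rscript $cli train     --structures demo/structures.smi --labels demo/labels.tsv --model-out demo/model.json
Rscript $cli validate  --structures demo/structures.smi --labels demo/labels.tsv --k 20 --seed 1
Rscript $cli predict   --model demo/model.json --structures demo/structures.smi --pa-cutoff 0.7
```

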