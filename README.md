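# lymphopatch

Patch-based deep-learning classification of nodal lymphoma on
histopathological images, with quality-controlled aggregation of patch
predictions to patient-level diagnoses.

The package is aimed at computational-pathology researchers who want the
*full protocol* of a patch-classification study as tested, reusable code:
annotation-polygon tiling, patient-level data splitting with leak
checking, training and selection of a compound-scaled convolutional
classifier, patch→case majority voting with two-level abstention,
balanced-accuracy evaluation, and SmoothGrad explanations. A synthetic
H&E-like lymph-node generator makes the whole pipeline runnable and
testable on one CPU in minutes, with no patient data and no GPU.

## The method

**Tiling.** Pathologist-drawn polygons on a scanned slide (known µm/px
scale) are tiled with non-overlapping 100 × 100 µm squares — 395 × 395 px
at the reference scale — kept only when fully inside the polygon and the
image. Patients with fewer than 10 tiles are flagged.

**Splitting.** Patients are split 60/20/20 into training / validation /
test (stratified by class); all tiles of a patient follow the patient,
and a checkpoint verifies that no patient leaks across subsets.

**Classifier.** A convolutional family indexed by φ with depth, width and
input resolution scaled jointly as α^φ, β^φ, γ^φ (defaults 1.2, 1.1,
1.15). Learning rates are screened for a fixed number of epochs from a
shared initialization; the best rate trains further with early stopping;
family members are compared on validation accuracy with a balanced-
accuracy tie-break.

**Quality-controlled evaluation.** Per-tile probabilities over the five
training classes (SLL/CLL, DLBCL, and tumor-free lymph nodes from lung,
colon, pancreas) are aggregated to three evaluation classes by summing
the tumor-free origins into one reference class. Then, for thresholds
*t*₁ (PQC) and *t*₂ (CQC):

- a tile is kept iff max*ₖ* *p(k)* ≥ *t*₁ (patch quality control);
- a case takes the modal argmax class of its surviving tiles, with vote
  fraction *f* = (modal count)/(surviving tiles), and abstains
  (UNCLASSIFIED) iff no tile survives or *f* < *t*₂ (case quality
  control);
- performance is the balanced accuracy over classified items,
  BACC = (1/K) Σₖ recallₖ, reported over the 5 × 5 grid
  *t*₁, *t*₂ ∈ {0.5, …, 0.9} together with the percentage of tiles
  failing PQC and of cases failing CQC.

**Explanations.** SmoothGrad: average input gradients of the class score
over 50 Gaussian perturbations (σ = 0.5% of the intensity range), take
absolute values, collapse channels by per-pixel maximum, normalize to
[0, 1).

## Worked example

The numbered scripts under `analysis/` run the study end to end with a
shared config (`analysis/pipeline.yaml`: 3 classes, 15 synthetic patients
per class, 12–24 tiles each, φ = 0):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_patches.R
Rscript analysis/03_split_cohort.R
Rscript analysis/04_train_classifier.R
Rscript analysis/05_qc_grid.R
Rscript analysis/06_saliency.R
```

A run prints, among other things:

```
Extracted 824 patches from 45 cases (per-case 12-24)
All cases meet the 10-patch minimum
[train seed=669737932] chosen learning rate: 0.01
Trained 16 epochs; best validation accuracy 98.1% at epoch 15 (overfit gap -0.3 pp)
Best cell: BACC 100.00% at PQC 50% / CQC 50% (0.0% of cases abstained)
```

meaning: 824 tiles were cut from the 45 annotated synthetic cases, the
learning-rate screen preferred 10⁻², the base family member reached 98.1%
validation tile accuracy, and after majority voting every one of the nine
held-out test patients was classified correctly, so the threshold grid is
flat at 100% balanced accuracy with no abstentions at this desk scale.
Outputs (tile index, cohort table, accuracy curves, per-tile probability
tables, the wide and long QC grids, confusion matrices, saliency
heatmaps/overlays) land under `results/run/<stage>/`, each stage with an
md5-digest entry in `results/run/manifest.json`.

The same machinery is available programmatically:

```r
library(lymphopatch)
cfg <- pipeline_config(workdir = "demo", seed = 1)
run_pipeline(cfg)
```

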