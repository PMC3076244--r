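# svmheatmap

Heat map molecule coloring for interpreting linear support vector machine
screening models in R.

Linear SVMs on sparse binary substructure fingerprints are strong
predictors on large screening collections, and — unlike kernelized models —
they are interpretable: the learned discriminant

```
f(x) = w·x + b,   x_j ∈ {0,1}
```

assigns each fingerprint feature `j` a weight `w_j`, in the spirit of a
Free–Wilson analysis. This package makes those weights visible on the
molecule itself. It provides:

* an **explicit-growth circular substructure fingerprint** (ECFP variant,
  default depth 4, 2²² hashed feature space) that records, per feature,
  exactly which atoms and bonds every occurrence covers — including the
  bonds to attachment points, and including all substructures that collide
  on one hashed id;
* a **liblinear-style linear SVM** (L2-regularized hinge loss, dual
  coordinate descent in C++) with a negative-class cost weight, plus
  repeated two-deep (nested) cross-validation with the standard grids
  (log₂C ∈ −5..8, log₂W₋₁ ∈ {−4,−2,0}) and a rare-feature filter
  (a feature must occur in ≥ 3 training molecules);
* **bond scores** `s_b = Σ_{f: b ∈ B(f)} w(f)`, full-set or
  single-molecule normalization to [0,1], and a red→orange→green
  two-part color gradient;
* **SVG depictions** with heat-colored bonds and CPK element-colored atom
  labels, single molecules or captioned grids;
* a **synthetic library generator** that plants activating/deactivating
  substructures with known bond indices, so the entire pipeline is
  verifiable against ground truth;
* a **CLI** (`inst/exec/svmheatmap`): `fingerprint | train | color |
  synth | render`.

Molecules are read from SMILES (organic subset + bracket atoms) or
SDF/MOL V2000; models persist as versioned JSON that refuses fingerprints
from a mismatched configuration. See the methods vignette
(`vignettes/heatmap-coloring.Rmd`) for the model, conventions and design
decisions.

## Worked example

Generate a labeled library with a planted activating fragment (in every
active) and a deactivating fragment (mostly in inactives), train, and
color:

```r
library(svmheatmap)

lib  <- generate_library(n_active = 50, n_inactive = 50, seed = 1)
fps  <- fingerprint_library(lib$mols)            # depth 4, 22-bit ids
data <- make_dataset(fps, lib$labels)

evaluate_cv(data, folds = 5, repeats = 2, seed = 1,
            C_grid = 2^(-2:4), W_grid = 1)
#> <cross-validation: 10 fold evaluations, mean AUC 1.000, mean ACC 1.000>

dtr   <- filter_rare_features(data, min_count = 3)
model <- train_linear_svm(dtr, C = 0.25, seed = 1)
#> <linear SVM: 268 weighted features, bias -0.2174, C 0.25, W-1 1>

cl <- color_molecule(model, fps[[1]], mode = "single_molecule")
#> <coloring of mol00001: 32 bonds, single_molecule normalization, f(x) = 1.188>
```

The clean planted library is linearly separable, so cross-validated AUC
and accuracy are 1.0. `f(x) = 1.188 > 0` classifies the compound active.
Per-bond output (bonds 24–31 are the planted activating fragment in this
molecule):

```r
data.frame(bond = seq_along(cl$raw), score = round(cl$raw, 3),
           nu = round(cl$nu, 3), color = cl$hex)[c(1:3, 24:27), ]
#>    bond  score    nu   color
#> 1     1  0.101 0.190 #FF3F00
#> 2     2  0.045 0.155 #FF3300
#> 3     3 -0.078 0.077 #FF1900
#> 24   24  1.214 0.895 #35C100
#> 25   25  1.230 0.906 #30C100
#> 26   26  1.379 1.000 #00C800
#> 27   27  1.096 0.821 #5BBB00
```

The planted bonds carry the molecule's highest scores and come out green;
the scaffold bonds sit near the red end. Across all 50 actives:

```r
cols <- lapply(fps[lib$true_labels == 1], function(f) color_molecule(model, f))
recovery_score(lib, cols, "activating")
#> [1] 1
```

Render to SVG:

```r
render_svg(cl, depiction_style(legend = TRUE), "mol00001.svg")
```

## Reproducing published-scale benchmarks (optional tutorial)

The package ships no external data. To reproduce typical literature-scale
results (e.g. AUC ≈ 0.91 on the Kazius Ames mutagenicity set, ≈ 0.90 on
MUV 548, ≈ 0.96 on MUV 846), obtain those datasets yourself, standardize
the structures (neutralize, canonical tautomers — the package does not do
this), convert to SDF with a `name,label` CSV, then:

```sh
inst/exec/svmheatmap fingerprint --in kazius.sdf --out fp.txt --labels labels.csv
inst/exec/svmheatmap train --fp fp.txt --model model.json --report cv.csv
inst/exec/svmheatmap color --model model.json --in compounds_of_interest.sdf \
    --csv colors.csv --outdir svg/
```

`cv.csv` holds per-fold AUC/ACC from the repeated two-deep
cross-validation. Runtimes are minutes for thousands of compounds; the MUV
sets (30 actives / 15 000 decoys each) are the heaviest. Note the SMILES/
SDF reader supports the organic subset plus common bracket atoms — exotic
organometallics in raw vendor files must be filtered or will be skipped
with warnings.
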