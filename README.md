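# hemepocket

Structure–function analysis of heme-binding pockets in R.

Heme proteins share one cofactor — the Fe–porphyrin complex — yet work
as oxygen carriers (OB), oxidoreductases (OR), electron-transport
proteins (ET), or engineered dual-function proteins (OB–OR).  If the
cofactor is the same, the function must be written in the protein
environment around it.  `hemepocket` turns that hypothesis into a
tested pipeline for structural bioinformaticians:

* **Site extraction** from PDBx/mmCIF `atom_site` records: altloc
  resolution by largest occupancy (altloc A at 0.5/0.5 ties), the
  25-heavy-atom Fe–porphyrin completeness check, axial-ligand detection
  (≤ 3.1 Å to the iron, waters allowed), a heme-coverage filter, and a
  greedy sequence-redundancy filter at a configurable identity
  threshold (99.99 / 80 / 60 / 25 %).
* **Function labels** from offline annotation tables via a fixed
  cascade — EC first digit, then GO, then keywords, then description —
  plus the dehaloperoxidase/myoglobin dual-function overrides, encoded
  as multi-label 0/1 vectors: OB = (0,1), OR = (1,0), OB–OR = (1,1),
  and ET = (0,0,1) in the three-label scheme.
* **Voxelization** of the host protein into binary 4-channel (C, N, O,
  S) occupancy grids in a heme-centric frame built from the four
  methine carbons (least-squares plane, x along CHA→CHC, 24 Å cube,
  1 Å voxels).
* **A 3D CNN classifier** (three 2×2×2 convolutions 64/128/128,
  batch norm, max pool, dense 128 → 64 → K, sigmoids; BCE loss, SGD
  lr 0.01, batch 32) with stratified five-fold cross-validation.  The
  dataset score is the exact-label-match accuracy
  `Sacc = Σ_c N_c^TP / Σ_c N_c`, reported with per-fold confusion
  matrices and per-class accuracy/recall/precision/specificity.
* **Occlusion analysis**: re-scoring trained fold models on grids with
  the outside (or inside) of the cube progressively zeroed, reported
  against the discarding depth r and the retained volume ((24−2r)³ /
  24³−(2r)³).
* **Cavity dispersion**: binary cavity vectors on a fixed 1 Å lattice
  within 8.5 Å of the iron, and the group statistic
  `d̄_I = (1/N_I) Σ_i ‖v_i − μ_I‖` measuring pocket-shape variability
  within a protein group.
* **A synthetic-site generator** — idealized porphyrin plus
  class-distinctive protein-like atom clouds with matching mmCIF and
  annotation files — so the whole pipeline runs and is tested with no
  database access.

The methods vignette (`vignettes/heme-pocket-analysis.Rmd`) documents
the model, the conventions and every numerical choice.

## Worked example

Generate a labelled synthetic dataset, run it through extraction and
labeling, cross-validate the classifier, and probe it by occlusion:

```r
library(hemepocket)

ds <- generate_dataset(classes = c("OB", "OR", "ET"),
                       n_per_class = 10, seed = 42, n_atoms = 200)
grids <- lapply(ds$sites, voxelize_site, edge = 24, voxel = 3)

cv <- cv_heme_cnn(grids, ds$classes, scheme = "three-label",
                  k = 5, epochs = 30, batch_size = 8, seed = 42)
print(cv)
#> 5-fold cross-validation (three-label), 30 samples
#>   Sacc = 1.000 +/- 0.000
print(cv$combined)
#>    OB OR ET Others
#> OB 10  0  0      0
#> OR  0 10  0      0
#> ET  0  0 10      0
```

`Sacc` is the fraction of samples whose full predicted label vector
matches the observed one; the combined matrix pools the five test
folds (rows = observed class, columns = predicted outcome, `Others` =
a bit pattern matching no class).  The small batch size suits the tiny
example — with 24 training samples per fold the default batch of 32
would make only one gradient step per epoch.

```r
occ <- occlusion_sweep(cv, grids, mode = "outside", r_values = c(0, 3, 6, 9))
print(occ[, c("r", "retained_volume", "sacc_mean")])
#>   r retained_volume sacc_mean
#> 1 0           13824 1.0000000
#> 2 3            5832 1.0000000
#> 3 6            1728 1.0000000
#> 4 9             216 0.2666667
```

At r = 0 the sweep reproduces the unoccluded score exactly; once the
mask eats into the region holding the class motifs the score collapses
to chance, localizing the information the network used.

Cavity-shape dispersion of the same sites:

```r
cav <- lapply(ds$sites, cavity_vector)
cavity_group_table(cav, ds$classes)
#>      group  n    d_bar        sd
#> 1       OB 10 20.59580 0.4161997
#> 2       OR 10 20.85067 0.3308005
#> 3       ET 10 19.33040 0.3400662
#> 4 Combined 30 23.35684 1.1067088
```

The combined group disperses more than any single class — pocket
shapes are more alike within a function class than across classes —
while a singleton group has `d_bar = 0` by construction.

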