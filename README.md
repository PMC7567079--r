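# retvasc

Quantification of retinal vascular architecture from fundus photographs.

Early diabetic retinopathy reorganizes the retinal vasculature — closed
capillary loops are lost, free-ending branches and disconnected
fragments accumulate — before any overt lesion is visible. `retvasc`
turns a fundus photograph into 20 interpretable architecture metrics and
compares groups of images statistically, so that these changes can be
tracked noninvasively over time.

## What it computes

The pipeline is: Canny edge detection → morphological cleanup (the
closing step fuses the double contour the detector draws along each
vessel into a solid band) → topology-preserving skeletonization →
skeleton graph. Skeleton pixels are classified by their 8-neighbourhood
(extremity ≤ 1 neighbour, slab = 2, node ≥ 3); node clusters are
junctions; traced paths become **branches** (extremity–junction),
**segments** (junction–junction) or **isolated elements** (no junction
in the component). Iterative pruning of dangling segments leaves the
loop-bearing **master** core, whose bounded faces are **meshes**
(enclosed areas, in px²). Per image the package reports:

| group | metrics |
|---|---|
| pixels | extremities, nodes |
| graph | junctions, branches (+ length), segments (+ length), isolated elements (+ length) |
| master core | master segments (+ length), master junctions |
| meshes | count, total area, mean mesh size, mesh index (= master length / master segments) |
| composites | branching interval (= segment length / branches), pieces, total length, branching length |

Group comparison uses unpaired two-tailed Student's t-tests (pooled
variance) per feature, and the design calculator uses exact
noncentral-*t* power: at Cohen's d = 1.5, α = 0.05, power 0.8,
allocation 1:1 it returns n = 9 per group with achieved power 0.8476.

A built-in synthetic fundus generator grows vascular trees on the pixel
lattice with exact, construction-time ground truth (junctions,
endpoints, loops, isolated elements, total length), renders them with
realistic width, background and noise, and is the basis of the
validation suite.

## Worked example

```r
library(retvasc)

# a synthetic fundus image with known ground truth
g <- generate_fundus(vascular_tree_spec(seed = 42))
g$truth[c("junctions", "loops", "isolated_elements")]
#> $junctions   [1] 25
#> $loops       [1] 3
#> $isolated_elements [1] 15

f <- run_pipeline(g$image, vasc_config())
f
#> <vasc_features>
#>   extremities            49
#>   nodes                  43
#>   junctions              21
#>   branches               21
#>   branch_length          1180.08
#>   segments               21
#>   segment_length         1393.76
#>   isolated_segments      14
#>   isolated_length        188.38
#>   master_segments        12
#>   master_segment_length  924.566
#>   master_junctions       2
#>   meshes                 3
#>   mesh_area              8209
#>   mean_mesh_size         2736.33
#>   mesh_index             77.0471
#>   branching_interval     66.3697
#>   pieces                 56
#>   total_length           2762.22
#>   branching_length       2573.84
```

The pipeline recovered all 3 loops as meshes, 21 of 25 junctions
(closely spaced bifurcations merge under the closing) and 14 of 15
isolated elements; lengths are in pixels (diagonal steps cost √2).

Statistics from printed summary data (mean, SD, n) work without raw
values:

```r
ttest_from_summary(3.44, 0.7265, 9, 4.0, 1.936, 9)
#> Student's unpaired t-test (two-tailed)
#>   group 1: 3.44 +/- 0.7265 (n = 9)
#>   group 2: 4 +/- 1.936 (n = 9)
#>   t = -0.8124, df = 16, P = 0.4285

required_sample_size(1.5, alpha = 0.05, target_power = 0.8, ratio = 1)
#> $n1 [1] 9    $n2 [1] 9    $total [1] 18
#> $achieved_power [1] 0.8476101
```

## Command line

```sh
inst/scripts/retvasc simulate --n-images 9 --group control --seed 1 --out ctrl/
inst/scripts/retvasc simulate --n-images 9 --group diabetic-like --seed 1 --out diab/
inst/scripts/retvasc analyze ctrl/*.png --out ctrl.csv
inst/scripts/retvasc analyze diab/*.png --out diab.csv
inst/scripts/retvasc compare ctrl.csv diab.csv --out report.json --alpha 0.05
inst/scripts/retvasc power --effect-size 1.5 --alpha 0.05 --power 0.8 --ratio 1
```

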