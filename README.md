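# emdmn

Quantification of **Emerin-rich micronuclei** in fluorescence microscopy
images, and the **Emerin-pauperization transcriptomic score**, for studies of
nuclear-envelope (NE) protein mislocalization in prostate cancer.

Micronuclei (MN) are small chromatin-containing structures separate from the
main nucleus. A subset of them accumulates the inner/outer nuclear-membrane
protein Emerin at roughly twice the NE staining level ("Emerin-rich" MN,
with reduced DAPI content), acts as a protein sink that pauperizes Emerin
from the NE, and marks cells with increased migratory and invasive
potential. This package reimplements, as tested reusable R code, the
ImageJ/QuPath-style analysis used to quantify that phenotype:

* **segcore** — ImageJ-style auto-thresholding (Otsu, Intermodes, Yen, on a
  256-bin 8-bit histogram with an optional dim-background floor),
  connected-component particle analysis (area, perimeter, centroid,
  circularity 4&pi;A/P&sup2;, solidity A/A<sub>hull</sub>), multi-page TIFF I/O.
* **mn_quant** — nucleus segmentation, per-nucleus NE reference intensity
  (ring = dilation &minus; erosion of the nucleus mask), MN detection with the
  0.2–12 µm² size gate, classification into *rich* vs *ne_level* by the
  MN/NE intensity ratio (rich when ratio &ge; 1.2; typical rich MN sit near
  2), per-field `rich MN / nuclei`, quartile stratification with the cohort
  cutoffs 0.07538 / 0.1280 / 0.1861, and the normal/pauperized phenotype
  rule (>85 % Emerin-negative cells or `rich MN/nuclei` &ge; 0.1861).
* **ratios** — DAPI content ratio (MN vs nucleus), NE/cytoplasm Emerin
  pauperization ratio (ring mean over cytoplasmic-annulus median), MN/NE
  Emerin ratio.
* **morphometrics** — nuclear area and shape, focal adhesion sizes
  (paxillin), signed MTOC–nucleus distance (negative when the centrosome
  sits over the nucleus), F-actin structure-tensor coherency
  (&lambda;&#8321;&minus;&lambda;&#8322;)/(&lambda;&#8321;+&lambda;&#8322;),
  spheroid metrics with the invading-cell rule, migration path statistics.
* **signature** — nCounter-style background correction and normalization,
  Mann–Whitney differential expression with median-based log2FC, the 9-gene
  score (mean log2 counts of *CXCR4, APOE, SPARC, VIM, GSN, ANXA2P2, SFRP1,
  COL18A1, FN1*) with upper-quartile classification, Kaplan–Meier / log-rank
  / Cox survival association.
* **synthetic_data** — phantom fields (elliptical nuclei with NE rims plus
  planted MN of both classes) and expression/survival cohorts with known
  ground truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(emdmn)

# a synthetic field: 20 nuclei, 4 Emerin-rich + 4 NE-level MN, 0.3 um/px
sim <- generate_field(phantom_params(seed = 42))
q <- quantify_field(sim$field)
q$summary
#> field: 20 nuclei, 4 Emerin-rich MN, 4 NE-level MN; rich MN/nuclei = 0.2000
head(q$records[, c("area_um2", "nucleus_id", "emerin_ratio_to_ne", "mn_class")], 4)
#>   area_um2 nucleus_id emerin_ratio_to_ne mn_class
#> 1     5.49          3          0.9925815 ne_level
#> 2     1.80          6          1.9783659     rich
#> 3     3.06         11          1.0175615 ne_level
#> 4     4.05         10          2.0032957     rich
stratify(q$summary$rich_per_nucleus)   # cohort quartile class
#> [1] >=p75

# a synthetic cohort: score, upper-quartile split, survival association
co <- generate_cohort(cohort_params(n_samples = 500, true_hr = 1.75, seed = 42))
st <- pauperization_score(co$matrix)
survival_association(co$survival, st$high_flag)
#> survival association: n = 500 (342 events)
#>   HR = 1.362 (95% CI 1.073-1.728)
#>   log-rank chi-square = 6.518, p = 0.01068
```

The per-MN table shows each detected particle's size, its assigned nucleus,
its Emerin intensity relative to that nucleus's NE, and the resulting class:
ratios near 2 are rich MN, ratios near 1 are NE-level MN. The field's
`rich MN/nuclei` of 0.20 exceeds the published 75th-percentile cutoff
(0.1861), so the field stratifies into the top class. In the cohort, the
high-score quartile carries an elevated hazard (the point estimate is
attenuated below the simulated 1.75 because the expression-based split
mislabels a few boundary samples).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "emdmn.R", package = "emdmn"))')" \
    all --out results/demo --seed 3 --n-fields 2
```

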