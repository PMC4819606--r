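# panelGMLVQ

Analysis pipeline for low-density qPCR cytokine panels profiled across
patient outcome groups — the setting of synovial biopsy studies in early
arthritis, where ~117 cytokine/chemokine transcripts are measured in four
small outcome groups (uninflamed controls, resolving arthritis, early
rheumatoid arthritis, established RA) and the goal is to find genes that
mark the earliest, still-reversible phase of disease.

The package covers the full chain:

* **Relative quantification & preprocessing** — `computeRQ()` converts Ct
  values to relative quantities `RQ = 2^-dCt` against a reference gene
  (non-detects at `Ct >= 40` become RQ = 0); `imputeZeros()` replaces zeros
  with the observed detection floor (the smallest non-zero RQ);
  `logTransform()` and `standardizeFeatures()` produce the feature matrix.
* **Univariate screen** — `screenGenes()` runs per-gene tie-corrected
  Kruskal-Wallis tests with Dunn's post-hoc pairwise z tests
  (Bonferroni-adjusted across pairs); `rankByGroupDifference()` builds the
  heat-map-style table of z-scored group means ranked by a chosen group
  contrast.
* **GMLVQ classification** — `trainGMLVQ()` fits generalized matrix
  relevance learning vector quantization: class prototypes plus a learned
  global metric `d(x,w) = (x-w)' Lambda (x-w)`, `Lambda = Omega'Omega`,
  `Tr(Lambda) = 1`, minimizing the GLVQ margin cost
  `E = sum_i Phi((dJ - dK)/(dJ + dK))` by monotone batch descent with an
  optional log-det metric regularizer. `relevanceProfile()` turns
  `diag(Lambda)` into a per-gene relevance ranking (back-rotated through
  the optional PCA front-end).
* **Evaluation** — `crossvalScores()` (leave-one-out by default, with
  per-fold preprocessing refit), `rocCurve()` / `aucScore()` (trapezoidal
  area == tie-adjusted Mann-Whitney statistic), `topKFeatures()`.
* **Synthetic cohorts** — `syntheticCohortSpec()` / `generateCohort()`
  draw seeded log-normal cohorts with planted group effects and
  detection-limit zero inflation; `studyDesignSpec()` encodes the default
  four-group, 117-gene scenario with a chronic-inflammation signature and
  an early-peak chemokine pair.
* **Orchestration** — `runPipeline()` runs everything end to end and
  writes CSVs plus a JSON manifest (config, seed, imputation constant) so
  runs are byte-for-byte reproducible; `inst/scripts/panel-gmlvq.R` is a
  command-line wrapper.

## Worked example

```r
library(panelGMLVQ)

cohort <- generateCohort(studyDesignSpec(seed = 1))
panel  <- cohort$panel
panel
#> CytokinePanel: 117 genes x 48 samples [rq scale]
#> groups: early_ra (n=17), established_ra (n=12), resolving (n=9), uninflamed (n=10)

lp <- preprocessPanel(panel)           # impute -> log2 -> standardize
screen <- screenGenes(lp, alpha = 0.05)
screen$nSignificant
#> [1] 21

model <- trainGMLVQ(lp, groups = c("early_ra", "resolving"), seed = 1)
topKFeatures(relevanceProfile(model), 5)
#> [1] "inflam03"  "CXCL7like" "inflam12"  "inflam01"  "inflam10"

cv  <- crossvalScores(panel, c("early_ra", "resolving"), seed = 1)
roc <- rocCurve(setNames(cv$score, cv$sample_id), cv$label, "early_ra",
                scheme = "loo")
roc
#> RocResult [loo]: AUC = 0.9869 (positive 'early_ra': n=17, negative: n=9)
```

21 genes screen as differentially expressed (the generator plants 20); the
early-peak chemokine-like genes rank among the top relevances of the
early-RA-vs-resolving classifier alongside the inflammation signature, and
the leave-one-out AUC quantifies how well that contrast generalizes at
n = 17 + 9.

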