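# mammocad

Associative rule-based computer-aided diagnosis (CADx) for medio-lateral
oblique (MLO) mammograms, for researchers who want a local, fully testable
implementation of an associative-classification imaging pipeline — no
cloud services, no external archives.

Instead of a discriminant classifier, the trained model is a base of
**class-constrained representative association rules**: bodies are
discretized texture-feature items, heads are sets of diagnosis keywords
(BI-RADS assessment categories 0–5, morphology and histology terms).  A
test image is reduced to an itemset and every distinct rule head *h* is
scored over the rules carrying it, counting full matches *nM* (body ⊆
itemset), partial matches *nP* and non-matches *nN*:

* **Condition 1** accepts *h* with weight `w1 = nM / (nM + nN)` when
  `w1 ≥ α`;
* **Condition 2** (tried only if Condition 1 fails) accepts with weight
  `w2 = (nM + nP) / (nM + nP + nN)` when `w2 ≥ δ`.

The engine can return several keyword sets per image, each with its weight
and the condition that accepted it.

The full pipeline: breast-contour identification and pectoral-muscle
removal (region-based level set + seeded region growing) → orthogonal-
polynomial edge detection with statistical edge/noise separation and
distance-regularized level-set refinement → a fixed-layout
1037-dimensional feature vector (four families: 113 orthogonal-polynomial,
448 sub-band statistical/spectral, 336 bivariate orthogonal-polynomial,
140 gradient co-occurrence slots) → joint inconsistency-based feature
selection and discretization → exact FP-growth mining with a
representative-rule (cover-operator) filter → diagnosis.  A phantom module
generates synthetic mammograms with analytic ground truth and labeled
transaction cohorts with planted rules, so every stage is testable
offline; see `vignettes/methods.Rmd` for the models, parameters and
design decisions.

## Worked example

Train on 200 synthetic transactions carrying two planted rules (5% item
noise), then diagnose a new itemset:

```r
library(mammocad)

spec <- transaction_cohort_spec(
  n_transactions = 300, item_universe = 12,
  keyword_universe = c("Benign finding", "Invasive ductal cancer"),
  planted_rules = list(
    list(body = c("item001", "item002"), head = "Benign finding"),
    list(body = c("item005", "item006"), head = "Invasive ductal cancer")),
  noise_rate = 0.05, seed = 42)
cohort <- generate_transactions(spec)

model <- cad_train(cohort = cohort[1:200],
                   config = pipeline_config(minsup = 0.05, minconf = 0.8))
print(model$rulebase, n = 4)
#> Rule base: 8 representative rules (minsup 0.05, minconf 0.8)
#>   {item002} -> {Benign finding}  sup 0.550 conf 0.957
#>   {item001} -> {Benign finding}  sup 0.520 conf 0.990
#>   {item001, item002} -> {Benign finding}  sup 0.500 conf 0.990
#>   {item006} -> {Invasive ductal cancer}  sup 0.410 conf 0.943
#>   ... 4 more

diagnose(model$rulebase, c("item001", "item002", "item009"),
         alpha = 0.5, delta = 0.5)
#> Diagnosis (alpha = 0.5, delta = 0.5): 1 accepted head(s)
#>   {Benign finding}  weight 0.750  condition 1  (nM=3 nP=1 nN=1)
```

Both planted rules are recovered with their observed supports and
confidences; the test itemset fully matches three of the five
`{Benign finding}` rule bodies and misses one, so Condition 1 accepts that
head with weight 3/4, while the malignant head finds no match and is
rejected.

The image path works the same way from pixel data:

```r
ph  <- generate_phantom(phantom_spec(
  lesions = list(list(center = c(70, 40), radius = 9, contrast = 55,
                      margin = "circumscribed"))))
pre <- preprocess_mammogram(ph$image)        # breast mask, pectoral removal
edges <- detect_edges(op_transform(pre$image, pre$aoi$aoi_mask))
rois  <- refine_contour(pre$image, edges)    # one ROI over the lesion
fv    <- extract_features(pre$image, roi_patch(rois$rois[[1]]$mask))
length(fv)
#> [1] 1037
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/mammocad-cli.R`
(`Rscript mammocad-cli.R phantom|preprocess|segment|features|train|test ...`).

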