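# eigenCoord

Eigen-spectrum **coordination analysis** of gene sets, with the
supporting stages of a hub-gene biomarker workflow.

## The problem

In case/control transcriptomics one often asks not whether single genes
change level, but whether a small gene set — say, three
neuroinflammation hub genes and a pathology anchor such as *MAPT* —
**co-varies more tightly** in one group than the other.  eigenCoord
quantifies this through the eigenvalue spectrum of the gene set's
inner-product matrix.  For each group, Z-score each gene across that
group's samples, stack the standardized rows into $X$ ($n$ genes
$\times$ $m$ samples), and form the Gram matrix

$$R = XX^\top, \qquad R_{ij} = a_i \cdot a_j = \sum_{s=1}^m x_{is}x_{js},$$

a scaled sample correlation matrix, hence symmetric positive
semi-definite.  Eigendecompose $R = Q\Lambda Q^\top$ and normalize,
$\lambda_i \leftarrow \lambda_i / \sum_k \lambda_k$, so the spectrum is
descending, non-negative, and sums to one.  A dominant $\lambda_1$
means the genes move together (coordination); a flat spectrum near
$1/n$ means independence.  Comparing the two groups' spectra rank by
rank localizes where coordination changes — for an equicorrelated
$n$-gene set the population spectrum is the closed form
$\big(\tfrac{1+(n-1)\rho}{n}, \tfrac{1-\rho}{n},\dots\big)$, so the
leading eigenvalue rises monotonically with the common correlation.

Around the core statistic the package provides the rest of the
workflow, each stage testable on simulated data:

* **`syntheticDesign()` / `simulateExpression()`** — block-correlated
  multivariate normal expression generator with group-specific module
  correlations, mean shifts and a planted-hub PPI edge-list generator
  (`simulateEdgeList()`).
* **`degTable()`** — two-group differential expression (per-gene Welch
  t, Benjamini–Hochberg adjustment, strict |logFC| > 1.5 and p < 0.05
  calls).
* **`readEdgeList()` / `dropIsolatedNodes()` / `degreeRanking()`** —
  confidence-filtered PPI ingestion and unweighted-degree hub ranking.
* **`runClassification()`** — weighted soft-voting ensemble (random
  forest, SVM, per-class Gaussian, logistic model; default weights
  2/2/1/1) on a seeded stratified 80/20 split, evaluated with
  from-scratch ROC/AUC and accuracy.
* **`runPipeline()`** — deterministic end-to-end run writing TSV/JSON
  stage outputs.

See `vignettes/eigen-coordination.Rmd` for the model, assumptions,
parameter rationale, and limitations.

## Worked example

Simulate a 19-sample study (10 AD, 9 control) in which three hub genes
plus the anchor *MAPT* form one module that is strongly coordinated in
the AD group (rho = 0.8) and weakly in controls (rho = 0.2), then
compare the spectra:

```r
library(eigenCoord)

design <- syntheticDesign(
  modules    = list(M1 = c("LCK", "ZAP70", "CD44", "MAPT")),
  rho        = list(AD = c(M1 = 0.8), CON = c(M1 = 0.2)),
  groupSizes = c(AD = 10L, CON = 9L), seed = 2024L)
se <- simulateExpression(design)

comp <- coordinationAnalysis(se, c("LCK", "ZAP70", "CD44"),
                             anchorGene = "MAPT", refGroup = "CON")
comp
#> SpectrumComparison: CON vs AD over 4 ranks
#>   largest-rank delta (B - A): +0.4527
#>   smallest-rank delta (B - A): -0.0933

lapply(comparisonSpectra(comp), function(s) round(spectrumValues(s), 4))
#> $CON
#> [1] 0.3486 0.3398 0.1936 0.1179
#>
#> $AD
#> [1] 0.8014 0.1154 0.0586 0.0247
```

Each spectrum sums to 1.  In the AD group 80% of the gene set's
variance-structure mass sits on the first eigen-axis — the four genes
move almost as one — while the control spectrum is much flatter.  The
positive rank-1 delta (+0.45) says coordination is higher in AD, the
direction planted by the design (0.8 vs 0.2); at these small sample
sizes the estimates scatter around the population values
(1 + 3·0.8)/4 = 0.85 and (1 + 3·0.2)/4 = 0.40.

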