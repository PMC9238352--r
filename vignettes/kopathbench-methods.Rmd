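---
title: "Methods: knockout-pathway benchmarking with topology-based perturbation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout-pathway benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Pathway enrichment methods are usually compared on data where nobody knows
the right answer. A gene-knockout experiment changes that: if a gene such as
an innate-immunity adaptor is deleted, every pathway that contains it is,
by construction, a true target of the perturbation, and every pathway that
does not contain it is a negative. `kopathbench` packages that idea as a
reusable benchmark: run a topology-based pathway scoring method on a
knockout-vs-wildtype transcriptome, label pathways by knockout-gene
membership, and summarize how well the method's per-pathway p-values
separate positives from negatives with a ROC metric panel.

The pipeline has five stages, each usable on its own:

1. **Gene statistics.** Per-gene log2 fold-change and a two-sided Welch
   unequal-variance t-test for each of three contrasts: A (septic knockout
   vs septic wildtype), B (septic knockout vs untreated wildtype), C
   (septic wildtype vs untreated wildtype).
2. **Automatic DEG selection.** Edges of the merged pathway network are
   scored from the gene statistics; a change-point on the sorted
   edge-score distribution yields the HES1 ("high edge score") cutoff, and
   genes incident to retained edges are the DEGs. No fixed fold-change or
   p-value cutoff is involved.
3. **Pathway perturbation scoring.** A signed-topology accumulation model
   (hypergeometric over-representation `pNDE`, bootstrap perturbation
   `pPERT`, combined `pG`, BH-adjusted `pGFdr`, Activated/Inhibited
   status).
4. **Knockout-ROC evaluation.** AUC with DeLong 95% CI, partial AUCs over
   the 90--100% specificity and sensitivity regions in original and
   McClish-corrected formats, and Youden's best p-value threshold.
5. **Venn intersection.** The three contrasts' DEG sets partitioned into
   the seven Venn regions, ranked within regions by best edge score.

# Models and formulas

## Edge scores and the HES1 threshold

Each measured gene receives the weight
\[ w_g = |\mathrm{lfc}_g| \cdot (-\log_{10} p_g), \]
and an edge \((u, v)\) of the merged network scores
\[ ES(u,v) = \sqrt{w_u \, w_v}. \]
The geometric mean keeps the score symmetric in the endpoints and exactly
zero when either endpoint is null. This surrogate is a deliberate,
documented choice: the upstream literature delegates its edge-score
definition to software we do not reproduce, so the package states its own
formula and tests it as such.

The DEG cutoff is found by sorting all edge scores in descending order and
fitting an at-most-one-change (AMOC) Gaussian segmentation in mean and
variance: the split \(k\) minimizes
\[ k \log \hat\sigma^2_{1..k} + (n-k) \log \hat\sigma^2_{k+1..n}, \]
which is the two-segment maximum-likelihood change point. HES1 is the
score at the split; retention uses \(ES \ge \mathrm{HES1}\) so ties at the
threshold are kept. A single change point is fitted because one threshold
per data set is what the analysis defines; an MBIC-style comparison with
the no-change model is reported as a diagnostic flag (`mbic_supported`)
rather than an error, because the pipeline always needs a cutoff and the
degenerate cases (all scores equal, fewer than 20 edges) are already
errors of their own.

## Perturbation accumulation

For pathway genes \(i, j\), the influence matrix is
\[ B_{ij} = \beta(j \to i) / N_{ds}(j), \]
with \(\beta = \pm 1\) from the KGML relation subtype (activation and
expression +1, inhibition and repression −1, other subtypes dropped) and
\(N_{ds}(j)\) the out-degree of \(j\). The perturbation factor solves the
fixed point \( PF = \Delta E + B \, PF \), where \(\Delta E\) is the DEG
log2 fold-change on the pathway and 0 elsewhere. The accumulation is
\( Acc = PF - \Delta E \) and the pathway's total accumulation
\( t_A = \sum_i Acc(i) \). When \(I - B\) is singular (possible with
cycles) the pathway is flagged not computable, excluded from ROC scoring,
and logged — no damping is applied, so reported numbers always come from
the exact linear system.

Two independent pieces of evidence are combined:

* `pNDE`: upper-tail hypergeometric probability of observing at least
  `NDE` DEGs on the pathway, with the universe restricted to measured
  genes that map to at least one pathway (configurable).
* `pPERT`: bootstrap two-sided tail of \(t_A\) around the null median.
  Each of `n_boot` resamples places `NDE` fold-changes, drawn with
  replacement from the full DEG fold-change pool, on `NDE` uniformly
  chosen distinct pathway genes. The add-one estimator
  \((1 + \#\{|t_A^{null} - m| \ge |t_A^{obs} - m|\})/(n_{boot}+1)\)
  keeps the p-value strictly positive. Because \(t_A\) is linear in
  \(\Delta E\), the implementation precomputes
  \(\mathrm{colSums}((I-B)^{-1} - I)\) once per pathway; the bootstrap is
  then pure sampling, which is what makes a 30-pathway, 2000-resample run
  take seconds. The test suite checks this shortcut against full
  re-solving and against exhaustive placement enumeration.

With \(c = pNDE \cdot pPERT\), the combined p-value is
\( pG = c - c\ln c \) (the tail probability of a product of two
independent uniforms), and `pGFdr` is the Benjamini--Hochberg adjustment
across pathways. Status is Activated when \(t_A\) exceeds the bootstrap
null median and Inhibited otherwise — the median rather than zero, so an
asymmetric null cannot bias the call.

## Knockout-ROC panel

Pathways containing the knockout gene are positives; scores are p-values
with fixed orientation (smaller = stronger call; no auto-flipping, which
can silently invert an AUC). The AUC is the Mann--Whitney statistic with
ties at 0.5, identical to the trapezoidal area under the empirical curve.
The DeLong confidence interval uses the placement-value variance; perfect
separation yields a degenerate `[auc, auc]` interval with a flag. Partial
AUCs integrate the curve over specificity (or sensitivity) in [0.9, 1]
with linear interpolation at the boundary; the McClish correction maps
\([pA_{min}, pA_{max}] = [w^2/2,\; w]\) (region width \(w\)) onto
[0.5, 1]. Youden's point maximizes \(J = se + sp - 1\) over midpoint
thresholds, breaking ties toward higher specificity and then lower
threshold.

# The synthetic world

The generator exists so every stage is testable without external
downloads. It emulates a small knockout microarray study in log2 space:

| Parameter | Default | Why |
|---|---|---|
| `n_genes` | 2000 | enough genes for stable null p-value histograms while keeping runs in seconds |
| `n_pathways`, `n_positive_pathways` | 30, 5 | the scale of a curated signaling-pathway benchmark |
| `pathway_size_range` | (20, 60) | mid-size signaling pathways; real curated pathways span roughly 30--400 genes |
| `inhibition_fraction` | 0.25 | signaling topologies are mostly activating with a sizable inhibitory minority |
| `baseline_mean`, `baseline_sd` | 8, 1.5 | typical normalized log2 microarray intensities |
| `noise_sd` | 0.25 | replicate-level noise of a clean array experiment |
| `delta_treatment`, `delta_ko` | 1.5 | a strong but realistic ~2.8-fold planted effect |
| `n_replicates` | 3 | a typical small microarray group size (the emulated study does not state its own) |

Pathways are random connected DAGs: nodes in a random topological order,
one guaranteed parent per non-root node, extra forward edges with
out-degree ~ Poisson(2). DAGs keep \(I - B\) invertible so default runs
never hit the singular branch (cycles can be switched on). The knockout
gene heads the topological order of its pathways, as a receptor-proximal
adaptor does, so it always has downstream targets. Downstream effects
carry the product of edge signs along the first path in topological
order. In septic samples, downstream genes of positive pathways shift by
\(\pm\delta_{treatment}\); in knockout samples the knockout gene shifts by
\(-\delta_{ko}\) and its downstream genes by \(\mp\delta_{ko}\) — the
knocked-out signal no longer reaches them. That propagation is the
package's reading of the knockout construct: without it, the knockout
contrast would carry no pathway-level signal and knockout-ROC benchmarking
would be vacuous. A side effect worth knowing: when
\(\delta_{treatment} = \delta_{ko}\), the two shifts cancel in contrast B
for downstream genes, so contrast B is deliberately the hardest of the
three.

What the generator does **not** emulate: probe-level artifacts beyond
optional duplication, normalization residue, correlated noise between
genes, batch effects, or realistic pathway overlap structure (overlap
arises only from sampling a shared universe). A green end-to-end test
therefore establishes that the machinery recovers a planted signal under
clean Gaussian noise — not that any biological result is correct.

# Numerical choices

* Welch rather than a moderated t: exactly specifiable, no hidden
  shrinkage; a variance floor of 1e-8 on the squared standard error keeps
  constant genes testable (df then falls back to \(n_1+n_2-2\)), and
  p-values are floored at 1e-300 so \(-\log_{10} p\) stays finite.
* With 3 replicates per group the Welch null is slightly conservative
  (about 3.5% of null genes at p < 0.05 instead of 5%); the calibration
  tests bound this rather than hide it.
* Change-point segment variances are floored at 1e-12; minimal segment
  length 2.
* Duplicate network edges deduplicate on (src, dst); a sign conflict
  keeps the first-listed pathway's sign and warns, with both pathways in
  the provenance.
* Probe collapse is explicit (`max_mean` default, `median` optional);
  reading a matrix with duplicate gene ids without asking for collapse is
  an error, not a silent aggregation.
* Bootstrap seeds derive as `seed + pathway position`, so results do not
  depend on evaluation order and a parallel driver could not change any
  value.
* Table cells round half away from zero (62.35 → 62.4) to match printed
  report conventions, not R's round-half-to-even.

# Design decisions that were genuinely open

* **Ranking key for Venn regions.** No ordering is prescribed for "top
  k" intersected DEGs; the package ranks by the maximum best-edge-score
  across contributing contrasts because edge score is the pipeline's own
  evidence measure (`min_p` is available as an alternative), with
  lexicographic tie-breaks for determinism.
* **Status from the bootstrap median, not sign(tA).** Robust when the
  null is asymmetric; on symmetric nulls the two agree.
* **Indirect-effect relations.** Dropped by default (weight table is
  configuration); whether the original analysis weighted them is unknown.
* **Universe for `pNDE`.** Measured genes on at least one pathway;
  restricting to mapped genes avoids inflating significance through
  unmappable background.

# Known limitations

* The edge-score formula is a surrogate (see above); absolute HES1 values
  are not comparable to other software, though the change-point mechanism
  is.
* DeLong intervals are asymptotic; with very few positive pathways the
  coverage test (15 positives / 30 negatives) is the relevant scale, and
  smaller benchmarks will under-cover.
* The bootstrap null conditions on `NDE` and ignores gene-gene
  correlation, as the underlying method family does.
* Real KGML uses a richer relation vocabulary than the four default
  subtypes; unmapped subtypes silently drop edges (by design, but worth
  auditing on real data via the parse summaries).
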