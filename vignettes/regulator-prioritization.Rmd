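---
title: "Prioritizing transcriptional regulators of a target gene"
author: "regprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing transcriptional regulators of a target gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regprior)
```

# The problem

Which transcription factors (TFs) drive the expression of a given target
gene? Perturbing every expressed TF is rarely feasible, so a practical
strategy is computational shortlisting followed by a reporter screen.
regprior implements such a shortlisting pipeline for a single target
locus:

1. **CRE calling.** Candidate cis-regulatory elements (CREs) around the
   target TSS are identified from histone-mark and accessibility peak
   evidence (H3K4me1, H3K4me3, H3K27ac, DNase), within ±20 kb of the
   TSS. Elements overlapping H3K4me3 peaks are classified as promoters,
   H3K4me1-only elements as enhancers, DNase-only elements as merely
   accessible. Elements are numbered 1..k in 5′→3′ gene order, so the
   promoter cluster — which sits at the 5′ end of the element series in
   the locus architecture this models — takes the lowest numbers, and
   the element immediately upstream of the major TSS with the strongest
   DNase signal is the core promoter.
2. **Binding-site counting (the "Bumscore").** Every motif in a
   JASPAR-style library is turned into a log2-odds PWM and scanned over
   each CRE sequence on both strands. A window is a predicted site when
   its score reaches the exact background p-value threshold (default
   p ≤ 1e-4). Overlapping same-TF hits are collapsed to the single
   best-scoring one, so palindromes are not double-counted. A TF's
   Bumscore is its total retained hit count across all CREs.
3. **Coexpression.** Pearson correlation between each TF's expression
   and the target's, computed on log2(CPM + 1) across samples;
   optionally also between TF expression and per-CRE H3K27ac enrichment
   across cell types.
4. **Composite ranking and selection.** The three evidence channels —
   Bumscore, target correlation, core-promoter accessibility for TFs
   with a promoter site — are combined as a rank product (geometric mean
   of descending ranks; lower is better). Candidates enter the selected
   set by either of two rules, with strict inequalities: Bumscore > 3
   and r > 0.3; or differential expression under the stimulus and
   Bumscore > 2. The union is capped (default 96) by composite score.
5. **Downstream target statistics.** Separately, ChIP peaks of a chosen
   regulator are assigned to genes whose TSS lies within 2 kb of a peak
   edge; targets are crossed with differential-expression status
   (UP/DOWN/NDE at FDR < 0.05 and linear fold change 1.5), and
   user-supplied genesets are tested for over-representation with the
   one-sided Fisher exact test plus Benjamini–Hochberg adjustment.

# The binding model and its exact p-values

For a position frequency matrix with counts $n_{bj}$, column sums $N_j$,
pseudocount $s$ and background $\pi$, the PWM entry is

$$ w_{bj} = \log_2 \frac{(n_{bj} + s\,\pi_b)/(N_j + s)}{\pi_b}. $$

Window scores are sums of independent per-column entries, so the exact
distribution of the score under the background model is the convolution
of the per-column distributions. regprior discretizes entries to a
lattice of 1e-3 bits at PWM construction time and convolves on that
lattice. Because scanning uses the *same* discretized entries, every
reported hit score is an exact lattice sum, and the dynamic-programming
tail probability at a hit score is exact for the scored matrix rather
than an approximation — the test suite checks it against exhaustive
enumeration of all $4^L$ k-mers to 1e-10. The lattice step of 1e-3 bits
perturbs each entry by at most 5e-4 bits, far below any selection
boundary used here. Windows containing N are scored with the per-column
minimum, so unknown bases can never create a hit at stringent p.

The threshold at p-value $p$ is the smallest lattice score $s$ with
$P_{bg}(S \ge s) \le p$. Note a finite-alphabet consequence: for a
motif of length $L$ no threshold can be more stringent than the
probability of the single best k-mer (e.g. $0.25^8 \approx 1.5\times
10^{-5}$ for uniform background and an 8-mer), so asking for a smaller
$p$ yields an unattainable threshold and zero hits by design.

# What the synthetic generator emulates

Because the study's raw data (motif database, expression compendium,
sequencing runs) are not reconstructible, validation is built on planted
signal. `simulateStudy()` generates, from a single master seed:

* a uniform-background locus (default 50 kb) with 7 planted elements of
  600 bp — one promoter-class element immediately upstream of the TSS
  and 6 enhancers placed non-overlapping downstream of the TSS within
  the 20 kb window, at least 500 bp apart so the caller's 200 bp merge
  gap never fuses them;
* a sharp true-regulator motif (counts 85/5/5/5 per consensus column,
  ≈1.76 bits per position, typical of a well-determined JASPAR motif)
  planted twice per element on random strands, among 50 decoy motifs
  drawn column-wise from a flat Dirichlet prior and never planted;
* Gaussian signal bumps (height 5, sd = element width / 4) per mark,
  with H3K4me3 only at the promoter, H3K4me1 only at enhancers, DNase
  everywhere (1.5× at the promoter) and H3K27ac everywhere, plus
  clipped Gaussian noise (sd 0.2); peak files are the planted element
  intervals per covered class;
* an expression matrix (40 samples) in which target and true TF follow
  a bivariate normal on the log2 scale with correlation 0.7
  (exponentiated to a CPM-like scale; correlating on log2(CPM+1) is
  what the pipeline does, so the correlation is planted on the scale it
  is measured on), decoys independent;
* a DE table in which exactly the configured fractions (default
  10%/10%) pass the strict thresholds, with the true TF planted as
  differentially expressed;
* ChIP peaks over a pseudo-gene roster with a configurable bound
  fraction, for the target-assignment and crosstab stages.

Each generator draws from its own RNG stream derived from the master
seed, so changing the sample count cannot perturb the locus sequence.

**What passing these tests does and does not show.** The generator's
background sequence is i.i.d. uniform — no GC skew, no repeats, no
homotypic decoy clusters; tracks have independent Gaussian noise rather
than read-count noise; expression is log-normal with a single planted
dependency. Perfect recovery under these conditions demonstrates the
machinery is correct and calibrated, not that real loci, where decoy
motifs cluster and marks correlate, would yield a unique clean answer.

# Numerical and design choices

* **Coordinates.** BED and bedGraph inputs are 0-based half-open; they
  are converted exactly once at the I/O boundary to the 1-based closed
  GRanges convention used internally.
* **Merging and support.** The element-merging gap (200 bp) and the
  minimum number of supporting cell types (default 1, i.e. a permissive
  union across cell types) are exposed because no published rule fixes
  them; stringency can be raised via `minCellTypes`.
* **Overlap resolution.** Among mutually overlapping same-TF hits the
  single best-scoring one is kept (ties: leftmost, then + strand). This
  is a greedy rule: in adversarial configurations a stronger hit
  spanning two weaker disjoint hits can reduce the count by one when
  the threshold loosens, a theoretical non-monotonicity that does not
  arise for the well-separated planted sites the benchmarks use.
* **Composite score.** The published description names three inputs
  (coexpression, promoter accessibility, binding-site count) but no
  formula; a rank product was chosen because it is scale-free, robust
  to the wildly different units of the three channels, and uses exactly
  the named inputs. Promoter accessibility is defined as the DNase
  aggregate over the core promoter for TFs with at least one
  promoter-class hit, 0 otherwise, and is likewise configurable.
* **Selection cap.** "Up to 96" is read as a cap on the rule union,
  applied by ascending composite score with ties broken by TF
  identifier, making the output order-independent and deterministic.
* **DOWN-regulation rule.** The published DOWN threshold ("fold change
  < 1.5") is read as the reciprocal (linear FC < 1/1.5, i.e.
  log2FC < −0.585), the only reading that makes DOWN disjoint from UP;
  `fcMin` is configurable.
* **Fisher test.** One-sided over-representation p-values come from the
  hypergeometric tail (`phyper`); the two-sided variant is delegated to
  `fisher.test`. Odds ratios get a 0.5 continuity correction only when
  a margin is zero, and only for reporting (flagged in the output).
  BH adjustment uses `p.adjust`.
* **Degenerate inputs.** Constant expression vectors raise an error
  rather than returning a silent zero correlation; an empty CRE set is
  a valid result (Bumscore 0 for every TF), while a missing promoter
  class yields a warning and no core promoter.

# Problem sizes used by the validation suite

The packaged tests and the acceptance script run, at the default study
conditions: 100 end-to-end planted-recovery simulations; correlation
recovery at 10,000 samples; 1,000 Fisher-z replicates at the null;
10 noise-free CRE-recovery loci; 20 PWM-vs-enumeration comparisons
(motif length ≤ 6); 100 strand-symmetry pairs; 200 Fisher-oracle
tables; 1,000 random selection tables. These sizes give the binomial
margins quoted in the tests (e.g. ≥95/100 recoveries) while keeping a
full run inside a few minutes on one CPU.

# Limitations

* The scanner is a 0-order-background PWM model: no higher-order
  background, no dimer spacing models, no motif discovery.
* CRE calling consumes peak calls; it does not call peaks from reads,
  and it performs no ChromHMM-style segmentation.
* The absolute candidate lists of the motivating study are not
  reproducible from public information (unspecified motif database and
  expression compendium); the package therefore validates properties
  and planted-signal recovery, not the study's literal TF list.

# A minimal session

```{r example}
cfg <- simulationConfig(seed = 1)
res <- runSyntheticBenchmark(cfg)
res$recovery
head(res$candidates[order(res$candidates$compositeRankScore),
                    c("tf", "bumscore", "rTarget", "selected")], 3)
```
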