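---
title: "cysPTM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cysPTM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Protein S-sulfenylation is a reversible oxidative modification of cysteine
thiols (Cys-SH to Cys-SOH) involved in redox signalling. Experimentally
mapping which cysteines of a proteome are sulfenylated is expensive, so a
sequence-based classifier is useful for triage: given a protein sequence and
a candidate cysteine, predict whether its local neighbourhood looks like a
sulfenylation substrate. cysPTM implements the full supervised workflow for
this problem — and, because nothing in it is specific to sulfenic acid
chemistry, for any cysteine-centered PTM with annotated sites.

# The procedure

1. **Window extraction.** Every cysteine yields a fragment of length
   $2n+1$ ($n = 10$ by default, a 21-mer) centred on the cysteine; positions
   beyond the protein termini are filled with the terminal symbol `X`.
   Annotated sites are labelled $+1$; all other cysteines of annotated
   proteins are presumed negative ($-1$).
2. **Homology reduction.** Duplicate 21-mers are removed within each of the
   training and testing sets (first occurrence kept) and across them
   (training copy kept). See *Design choices* for why the window-level rule
   is applied unconditionally rather than only between proteins above the
   30 % identity threshold.
3. **Encoding.** Eight encoders map a fragment to a named numeric vector:
   one-hot binary ($21 \times 20 = 420$), amino-acid composition (21),
   amino-acid-pair composition ($21^2 = 441$), BLOSUM62 rows rescaled to
   $[0,1]$ (420), position weight matrix probabilities estimated from the
   positive training windows (21), a PSI-BLAST PSSM window squashed through
   the logistic function (420), solvent-accessibility and secondary-structure
   tracks (21 / 63), and per-position AAindex physicochemical values (21 per
   property). Hybrid features are concatenations.
4. **Property selection.** Each candidate AAindex property gets an F-score
   $$F_i = \frac{(\bar{x}_i^{(+)}-\bar{x}_i)^2 + (\bar{x}_i^{(-)}-\bar{x}_i)^2}
   {\frac{1}{n^+-1}\sum_k (x^{(+)}_{k,i}-\bar{x}_i^{(+)})^2 +
    \frac{1}{n^--1}\sum_k (x^{(-)}_{k,i}-\bar{x}_i^{(-)})^2}$$
   per window position, aggregated by the arithmetic mean. The top
   properties are re-ranked by single-feature cross-validated accuracy and
   appended to a base feature (typically the PSSM) by forward selection;
   the prefix with maximal cross-validated MCC wins.
5. **Classification.** A soft-margin SVM with RBF kernel
   $K(s_i, s_j) = e^{-\gamma\|s_i - s_j\|^2}$, features min-max scaled to
   $[-1,1]$ on the training data, $C$ and $\gamma$ chosen by grid search on
   cross-validated MCC. Evaluation uses stratified 5-fold cross-validation
   with confusion counts pooled over folds, plus an independent test on the
   held-out, homology-reduced set; metrics are Sn, Sp, Acc and MCC (MCC
   defined as 0 when a denominator factor vanishes).
6. **Composition analysis.** Position-specific residue frequencies and a
   two-sample-logo style per-cell enrichment test (two-sample $t$ on binary
   occurrence indicators; Fisher's exact available) compare fragment sets,
   e.g. positives vs negatives, or one PTM's sites vs another's.

# Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_n` | 10 | flank width; window = 2n+1 residues |
| `identity_threshold` | 0.3 | protein identity above which sequences count as homologous |
| `test_fraction` | 0.2 | per-class held-out fraction (the source data's own split ratio is not derivable, so this is a free parameter) |
| `C`, `gamma` | grid-searched | SVM cost and RBF width; default grid follows the usual exponential convention $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ |
| `class_weighting` | `"balanced"` | per-class penalty $C \cdot n/(2 n_c)$; real site data is ~1:7 imbalanced and an unweighted fit would not produce the near-equal Sn/Sp this method family reports; switchable to `"none"` |
| `cv_k`, `seed` | 5, user-set | folds and the master seed; every random step (split, folds) is seed-derived |
| `alpha` | 0.01 | per-cell significance level of the enrichment test, uncorrected by default (Bonferroni available) |
| `normalize` (AAindex) | `"zscore"` | standardize the 20 index values before positional encoding; `"raw"` reproduces the unnormalized variant |

# The synthetic data generator

`generate_dataset()` emulates the statistical structure reported for
S-sulfenylation neighbourhoods rather than any real proteome:

* **Composition.** Flank residues are drawn per position from a uniform
  background (1/20 each; uniform makes binomial tolerance bounds trivial).
  Positives receive additive probability boosts — K and R (+0.10 each) at
  positions −10, −8…−6, −4, −2, +4…+8 and E (+0.15) at −3, +1, +3, +4;
  negatives are tilted toward L/C/H/M/F/Y (+0.04 each at every flank
  position). Boosts are additive *exactly*: the boosted residue's
  probability is background + boost and only the residual mass is
  renormalized, so a boost of $b$ yields an expected frequency difference
  of $b$ against the other class.
* **Solvent accessibility.** Per-residue ASA percent is uniform on
  (20, 60) for negatives and shifted by `asa_shift` (default +0.2 on the
  0–1 scale) for positives — a flat elevated-exposure profile.
* **Informative physicochemical axis.** Positives' residual (non-boosted)
  probability mass is tilted by $e^{-\beta z_r}$ where $z_r$ are the
  standardized values of a hydropathy-style index and $\beta = 0.8$: the
  positive class prefers hydrophilic residues, mirroring the exposed
  character of sulfenylation substrates. The index ships as a
  synthetic-labelled AAindex entry (`SYNTH_HYDRO`).
* **PSSM profiles.** Each protein's profile column is the pseudocounted
  half-bit log-odds of (observed residue + 3 draws from a 70 % conserved /
  30 % background "homolog" distribution + 1 background pseudo-observation).
  The profile is therefore a stochastic recoding of the protein's own
  sequence: it carries real signal, but only through the sequence. We
  deliberately do **not** derive the profile from the class-conditional
  generating distribution — that variant hands the classifier the class
  label directly (a PSSM-only model saturates at MCC 1.0), which no real
  evolutionary profile of a PTM substrate does, and which would make any
  measured improvement from added features meaningless.

What a green test on this generator does *not* establish: performance on
real proteomes (real backgrounds are non-uniform, sites cluster on homologous
proteins, ASA and secondary structure come from imperfect predictors, and
real PSSMs encode family structure far richer than a mutated-copy model).
The generator's job is to verify that each stage recovers *known, planted*
structure at the right scale, not to forecast real-data accuracy.

# Numerical choices

* **PSSM squashing**: raw PSI-BLAST scores are unbounded; each score $s$
  maps through $1/(1+e^{-s})$ so all encoders emit comparable ranges before
  the model-level $[-1,1]$ scaling. Terminal-padding rows are all-zero.
* **BLOSUM62** rows are rescaled by the matrix's global min/max (−4, 11),
  so the W–W score maps to exactly 1.
* **X handling**: all-zero rows for binary/BLOSUM62/PSSM/tracks (the least
  informative choice), a 21st alphabet symbol for the composition features
  (AAC/AAPC/PWM, where the terminal signal is part of the model), and 0 —
  the standardized mean — for AAindex.
* **Scaler**: constant training features map to 0; test values are clipped
  to $[-1,1]$. The scaler is fitted strictly inside each CV fold.
* **SMO solver**: maximal-violating-pair working-set selection, stopping
  tolerance $10^{-3}$ (the LIBSVM default), kernel precomputed densely
  (training sets here are $\le$ a few thousand rows). Ties in the grid
  search resolve toward smaller $C$, then smaller $\gamma$.
* **F-score degeneracy**: zero numerator returns 0 even when the
  denominator is also 0; zero denominator with positive numerator returns
  the `+Inf` sentinel and sorts first with a warning.
* **Enrichment test**: the two-sample $t$ on 0/1 indicators is computed in
  closed form from the cell counts (Welch degrees of freedom); cells with
  zero variance in both sets get $p = 1$ when the frequencies agree and 0
  otherwise.

# Design choices where the design was open

* **Window-level homology reduction is unconditional.** The source
  procedure re-compares fragments only between proteins above the 30 %
  identity threshold, yet also requires the final train/test sets to share
  no fragment sequence. Two identical 21-mers are themselves stronger
  homology evidence than a 30 % full-length identity, so we deduplicate
  identical windows regardless of the protein-level score; this is the only
  reading that guarantees the disjointness invariant.
* **AAPC adjacency**: "pair composition" is read minimally as the 2n
  adjacent ordered pairs; the pair alphabet is $21^2$ and the encoding is
  configurable in principle but not extended to gapped pairs.
* **Positional F-score aggregation** is the arithmetic mean over the
  $2n+1$ positions (the source computes a value per position but never
  states the aggregate).
* **Forward selection** defaults to *cumulative* mode (every ranked
  candidate is retained, producing the familiar performance-vs-step curve);
  *greedy* mode (keep only improving candidates) is a switch. The reported
  best model is the MCC-maximal prefix in either mode; ties go to the
  smaller model.
* **Pooled vs averaged CV**: the single estimate is computed from counts
  summed over folds (micro-average); per-fold reports are returned
  alongside for macro-style summaries.
* **Decision threshold** is fixed at 0; no post-hoc threshold tuning.

# Known limitations

* The pairwise-identity homology screen is quadratic in the number of
  proteins and aimed at desk-scale datasets; no clustering shortcut
  (CD-HIT-style) is provided.
* The SMO implementation precomputes the dense kernel; memory grows as
  $O(n^2)$ and the practical limit is roughly $10^4$ training fragments.
* PSI-BLAST, ASA and secondary-structure predictors are consumed as files,
  never run; predictions requiring those encoders fail fast when the files
  are absent.
* Probability calibration, non-RBF kernels and ROC analysis are out of
  scope.
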