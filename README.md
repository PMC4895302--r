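# cysPTM

Sequence-based prediction of cysteine S-sulfenylation sites — and,
generically, of any cysteine-centered post-translational modification —
from protein sequence.

## The problem

S-sulfenylation reversibly oxidizes a cysteine thiol (Cys-SH) to sulfenic
acid (Cys-SOH) and regulates redox signalling, apoptosis and transcription.
Mapping which cysteines are modified is laboratory-expensive, so a
classifier that scores every cysteine of a protein from sequence alone is a
useful triage tool for proteomics groups. cysPTM implements the complete
supervised workflow: window extraction, homology reduction, eight feature
encodings, physicochemical-property selection, an RBF-kernel SVM with
cross-validation, and position-specific enrichment statistics. A synthetic
data generator with the documented compositional structure of
S-sulfenylation neighbourhoods makes every stage testable offline.

## The method in brief

Each candidate cysteine becomes a 2n+1-mer window (n = 10, termini padded
with `X`), encoded by any of: one-hot binary (420 dims), amino-acid
composition (21), amino-acid-pair composition (441), rescaled BLOSUM62 rows
(420), a position weight matrix from positive training windows (21), a
PSI-BLAST PSSM window squashed through the logistic (420), ASA /
secondary-structure tracks (21 / 63), and per-position AAindex
physicochemical values (21 per property).

Candidate properties are screened by the F-score

    F(i) = [ (x̄ᵢ⁺ − x̄ᵢ)² + (x̄ᵢ⁻ − x̄ᵢ)² ] /
           [ 1/(n⁺−1) Σₖ (xₖᵢ⁺ − x̄ᵢ⁺)²  +  1/(n⁻−1) Σₖ (xₖᵢ⁻ − x̄ᵢ⁻)² ]

ranked by single-feature cross-validated accuracy, and added to a base
feature by forward selection, keeping the prefix with maximal CV MCC.
Classification uses a soft-margin SVM with kernel K(sᵢ,sⱼ) = exp(−γ‖sᵢ−sⱼ‖²)
(features scaled to [−1,1]; C, γ grid-searched; the quadratic program is
solved by a sequential-minimal-optimisation routine in compiled code).
Performance is reported as Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = (TP+TN)/total and MCC, with counts pooled over stratified 5-fold CV
plus an independent homology-reduced test set.

## Worked example

```r
library(cysPTM)

# 1. Simulate a labelled dataset with the documented enrichment pattern
data_dir <- file.path(tempdir(), "demo")
d <- generate_dataset(synthetic_config(n_pos = 100, n_neg = 100, seed = 7))
paths <- write_synthetic_dataset(d, data_dir)

# 2. Train: PSSM encoding, 5-fold CV, small C grid
cfg <- run_config(fasta = paths$fasta, sites = paths$sites,
                  pssm_dir = paths$pssm_dir, encoders = "pssm",
                  test_fraction = 0.2, C_grid = c(1, 8), cv_k = 5,
                  seed = 42, out_dir = file.path(tempdir(), "run"))
res <- run_train(cfg)
print(res$cv)
print(res$independent)
```

```
[cysPTM] read 200 proteins, 200 site annotations
[cysPTM] extracted 404 labelled fragments (100 positive)
[cysPTM] after split + homology reduction: train 323, test 81
[cysPTM] encoded training matrix: 323 x 420
[cysPTM] grid search chose C = 1, gamma = 0.00238
[cysPTM] cross-validation: Sn = 0.950  Sp = 0.951  Acc = 0.950  MCC = 0.873  (TP 76, FP 12, TN 231, FN 4)
[cysPTM] independent test: Sn = 0.900  Sp = 0.902  Acc = 0.901  MCC = 0.757  (TP 18, FP 6, TN 55, FN 2)
Sn = 0.950  Sp = 0.951  Acc = 0.950  MCC = 0.873  (TP 76, FP 12, TN 231, FN 4)
Sn = 0.900  Sp = 0.902  Acc = 0.901  MCC = 0.757  (TP 18, FP 6, TN 55, FN 2)
```

200 synthetic proteins carry 404 cysteines (the annotated centre of each
window plus cysteines landing in flanks, presumed negative). After the
stratified 80/20 split and duplicate-window removal, 5-fold CV on the PSSM
encoding classifies held-out windows at MCC 0.87; the truly held-out test
set gives MCC 0.76 — lower, as expected for data never seen in selection.

```r
# 3. Which residues distinguish positives? (two-sample logo)
pos <- d$fragments[d$fragments$label == 1, ]
neg <- d$fragments[d$fragments$label == -1, ]
logo <- two_sample_logo(pos, neg, alpha = 0.01)
head(logo[order(logo$p_value), ], 5)
```

```
   position residue direction freq_a freq_b      p_value
31       -3       E  enriched   0.21   0.00 1.443920e-06
30       -3       C  depleted   0.00   0.16 3.408401e-05
48        4       E  enriched   0.24   0.04 4.135971e-05
12       -8       K  enriched   0.22   0.03 4.521699e-05
38        1       E  enriched   0.20   0.02 4.594511e-05
```

The planted pattern is recovered: glutamate enriched at −3/+1/+4, lysine at
−8, cysteine (a negative-class marker) depleted around the site.

```r
# 4. Score new proteins
preds <- run_predict(res$model, paths$fasta, pssm_dir = paths$pssm_dir)
head(preds, 3)
```

```
  protein_id position decision_value predicted_label
1  SPOS00001       11      0.8181914               1
2  SPOS00001       17     -0.4835098              -1
3  SPOS00002       11      1.0001582               1
```

One row per cysteine; `predicted_label` is the sign of the SVM decision
value.

The same workflow is available from the shell:

```sh
Rscript -e 'cysPTM::cli_main()' generate --out demo --n-pos 100 --n-neg 100 --seed 7
Rscript -e 'cysPTM::cli_main()' train --config config.json --out run
Rscript -e 'cysPTM::cli_main()' predict --model run/model.rds --fasta demo/proteins.fasta \
        --pssm-dir demo/pssm --out predictions.tsv
```

## Scope notes

PSI-BLAST, ASA predictors (RVP-Net-style) and secondary-structure predictors
(PSIPRED-style) are *consumed as files*, never run; functional-enrichment
analysis and database curation are out of scope. See
`vignettes/cysPTM-methods.Rmd` for the model details, parameter defaults and
design rationale.
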