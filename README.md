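# lbcleav

Dicer cuts each arm of a pre-miRNA hairpin at a defined position (CD-5p and
CD-3p), and where exactly it cuts is shaped by the loops and bulges of the
hairpin stem. `lbcleav` predicts these cleavage sites with an SVM over binary
encodings of short windows centered on candidate cut sites. Its core is a
**length-aware loop/bulge encoding**: a token for a nucleotide inside an
unpaired run of length *l* is written as a block of *k* ones at an
*l*-dependent offset in an (*M* + *k* + 3)-dimensional slot vector (*M* =
largest run length in the training data), so that two loop tokens satisfy

    x1 . x2     = max(k - |l1 - l2|, 0)
    ||x1-x2||^2 = 2 min(|l1 - l2|, k)

and an RBF kernel between them decays smoothly with the difference in loop
lengths, saturating at |l1 − l2| ≥ k. The classic per-nucleotide one-hot
patterns (sequence-only 4w, structure 8w, extended 10w with L as a fifth
symbol) are included for comparison.

The package is aimed at people studying miRNA biogenesis who have precursor
sequences, predicted secondary structures (dot-bracket), and mature-arm
annotations, and want to train, evaluate, and apply a cleavage-site
predictor — plus a synthetic hairpin generator with planted cleavage cues so
the whole pipeline is testable without external data.

## What it provides

* dot-bracket parsing, loop/bulge run annotation, apex detection, and
  complementary-strand resolution for windows (`parse_dotbracket()`,
  `annotate_loops()`, `find_apex()`, `complementary_segment()`)
* positive/negative window construction around annotated cleavage sites,
  with the 6-nt negative offset rule (`make_windows()`)
* the four binary encodings and closed-form loop-kernel oracles
  (`encoding_scheme()`, `encode_windows()`, `loop_dot()`, `loop_sqdist()`)
* RBF-SVM training and fivefold precursor-split cross-validation with
  Sn/Sp/Ac/MCC, per-fold variance, and pooled ROC/AUC (`cleav_fit()`,
  `cross_validate()`, plus `tidy()`/`glance()`/`autoplot()` methods)
* a shift-window scanner that scores every site and calls CD-5p/CD-3p by
  arm-wise arg-max, with cumulative end-absolute-error (EAE) reporting
  (`cleav_fit_arms()`, `scan_precursor()`, `predict_sites()`,
  `eae_profile()`)
* a seeded synthetic hairpin generator with loop-length and sequence-motif
  cleavage cues (`generate_dataset()`), file loaders/writers (FASTA, Vienna
  dot-bracket, annotation TSV, SVM-light features), and a command-line
  script (`inst/scripts/lbcleav`) with `simulate` / `encode` / `train` /
  `eval` / `scan` subcommands.

## Worked example

```r
library(lbcleav)

# 120 synthetic hairpins; a 3-nt bulge ending at the true cut is planted
# with probability 0.9 per arm
ds  <- generate_dataset(synth_params(n_precursors = 120,
                                     signal_strength = 0.9, seed = 42))
win <- make_windows(ds, w = 10)          # positive + negative windows per arm
win[1:4, c("id", "arm", "label", "center", "arm_tokens")]
#> # A tibble: 4 × 5
#>   id         arm   label center arm_tokens
#>   <chr>      <chr> <int>  <int> <chr>
#> 1 synth-0001 5p        1     21 L3 U L3 L3 L3 G G U U U
#> 2 synth-0001 5p       -1     27 G U U U L1 U A A A G
#> 3 synth-0001 3p        1     77 U A A A A L3 L3 L3 C L1
#> 4 synth-0001 3p       -1     71 G C U L2 L2 U U A A A

cv <- cross_validate(win, encoding_scheme("lbsize", w = 10, k = 3), seed = 42)
glance(cv)
#> # A tibble: 2 × 11
#>   arm      sn    sp    ac   mcc   var_sn   var_sp   var_ac  var_mcc   auc folds
#>   <chr> <dbl> <dbl> <dbl> <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <dbl> <int>
#> 1 3p    0.917 0.983 0.95  0.902 0.000868 0.000521 0.000564 0.00223  0.957     5
#> 2 5p    0.933 0.983 0.958 0.919 0.00226  0.000521 0.000217 0.000749 0.974     5

model <- cleav_fit_arms(win, encoding_scheme("lbsize", w = 10, k = 3))
scan  <- scan_precursor(model, ds$seq[1], ds$db[1], id = ds$id[1])
scan
#> <cleav_scan> 89 sites (synth-0001)
#> # A tibble: 2 × 3
#>   arm    site score
#>   <chr> <int> <dbl>
#> 1 5p       21  1.01
#> 2 3p       77  1.00
ds[1, c("cd5p", "cd3p")]   # planted truth: 21 and 77 — both recovered
```

Reading the output: the tokens `L3 L3 L3` just before the positive centers
are the planted loop-length cue; the per-arm lines of `glance(cv)` are the
fivefold means (`sn`, `sp`, `ac`, `mcc`), their fold variances, and the
pooled AUC — here the loop-length encoding separates positives from
negatives with ~95% accuracy; the scan arg-max recovers both planted cut
sites exactly. `autoplot(cv)`, `autoplot(cv$roc[["5p"]])` and
`autoplot(scan)` plot the per-fold metrics, the ROC curve and the score
profile.

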