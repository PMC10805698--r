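---
title: "Attention-based multiple instance learning for somatic mutation sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple instance learning for somatic mutation sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatic mutation data are labelled at the *sample* level — a tumour has a
type, a microsatellite status, a treatment response — while the measurements
are individual mutations, of which a sample may carry tens to hundreds of
thousands. Conventional pipelines collapse each sample to a fixed-length
vector (for example a count over the 96 trinucleotide substitution
contexts) before any learning happens, which weights every mutation equally
and fixes the featurization in advance.

`mutmil` treats a sample as a **bag** of mutation **instances** — the
multiple instance learning (MIL) setting — and learns, end to end:

1. an **instance encoder** over "genomic concepts" (local sequence context,
   SBS96 category, genomic position bin, gene identity, reading frame);
2. a per-instance, per-head **attention weight** in (0, 1);
3. a permutation-invariant **aggregation** of attended instance features
   into a sample vector;
4. a classifier head on that vector.

Because attention is explicit, the fitted model *explains itself*: the
high-attention instances of a class are the mutations the model considers
salient, and their sequence logos expose the motifs it has learned.

## Model

### Adaptive activations

Three smooth activation functions with trainable curvature are used
throughout, all built on the adaptive square root

$$\mathrm{ASR}(x,\alpha)=\sqrt{e^{\alpha}+x^{2}},$$

a smooth envelope of $|x|$. The adaptive rectifier is
$\mathrm{ARU}(x,\alpha)=\tfrac12\,(x+\mathrm{ASR}(x,\alpha))$ — strictly
positive, strictly above $\mathrm{ReLU}(x)$, and converging to ReLU as
$\alpha\to-\infty$ — and the adaptive sigmoid is

$$\mathrm{ASU}(x,\alpha_l,\alpha_u)=
\frac{x+\mathrm{ASR}(x,\alpha_l)}{\mathrm{ASR}(x,\alpha_l)+\mathrm{ASR}(x,\alpha_u)}
\in(0,1).$$

The input enters only through $x^2$, never as $e^x$, so the units cannot
overflow inside the large sums a MIL aggregation produces. Defaults are
chosen so that at $x=0$ ARU matches softplus in value
($\alpha_0=2\log(2\log 2)$; the slope is $1/2$ for every $\alpha$) and ASU
matches the logistic function in both value and slope
($\alpha_l=\alpha_u=2\log 2$). The $\alpha$ parameters are trained per
unit.

### Attention and aggregation

Instance features $h_i$ (encoder output) yield per-head attention
$a_{ik}=\mathrm{ASU}(w_k^{\top}h_i+c_k)$. Three aggregations are
available:

* **mean** — per head, $\sum_i a_{ik}h_i / \sum_i a_{ik}$: a weighted
  average, insensitive to bag size;
* **sum** — per head, $\log(1+\sum_i a_{ik}h_i)$ elementwise: the log
  tames the potentially large totals, and because instance features are
  activated (non-negative) the sum is monotone — bag size and key-instance
  *counts* remain visible to the head. `log1p` keeps absent features
  exactly neutral;
* **dynamic** — a first single-head weighted mean is broadcast back to
  every instance, a second attention is computed from the instance
  features concatenated with that sample vector, and the final aggregation
  uses the second attention. This lets attention itself depend on bag
  context.

Head vectors are concatenated (with any per-sample covariates) and passed
to a dense head; multiclass models end in a softmax, binary models in a
single ASU-squashed logit. With one head per class, heads behave as
class-specific attention.

An L1 activity penalty on the attention output (`attention_l1`, default
0.05 in the pipeline configs) pushes background instances toward zero
attention. Without it, attention confounds importance with rarity; with
it, key and background instances separate cleanly (the presence-task test
measures exactly this).

### MIL instance dropout

At every gradient update each bag is subsampled to
$\lceil(1-\mathrm{rate})\,n\rceil$ instances (never below 1); evaluation
always uses all instances. This is simultaneously a memory control and a
strong data augmentation, since every epoch sees different versions of
each sample.

### Ragged batching

Bags are stored as one instance matrix plus an integer bag index; every
reduction is segment-wise (`rowsum`). Nothing is ever padded to the
largest bag, so memory scales with the number of instances, not
`max bag size * n_bags`.

### Training

Class-weighted cross-entropy (weights $n/(C\,n_c)$, i.e. inverse class
frequency with sample-weighted mean 1) plus the attention L1 and weight
L2 penalties, minimized by Adam over stratified mini-batches of bags
(proportional class representation per batch, reshuffled every epoch).
Early stopping monitors validation weighted cross-entropy. All gradients
are derived by hand and pinned against central finite differences in the
test suite (relative error below $10^{-4}$ across every architecture
variant: mean/sum/dynamic aggregation, ARU/ReLU/conv encoders, softmax
and ASU heads, sample covariates, both penalties).

## Genomic concepts

* **Sequence concept**: four width-$W$ arrays over \{A, C, G, T, PAD\} —
  5' flank, reference allele, alternate allele, 3' flank — in both the
  forward and reverse-complement orientation. Flanks are proximal-aligned
  (the mutation-adjacent base sits at a fixed index, PAD fills the distal
  end) so convolutional kernels see the variant at a stable offset.
  $W=6$ for classification-scale context, $W=20$ for repeat-sensitive
  tasks.
* **SBS96**: the 96 pyrimidine-centred substitution contexts in the
  conventional signature ordering (C>A, C>G, C>T, T>A, T>C, T>G; flanks
  lexicographic), plus a 97th outgroup so that indels, multi-base
  substitutions and ambiguous contexts are never discarded. Indices are
  0-based (0–95, outgroup 96).
* **Position bin**: chromosomes laid end to end;
  `floor((offset + pos - 1) / bin_size)` with 1 Mb as the canonical bin
  size.
* **Gene**: alphabetically sorted vocabulary with a terminal OTHER
  category, so the mapping is independent of training-fold order.
* **Reading frame**: strand plus CDS position modulo 3, one-hot (5
  columns); noncoding variants are the zero vector.

The sequence encoder gives each component block 8 independent kernels:
shared-weight 1-D convolutions of width 6 positions with ARU activation
and global max pooling. Weight sharing is what lets a kernel recognize a
homopolymer run regardless of its offset within the flank; a block-dense
variant (`kernel_type = "dense"`) is available but generalizes poorly on
repeat-detection tasks, which is visible in its test AUC.

## MAF processing

Records are read from tab-delimited MAF-style tables under a configurable
column dialect (MC3 names or minimal canonical names). Filtering follows
the retention rules for such call sets: a record is kept iff its FILTER
flags are a subset of the allowed set (so combinations of allowed flags
pass), and optionally iff it falls entirely within coverage intervals
(BED, 0-based half-open; insertions use their 1-bp anchor).

Consecutive same-sample SBS calls (adjacent positions on one chromosome)
are merged into a single multi-nucleotide record when the read counts
agree by **any** of: max deviation of any alt/ref count from the run mean
below 5 reads; that deviation below 5% of the mean; or max pairwise VAF
difference below 5%. All three tolerances are arguments. Merged counts
are run means rounded half-up — any monotone summary would do; the mean
is symmetric and keeps the merged evidence inside the constituents'
range. Merging is idempotent because a merged record is no longer an SBS.

## The synthetic task suite

The generators give every module a desk-scale test surface and are
first-class, deterministic functions of a `task_spec` (seeded). They are
*analogs* probing the axes the model design cares about, not replications
of any dataset:

* **presence** — positive bags plant a key categorical code at the
  witness rate (default conditions for the benchmark: 500 training / 200
  test bags of 50–100 instances, witness rate 0.05). Tests demand
  held-out AUC ≥ 0.95 (mean over 3 seeds) *and* higher median attention
  on key instances in every seed.
* **count** — the label is whether the absolute number of key instances
  exceeds a threshold, with bag size varying independently so the key
  *fraction* is uninformative. This is where log-sum aggregation must
  beat the weighted mean (asserted as 4 of 5 paired seeds).
* **context** — a key code matters only when a marker code co-occurs.
  Negative finding, stated plainly: at this scale both dynamic and
  static-mean models solve the task (~100% accuracy), because the
  nonlinear head can compose the two presence signals after aggregation.
  The dynamic path is therefore validated mechanically (gradient check,
  permutation invariance through both rounds, trainability) rather than
  by an accuracy gap.
* **repeat_indel** — the microsatellite-instability analog: positives are
  enriched for 1-bp deletions inside planted mononucleotide runs (length
  5–15) in 20-nt concepts; background instances are SBSs and non-repeat
  deletions (windows with any run ≥ 5 are rejected, so the planted runs
  are the only separating signal). Ground-truth key flags are retained;
  an independent oracle (run-length encoding of the window) reproduces
  them exactly in tests.
* **consequence** — a toy genome of random single-exon ORFs on both
  strands; variants are labelled by a brute-force oracle over the
  standard genetic code into frameshift/in-frame indels, missense,
  nonsense, silent and noncoding. With the reading-frame feature a dense
  encoder reaches ≥ 0.9 macro-recall on missense/nonsense/silent; without
  it those three classes stay confusable while the indel classes remain
  learnable — the directional claim the tests assert. There is no splice
  class: single-exon ORFs have no splice sites.

One generator (`write_presence_maf_task()`) emits FASTA + MAF + labels
files, so the entire real-data path — `read_maf()` →
`filter_by_flags()` → `merge_consecutive_snvs()` → `sbs96_index()` →
bags → model — is exercised end to end on synthetic data by the pipeline
tests.

What the generators do **not** emulate: realistic trinucleotide
background frequencies, mutational-signature mixtures, copy-number or
purity effects, caller-specific artifacts, or bags of 10^5 instances.
Passing these tests shows the machinery is correct and the architecture
can discover planted structure at desk scale; it does not certify
performance on real tumour cohorts.

## Interpretability

* `attention_weights()` returns the per-instance, per-head attention used
  for the final aggregation.
* `attention_zscores()` standardizes a feature-by-head attention table
  per head (mean 0, sd 1 across features), averages over heads and then
  over cross-validation folds; zero-variance heads contribute 0 with a
  warning. The result is invariant to per-head affine rescaling.
* `top_attention()` takes the top `ceiling(frac * n)` instances of a head
  (default 5%), ties broken by stable input order.
* `cluster_instances()` k-means (unit-variance scaling by default, raw as
  a flag) with clusters relabelled in descending median-attention order.
* `logo_matrix()` builds position probability matrices over the
  5' | allele | 3' layout, excluding PAD from each column's denominator,
  separately per variant class; `information_bits()` reports
  $2-H(p)$ bits per position. These bits are a lower bound on the motif
  information when one head attends to several distinct motifs; that
  caveat travels in the PPM object's metadata rather than being
  corrected for.

## Numerical and design choices

* **Seeds.** Every stochastic component (initialization, batching,
  instance dropout, generators, k-means) is driven by an explicit seed;
  training is bit-reproducible on CPU.
* **Attention normalization.** Mean mode divides by the per-bag attention
  total (a weighted average); sum mode uses raw ASU weights so totals
  stay informative.
* **L2 scope.** Weight decay applies to dense/conv weight matrices, not
  to biases, curvature parameters or attention weights (decaying
  attention weights toward zero fights the L1's separating pressure).
* **Empty bags** error at evaluation; instance dropout can never create
  one (floor of 1 instance).
* **Degenerate merges.** A zero mean count makes the percentage criterion
  fail unless the deviation is exactly zero; a zero-depth variant makes
  the VAF criterion fail.
* **Reference binary architecture.** `msi_reference_config()` ships a
  named reference stack for repeat-detection tasks: 8 ARU kernels per sequence
  component, 128-wide ReLU fuse with 0.01 L2, dropout 0.5, single ASU
  attention head with 0.05 L1, log-sum aggregation, 256/128 ReLU head
  with 0.5 dropout, instance dropout 0.4. That regularization budget is
  calibrated to cohort-scale data (~10^5 instances); with a few hundred
  bags it reliably collapses to the trivial constant solution (dead ReLU
  fuse units cannot recover, and the dropout noise dominates the
  gradient). The desk-scale tests therefore override to an ARU fuse —
  whose gradient is everywhere positive, eliminating the dead-unit
  failure mode — no hidden dropout, no L2 and instance dropout 0.2,
  keeping the rest of the stack. Measured this way the repeat-indel AUC
  is 0.94–0.98 across generation seeds.
* **Problem sizes.** The shipped tests and the acceptance script use 500
  training bags for the bag tasks, 2 000 instances per class for the
  consequence task and 80-epoch budgets — sizes at which every benchmark
  is stable yet the whole suite runs in minutes on one CPU.

## Known limitations

* The hand-written numeric core is plain BLAS-backed R; it is meant for
  desk-scale experiments (10^4–10^5 instances), not cohort-scale GPU
  training.
* VCF input is not parsed (MAF only); WIG coverage files are generalized
  to BED intervals.
* Multiclass attention heads share a joint softmax head; per-head
  one-vs-rest readout is not implemented.
* The dynamic-attention advantage over static attention, where it exists,
  is not demonstrable at this scale (see the context task above).
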