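---
title: "Concept embeddings from co-occurrence matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept embeddings from co-occurrence matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptCooc)
```

## The problem

Clinical data are multimodal: the same medical concept surfaces as a
phrase in a journal article, a term in a clinical note, and a billing
code in a claims table. Embedding methods built for text (word2vec,
GloVe) cannot consume billing codes directly — but both methods reduce,
analytically, to the factorization of a term–term co-occurrence matrix.
That reduction is the organizing idea of this package: map every source
into a common concept-identifier (CUI) space, count concept
co-occurrences with a source-appropriate rule, sum the counts into one
master matrix, and factorize that matrix. Any data source that can
produce pairwise co-occurrence counts can then contribute to a single
embedding space.

## Normalization: from raw text to concept tokens

Multi-word concepts must become single tokens before windows are
counted. `normalizeText()` lowercases, strips punctuation (every
non-alphanumeric character except intra-token hyphens is a separator;
digits survive as tokens), and replaces dictionary phrases with their
CUIs by a left-to-right greedy longest-match scan: at each position the
longest matching phrase wins and the scan resumes after it. Industrial
concept recognizers resolve overlapping mentions with richer machinery;
greedy longest-match is the transparent, deterministic baseline, and
with an adequate dictionary it reproduces reference normalizations
token for token:

```{r normalize}
dict <- conceptDictionary(
  c("bronchopulmonary dysplasia", "lung", "injury", "preterm infant",
    "resulting from", "oxygen", "mechanical ventilation"),
  c("C0006287", "C0024109", "C3263722", "C0021294", "C0678226",
    "C0030054", "C0199470"))
normalizeText(paste(
  "Bronchopulmonary Dysplasia was first described by Northway and",
  "colleagues in 1967 as a lung injury in a preterm infant resulting",
  "from oxygen and mechanical ventilation."), dict)
```

Tokens already shaped like CUIs pass through verbatim, so a corpus that
was normalized elsewhere can be re-ingested. Token streams are then
`chunkWindows()`-ed into consecutive *non-overlapping* windows of
`L = 10` tokens (chunked, not sliding — each token belongs to exactly
one window; the final window may be shorter).

## Counting co-occurrences

Three counting rules, one symmetric zero-diagonal integer matrix
(`CoocMatrix`) each:

* **Text** (`textCooccurrence()`): each unordered pair of distinct
  concepts co-present in a window gains one count — once per window
  regardless of token multiplicity. We count *presence*, not token
  products (a `multiplicity = "product"` switch exists for sensitivity
  checks).
* **Claims-style events** (`temporalCooccurrence(mode = "rolling")`): a
  pair counts once per patient if any two of that patient's events
  carrying the two CUIs lie within `spanDays = 30` days of each other.
  Once-per-patient is the conservative reading of "the number of
  patients in which two codes appear in any 30-day period".
* **Notes-style events** (`mode = "calendar"`): days are cut into fixed
  30-day bins anchored at each patient's first event (per-patient
  anchoring is a documented choice; nothing in the counting depends on
  calendar dates), and a pair counts when both CUIs fall in one bin.
  By default this, too, is recorded once per patient, which makes the
  rolling count a cell-wise upper bound of the calendar count (any
  same-bin pair is within the span); `perPeriod = TRUE` switches to
  once-per-(patient, bin) multiplicity.

`mergeCooccurrence()` aligns vocabularies (sorted union — sorting makes
merged artifacts byte-stable across platforms) and sums cell-wise.
Self co-occurrence is excluded everywhere: the diagonal carries no
information any benchmark here could use.

## SPPMI + SVD ("word2vec-style") embeddings

Skip-gram with negative sampling implicitly factorizes a shifted
positive pointwise-mutual-information matrix, so we factorize that
matrix directly. On every nonzero cell of the count matrix (natural
log throughout; the shift is `log k`, so the log base merely rescales):

$$\mathrm{PMI}(w,c) = \log\frac{p(w,c)}{p_\alpha(w)\,p_\alpha(c)},
\qquad
\mathrm{SPPMI}(w,c) = \max\bigl(\mathrm{PMI}(w,c) - \log k,\, 0\bigr).$$

Conventions, stated exactly because dialects differ:

* $p(w,c)$ = pair count divided by the total number of co-occurrence
  *events* $N$ (the sum of the upper triangle); summed over unordered
  pairs, the joint probabilities add to one.
* $p(w)$ = the concept's *participation* (row sum) divided by the total
  participation $2N$. Margins come from the co-occurrence matrix
  itself, not from raw corpus token counts — the only definition that
  survives merging across sources.
* Smoothing: each margin is raised to `alpha = 0.75` and the powered
  margins renormalized to sum to one. The matrix is symmetric, so the
  "word" and "context" margins coincide and both are smoothed.
* `k = 1` by default — no shift, just the positive clip. Cells clipped
  to zero are dropped from sparse storage; zero is also the implicit
  value, so the factorization is unchanged.

The truncated SVD $X \approx U_d \Sigma_d V_d^\top$ then yields word
vectors $\tilde W = U_d \Sigma_d^{p}$, context vectors
$\tilde C = V_d \Sigma_d^{p}$, and the released embedding
$W = \tilde W + \tilde C$. The exponent defaults to $p = 0.5$ — the
symmetric split of the singular values between the two factors, which
is what "symmetrically scaled" means in the factorization literature;
$p = 1$ (all scale on the word side) is one argument away
(`sigmaPower`). At $p = 0.5$ and full rank,
$\tilde W \tilde C^\top$ reconstructs the SPPMI matrix exactly, which
the tests assert to $10^{-8}$.

The SVD itself is computed densely by LAPACK (`svd()`), exact and
deterministic, then truncated to rank `d`. At the vocabulary sizes this
package targets (hundreds to a few thousand concepts) the dense
decomposition takes seconds; iterative Lanczos solvers only pay off
orders of magnitude beyond that.

`pcaEmbeddings()` is the baseline: the same truncated SVD applied to
the *raw* counts, embedding $U_d \Sigma_d$.

## GloVe embeddings

`trainGlove()` minimizes the weighted least-squares objective over
nonzero cells (zero cells are excluded: their weight is zero and
$\log 0$ undefined),

$$\sum_{(w,c):\,y_{wc}>0} f(y_{wc})
 \bigl(\vec w \cdot \vec c + b_w + b_c - \log y_{wc}\bigr)^2,
\qquad
f(y) = \begin{cases}(y/y_{\max})^{\alpha} & y < y_{\max}\\ 1 &
y \ge y_{\max}\end{cases}$$

with $y_{\max} = 100$ and $\alpha = 0.75$. Choices the objective alone
does not fix:

* **Optimizer**: per-parameter adaptive gradient (AdaGrad), the
  canonical GloVe choice, base step 0.05, accumulators initialized at
  one. Each epoch visits every nonzero unordered cell once in a
  freshly shuffled order and applies both orientations' updates
  (the symmetric matrix is stored once; updating both orientations per
  visit matches the full-sum objective without double counting).
* **Initialization**: all parameters uniform on $(-0.5/d,\, 0.5/d)$,
  seeded; biases included.
* **Determinism**: single-threaded; identical seeds give bit-identical
  models. The released embedding is $\vec w + \vec c$ row-wise.

Epochs and learning rate have no reference values; 30–50 epochs at the
default rate drive toy problems to their attainable zero-loss solutions
(asserted in the tests) and descend monotonically in practice on
larger ones.

## The bootstrap power benchmark

Ranking metrics penalize embeddings for ranking *unlisted* true
relationships above listed ones. The benchmark here asks a calibrated
question instead: *what fraction of known related pairs score above
chance for their kind?*

For a known pair $(x, y)$, `relationshipPower()` builds a null
distribution of cosine similarities from `n = 10000` bootstrap draws:
one concept sampled with replacement from $x$'s category, one from
$y$'s (redrawing identical twins — a concept paired with itself has
cosine 1 by construction), cosine recorded. The pair is *discovered*
iff its observed cosine **strictly** exceeds the empirical 95th
percentile of its null, taken as the order statistic at
$\lceil(1-\mathrm{level})\,n\rceil$ of the sorted samples — stated
explicitly because quantile conventions differ; ties at the threshold
are non-discoveries. Power is the discovered fraction of evaluable
pairs; pairs with an unembedded concept are dropped and reported via
`nTotal - nEvaluable`.

Null distributions are cached per unordered category pair within a
call (10,000 draws per category pair, not per relationship): the
benchmark's meaning is unchanged and the cost drops by orders of
magnitude. For the same-semantic-type benchmark the null must instead
mix categories — `nullMode = "marginal"` draws both concepts from the
pooled vocabulary subject to their categories differing.

Calibration is the design invariant: feed the benchmark random
category-matched pairs with no planted signal and measured power must
sit near the 5% level — the tests hold it inside [0.035, 0.065], the
99% binomial band at 1,000 pairs. `humanSimilarityCorrelation()`
covers the remaining benchmark family: Spearman rank correlation
(average-rank ties) between mean human similarity scores and embedding
cosines; fewer than three evaluable pairs, or all-tied scores, are
errors rather than numbers.

## The synthetic study data

Real claims tables, clinical notes and licensed vocabularies cannot
ship with a package. The generators in `syntheticSpec()` /
`generateThesaurus()` / `generateCorpus()` / `generateEventStream()`
produce structurally faithful stand-ins with *known* ground truth, so
recovery is measurable:

* **Thesaurus**: 100 synthetic CUIs (`C9xxxxxx`) in 4 semantic-type
  clusters; 1–3-token surface phrases, each opening with a
  concept-unique head word so greedy longest-match inverts the
  rendering exactly.
* **Corpus**: 240 documents of 100 tokens, built window-aligned in
  normalized token space (10 blocks of 10), then rendered to raw text
  by phrase expansion, an initial capital and a terminal period. Each
  slot is a concept with probability 0.3 (drawn from the block's theme
  cluster with probability 0.8, else uniformly) or a background word
  from a Zipf-like distribution (exponent 1.1, 200 word types) —
  heavy-tailed margins being the one statistical feature of natural
  text the counting pipeline is sensitive to.
* **Planted pairs**: 20 within-cluster, concept-disjoint pairs; when
  the first member lands in a window, the partner is co-inserted into
  that window with probability $\lambda$ (default 0.9). $\lambda$ is
  the effect size: at 1 every window containing *a* contains *b*; at 0
  the pair co-occurs at the background rate.
* **Events**: 2,000 patients, 20 background events each, uniform days
  over a two-year horizon (only the relative ≤ 30-day structure
  matters downstream). Per planted pair and patient: with probability
  0.25 the patient carries the index concept, and the partner lands
  within 30 days with probability $\lambda$, else far away (> 60
  days) — so the within-period co-occurrence rate among carriers is
  $\lambda$ in expectation, which the tests verify to ±0.05 at
  $\lambda = 0.5$.

What the generator does **not** emulate: real UMLS semantic-type
hierarchy depth, polysemous surface forms, abbreviations and negation,
visit-level temporal autocorrelation, and billing-code idiosyncrasies.
Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct and calibrated — not that any particular clinical
corpus will yield embeddings of a particular quality.

## End-to-end recovery, and the problem sizes the tests use

The headline test runs the whole chain — generate, normalize, window,
count, SPPMI, SVD at $d = 50$, benchmark — and requires power ≥ 0.8 on
pairs planted at $\lambda = 0.9$ while 1,000 random category-matched
pairs on the *same* embeddings stay inside the calibration band.
Monotonicity (power at $\lambda = 0.8$ ≥ power at $\lambda = 0.4$) is
checked with 48 planted pairs — the cluster capacity of the
100-concept study — because at 20 pairs the binomial noise
(±0.09) would dominate the comparison. Unit tests run on matrices of
order 5–50; the PMI and GloVe-loss implementations are checked against
dense brute-force oracles to $10^{-10}$; the calibration tests use
500 Gaussian concepts at $d = 50$ with 10,000 null draws. All
randomness flows from fixed seeds; the whole suite is deterministic.

## Degenerate inputs and numerical conventions

* An all-zero count matrix is an error for PMI and GloVe (nothing to
  normalize or fit), while empty text/event streams yield legitimate
  all-zero count matrices.
* A zero embedding vector is an error wherever a cosine is needed — it
  has no direction.
* A bootstrap category with fewer than two embedded concepts is a
  degenerate null and an error, as is a marginal null over a single
  category.
* SPPMI storage drops exact zeros (`drop0`); symmetry is validated at
  construction to zero tolerance for counts and $10^{-12}$ for reals.
* Embedding text formats print 12 significant digits; round-trips are
  asserted below $10^{-10}$.

## Limitations

Dictionary-based normalization knows nothing of word sense, negation
or abbreviation; the dense SVD bounds practical vocabularies to a few
thousand concepts on one machine; GloVe training in R is single-thread
and O(cells × epochs × d); and the benchmark measures discovery
relative to category-matched chance, which depends on the supplied
category map being meaningful. None of these affect the method's
definitions — they bound the scale and the interpretation.
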