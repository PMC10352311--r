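---
title: "Methods: similarity-based teratogenicity ranking and knowledge-graph clique mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based teratogenicity ranking and knowledge-graph clique mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teratorank)
```

## The problem

Most small molecules — including the tens of thousands of preclinical
compounds profiled in perturbational transcriptomics screens — have never
been assessed for reproductive toxicity: whether they cross the placental
barrier, and whether they belong with the FDA pregnancy categories D and X
(evidence of fetal risk; X contraindicated). Direct experimental assessment
at that scale is impossible, but two kinds of compound-level feature spaces
are available for essentially every compound: the transcriptomic signature it
induces in cell lines, and its chemical structure. `teratorank` ranks all
compounds in such a collection by their similarity to the small labeled sets
of known positives, evaluates those rankings honestly with held-out labels,
and embeds the results in a typed birth-defect/gene/drug knowledge graph
where three-node cliques propose mechanistic hypotheses (a drug perturbs a
gene whose disruption is known to cause the same defect the drug is
associated with).

## Drug–drug similarity

**Expression.** Each drug's per-condition differential-expression vectors
(characteristic-direction coefficients over a common gene axis) are collapsed
to a consensus by the unweighted element-wise mean across all profiled
conditions (`consensus_signature()`); we deliberately do not stratify by cell
line, trading context specificity for a single comparable vector per drug.
The drug–drug matrix is then the cosine similarity between consensus
vectors:

$$S_{ij} = \frac{\langle v_i, v_j\rangle}{\lVert v_i\rVert\,\lVert v_j\rVert}.$$

A drug whose consensus is identically zero has no direction; rather than
propagate NaNs we set its row, column and diagonal entry to 0, flag it
(attribute `zero_rows`, with a warning), and exclude it from meaningful
ranking. For the knowledge graph we also retain each drug's top `k = 25` up-
and down-regulated genes (`top_k_genes()`): a pure order statistic on the
coefficients, ties broken by ascending gene id over one full ordering so the
two sets can never overlap, zeros eligible like any other value. Keeping only
25 genes per direction bounds the graph size at the cost of discarding
weaker but real effects.

**Structure.** SMILES are hashed into binary circular (Morgan-family)
fingerprints. The backend is OpenBabel's ECFP implementation (via
ChemmineR/ChemmineOB), with `ECFP<2·radius>` computed at its native 4096
bits and folded in halves down to the default 2048 bits; radius 2
(ECFP4-equivalent) is the community default. Bit patterns from other ECFP
implementations will differ in the individual hash positions while sharing
the family's statistical behavior; all downstream similarity operations see
only the binary matrix. Molecules without at least one bond cannot be
fingerprinted by this backend; unparseable records are dropped per record
with a warning and the batch continues.

Plain Tanimoto similarity over hashed fingerprints is biased toward large,
feature-rich molecules whose fingerprints share many common bits. We
therefore weight each bit by its inverse document frequency before taking
cosines:

$$\mathrm{idf}_j = \ln\frac{N}{\mathrm{df}_j},\qquad
  S_{ij} = \cos\!\left(b_i \odot \mathrm{idf},\; b_j \odot \mathrm{idf}\right),$$

where $\mathrm{df}_j$ counts the compounds with bit $j$ set. Bits set in
every compound get weight exactly 0 ($\ln 1$), so ubiquitous substructures
carry no information — the matrix is invariant to appending an all-ones bit
column. Bits set in no compound are also weighted 0 to avoid infinities. A
smoothed variant $\ln(N/(1+\mathrm{df}))$ (floored at 0) is available behind
`variant = "smoothed"`; the plain form is the default because it has the
exact ubiquity-invariance property. `tanimoto_matrix()` is kept as the
comparison baseline. We store *similarities* (higher = closer) throughout,
because the ranking step rewards proximity to positives.

## Semi-supervised scoring

Given a similarity matrix $S$ and a set $P$ of labeled positives, every drug
is scored by its mean similarity to the positives, excluding itself:

$$\mathrm{score}_i = \frac{1}{|P \setminus \{i\}|}\sum_{p \in P \setminus \{i\}} S_{ip}.$$

Removing the diagonal matters: a positive would otherwise import its own
perfect self-similarity and trivially float to the top. Positives keep a
score (their similarity to the *other* positives) so that known drugs appear
in the ranked output alongside novel candidates. A sole positive scoring
itself has no peers; its score is undefined (`NA`) and it ranks last.
Ranking is descending (rank 1 = most similar), ties broken by ascending drug
id, undefined scores after all defined ones — every ranking the package
produces is bit-reproducible.

**Aggregation.** Two combiners merge the expression- and structure-based
rankings. *Top Rank* takes each drug's best rank across the inputs; it is
order-based, parameter-free and robust to the two scores living on different
scales. The *weighted* combiner learns one global weight per modality (plus
a bias) on a pre-task: one-vs-rest classification of drugs into
mechanism-of-action (MOA) classes with at least 10 members, using the same
SSL scores (per task) as features. The model is
$p = \sigma(w^\top z + b)$ on per-modality z-scored features, trained with
binary cross-entropy weighted by inverse class frequency (the positive class
is rare), optimized with Adam (learning rate 0.01, 500 full-batch epochs —
the optimizer family is part of the method; the hyperparameters are fixed
package defaults), and the whole fit is repeated 10 times with reshuffled
row order and re-initialized parameters; the reported weights are the mean
over repeats, with per-repeat final losses kept in `training_log` so the
variance across repeats is inspectable. We use the *population* z-score
(divisor $n$) consistently in training and application; with two drugs the
z-scores of $(1,-1)$ are then exactly $(1,-1)$, which keeps hand-worked
sigmoid examples exact. Weights are global, not per-MOA: per-task weights
could not be transferred to the placental-crossing and category-D/X sets.

## Evaluation: bridge plots and the permutation-normalized NES

To evaluate a ranking against held-out positives we use a
Kolmogorov–Smirnov-like random walk ("bridge plot"): walking the ranked list
from top to bottom, the running sum steps up $1/|P|$ at a positive and down
$1/(N-|P|)$ otherwise, so it starts and ends at zero. The enrichment score
is the maximum prefix value of the walk (the empty prefix counts, so
$ES \in [0,1]$). This one-sided definition rewards positives at the leading
edge, which is where predictions are consumed; a `max_abs` variant (largest
absolute excursion, sign preserved) is available behind the `variant`
argument for diagnostic use.

Raw ES depends on $N$ and $|P|$, so it is normalized by its own permutation
null: `n_perm` (default 10,000) draws place $|P|$ pseudo-positives uniformly
without replacement among the $N$ positions — permuting labels, not scores —
and

$$NES = \frac{ES}{\mathrm{mean}_b\, ES^{(b)}}.$$

Under the null, NES averages 1; a perfect ranking of a small positive set
reaches NES well above 3. When $ES = 0$ we define $NES = 0$ rather than
dividing. Internally the permuted ES uses the closed form over sorted
positive positions $q_1 < \dots < q_P$,
$ES = \max(0, \max_j\, j/P - (q_j - j)/(N-P))$, which is exact (the walk's
maximum occurs immediately after a positive step) and keeps 10,000
permutations cheap at any $N$.

The hold-out benchmark (`holdout_benchmark()`) splits the positives into a
seed half used for scoring and an evaluation half, ranks all drugs with the
seed labels only, *removes the seed positives from the ranked list* — they
carry label information and would otherwise inflate the leading edge — and
computes the NES of the evaluation positives on what remains. The default
split fraction is 0.5; it is configurable (`fraction`), and a third is a
common alternative choice for sparser label sets. The split and the
permutations share one integer seed, so a benchmark is a pure function of
(data, labels, fraction, n_perm, seed).

## The knowledge graph

Nodes are typed (`BirthDefect` with HPO CURIE ids, `Gene` with upper-case
symbols, `Drug` keyed by PubChem CID with name fallback) and carry an
enumerated property set (drugs: SMILES, placental-crossing score and rank;
genes: pLI, pHI, pTS, RVIS and its percentile; birth defects: MedDRA code);
strict mode rejects unknown keys so schema drift is caught at ingestion.
Edges are typed by relation with declared endpoint types
(birth defect–gene: HPO, Geneshot; birth defect–drug: FAERS, Drugshot;
drug–gene: drug_target, upregulates, downregulates; drug–drug:
expression_cosine; gene–gene: pos_correlated, neg_correlated), carry an
optional weight and a provenance `resource` string, and must be unique per
(source, target, relation); self-loops are rejected. JSON export/import
round-trips the graph exactly; CSV bulk-load and Cypher MERGE text exports
serve database ingestion.

**Co-expression edges.** From a gene–gene correlation matrix, each gene
contributes its $k = 5$ most positively and $k$ most negatively correlated
partners — a pure order statistic on $r$, so in a skewed matrix a "most
negative" partner may have $r > 0$. The relation label is assigned by the
sign of $r$ and the edge weight is $r$ itself, so consumers can filter for
true anticorrelation regardless of which end of the order statistic selected
the edge. Selections from both endpoints of a pair are deduplicated to one
undirected edge; ties break by ascending partner id.

**Over-representation statistic.** Birth-defect/drug co-reporting is scored
with the G statistic of a 2×2 contingency table,
$G = 2\sum_{\text{cells}} O \ln(O/E)$ with independence expectations $E$,
one-sided: if the defect-and-drug cell is below expectation the statistic is
0 (under-representation is not evidence of risk). Cells with $O = 0$
contribute 0; zero margins are errors. No significance cutoff is applied by
the function — callers filter, because any threshold belongs to the
consuming analysis.

**Cliques.** `find_cliques()` reports every (birth defect, gene, drug)
triple whose three pairwise links exist, once, in deterministic id order,
treating stored edge direction as irrelevant within a type pair; it is
join-based and is tested against exhaustive triple enumeration.
`filter_cliques()` keeps cliques whose drug ranks strictly below
`max_rank = 3000` in the placental-crossing ranking and is not already a
known positive — the "novel and plausibly exposed" filter that turns the
clique list into hypotheses worth reading.

## Synthetic study conditions

The generators in `synthetic_spec()` produce every input the pipeline needs,
with planted structure so recovery is a testable property rather than an
anecdote. The reference conditions are 200 drugs × 500 genes with 20
positives; positive signatures share a random unit-direction centroid scaled
by `effect = 3` noise-SDs on top of iid standard-normal coefficients, so
with `effect = 0` positives are exchangeable with the background.
Fingerprints draw iid Bernoulli(0.05) background bits — matching the
sparsity of real hashed fingerprints — and positives share a 30-bit
scaffold, each scaffold bit flipped off with probability 0.1. The MOA
pre-task plants class-separable scores on the informative modality
(in-class mean shift 2 SD) and pure noise on the other. The KG generator
draws typed nodes with properties in valid ranges, background edges at
density 0.05, and a configurable number of guaranteed triangles returned as
ground truth.

What the generator does *not* emulate: gene–gene covariance of real
expression panels (noise is isotropic, which suffices for cosine geometry
but understates the correlation of real similarity estimates), realistic
SMILES/chemistry (fingerprint generators produce bit matrices directly), and
literature co-mention count distributions. Passing recovery tests on these
conditions demonstrates that the machinery is correct and sensitive at
realistic signal strengths — not that any particular real-world label set
will reach a given NES.

## Numerical choices and degenerate inputs

- Ties everywhere break by ascending id (gene or drug): rankings, top-k
  sets, co-expression partner selection. Determinism is a contract.
- `top_k_genes()` with `2k` exceeding the gene axis warns and splits the
  genes by rank position (top half up, rounded up) without overlap.
- All-zero signature or weighted-fingerprint rows: similarity 0 everywhere,
  diagonal 0, flagged; sole-positive self-scores: `NA`, ranked last.
- Cosines are clamped to $[-1, 1]$ against floating-point overshoot.
- `n_perm < 100` warns (unstable normalization); `fraction` outside (0,1),
  empty positive sets, positives missing from the universe, zero 2×2
  margins, and `k` ≥ gene count are errors.
- Seeds: every stochastic step (generators, splits, permutations, training
  shuffles) takes one integer seed and is bit-reproducible from it.

The test suite runs the hold-out recovery at the reference conditions across
20 seeds with 1000 permutations, the null calibration on 200 random rankings
of 500 drugs (25 positives, 1000 permutations), and the exhaustive clique
oracle on 100 random graphs of up to ~20 nodes; these sizes make the whole
suite complete in well under a minute while leaving the statistical
assertions comfortably powered.

## Known limitations

- Consensus averaging masks cell-context-specific effects by design.
- The OpenBabel ECFP backend's bit positions differ from other
  implementations; similarity *matrices* are comparable, individual bits are
  not.
- SSL scores are similarities, not calibrated probabilities; they order
  compounds within one collection and should not be compared across
  collections.
- The weighted combiner assumes the pre-task's modality usefulness
  transfers to the target label sets; when it does not, Top Rank is the
  safer default.
- Graph-embedding link prediction and literature-mining edge construction
  are out of scope.
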