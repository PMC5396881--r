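---
title: "Methods: resampling-based MeSH term enrichment for drug-drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling-based MeSH term enrichment for drug-drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddimesh)
```

## The problem and the data

Drug–drug interactions (DDIs) are documented across an enormous, manually
curated literature. Every PubMed record carries MeSH headings: controlled
descriptors placed in a tree whose dot-separated tree numbers encode
hierarchy (`D12.776` is the proteins branch; `G03`, `G04`, `G06`, `G07`
cover metabolic, physiological and pharmacological phenomena and diet).
`ddimesh` treats those headings as the observable and asks, for one query
drug at a time, which headings mark its DDI-related literature.

A corpus — fetched live with `fetch_pubmed()` using the query
`"<drug> [MeSH Terms]"`, or loaded from MEDLINE flat text / PubMed XML — is
first filtered (an inclusive publication-date cutoff; optionally the removal
of review articles for a primary-literature sensitivity analysis) and then
partitioned by `partition_corpus()`: an article belongs to group A
(DDI-related) iff at least one of the eight interaction descriptors appears
among its headings, otherwise to group B. Matching is on the bare
descriptor: qualifiers (`/pharmacokinetics`) and major-topic markers are
stripped everywhere in the package, because the unit of analysis is the
MeSH term, not the term/subheading pair. Abstract text never enters the
partition; free-text matching would make the groups irreproducible across
indexing conventions. Only the eight literal descriptors are used — no
descendants of the interactions tree node — and the set is overridable for
sensitivity analyses.

## The enrichment test

Candidate terms are all descriptors in group A, bucketed by
`classify_terms()` with precedence interaction > drug > protein >
phenomena. Interaction descriptors define the partition and are never
candidates; drug identity (membership in a user-supplied FDA-approved drug
list matched to the vocabulary by normalized name) outranks tree position;
tree membership is segment-wise, so `D12.77` is not under `D12.776`. The
query drug's own descriptor is excluded — it is the corpus selector and
appears everywhere by construction. The drug list is intersected with the
vocabulary *before* counting, so out-of-vocabulary names can never surface
as candidates.

For each candidate term with group A count $n_t$, `null_distribution()`
draws $R$ subsets of size $|A|$ from group B uniformly without replacement
(with replacement across draws), counts every term in every draw, and sets
$\mu_t$ and $\sigma_t$ to the sample mean and sample standard deviation
($R-1$ denominator) of the draw counts. Then

$$Z_t = \frac{n_t - \mu_t}{\sigma_t}, \qquad p_t = P(\mathcal N(0,1) \ge Z_t).$$

Terms with $n_t > 5$ (strict) and $p_t < 0.1$ are selected.

Design choices worth recording:

* **One shared draw set for all terms.** All terms are counted on the same
  subsets. This preserves the cross-term correlation structure, is
  term-count-fold cheaper than per-term resampling, and changes nothing
  marginally.
* **One-sided upper tail.** The scientific hypothesis is over-representation
  in DDI-related articles; depletion is never significant
  (`z_pvalue(0, 5, 1)` ≈ 1).
* **Degenerate nulls.** A term present in every (or no) group B article has
  $\sigma_t = 0$; the p-value is then 0 if $n_t > \mu_t$ and 1 otherwise,
  with an infinite $Z$ sentinel rather than an error or NaN.
* **No multiple-testing correction by default**, matching the permissive
  raw-p selection rule above; `sampling_config(correction = "BH")` applies
  Benjamini–Hochberg and selects on the adjusted p-value for users who want
  FDR control.
* **Exact oracle.** For a term in $K$ of $N$ group B articles the draw count
  is hypergeometric, with mean $nK/N$ and SD
  $\sqrt{n\frac{K}{N}(1-\frac{K}{N})\frac{N-n}{N-1}}$. The test suite checks
  the resampler against exhaustive subset enumeration at $N = 10$, $n = 5$
  (all 252 subsets) and against this closed form.

### Calibration: what the resampled null does and does not control

The null distribution is built from group B alone. That is exactly the right
null for the question "could this count have arisen by drawing $|A|$
articles at random from the DDI-unrelated pool?" — and the suite verifies
that p-values are uniform when observed counts are generated by that very
mechanism. It is, however, mildly anti-conservative when group A is an
*independent* sample: the variance of $n_t$ under independent sampling is
binomial, $|A|\,p(1-p)$, while the resampled null SD carries the
finite-population factor $\frac{N-n}{N-1}$ (≈ 0.8 at $|A| = 200$,
$|B| = 1000$) and the estimated $\mu_t$ contributes additional variance
$\frac{|A|^2}{|B|}\frac{p(1-p)}{1}$. Together
$\mathrm{Var}(Z) \approx (|A|p\bar p + |A|^2 p\bar p/|B|)/(|A|p\bar p
\cdot \frac{N-n}{N-1}) = 1.5$ at those sizes, so the realized
type-I rate at nominal $\alpha = 0.1$ is about 0.14–0.15 rather than 0.10.
The acceptance suite measures this honestly (and the corresponding check is
expected to exceed the nominal band); practitioners should read the 0.1
threshold as a permissive screen, exactly as the strict count filter
($n_t > 5$) and downstream manual validation imply. Power is unaffected in
practice: terms planted at a four-fold prevalence ratio over a 5% background
are recovered essentially always at $|A| = 200$ (recovery ≥ 99% across 100
replicate corpora in the acceptance run).

## Co-occurrence and networks

`build_incidence()` produces the binary article × term matrix $I$;
`build_adjacency()` computes $I^\top I$ in exact integer arithmetic, so the
diagonal is each term's document frequency. The display matrices of the
pipeline are cross co-occurrence counts (selected drug terms × selected
protein or phenomena terms, over group A), row-normalized as
$\text{count}/\text{row total}$ so each drug's mechanism profile sums to 1;
all-zero rows are left at zero and flagged. Axis orders come from
agglomerative hierarchical clustering on Euclidean distances
(`stats::hclust`); the linkage had to be chosen (only the distance is
canonical) and defaults to complete, with single/average available.
Clustering operates on the normalized matrix, since that is the displayed
quantity.

`build_pair_network()` restricts group A to articles co-mentioning a partner
drug and connects the query drug, partner drug, selected protein and
phenomena terms, and the interaction descriptors present, weighting edges by
co-occurrence counts within that subset. Edges below `min_weight` (default
2, suppressing singleton co-mentions that make real-corpus networks
near-cliques) are dropped; the threshold is recorded in the provenance and
the weights are asserted in tests to equal the corresponding
`build_adjacency()` entries on the same subset. Export is GraphML (node
category and display color group, edge weight, provenance as graph
attributes — lossless round trip) or plain edge-list TSV.

## ROC validation

Given gold-standard labels, candidate terms are ranked by p-value (the
pipeline's only continuous per-term score; any strictly monotone transform
of it, e.g. $Z$, gives the identical curve). `roc_curve()` emits one point
per distinct score plus the endpoints, moving tied scores together so the
trapezoidal `roc_auc()` equals the pairwise Mann–Whitney statistic
$P(\text{pos outranks neg}) + \tfrac12 P(\text{tie})$ to machine precision —
an identity the suite checks against brute-force threshold sweeps, pairwise
enumeration, and `pROC`. `cutoff_sweep()` re-evaluates the AUC as the
frequency filter $n_t > c$ varies over $c = 0..6$, reporting `NA` (rather
than stopping) where a restriction loses one label class.

## The synthetic corpus generator

`generator_spec()`/`generate_corpus()` emulate precisely the structure the
test assumes: per-article independent Bernoulli term inclusion at
category-labelled prevalences, elevated in group A by a risk ratio
($p_A = \min(1, RR \cdot p_B)$); one interaction descriptor per group A
article; the query drug descriptor everywhere; optional review flags
(`round(fraction * n)` per group, recorded by PMID); publication dates
uniform over a year range. Pairwise co-mention excess $e$ is planted in
group A by a marginal-preserving mixture — with probability $e$ both terms
are forced present, otherwise both are drawn independently at
$(p-e)/(1-e)$ — validated against $e \le \min(p_i, p_j)$ so marginal
prevalences are exactly preserved. Auto-generated decoys carry tree numbers
that classify them into their intended category, making the vocabulary
fixture self-describing. Every generated corpus returns its realized ground
truth (per-term per-group counts, review PMIDs, joint co-mention counts),
and the suite's self-audit asserts pipeline counts equal the truth record
exactly.

What the generator does **not** emulate: the heavy cross-term correlation of
real MeSH indexing, realistic indexing density, abstract text, or citation
structure. Passing tests therefore demonstrate algorithmic correctness and
the statistical properties stated above under exchangeable group B articles
— not performance on a live PubMed snapshot, which additionally depends on
indexing practice and on the gold standards used for validation.

## Problem sizes, determinism and numerical choices

The statistical checks run at the sizes the claims are stated for:
enrichment calibration and power at $|A| = 200$, $|B| = 1000$, 30 null /
10 planted terms, 1000 resamples, 100 replicate corpora; co-occurrence
algebra against per-cell brute force at 200 articles × 50 terms; the AUC
identity on 1000 random tied rankings; unit fixtures are much smaller. All
randomness flows through explicit seeds (`sampling_config(seed = )`,
`generator_spec(seed = )`, the acceptance script's `--seed`), restored
afterwards via `withr`, and two pipeline runs under one configuration are
asserted byte-identical up to timings, with a configuration hash stamped
into every tabular artifact. Term comparison is case-insensitive on
NFC-normalized, trimmed text while stored forms keep canonical casing;
enrichment ties are broken by descending count then term so orderings are
total; `cluster_order()` returns the identity permutation below two rows;
MEDLINE parsing never silently drops records (unparseable ones are counted
in a `problems` attribute).

## Known limitations

* The enrichment p-value inherits the anti-conservatism quantified above;
  it is a screening statistic, not a calibrated test against independent
  group sampling.
* Entry-term (synonym) resolution is off by default; MEDLINE records
  already carry canonical descriptors, but vocabularies from other sources
  may need the `entry_terms` mapping.
* Supplementary concept records (chemical SCRs) are not mapped; candidate
  drugs must be main-heading descriptors.
* Headline results on real corpora depend on the PubMed snapshot date; the
  date cutoff makes runs reproducible only against a fixed snapshot or
  cache.
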