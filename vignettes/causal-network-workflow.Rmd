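---
title: "Methods: from expression changes to causal networks and biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from expression changes to causal networks and biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`causalpath` is a staged analysis for two-group disease transcriptomics:
differential expression, gene-set enrichment, topological regulator
inference, key-pathway identification, causal-network reconstruction, and a
multi-evidence key-gene score. This vignette is the package's account of
each stage — the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## Differential expression

`moderated_t()` assumes log2-scale, approximately normal expression with
gene-specific variances exchangeable across genes. Each gene's pooled
two-group variance $s_g^2$ (on $d_g = n_1+n_2-2$ df) is shrunk towards a
scaled inverse-chi-square prior $(d_0, s_0^2)$ estimated by method of
moments on $\log s_g^2$: the mean and variance of $\log s_g^2$ under the
model are known digamma/trigamma expressions, and $d_0$ is recovered by
Newton inversion of the trigamma function. The moderated statistic
$\tilde t_g = \Delta_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ with
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$ is referred to a $t$
distribution on $d_0 + d_g$ df (standard normal when $d_0 = \infty$).

Edge cases are explicit: when the observed dispersion of $\log s_g^2$ does
not exceed what the chi-square alone implies, $d_0 = \infty$ and all genes
are scored at the common variance $s_0^2 = \overline{s^2}$ — this is the
expected regime for the homoscedastic synthetic generator. A gene with zero
variance and zero difference scores $t = 0, p = 1$; zero variance with a
nonzero difference is scored at a machine-minimum variance floor and
logged. Two limits pin the implementation: at $d_0 = 0$ it must equal the
classical pooled t (checked to 1e-10 against a directly coded oracle), and
the independent `limma::eBayes` implementation of the same published method
must agree on the fitted prior and statistics (checked to 1e-6/1e-8 on a
heterogeneous-variance fixture).

DEG calling (`call_degs()`) uses the linear fold-change rule: called iff
$2^{|\log_2 FC|}$ is *strictly* above `fc_cut` (default 1.2, the
transcript-list convention; "above" is read strictly, so FC = 1.20 exactly
is not called). For protein lists — and for any analysis where the DEG list
feeds network inference, see below — the `p_cut = 0.05` gate is added. No
multiplicity correction is applied at this stage because the downstream
stages consume the list as a signature, not as individual discoveries; any
p gate is explicit caller input.

## Enrichment

`enrich()` evaluates one-sided (over-representation) hypergeometric tails;
depletion is out of scope. The universe $N$ defaults to the union of the
collection's members — the natural background when the ontology defines the
measurable vocabulary — and can be overridden with a measured-gene universe
(`restrict_to_universe = TRUE` then also trims the sets; default off, since
whether platform intersection should shrink the sets is a dataset-level
judgement). Query genes outside the universe are dropped with a logged
count. BH FDR is computed per collection; significance calls elsewhere in
the pipeline use the raw p at $\alpha = 0.05$, with the FDR column emitted
alongside. The tail itself is evaluated through the log-space hypergeometric
CDF; tests compare it against exhaustive enumeration of every valid
$(r, n, R, N)$ with $N \le 12$.

## Regulators

Both regulator tests treat the interaction network as a directed causal
substrate: regulation flows along edge direction. `direct_regulators()`
therefore uses *outgoing* neighbours by default (`mode = "all"` covers
binding-only networks), excludes the candidate from its own universe
($N = |V| - 1$), and scores the DEG content of its neighbourhood by the
same hypergeometric tail.

`hidden_nodes()` scores remote (upstream) regulators by shortest-path
traversal: for node $v$, $k_v$ = DEG-pair shortest paths with $v$ interior,
$K$ = all DEG-pair shortest paths, $m_v$ and $M$ the same over all ordered
node pairs. *All* shortest paths per pair are counted (deterministic,
order-independent), endpoints never count, and each quantity is a path
count, so $k_v \le \min(m_v, K)$ and $\max(m_v, K) \le M$ always hold, and
when the DEG set is the whole node set, $K = M$, $k_v = m_v$ and every
p-value is exactly 1. The counters come from a per-source BFS with
path-count ($\sigma$) and suffix-count accumulation, implemented in C++ and
verified against brute-force all-shortest-path expansion on random
digraphs, plus a conservation identity (total interior traversals equal
path lengths minus one, summed over paths).

The analytic null treats each all-pairs path as an independent draw. That
is convenient and fine for *ranking*, but anti-conservative for *calling*
on realistic networks: traversals through a node are strongly correlated
(one upstream branch redirects thousands of paths), so the effective sample
size is far smaller than $M$ and on a 1000-node network more than half the
nodes can reach nominal significance. The permutation null
(`null = "permutation"`) redraws DEG-sized node sets uniformly and
recomputes $k_v$; its empirical tail is honest but floored at
$1/(n_{perm}+1)$, which BH across ~1000 candidates cannot use at feasible
$n_{perm}$, so the `tail = "normal"` option scores $k_v$ as a z-value
against the permutation mean and SD. The pipeline drivers gate the remote
list on that z-tail's BH FDR; the default *statistic* remains the analytic
one. A path-length cap is deliberately not imposed (networks at this scale
have small diameter; capping would silently change $K$ and $M$).

The pipeline's "expression regulators" are the union of BH-significant
direct regulators and hidden nodes: both kinds are, by definition, genes
responsible for the observed changes.

## Key pathways and causal networks

`identify_key_pathways()` compares three enrichment runs over the same
collection — DEG list, regulator list, and their union (the combination
set; the union is the only combination whose enrichment is a single p per
pathway) — and flags synergy: $p_{combo} < \min(p_{deg}, p_{reg})$ with all
three $\le \alpha = 0.05$. The gate matters: without it, a pathway trivially
"improves" by adding any overlapping regulator to a non-enriched DEG
overlap. The flagged inequality is re-checked post hoc by a test across
synthetic runs.

`reconstruct_causal_network()` marks DEGs and regulators as affected,
then searches each key-pathway topology for simple directed paths from an
affected trigger (ligand or receptor role) to an affected transcription
factor with at most `max_gap = 0` unaffected interior nodes and a
consecutive affected run of at least `min_stretch = 2`. The run is measured
over the whole path including trigger and TF — measuring interior nodes
only would reject the legitimate one-gap cascade L\*→R\*→K→TF\* at
`max_gap = 1`. Only *maximal* cascades are reported: a qualifying path that
is the suffix of a longer one (its trigger sits mid-cascade) is absorbed,
so a fully affected chain yields exactly one cascade. Cycles are never
revisited (simple paths). Cascade edges merge across pathways with
per-edge provenance; functional-module groups attached to a map join the
network when at least one member is affected. Monotonicity holds as
coverage: enlarging the affected set never loses a cascade, though a
cascade may extend.

## Key genes and the panel

`collect_evidence()` derives the ten binary criteria purely from upstream
artifacts; `score_gene()` counts them (0–10). Criteria that depend on
ontologies not supplied in a given configuration (GO process/function,
process networks, toxicity networks) score 0 and are logged as unavailable,
so totals are comparable only within one configuration — in the synthetic
workflow the effective maximum is 7. `build_panel()` keeps blood-expressed,
directional candidates and ranks by (score desc, |log2FC| desc, gene id
asc) — the tie-break is not prescribed by the scoring definition and was
chosen for determinism; the output is invariant to input order. Panels
short of 25 + 25 are returned short, with a warning, never padded.

## The synthetic generator

`sim_config()` defaults encode the reference study conditions used by the
recovery tests: 1000 genes, 10 samples per group, planted effect
$|\log_2 FC| = 1$ against noise SD 0.5, three regulators with 20 targets
each on a 1000-node/3000-edge preferential-attachment network (hub-like
drivers are the premise of topological regulator inference), and a
20-pathway ontology of 30-gene sets with two planted-enriched maps (60%
seeded with planted targets) and one causal map per regulator carrying a
ligand→receptor→transducer→transducer→TF topology with the TF wired to its
targets. Expression is homoscedastic log2 Normal(8, 1) baselines plus
N(0, noise_sd) noise; one global seed derives per-stage sub-seeds so stages
re-run independently and every artifact is reproducible byte for byte.

Two generator properties deserve explanation. First, every causal map
includes the full planted TF panel as members. Canonical pathway maps share
their transcription-factor layer, and at this scale the sharing is what
makes regulator enrichment informative at all: a 30-gene pathway containing
exactly one of three regulators has a *minimum achievable* regulator
enrichment p of $P(X \ge 1) \approx 0.14$ on a 600-gene universe — no
outcome could pass the 0.05 gate. Second, the upstream chain genes are
planted as up-regulated DEGs: an affected cascade must be affected to be
recoverable.

At the reference conditions, the fold-change-only DEG rule admits roughly
24% of null genes ($\Delta$ has SD $0.5\sqrt{2/10} \approx 0.22$ against a
cut of 0.263 log2 units). That is faithful to the rule and harmless for
enrichment and over-connectivity (planted signal dominates), but it floods
the shortest-path sub-network with noise pairs; the hidden-nodes recovery
scenario therefore uses the p-gated rule, appropriate whenever the DEG
list feeds network inference. That scenario — chosen once as the package's
demonstration of remote-regulator detection — is a single regulator
reaching its 20 targets through intermediate transducers
(`target_path_len = 2`) on a sparse 300-node/450-edge backbone, where
shortest paths are informative; on dense backbones, backbone shortcuts
bypass the planted cascade and no traversal statistic can recover it.

What passing tests show — and do not. The generator emulates the
*statistical structure* the stages assume: two groups, planted shifts,
hub-structured directed interactions, set-based enrichment, annotated
topologies. It does not emulate probe effects, batch structure, RNA-seq
count distributions, correlated co-expression beyond the planted structure,
or literature-biased network annotation. Recovery of planted structure
therefore validates the machinery, not the biology of any particular
dataset.

## Problem sizes and runtime

The test suite runs the reference conditions over 50 seeds for regulator /
key-pathway / cascade recovery, 100 seeds for planted-pathway enrichment
ranking, 25 seeds each for over-connectivity and hidden-nodes recovery,
2000-gene null calibrations for type-I control, exhaustive enumeration to
$N \le 12$ for the hypergeometric oracle and 100 random digraphs ($\le 15$
nodes) for the traversal oracle; the whole suite completes in about three
minutes on one CPU.

## Known limitations

Shortest paths are unweighted; edge effects (activation/inhibition) are
carried as annotation but do not constrain cascade sign consistency;
regulator activity direction is not inferred; the hidden-nodes permutation
null resamples node sets uniformly rather than degree-matched (a
degree-matched null would be stricter on hubs); and the manual curation
step by which a rule-based candidate panel becomes a hand-tailored final
biomarker list is, by its nature, not automated.
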