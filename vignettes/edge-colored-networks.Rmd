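---
title: "Edge-colored drug-target networks: model, measures and bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-colored drug-target networks: model, measures and bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternet)
```

## The representation

A drug–target dataset over $n$ drugs $D = \{d_1,\dots,d_n\}$ and $m$
targets $T = \{t_1,\dots,t_m\}$ is modelled as a bipartite network whose
edges carry one of three colors. Every pair $(d_i, t_j)$ is in exactly one
of three states:

* **active** — a determination (experimental or computational) found the
  drug active against the target;
* **inactive** — a determination found it inactive;
* **unknown** — no determination exists.

The crucial modelling commitment is *unknown-by-omission*: a pair that no
record mentions is assigned unknown status, never inactive. Public
interaction databases overwhelmingly report actives; treating silence as
inactivity (as decoy-style benchmarks do) discards the distinction between
"measured and inactive" and "never measured", and that distinction is
exactly what the completeness measures and degree bounds below quantify.
`dt_network()` applies this convention; the escape hatch
`unknown_as_inactive = TRUE` exists for deliberately decoy-style data.

The network is stored as an $n \times m$ ternary status matrix.
`decompose_network()` splits it into three binary biadjacency matrices
$A_+$, $A_-$, $A_*$ that partition the pairs:

$$a_+(d_i,t_j) + a_-(d_i,t_j) + a_*(d_i,t_j) = 1
  \quad\text{for all } i, j.$$

Row sums of $A_+$ are the **polypharmacology** degrees
$\hat\pi_{PP}(d_i)$ (how many targets a drug is active against); column
sums are the **polyspecificity** degrees $\hat\pi_{PS}(t_j)$ (how many
drugs hit a target). Because the target–drug relation is simply the
transpose of the drug–target relation, the two notions are *dual*:
polyspecificity in a network equals polypharmacology in its transpose
(`t()` on a `dtnet`). The package asserts this duality property across
seeded random networks in its test suite.

## Classification of measured activities

Quantitative records (potency readouts in µM) are binarised by
`classify_activity(value, threshold, direction)`:

* `threshold` — default **10 µM**. Potency thresholds for calling a
  compound active conventionally lie in the 1–10 µM range; 10 µM is the
  permissive end, appropriate when the goal is to enumerate possible
  polypharmacology rather than select leads.
* `direction` — default `"at_most"`: a potency value (IC50, Ki, EC50) at
  or below the threshold is active, matching how such readouts are
  interpreted (smaller means stronger). The opposite reading — active when
  the readout is at or *above* a threshold — occurs for non-potency
  activity scores, so `"at_least"` is available as an explicit option
  rather than hard-wiring either convention. The boundary is inclusive in
  both directions.

Classification never emits `unknown`: unknown status arises only from
absent data, not from any measured value.

When multiple records disagree about one pair, the default `conflict
policy` is `"error"`: interaction data is of notoriously uneven quality,
and silent reconciliation should be opt-in. `"any_active"` (one active
determination wins) and `"majority"` (ties fall back to unknown — the
honest answer when the evidence is balanced) are provided. Reliability
weighting of sources is *not* implemented; no principled weighting scheme
is available for the data this package targets, and an unprincipled one
would be worse than a loud error.

## Completeness and uncertainty

With $\hat\mu_+ = \sum_{ij} a_+$, $\hat\mu_- = \sum_{ij} a_-$,
$\hat\mu_* = \sum_{ij} a_*$, global data completeness is

$$C_{DT} = \frac{\hat\mu_+ + \hat\mu_-}{\hat\mu_+ + \hat\mu_- + \hat\mu_*}
 \in [0, 1],$$

the fraction of all $n\,m$ pairs whose status has been determined
(`completeness()`). The denominator is fixed at $n\,m$, so only two of the
three counts are free.

Per entity, the three colored degrees sum to the opposite side's
cardinality, e.g. for a drug
$\hat\pi_{PP}(d_i) + \hat k_-(d_i) + \hat\varepsilon_{PP}(d_i) = |T|$.
`local_uncertainty()` deliberately computes the unknown degree
$\hat\varepsilon$ by *rearranging* this identity
($|T| - \hat\pi_{PP} - \hat k_-$) rather than counting unknown cells; the
test suite cross-checks the rearrangement against direct counting on every
test network, which verifies the partition identity end to end.

## Degree bounds under missing data

If every determination is correct, the true active degree of an entity is
bracketed by two extreme scenarios: all its unknown pairs inactive (lower
bound = observed active degree $\hat\pi$) or all active (upper bound =
$\hat\pi + \hat\varepsilon$):

$$\hat\pi \;\le\; \pi_{\text{true}} \;\le\; \hat\pi + \hat\varepsilon.$$

`degree_bounds()` reports these intervals; their width is exactly the
entity's local uncertainty, so each new determination — even an
*inactivity* — tightens them. That is the practical argument for databases
reporting inactives. The cap $\hat\pi + \hat\varepsilon \le m$ (or $n$) is
attained only in a complete bipartite active network.

Caveat: the lower bound is only as good as the determinations. Measurement
and curation errors can make reported actives spurious, in which case the
observed active degree is not a true lower bound. The package implements
the combinatorial bounds exactly as defined and leaves error modelling to
the user; no error model is assumed anywhere.

## Profile vectors and similarity

`entity_profiles()` represents each entity as the 3-vector
(active, inactive, unknown). `profile_distance()` offers Euclidean
distance and cosine similarity; since components are non-negative counts,
cosine similarity lies in $[0,1]$. Cosine similarity of a zero vector is
mathematically undefined and raises an error — returning a conventional 0
or 1 would silently distort any downstream clustering. Clustering itself
is out of scope; `profile_distances()` emits the pairwise table for
whatever method the user prefers.

## The synthetic generator and what tests can show

`generate_random_network(n, m, p_active, p_inactive, p_unknown, seed)`
draws each pair's status i.i.d. from a categorical distribution, and
`mask_network(truth, hide_fraction, drop_inactives, seed)` turns a fully
determined ground truth into a database-style incomplete view: a random
subset of pairs becomes unknown, and optionally all inactives are hidden
(actives-only reporting). Masking hides statuses but never flips them, so
on every (truth, masked) pair the bounds computed from the masked view
must bracket the truth's active degrees — the property suite asserts this
over 100 seeded trials at $30 \times 15$ with hide fractions 0.1/0.3/0.6,
sizes chosen to exercise the combinatorics well beyond the packaged
8 × 4 example while keeping the whole suite fast.

Two deliberate simplifications: masking hides an *exact* count
`round(hide_fraction * n * m)` of pairs (per-pair Bernoulli hiding is
available behind `bernoulli = TRUE`), which makes the expected
completeness of a masked view sharp rather than stochastic and lets tests
assert equalities; and sampling is uniform over pairs — real interaction
data is strongly biased toward popular target classes and well-studied
drugs, so passing these tests demonstrates correctness of the
combinatorial machinery, not robustness to the sampling biases of real
databases. All generators require an explicit seed; the seed fully
determines the output.

## Numerical and formatting choices

* All degree and count computations are exact integer arithmetic; the only
  floating-point quantity is $C_{DT}$ and the profile distances.
* $C_{DT}$ is carried at full precision; *display* rounding is three
  decimals, half-up (`round_half_up()`), under which $26/32 = 0.8125$
  prints as `0.813`. Base `round()` would give `0.812` (half-to-even).
  The CLI's `--digits` flag controls this.
* Majority conflict resolution breaks exact ties toward `unknown`.
* Label handling: labels are case-sensitive and whitespace-trimmed; the
  drug and target namespaces must be disjoint (the graph is bipartite),
  with `suffix_sides = TRUE` as a documented escape hatch appending `:D` /
  `:T`.
* Ordering is first-seen everywhere (universe order when universes are
  given); all outputs are deterministically ordered.
* The status matrix is stored dense. At the scales this package targets
  (up to a few thousand entities per side) a dense character matrix is
  well below memory limits; a sparse backing would change nothing
  semantically and is left as a future optimisation.

## Worked example

The packaged 8-drug × 4-target network exercises every quantity:

```{r example}
net <- load_worked_example()
net
summary_table(net)
completeness(net)
```

## Known limitations

* No structure-based reasoning: entities are opaque labels, and the
  formalism is purely phenomenological.
* No live database connectors; input is files or data frames.
* No statistical network modelling (degree distributions, null models) and
  no weighted or fuzzy edge states — the representation is ternary and
  combinatorial.
* The generator does not simulate target-class popularity bias.
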