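---
title: "Identifying molecules from proton NMR line spectra by guided tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying molecules from proton NMR line spectra by guided tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrts)
```

## The problem

A ¹H NMR spectrum is highly characteristic of a molecule, but going from a
spectrum back to a structure is an inverse problem: spectra can be predicted
from structures, not the other way around. Database lookup answers it only
for molecules that are already catalogued. `nmrts` instead searches chemical
space directly: it *generates* candidate molecules as SMILES strings,
predicts each candidate's line spectrum, and keeps the candidates whose
spectra match the target. Identification succeeds when a generated molecule
reproduces the target spectrum exactly.

## The model

**Spectrum representation.** A spectrum is a bare list of chemical shifts in
ppm, one entry per proton. Peak degeneracy is kept (a methyl group
contributes three equal entries), intensities, line widths and spin-spin
coupling are not modelled. All comparisons treat the list as a multiset.

**Spectral match.** Two spectra are compared with the first Wasserstein
distance between the empirical distributions that place mass $1/n$ on each
of a spectrum's $n$ shifts:
$$\mathrm{WD}(a, b) = \int_0^1 \lvert F_a^{-1}(q) - F_b^{-1}(q) \rvert \, dq,$$
computed exactly over the merged set of quantile breakpoints. Normalizing to
unit mass makes molecules with different proton counts comparable; the
proton-count mismatch is punished separately.

**Evaluation score.** A candidate molecule $M_g$ is scored against the
target $M_t$ by
$$\mathrm{Score}(M_g, M_t) = 1 - \tanh\big(\mathrm{WD}(M_g, M_t) +
\alpha \cdot \mathrm{Penalty}(M_g, M_t)\big), \qquad
\mathrm{Penalty} = \lvert C(M_g) - C(M_t)\rvert + \lvert H(M_g) - H(M_t)\rvert,$$
where $C(\cdot)$ and $H(\cdot)$ are carbon and hydrogen counts. The score
lies in $[0, 1]$ and equals exactly 1 only for a perfect spectral and
atom-count match (distances below $10^{-12}$ ppm are treated as zero for
floating-point hygiene). $\alpha$ (default 0.1 ppm-equivalents per
mismatched atom) keeps a one-atom mismatch informative rather than
saturating, given typical inter-spectrum distances of 0.5–3 ppm.

**Search.** Monte Carlo tree search over SMILES prefixes: each tree node is
one SMILES token. Selection descends by the prior-weighted upper confidence
bound
$$u_i = \frac{s_i}{v_i + w_i} + C\, p_i\,
\frac{\sqrt{v_p + w_p}}{1 + v_i + w_i},$$
with $s_i$ the node's accumulated score, $v_i$ its visits, $w_i$ its
*virtual* visits (selections currently in flight, so concurrent descents
diversify), $p_i$ the policy prior, and $v_p, w_p$ the parent's counts. The
exploitation term is defined as 0 for unvisited nodes, so fresh children
compete through $C p_i$ alone. At the first unexpanded node, children are
added for every vocabulary symbol with priors from the policy; the chosen
prefix is completed by sampling the policy to the end marker (a rollout) and
the completed string is canonicalized, predicted, scored, and the score
backpropagated. Evaluation failures (unparseable strings, hydrogen-free
molecules) score 0 and never interrupt the loop. Exploration constant
$C = 1$ by default.

**Terminal exhaustion.** The string space below a node is finite and the
spectrum predictor deterministic, so re-evaluating a completed terminal
through selection gains nothing. Once a selection ends on a terminal, that
terminal is closed, and ancestors whose expanded child sets are entirely
closed are closed too. Without this, selection eventually locks onto the
best terminal found and replays it for the rest of the budget. Duplicate
strings produced by *rollouts* are still evaluated (from cache), counted
against the budget and backpropagated normally.

**Trie preloading.** When a reference database is available, every database
molecule is scored against the target (the best one is the *database-search
baseline*), and the token paths of the top `trie_size` strings are inserted
into the tree before the search starts, each node on a path receiving the
string's score and one visit — the same bookkeeping as a backpropagation.
The search therefore starts from an informed tree whose promising branches
are already warm, rather than from a bare root.

## The policy

The next-symbol policy is trained on a SMILES corpus and serves two roles:
priors $p_i$ for expansion, and the rollout sampler.

Two backends satisfy one interface. The **Markov backend** (default) stores
exact corpus statistics for all context lengths up to `order` with additive
smoothing; with `interpolation` $< 1$ the estimates of all matched context
lengths are blended Jelinek–Mercer style, so a continuation seen at *any*
order keeps non-vanishing probability. This matters for identification:
the target is absent from the corpus by construction, and its spelling may
use token patterns that never occur at the longest context length. The
**recurrent backend** is a small Elman network trained by stochastic
gradient descent with backpropagation through time; it learns context
implicitly and is closer to the original design, at substantially higher
training cost. Unit tests and the reference protocol use the Markov
backend because its statistics are exact and its behaviour is independent
of neural-training idiosyncrasies.

**Grammar masking.** A finite-context model cannot see an unclosed
parenthesis or ring bond beyond its window, and therefore assigns real
probability to continuations no SMILES grammar allows (ending a string
inside a branch, closing a branch that was never opened). With masking
enabled (the default), syntactically impossible next tokens are zeroed and
the distribution renormalized. In measurements on the bundled protocol this
halves the number of wasted evaluations: without the mask roughly half of
all evaluated strings were syntactically invalid, and their zero scores
systematically depressed the means of good branches.

**End marker.** The end marker is absorbing (querying past it returns it
with probability 1), and rollouts truncated at `max_length` (default 80
tokens, comfortable for molecules under 500 Da) are flagged rather than
treated as errors.

## Spectrum prediction

The search treats spectrum prediction as a black-box oracle: any
deterministic function from canonical SMILES to a per-proton shift list.
The bundled **surrogate predictor** classifies each proton's environment
from the explicit-hydrogen molecular graph — aliphatic, vinylic, aromatic,
aldehyde C–H, alkyne C–H, O–H, N–H, with increments for neighbouring O, N,
unsaturated carbons, and for hydroxyl/amine protons attached next to
carbonyl or aromatic systems — and assigns the class's typical ¹H shift
(e.g. aliphatic CH ≈ 0.9 ppm, aromatic CH ≈ 7.2 ppm, aldehyde CH ≈ 9.6 ppm,
carboxylic O–H ≈ 11.5 ppm) plus a deterministic jitter of at most ±0.3 ppm
derived from a polynomial hash of the proton's radius-2 environment.
Symmetric protons therefore coincide exactly, distinct environments are
distinguishable, and repeated predictions are bit-identical — the
properties the search relies on. The shift table is a set of documented
modeling constants, not fitted values, and can be overridden.

A **file-exchange adapter** supports external backends (e.g. a
quantum-chemistry pipeline): a request JSON is written per molecule, a
response with TMS-referenced per-proton shifts is awaited, and the shift
count is validated against the molecule's hydrogen count. Timeouts and
count mismatches surface as typed errors.

Caching is keyed by canonical SMILES, so each molecule is predicted at most
once per run regardless of how many spellings of it the search generates.

## The synthetic corpus

`generate_corpus()` emulates a reference database of small organic
molecules: alkyl chains (1–8 carbons) and aromatic cores (benzene,
pyridine, furan) bearing up to two substituents from a fixed set of common
oxygen/nitrogen groups, enumerated combinatorially, canonicalized,
filtered to uncharged C/H/N/O molecules under 500 Da with at least one
proton, deduplicated, and sampled in seed-shuffled order. The scheme
capacity is a few thousand molecules; requests beyond it fail with the
attainable count.

`make_identification_case()` holds one corpus molecule out: its predicted
spectrum and atom counts become the search target, and the molecule is
removed from the corpus used for policy training and trie preloading, so
the target is never in the database — identification must construct it.

What passing the round-trip protocol shows — and what it does not: the
surrogate's spectra are cleaner than real or quantum-chemically computed
ones (no conformational averaging, no solvent effects, no coupling, no peak
overlap), and the corpus grammar is far simpler than a real molecular
database. Success here demonstrates that the search machinery can invert
its own oracle at desk scale; it does not demonstrate identification
performance against experimental spectra.

## Reference protocol and problem sizes

The package's round-trip protocol uses a 500-molecule corpus (seed 2026),
ten held-out targets drawn uniformly (seed 77), policy order 5 with
interpolation 0.8, exploration constant 1, penalty weight 0.1, trie size
50, and a budget of 2000 evaluations per target with early stopping on an
exact match. The trie-benefit comparison runs trie sizes 0, 1, 10 and 50
at a budget of 400 evaluations over 20 seed-pinned runs and compares mean
best scores. Unit tests use a 60-molecule corpus. These sizes keep the
whole suite in the minutes range while leaving the search a nontrivial
space; they are stated here so results can be reproduced exactly.

## Numerical and design choices

- The selection rule's typeset form in the source material is ambiguous; the
  PUCT-style reading above is adopted, consistent with the symbol
  definitions and the virtual-loss literature. Zero-denominator convention:
  exploitation is 0 for unvisited nodes.
- Virtual loss is 1 per in-flight selection, applied to $w$ only. The
  reference execution mode is sequential; the bookkeeping supports bounded
  in-flight windows.
- Selection ties break by higher prior, then lower child index, for
  deterministic replay.
- Expansion creates children for the whole vocabulary at once, including
  symbols with near-zero priors.
- Duplicate generations count against the budget (cache makes them cheap).
- Scores of failed evaluations are 0, the infimum of the score range, which
  steers the search away without terminating it.
- All randomness (corpus shuffling, rollouts, policy training) is seeded;
  a search replays identically under the same seed.

## Limitations

- Hyperfine (J) coupling, intensities and line shapes are not modelled, so
  positional isomers of aromatic rings that differ only in coupling
  patterns are genuinely ambiguous to this representation.
- O–H and N–H environments overlap in the surrogate's 1–5 ppm band, the
  same ambiguity the underlying method exhibits.
- Long candidates (20+ tokens) exhaust desk-scale budgets before their
  neighbourhood is covered; recovery rates drop with target size.
- OpenBabel's aromaticity perception governs canonical forms; canonical
  strings are internally consistent but not guaranteed to match other
  toolkits' canonical spellings.
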