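---
title: "Compiling reaction-contingency networks into bipartite Boolean models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling reaction-contingency networks into bipartite Boolean models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnbool)
```

## The modelling problem

Mechanistic models of signal transduction are built from empirical
observables: a phosphorylation at a specific residue, a bond at a specific
binding domain. These *elemental states* combine combinatorially into
microstates, which makes microstate-based formalisms (ODE systems, Petri
nets) unusable for large signalling networks, and the rate constants needed
to parametrise quantitative models are mostly unmeasured. `rxnbool`
implements a parameter-free alternative: a reaction-contingency network —
a list of *elemental reactions* (each defined only by the states it
synthesises, degrades, produces or consumes) and a list of *contingencies*
(Boolean constraints attaching states and inputs to reactions) — is
compiled into a *bipartite Boolean model* with two generic update rules,
one for reaction targets and one for state targets. No parameters are
fitted at any point; the network structure alone defines the model, and
synchronous simulation to an attractor predicts system-level behaviour.

The two target kinds deliberately mean different things. A reaction target
is true when the regulatory layer permits the reaction (its contingencies
hold and its reacting components are present) — necessary but not
sufficient for it to fire, since the source states must be there too. A
state target is true when a functionally relevant pool of molecules
carries that state. Both describe the system level, not single molecules:
two states that exclude each other on one molecule (phosphorylated and
unphosphorylated forms of one residue) are routinely both true.

## The update rules

Writing $C_i$ for components, $R_i$ for reactions and $S_i$ for states,
the building blocks are:

* **Component presence.** A component with sites is present iff every site
  carries some state: $C_i = \bigcap_{\text{site } j} \bigcup_{\text{state }
  k \text{ on } j} S_k$. A component with no sites ("generic", e.g. a
  catalyst-only phosphatase) is its own state target.
* **Primed reactions.** $R'_i = R_i \cap \bigcap_j S_j$ over the states
  $S_j$ consumed by $R_i$: an eligible reaction still does nothing without
  its substrate. Effects carry their own source states where these differ
  from the reaction's consumed set (see degradation below).
* **Contingencies.** $L(R_i)$ conjoins all required (`!`) effectors with
  the negations of the absolutely inhibitory (`x`) ones. Quantitative
  contingencies (`K+`/`K-`) have no interpretation in a deterministic
  Boolean system; by default they are dropped (treated as `0`), and
  `compile_options(k_plus = "strict", k_minus = "strict")` folds them in
  as `!` and `x` instead. `0` and `?` never enter an expression.

The **reaction update rule** is
$R_i(t+1) = K(R_i; t) \cap L(R_i; t)$, with $K(R_i)$ the conjunction of
the reacting components' presence expressions.

The **state update rule** encodes the hierarchy *synthesis > degradation >
production > consumption*, which follows from a quasi-steady-state view of
each Boolean time step (a protein both synthesised and degraded is
present; a phosphosite with kinase and phosphatase active shows both
forms; a degraded protein loses its modified forms regardless of kinase
activity):

$$S_i(t+1) = \Sigma(S_i) \cup \Big(K(S_i) \cap \bigcap_{\mathrm{deg}}
\overline{R'_k} \cap \big[\bigcup_{\mathrm{prod}} R'_l \cup (S_i \cap
\bigcap_{\mathrm{cons}} \overline{R'_m})\big]\Big)$$

$\Sigma$ is the synthesis term: for a neutral state, the union of primed
synthesis reactions; for a state one production step from neutral, the
primed synthesis of its neutral counterpart conjoined with the union of
its primed producers. All networks this package targets keep states one
step from neutral; deeper synthesis paths raise a compile-time error
(and a validation diagnostic beforehand). Empty collections take their
neutral element: no producers contributes FALSE, no degraders or
consumers contributes TRUE. The producer combinator is a union — "the
state is being produced by some reaction" — not an intersection.

All targets update simultaneously (synchronous deterministic scheme).
Updating the source and product states of one reaction in different ticks
would manufacture artefacts, so no asynchronous or probabilistic schemes
are offered.

### Degradation expansion

A degradation reaction for component X degrades every state X carries.
Two refinements, both derived from the effect-mode definitions applied to
the underlying rewrite:

* A bond X--Y whose partner Y survives is *consumed*, not degraded (the
  rewrite is X--Y → Y--0, and Y appears on the product side), and the
  partner's empty domain Y--0 is conditionally produced, guarded by the
  bond. This is what conserves Y when X is degraded out of a dimer. With
  the bond classed as a degradation instead, the dimer can never assemble
  under an active degradation clamp, the release never fires, and Y is
  silently lost — measurably: two interaction-motif configurations then
  converge to all-false instead of conserving B. Intra-molecular bonds
  (both carriers on X) stay degradations and release nothing.
* A degradation gated by a single required contingency whose effector is a
  top-level OR is duplicated, one reaction per disjunct. This mirrors the
  published tool's accounting of degradation targets; the exact published
  duplication semantics is defined in the language reference rather than
  derivable here, so parity beyond the top-level-OR case is not claimed.

### Source-state smoothing

The raw rules produce spurious period-two oscillations whenever an active
modification or interaction cycle runs with only one of the mutually
exclusive forms initiated: each firing depletes its own source pool, so
the two half-reactions alternate out of phase. Over a large pool of
molecules such phase locking is unphysical, so the default compilation
*smooths* the source-state check of producing reactions: each source
state $S_j$ in a producing primed reaction becomes $S_j(t) \cup
S_j(t+1)$, where $S_j(t+1)$ is the full non-smoothed update expression of
$S_j$ expanded in time-$t$ targets. The expansion is exactly one level
deep and never recursive; the synthesis term and the degradation and
consumption checks are left unsmoothed, so the hierarchy is untouched.
Smoothing removes the oscillations and changes nothing else: every motif
configuration whose raw attractor already matched its expected steady
state keeps the identical point attractor (verified exhaustively by the
motif suite). Its only cost is larger update expressions. The smoothing
assumption breaks down for few molecules and slow reactions, where
out-of-phase behaviour can be real; `compile_options(smoothing = FALSE)`
restores the raw rules.

## Validation fixtures

### The two minimal motifs

The state rule was designed against the two smallest complete test beds:

* a **modification motif** — component A with one phosphosite (states
  `A_[(r)]-{0}`, `A_[(r)]-{P}`) and four reactions: synthesis (produces
  the neutral state), degradation (either state), phosphorylation and
  dephosphorylation;
* an **interaction motif** — components A and B with one binding domain
  each (states `A_[d]--0`, `B_[e]--0`, `A_[d]--B_[e]`) and four
  reactions: synthesis of A, degradation of A (releasing `B_[e]--0` from
  the dimer), association and dissociation.

The motif reactions are clamped constants (constitutively true or false),
not contingency-gated: the motifs isolate the state update rule.
Enumerating clamps and initial state values gives $2^6 = 64$ and
$2^7 = 128$ configurations. For each configuration an *expectation
oracle* states the desired steady state. The oracles are closed-form case
analyses written down from the motifs' design rules, independent of the
update-rule calculus: no reactions — the initial state persists; an
active cycle without turnover — both forms present once the components
are; one cycle direction only — the pool collects in the product form;
degradation without synthesis — the degraded component's states clear
(the interaction motif releasing and conserving free B); synthesis — the
neutral state always present, downstream states present iff actively
produced or initially present with every removal route off.

Rows of the interaction table that the design rules do not fix uniquely
were completed by the same quasi-steady-state reasoning and the whole
128-row table frozen at `inst/extdata/interaction_expected.csv`; the
runtime oracle only reads the frozen file, and a test checks the
generating analysis still reproduces it, so the oracle and the engine
cannot drift together. `run_motif_suite()` compiles every configuration,
simulates it from its initial vector and compares point attractors
against the oracle (a cyclic attractor never matches). The expected
outcome, which the test suite asserts: 62/64 raw — the two exceptions
being the cycle configurations initiated in a single state, each a
period-two oscillation — and 64/64 and 128/128 with smoothing.

### The HOG pathway

`hog_model()` builds a small real pathway, the Sln1 branch of the yeast
high-osmolarity glycerol (HOG) MAP kinase cascade, as a transcription in
the package's model dialect. Under turgor, the sensor Sln1
autophosphorylates (`!` `[Turgor]`) and relays the phosphate Sln1 → Ypd1
→ Ssk1; phosphorylated Ssk1 cannot activate the cascade. Unphosphorylated
Ssk1 binds the MAPKKK Ssk2 (a bidirectional interaction gated
`x Ssk1-{P}`), the bound form drives Pbs2 → Hog1 → Hot1 (each kinase step
requiring the upstream activation), and a generic phosphatase reverses
the Ssk1, Pbs2, Hog1 and Hot1 phosphorylations. The compiled model has 29
targets: 12 reaction targets (the interaction contributes its association
and dissociation halves), 15 elemental states, one generic component
state for the phosphatase, and the input `[Turgor]`.

A note on this reconstruction: a naive transcription with seven
phosphosites and a phosphorylation-based Ssk2 activation yields only 14
elemental states and cannot reach the published target structure. The
Ssk1–Ssk2 *interaction* variant used here matches both the structure
(15 elemental states, 12 reaction targets after the bidirectional split)
and the biology — unphosphorylated Ssk1 binding and activating Ssk2 is
the accepted mechanism of this branch.

The behavioural checks mirror the pathway's physiology. Linear model,
smoothed: a three-phase input-toggling workflow (off → on → off) reaches
point attractors with `Hot1-{P}` always inverted relative to `[Turgor]`.
Linear model, raw: every phase ends in a period-two attractor — the
constitutive phosphatase/kinase and association/dissociation cycles keep
oscillating, which is exactly why smoothing is the default. Cyclic model
(adding the physiological feedback `[Turgor] out Hot1_[(S)]-{P}`,
abstracting glycerol accumulation): started from the linear model's off
attractor, the system settles into a genuine limit cycle in which turgor
itself switches on and off.

## Numerical and design choices

* **Determinism.** Compilation is a pure function: target order follows
  declaration order (states, then reactions, then inputs), symbols are
  sanitised deterministically with a numeric de-collision suffix, and the
  engine is synchronous and exact, so identical inputs give byte-identical
  `.boolnet` files and identical trajectories.
* **Attractor detection** hashes every visited vector (exact first
  recurrence; no sampling). The state spaces handled here are tiny
  compared to the full $2^n$ — only one trajectory is followed — so
  memory is never a concern at this scale. Exhaustive initial-state
  scans are deliberately out of scope.
* **Default initial vector.** Neutral elemental states and generic
  component states true, everything else false — a deliberately
  artificial "all pools neutral" start from which the model finds its own
  off state. One refinement: a target whose rule is a clamped constant is
  initialised at that constant, so clamped targets never change value.
* **Input toggling.** Phase 1 runs with inputs false; each later phase
  flips the toggled inputs in the seed vector (identity self-updates make
  the values stick) and re-simulates from the previous attractor. The
  workflow stops when an attractor recurs — compared with the toggled
  inputs masked out, so an input-insensitive model stops after two
  phases — or after `max_phases` (default 10). If a phase ends in a
  cyclic attractor the next phase continues from the attractor's first
  state; the toggling step strictly expects point attractors, so this
  fallback is a pragmatic choice, recorded in the result.
* **Problem sizes.** The motif suites enumerate all 64 + 128
  configurations per smoothing setting and the HOG models have 29
  targets; the full test suite and the acceptance script each run in
  seconds on one core.

## What the fixtures do and do not show

The motifs and the HOG transcription exercise every reaction type the
compiler knows (synthesis, degradation with bond release,
(de)phosphorylation, phosphotransfer, autophosphorylation, bidirectional
interaction), nested and quantitative contingencies, inputs and outputs.
They are still idealised: clamped reactions stand in for unmodelled
regulation, and the expectation oracles encode designed behaviour, not
measurements. Passing them shows the compiler implements the calculus and
that the calculus reproduces the designed motif behaviour and the known
input-output logic of one well-understood pathway — not that any larger
curated network is biologically correct. Larger models (the compiler
imposes no size limit) bring their own curation problems: constitutively
active branches, missing turnover constraints and similar reconstruction
gaps surface as wrong attractors, which is precisely the validation use
the method is intended for.

Other known limitations: Excel-based model files are not read (transcribe
to the text dialect); there is no export to rule-based languages or
graphical formats; quantitative contingencies are either ignored or made
absolute, with nothing in between; and states more than one production
step from their synthesised neutral state are rejected rather than
supported by an extended synthesis term.
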