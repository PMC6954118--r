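# rxnbool

Parameter-free bipartite Boolean models from reaction-contingency
descriptions of signal transduction networks.

## The problem

Signal transduction works through site-specific state changes —
phosphorylation of particular residues, bonds between particular domains.
Models that enumerate full molecular configurations (microstates) explode
combinatorially, and quantitative models additionally need rate constants
that are mostly unmeasured. `rxnbool` is for modellers who have the
*structure* of a network — which elemental reactions exist, and which
elemental states each reaction depends on — and want to simulate and
validate it without fitting a single parameter.

A model is two tables: an **elemental reaction list** (each reaction
defined only by the states it synthesises, degrades, produces or
consumes) and a **contingency list** (Boolean constraints `!`, `x`, `K+`,
`K-`, `0`, `?` attaching states and inputs to reactions). The compiler
turns this into a bipartite Boolean network with one update rule per
**reaction target**,

    R_i(t+1) = K(R_i) ∧ L(R_i)

(reacting components present, strict contingencies satisfied), and one
per **state target**,

    S_i(t+1) = Σ(S_i) ∨ ( K(S_i) ∧ ⋀_deg ¬R'_k ∧ [ ⋁_prod R'_l ∨ (S_i ∧ ⋀_cons ¬R'_m) ] )

where `R' = R ∧ (source states)` is a reaction primed with its substrate,
`Σ` is the synthesis term and `K(S_i)` the carrier-presence expression.
The rule encodes the hierarchy synthesis > degradation > production >
consumption. By default, producing reactions are *source-state smoothed*
(`S_j` widens to `S_j(t) ∨ S_j(t+1)`, expanded one level), which removes
the spurious out-of-phase oscillations of modification and interaction
cycles and changes nothing else. A synchronous engine simulates the
compiled model to its exact attractor, and an input-toggling workflow
probes input-output behaviour. Models are written and read in the
standard BoolNet text format.

## Worked example: the HOG pathway

The package ships a transcription of the Sln1 branch of the yeast
high-osmolarity glycerol (HOG) pathway: under turgor, Sln1
autophosphorylates and relays the phosphate via Ypd1 to Ssk1;
unphosphorylated Ssk1 binds and activates the MAPKKK Ssk2, which drives
the Pbs2 → Hog1 → Hot1 kinase cascade against a constitutive phosphatase.
Low turgor therefore switches the pathway on, high turgor off.

```r
library(rxnbool)

net <- hog_model()
net
#> <rxncon_network> 12 reactions, 16 states, 5 contingencies, 1 input(s)

m <- compile_bbm(net)          # smoothing on by default
m
#> <bbm> 29 targets (16 state, 12 reaction, 1 input); smoothing on

wf <- input_toggle_workflow(m, inputs = "Turgor")
wf
#> <workflow_result> 3 phase(s), termination: attractor_revisited
#>   phase 1: inputs {Turgor=0}, period 1
#>   phase 2: inputs {Turgor=1}, period 1
#>   phase 3: inputs {Turgor=0}, period 1
```

The 29 targets are 12 reactions, 15 elemental states plus the generic
phosphatase's component state, and the input `[Turgor]`. The workflow
simulates from the default initial vector (all neutral states true) to
the pathway's natural off state, then toggles turgor twice; every phase
ends in a point attractor (`period 1`), and it stops when the third
attractor revisits the first. Inside the high-turgor attractor the relay
has fired and shut the cascade down:

```r
att <- wf$phases[[2]]$result$attractor[[1]]
att[c("Ssk1_RR_P", "Ssk1_kd_Ssk2_rd", "Hog1_T_P", "Hot1_S_P")]
#>       Ssk1_RR_P Ssk1_kd_Ssk2_rd        Hog1_T_P        Hot1_S_P
#>            TRUE           FALSE           FALSE           FALSE
```

Phosphorylated Ssk1 is present, so the Ssk1–Ssk2 complex cannot form and
the downstream phosphorylations are off — the transcription-factor output
`Hot1-{P}` is the inverse of the turgor input in all three phases.
Compiling with `compile_options(smoothing = FALSE)` instead leaves every
phase in a period-two cyclic attractor, which is why smoothing is the
default. `hog_model(cyclic = TRUE)` closes the physiological feedback
loop (`[Turgor]` driven by `Hot1-{P}`) and yields a limit cycle in which
turgor itself oscillates.

The motif suites that validate the update rules against their designed
steady-state expectations are available directly:

```r
cmd_validate_motifs()
#> modification 62/64 (raw), 64/64 (smoothed); interaction 109/128 (raw), 128/128 (smoothed)
```

The two raw modification mismatches are the phosphorylation cycles
initiated in a single state — the period-two source-depletion
oscillations that smoothing exists to remove.

A command-line wrapper with verbs `compile`, `simulate`, `workflow` and
`validate-motifs` is installed at
`system.file("exec", "rxnbool", package = "rxnbool")`; `compile` writes
the `.boolnet` model, `_symbols.csv` map and `_initial_vals.csv` vector,
and `--smoothing`, `--k-plus` and `--k-minus` expose the compile options.

See `vignette("bipartite-boolean-models")` for the full account of the
update rules, the smoothing construction, the motif oracles and the
design choices.

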