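---
title: "A contextual gating model of entorhinal-hippocampal memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A contextual gating model of entorhinal-hippocampal memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hippoctx` simulates context-dependent associative memory in the
entorhinal-hippocampal system with rate-coded point neurons. Five cell
populations are modeled: the superficial (ECin) and deep (ECout) layers of
the lateral entorhinal cortex, the dentate gyrus (DG), and areas CA3 and
CA1. Cortical inputs describing an odor discrimination problem (two odor
cues X and Y, and a reward pool R identifying the baited odor) arrive at
ECin as binary 6-of-24 codes; the hippocampus must learn the association
and later complete the missing R pattern at ECout from the odor cues
alone.

Each cell integrates a shunting membrane equation

$$\frac{dV_m}{dt} = \tau\left[\bar g_l (E_l - V_m) + g_e \bar g_e (E_e -
V_m) + g_i \bar g_i (E_i - V_m)\right],$$

with activity given by a saturating half-wave rectifier
$y = \chi/(1+\chi)$, $\chi = \Upsilon\,[V_m - \theta]_+$. The inhibitory
drive $g_i$ is shared across a layer and set each step by a
k-winners-take-all (kWTA) rule: the layer computes, for each cell, the
inhibition level at which that cell would sit exactly at threshold given
its excitatory drive and its own inhibitory conductance, and places $g_i$
between the k-th and (k+1)-th largest of these supports
($g_i = g_\theta^{k+1} + q\,(g_\theta^k - g_\theta^{k+1})$, floored at
zero). Layer conductances, reversal potentials, the activation gain and
threshold, $q = 0.25$, and the kWTA fractions (25% in the entorhinal
layers, 1% in DG, 2.5% in CA3/CA1) follow the model's standard parameter
table; see `layer_params()`.

Connectivity follows the known anatomy: perforant-path projections from
ECin to DG, CA3 and CA1 (25% connection probability), sparse potent mossy
fibers from DG to CA3 (4%, absolute scale 10, relative weight 3.5), full
Schaffer collaterals from CA3 to CA1 (absolute scale 5), full CA3
recurrent collaterals, full CA1 to ECout back-projections (relative
weight 2), and a one-to-one intracortical return from ECout to ECin.
Trisynaptic pathways learn by pure Hebbian updates
($\Delta w = y^+ (x^+ - w)$, self-bounding); the monosynaptic pathways
(ECin to CA1, CA1 to ECout, ECout to ECin) mix a small Hebbian fraction
($k_{hebb} = 0.05$) with a contrastive-Hebbian error term
($\Delta w = x^+ y^+ - x^- y^-$, soft-bounded), all scaled by a learning
rate and clipped to $[0, 1]$.

### Contextual gating

The model's central hypothesis is that top-down (prefrontal) signals
contextualize memory by biasing DG excitability. The DG is partitioned
into four equal contextual ensembles; under normal operation the maximal
inhibitory conductance $\bar g_i$ of every granule cell outside the
current context's ensemble is raised from 1 to 5, so the layer-wide kWTA
competition is effectively confined to one ensemble. Inactivating the
prefrontal cortex (the muscimol condition) removes the bias: all granule
cells return to normal excitability and every ensemble competes. Because
DG selects CA3 attractors through the mossy fibers, contextual gating of
DG decides which memories can be encoded into, and completed by, the CA3
recurrent network. A mossy-fiber lesion (`set_mossy_lesion()`) severs
exactly this link and abolishes the context effects.

### Theta-phase trial structure

A trial runs three settling phases of 30 steps each. In the first minus
half-phase the CA3 influence on CA1 is gated off: CA1 forms an
auto-encoded representation of its entorhinal input. In the second minus
half-phase the direct ECin input to CA1 is gated off instead: CA1 is
driven purely by CA3 pattern completion, and the model's recall - the
reward field of ECout at the end of this phase - is read here. During the
plus phase the full pattern (including the revealed reward code) is
presented and ECout is clamped to it; weights update at its end.

Two details of the phase scheme are deliberate design choices of this
package. First, the reward field is absent from ECin during both minus
half-phases of every trial (the animal does not know the outcome before
choosing); it appears only in the plus phase. This makes the per-trial
performance readout a genuine cued recall rather than an echo of the
input. Second, CA1 receives both its input streams during the plus phase,
so its encoding representations are conjunctive - they carry both the
entorhinal cue and the hippocampal (context-specific) completion. We found
the conjunctive plus phase essential for storing conflicting lists: with a
purely monosynaptically driven plus phase, two lists sharing the same odor
cues select overlapping CA1 cells and the second list overwrites the
first's output mappings, collapsing context-guided retrieval (about 70%
on the first list after the second is learned, versus about 97% with the
conjunctive representation).

CA1 and ECout membrane potentials reset to rest at every phase start, all
other layers at trial start. Resetting ECout alongside CA1 keeps the
phase-2 readout strictly a function of the pathway that owns CA1 in that
phase; with carry-over, the first half-phase's monosynaptic output (which
the contrastive rule trains toward a context-blind cue-to-answer mapping)
persists through a weakly driven recall phase and masks retrieval
deficits.

## Numerical choices

*Integration.* The membrane equation is integrated with a semi-implicit
(backward Euler) step at rate `tau = 0.3` per 1-ms step. The fixed point
is identical to the forward form, but the step is unconditionally stable;
forward Euler would require `tau * g_total < 2`, and contextual
suppression alone (suppressed $\bar g_i = 5$ against kWTA drives of order
1.5) breaks that bound, let alone learned mossy-fiber drives.

*Net input scaling.* The summed drive a cell receives from one projection
is divided by (number of received connections) x (expected activity of
the sending layer, i.e. its kWTA fraction). This keeps dense cortical
pathways and sparse potent pathways (mossy fibers, CA3 recurrents) on the
same conductance scale, so the tabulated conductances and scale factors
are meaningful for both. With the expected activity set to 1 the rule
reduces to a plain average over received connections.

*kWTA with heterogeneous inhibition.* Contextual suppression makes
$\bar g_i$ per-cell. The kWTA ranking therefore uses the support
$g_\theta(g_e)/\bar g_i$ per cell, which reduces exactly to the textbook
rule when $\bar g_i$ is uniform, and makes one layer-wide competition
behave like a competition within the facilitated ensemble when it is not.

*Weight contrast enhancement.* CA3 recurrent collaterals transmit a
sigmoidal contrast-enhanced function of their stored weights
(`wt_sig()`, gain 6, midpoint 0.8 - just above the 0.75 initialization
ceiling). Learning always operates on the linear weights. Without it,
never-trained cells (whose uniform [0.25, 0.75] weights average half
transmission on every input) stay competitive with tuned engram cells
during recall, and pattern completion degrades with every imperfectly
reinstated input. We confine the enhancement to the recurrent collaterals:
applied to the feedforward encoding pathways it has the opposite
pathology, letting previously tuned cells dominate the competition for
*new* patterns and collapsing pattern separation across lists.

*Learning rates.* The learning rates are not published for this model;
they are exposed in `network_config()` and default to 0.7 for the
Hebbian pathways and 0.3 for the mostly error-driven pathways. They were
calibrated once, during model development, so that a control rat acquires
an eight-problem list to criterion (90% in two consecutive blocks) in
roughly six to eight blocks with visible learning inside the first three
blocks - the regime the behavioral protocols assume - and were then
frozen. Substantially faster error-driven learning lets the monosynaptic
pathway relearn cue-to-answer mappings within a list's training window,
which erodes the context specificity of retrieval; substantially slower
rates push criterion beyond 20 blocks and flatten every early-training
contrast.

*Ties and degenerate input.* kWTA ties put cells at exactly $g_i$ below
threshold (conservative); a layer with no suprathreshold support gets
$g_i = 0$ and stays silent; cells with no incoming connections from a
projection receive zero drive from it.

## The behavioral protocols

All stimuli are generated by `make_experiment_stimuli()`: independent
6-of-24 binary odor codes; a list of eight problems $\{X_i, Y_i\}$ with a
random baited side; the same pairs with reversed reward for the
context-reversal task; two "lifetime experience" pre-training lists
$\{X_i, Z_i\}$ and $\{Z_i, Y_i\}$ that each share one odor with the main
list (run for 10 blocks each in contexts C and D before every experiment
unless disabled); and a conflicting second list in which one odor of each
pair is retained, its partner replaced by a novel odor, and the retained
odor's reward prediction reversed.

Five protocol runners reproduce the inactivation experiments:
`run_navawongse()` (context-guided retrieval with and without the bias),
`run_p1a()` (concurrent acquisition and test with inactivation windows),
`run_p1b()` (blocked one-at-a-time acquisition), `run_p2()` (conflicting
list in same vs. different context, 2x2 with inactivation), and
`run_p3()` (inactivation during the first list only; the facilitation
reversal). Each returns a tidy trial log; `summarize_blocks()`,
`condition_block_anova()`, `interference_index()`, `p1a_test_drop()` and
`classify_error()` implement the standard analyses. Per-trial performance
maps recall error E onto
$P = \max(50, 100\,(1-E)^{10}/(0.5^{10} + (1-E)^{10}))$, which floors at
the 50% chance level of a two-alternative choice and stays below 100.

The criterion rule (90% mean block performance in two consecutive
blocks) is capped at 50 training blocks; a simulated rat that never
reaches criterion is flagged (`criterion_block = NA`) and continues into
the test phase with whatever it has learned, rather than aborting the
group.

## What the generator emulates, and what it does not

The synthetic odors are independent uniform 6-of-24 codes: they model
arbitrary, discriminable, equally salient odors with no similarity
structure. Real odors have correlated neural codes and generalization
gradients; none of the simulations here depend on them, but effects that
hinge on graded stimulus similarity are outside what a passing test
demonstrates. Likewise the four disjoint DG ensembles idealize contextual
coding (biological ensembles overlap by about 1% and are continually
reshaped by neurogenesis), so context separation in the model is exact by
construction rather than statistical. Reward learning is reduced to a
nearest-pattern choice on the recalled reward field; there is no
value learning, no vicarious trial and error, and no motivational state.

## Known limitations

Two qualitative results deviate from the target phenomena at the default
study sizes, for reasons that appear structural rather than statistical;
both are asserted honestly (and fail) in the acceptance suite:

* *Re-access of memories encoded under inactivation.* Associations
  encoded while the bias is removed recruit granule cells scattered over
  all ensembles (only about a quarter fall in the current context's
  ensemble). Once the bias is restored, the layer-wide competition
  confines recall to the context ensemble, and the scattered engram
  cannot be re-ignited: rats inactivated for the first three blocks of a
  list restart learning afterwards instead of converging with controls by
  block five. The same property strengthens the (reproduced) facilitation
  of conflicting-list learning after inactivation.

* *Error taxonomy.* During conflicting-list acquisition the model makes
  more non-perseverative than perseverative errors, the reverse of the
  behavioral finding. Pattern separation is strong enough that a
  half-changed cue rarely completes to the old engram - which removes the
  main generator of perseverative choices - while problems whose new
  answer is the retained odor must additionally unlearn the old readout
  and accumulate errors.

* *Facilitation without pre-training.* For the same reason - near-total
  separation of half-overlapping cues within a context - control rats
  suffer little proactive interference from the first list when no
  lifetime pre-training is simulated, so the predicted residual
  facilitation of second-list learning after inactivation (and its
  decline with denser dentate activity) is a fraction of a percentage
  point and statistically indistinguishable from zero. With pre-training
  enabled, the facilitation reversal is large and robust.

The sparseness sweep, the dentate-activity prediction (counted as
distinct granule cells recruited across a session, the c-Fos analogue;
per-trial counts are pinned at k by exact kWTA), the mossy-fiber lesion,
and the pre-training dependence of the retrieval deficit all behave as
predicted; see `tests/testthat/test-acceptance.R` for the precise
assertions and the problem sizes used (ten simulated rats per group,
default network sizes of 72/1600/240/400/72 cells for
ECin/DG/CA3/CA1/ECout).
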