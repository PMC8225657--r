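---
title: "Simulating single cells from regulatory networks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single cells from regulatory networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grnsim produces single-cell datasets in which every observation has a
known cause. This vignette explains the generative model, the parameters
that matter, and the design choices taken where several defensible
options existed. It states no numbers that the package's tests and
acceptance script do not themselves compute.

## The generative model

### From module network to gene regulatory network

The dynamic process is specified coarsely as a *module network*: modules
of co-regulated genes connected by signed interactions. A module can
have basal expression (it transcribes without an activator) and can be
marked active during the warm-up ("burn") phase that establishes the
initial expression state. The topology of the module network is what
determines the topology of the resulting trajectory: a chain of
upregulating modules yields a linear process; making the last module
repress the first closes the chain into a cycle; two mutually repressing
modules form the decision point of a bifurcation; a bifurcation resolved
during the warm-up phase, followed by a shared chain, yields a
converging process. The catalogue (`list_backbones()`) provides 14 such
designs. Only the linear, cyclic, bifurcating, converging and
disconnected archetypes are canonical; the other nine are compositions
of the same motifs (trees, loops, consecutive and converging
bifurcations) chosen to cover the topology space evenly, and their exact
make-up is a design of this package.

The gene-level network is generated in four steps: transcription
factors (TFs) are assigned to modules (at least one per module, the rest
uniformly at random) and inherit the module's basal expression and
warm-up flag; module interactions are expanded to TF-level edges
(deterministically, as the full bipartite set, so every TF of a
regulated module is regulated); target genes are drawn from a reference
network weighted by PageRank (damping 0.85) and wired by the induced
subgraph, capped at 5 regulators per target and guaranteed downstream of
at least one TF; housekeeping genes are collected by breadth-first
search in the reference network and remain completely disconnected from
the TF/target part. In place of an experimentally derived reference
network the package ships a preferential-attachment generator
(`generate_reference_network()`) producing hub-dominated directed graphs
with bounded in-degree; any user edge list can be supplied instead. The
reference network only shapes the wiring of targets and housekeeping
genes; effects of induced edges are drawn activating with probability
0.75 and strengths log-uniform on [1, 10] (rounded up), since no
empirical assignment is available for synthetic wiring. A target or
housekeeping gene whose sampled regulators are all repressors is given
basal expression 1, otherwise it could never be expressed.

### From network to reactions

Each gene contributes three molecular species — pre-mRNA $x_G$, mature
mRNA $y_G$, protein $z_G$ — and six reactions: transcription
($x_G{+}1$), splicing ($x_G{-}1, y_G{+}1$), translation ($z_G{+}1$,
catalytic in $y_G$) and one degradation per species. All propensities
except transcription are linear (rate constant × molecule count).

Transcription follows a thermodynamic promoter model. With $N$
regulators, the promoter occupies $2^N$ bound states; state $j$ has
statistical weight $w_j = \prod_{i \in j} \nu_i$ with
$\nu_i = (z_i / k_i)^{n_i}$ the Hill occupancy of regulator $i$
($k_i$ = abundance at half-occupation, $n_i$ = Hill coefficient), and a
relative activation $\alpha_j \in [0, 1]$. Taking $\alpha_j = 0$
whenever a repressor is bound and 1 otherwise, and introducing a basal
activity $ba$ and a regulator synergism $sy$, the $2^N$-term average
collapses to

$$ f(z_1,\dots,z_N) \;=\; xpr \cdot
   \frac{ba - sy^{|R^+|} + \prod_{i \in R^+} (\nu_i + sy)}
        {\prod_{i \in R} (\nu_i + 1)} $$

where $R$ indexes all regulators and $R^+$ the activators. The test
suite verifies this closed form against a brute-force enumeration of all
$2^N$ states (to relative error below $10^{-12}$ for $N \le 10$), its
monotonicity in each regulator, and its limits ($f = xpr \cdot ba$ with
all regulators absent; the activator-product form at $ba = sy = 1$).
For non-negative occupancies and $ba \in [0, 1]$ the numerator is
bounded by the denominator, which is what keeps the per-interaction
regulatory effects (below) in $[-1, 1]$.

Two readings in the source model description were ambiguous and resolved
as follows: the promoter-state weight condition is read as "regulator
$i$ is bound in state $j$" (bit $i$ of the state index), the only
reading consistent with the worked two-regulator case; and splicing is
read as converting one pre-mRNA into one mature mRNA.

### Kinetic constants

Rates are per simulation time unit, roughly an hour of real time, with
defaults reflecting typical mammalian medians: mRNA half-life 2.5,
protein half-life 5 (degradation = $\ln 2$ / half-life), splicing and
translation 2 events per molecule per time unit, and a pre-mRNA
production rate of `10 * base_mrna_production` (the 10-fold
amplification keeps copy numbers high enough that trajectories are not
drowned in shot noise). These are configuration defaults
(`kinetics_config()`), not measured values.

The mapping from an interaction's integer *strength* to its
half-occupation constant is a package design choice the source model
leaves unstated: $k_i$ is the regulator's expected steady-state
abundance divided by the strength, log-normally jittered (sd 0.25).
Stronger interactions therefore respond at lower regulator abundance.
Hill coefficients are drawn uniformly from [1, 2] by default — smooth
but switch-capable responses; the model remains well behaved up to the
typical upper bound of 10. The jitter and the Hill draws are the only
stochastic parts of a kinetics draw, and are what makes batch and
paired-trajectory datasets differ. Regulation acts through the
regulator's protein by default (proteins are the acting species);
`regulator_layer = "mrna"` switches to mRNA.

## Simulation

Cells are simulated with the exact direct-method SSA: waiting time
$\tau = \ln(1/r) / \sum_j \text{prop}_j$, reaction $j$ chosen with
probability proportional to its propensity. The core is compiled (Rcpp)
and uses R's RNG, so runs are reproducible from R seeds. Approximate
accelerations (tau-leaping) are deliberately not implemented. Each run
starts from an empty cell, executes a warm-up phase (default 2 time
units) in which only warm-up-marked modules and housekeeping genes are
transcribed, then the main phase (default `total_time = 15`, within the
usual 10–20 range). The default was set by measuring the emergent
cascade speed under the default kinetics: one module takes roughly 3
time units to activate the next, so a five-module chain needs ~12 time
units after warm-up. Censuses are recorded every 0.01 time units by
default (0 records every event), including molecule counts, all reaction
propensities, and the number of firings per interval — the raw material
for the velocity and network ground truths. 32 independent runs back one
dataset by default; the number is a free parameter.

## Ground truths

**Trajectory.** The reference ("gold standard") trajectory integrates
the same propensity functions deterministically (mean-field ODE, lsoda)
along each state-network transition, starting from the end state of the
upstream transition and masking TF transcription by the modules
prescribed for that transition. A noise-free reference makes the
correlation mapping stable, which is why a deterministic integration is
used rather than one stochastic draw. Each transition of length $L$ is
integrated for $L \times$ `tau_per_length` (default 3, matched to the
measured cascade speed). Cells are mapped to the reference point with
the highest Spearman correlation over TF mature-mRNA features; ties —
frequent on plateaus, where rank patterns repeat — are broken by
Euclidean distance and then towards the earliest pseudotime. Pseudotime
is the geodesic distance from the start (summed upstream transition
lengths plus the fractional position), rescaled to [0, 1].

**RNA velocity.** The true velocity of a gene in a cell is the
transcription propensity minus the mature-mRNA degradation propensity at
the cell's census state (a `"premrna"` switch uses the pre-mRNA
degradation propensity instead, as the definition is ambiguous about the
layer). Note that at stationarity the mean of this quantity is slightly
positive — pre-mRNA degradation diverts part of the transcription flux
before splicing — so it approximates $dy/dt$ exactly only when pre-mRNA
degradation is slow relative to splicing; the acceptance script reports
the correlation between the two on the mean-field trace.

**Cell-specific network.** The regulatory effect of $R$ on $T$ in state
$S$ is
$(\text{proptrans}_T(S) - \text{proptrans}_T(S[z_R \leftarrow 0])) / xpr_T$:
the drop in transcription propensity when the regulator is removed,
scaled to $[-1, 1]$. The printed form of this definition zeroes $z_T$;
the accompanying text says the *regulator* is set to zero, and only that
reading yields a per-interaction activity, so $z_R$ is zeroed. For the
binary ground truth an interaction is active when
$|\text{regeffect}| \ge 10^{-4}$ (a threshold is needed for AUROC/AUPR
and none is prescribed; at threshold 0 "active" means any nonzero
effect).

## Experiment emulation

Snapshot sampling allocates $N_i = N \cdot L_i / \sum L$ cells to each
transition (largest-remainder rounding so the allocations sum exactly to
$N$; the formula as printed in the source description,
$N / (L_i / \sum L)$, grows with $1/L_i$ and cannot sum to $N$, so the
evident intent is implemented). Warm-up states are never sampled.
Time-series sampling divides $[0, T]$ into $k = 8$ windows separated by
gaps of $g = 0.75$. Molecules are then drawn per cell: a library size
from either a log-normal model (median 5000 counts, CV 0.6 — typical of
droplet protocols — and overridable by the empirical totals of any user
count matrix) and a single multinomial draw over all $3G$ species with
probabilities proportional to capture rate × true abundance. Capture
rates are drawn once per species from $N(1, 0.05)$ — read as standard
deviation 0.05 — truncated at 0. Observed totals therefore equal the
drawn library sizes exactly.

Batch effects are emulated by sharing the module network and GRN but
redrawing kinetics per batch; paired-trajectory datasets (for trajectory
alignment benchmarks) share one GRN and draw kinetics, gold standard and
cells twice.

## Evaluation metrics

`dtw_align()` is the classical dynamic-programming DTW with steps
(1,0), (0,1), (1,1); the tests check it against exhaustive path
enumeration on small grids. The alignment score
(`abwap()`) integrates $|pt_1 - pt_2|$ against $pt_1 + pt_2$ along the
path by the trapezoid rule and subtracts from 1, so identical
pseudotimes aligned index-by-index score 1 and the degenerate alignment
scores 0. Velocity predictions are scored per gene by Spearman
correlation with the true velocities, and directionally by the
waypoint cosine: 100 waypoints uniformly spread over the trajectory,
cells weighted by a Gaussian kernel on geodesic distance (bandwidth =
median nearest-waypoint spacing, since none is prescribed), weighted
average embedded velocity compared with the local direction of the
embedded reference trajectory. The embedding is caller-supplied; the
bundled default is a deterministic PCA projection of the true spliced
counts so no external tool is needed. Cell-specific network predictions
keep the top 10,000 interactions per cell and are scored by rank-based
AUROC and average precision (step-wise precision–recall integration)
against the binarised ground truth, averaged over cells.

## What the defaults do and do not emulate

The generator reproduces: discrete molecule counts with intrinsic
(shot) noise, spliced/unspliced/protein layers, trajectory-structured
heterogeneity, library-size variation, species-level capture
efficiency, batch-like kinetic variation. It does not model: UMI
collisions or amplification noise, doublets, ambient RNA, cell-cycle or
extrinsic covariates, motif/sequence information, or cell–cell
communication. Tests passing on these data show that a method can
recover structure a mechanistic model generated; they do not show
robustness to the artefacts listed above.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks are stable: oracle
comparisons at up to 10 regulators; stationary statistics from a single
gene simulated for 600 time units; pipeline checks on linear-backbone
datasets of 50 genes × 300 cells (16 SSA runs) and paired datasets of
30 genes × 2 × 100 cells. A desktop-scale dataset of a few hundred genes
and a few thousand cells takes on the order of a minute.

## Known limitations

Mean-field gold standards linearise away stochastic branch choice, so
for backbones whose decisions happen in the main phase the reference
branch a cell is mapped to is decided by correlation, not by the cell's
own realised decision. Pseudotime–simulation-time agreement degrades
when a stochastic run stalls at a decision point (the cell genuinely is
earlier in the process than the clock suggests). Converging state
networks assign the converged state the expression of the
first-reached upstream branch. Disconnected processes are modelled as a
warm-up-phase decision between otherwise independent lineages.
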