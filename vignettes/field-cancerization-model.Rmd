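---
title: "A hybrid cellular-automaton model of the cancer field effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid cellular-automaton model of the cancer field effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldCA)
```

## The model

Field cancerization is the process by which chronic carcinogen exposure —
tobacco smoke and alcohol in the case of head-and-neck squamous cell
carcinoma (HNSCC) — preconditions a region of histologically benign
epithelium toward cancer. Tumors then arise inside this *field* of
genetically altered cells, and excising the tumor while leaving the field
behind invites rapid recurrence.

`fieldCA` simulates this process as a hybrid cellular automaton on an
N × N toroidal lattice. Each site is empty or holds one cell of six
classes: normal tissue cells (NTC), mutated normal tissue cells (MNTC),
normal stem cells (NSC), mutated normal stem cells (MNSC), cancer stem
cells (CSC) and tumor cells (TC). Every cell carries

* a gene-expression vector $E(t) \in \mathbb{R}^G$ (0 = normal expression),
* a phenotype-probability vector $P(t) = (p, q, a, d)$ over proliferation,
  quiescence, apoptosis and differentiation, with $\sum_i P_i = 1$,
* transit-amplifying bookkeeping $(\bar\tau, \bar n)$ and a lineage id,
* its age $\alpha(t)$ in time-steps since the last mitosis.

One time-step represents one cell cycle ($\tilde c = 10$ h for tongue
epithelium), so a cell performs exactly one phenotypic action per step.

### The gene network

Expression changes are computed per cell by a two-layer perceptron. Its
input is $X = [c_1, \dots, c_C, \alpha]$ — the local carcinogen
concentrations and the cell age — and its output
$\bar\delta = \gamma(W_Y\, \gamma(W_X X) + b)$ is the vector of maximum
per-gene expression changes this step, where

$$\gamma(\xi) = \frac{\xi}{1 + \nu\,\xi^2}, \qquad \nu = 10^6$$

is an odd activation with a single maximum $1/(2\sqrt\nu) = 5\times10^{-4}$
at $\xi = 1/\sqrt{\nu} = 10^{-3}$. The carcinogen columns of $W_X$ hold
per-gene signs (+1 up-regulation, −1 down-regulation, 0 none) taken from
the panel annotation; the age column holds $\pm 10^{-7}$ with signs redrawn
each step from Bernoulli(½) flips, modelling undirected replication errors
that accumulate with age. $W_Y$ encodes gene–gene regulation: diagonal
weights built as 0.1 plus 0.1 per regulated gene (TP53, taken to interact
with all panel genes, gets 1.0) and off-diagonal ±0.01 per activation.
Each gene then moves by $e_j \mathrel{+}= z_j\,\bar\delta_j$ with
independent $z_j \sim U(0,1)$. Genes whose $|e_j|$ reaches the mutation
threshold $\bar M = 0.1$ acquire a reinforcing bias $b_j = \pm\beta$
($\beta = 10^{-3}$), which drives the network output for that gene to the
activation maximum — mutations entrench themselves.

A gene is *positively mutated* when it moves past the threshold in the
cancer direction (suppressor down, oncogene up); a cell with at least
$\Upsilon = 4$ positively mutated genes is classed mutated. During the
genetic-instability stage every mutated gene acts on the genes it is
related to (matrix $R$): positively mutated sources push their targets
toward the cancer direction, protectively mutated sources repair them
toward 0, each related pair firing with probability 0.45 and moving the
target by at most $1/\nu$. We restrict this stage to *mutated* sources:
instability is a mechanism of mutated genes influencing related genes,
and letting unmutated genes repair constantly would leave unmutated TP53
(related to all genes) suppressing every gene at once — under combined
exposure, whose opposing TP53 weights cancel, no field could ever form.

### The default HNSCC panel

The shipped panel (`hnsccPanel()`, editable YAML in
`inst/extdata/hnscc_panel.yaml`) covers five tumor suppressors (TP53,
TP73, RB, TP21, TP16) and five oncogenes (EGFR, CCDN1, MYC, PIK3CA, RAS)
with two carcinogen columns. Column 1 is the alcohol-type exposure and
column 2 the smoking-type exposure; the ordering is a named field of the
panel file, chosen so that ethanol up-regulates TP53 as its +1 entry
requires. Phenotype effects of each gene (e.g. mutated TP53: proliferation
up, apoptosis and quiescence down) are stored as per-gene annotations and
compiled into the 4 × G increment matrices $\bar U = -\bar D$ with
magnitude $10^{-6}$; each increment is applied with probability 0.35 per
step and balanced against quiescence, after which the vector is clipped at
0 and renormalized. The matrices $W_Y$ and $R$ are generated from the
panel's regulation lists by the construction rules above rather than
transcribed, and the unit tests pin the resulting diagonals and row sums.

### Cell classes, hierarchy and competition

The per-class initial phenotype table is built from the cell cycle length
$\tilde c$, the tissue and stem lifespans ($\bar c_1 = 250$ h,
$\bar c_2 = 25{,}550$ h), proliferation factors $\bar p_1 = 0.65$,
$\bar p_2 = 14.75$, the apoptotic factor $\bar\alpha = 1.625$ and the
differentiation factor $\bar d = 1.485$: initial apoptosis is
$\bar a_k = \tilde c / \bar c_k$, mutated classes divide it by
$\bar\alpha$, cancer classes by $(5\bar\alpha)^2$, stem classes carry
differentiation mass $\bar d \tilde d$ with
$\tilde d = 1/(2^{\Theta+1}-2)$, and quiescence takes the remainder so
each row sums to 1 exactly.

Differentiating stem cells produce transit-amplifying cells (TACs): the
daughter carries its destination class (NTC, MNTC or TC for NSC, MNSC,
CSC parents) with $\bar\tau = 1$, receives a proliferation boost of 1/3
(taken from quiescence), and every division advances the generation
counter on both cells until $\bar n = \Theta = 2$, at which point the flag
clears — a clone of at most $2^{\Theta+1}-2 = 6$ cells. Representing TACs
by their destination class keeps the gap between the first CSC and the
first TC short (≈3–4 steps, the differentiation waiting time); a latent
TAC class would delay the first TC by the full amplification time.

Competition is fitness-based:
$f = w_p P_p - w_a P_a - w_{age}\,\alpha/L + \text{bonus}\cdot
1[\text{CSC or TC}]$ with $L$ the class lifespan in steps and unit default
weights — the minimal form that is increasing in proliferation, decreasing
in apoptosis and age, and favors cancer classes. Proliferation and
differentiation into an occupied site succeed only against a less fit
occupant, except that CSC/TC parents kill a fitter non-cancer occupant
with probability $\kappa = 0.2$. Quiescent cells move with probability
0.25 into empty neighbors; only CSC/TC may displace-and-kill while moving
(probability 0.2, and against another cancer cell only when the victim is
less fit). Mutation classification is re-evaluated every step, so NTC ↔
MNTC and NSC ↔ MNSC are reversible; CSC and TC are absorbing. Mutated
stem cells become CSCs with probability $2.5\times10^{-6}$ per step.
Dedifferentiation (probability $10^{-4}$ when a non-stem cell sees no
stem cells, or at least six empty sites, in its Moore neighborhood)
maintains the stem-cell share; it maps NTC→NSC, MNTC→MNSC and TC→CSC.

We restrict spontaneous CSC conversion to *mutated* stem cells by default
(`cscFromNormalStem = FALSE`): applied to all stem cells, the default rate
would generate roughly two dozen spontaneous cancers in a 10-year
carcinogen-free simulation, while carcinogen-free tissue is required to
stay healthy. The permissive reading remains available via the flag.

### Step timeline and reproducibility

Each step applies, in order: (1) the gene-network forward pass, (2) the
expression update, (3) genetic instability, (4) the phenotype update, (5)
class transitions (mutation status, TAC maturation, CSC conversion), (6)
dedifferentiation, (7) one sampled phenotypic action per cell with
movement, (8) a scheduled excision. Stages 1–6 are per-cell and read no
other cell's mid-step values (stage 6 reads the start-of-step class
snapshot); stage 7 walks the sites in a fresh uniform random permutation
with sequential conflict resolution (the first actor claims a site, cells
born or moved this step do not act again). The paper-level sources are
silent on the update order; the random permutation avoids directional
sweep artifacts. On a class change the phenotype vector is reset to the
new class's initial row — the simplest rule consistent with the initial
table's role, since accumulated phenotype drift is orders of magnitude
smaller than the between-class differences. The whole simulation consumes a single R RNG
stream in a documented order (cells row-major for stages 1–6, genes in
panel order, then the permutation and per-site action draws), so a
`set.seed()` makes runs bit-reproducible; seeds and the full configuration
are echoed into run metadata.

## Calibration

With the default constants, unit carcinogen concentrations sit deep in the
activation's decaying tail ($\gamma(1) \approx 10^{-6}$), so per-step
pre-bias expression changes are $\sim 10^{-6}$ and no gene could reach
$\bar M = 0.1$ within any plausible exposure history. The age
channel, by contrast, already operates near the activation peak for old
stem cells. A single global output scale therefore cannot calibrate the
model: any factor large enough to make carcinogen-driven mutation
observable amplifies the undirected age-sign random walk of old stem
cells past the mutation threshold, seeding mutants in carcinogen-free
tissue. We expose two knobs instead, both defaulting to 1 (the printed,
uncalibrated parameterization) and both recorded in run metadata:

* `carcinogenGain` — an input gain mapping unit concentration into the
  activation's responsive range; experiments use $10^{-3} = 1/\sqrt\nu$,
  placing full exposure at the activation peak.
* `expressionScale` — a global output gain; experiments use 5.

Under this calibration (chosen once, from the drift analysis above) a
fully exposed cell accumulates its fourth positively mutated gene after a
few hundred steps — months of exposure at the 10-hour cell cycle — while
carcinogen-free tissue remains quiet: the age-driven
random walk of a stem cell's most responsive gene stays well inside the
threshold over its lifespan. Because the mutated-cell criterion needs
four positively mutated genes and the alcohol-type column drives only
three genes toward cancer (EGFR, CCDN1, RAS; it pushes TP53, TP21 and
TP16 *away* from their cancer direction), alcohol-only exposure produces
no mutated cells at all — while the smoking-type column drives eight genes
toward cancer and forms a field reliably. The potency ordering is thus
structural, not a tuning outcome.

## Desk-scale experiment designs

The packaged tests run every experiment at reduced scale on one CPU; the
vignette states these sizes as the package's choices.

* *Homeostasis*: 128², zero carcinogens, 1,000 steps at the uncalibrated
  defaults. The tissue settles near 58% NTC / 7.5% NSC / 34% empty with
  no mutated classes; conservation of the $N^2$ sites is asserted every
  step.
* *Carcinogen potency*: 5 replicates per arm, 128², the centered Gaussian
  exposure $c(x,y) = \exp(-((x-\mu)^2+(y-\mu)^2)/2\sigma^2)$ with
  $\mu = N/2-1$, $\sigma = N/15$, 600 steps, smoking-only vs alcohol-only.
* *Excision*: 5 seed-matched pairs at 128² under a broader Gaussian
  ($\sigma = N/4$) of both carcinogens, so that a substantial healthy
  margin survives field removal; excision triggers 18 months after the
  first TC; recurrence censored at the 3,600-step horizon. The paper-width
  Gaussian holds too few stem cells in its core for the $2.5\times10^{-6}$
  CSC rate to fire on any desk-scale horizon, which is why the excision
  and clonality designs widen or flatten the exposure rather than raise
  any rate.
* *Clonality vs grid size*: uniform exposure of both carcinogens; runs
  proceed to the first TC (capped) plus a fixed 300-step window, then
  lineages holding CSC/TC cells are counted. CSC conversions arrive at
  rate `cscProb` × (mutated stem cells), which scales with grid area:
  64² grids mostly stay monoclonal within the window while 256² grids
  accumulate several cancer lineages.

## What the simulations do and do not show

The generator emulates the qualitative biology: homeostatic tissue with a
maintained stem-cell hierarchy, carcinogen-shaped field growth, stochastic
cancer initiation through the stem compartment, faster recurrence when a
field is left behind, and predominantly polyclonal fields on large
domains. It does not model telomeres, immune response, angiogenesis,
HPV-type viral input, carcinogen pharmacokinetics or 3-D tissue
architecture, and the gene network is a stylized encoding of known
regulation signs, not a fitted model — absolute event times in calibrated
units should not be read as patient-scale predictions. Passing tests
demonstrate internal consistency and the qualitative orderings above, not
quantitative agreement with clinical HNSCC incidence.

## Numerical choices

* Activation outputs are bounded by $1/(2\sqrt\nu)$, not by the naive
  $1/\nu$; tests assert the analytic bound and the looser $10^{-3}$
  envelope.
* Phenotype vectors are clipped at 0 and renormalized after each update;
  if a vector ever degenerates to all-zero mass it falls back to pure
  quiescence.
* Repair during genetic instability never overshoots 0.
* Initial ages are drawn uniformly over one expected class lifespan to
  avoid synchronized apoptosis cohorts (`coldStart = TRUE` restores
  all-zero ages for deterministic unit tests).
* Exact-count randomized rounding makes seeded class counts match the
  configured fractions to within one site.
* Excision geometry removes the Chebyshev-2 block around each TC
  ("two rings"), the only shape-coherent reading of the removal rule.
* The dedifferentiation trigger uses "no stem cells or at least six empty
  neighbors"; both thresholds are configuration fields because the two
  prose statements of the rule disagree.
* Months convert at 730.5 h/month and $\tilde c$ h/step, so 18 months
  ≈ 1,315 steps at the default cell cycle.

## A worked run

```{r, eval = FALSE}
library(fieldCA)
panel <- hnsccPanel()
cfg <- simConfig(carcinogenGain = 1e-3, expressionScale = 5)
g <- gaussianField(128)
fields <- list(carcinogenField("alcohol", g), carcinogenField("smoking", g))
set.seed(1)
state <- initGrid(128, cfg, panel)
res <- runSimulation(state, panel, fields, cfg, steps = 1500,
                     recordStride = 10, seed = 1)
eventRecord(res)
plotClassFractions(res, months = TRUE)
```
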