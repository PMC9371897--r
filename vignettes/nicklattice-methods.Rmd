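---
title: "Modelling ligation-induced stabilization and reconfiguration of DNA lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligation-induced stabilization and reconfiguration of DNA lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicklattice)
```

## The system

Addressable DNA wireframe lattices are assembled from junction motifs —
4-arm (J4) or 3-arm (J3) junctions, or double-crossover (DX) tiles — in
which every component strand occupies a unique designed position. Each
motif arm carries an intramotif *root* duplex and a single-stranded *stem*
domain; two facing stems hybridize into an intermotif edge. Because the
strand backbones are discontinuous, every edge carries two *nicks*: points
where a 3'-hydroxyl and a 5'-phosphate abut on a continuous complementary
template. A DNA ligase can seal each nick into a phosphodiester bond,
fusing the short stem duplex with the adjacent root into one long ligated
segment (21 bp for an 11-bp root + 10-nt stem design).

Sealing has two consequences this package models:

* **Stabilization.** A short stem duplex buried inside a long covalent
  segment can no longer dissociate on its own (a kinetic interlocking
  effect). Ligated lattices therefore melt some 20 °C above unligated
  ones.
* **Programmability.** Whether a given nick is sealable is controlled per
  nick by 5'-phosphorylation. Leaving chosen edges unligatable and then
  heating above the unligated-stem melting regime dissociates exactly
  those edges: sub-lattice shapes can be carved out (loss of ligation
  function), or transient sticky-end boundary overhangs can be locked in
  to roll a sheet into a tube (gain of function).

## The lattice graph model

`build_lattice()` turns a `lattice_design()` (motif type, grid size,
domain lengths, boundary policy, phosphorylation mask) into an explicit
typed graph: motifs, strands, duplexes (intramotif roots, intermotif
stems, boundary sticky ends), edges and nicks.

The wiring rule for J4 motifs: each motif has one strand per arm; in
cyclic arm order, the strand of arm $k$ runs 5'→3' through stem($k$),
then the inward root half of arm $k$, then the outward root half of arm
$k+1$. Each intermotif edge then carries exactly two nicks, one per
junction, and each nick has three strand roles: the strand whose 5' end it
joins (label X~I~), the strand whose 3' end it joins (X~II~), and the
continuous complementary strand across it (the template, label Y).

```{r}
lat <- build_lattice(builtin_design("J4-I"))
lat
count_nicks(lat)
sum(lat$edges$class == "intermotif")
```

A 6×6 J4 lattice has 60 intermotif edges and 120 nicks; a fully ligated
lattice closes one covalent 4-strand ring around every interior plaquette
(25 rings for 6×6). The J3 brick-wall (6×7, 108 nicks, 18 free arms) and
the two DX-tile lattices (146 and 110 nicks) are available as
shipped configurations. The J3 horizontal/vertical wiring follows a
parity rule (motif $(r,c)$ carries a south arm iff $r+c$ is even); the DX
wiring is a deliberately minimal construction — half-offset brick rows
with 11 sticky-end joints per row gap, DX-I adding one internal nick per
tile — chosen to realize the reference nick counts. Both are disclosed
as constructions of this package rather than transcriptions of a specific
strand diagram.

## Ligation simulation and product enumeration

`seal_nicks()` seals each ligatable nick independently with probability
$p$ (the per-nick ligation efficiency). One uniform draw per nick, in
stable nick-id order, makes the sealed set nondecreasing in $p$ under a
fixed seed — every downstream Monte-Carlo curve is exactly monotone, not
just statistically so.

`enumerate_products()` walks the covalent successor structure to list the
product species (member strands, length, circular or linear);
`product_distribution()` averages species frequencies and mass fractions
either exactly (summing all $2^N$ sealed states, capped at $N \le 22$) or
by Monte Carlo. On the 2×2 calibration lattice the single designed ring
closes with probability $p^4$, so `estimate_efficiency()` inverts an
observed circular fraction to $\hat p = f^{1/4}$:

```{r}
l2 <- build_lattice(builtin_design("J4-I_2x2"))
d <- product_distribution(l2, p = 0.89, mode = "exact")
circ <- d$species[d$species$circular, ]
circ$frequency
estimate_efficiency(circ$frequency, n_nicks = 4)
```

## Lock-in and the intermediate thermal regime

Temperature enters as a regime, not a degree scale. Below the stem/root
melting nothing dissociates; above the melting of the long ligated
segments only covalent products remain. The interesting regime is the
intermediate one (heating above ~50 °C for a 10-bp-stem design):

* a strand with a sealed terminal nick (X~I~ or X~II~) is **fully**
  locked — it is covalently buried in a longer segment;
* a strand whose terminal nicks are all unsealed is retained only
  **partially**, by default when every nick it templates (its Y nicks) is
  sealed, so that its pairing domains sit on continuous ligated templates;
* everything else dissociates.

Retention is computed as an increasing closure: the fully locked strands
seed the assembled network, and partially held strands join only if a
locked duplex connects them (directly or through other partial strands)
to it. The closure direction matters: a decreasing cascade would let
pairs of unligated strands mutually anchor and survive at $p = 0$,
contradicting the requirement that an unligated assembly dissolves
entirely in this regime. An unligated intermotif stem duplex itself
dissolves (it is above its melting regime); only boundary sticky-end
duplexes at or above the permanence length (default 10 bp, the
sticky-end positive control) persist without ligation, and nicks sitting
on such permanent duplexes are exempt from the Y-nick requirement.

`intact_proportion()` Monte-Carlos this model. Two criteria are offered:

* `all_strands_retained` (default): one lost strand counts as failure.
  This is deliberately conservative — some scored dissociation events
  would be transient in reality — and on a 6×6 lattice it is a very
  strict yardstick: with 144 strands, each failing with probability
  $\approx (1-p)^3$, the all-strands indicator is small even at
  $p = 0.7$.
* `single_connected_component`: the retained strands form one hybridized
  assembly; loss of individual strands is tolerated. This criterion
  captures the observation that efficiencies above ~0.7 suffice for
  gross lattice survival.

```{r}
l6 <- build_lattice(builtin_design("J4-I"))
intact_proportion(l6, p = 0.7, n_reps = 200, seed = 1)$intact_fraction
intact_proportion(l6, p = 0.7, n_reps = 200, seed = 1,
                  criterion = "single_connected_component")$intact_fraction
```

The Monte-Carlo path is validated against an independent exhaustive
enumeration (`intact_proportion_exact()`) on the 8-nick 2×2 lattice.

## Melting curves

Survival rates $S(T)$ (band intensity after incubation at $T$, normalized
to an untreated control) are fitted with a Boltzmann sigmoid
$$S(T) = S_\mathrm{bot} + \frac{S_\mathrm{top} - S_\mathrm{bot}}
 {1 + e^{(T - T_{1/2})/w}},$$
or with a two-transition mixture (`fit_double_boltzmann()`, weights
$\varphi$ and $1-\varphi$, ordering $T_1 < T_2$ enforced by fitting the
nonnegative gap) for designs whose short stems melt in a first stage well
below the roots. The melting temperature is defined as the temperature at
which the *fitted* curve crosses $S = 0.5$ — not the inflection
parameter; the two differ whenever the plateaus are not exactly 0 and 1.
Fits are unweighted least squares on the raw replicate points via
minpack.lm; the double fit is multi-started from steepest-descent and
level-crossing seeds and keeps the lowest-RSS solution.

```{r}
truth <- melt_truth("single", T_half = 53, w = 3, noise_sd = 0.05)
fit <- fit_boltzmann(gen_survival_dataset(truth, seed = 1))
fit$Tm
```

Closed-loop recovery (synthetic truth → noisy data → fit) is the test
strategy: measured Tm values are wet-lab quantities that cannot be
recomputed, but the fitter's ability to recover a known truth within
1 °C (single) / 2 °C (double transitions) can be verified exactly.

## Reconfiguration, tubes, rings

`reconfigure()` applies a phosphorylation mask, seals at $p$, applies the
intermediate-regime survival model and compares the surviving hybridized
components against a target motif shape. The three shipped mask fixtures
are straight-seam carving patterns on the 6×6 J4-I lattice leaving 96, 96
and 108 of 120 nicks ligatable; at $p = 1$ each carves exactly its target
sub-lattice. The seam geometry of the shipped masks is this package's
own construction, chosen to realize those ligatable counts.

`classify_topology()` handles the sheet-to-tube gain-of-function mode: a
boundary sticky-end duplex is *permanent* when it is complementary and
either one of its nicks is sealed or its length reaches the permanence
threshold; the lattice is tubular when every row's east–west wrap is
closed. The four boundary variants of `tube_design()` (3-nt complementary
/ non-complementary / unligatable overhangs, 10-bp sticky ends) reproduce
the expected control truth table.

`ring_census()` collects the covalent rings of an outcome and links two
rings when they share a duplex in the assembled state — a declared,
conservative surrogate for topological catenation in a woven lattice,
isolated behind one predicate so a geometric test could replace it.
`percolation_probability()` estimates the chance that one interlocked
ring component spans all four lattice sides (chain-mail regime), and
`exonuclease_survival()` applies the covalent-circularity survival rule.

## Reproducing the workflow

The `analysis/` directory holds numbered driver scripts
(`01_lattice_accounting.R` … `05_reconfiguration.R`) that run the full
workflow with the package's default study conditions and write tables to
`results/`. All randomness is seeded; design fixtures regenerate
byte-identically via `gen_fixture_designs()`.
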