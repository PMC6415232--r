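---
title: "Equilibrium and collapse of the charged bead-spring chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium and collapse of the charged bead-spring chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccgel)
```

## The model and its assumptions

The package implements the equilibrium theory of a "one-dimensional
gel": an infinite line of identical unit point charges connected by
identical Hooke springs of zero rest length. Without charge the chain
would collapse to a point; the screened Coulomb repulsion between beads
stretches the springs to a common equilibrium length $b_{eq}$, which we
take as the measure of swelling. The treatment is mean-field
throughout: the solvent is a dielectric continuum characterised by one
number, the Bjerrum length

$$ l_B = \frac{e^2}{4\pi\epsilon_0\epsilon k_B T}, $$

beads have no excluded volume, the chain is long enough to neglect end
effects, and dissolved salt enters only through the Debye constant
$\kappa^2 = 4\pi l_B \sum_i c_i z_i^2$. Only the added salt
contributes to $\kappa$; the chain's own counterions do not. Because
$\kappa \propto \sqrt{l_B}$ at fixed molarity, every sweep over $l_B$
recomputes $\kappa$.

Two closed-form free energies per bead (in $k_BT$) describe the two
charge-density regimes, separated by the counterion-condensation
threshold $b = z\,l_B$:

$$ g_{dh}(b) = \tfrac12 a b^2 - \frac{l_B}{b}\ln(1 - e^{-\kappa b}),
   \qquad b > z\,l_B, $$

$$ g_{cc}(b) = \tfrac12 a b^2
   - \frac1z\Big(2 - \frac{b}{z l_B}\Big)\ln(1 - e^{-\kappa b})
   - \frac1z + \frac{b}{z^2 l_B}, \qquad b < z\,l_B. $$

The $g_{cc}$ expression combines the spring energy with the nonlinear
electrostatic free energy of a condensed-counterion layer: reduced net
charge, translational entropy of the condensed ions, and the
determination of the layer volume. The grouping of terms used here is
the unique one under which $g_{cc}(z l_B) = g_{dh}(z l_B)$ identically
— at the threshold the logarithm coefficients both reduce to $1/z$ and
the last two terms cancel. Continuity is physically required (the two
branches describe the same chain at the same spacing) and is enforced
as a randomised test at $10^{-12}$.

## Equilibria, bistability, and the transition funnel

On each branch, $b_{eq}$ is the root of $\partial g/\partial b = 0$
with positive curvature. A branch's root is physical only on its own
side of the threshold: the solver returns roots on the wrong side
flagged invalid rather than erroring, because branch termination — the
root crossing $b_{eq} = z\,l_B$ — is precisely what delimits the
transition range. Over an interval of Bjerrum lengths both branches
hold valid minima and the piecewise landscape is a double well whose
barrier sits exactly at the junction $b = z\,l_B$: a stretched
counterion-free state coexists with a contracted condensed state.
`find_overlap_range()` locates the interval edges by bisection on the
signed quantity $b_{eq}(l_B) - z\,l_B$, one branch per edge, after a
coarse bracketing sweep (step 0.05 nm, small enough not to miss the
narrow intervals that occur at large $a$). `funnel_map()` repeats this
over a grid of spring constants; the widths shrink monotonically with
$a$, the per-$a$ intervals merging into a funnel centred on the line
$b_{eq} = z\,l_B$ in the $(l_B, b_{eq})$ plane.

## The collapse model

Condensed counterions sitting between adjacent beads can act as
additional bonds. Condensation theory puts the local concentration of
condensed counterions at $1/(8\pi e l_B b^2)$ per unit volume ($e$ =
Euler's number); those within a cylinder of volume $\pi l_B^2 b$ per
bead — $(1/8e)\,l_B/b$ ions — are close enough to matter, and each is
assumed to add $t$ to the spring constant:

$$ a(b) = a_0 + \frac{1}{8e}\,t\,\frac{l_B}{b}. $$

This makes the elasticity nonlinear and self-reinforcing: contraction
stiffens the springs, which resists Coulomb stretching, which
contracts further. The construction is self-consistent only while the
full condensed layer, of radius $R = \sqrt{8e(l_B/b - 1)}\,b$, is wider
than $l_B$; the admissible ratios are the roots of
$x^2 - 8e\,x + 8e = 0$, $x = l_B/b \in (1.05, 20.7)$ to printed
precision. `validity_window()` returns the full-precision roots and the
solvers warn, rather than stop, when a solution leaves the window.

Two solution schemes are provided, because the feedback can be closed
in two ways:

* **composite** (default): substitute $a(b)$ into the spring term and
  minimise $g(b) = \tfrac12 a(b) b^2 + g_{cc}^{elec}(b)$ directly. The
  stiffening contributes a constant force $\tfrac12 (1/8e)\,t\,l_B$ to
  the stationarity condition.
* **iterative**: freeze $a$, solve the rigid branch, update $a$ from
  the new $b_{eq}$, repeat to a fixed point. Here the stiffening force
  is $(1/8e)\,t\,l_B$ — twice the composite weight, because a frozen
  $a$ ignores that stretching sheds active counterions.

The two fixed points therefore differ quantitatively (the iterative
one is always more contracted); this is a genuine modelling choice, not
a numerical discrepancy. Both reproduce the three collapse regimes that
the model is built to exhibit — $t = 0$: only the mild passive
contraction of condensation; moderate $t$ (e.g. 4 nm⁻²): little effect
near the threshold, substantial contraction at large $l_B$; large $t$
(e.g. 50 nm⁻²): stiffening dominates $a_0$ from the outset and strong
contraction begins right at the condensation threshold. The composite
scheme is the default because it minimises a single well-defined free
energy.

## Parameters and defaults

| parameter | units | default | meaning |
|---|---|---|---|
| `a0` | nm⁻² | — (required) | bare spring constant; must be > 0 — with $a = 0$ the DH branch has no bounded minimum |
| `z` | — | 1 | unsigned counterion valence; sets the threshold $z\,l_B$ |
| `t` | nm⁻² | 0 | stiffening per active condensed counterion |
| `temperature` | K | 298.15 | used only when the solvent is given as a dielectric constant |
| `b_range` | nm | (10⁻³, 10²) | search bracket for $b_{eq}$; spans every regime treated here with wide margin |
| `tol` | nm | 10⁻¹⁰ | convergence tolerance on $b_{eq}$, far below any two-decimal quantity of interest |
| overlap `tol` | nm | 10⁻⁴ | bisection tolerance on the interval edges |

Physical constants are the 2019 SI exact values; concentrations convert
to number densities as mol/L × N<sub>A</sub> × 10⁻²⁴ nm⁻³. A root
within 10⁻⁸ nm of the threshold counts as "at threshold, valid", since
a branch legitimately terminates exactly there.

## Numerical choices

Stationary points are found from the analytic derivative: a 600-point
log-spaced scan of the bracket locates descending-to-ascending sign
changes, each polished by `uniroot` at $10^{-12}$; among multiple
minima the one of lowest $g$ is reported. This is robust to the
two-minima landscapes of the transition range, where blind
minimisation could land in either well. The logarithm
$\ln(1 - e^{-\kappa b})$ is evaluated via `expm1` for accuracy at small
$\kappa b$; the unscreened limit $\kappa \to 0$ makes the per-bead free
energy diverge (an infinite unscreened line charge) and is rejected
with guidance rather than returned as `-Inf`. Tests cross-check every
solved equilibrium against a derivative-free brute-force oracle: a
coarse log grid followed by a $10^6$-point fine grid (resolution
2×10⁻⁸ nm) around the coarse argmin, agreeing to 10⁻⁶ nm. Free-energy
values are checked to 10⁻¹³ against values frozen from a 50-digit
transcription of the formulas in an independent arbitrary-precision
evaluator.

Degenerate inputs: `solve_branch` refuses chains with $t > 0$
(directing to `solve_collapse`); brackets that exclude the minimum
produce an explicit "no equilibrium"/"collapsed to bound" diagnostic
rather than a clipped number.

## Presets

The built-in presets fix the parameters of the model's canonical
scenarios: `fig1` ($l_B$ = 1.7 nm, 1:1 salt at 0.01 and 0.001 M,
spring-constant sweep on the condensed branch), `fig2`/`fig3` (the
transition range and its double-well landscape at $a$ = 0.1 nm⁻²,
0.01 M, $l_B$ = 2.0 nm for the landscape), `fig4` (funnel for $a$ = 5,
1, 0.1 nm⁻²), `fig5` (condensed branch to $l_B$ = 40 nm) and `fig6`
(collapse curves, $t$ = 0, 4, 50 nm⁻²). Where a scenario leaves a
parameter unstated (`fig5`/`fig6` salt, `fig6` $a_0$) the presets use
the family values 0.01 M and $a_0$ = 0.1 nm⁻². Grid resolutions are
plotting choices: 0.05 nm in $l_B$ for sweeps, 0.005 nm in $b$ for
landscapes, 0.25 nm in $l_B$ for collapse curves — every preset runs in
seconds.

## What the tests do and do not show

The model is deterministic and closed-form, so the test suite probes
exact structure rather than statistical recovery: branch continuity,
the algebraic identities of the condensed layer, oracle equivalence of
the solvers, the monotonicities (stiffer springs stretch less, lower
salt swells more, the funnel narrows with $a$), band structure of the
Bjerrum sweep, and the three collapse regimes. Passing says the
implementation solves *this* model faithfully; it says nothing about
how well a one-dimensional mean-field chain describes a real
three-dimensional gel — no excluded volume, no inter-chain
interactions, no Donnan equilibrium, no dielectric saturation, and no
dynamics (the fluctuations between the two wells are described only by
the double-well topology, not by rates).

One numerically delicate point is deliberate: the condensed branch at
$t = 0$ is *not* monotone in $l_B$ — it swells slightly to a shallow
maximum near $l_B \approx 5$ nm (at $a_0$ = 0.1 nm⁻², 0.01 M) before
the gradual ≈25% contraction at high Coulomb strength, because
$\kappa \propto \sqrt{l_B}$ strengthens screening only slowly. The
monotone-contraction test therefore starts past the maximum.

## Known limitations

Beyond the model-level assumptions above: the overlap-range edge
definition (branch root crossing $b_{eq} = z\,l_B$) is the natural one
and reproduces the known endpoints, but near-grazing crossings at very
large spring constants may need a finer `coarse_step`; the iterative
collapse scheme is not guaranteed to converge for extreme $t$ (it is
capped at 200 iterations and reports its iteration count); and the CLI
writes floats at 12 significant digits, so files round-trip to ~5×10⁻¹²
relative, not to machine precision.
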