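---
title: "Event-driven 1D circuit analysis of droplet microfluidic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven 1D circuit analysis of droplet microfluidic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropnet)
```

## The model

Passively operated droplet chips are designed on the one-dimensional
hydraulic circuit model. For laminar, viscous, incompressible flow the
pressure drop across a channel is linear in its volumetric flow rate,

$$\Delta P = Q\,R,$$

so a microfluidic network is an electric-circuit analogue: channels are
resistors, pumps are sources, and the flow state (all $Q$ and $\Delta P$)
follows from two balance laws — the flows into a node sum to the flows out of
it, and the directed pressure gradients around any closed cycle sum to zero.

dropnet represents the chip as a directed graph. Edge direction is only the
*counting direction* of the flow; negative solved $Q$ means flow against it.
One balance equation is written per node (minus a reference node held at the
ambient pressure) and one pressure equation per fundamental cycle. The cycle
basis is built from a spanning tree (one cycle per chord), so a connected
graph with $|E|$ edges and $|V|$ nodes yields exactly $|E|-|V|+1$ cycles and
the system is square. It is solved by dense LU decomposition with row
equilibration and one step of iterative refinement; node-balance and
cycle-closure residuals are reported with every solve and stay below
$10^{-9}$ relative across the test fleet. The relative residuals are floored
at $10^{-3}$ of the network's flow/pressure scale, so stagnant side branches
(whose own gradients sit at round-off level) are measured against the problem
scale rather than against themselves.

### Channel resistance

For a rectangular channel of length $L$, width $w$, height $h$ and carrier
viscosity $\mu_c$, with section ratio $h/w < 1$:

$$R = \frac{a\,\mu_c\,L}{w\,h^3}, \qquad
  a = 12\left[1 - \frac{192\,h}{\pi^5 w}
  \tanh\!\left(\frac{\pi w}{2h}\right)\right]^{-1}.$$

This is the leading term of the exact Fourier-series duct solution; the
test suite verifies agreement with a 200-term series within 0.6 % over
$h/w \in (0, 0.9]$, with the error vanishing in the thin-slit limit.
`rect_channel_resistance()` enforces $h/w<1$ as a hard domain error; the
network layer orients each cross-section so the wider dimension plays the
role of $w$, which is exact because the physical resistance is symmetric
under $w \leftrightarrow h$. That is how 15–25 µm wide, 50 µm tall trap gaps
are handled.

### Droplets

A confined droplet (plug length $L_d$ greater than the channel width) adds a
resistance to the channel it occupies. At small capillary number and small
viscosity ratio the droplet's internal viscosity can be neglected and the
plug resistance is estimated as a fixed multiple of the continuous-phase slug
it displaces:

$$R_d = f_{\mathrm{plug}}\,\frac{a\,\mu_c\,L_d}{w\,h^3},
  \qquad f_{\mathrm{plug}} = 3 \text{ by default},$$

exposed as `plug_factor`. A channel holding $n$ droplets has
$R^* = R + n R_d$, which assumes droplets are spaced a few channel widths
apart so their perturbations do not interact; the engine counts violations of
that spacing (configurable, default 3 widths) as warnings rather than errors.
An unconfined droplet ($L_d \le w$) is a hard error in
`droplet_resistance()`; inside the engine it simply contributes no
resistance on that edge.

Droplets move faster than the mean carrier speed by a constant slip factor,

$$v_d = \alpha_s\,\frac{Q}{w\,h}, \qquad \alpha_s = 1.28,$$

valid for plug lengths between $1.5w$ and $7.2w$ and capillary numbers
between 0.001 and 0.01 without surfactant. `regime_check()` flags departures
from these windows as warnings — the model is an engineering estimate and a
hard failure would block design exploration.

### Laplace pressure

A droplet of radius $r_d$ resists being squeezed into a gap of width
$w_{\mathrm{gap}}$ up to the capillary threshold

$$\Delta P_{\mathrm{Lap}} =
  2\gamma\left(\frac{2}{w_{\mathrm{gap}}} - \frac{1}{r_d}\right):$$

the front meniscus takes the in-plane radius $w_{\mathrm{gap}}/2$ while the
rear keeps the droplet curvature, and the out-of-plane (height) curvature is
common to both menisci and cancels. The threshold is linear in the
interfacial tension $\gamma$ and vanishes with it.

## The event-driven engine

Between droplet events the flow state is constant, so droplet motion is
piecewise linear and the simulation can jump from event to event:

1. **Compute flow state** — assemble $R^* = R + nR_d$ per channel (occupied
   trap gaps additionally multiplied by the clog factor) and re-solve the
   Kirchhoff system. The result is cached and reused until an event
   invalidates it; an instrumentation counter verifies exactly one solve per
   event.
2. **Check objectives** — every registered objective is evaluated against
   the fresh flow state and reported; violations are logged and, only if
   `fail_fast` is set, stop the run.
3. **Next event** — the minimum over the next scheduled injection and, per
   flowing droplet, the remaining edge length divided by its speed.
   Zero-speed droplets contribute no event. Simultaneous events (within
   $10^{-12}$ s) are processed in droplet-id order.
4. **Advance** — all flowing droplets move by $v_d\,\Delta t$; the
   triggering droplet is injected, routed across its node, captured,
   merged, or removed at an outlet; per-edge counts and trap occupancy are
   updated and the flow cache invalidated.

Routing follows the highest outgoing volumetric flow at the node; exact ties
break deterministically to the lowest edge index. A droplet belongs to
exactly one edge (its head's edge) and transitions are instantaneous —
the resistance bookkeeping counts whole droplets per channel, so partial
straddling is unmodeled. Identical inputs give identical logs.

## The trap-and-merge cascade

The bundled case study is a cascade of trapping-well pairs fed by two
droplet streams. Per stream and pair: an entrance channel leads from the
junction J to the well (modelled as a short wide channel of length and width
$2r$); two narrow gaps (width $w_{\mathrm{gap}}$, length $L_2$) leave the
well in parallel to the downstream node D; a bypass of length
$L_{\mathrm{bypass}}$ connects J directly to D. The two facing wells of a
pair are joined by a narrow intersection channel (width $w_i$). This is the
fewest-element rendering of the published trap-pair topology; whether the
bypass rejoins per stream or into a shared manifold is ambiguous in the
source figure, so both are available (`bypass_topology`, default
per-stream). The template has closed-form counts of $8n+4$ nodes and
$13n+5$ edges for $n$ pairs.

Three objectives guard the working principle:

* **flow ratio** — at each junction with an *empty* well,
  $Q_{\mathrm{trap}} > Q_{\mathrm{bypass}}$ (the droplet must enter the
  well); with an *occupied* well the ratio must have flipped.
* **inter-trap squeeze** — the pressure difference between facing wells must
  stay below the Laplace pressure of their intersection.
* **downstream squeeze** — the well-to-downstream pressure difference must
  stay below the Laplace pressure of the exit gaps.

A trapped droplet clogs its two exit gaps: their resistances are multiplied
by a configurable `clog_factor` (default $10^4$). The published description
only requires the flow into an occupied trap to drop drastically, without a
mechanism; a large finite factor realises that while keeping the system
regular, and the trapped droplet itself contributes no channel resistance
(avoiding double counting). Squeeze-through is *not* simulated: a violated
squeeze condition is flagged but the droplet stays put — the 1D model has no
squeezing dynamics. Merging is instantaneous once both wells of a pair are
occupied.

### Default fixture parameters

The source study's device geometry lives in an earlier publication and is
not reproduced here, so the fixture ships one documented default set, chosen
once against the model's validity constraints and kept fixed:

| parameter | default | constraint it satisfies |
|---|---|---|
| channel width × height | 100 × 50 µm | $h/w = 0.5 < 1$ |
| trap radius $r$ | 100 µm | droplet $r_d = 90 \le r$ |
| entrance $L_1$ | 200 µm | follower does not touch a trapped droplet |
| gap width × length | 15 × 50 µm | retains $r_d = 90$ µm droplets |
| intersection $w_i \times L_i$ | 15 × 200 µm | weak stream coupling (below) |
| bypass $L_{\mathrm{bypass}}$ | 4000 µm | $Q_{\mathrm{trap}} > Q_{\mathrm{bypass}}$ |
| droplet $L_d$ | 250 µm | confined, $2.5w$ inside the 1.5–7.2 $w$ slip window |
| $\mu_c$, $\mu_d$, $\gamma$ | 5 mPa s, 1 mPa s, 0.05 N/m | $\lambda = 0.2$, Ca $\approx 2\times10^{-3}$ |
| inlet pressure | 50 mbar | all squeeze margins comfortable |
| pairs | 5 | studied cascade depth |

The intersection deserves a note: it is a droplet-merge port, not a carrier
path. If it is made as conductive as an ordinary channel, carrier flow
sneaks from a clogged well through the intersection into the facing well's
gaps and can transiently flip the facing *empty* well's flow ratio — a
pressure-independent effect, since flow ratios in a linear network do not
depend on the driving pressure. The default narrow intersection keeps the
streams weakly coupled so the working principle holds at every decision
instant.

The exploration grid studied by the robustness and exploration drivers is
$w_{\mathrm{gap}} \in \{15, 25\}$ µm $\times$ $L_{\mathrm{bypass}} \in
\{3000, 4000, 5000\}$ µm.

## Design exploration

* `min_bypass_length()` reduces the bypass stepwise and reports the smallest
  tested length for which the first injected droplet still enters the empty
  first well; the search range must bracket the transition and an optional
  bisection refines the boundary.
* `max_pressure()` increments the inlet pressure, runs a full cascade
  loading at each level, and returns the largest pressure with no objective
  violation at any evaluated flow state, together with the limiting
  objective (the squeeze conditions, in every configuration we examined).
  Pressures above the 5 bar PDMS operating ceiling are refused.
* `loading_time()` measures the simulated time from the first injection
  until every pair is occupied and merged, erroring with a timeout
  diagnostic (partial occupancy attached) if the cascade never fills and
  with a mis-route diagnostic if a droplet enters an occupied well.
* `robustness_report()` condenses a list of specifications into one row
  each: empty-trap flow ratio, maximal pressure, bypass margin, and
  qualitative flags (ratio below a configurable margin; pressure ceiling
  below a comfort margin; bypass long enough to cut throughput).

On the default fixture these drivers reproduce the qualitative design rules
the simulation-before-fabrication study reports: the minimal bypass is much
shorter at the wider gap; the pressure ceiling falls with bypass length and
rises for narrower gaps (higher Laplace threshold); loading time grows with
cascade depth and falls with pressure. The test suite asserts exactly these
trends; absolute numbers depend on the unpublished device geometry and are
deliberately not asserted.

## Numerical choices and problem sizes

* Linear algebra: dense LU (`solve()`) after row equilibration, one
  iterative-refinement step; networks of interest stay below ~600 edges,
  where assembly is O(non-zeros) per event thanks to a precomputed sparsity
  pattern for the cycle rows.
* Event ties: $10^{-12}$ s window, droplet-id order.
* Routing ties: lowest edge index.
* Positions are fractional in $[0,1]$ along the directed edge and clamped
  after each advance.
* The test fleet sizes were chosen to keep the whole suite around five
  minutes: 500 random solver networks of 5–50 edges, fixed-step oracle
  integrations at $2\times10^{-5}$ of a channel transit, cascade sweeps at
  15/30/45 pairs and 100/200/300 mbar, and one 45-pair, 90-droplet
  end-to-end load (~4200 events).

## What the synthetic fixtures do and do not show

The generated networks (ladders, loops, random connected graphs) and the
trap cascade exercise the solver, the event loop and the objective logic
under exactly the model's assumptions: quasi-static Stokes flow, whole-plug
resistance increments, constant slip, instantaneous transitions and merges.
Passing them shows the implementation is faithful to the 1D model — it does
not validate the model itself against a physical chip. Effects outside the
model are out of scope by construction: droplet formation, splitting and
mixing dynamics, squeezing motion through gaps, film/corner leakage past
trapped droplets, channel compliance and transient pressure dynamics, and
temperature-dependent viscosity. Where the model's own validity windows are
left (capillary number, viscosity ratio, plug length, droplet spacing) the
package warns and continues, because that is how the model is used in
practice: as a fast, conservative screen before fabrication.
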