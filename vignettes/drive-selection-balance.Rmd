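---
title: "Modeling self-limiting suppression by drive-selection balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling self-limiting suppression by drive-selection balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivebalance)
```

## The problem and the model

Sterile-male programs suppress pest populations but lose their causal agent
every generation, so they need large, sustained releases.  Gene drives
persist and spread, but spread is exactly what a *localized* program must
avoid.  `drivebalance` models a middle course: a **protected
dominant-negative editor (PDNE)** — an autosomal construct that

1. disrupts a haplosufficient (HS) gene, so two construct-bearing (or
   otherwise nonfunctional) copies are lethal (recessive cost, the
   "toxin" on the construct itself);
2. carries a germline editor (Cas9 + gRNA) that converts wild-type target
   alleles into *dominant* lethal edits in heterozygous carriers; and
3. is protected in cis against its own edits (in the single-locus design a
   premature stop upstream of the edited site; in the two-locus design a
   recoded rescue copy of the haploinsufficient target).

At construct frequency $q$ (censused at hatching, after embryonic edit
deaths), recessive lethality gives fitness $w_{rec} = 1-q$, and preferential
transmission through edit deaths gives $w_{dom} = 1/(1-q)$.  Their product
is 1 at every frequency: drive exactly balances selection, and the construct
neither spreads nor declines.  It nevertheless imposes a reproductive load

$$L(q) = \frac{2q}{1+q},$$

half from dying construct homozygotes, half from dominant lethal edits in
the unprotected gametes of heterozygotes.  `fitness_components()`,
`reproductive_load()`, `analytic_step()` and `analytic_recursion()`
implement this single-locus, single-sex model by genotype enumeration
rather than transcribed algebra; the idealized identity (`analytic_step(q)
== q` to 1e-12) anchors the implementation, and a cross-check against the
multi-locus gamete engine keeps the two code paths consistent.

Drive is prevented — the construct's fitness stays below one at all
frequencies — whenever $(s - hs)/(1 - hs) \ge u$ for homozygous construct
cost $s$, heterozygous cost $hs$ and editing rate $u$
(`no_drive_condition()`).  With $s = 1$ the construct can never drive.

## Demography

`simulate_release()` embeds the genetics in a discrete-generation, two-sex,
two-stage life cycle, normalized so the wild-type equilibrium has one adult
female and one adult male.  Each generation: released males are injected;
every fertile female mates once with a father drawn in proportion to
fertile-male counts; each female produces $2R_m$ juveniles; early-acting
genetic deaths occur; juveniles pass uniform density-dependent survival
$$\sigma(J) = \frac{1}{1 + (R_m - 1)\,(J/J_0)^{\theta}},$$
with $J_0 = 2R_m$ the wild-type juvenile cohort; late-acting deaths occur;
survivors are the next adults.  With $\theta = 1$ (the default,
`dd_exponent`) this is the Beverton–Holt form: it has the wild-type fixed
point exactly, low-density growth $R_m$, and is the conventional choice for
insect models of this kind.  The exponent is exposed so other compensation
shapes can be explored.

Because density-dependent mortality is uniform across genotypes, allele
frequencies in the demographic model follow the analytic recursion exactly
(verified to 1e-10 in the tests); density dependence shapes only the
counts.

Timing matters and is configurable per cost (`timing_edit`,
`timing_construct`, each `"early"`, `"late"` or `"fertility"`).  The
analytic census convention has edit deaths embryonic and construct deaths
post-census; the demographic comparisons follow the reference
configuration in which all costs act after density-dependent mortality —
early deaths are partially compensated by relaxed competition, which is
exactly why sterile males (early) underperform late-acting lethals at equal
release rates.

## Strategies

`make_strategy()` resolves a name plus options into loci, parameters and a
release genotype: `sit`, `ridl`, `fsridl`, `xs` (X-shredder), `yle`
(Y-linked editor), `fsridl_drive`, `pdne1`, `pdne2`, plus homing and
cleave-and-rescue boosters for the PDNE.  The parameter baseline is always
the idealized case (perfect efficiencies, no side costs, all deaths late);
overrides express the robustness deviations: editing rate `u`, edit cost
and dominance `s_edit`/`h_edit`, recessive-edit fraction `frac_recessive`,
construct dominance `h_construct`, and per-component loss-of-function rate
`mu_lof`.

Design choices worth recording, made where the source material left the
mechanism open:

* **Protection in cis is structural.**  The construct haplotype simply can
  never carry an expressed edit; there is no separate "protected edit"
  allele class.
* **Edited alleles keep host-gene function.**  The dominant-negative edit's
  entire cost is `s_edit`/`h_edit`: an edit homozygote pays `s_edit`, not
  recessive lethality.  This is what produces the observed robustness
  cliffs — once residual fitness $1-s_{edit}$ exceeds the load needed for
  the suppression goal, cleavage-resistant edited alleles replace the
  population and the strategy fails (at $R_m = 20$ the asymptotic load
  equals $s_{edit}$, so 95% suppression survives roughly 10% residual
  fitness, and about 50% at $R_m = 2$).  Recessive-class edits
  (`frac_recessive`) are, by contrast, plain nulls of the host gene.
* **Female-specific designs are doublesex-like.**  With `sex_limited_edit =
  "female_only"` the edit sits in a female-specific transcript: males are
  exempt from its dominant cost *and* the edited allele is a fully
  functional host-gene copy in males.  The construct's recessive lethality
  stays bisex.  This reproduces the reference behavior that female-specific
  editing costs almost nothing in efficiency.
* **Editing requires an intact construct allele** (both Cas9 and gRNA on
  the same haplotype); components do not complement in trans.
  Loss-of-function mutation acts per component, independently, during
  gamete formation, and derivatives retain the construct's recessive cost —
  which is why no derivative can outrun the intact construct.
* **The homing booster cleaves first.**  In carriers of both a functional
  Cas9 source and the booster gRNA, wild-type alleles at the construct
  locus home with probability `homing_rate` and are restored to wild type
  otherwise; only the restored fraction is exposed to ordinary editing.
  Under the idealized `homing_rate = 1` the order is immaterial.
* **The Y-linked editor edits the transmitted X** (`X_edit`): daughters of
  carrier males die, sons carry the editor.  Under idealized parameters
  this is indistinguishable from an autosomal female-lethal that homes in
  males (`fsridl_drive`), and the two trajectories coincide exactly.

## Searches and experiments

`min_release_rate()` bisects the per-generation release proportion $\rho$
(males released / original male population) for a suppression goal —
first passage of the adult female count below $(1-\text{target})F_0$
within a horizon; a value-at-horizon variant is available.  Suppression is
monotone in $\rho$, which the bracketing relies on; the default bracket is
$[0, 20]$ and targets unattainable at the cap are flagged rather than
raised.  `fold_efficiency()` compares two searches (e.g. SIT / PDNE),
`parameter_sweep()` traces robustness curves, `lof_derivative_scan()`
tracks deletion derivatives against the release frequency, and
`linkage_correlation()` computes the construct–booster haplotype
correlation $\,(p_{GB} - p_G p_B)/\sqrt{p_G(1-p_G)p_B(1-p_B)}$.

Numerical conventions: release counts are $\rho M_0$ with $M_0$ the
pre-release equilibrium male count; released adults bypass their own
viability (they are reared under repression); gamete probabilities below
1e-15 are pruned and distributions renormalized; frequencies are reported
at the adult census, sexes pooled; bisection runs to an absolute tolerance
of 1e-4 in $\rho$ by default (tightened to 1e-6 where ratios of small
thresholds are reported).  "Within $T$ generations" counts $T$ rounds of
releases-then-reproduction from the pre-release equilibrium.

## Problem sizes and what the tests show

The test suite and the acceptance script run the deterministic engine at
the reference conditions themselves: horizons of 5–36 generations for the
threshold grid ($R_m \in \{2, 6, 20\}$, targets 67–99%), 20–60 generations
for time courses, a $20^3$ grid for the drive-prevention inequality, and a
0.5-percentage-point grid for the residual-fitness sweep.  These all
complete in seconds to a few minutes on one core because genotype state
spaces are small (6–80 genotypes) and the recursion is expected-value
linear algebra.

The engine is deterministic and infinite-population: it emulates the
expected dynamics of large, well-mixed populations under random mating and
equal mating competitiveness of released males.  It does not emulate
demographic stochasticity at low counts, spatial structure, inbreeding,
parental deposition of editor components, or resistance alleles other than
the modeled edit classes — so elimination here means the deterministic
trajectory passes below any threshold, not extinction certainty, and
passing tests say nothing about spatially structured or very small
populations.

## Known limitations

* Single panmictic population; no age structure beyond juvenile/adult.
* One mating per female; male abundance never limits female fecundity
  (extinction requires the male pool to vanish or all matings to be
  lethal-bearing).
* The cleave-and-rescue booster implements the reference configuration
  (female-specific second target rescued by the construct, linked at
  `booster_r`) and is intended for qualitative linkage dynamics, not
  threshold tables.
* A reserved `seed` config field exists for interface compatibility; no
  code path draws random numbers.
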