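---
title: "Analytic stationary distributions by network translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic stationary distributions by network translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crntrans)
```

## The problem

The long-term behaviour of a stochastic biochemical reaction network is its
stationary distribution — the steady-state solution $\pi(\mathbf n)$ of the
chemical master equation (CME) over copy-number states
$\mathbf n \in \mathbb Z_{\ge 0}^d$. For *complex balanced* networks a classic
product-form result applies: if a mass-action network is weakly reversible
(every linkage class of the reaction graph is strongly connected) and has
deficiency zero ($\delta = |\mathcal C| - l - s$, complexes minus linkage
classes minus stoichiometric rank), then
$\pi(\mathbf n) \propto \mathbf c^{\mathbf n} / \prod_i n_i!$ with
$\mathbf c$ any positive steady state of the deterministic model. Most
biologically interesting networks — in particular autophosphorylation motifs,
where a bimolecular forward step ($2A \to A + A_P$) has a unimolecular
reverse ($A_P \to A$) — violate both conditions.

`crntrans` implements a structure-transformation route around this
obstruction:

1. **Network translation.** Reactions sharing a stoichiometric vector
   $\gamma = \nu' - \nu$ may be merged (summing propensities), and a reaction
   may be shifted by any vector added to both its source and product complex.
   Both operations preserve every per-$\gamma$ propensity sum, hence the CME
   and all stochastic dynamics, while changing $|\mathcal C|$, $l$ and weak
   reversibility. `search_translations()` looks for a translation that is
   weakly reversible with deficiency zero.
2. **Propensity factorization.** The translated propensities
   $\tilde\lambda_k$ generally no longer follow mass action. The pipeline
   requires the form
   $\tilde\lambda_k(\mathbf n) = \kappa_k\,\theta(\mathbf n)\,
   \omega(\mathbf n - \nu_k)\,\mathbf 1\{\mathbf n \ge \nu_k\}$
   on a lattice domain $\Gamma = \{\mathbf n \ge \mathbf b\}$, where the base
   point $\mathbf b$ is fixed by the requirement that
   $\tilde\lambda_k > 0$ exactly when $\mathbf n \ge \nu_k + \mathbf b$.
3. **Complex balance.** With rate constants $\kappa_k$, the deterministic
   mass-action model of the translated network admits a complex balanced
   equilibrium $\mathbf c > 0$ (guaranteed at deficiency zero with weak
   reversibility): at every complex, in-flow equals out-flow.
4. **Assembly.** $\pi(\mathbf n) = M\,\mathbf c^{\mathbf n}/\theta(\mathbf n)$
   on $\Gamma$ (zero outside), normalized over the irreducible state space —
   a finite stoichiometric compatibility class when conservation laws bound
   the state, otherwise $\Gamma$ itself.

Every derivation is verified post hoc against the CME of the *original*
network, so the pipeline's answer never rests on the intermediate theory
alone.

```{r egfr}
net <- builtin_network("egfr")
d <- derive(net)
d
```

## Numerical design

**No symbolic algebra system is used.** All quantities are computed
numerically, in log space ($\theta$ grows factorially), with closed forms
recognized where they exist (the Poisson profile for pure mass action; the
Bessel-type marginal below). Identities that a computer-algebra route would
prove symbolically are asserted numerically on exhaustive windows at
tolerance $10^{-8}$–$10^{-10}$, and in the test suite additionally at several
random positive rate draws, which distinguishes structural identities from
numeric coincidence.

**Factorization as a log-linear system.** Taking logs of the factorization
condition couples three unknown families — $\log\theta$ on the working
region, $\log\omega$ on its source-shifted copy, and $\log\kappa_k$ — through
one linear equation per (reaction, state with positive propensity). The
solver runs exact unit propagation from the gauge
$\theta(\mathbf b) = \omega(\mathbf b) = 1$: whenever an equation has a
single unknown it is inferred; when propagation stalls, the system is
genuinely underdetermined on the remaining component (this happens
systematically on conserved networks, whose recurrences only couple states
within one stoichiometric class) and one unit gauge is added. A sparse
least-squares fallback covers topologies propagation alone cannot order. A
full residual scan then either certifies the factorization exactly or
returns a counterexample (reaction, state) — the non-factorizable outcome,
which is how extended autophosphorylation networks with an extra
trans-phosphorylation reaction are reported.

The factorization has genuine gauge freedom beyond the base-point
normalization: $\theta$ can be tilted by $t^{n_i}$ per species with
compensating changes in $\omega$, $\kappa$ and $\mathbf c$. All *reported*
relations (e.g. $c_A = \kappa_1/\kappa_2$ for the merged-production cycle)
and the distribution $\pi$ itself are gauge-invariant; tests compare only
such invariants.

**Complex balance via the complex-graph chain.** The vector
$(\mathbf c^{z})_{z \in \mathcal C}$ is complex balanced precisely when it is
a stationary measure of the continuous-time Markov chain on the complexes
with jump rates $\kappa$. Per linkage class that stationary vector is the
(positive, unique up to scale) null vector of the class Laplacian; the
remaining log-linear system $\nu_z \cdot \log\mathbf c = \log x_z + \mu$ is
solved by least squares and polished by damped Gauss–Newton to relative
residuals below $10^{-12}$. Inputs without a positive solution return a
`no_cbe` outcome rather than an error.

**Normalization.** Finite classes are summed exactly (log-sum-exp). On the
infinite lattice an adaptive rectangular truncation doubles any axis whose
outermost face still carries relative mass above `tail_tol` (default
$10^{-12}$, cap 768 per axis). Symbolic summation is out of scope; the
truncated sum is the source of truth, and the cap turns a non-summable
measure into an explicit error. Summability is a real constraint, not a
technicality: for the merged-production example (birth, autocatalysis
$A \to 2A$ at rate $a_4$, coupled production $A \to A+B$ at rate $a_2$,
joint decay), the analytic measure exists for all positive rates but its
$A$-tail scales like $(a_4/a_2)^n n^{a_1/a_4 - 1}$, so the distribution
exists only when $a_2 > a_4$; the bundled fixture uses rates
$(10, 1, 3, 1)$ on the summable side.

**Translation search.** Shift assignments are enumerated depth-first with
$\|s\|_\infty \le$ `max_shift` (default 2), non-negative translated
complexes, and complex order bounded by the maximal original order plus
`max_shift`. The load-bearing prune is structural: the number of translated
complexes minus connected components is monotone in the partial assignment
and must end exactly at the stoichiometric rank $s$ for deficiency zero, so
any partial assignment exceeding $s$ is cut. For networks with more than two
species, shifts are further restricted to the species support of each
reaction's own complexes — a documented search-space bound that all known
worked examples satisfy. Search budgets are explicit; exhaustion is reported
as truncation, never silently treated as "no translation".

## What the simulator validates

`gillespie()` is an exact direct-method SSA (compiled fast path for
propensities that flatten to sums of mass-action terms, an R fallback for
general kinetics). Because translation preserves per-$\gamma$ propensity
sums, the original and translated networks driven by the same random stream
produce identical jump times and identical $\gamma$-attributed paths once
reactions are grouped by stoichiometric vector — a path-level test of CME
preservation. Distribution-level validation compares analytic marginals with
end-state histograms ($10^4$ runs; the Monte-Carlo noise floor for a
marginal with effective support $K$ is about $\tfrac12\sqrt{K/n}$, which
sets the 0.03 tolerance) and with holding-time-weighted occupancy averages
for the long toggle runs, which extract far more information per simulated
event.

## The autophosphorylation marginals

For the asymmetric trans-autophosphorylation network at rates
$(\alpha_1, \alpha_2, \alpha_3, \alpha_4)$ the derived joint law factorizes:
the phosphorylated form is exactly Poisson with rate $\alpha_1/\alpha_3$ —
synthesis and degradation alone set its long-term statistics — and the
unphosphorylated form has
$\pi(n) \propto r^n / (n!\,(n-1)!)$ for $n \ge 1$, governed solely by the
composite parameter $r = (\alpha_1/\alpha_2)(1 + \alpha_4/\alpha_3)$, with
normalizing constant $\sqrt r\, I_1(2\sqrt r)$ (modified Bessel function).
This marginal is sub-Poissonian at every $r$, and its coefficient of
variation is maximized near $r \approx 1.8$:

```{r cv}
cv <- bessel_marginal_cv()
c(r_max = cv$r_max, cv_max = max(cv$cv))
```

## Multi-timescale reduction

The genetic toggle switch couples fast protein kinetics (expression,
trans-autophosphorylation $2X \to X + X_P$, dephosphorylation, degradation
of the phosphorylated repressor) to slow, $\epsilon$-scaled promoter
binding/unbinding. The fast subnetwork with gene copies frozen is
EGFR-like; its translation is weakly reversible with deficiency zero, so the
conditional stationary distribution given each gene state is derived
analytically ($A_P \mid \text{active} \sim$ Poisson(50),
$A_P \mid \text{repressed} \sim$ Poisson(7.5) at the bundled parameters).
The unconditional marginal is approximated by the $\rho$-weighted mixture of
conditionals, with $\rho$ the stationary vector of the quasi-steady-state
(QSS) chain over joint gene states whose binding rates use the conditional
repressor means. `reduce_model()` applies the same substitution to build a
genes-only model for slow-dynamics questions such as repressor residence
times. One modelling choice deserves record: with degradation acting on the
*unphosphorylated* protein the translated fast subnetwork would contain two
reactions sharing source $A$ with non-proportional propensities, which
provably cannot satisfy the factorization condition (reactions sharing a
translated source must have a constant propensity ratio); degradation
therefore acts on the phosphorylated form, which also leaves the
fast-subnetwork deficiency at three.

The mixture is an $\epsilon \to 0$ approximation. At the bundled rates the
promoter switching propensity is $\epsilon k_b \langle n_{B_P}\rangle
\approx 100\,\epsilon$ per time unit against a protein relaxation rate
$\alpha_{deg} = 0.2$, so timescale separation requires roughly
$\epsilon \le 10^{-4}$ (at $10^{-2}$ switching is *faster* than relaxation
and the true marginal is unimodal). Validation therefore asserts agreement
(total variation $< 0.05$) at $\epsilon = 10^{-4}$ — still two orders of
magnitude more relaxed than the regime the model is meant for — plus the
monotone degradation of the approximation as $\epsilon$ grows through
$10^{-2}$ and $10^{-1}$. Residence times of the repressed gene are
exponential with rate $\epsilon k_u$ in both the full and the reduced model,
so their agreement is checked at $\epsilon = 10^{-2}$ where many
bind/unbind cycles are cheap to simulate.

## Random-network survey

The survey samples Erdős–Rényi random reaction networks over the complex
universe of total order $\le 2$ (for two species: $0, A, B, 2A, 2B, A+B$):
each unordered complex pair is an edge with probability $p$, each edge gets
a uniformly random direction (the deficiency does not depend on directions),
and every reaction is mass action with rate one. At $p = 0.5$ about 0.36% of
networks have deficiency zero — essentially the probability that at most a
couple of edges fall together compatibly — and the fraction that *can be
translated* to deficiency zero within shift bound 2 is several times larger,
because any set of reactions whose stoichiometric directions fit on a small
complex motif (a single pair, two independent pairs, or a triangle) can be
collapsed by shifting. The survey reports both fractions with binomial
confidence intervals, and budget-exhausted searches are tallied separately
as not translatable.

```{r survey}
sv <- survey(random_crn_model(2, 2, 0.5, seed = 1), 20000)
sv
```

## Problem sizes and limitations

The bundled analyses use the fixture parameters throughout: conserved
classes of size $T_0 = 80$ (sequential autophosphorylation) and $T_0 = 60$
(cis/trans positive feedback) are summed exactly; open networks are
truncated at tail mass $10^{-12}$ (boxes around $130 \times 100$ states for
the receptor example); SSA validation uses $10^4$ end states per fixture and
$3 \times 1.5\cdot 10^5$ time units of occupancy averaging for the toggle;
the survey uses $10^6$ samples for the deficiency-zero fraction and $10^4$
for the translatability ratio.

Known limitations, by design:

* Factorization validity is certified on the working window or conserved
  class, not globally; for rational propensities the recurrences telescope,
  so window certificates extend in practice, but no symbolic proof is
  attempted.
* Irreducibility of infinite state spaces is certified only on the
  truncation used for normalization.
* The translation search is complete only within its bounds (`max_shift`,
  complex order, species-support restriction for $d > 2$, node budget);
  a negative search result means "none within bounds".
* The QSS slow chain substitutes conditional *means* of free repressor
  copies into binding propensities; sequestered (gene-bound) copies are
  outside the fast counts, so no further correction is applied.
* Synthetic random networks share none of the rate heterogeneity of curated
  biological models; the survey speaks to graph structure, not to kinetics.
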