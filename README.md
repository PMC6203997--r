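# dyadfit

Dyadic data analysis for distinguishable dyads by maximum-likelihood
covariance-structure modeling.

When both members of a couple (or any patient–caregiver, parent–child,
doctor–patient pair) are measured, their scores are not independent, and
person-level regression gives biased answers. `dyadfit` implements the
three classical models for such data:

- **APIM** (Actor–Partner Interdependence Model): each member's predictor
  `X_i` affects their own outcome (`a_i`, the *actor* effect) and the
  partner's outcome (`p_ij`, the *partner* effect), with a free `X1–X2`
  covariance (compositional effect) and residual `Y1–Y2` covariance
  (residual nonindependence).
- **MIM** (Mutual Influence Model): actor effects plus reciprocal
  *feedback* paths `Y1 ⇄ Y2` between the outcomes, a nonrecursive system
  in which each predictor reaches the partner's outcome only indirectly,
  through one's own outcome.
- **CFM** (Common Fate Model): the four observed scores are indicators of
  two dyad-level latent variables (unit loadings), and the causal path
  `b` runs between the latents, with residuals correlated within person.

Models are specified in RAM form and fitted by minimizing the ML
discrepancy

    F_ML = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p,   Σ(θ) = F(I−A)⁻¹S(I−A)⁻ᵀFᵀ,

with `χ² = n·F_ML` at the minimum, standard errors from the observed
information, equality constraints by shared parameter labels, and nested
models compared by Δχ². Because fitting needs only `(n, means, SDs,
correlations)`, published analyses can be reproduced exactly from a
descriptive table — no raw data required. A seeded multivariate-normal
dyad simulator with known APIM/MIM/CFM structure supports
parameter-recovery and type-I-error experiments.

## Worked example

The package ships the summary moments of a study of anxiety (HADS-A,
0–21) and marital satisfaction (ENRICH, 10–50) in 141 infertile couples.
The full APIM battery — saturated, actor-equal, partner-equal, doubly
constrained — in four lines:

```r
library(dyadfit)
m <- infertile_couples_moments()   # n = 141, 4 means/SDs, 6 correlations
d <- dyad_design(roles = c("man", "woman"),
                 predictor = "anxiety", outcome = "satisfaction")
fits <- lapply(c(basic = "basic", actor = "actor_equal",
                 partner = "partner_equal", both = "both_equal"),
               function(v) fit_ml(build_apim(d, v), m))
cat(render_fit_table(fits), sep = "\n")
```

The saturated column prints `actor_man −0.458*** (0.122)`,
`actor_woman −0.444*** (0.122)`, `partner_woman_man −0.253* (0.117)` and
`partner_man_woman −0.151 (0.127)`: each point of a man's anxiety costs
him 0.46 satisfaction points, and his wife's anxiety costs him another
0.25, while the reverse partner effect is not significant. Tying the
actor effects gives the pooled `actor −0.451*** (0.083)` at the price of
`Δχ²(1) = 0.006, p = 0.94` — the two actor effects are
indistinguishable. The feedback and common-fate views of the same data:

```r
f_mim <- fit_ml(build_mim(d), m)
mim_indirect_effects(f_mim)
#   from_role to_role estimate    se     z     p
#         man   woman   -0.123 0.083 -1.49 0.136
#       woman     man   -0.206 0.089 -2.32 0.020
f_cfm <- fit_ml(build_cfm(d), m)
cfm_latent_r2(f_cfm)   # 44.3 (% of latent satisfaction explained)
```

`run_hypothesis_suite(m, d)` runs all of the above and prints a
seven-row decision table. The same analyses are scriptable from a shell
via the installed `exec/dyadfit` front end (`summarize`, `fit`,
`simulate`, `hypotheses` subcommands on a YAML config).

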