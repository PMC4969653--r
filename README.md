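# ph2adapt

Exact design of single-arm two-stage phase II clinical trials with a
binary endpoint, including a **minimax adaptive** design in which the
second-stage sample size shrinks as first-stage responses accumulate.

## The problem

A phase II trial tests the response rate π of a new treatment,

  H₀: π ≤ π_u   versus   H_a: π ≥ π_a,

with exact one-sided type I error ≤ α at π_u and power ≥ 1 − β at π_a.
Two-stage designs enrol n₁ patients, look at the interim response count
S, and stop or continue.  The package searches four design families,
all with exact binomial error computations:

* **Simon designs** — futility stop if S ≤ r₁, otherwise continue to n
  patients, reject iff the total count x > r.  *Minimax* minimises the
  maximum sample size (MSS), then the expected sample size under the
  null (ESS₀); *optimal* minimises ESS₀.
* **Minimax-EF designs** — additionally stop *and reject* if S > r₂.
* **Minimax adaptive designs** — per-response second-stage sizes n₂(S)
  and critical values r(S), with n₂(S) non-increasing in S, a futility
  prefix (S = 0 always stops) and an efficacy suffix.  Found by a
  branch-and-bound over conditional error functions
  P(s | r(s), n₂(s), π) = 1 − B(r(s) − s; n₂(s), π), minimising
  ESS₀ = Σ_s (n₁ + n₂(s)) b(s; n₁, π_u) at the smallest feasible MSS.
* **Admissible adaptive designs** — minimisers of the Bayes risk
  T(q) = q·n + (1 − q)·ESS₀ for a weight q ∈ [0, 1], read off the lower
  envelope of the candidate designs' lines.

All searches are exact and deterministic; results are certified optimal
unless an explicit node budget is set (see the vignette).

## Worked example

A urothelial carcinoma trial targets α = 0.1, power 80 %, π_u = 35 %,
π_a = 50 %:

```r
library(ph2adapt)
spec <- design_spec(alpha = 0.1, beta = 0.2, pi_u = 0.35, pi_a = 0.5)

search_simon(spec, "minimax")
#> Simon two-stage design: (r1/n1, r/n) = (10/31, 21/49)
evaluate_design(search_simon(spec, "minimax"), spec)
#>   type I error 0.0966 | power 0.8012 | ESS0 40.81 | PET0 0.455 | PETa 0.035 | MSS 49

search_minimax_ef(spec)
#> Minimax-EF two-stage design: ((r1,r2)/n1, r/n) = ((11,16)/32, 21/49)

res <- find_minimax_adaptive(spec)
res$design
#> Adaptive two-stage design: n1 = 21, MSS = 49
#>   S <= 6  : stop, futility
#>   S  = 7  : continue, n2 = 28 (n = 49), reject if x > 21
#>   S  = 8  : continue, n2 = 28 (n = 49), reject if x > 21
#>   S  = 9  : continue, n2 = 28 (n = 49), reject if x > 21
#>   S  = 10 : continue, n2 = 28 (n = 49), reject if x > 21
#>   S  = 11 : continue, n2 = 28 (n = 49), reject if x > 21
#>   S  = 12 : continue, n2 = 28 (n = 49), reject if x > 20
#>   S  = 13 : continue, n2 = 23 (n = 44), reject if x > 18
#>   S >= 14 : stop, efficacy
res$metrics
#>   type I error 0.0999 | power 0.8001 | ESS0 38.89 | PET0 0.360 | PETa 0.134 | MSS 49
```

All three designs share the minimax MSS of 49, but the adaptive design
needs about two fewer patients in expectation under the null (38.89 vs
40.81 for Simon's minimax and 39.17 for the EF design): with many
interim responses the trial either stops early for efficacy or finishes
with a smaller second stage.  A schedule can be written to CSV/JSON
with `write_schedule()`, re-read with `read_schedule()`, and re-scored
with `evaluate_design()`; `simulate_design()` cross-checks any design
by Monte-Carlo.

A command-line interface wrapping the same functions is installed as
`exec/ph2adapt` inside the package directory:

```sh
Rscript "$(Rscript -e 'cat(system.file("..", "exec", "ph2adapt", package="ph2adapt"))')" \
  simon --alpha 0.1 --beta 0.2 --pi0 0.35 --pi1 0.5 --criterion minimax --json
```

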