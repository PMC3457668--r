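# lagrmsd — lagged RMSD convergence diagnostics for MD trajectories

`lagrmsd` answers a deliberately modest question about a molecular
dynamics simulation: **can we show that it has *not* yet run long
enough?** No check can prove complete sampling, but specific failures of
stationarity can be detected — and should be, before any conclusion is
drawn from a trajectory of a solvated protein complex.

The diagnostic is *lagged RMSD analysis*:

1. For a time lag Δt, average the RMSD
   `RMSD(a,b) = [ (1/N) Σᵢ ‖xᵢ(b) − xᵢ(a)‖² ]^{1/2}`
   (optionally after Kabsch superposition) over **all** frame pairs
   separated by Δt. Unlike the familiar RMSD-to-first-frame curve this
   average is stable, and unlike block averaging it stays specific to a
   single time separation.
2. Fit the saturating curve with a Hill function
   `RMSD̄(Δt) ≈ a·Δtᵞ / (τᵞ + Δtᵞ)` — plateau `a`, half-saturation lag
   `τ` (with `f(τ) = a/2` exactly), sigmoidicity `γ`. Lags run up to
   half the analysis window, on a dense-then-sparse schedule that gives
   the informative short-lag rise its weight in the fit.
3. Repeat while discarding a growing initial offset `t_offset` on
   `[0, t_max/2]`, and model the fitted plateau as
   `a(t_offset) = a₀ + β·exp(−λ·t_offset)`. The limit `a₀` estimates
   the RMSD between two *totally unrelated* configurations of the
   visited region, free of initial-phase bias.
4. If the fitted parameters keep drifting with the offset, the run is
   flagged **not stationary** — it has not yet run long enough. The
   quantitative rule (relative tail drift of `a` and `τ` below 5% by
   default) is explicit, configurable and reported with the verdict.

Everything is validated against a synthetic Ornstein–Uhlenbeck
trajectory generator with exact discretization, for which the unaligned
lagged RMSD has the closed form `√(6σ²(1 − e^{−Δt/τ_c}))` with plateau
`√6·σ` — an independent oracle for the whole pipeline.

## A worked example

A stationary fluctuating system whose every coordinate starts 5σ away
from equilibrium — a caricature of an un-equilibrated production run:

```r
library(lagrmsd)

traj <- generate_ou_trajectory(n_atoms = 400, n_frames = 4000,
                               sigma = 1, tau_c = 100, dt_ps = 1,
                               seed = 85, init_displacement = 5)

res <- analyze_convergence(traj, n_offsets = 11,
                           schedule_args = list(dense_upto = 60,
                                                dense_step = 3,
                                                sparse_count = 30))
res
#> offset_sweep: 11 offsets on [0,  1999.5 ] ps; 11 converged fits
#>   verdict: stationary
#>   tail drifts: a 0.0138, tau 0.0338 (tol 0.05)
#>   extrapolated plateau a0 = 2.61492 A

res$fits[[1]]
#> hill_fit: a = 2.76461 (se 0.0249), tau = 34.3084 ps (se 1.01),
#>           gamma = 0.894715 (se 0.0274)
#>   rss = 0.140078 over 50 points
```

Reading the output: at `t_offset = 0` the transient inflates the fitted
plateau (2.76) and half-saturation lag; once the offsets discard the
initial phase the parameters settle (tail drift of `a` 1.4%, verdict
`stationary` — the *rest* of the run is fine), and the extrapolated
unrelated-configuration distance `a₀ = 2.61` approaches the exact OU
plateau `√6 ≈ 2.449`. A drifting or too-short trajectory instead
returns `not_stationary`.

`plot(res)` draws the plateau-versus-offset decay;
`plot(res$curves[[1]], fit = res$fits[[1]])` the lag curve with its
Hill fit.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","lagrmsd.R",package="lagrmsd"))')
Rscript "$CLI" simulate --out traj.xyz --n-atoms 100 --n-frames 2000 --seed 1
Rscript "$CLI" analyze  --input traj.xyz --no-align --out-dir results/
```

`analyze` accepts multi-model PDB (`--frame-spacing-ps` required), XYZ,
or a precomputed square RMSD matrix (`--format matrix`), and writes
per-offset fit tables (TSV), stacked lag curves, the decay fit and a
JSON summary with the verdict. A flat `key: value` config file
(`--config`) makes any run reproducible from the config plus input
alone.

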