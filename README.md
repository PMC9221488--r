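# vinecmc

Corticomuscular coupling networks via R-vine copulas, with GARCH marginal
filtering, data-driven network thresholding, and a spectral
Granger-causality baseline.

## What it does

Simultaneous EEG and surface-EMG recordings carry statistical coupling
between cortical oscillations and muscle activity (corticomuscular
coupling). Linear coherence misses the nonlinear, tail-heavy structure of
these signals. `vinecmc` measures coupling with a copula approach:

1. **Preprocessing** (`preprocess()`): zero-phase order-4 Butterworth
   bandpass per modality (EEG 0.05–100 Hz, EMG 30–200 Hz by default), a
   Q = 30 biquad mains notch, and full-wave rectification of EMG after
   filtering. `load_signals()` reads CSV/TSV recordings with a channel
   manifest; `epoch_trials()` cuts fixed-length trials.
2. **Marginal filtering** (`fit_garch()`): each channel is fit with an
   AR(1) + GJR-GARCH(1,1) model with standardized Student-t innovations;
   the probability-integral transform (`pit_transform()`) of the
   standardized residuals yields approximately uniform, serially
   decorrelated margins, so the remaining cross-channel dependence is pure
   copula.
3. **R-vine construction** (`build_rvine()`): tree 1 is the maximum
   spanning tree of the channels under |Kendall τ| weights (Prim's
   algorithm); each edge gets a bivariate pair copula selected by AIC (or
   BIC) from independence, Gaussian, Student-t, Clayton, Gumbel and Frank
   families with 90°/180°/270° rotations; higher trees condition through
   h-functions and obey the proximity condition. Sampling
   (`sample_rvine()`), density evaluation (`vine_log_density()`) and
   structural validation (`validate_rvine()`) are included.
4. **Network analysis** (`normalize_blocks()`, `threshold_select()`,
   `graph_metrics()`): the |τ| matrix is min-max normalized separately in
   the EEG–EEG, EMG–EMG and cross blocks; the binarization threshold is
   the largest grid value whose average node degree (averaged across
   condition networks) still satisfies K ≥ 2 ln N; the binary networks are
   summarized by characteristic path length L, clustering coefficient C,
   degrees and core (maximum-degree) nodes.
5. **Granger baseline** (`spectral_gc()`, `gc_matrix()`): Geweke's
   frequency-domain causality from a bivariate VAR (AIC order selection),
   averaged over a frequency band (8–30 Hz by default), as a directed
   linear reference against the copula networks.
6. **Ground-truth synthesis** (`make_scenario()`, `simulate_scenario()`):
   channels are coupled at the innovation level through a known R-vine
   (an EEG chain, an EMG chain and one cross-modal bridge; Gaussian pairs,
   τ = 0.5 within and τ = 0.15 across modalities) and pushed through the
   GARCH recursion, so structure- and parameter-recovery can be tested
   against an analytic truth (`scenario_tau_matrix()`, `true_network()`).

`run_pipeline()` chains steps 1–5 across task conditions and writes
TSV/JSON artifacts; `inst/cli/vinecmc.R` is a command-line front end with
`simulate`, `preprocess`, `granger` and `run` subcommands.

## Worked example

Simulate the reference 14-channel scenario and recover its structure
end to end (about two minutes on one CPU):

```r
library(vinecmc)

sc <- make_scenario(seed = 42)   # 8 EEG + 6 EMG, 3000 samples @ 1 kHz
sim <- simulate_scenario(sc)

fit <- fit_garch(sim$cm$data[1, ])
round(fit$params, 4)
#>      c0      c1   omega   alpha    beta   gamma     dof
#> -0.0145  0.1966  0.0821  0.0520  0.7795  0.0774  9.5386
# (truth: 0, 0.2, 0.05, 0.05, 0.85, 0.05, 8)

res <- run_pipeline(list(hold = sim$cm), run_gc = FALSE, seed = 1)
res$threshold
#> [1] 0.35

res$conditions$hold$vine
#> <vine_model> 14 variables, 13 trees, loglik 12381.41 (AIC -24658.81)
#>   T1 Cz-C3: gaussian tau=0.486
#>   T1 C3-C4: gaussian tau=0.491
#>   ...
#>   T1 Cp1-BB: gaussian tau=0.147     <- the EEG-EMG bridge
#>   ...

head(res$conditions$hold$tree1$edges)
#>   from  to from_modality to_modality   family       tau bridge
#> 1   Cz  C3           EEG         EEG gaussian 0.4859207  FALSE
#> 2   C3  C4           EEG         EEG gaussian 0.4908157  FALSE
#> 3   C4 Cp1           EEG         EEG gaussian 0.5019541  FALSE
#> ...

m <- res$conditions$hold$metrics
c(L = m$L, C = m$C)
#>         L         C
#> 1.6593407 0.7795918

res$conditions$hold$core_nodes
#> Cp1 Cp2
#>   4   5
```

All 13 first-tree edges of the generating vine — both chains and the
single cross-modal bridge `Cp1–BB` — are recovered exactly, with each
pair-copula τ within sampling error of its target (0.5 within modality,
0.15 on the bridge).

For real recordings, point `run_pipeline()` (or the CLI `run`
subcommand) at CSV/TSV files plus a YAML channel manifest and set
`preproc = TRUE`.

## Package layout

- `R/preproc.R` — loading, filtering, epoching
- `R/garch.R`, `src/garch.cpp` — marginal model, likelihood, PIT
- `R/paircopula.R`, `src/kendall.cpp` — pair-copula families,
  h-functions, Kendall τ (Knight's O(n log n) algorithm)
- `R/rvine.R` — structure selection, density, sampling, validation
- `R/granger.R` — Geweke spectral Granger causality
- `R/network.R` — block normalization, threshold rule, graph metrics
- `R/synth.R` — ground-truth scenario generator
- `R/pipeline.R` — end-to-end driver and artifact writer
- `inst/cli/vinecmc.R` — command-line interface
- `vignettes/vine-copula-coupling.Rmd` — methods vignette

## License

MIT
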