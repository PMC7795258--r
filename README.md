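# labimpute

Comorbidity-guided ("hybrid") imputation of laboratory values extracted
from electronic health records.

Laboratory measures in EHR data are sparse, and the sparsity is missing not
at random: a test is resulted mostly for patients whose values are low,
average or high in a clinically meaningful way. `labimpute` is for
biostatisticians and informaticians who need to densify such lab matrices
before modelling. Instead of imputing the whole cohort with one global
model, it stratifies patients by their diagnosis history and imputes within
each stratum:

1. **QC** — per-patient medians; each lab fitted with a three-component
   Gaussian mixture `f = N(μ₁,σ₁²) + N(μ₂,σ₂²) + N(μ₃,σ₃²)` and filtered to
   the accepted range
   `c_low = max(minᵢ(μᵢ − 3σᵢ), 0)`, `c_high = maxᵢ(μᵢ + 3σᵢ)`.
2. **Latent comorbidities** — binary patient × ICD matrix `A` (a code
   counts only if recorded ≥ 2 times in the chart), truncated SVD
   `A_g = U_g S_g V_gᵀ` at abstraction level `g`, a column-sum noise cut,
   then k-means on the rows of `A_g`.
3. **Cluster-wise chained-equations imputation** — a fully conditional
   specification engine with predictive-mean-matching (pmm) and
   regression-forest (rf) conditional models, run per cluster; both models
   only ever impute values drawn from the variable's observed set.
4. **Evaluation** — withhold observed cells per lab, impute the same masked
   matrix with the hybrid (cluster-wise) and the standard (global) strategy,
   and report the per-configuration mean RMSE difference
   (hybrid − standard; negative favours the hybrid strategy).

Because clinical source data are private, the package includes a synthetic
cohort generator (`default_spec()`, `generate_cohort()`) with planted
patient groups, calibrated per-lab missingness, an MNAR measurement
mechanism and injected gross outliers, plus the ground truth for all of it.
All shipped data are synthetic.

## Worked example

```r
library(labimpute)

cohort <- generate_cohort(default_spec("tiny"))   # 300 patients, 8 labs, 40 ICD codes
m  <- aggregate_median(cohort$lab_observations,
                       patients = cohort$truth$clusters$patient_id)
#> aggregate_median: excluded 1 lab(s) with missingness > 0.75
qc <- filter_outliers(m)$matrix
qc
#> <lab_matrix> 300 patients x 7 labs, 37.9% cells missing

report <- run_experiment(
  qc, cohort$diagnoses,
  grid = experiment_grid(methods = "pmm", cluster_counts = c(1, 4),
                         abstraction_levels = c("20", "full"), batches = 0.75),
  seed = 1, holdout_per_lab = 20, repeats = 2
)
report
#>   method cluster_count abstraction_level missingness_batch mean_rmse_hybrid
#> 1    pmm             1                20              0.75            9.329
#> 2    pmm             1              full              0.75            9.329
#> 3    pmm             4                20              0.75            7.405
#> 4    pmm             4              full              0.75            7.257
#>   mean_rmse_standard mean_rmse_difference repeats
#> 1              9.329                0.000       2
#> 2              9.329                0.000       2
#> 3              9.329               -1.924       2
#> 4              9.329               -2.072       2
```

Reading the output: each row is one configuration (method × cluster count K
× abstraction level g × missingness batch). `mean_rmse_difference` is the
hybrid-minus-standard RMSE on the withheld cells, averaged over labs and
repeats; here clustering into K = 4 groups improves imputation by about 2
RMSE units on this cohort, and K = 1 is exactly the global algorithm, so its
difference is exactly zero. `autoplot(report)` draws the per-lab
differences; `attr(report, "per_lab")` holds them as a table.

A command-line interface over the same functions ships in
`inst/cli/labimpute.R`:

```sh
Rscript inst/cli/labimpute.R simulate --scale tiny --seed 3 --out cohort/
Rscript inst/cli/labimpute.R evaluate --config config.yaml --out results/
```

where `config.yaml` names the input CSVs (or a `simulate:` block), the seed,
`holdout_per_lab`, `repeats`, and a `grid:` with `methods`,
`cluster_counts`, `abstraction_levels` and `batches`.

## Documentation

The methods vignette (`vignettes/hybrid-imputation.Rmd`) describes the
models, the tunable parameters and their defaults, the synthetic generator's
mechanism and calibration contract, the numerical conventions (EM
initialization, tie-breaks, boundary conventions, seed fan-out), and known
limitations — including when the tri-modal filter cannot separate a gross
error population from a genuine patient subgroup.
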