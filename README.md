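# ddcnv

Absolute copy-number quantification from droplet digital PCR (ddPCR), with
the downstream statistics for extreme-phenotype case–control studies of
copy number variants (CNVs).

## The problem

Association studies of CNVs stand or fall on *absolute* copy number:
relative methods (qPCR, array CGH) cannot reliably distinguish 1 vs 2 vs 3
copies per diploid genome. ddPCR partitions a reaction into >10,000
droplets; under Poisson partitioning the fraction of positive droplets
*k/n* fixes the template concentration absolutely:

    λ̂ = −ln(1 − k/n)        [mean copies per droplet]

Duplexing the CNV assay (FAM) against a reference locus carried at exactly
two copies per diploid genome (RNaseP, VIC) converts concentrations into
copy number:

    ĉ = 2 · λ̂_target / λ̂_reference

A sample is genotyped at integer copy number *m* ∈ {1, 2, 3} when the 95%
confidence interval of ĉ contains *m* and no other candidate integer;
unresolved samples are repeated and, if still unresolved or discordant,
excluded. Carrier status (deletion ĉ < 2, or gain ĉ > 2) is then tested
against membership of extreme high vs low systolic blood-pressure groups —
an extreme-phenotype design that concentrates the power of a much larger
random sample into ~190 genotyped subjects — by logistic regression
adjusted for age, BMI and sex, with within-group Wilcoxon rank-sum tests
of BP by genotype.

The package implements every stage — droplet-level simulation,
quantification with delta-method/Clopper–Pearson intervals, merged-well
replicate pooling, ratio CIs, integer calling with exclusion logic, the
extreme-cohort design arithmetic (treatment adjustment, decile selection,
standardized separation, effective sample size), association statistics,
and dMIQE-style run summaries — and is for statistical geneticists and
assay developers who want the full workflow testable without instrument
data.

## Worked example

```r
library(ddcnv)

# one well: 5,000 positive of 14,000 droplets
estimate_lambda(5000, 14000)
#> ddPCR concentration estimate: lambda = 0.44183 copies/droplet
#>   95% CI [0.42949, 0.45418]  (k = 5000 / n = 14000 droplets, 1 well, delta interval)

# full pipeline on a simulated extreme cohort (96 high / 92 low subjects,
# one deletion assay, ~40% of samples run in duplicate)
res <- run_pipeline(pipeline_config(seed = 42), out_dir = "run1")
res$freq_table
#> Copy-number frequencies by extreme group
#>     assay_id group cn count  pct n_group
#> 1 Hs01327571  high  1     9  9.5      95
#> 2 Hs01327571  high  2    86 90.5      95
#> 3 Hs01327571   low  1     3  3.3      91
#> 4 Hs01327571   low  2    88 96.7      91
res$association
#> Logistic association of extreme-high group with carriage (n = 95 high / 91 low)
#>   adjusted for: age, bmi, sex
#>   carrier effect: beta = 0.353 (OR = 1.424, 95% CI 0.213-9.507), p = 0.7155
#>   status: ok
```

The frequency table shows the deletion (1 copy) enriched in the simulated
high-BP group (9.5% vs 3.3% carriers), mirroring the configured group
prevalences; `lambda = 0.44183` is −ln(1 − 5000/14000) exactly. The
covariate-adjusted odds ratio is attenuated relative to the crude carrier
contrast because age and BMI themselves separate the extreme groups
strongly — the expected behaviour of full adjustment in an extreme design
of this size. `run1/` holds the wells CSV, estimates TSV, calls TSV, a
JSON report and a text summary; re-running with the same seed reproduces
them byte for byte.

Design arithmetic:

```r
d <- cohort_design(population_mean_sbp = 122, population_sd_sbp = 14.3,
                   n_high = 96, n_low = 92,
                   mean_high = 165.9, mean_low = 98.6)
standardized_separation(d)   # 4.706 population SDs
effective_sample_size(d)     # 1041 random subjects (D^2/4 * N convention)
```

## Documentation

The methods vignette (`vignettes/ddpcr-cnv-methods.Rmd`) describes the
statistical model, interval choices, the calling rule and its edge cases,
what the simulator does and does not emulate, and known limitations.
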