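# phagetrack

Clone-level tracking of donor phages in fecal microbiota transplantation
(FMT) cohorts, from viral-contig annotations and genome sequences to donor
engraftment efficacy and longitudinal phageome statistics.

## What it does, and for whom

In a placebo-controlled FMT trial, stool metagenomes from donors and
recipients yield assembled contigs that viral-prediction tools annotate with
gene counts, scores and completeness. `phagetrack` takes the analysis from
there:

1. **Screen** contigs into uncultivated virus genomes (UViGs): include when
   `viral_genes >= 1` OR `host_genes == 0` OR `score >= 0.95` OR
   `hallmark_genes >= 3`; discard false positives when `host_genes > 4` OR
   host-to-viral gene ratio `HVR > 0.386`.
2. **Cluster** UViGs into viral OTUs (vOTUs) at `ANI >= 95%` over
   `AF >= 0.85` of the smaller sequence (greedy centroid clustering, longest
   member as representative), using a built-in fragment-mapping ANI
   estimator; keep vOTUs whose representative has completeness `>= 90%`.
3. **Detect clones** within vOTUs at `ANI >= 99.4%` over `AF >= 0.85` and
   call an **engraftment event** whenever a sex-matched donor clone appears
   in a recipient from week 6 onward, absent from that recipient's
   baseline. Donor **engraftment efficacy** is the fraction of a donor's
   vOTUs that engrafted; vOTUs carried by several donors credit each one.
4. **Quantify**: a non-redundant gene catalog (95%/85%), counts to
   RPK = count/(length/1000), CPM = RPK/&Sigma;RPK &times; 10^6; UViG abundance =
   median CPM over its genes (zeros included); vOTU abundance = sum over
   member UViGs.
5. **Analyze** the consequences: Shannon diversity (H = &minus;&Sigma;p ln p),
   Bray-Curtis dissimilarities (&Sigma;|a&minus;b| / &Sigma;(a+b)), phageome
   partitions (donor-shared / conserved-from-baseline / novel), vOTU
   stability categories, temperate vs virulent totals, with Wilcoxon,
   chi-squared + residual post hoc, Pearson correlation and linear
   mixed-effects treatment-by-time contrasts, all under Benjamini-Hochberg
   FDR.

Because trial sequencing data cannot ship in a package, a **synthetic
cohort generator** with full ground truth (clone pairs, transfers, lineage
maps) is included; every stage is validated against it.

## Worked example

```r
library(phagetrack)

res <- runPhageomePipeline("run1", simConfig = defaultSimConfig(seed = 1))
res$funnel
#>                 stage count
#> 1             contigs  2365
#> 2      putative_viral  2365
#> 3 post_false_positive  2365
#> 4               votus   805
#> 5            hq_votus   805

evaluateEngraftment(res$events, res$sim, res$hqVotus)
#>   recall precision n_truth n_called_fmt n_called_placebo
#> 1      1         1      86           86                0

head(res$efficacy$efficacy, 3)
#>   donor n_votus_donor n_engrafted  efficacy
#> 1  DF01            15          11 0.7333333
#> 2  DF02            18          10 0.5555556
#> 3  DF03            13           5 0.3846154
```

Reading the output: all 2365 simulated contigs pass the screen (the
generator draws annotations that satisfy it), they collapse into 805 vOTUs,
and all 86 true donor-to-recipient transfers are recovered as events with no
false positives — including zero events in the placebo arm, which receives
no transfers and acts as a specificity control. Donor efficacies differ and
correlate with donor diversity, as the generator's logistic transfer model
dictates. The run directory contains every stage table (`screen_decisions`,
`votus`, `clones`, `votu_abundance`, `events`, `efficacy`, `partition`,
`stats/*`, `summary.tsv`) plus the effective `config.yaml`;
`pipelineReport("run1")` assembles the five headline tables and plots.

A shell entry point for the same flow is in
`inst/scripts/phagetrack.R` (`simulate`, `run-all`, `report`).

## Scope

The package consumes the *outputs* of upstream tools (assembly, viral
prediction, completeness estimation, lifestyle/host annotation, read
alignment) as plain tables; it does not run them. See the methods vignette
(`vignettes/phageome-methods.Rmd`) for the models, assumptions, parameter
defaults and known limitations.
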