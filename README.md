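# modscreen

Screening for **genetic and transcriptomic modifiers of cancer onset and
progression** in small cohorts. The package is aimed at statistical
geneticists and cancer epidemiologists working on rare tumours, where
cohorts of tens of patients rule out agnostic genome-wide scans and the
practical designs are *focused screens with built-in independent
validation*:

1. **Candidate-SNP age-of-onset cascade.** A panel restricted to
   GWAS-catalog lead SNPs and their LD proxies (r² ≥ 0.8, ≤ 500 kb,
   proxy MAF ≥ 0.01, HWE exact p ≥ 1e-6, call rate ≥ 0.95) is tested for
   association with age at diagnosis by two-sided rank tests:
   Mann–Whitney *U* with heterozygous and minor-homozygous carriers pooled
   (pooling is automatic when minor homozygotes ≤ 4), or Kruskal–Wallis
   over the three genotype groups. SNPs pass discovery at raw *p* < 0.05,
   pass validation at raw *p* < 0.05 **with the same allele class showing
   the earlier median onset**, and are finally tested in a replication
   cohort on another platform (via the most closely linked genotyped
   proxy) with Bonferroni adjustment over the SNPs actually tested there:
   *p*ₐdⱼ = min(1, m·p).
2. **Repeated-split expression survival screen.** For each gene, the
   expression cut-point *c* maximizes the standardized log-rank statistic
   |S(c)| = |O₁ − E₁| / √V over splits leaving ≥ ceil(0.1·n) samples per
   side; the high/low groups are compared by the Mantel–Haenszel log-rank
   test, χ² = (ΣO − ΣE)²/ΣV. The cohort is split 50:50 into
   discovery/validation pairs 10 times; genes advancing from discovery
   (raw *p* < 0.05) must validate (Bonferroni-adjusted *p* < 0.05 over the
   genes advanced in that split, consistent direction) — genes validated
   in **≥ 6 of 10 splits** are hits. A two-cohort shared-probe variant
   covers paired cohorts on different array platforms.

Supporting layers: SNP panel QC with a per-rule exclusion ledger
(chromosome/position filters, triallelic, duplicates, monomorphic,
X-to-females restriction, call rate, MAF), an exact Hardy–Weinberg test,
local r² computation from phased haplotypes, Kaplan–Meier estimation and
export, VCF/TSV readers and writers, a CLI (`exec/modscreen`), and a
synthetic-cohort generator that plants genotype–onset effects,
expression–hazard effects and LD block structure so every stage is
testable with known ground truth.

## Worked example

Simulate three cohorts sharing one planted onset-modifier SNP
(carrier median-onset ratio 0.4, MAF 0.2) among 60 null SNPs, and run the
cascade:

```r
library(modscreen)
set.seed(7)
maf <- c(rs_planted = 0.2,
         setNames(runif(60, 0.05, 0.5), paste0("rs_null", 1:60)))
cohort <- function(n, k) {
  g <- simulate_genotypes(n, maf, seed = 100 + k)
  ages <- simulate_onset_ages(g[, "rs_planted"], baseline_median = 2,
                              effect = c(1, 0.4), dispersion = 0.5,
                              seed = 200 + k)
  list(genotypes = g, ages = ages)
}
brz1 <- cohort(26, 1); brz2 <- cohort(16, 2); adult <- cohort(92, 3)
report <- run_cascade(brz1, brz2, adult, names(maf))
report
#> Age-of-onset association cascade
#>   panel                    61
#>   discovery_tested         60
#>   discovery_significant    1
#>   validation_tested        1
#>   validation_significant   1
#>   replication_tested       1
#>   replication_significant  1
#>   survivors: rs_planted
```

One null SNP is monomorphic in the discovery draw (60 of 61 testable); the
planted SNP alone passes discovery, validates with a consistent direction,
and replicates. In the replication cohort its carriers were diagnosed at a
median 1.01 vs 1.95 (simulated years) for major homozygotes —
*p* = 9.2e-08, Bonferroni-adjusted over the single SNP tested.

The expression screen, with two genes planted at hazard ratio 6 among 48:

```r
sim <- simulate_expression_survival(
  48, 80,
  planted = data.frame(gene = c("gene_3", "gene_11"), hazard_ratio = 6,
                       cutpoint_quantile = 0.5),
  censoring_rate = 0.3, seed = 300)
scr <- run_split_screen(sim$expression, sim$clinical, seed = 301)
scr[scr$is_hit, c("gene", "hit_count")]
#>            gene hit_count
#> gene_3   gene_3         8
#> gene_11 gene_11        10
#> gene_23 gene_23         6
```

Both planted genes are recovered (validated in 8 and 10 of the 10
splits). `gene_23` — a null gene — also reaches the 6-split threshold:
because every split resamples the same cohort, a gene that is by chance
associated with survival at the cohort level can validate repeatedly.
The methods vignette quantifies this behaviour and what it implies for
reading hit lists.

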