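# consensusOR

Consensus-phenotype, inter-omic pathway over-representation analysis for
drug-sensitivity pharmacogenomics.

## The problem

Cell-line panels such as the NCI60 pair molecular profiles (transcript
abundances on an expression array, metabolite levels from a metabolomic
assay) with per-drug sensitivity phenotypes, the replicate-averaged
−log(GI50). A recurring question is which *biochemical pathways* — not
individual genes — determine sensitivity to a drug class, and whether
combining evidence across omic levels reveals pathways invisible to either
level alone. `consensusOR` implements that analysis as a tested pipeline
for anyone working with feature × sample abundance matrices, per-drug
phenotype vectors and a two-namespace (gene + metabolite) pathway
database, together with the null models needed to judge how much of the
resulting consensus is chance.

## The method

For each drug, every feature is correlated to −log(GI50) (Pearson *r* over
pairwise-complete samples; two-sided p from the t transform). Features
significant at a deliberately permissive Benjamini–Hochberg FDR of 60%
form the drug's gene and metabolite panels — permissive, so the pathway
stage is adequately powered. Each pathway *i* is then tested for
over-representation with the hypergeometric upper tail

&nbsp;&nbsp;&nbsp;&nbsp;p = P(X ≥ k),&nbsp;&nbsp;X ~ Hypergeom(m, N_i, K)

where K is the panel size, k the panel members inside the pathway, m the
measured background, and N_i the pathway's *effective size*: proteins
expanded to their measured probesets (a protein mapping to several
probesets contributes all of them; unmapped proteins contribute nothing)
and currency metabolites (phosphate, diphosphate, NADP+) removed. The
gene- and metabolite-side p-values are combined into a joint inter-omic
probability p_J = p_G · p_M (a namespace with nothing measured contributes
p = 1), and a pathway is associated with a drug when p_J < 0.05.

Pathways associated with a majority of a drug class (≥ 3 of 4 by default)
form the **consensus set**. Two null models calibrate it: model I redraws
random feature panels of matched size and reruns the whole joint pipeline;
model II assumes pathways are picked at random (exact Poisson-binomial
over the per-drug selection counts). Cumulative FDR at threshold n is the
null-expected over observed count of pathways in ≥ n drugs. A permutation
test (shuffling the metabolite p-value list against the gene list)
quantifies the gain of joint combination per drug. A global drug ×
pathway binary association matrix with complete-linkage/Hamming
clustering profiles a whole compound panel, and a specificity screen
separates class-specific consensus pathways from promiscuously associated
ones.

Because the original panel data are not redistributable, the package
includes a synthetic-data module that emulates the panel's shape (58
samples, 154 metabolites, thousands of probesets, hundreds of pathways)
with planted gene-signal, metabolite-signal and *split-signal* pathways —
the latter calibrated so each single-omic p is unremarkable while the
joint product is significant, the regime where inter-omic integration
pays off.

## Worked example

```r
library(consensusOR)

bundle <- generate_synthetic(synthetic_config(seed = 1))
res <- run_interomic_analysis(bundle$gene, bundle$metabolite,
                              bundle$phenotypes, bundle$db)
res$panel_sizes
#>        drug_id n_genes n_metabolites
#> 1 class1_drug1     352            76
#> 2 class1_drug2     338            73
#> 3 class1_drug3     374            63
#> 4 class1_drug4     372            67
res$consensus$joint
#> consensus_table: 200 pathways x 4 drugs
#>   pathways associated with exactly n drugs:
#>  1  2  3  4
#> 15  9  2 14
#>   consensus at threshold >= 3: 16 pathways
```

The per-drug panels hold the features passing the 60% FDR cutoff; the
exact-n histogram says how many pathways are jointly significant for
exactly n of the four drugs, and 16 pathways pass the majority criterion.
How much did inter-omic combination add over the single-omic analyses?

```r
single <- union(res$consensus$gene$consensus,
                res$consensus$metabolite$consensus)
unlist(consensus_gain(single, res$consensus$joint$consensus))
#>     base    added gain_pct
#>       12        4       33
```

Null model II turns the observed per-drug selection counts into the
consensus expected by chance, and the cumulative FDR says how trustworthy
each threshold is — here 7.6% of the ≥ 3-drug consensus would be expected
under random pathway selection:

```r
S <- vapply(res$enrichments, function(e) length(significant_pathways(e)), 0L)
nm2 <- null_model_II(S, eligible_universe(bundle$db))
cumulative_fdr(res$consensus$joint$exact_n, nm2$expected_exact_n)
#>   n observed_cum expected_cum fdr_pct
#> 1 1           40       79.418   100.0
#> 2 2           25       14.333    57.3
#> 3 3           16        1.210     7.6
#> 4 4           14        0.039     0.3
```

Because the data are synthetic, recovery can be scored against the
planted truth:

```r
evaluate_recovery(res, bundle$truth)[c("sensitivity", "fdp")]
#> $sensitivity
#>       gene_signal metabolite_signal      split_signal
#>              1.00              0.75              0.50
#> $fdp
#> [1] 0.31
```

For file-based, re-entrant runs (with a JSON manifest of parameters,
seeds and output checksums) see `run_config()` / `run_pipeline()`, which
read the TSV/GMT dialects written by `write_synthetic()`.

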