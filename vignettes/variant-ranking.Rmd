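---
title: "Weighted variant ranking: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted variant ranking: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankvar)
library(data.table)
```

## The scoring model

`rankvar` ranks biallelic single-nucleotide variants by a single additive
score built from per-source *encoded weights*. For a variant $v$ with
annotation sources $s \in S$ (region class, novelty, eight
deleteriousness predictors, four conservation tracks, three
population-frequency databases, ENCODE overlap, ClinVar, GWAS catalog),

$$\mathrm{score}(v) \;=\; \sum_{s \,\in\, S_{\text{enabled}}} w_s \, e_s(v),
\qquad w_s, e_s \in [0,1].$$

The encodings are deliberately coarse — tier weights for region class,
0/1 (or 0/0.5/1 for PolyPhen2) for predictions, a hard threshold for
conservation, $1-\mathrm{AF}$ for frequency, 0/1 flags for the rest. The
point of the additive form is robustness to annotation discrepancy: no
single predictor's disagreement can move a variant more than its one
weighted unit, and a variant that is simultaneously functional, novel,
conserved and predicted deleterious by many tools accumulates a score no
background variant can reach. The model assumes sources are worth
combining additively; it makes no claim of calibration against labelled
pathogenic/benign truth sets, and the score is an ordering device, not a
probability.

INDELs are excluded from scoring entirely and reported in a side table:
the categorical prediction/conservation annotations the score feeds on
are not consistently defined for them. CADD is carried into the output
for comparison but never summed — it is itself an aggregate, and adding
it would double-count the sources it was trained on.

## Parameters that matter

```{r}
cfg <- weight_config()
cfg
```

* **User weights** (`weights`, unitless in $[0,1]$, default 1 per
  source). They scale the encoded values linearly. The composition of
  user weights with encoded weights was an open design point; linear
  scaling is the simplest form in which "disable source" and "weight 0"
  coincide, which we adopt as an invariant (tested property).
* **Conservation cutoffs** (`cutoffs`; raw score units of each track).
  GERP++ uses $>2$ — strictly greater, so a score of exactly 2 encodes
  0. The PhyloP ($>2$), phastCons ($>0.6$) and SiPhy ($>12$) defaults
  are not prescribed by the method's source description; they are the
  thresholds commonly used with dbNSFP-style annotations and are
  configurable. Treat them as conventions, not calibrated values.
* **`freq_mode`**: one $1-\mathrm{AF}$ term per database (default,
  because the databases are independent evidence of commonness) or a
  single term on the maximum AF across databases. The per-database
  default makes a fully absent variant contribute 3 units of rarity.
* **`encode_mode`**: the ENCODE element / TFBS / conserved-site booleans
  collapse into one any-of flag by default; `per_flag` scores them
  separately (raising the attainable maximum by 2).
* **`gene_score`**: gene summaries use the gene's best variant score by
  default (a representative-variant reading of "top candidate gene");
  `sum` mode is available for burden-style sensitivity analyses, where
  mutation-rich genes should rise.

Missing annotations are resolved asymmetrically, and deliberately so:

* a missing prediction, conservation score or flag encodes **0** — the
  score uses only the information available, and absence of evidence of
  deleteriousness must not look like evidence;
* a missing allele frequency encodes **1** — absence from a population
  database is itself evidence of rarity, and novelty is exactly the
  signal the score is designed to reward;
* in the **MAF filter**, by contrast, a missing AF is treated as **0**
  (i.e. passes any ceiling): a rare-variant filter that discarded novel
  variants would defeat its purpose. The two conventions point in the
  same scientific direction (keep and up-weight the unseen variant) even
  though numerically they look opposite.

## Ranking, ties and degenerate inputs

Variants are sorted by score descending and assigned *dense* ranks: tied
scores share a rank and the next distinct score takes the next integer,
so "the gene at rank 4" is reproducible regardless of tie sizes. Within
a tie, rows are ordered lexicographically by (chromosome, position, ref,
alt), which makes output files byte-stable under input permutation
(tested property). Score ties are compared on exact floating-point
equality; since every encoded weight is a small rational and the sum is
over at most 20 terms of well-separated magnitudes, genuinely equal
annotation profiles produce bit-identical sums.

Degenerate inputs are defined rather than rejected: an empty table ranks
to an empty table; an all-INDEL input yields an empty ranked table and a
populated INDEL table; a missing or unknown region annotation falls to
the intergenic tier (with a warning for unknown tokens); multi-allelic
VCF records are dropped and counted, since the encodings are defined per
alternate allele. Filters always recompute ranks on the surviving set.

The inheritance-model filters act at gene granularity but return
variants: every variant of a qualifying gene is kept by default so the
result remains a rankable table (a `functional_only` switch drops the
qualifying genes' non-functional variants). Recessive counting is purely
count-based — two functionally important variants in a gene qualify it
without any phase or compound-heterozygosity check, and the X-recessive
filter requires one functional variant on an X-linked gene (not two),
matching the count-based definitions of the other models. Genes with
multiple `;`-separated symbols attribute their variants to every symbol,
consistent with how ANNOVAR emits overlapping genes.

## What the synthetic exome is — and is not

`generate_background()` draws variants with (i) region-class proportions
dominated by intronic/intergenic classes with ~10% exonic, (ii) allele
frequencies from a Beta(2, 1) spectrum (mostly common, mean 2/3) with a
5% per-database missingness rate, (iii) 95% of variants carrying dbSNP
ids, (iv) predictions mostly tolerated (5% deleterious per algorithm,
independently) and conservation scores mostly below cutoff, and (v) a
2% INDEL admixture. `spike()` then appends novel, functional, rare,
uniformly-deleterious variants in a chosen gene — the two-sided contrast
the spike-in validation design needs: a spiked variant attains the
maximal encoded weight on every deleteriousness, conservation, rarity
and novelty source (score 17 under defaults), while the independence of
the background annotations makes such an accumulation vanishingly rare
among background variants.

That is precisely what passing spike-in tests do and do not show. They
demonstrate that the encoder, ranker and filters compose correctly and
that a variant with uniformly supporting evidence rises to the top
through 30,000 distractors. They do not demonstrate performance on real
exomes, where predictors are correlated, frequency spectra are
rare-heavy, annotations are missing in blocks, and causal variants
rarely carry unanimous support. The generator is a test harness, not a
population-genetics simulator: there is no linkage, no site-frequency
realism, no per-gene mutation-rate structure.

Problem sizes in the shipped tests reflect this purpose: encoding and
algebra properties run on hundreds of variants; the dual-route
score-equality check uses 1,000; the spike-in recovery experiments use
30,000-variant backgrounds over 20 seeds per design — large enough that
recovery is a statement about contrast, small enough to run routinely.

## Case-control counting conventions

`count_genotypes()` tallies homozygous-**alt** carriers, heterozygotes
and total called alleles per group. Homozygous-reference calls add
alleles but are not counted as "homozygous" — at a variant site, hom-ref
carries no carrier signal, and conflating the two would make the
cases-only predicate useless. Half-missing diploid calls (`./1`) are
treated as fully missing (conservative: an allele is only counted when
the whole call is trusted), and haploid calls contribute one allele with
no ploidy inference beyond the GT field itself. The module filters by
contrast predicates only; association statistics are out of scope, as
the tallies are inputs to ranking, not hypothesis tests.

## Known limitations

* Weights are user-specified priors, not learned; the default of 1 per
  source treats all sources as equally informative.
* The score ignores genotype quality, depth and strand evidence —
  upstream VCF filtering is assumed.
* The ANNOVAR header dialect varies across database releases; the
  built-in column map covers common multianno headers and accepts
  user overrides, but unrecognized annotation columns are carried as
  opaque extras rather than scored.
* Coordinates are passed through as given (1-based convention); no
  liftover is attempted.
```{r session}
sessionInfo()
```
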