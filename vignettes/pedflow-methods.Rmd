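---
title: "Family-based analysis of multiplex disease pedigrees with pedflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based analysis of multiplex disease pedigrees with pedflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedflow)
```

pedflow implements the genetic analyses used to dissect complex disease in
very large multiplex pedigrees — families with dozens of cases spread over
several generations, where neither a purely Mendelian model nor a standard
case/control design fits. The package covers the whole chain: pedigree
representation and kinship, genotype quality control, genetic risk scores
from known common risk loci, affected-only parametric linkage, haplotype-flow
reconstruction, within-family imputation of rare exome variants,
kinship-adjusted association, a variant prioritization cascade, and a
synthetic-data generator that makes every stage testable against simulation
truth. This vignette explains the models, the parameters that matter, and
the design decisions taken where the methodology left room.

## Pedigrees and kinship

A `Pedigree` is a validated table of individuals: founders have no parents
in the pedigree, non-founders have both, the graph is acyclic, and a
topological generation index orders parents before children. Founders who
marry into the family are treated as unrelated and non-inbred; the expected
kinship matrix follows the classic recursion (`pedigree_kinship`), so
phi(i,i) = 1/2 for every non-inbred individual, 1/4 for parent–offspring and
full siblings, 1/16 for first cousins. Sex is carried for reporting but
never used in autosomal computations, so sex-anonymized pedigrees are fully
supported.

Two genotype-based estimators complement the pedigree expectation. The
genomic relationship matrix (`genomic_kinship`) is the standardized
cross-product of dosages averaged over non-missing SNPs; on this scale an
outbred self is ~1 and half the off-diagonal is comparable to phi. The
moment estimator `pairwise_ibd_moments` recovers the probabilities of
sharing 0/1/2 alleles identical by descent from identity-by-state counts at
independent SNPs, clipping to [0,1] and renormalizing; pi-hat = P1/2 + P2.
Both are used to confirm recorded relationships, and the IBD machinery
remains available to cross-check the flow reassembly described below.

## Splitting large pedigrees

Exact inheritance-vector inference costs 2^(2n) states for n non-founders,
so pedigrees with hundreds of members must be cut up. `split_pedigree`
decomposes the pedigree into nuclear families and greedily re-merges them
while the Lander–Green bit size 2n − f stays within `max_bits` (default 20,
the conventional ceiling for exact multipoint engines). Connector
individuals — a child in one nuclear family, a parent in another — are
duplicated across chunks and recorded in an overlap map. Because the
exact-HMM cost is 2^(2n)·4^f rather than 2^(2n−f), the splitter also
accepts `max_meioses` and `max_founders` caps; the flow reconstruction uses
12 and 6 by default, i.e. at most 4096 inheritance vectors and 4096
founder-allele assignments per chunk. Any decomposition satisfying the
coverage conditions (every individual in a chunk, every parent–child link
covered, connectors shared) is acceptable; the greedy strategy simply keeps
chunk counts low.

## Genotype quality control

`snp_qc_filter` applies three marker filters: missingness above 1%
(computed over all samples), minor allele frequency below 1%, and
Hardy–Weinberg deviation in founders at a plain 1-df chi-squared P below
1e-5 (observed versus HWE-expected genotype counts, no continuity
correction, founders only so transmission cannot masquerade as
disequilibrium). Markers with no called founders skip the HWE test and are
logged. The filters are pure thresholds, hence idempotent.

Mendelian cleaning follows the duo/trio rules: an impossible transmission
(child 2 with a parent 0, child 0 with a parent 2, or a heterozygous child
of two identical homozygotes) blanks the child and the implicated
parent(s) at that SNP. Extended-pedigree inconsistency propagation is out
of scope — only conflicts visible within a duo or trio are detected, which
is the conservative reading of the cleaning rule. `mendelian_fill` then
fills only forced child genotypes (both parents homozygous, or one 0 and
one 2 giving an obligate heterozygote); by construction it can never create
a new inconsistency.

## Genetic risk scores

A risk locus contributes `dosage × log(OR)` in natural-log units, assuming
additivity within and between loci. The exception is a genotype-class
group (as used for the three main NOD2 lesions): the combined count of
variant alleles across the group selects a single class log-OR — one
variant, or two-and-more (homozygous or compound heterozygous) — rather
than a sum of per-variant terms. Class odds ratios are mandatory
configuration with no built-in defaults, since published per-allele ORs do
not determine them. A missing genotype contributes its HWE expectation at
the risk-allele frequency (2·RAF·log OR), keeping scores comparable across
missingness patterns; individuals with no observed loci are excluded
rather than scored zero, and individuals with under half the panel
observed are flagged.

Reference distributions are simulated (`simulate_reference`, default
n = 1000 per group): control genotypes from HWE at the RAF, case genotypes
from P(g | case) proportional to P(g | HWE)·OR(g) — the exact Bayes
reweighting, which the tests verify against a closed-form enumeration over
the three genotypes. Group comparisons use the two-sided
Mann–Whitney–Wilcoxon test. Because scores are log odds, a "fold
difference" is ambiguous; `compare_grs_groups` therefore reports both
`exp(median(group) − median(reference))` and the raw medians, leaving the
scale explicit.

## Affected-only parametric linkage

`lander_green_lod` implements the Lander–Green hidden Markov model over
inheritance vectors: one bit per meiosis, Haldane recombination fractions
between markers, forward–backward message passing with per-bit transition
mixing, and founder-allele emission sums (founder haplotypes are i.i.d.
draws at each marker, so emissions enumerate the 4^f allele assignments).
The LOD at a position x is log10 of the likelihood ratio of the disease
locus at x versus unlinked, with the phenotype likelihood computed from a
parametric `disease_model`. Unaffected individuals are coded unknown — the
affected-only design guards against incomplete penetrance. The default
model is dominant with disease allele frequency 0.001 and penetrances
(0.05, 0.5, 0.5): the 5% phenocopy rate is the one firmly specified
parameter; the rest are explicit, configurable placeholders. The
evaluation grid defaults to 0.5 cM. A simple r² < 0.1 founder-LD pruning
pass (`ld_prune`) prepares an informative marker subset.

Correctness rests on an independent oracle: `single_point_lod_bruteforce`
enumerates the full joint likelihood — all founder marker-allele
assignments, all founder disease-allele assignments, and both inheritance
patterns coupled by Hamming distance — with no message passing and no
founder-symmetry shortcuts. The acceptance suite checks the HMM against
this oracle on 50 random pedigrees of up to 12 meioses; agreement is at
machine precision (~1e-14, against a 1e-6 requirement).

## Haplotype-flow reconstruction

The flow of founder haplotypes is decoded per chunk by Viterbi over the
same HMM: the single most probable inheritance path, converted to
founder-haplotype labels `<founder>|A` / `<founder>|B` per individual per
locus, with the posterior probability of the decoded state as confidence.
Viterbi (rather than locus-wise posterior maximization) guarantees one
consistent inheritance path. Labels are identifiable only up to swapping a
founder's two haplotypes, and evaluation is always modulo such swaps.

Reassembly across chunks works through the connectors: chunks are
processed in topological order (a chunk waits for the chunk in which each
of its local founders is a child), and a connector's already-resolved
phased allele content is pinned into the next chunk's emission — chunk
haplotype A is identified with the resolved paternal track, so no
orientation search is needed and the connector's phase information
transfers losslessly. Where the pinned content contradicts a chunk's own
genotypes at a locus (possible when the upstream phase was itself wrong),
that locus falls back to the unconstrained emission. Pairwise IBD
estimates remain available as an independent check on the reassembly.

Two limitations are intrinsic and worth knowing. First, at loci where a
parent is homozygous, which haplotype a child received is genuinely
unidentifiable; the HMM interpolates through such runs using flanking
markers, and errors concentrate at chromosome ends where only one flank
exists. Second, when two of k children recombine in the same uninformative
interval, flipping the founder's phase for the rest of the chromosome
costs exactly as many recombinations as the truth — a tie no exact decoder
can break; small sibships are most exposed. Validation therefore uses a
balanced three-generation pedigree (sibship 5, every child reproducing
with a founder spouse, 37 individuals) and a maximally informative
biallelic panel (founder allele frequency 0.5, 200 markers at 0.5 cM) —
the analogue of the LD-pruned informative marker set a linkage study would
select. Under those conditions reconstruction accuracy, scored per allele
slot over non-founders modulo founder label swaps, is 0.99 on average
(minimum 0.989 over 12 seeds).

`max_haplotype_sharing` reports, per locus, the maximum number of distinct
cases carrying any one founder haplotype, with ties, plus the genome-wide
maximum — the statistic that bounds how much of the family any single
locus could explain.

## Within-family imputation

A rare exome variant seen in sequenced family members is mapped to founder
haplotypes by `assign_founder_haplotype`: the minimal label set such that
every sequenced carrier holds at least one label (a homozygote needs two,
counted with multiplicity) and no sequenced non-carrier holds any. The
search is exhaustive over single labels and pairs, which suffices because
a rare variant enters a family on at most two founder haplotypes;
ambiguous minimal sets resolve lexicographically, and an empty search is a
conflict (the strict all-carriers rule is the default; a
`max_noncarrier_hits` knob relaxes it). Variants between flow loci take
the flanking label only when both flanks agree, per individual and
haplotype side — a deliberately conservative rule. `impute_from_flow` then
assigns each non-sequenced individual the number of assigned labels it
carries; observed genotypes are authoritative and never overwritten, and
unknown flow yields missing, not zero. On gene-dropped data with 60% of
members sequenced, imputed dosages match truth in ≥98% of imputable
individuals.

## Kinship-adjusted association

`fit_lmm_null` fits y = mu + g + e with cov(g) = sigma_g²·K by restricted
maximum likelihood: one eigendecomposition of K, then a one-dimensional
profile optimization over the variance ratio (log-ratio interval ±12,
boundary at zero genetic variance checked explicitly). Binary affection is
analyzed quantitatively on the 0/1 scale, the standard fast-LMM approach
for family data; no liability-threshold transform is applied. Eigenvalues
below 1e-8 are clipped (duplicated samples make K singular but valid);
matrices with eigenvalues below −1e-6 are rejected. The null model is
intercept-only.

`wald_test` is generalized least squares with the null-model variance
ratio, the residual variance re-estimated under the alternative so that
with K = I the test reduces exactly to the OLS Wald test; P values come
from the standard normal, two-sided. Calibration was checked by
simulation: 2,000 null markers on a 302-member pedigree phenotype give a
type-I error within the binomial band around 0.05, and variance-component
recovery at n = 302 over 200 replicates is within 3% of truth (15%
required).

`min_theoretical_p` answers "what is the best P this family could ever
show?": a hypothetical variant carried by every affected individual and no
terminal unaffected individual (unaffected with no affected descendants).
Connecting individuals take carrier-consistent values resolved toward
carriage — the most conservative fill, since unaffected carriers weaken
the association. On a 302-member pedigree with 50 cases spread across the
terminal branches the bound is ~1e-22, comfortably below the 1e-16
benchmark for families of this size.

## Variant prioritization cascade

The exome cascade operates on an annotation table (one row per variant
transcript) and applies, as pure conjunctions (hence order-invariant):
autosome restriction; a consequence filter keeping start/stop/splice/
frameshift classes in any transcript, or missense predicted deleterious by
CAROL or Condel or with CADD strictly above 20 (the CADD clause attaches
to missense only — a synonymous variant with CADD 30 is still dropped; a
config switch can widen it); a frequency filter dropping variants strictly
above 2.5% in any reference population or 5% in a local panel (missing
frequencies never exclude); and a per-family case-missingness limit
(defaults 20 and 10). Sharing-based prioritization keeps variants carried
by ≥60% of genotyped cases in the whole family or any designated
subfamily — "observed in" means a non-missing dosage ≥1, and the
denominator is genotyped cases, since missingness should not count
against a variant. Ranking is by minimum Wald P across units, ascending,
ties broken by genomic coordinate, unranked variants last and flagged.
The tests verify every stage count against independent set-arithmetic on a
400-variant random table, exactly.

## The synthetic-data generator

The generator exists so that every inference stage can be validated
against known truth; it emulates the statistical structure of a large
multiplex family rather than any particular dataset:

* **Structure** — one founder couple; each child marries a new founder
  spouse with probability 0.7 and produces a sibship of 1 + Poisson(mean−1)
  children; the default mean of 10 reproduces the large-sibship regime
  (quartiles bracketing 8–11) of ultra-large families, and four
  generations at these defaults give several hundred members.
  `balanced_pedigree` provides the deterministic counterpart for
  benchmarks.
* **Genotypes** — founder haplotypes i.i.d. per marker under HWE;
  meioses recombine between adjacent markers at the Haldane fraction of
  the map spacing (default 0.5 cM). The gene drop returns the true
  haplotype flow alongside the genotypes.
* **Phenotypes** — logistic liability: baseline prevalence 1.3% for an
  average-risk individual, plus common risk-locus contributions
  (g − 2·RAF)·log OR — centered so the baseline keeps its meaning under a
  127-locus panel — plus the log-OR of any carried rare causal variant
  placed on a named founder haplotype. Phenocopies: non-carriers of every
  causal variant become affected with probability 0.05 regardless of
  liability, mirroring the 5% phenocopy rate of the linkage model.
* **Emission** — PED/FAM, plain-text VCF, marker map, risk-locus table,
  truth flow, and an annotation table with decoy variants constructed to
  fail exactly one cascade stage each, so survivor counts are known.

What the generator does **not** emulate: linkage disequilibrium among
framework SNPs (founder haplotypes are locus-independent), genotyping
error and missingness (injected explicitly by tests that need them),
population stratification, and age-dependent penetrance. Passing tests
therefore demonstrate the inference machinery, not robustness to every
artifact of real array data.

## Validation problem sizes

The test-suite and acceptance checks use: 50 random pedigrees of ≤12
meioses for the linkage oracle; a 37-member balanced three-generation
pedigree with 200 informative SNPs for flow and imputation; a 302-member
four-generation pedigree for REML recovery (200 replicates), type-I error
(2,000 tests) and the best-case P bound; 20 seeds of the full
QC → flow → imputation → LMM → cascade pipeline for causal-variant
recovery (top-5 rank in ≥80% of seeds; observed 90%); and a 400-variant
random annotation table for the cascade oracle. These sizes were chosen as
the smallest that make the statistical assertions stable.

## The end-to-end pipeline

`run_pipeline` executes the stages in dependency order
(qc → kinship → {grs, linkage, flow} → impute → assoc → prioritize, with
descriptive statistics independent), logs every output with an md5
checksum into an append-only run directory, skips stages whose
dependencies failed while letting independent branches continue, and is
byte-identical on rerun for deterministic stages. A YAML config mirrors
`run_config`; the thin `inst/exec/pedflow` script exposes `simulate`,
per-stage and `all` subcommands for shell use.

## Known limitations

Exact inference bounds chunk sizes, so very large sibships (≥9 children)
must stand alone as chunks and anything larger is rejected rather than
approximated; no MCMC fallback is provided. X-chromosome kinship and
linkage, multi-allelic markers, logistic mixed models, and
population-LD-based imputation are out of scope. The flow decoder commits
to a single Viterbi path; per-locus posterior label probabilities beyond
the path confidence are not reported.
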