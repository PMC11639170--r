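---
title: "Detecting introgression under among-species rate variation"
author: "introClust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression under among-species rate variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The ABBA–BABA framework detects introgression in a species quartet — an
ordered trio P1, P2, P3 (with P1 and P2 sisters) and an outgroup P4 — from
an imbalance in derived-allele sharing. With the derived allele "B" defined
per site as the allele at lower frequency among the outgroup's alleles,
Patterson's D is

$$D = \frac{C_{ABBA} - C_{BABA}}{C_{ABBA} + C_{BABA}}, \qquad
C_{ABBA} = \sum_i (1-f_{B,P1,i})\,f_{B,P2,i}\,f_{B,P3,i}, \quad
C_{BABA} = \sum_i f_{B,P1,i}\,(1-f_{B,P2,i})\,f_{B,P3,i},$$

summed over all retained bi-allelic polymorphic sites. Under incomplete
lineage sorting alone, $E[D] = 0$. The catch is that this expectation also
assumes equal substitution rates in P1 and P2. In old species groups that
assumption routinely fails, and homoplasies — independent substitutions at
the same site on different branches — then accumulate asymmetrically: the
faster sister shares more coincident derived alleles with the non-sister
*and* with the outgroup, and reversals on the faster branch add further
asymmetry. The net effect is a strongly significant D without any gene
flow, misdirected toward one or the other non-sister pair depending on
whether the focal branch is fast or slow.

This package implements the D-statistic with block-jackknife significance,
a positional *clustering test* that discriminates such rate-variation
artefacts from genuine introgression, two tree-set statistics
(constrained Dtree, dMRCA), and the four-taxon coalescent simulation design
needed to study all of them end to end.

## The ABBA-site clustering test

Introgressed haplotypes enter a genome as contiguous tracts carrying many
linked variants, so the sites supporting the excess pattern cluster along
chromosomes; homoplasies arise one by one and scatter homogeneously. The
test makes this operational:

1. **Strong sites.** A site is a *strong ABBA site* when
   $(1-f_{P1})f_{P2}f_{P3}(1-f_{P4}) + f_{P1}(1-f_{P2})(1-f_{P3})f_{P4} > 0.5$ —
   i.e. most sampled alleles jointly support the ABBA configuration in
   either polarization. *Strong BABA sites* satisfy the analogous
   expression with P1 and P2 exchanged.
2. **Index vectors.** For the *sensitive* version, record the 0-based
   ordinals of strong ABBA sites within the vector of all polymorphic
   sites of each chromosome; concatenate chromosomes with cumulative
   offsets; divide by the total background length to obtain values in
   $[0,1]$. The *robust* version replaces the background with the strong
   ABBA and strong BABA sites only.
3. **Test.** Compare the normalized ordinals to Uniform(0,1) with a
   one-sample Kolmogorov–Smirnov test. Significance indicates clustering,
   supporting genuine introgression.

The two versions trade power against robustness. The sensitive version
uses all polymorphic sites as its yardstick and therefore picks up even
moderate clustering, but local mutation-rate variation inflates the
density of *all* site types in hotspots, including ABBA-pattern
homoplasies, which can produce weak false positives. The robust version
measures strong ABBA sites against strong BABA sites; both densities scale
identically with the local mutation rate, cancelling that artefact, at the
cost of power when strong BABA sites are few (e.g. very strong
introgression with little ILS, where clustering has nothing to stand out
against).

### Numerical choices

* The KS statistic is computed directly from the sorted ordinals
  ($\max_i \max(i/n - x_{(i)},\ x_{(i)} - (i-1)/n)$). P-values use the
  exact small-sample distribution (Marsaglia–Tsang–Wang matrix power)
  below $n = 50$ and the asymptotic Kolmogorov distribution above, with
  the theta-function series for small $\sqrt{n}D$ where the alternating
  series converges poorly. Ties from discrete ordinals are ignored — with
  thousands of sites the discreteness effect is negligible.
* At least `minSites = 10` strong ABBA sites are required before a p-value
  is reported (`status = "insufficient_sites"` otherwise); a KS test on
  fewer points is not meaningful.
* All p-values are floored at `2.3e-16` so that extreme results remain
  comparable across datasets.
* The test runs after the D-orientation rotation, so "ABBA" always denotes
  the excess pattern (set `rotate = FALSE` to disable).
* The background of the sensitive version consists of the retained
  bi-allelic sites — the same single filtering pass used for D, keeping
  the two statistics consistent.

## D-statistic details

* **Polarization.** The derived allele is the rarer allele among the
  outgroup's called alleles. When the outgroup is exactly 50/50, the
  globally rarer allele (summed over the four species) is taken, with a
  final tie broken toward the VCF ALT allele; the number of such ties is
  logged and a `tieRule = "drop"` alternative is available. This rule is
  deterministic and invariant to REF/ALT relabelling.
* **Site filters.** Non-SNP records, sites with more than two alleles
  observed across the four species, sites where any species has no called
  allele, and monomorphic sites are dropped, with per-category counts kept
  in the table's metadata. Frequencies are computed over called alleles
  only.
* **Rotation.** When D would be negative, the P1 and P2 roles are swapped
  (exchanging CABBA and CBABA) so that the reported D is non-negative; the
  flag records the swap. A rotated result for a no-migration scenario with
  a fast P2 branch is exactly the misdirected-signal pathology described
  above.
* **Jackknife.** Significance uses a 20-block delete-one jackknife:
  contiguous blocks of equal *variant count* (the interpretation we adopt
  for "equally sized subsets"; equal-bp blocks are available via
  `equalBp = TRUE`), never spanning chromosome boundaries, with
  $Z = D/\widehat{SE}(D)$ and a two-sided normal p-value. Equal variant
  counts stabilize the jackknife when variant density varies along the
  genome.
* Raw p-values are reported; `bonferroni()` is a helper for users running
  many trios or datasets.

## Tree-set statistics

`readTreeSet()` parses rooted four-taxon newick trees (rooting unrooted
input on P4), determines each tree's ingroup trio topology, and filters
trees whose single internal branch after pruning P4 — well-defined for
four-taxon trees — is shorter than 0.001 substitutions/site, treating them
as uninformative.

The constrained **Dtree** compares the counts of the two discordant
topologies, $D_{tree} = (C_{P2,P3} - C_{P1,P3})/(C_{P2,P3} + C_{P1,P3})$,
with a one-sided *exact* binomial test of $C_{P2,P3} > C_{P1,P3}$ (the
normal approximation saves nothing at typical tree counts and fails at
small ones). The unconstrained variant (2nd- vs 3rd-most frequent
topology) is available behind `constrained = FALSE` but is not the
default, since it underestimates strong introgression whenever the most
frequent topology is no longer the species tree.

**dMRCA** takes ultrametric local time trees, averages the P1–P2, P1–P3
and P2–P3 MRCA ages over trees, and reports the difference between the two
largest means. Without introgression the two deep pairs date the same node
(the trio root) and dMRCA sits near zero. The identities of the two oldest
pairs are always reported: with a very fast P2 branch the oldest pairs can
stop being P1–P3/P2–P3 altogether, in which case dMRCA is not
interpretable as introgression evidence — the package reports the
identities and leaves the judgement to the user. There is no formal null
test; the statistic ranks hypotheses for confirmation by other methods.

## The simulation design

The generator reproduces the study conditions: species tree
(((P1,P2),P3),P4) with the P1/P2 split at $t \in \{1,2,3\}\times10^7$
generations and P3/P4 branching $10^7$ and $2\times10^7$ generations
earlier (constant internode distances, hence near-constant ILS);
$N_e \in \{10^4, 10^5\}$ diploid for every species; a single chromosome of
$2\times10^7$ bp with uniform recombination $r = 10^{-8}$; HKY mutations
($\kappa = 2$, uniform base frequencies, uniform ancestral alleles) at
$\mu \in \{1, 2\}\times10^{-9}$; five diploid samples per species;
symmetric P2–P3 migration at
$m \in \{0, 10^{-9}, 10^{-8}, 10^{-7}, 10^{-6}\}$ during a window opening
at the P1/P2 split and closing $2.5\times10^6$ generations later toward
the present; and a P2 rate-scale factor $s \in \{0.25, 0.5, 1, 2, 4\}$.
The full cross-product is 300 parameter combinations
(`scenarioGrid()`).

**Rate scaling by sampling times.** Coalescent engines do not vary the
mutation rate among branches, so the P2 branch is instead stretched or
shrunk: for $s<1$, P2 is sampled $(1-s)\,t$ generations in the past; for
$s>1$, every divergence (and the migration window) is shifted
$(s-1)\,t$ generations deeper and P1/P3/P4 are sampled at the shift time
while P2 stays at the present. Either way only the P2 terminal branch's
mutation input changes, and — crucially — the homoplasy and reversal
structure matches what a genuinely faster or slower branch would produce.
A direct `rateScaling = "branch_rate"` alternative (thinning or
overlaying mutations on P2-resident edges) is provided for
cross-validation of the work-around.

**Ground truth.** From the genealogical record the package measures: the
union of chromosome intervals whose ancestry crossed between P2 and P3
through a migration event for at least one sampled lineage (the most
inclusive reading of "affected by introgression"; the merged intervals are
exposed for stricter re-definitions); single-topology tracts, i.e. maximal
runs of local trees sharing one rooted trio topology for one haploid
genome per species (the same data reduction used for tree-based
analyses); the mean recombination-unbroken segment length
$L/\#\text{distinct trees}$; per-pair $d_{xy}$; and variable /
multi-allelic site counts. For $d_{xy}$ the closed-form expectation
$\mu\,(t_{i}+t_{j}+4N_e)$ (branch lengths of the two tips plus the
ancestral coalescent) serves as an oracle in the tests; observed values
sit a few percent below it because of multiple hits, which is why the
tests allow 5–7%.

**Window alignments.** For tree-based methods the canonical schemes cut
5000×200 bp, 2000×500 bp or 1000×1000 bp windows, with starts spaced
$L/n$ apart (the counts imply uniform spacing covering 1 Mbp of the
20 Mbp). Per species and variable site only the first allele of the first
individual is used; invariant columns are filled with a single random
base shared by all four rows.

## Problem sizes

The simulations in the test suite and the acceptance script use the study
parameters on shortened chromosomes, a choice we make to keep the runs
desk-sized: the 20-Mbp study scale costs tens of minutes per replicate,
and nothing about the statistics under test requires it. Intensive
quantities (D, introgressed fraction, $d_{xy}$, tract means) are reported
as measured; sums over sites (CABBA, variable-site counts) are rescaled to
the 20-Mbp reference length via their per-bp density, which is unbiased
because both are sums of per-site terms. Point bounds that were stated for
20-Mbp datasets (e.g. "D below 0.015 under the null") are checked in the
test suite with an explicit $2\,\widehat{SE}$ sampling allowance from the
block jackknife, since the sampling standard deviation of D scales as
$\sqrt{20\,\text{Mbp}/L}$; the acceptance script reports the measured
values themselves, without allowances. Because the null-D bound is the
tightest of these quantities, the acceptance script builds its null
dataset from three independently simulated 2-Mbp chromosomes analysed
jointly — statistically a single 6-Mbp multi-chromosome dataset — to
bring the sampling noise of D close to the study scale. Calibration replicates (the
20-replicate null panel for the clustering test) use the
$N_e = 10^4$, $\mu = 2\times10^{-9}$ corner of the study grid, where the
coalescent is cheapest, at $L = 5\times10^5$ bp — large enough that
strong-site counts comfortably exceed the `minSites` reporting threshold.

## What the generator does and does not emulate

It reproduces coalescent genealogy structure, recombination, timed
continuous migration, HKY homoplasy and reversal structure, within-species
polymorphism, and branch-rate asymmetry — the ingredients that create both
the artefact and the signal. It does not emulate: among-site mutation-rate
variation or recombination-rate maps (supported as untested configuration
hooks only), selection, gene conversion, missing data, genotyping error,
or reference bias. Passing tests therefore demonstrate correct behaviour
of the statistics under the modelled processes, not robustness to
empirical nuisances such as hotspot-driven clustering — which is exactly
the artefact the robust test version exists for, and why both versions are
reported.

## Known limitations

* The clustering test needs contiguous genomic blocks; heavily fragmented
  assemblies dilute positional signal.
* Large low-recombination regions (e.g. inversions) can carry ILS-derived
  tracts that cluster like introgression; scanning per chromosome and
  inspecting the per-site label table (`writeSiteLabelsTSV()`) is the
  recommended diagnostic.
* The robust version loses power when nearly the whole chromosome is
  introgressed (few strong BABA sites, long uniform blocks); the
  combination of a very high D with a significant sensitive test covers
  that regime.
* Dtree consumes externally inferred trees; inference artefacts such as
  long-branch attraction enter upstream of the statistic and are only
  weakly visible in it.
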