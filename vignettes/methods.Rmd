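---
title: "Epigenome-aware polygenic risk modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenome-aware polygenic risk modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprs)
```

## The model

Classical polygenic risk scores are weighted sums of allele dosages: linear
in genotype, blind to regulatory mechanism, and weak where risk is carried
by rare variants. This package implements an alternative in which imputed
epigenomic signals act as intermediaries between genotype and phenotype:

1. **Personal genome construction.** Phased SNV genotypes are substituted
   into the reference to produce the two haploid sequences of each
   individual. Only single-nucleotide variants are handled, so sequence
   length is conserved and every downstream coordinate is shared across the
   cohort. Statistical phasing cannot assign parent of origin, so the two
   haplotype slots are arbitrary labels; every downstream step is invariant
   to their order (see *Diploid combination* below).
2. **Windowed feature extraction.** Each selected LD block is tiled with
   fixed-geometry model input windows (default 196,608 bp with 896 central
   non-overlapping 128 bp bins, i.e. a 114,688 bp central region). A
   sequence-to-feature extractor maps each haploid window sequence to a
   `bins x tracks` matrix. The extractor is a pluggable contract; the
   package ships a deterministic synthetic extractor (below) so the whole
   pipeline runs and is testable without pretrained model weights.
3. **Per-bin local PCA.** For each bin, the feature vectors of all
   training individuals — both haplotypes entering as separate
   observations — are reduced to `d' = 5` principal components. The two
   haplotype projections are averaged (the diploid mean rule) and the
   per-bin vectors concatenated in (window, bin, component) order, giving
   `896 x 5 = 4480` predictor features per default-geometry window.
4. **Block selection and risk modeling.** LD blocks are retained when they
   contain at least one variant with a GWAS p-value below a threshold
   `P0`; summary statistics can be supplied externally or computed by the
   built-in allelic chi-square scan on the training split. A
   gradient-boosted trees classifier (regressor for continuous traits) is
   trained on the concatenated block features; evaluation reports the test
   auROC `A` and the relative gain over random guessing
   `lambda = (A - 0.5)/0.5`.

The stride of the window tiling equals the central length, so central bins
tile each block without overlap or gaps; the last window may extend past
the block end, and windows that would overhang a contig are shifted inward
and flagged. Note one arithmetical choice: `896 x 128 = 114,688` bp is
used consistently as the central length.

## The phenotype simulator

The simulator generates phased cohorts and binary phenotypes from a
four-component liability model

$$g(\mu_i) = \alpha_0 + y_i^{epi} + y_i^{direct} + y_i^{env} + y_i^{inter},$$

with a logit link in Bernoulli mode. The components are:

- **Epigenetic**: $y_i^{epi} = \sum_{g \in G}\sum_{t \in T}\sum_{k \in S_g}
  X_{ik} B_{tk} e_{gtk}$, where $G$ holds one causal gene per LD block,
  $S_g$ the causal variants in regulatory elements within 1 Mb of the gene
  (100 per gene by default), $B_{tk}$ the binary TF-binding indicator, and
  $e_{gtk} \sim N(0, \sigma_t^2)$ with $\sigma_t^2 \sim \mathrm{IG}(3, 1)$
  (shape/scale parameterization, mean 1/2; the shape/rate reading was the
  other candidate and is noted here because the two differ only in scale,
  which the exact rescaling below absorbs anyway).
- **Direct**: $y_i^{direct} = \sum_{k \notin \cup_g S_g} X_{ik}\beta_k$
  over SNVs outside regulatory elements of causal genes,
  $\beta_k \sim N(0,1)$.
- **Interaction**: disjoint random pairs $(p, q)$ of causal variants with
  multiplicative effects $\gamma_{pq} X_{ip} X_{iq}$,
  $\gamma_{pq} \sim N(0,1)$; the number of pairs is
  `round(f_inter * |causal| / 2)`.
- **Environment**: $y_i^{env} \sim N(0,\, 1 - h^2_{epi} - h^2_{direct} -
  h^2_{inter})$.

$X_{ik}$ is the per-site standardized dosage (population mean 0, variance
1; the standard "normalized genotype" convention — the population-variance
denominator makes the variance bookkeeping exact). Each genetic component
is affinely rescaled to population mean 0 and *exactly* its target
variance; the environmental component is sampled, not rescaled. A raw
genetic component that comes out constant while its target variance is
positive is a degenerate draw and raises an error rather than being
silently rescaled.

Labels come from thresholding by default — the `round(n * prevalence)`
largest liabilities are cases, ties broken by a seeded random order, with
`alpha0` reported as minus the implied cut — because that reading makes
the expected case count exact at the default prevalence 0.5. The
alternative Bernoulli mechanism (intercept calibrated by monotone
root-finding so the mean case probability equals the prevalence within
1e-8) is available as `phenotype_mode = "bernoulli"`.

Key dials and their defaults:

| parameter | default | meaning |
|---|---|---|
| `n` | 4000 | individuals |
| `causal_per_gene` | 100 | causal variants per causal gene |
| `prevalence` | 0.5 | sample case fraction |
| `rare_fraction` | 0 | fraction of contributing sites drawn rare |
| `rare_range` | [0.001, 0.01) | rare MAF range ("rare" = MAF < 0.01, the conventional cutoff) |
| `common_range` | [0.05, 0.5] | common MAF range |
| `f_inter` | 0.5 | fraction of causal sites entering interaction pairs |
| `ld_rho` | 0 | latent-factor haplotype correlation; `ld_group_bp` sets the factor width |

`rare_fraction` applies to *all* phenotype-contributing sites (regulatory
causal and direct-effect sites): the rare-variant dial must reach the
direct component for a pure-direct architecture to become rare-driven.
The resulting MAF spectrum is bimodal by construction, which is what makes
the linear baseline's common-variant filter (below) well defined.

LD is modeled, optionally, by one latent Gaussian factor per haplotype per
`ld_group_bp` stretch of a block: allele indicators are thresholded from
$\sqrt{\rho}\, z_{group} + \sqrt{1-\rho}\,\varepsilon$. This gives blocks
a local, approximately low-rank correlation structure while preserving
marginal MAFs. It reproduces two qualitative properties of real LD blocks
— common variants tag each other strongly, rare variants are poorly
tagged — but not recombination-map detail or allele-age structure.

## The synthetic extractor

The synthetic extractor makes the pipeline testable at desk scale and
gives the simulator a ground-truth chain from sequence to feature to
phenotype. Per bin (extended by `flank` bp on each side) it computes
occurrences of `n_motifs` fixed consensus motifs (counted by start
position), the GC fraction, and the 16 dinucleotide frequencies, then maps
this vector through a fixed seeded linear projection and a softplus
nonlinearity to `d` tracks. Track labels carry tissue/assay tags so the
tissue-restriction mechanism (`select_tracks`) can be exercised.

Two properties matter:

- **Locality.** A substitution can only affect bins within
  `flank + motif_length - 1` bp (the receptive flank) — exactly testable,
  unlike a real sequence model's soft receptive field.
- **Site resolvability.** Motif counts respond only to motif gain/loss;
  GC responds to every A/T-to-G/C substitution but moves all tracks along
  a single direction, so with motif counts + GC alone a bin's
  cross-individual feature response is effectively rank one and per-bin
  PCA cannot distinguish the sites within a bin. The dinucleotide channels
  give each substitution a context-specific signature, analogous to a
  trained model's rich response to any local sequence change. Without
  them, the feature path carries almost no non-regulatory genetic signal
  and the feature-based model could not track a genotype model even in
  principle.

In sequence-coupled simulation mode, causal regulatory sites are planted
inside motif instances of the extractor's own motif set: the reference
allele carries the consensus, the alternate allele destroys the instance,
and the binding matrix `B` records the planted motif's TF. Regulatory
disruption is then genuinely visible in the features, which is the premise
of the method being modeled.

## Dimension reduction choices

- **Fit population.** Per-bin PCA is fitted on the training split only;
  held-out samples are transformed with frozen models. The source
  procedure is silent on this; fitting on all samples would leak test
  information into the representation.
- **Pooling.** Both haplotypes of each training individual enter the fit
  as separate observations (`2 x n_train` vectors per bin), matching the
  per-haplotype feature sets the reduction is defined over.
- **Diploid combination.** The per-bin projections of the two haplotypes
  are averaged by default. The mean rule is invariant to haplotype order
  (phasing slots are arbitrary) and yields one `d'`-vector per bin per
  individual, consistent with the 4,480-feature count per window; `sum`
  and `concat` are available as alternatives.
- **Sign and degeneracy.** Each component's largest-magnitude loading is
  forced positive (reproducibility across LAPACK builds). If the data rank
  is below `d'`, trailing components are zero columns and the model is
  flagged; projections onto them are zero, so downstream shapes never
  change.
- **Centering only.** Tracks are model outputs on comparable scales; no
  per-track rescaling is applied, keeping the reduction a plain PCA.

## Risk models

- **GBRT** (xgboost): 500 trees, depth 3, learning rate 0.05, row
  subsampling 0.8, early stopping on a seeded 10% carve-out of the
  training set, single-threaded with a fixed seed so fits are
  deterministic. These are conservative defaults; the source gives none.
- **Linear baseline**: an L2-penalized (ridge) logistic regression on
  standardized dosages, cross-validated with seeded folds. It stands in
  for summary-statistic linear PRS methods, which operate on common SNP
  genotypes; accordingly it is restricted to common variants
  (MAF >= 0.05, the simulator's common-range boundary — any cutoff inside
  the bimodal MAF gap selects the same sites). This restriction is the
  mechanism behind the rare-variant degradation the benchmarks measure,
  exactly as common-SNP linear PRS degrade on rare-variant architectures.
- **Genotype-PCA-GBRT**: GBRT on the top 20 training-fitted genotype
  principal components. With weak or factor-less synthetic LD this
  compression is information-destroying (site effects are idiosyncratic,
  not low-rank), so this arm underperforms at desk scale in a way it need
  not on real, strongly structured LD blocks; the benchmark reports it but
  the qualitative nonlinear-versus-linear comparison rests on the
  full-information arms.
- **Combination.** Multiple blocks are combined by feature concatenation
  by default; the alternative per-block weighted combination fits a
  logistic regression of training labels on per-block scores and applies
  the fitted weights to test scores.

Evaluation is the rank-based (Mann-Whitney) auROC with half-credit for
ties, plus `lambda = (A - 0.5)/0.5`; regression tasks report
`R^2 = 1 - SS_res/SS_tot` on the test set.

## Reduced-scale study conditions

The acceptance suite reruns the three simulation experiments behind the
method's motivating findings at desk scale, with 20 replicates each and a
shared synthetic extractor (4,096 bp windows, 16 bins of 128 bp, 24
tracks, 6 motifs, flank 8 bp). Problem sizes were chosen once so that each
experiment exercises its mechanism within a single-CPU test budget:

- **Interaction experiment** (linear versus nonlinear): n = 4,000,
  40 direct + 20 neutral sites per block, variance split 30% direct / 70%
  interaction over 10 causal-site pairs, local LD factors
  (rho = 0.8, 256 bp groups). Interaction variance must dominate for the
  nonlinear gain to be visible at desk-scale n; with many weak pairs, no
  method can learn them at these sample sizes.
- **Rare-variant experiment**: n = 2,000, 80% direct / 20% interaction,
  rare fraction 0, 0.5, 1. The site budget keeps the feature map in the
  regime where reduced features outnumber sites per window — the regime
  the full-geometry method operates in (4,480 features versus a few
  hundred SNVs per window), so the feature path's fidelity at desk scale
  matches its full-scale character.
- **Epigenetic-share experiment**: n = 800, 100 direct + 100 neutral
  sites, interaction share fixed at 10%, epigenetic share 0%, 50%, 100% of
  the remainder, sequence-coupled. Here the background site load is
  deliberately high: the feature path resolves planted regulatory
  disruptions better than diffuse direct effects, which is exactly the
  asymmetry the experiment measures.
- **Null check**: all genetic variance proportions zero, n = 1,200; every
  method's 20-replicate mean auROC must lie in [0.45, 0.55].

These synthetic cohorts emulate controllable MAF spectra, regulatory
annotation structure, and the four-component liability; they do **not**
emulate recombination-derived LD patterns, population structure or
relatedness, genotyping error, indels, or a trained sequence model's
biology. Passing tests therefore demonstrate that the implementation
realizes the specified mechanisms and orderings, not that the method
attains any particular accuracy on real cohorts.

## Numerical and degenerate-input conventions

- Internal coordinates are 0-based half-open; VCF positions (1-based) are
  converted at the I/O boundary; BED is read natively as 0-based.
- Missing genotypes (`./.`) become homozygous reference with a counted
  warning; an unphased genotype at a retained site is an error, since
  phasing is a precondition of haplotype construction.
- Reference bases outside {A, C, G, T} pass through unchanged; a variant
  whose stated reference base disagrees with the sequence is an error
  naming the position and both bases.
- Blocks shorter than the central length get one window centered on the
  block midpoint; contigs shorter than the input length are an error.
- Bernoulli-mode intercept calibration brackets the root between
  `logit(prev) - max(eta)` and `logit(prev) - min(eta)` and solves to
  1e-12; the all-equal-liability case short-circuits to the closed form
  `logit(prev) - eta`.
- Quantile bin sets have `max(1, floor(q * M))` members with ties broken
  by bin order; top and bottom sets are disjoint whenever `2|set| <= M`.
- All randomness flows from named child seeds derived from a master seed,
  so every simulation, split, carve-out and fit is reproducible from one
  integer.

## Known limitations

- The extractor contract is implemented only by the synthetic extractor;
  wrapping a pretrained model is out of scope here, though any function
  honoring the length-in / bins-by-tracks-out contract can be dropped in.
- Only SNVs are supported: no indels or structural variants, and no
  phasing — phased input is assumed.
- The per-block weighted combination uses unregularized logistic
  regression and can be unstable with many blocks and few training
  samples; concatenation is the default for that reason.
- Genotype-PCA compression at a fixed 20 components is a faithful
  implementation of an underspecified baseline, but its desk-scale
  behavior is dominated by the synthetic LD rank (see above).
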