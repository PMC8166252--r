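---
title: "Screening primate genes for episodic positive selection: models, tests and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening primate genes for episodic positive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primsel)
```

## The problem

A protein-coding gene evolving under positive selection on one lineage —
say, the human terminal branch of the primate tree — leaves a signature in
its codon alignment: an excess of nonsynonymous substitutions at a subset of
sites on that branch. `primsel` implements a complete desk-scale screen for
this signature: ortholog-set curation, codon alignment, two independent
likelihood tests for episodic selection on a marked foreground branch,
site-level detection, a two-method consensus, and a verification cascade
that interrogates candidate sites against modern-human polymorphism,
linkage disequilibrium, archaic-human genotypes and great-ape population
panels. A full synthetic-data layer generates every input the pipeline
consumes, so the whole screen can be exercised and calibrated without any
external genome resource.

## The codon substitution model

The engine is a GY94-style Markov model on the 61 sense codons of the
universal code. The instantaneous rate from codon $i$ to $j$ is zero unless
the codons differ at exactly one position, and otherwise

$$q_{ij} \propto \pi_j \cdot \kappa^{\,[\text{transition}]} \cdot
  \omega^{\,[\text{nonsynonymous}]},$$

with $\kappa$ the transition/transversion rate ratio, $\omega = d_N/d_S$,
and $\pi$ the equilibrium codon frequencies (estimated by F3x4 from the
alignment by default; F1x4 and equal frequencies are available, and a
0.5-count nucleotide pseudocount keeps $\pi$ strictly positive on sparse
alignments). `build_rate_matrix()` normalises each matrix to one expected
substitution per codon per unit time, the standard single-model convention.

**Shared time scale across site classes.** Within a mixture, classes must
share one clock: if each class's matrix were independently normalised, a
selected class with $\omega_2 = 8$ would differ from a neutral class only in
the *composition* of its substitutions, not their number — erasing most of
the signal that branch-site tests exist to detect. The engine therefore
rescales each class's branch lengths by its rate relative to the neutral
matrix, $(\text{syn} + \omega\,\text{nonsyn})/(\text{syn} + \text{nonsyn})$
(`relative_rate()`), where syn/nonsyn are the stationary synonymous and
nonsynonymous rate flows at the given $\kappa$ and $\pi$. Branch lengths are
thus expressed in neutral-equivalent substitutions per codon. The simulator
uses exactly the same convention, so model and generator are consistent by
construction.

Transition probabilities $P(t) = e^{Qt}$ come from a symmetrized
eigendecomposition (the chain is reversible); a scaling-and-squaring series
is kept as an independent cross-check, with agreement required at $10^{-10}$.
Likelihoods are computed by Felsenstein pruning over compressed site
patterns with per-node scaling, in compiled code; codons containing `N` or
gaps are missing data (all-ones partials), so an all-missing column has
log-likelihood exactly zero.

## The branch-site mixture (Model A)

Four site classes: class 0 (purifying, $\omega_0 \in [0,1]$ everywhere),
class 1 (neutral, $\omega = 1$), and classes 2a/2b, which behave like
classes 0/1 on background branches but take $\omega_2$ on the foreground
branch ($\omega_2 \ge 1$ in the alternative model, $= 1$ in the null). The
proportions derive from $(p_0, p_1)$ in the usual proportional way.
Parameters are estimated by bounded L-BFGS-B on transformed scales (logit
proportions and $\omega_0$, $\log \kappa$, $\log(\omega_2 - 1)$) with a
relative log-likelihood tolerance of $10^{-8}$, at most 500 iterations per
start, and 3 seeded starts by default in `fit_model()`.

Two numerical choices matter for speed and are worth stating:

* **Component memoization.** The Model A objective is assembled from four
  per-class pruning components cached on their parameter values. A
  finite-difference step on a mixture proportion then costs nothing, and a
  step on one $\omega$ recomputes only the classes that depend on it.
* **Foreground-path updates.** Classes 2a/2b differ from classes 0/1 only on
  the foreground branch, so their pruning passes reuse the stored partials
  of the base classes and recompute only the foreground-to-root path.

Branch lengths come from the fixed species tree. `branch_site_lrt()`
re-estimates a single rate scale (plus $\kappa$ and a one-ratio $\omega$)
under the M0 model and holds lengths fixed at that scale for the branch-site
fits; $\kappa$ is by default fixed at its M0 estimate (option
`kappa = "free"` re-estimates it inside Model A). With a fixed species-tree
topology shared by all genes, a per-gene overall rate is the quantity that
actually varies; full per-edge re-estimation is available nowhere in this
package and is a stated limitation.

## The two gene-level tests and their null distributions

The **branch-site LRT** compares the alternative ($\omega_2$ free) and null
($\omega_2 = 1$) fits: $2\Delta\ell$, clamped at zero. Because the null
pins $\omega_2$ at the boundary of the alternative's parameter space, the
asymptotic null is the 50:50 mixture of a point mass at zero and
$\chi^2_1$; this is the default reference. The plain $\chi^2_1$ is
available (`null_dist = "chisq1"`) as a deliberately conservative option.
The default was chosen because, in the package's own calibration
simulations, the mixture holds the empirical size below nominal while the
$\chi^2_1$ reference costs enough power to miss moderate episodic signals;
both choices are validated by the size simulation in the test suite.

The **aBSREL-style test** keeps the distinguishing feature of per-branch
rate variation at desk scale: each background branch carries its own single
$\omega$ (fitted in a shared stage followed by per-branch Brent refinement
passes on a mutable transition-matrix cube), while the foreground branch
carries a two-class distribution $\{\omega^- \le 1$ w.p. $1-w$, $\omega^+$
w.p. $w\}$. The null caps $\omega^+ \le 1$. The statistic is referred to an
equal mixture of $\chi^2_1$ and $\chi^2_2$ — an approximation for this
boundary-plus-nuisance situation, validated by simulation rather than
derived. Adaptive selection of the number of rate classes per branch is out
of scope.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`bh_adjust()`, delegating to `stats::p.adjust`). The consensus rule
intersects the two methods at raw $p < 0.05$ per method (q-values are
reported alongside), mirroring a screen that counts per-method candidates
before correction and then keeps the overlap.

## Site-level detection

**Bayes empirical Bayes.** Given the alternative-model MLE,
`beb_posteriors()` computes the posterior probability that each site
belongs to the positively selected classes, integrating parameter
uncertainty over a grid prior: 10 uniform points per dimension over
$(p_0, p_1', \omega_0, \omega_2)$ with equal prior mass per cell. The
$(p_0, p_1)$ simplex is covered by mapping $p_1 = (1 - p_0)\,p_1'$; the
$\omega_0$ grid spans $[0,1]$ and the $\omega_2$ grid $[1,11]$ (midpoints).
$\kappa$, $\pi$ and branch lengths stay at their estimates. Sites with
posterior $\ge 0.95$ are flagged (configurable). The implementation
factorises the grid through the per-class likelihoods (121 pruning passes
rather than $10^4$); a direct cell-by-cell summation must agree to
$10^{-10}$ and does, in the test suite.

**MEME-style per-site test.** Per site, all branches share a purifying rate
$\omega^- \le 1$ while the foreground branch draws, with probability $w$,
an unconstrained $\omega^+$; the null caps $\omega^+ \le 1$. A single
site's mixture likelihood is log-linear in $w$, so its maximum sits at a
boundary ($w \in \{0, 1\}$); the fit therefore profiles deterministically
over an $(\omega^-, \omega^+)$ grid ($\omega^-$: 7 points in $[0,1]$;
$\omega^+$: those plus 1.5, 2, 3, 5, 8, 15, 30) with spectral
decompositions computed once per gene. The null maximises over the
$\omega^+ \le 1$ sub-grid, so the statistic is nonnegative by construction.
The per-site reference is the equal mixture of $\chi^2_1$ and $\chi^2_2$,
again validated by the site-level size simulation. Invariant and all-data-
missing sites short-circuit to $p = 1$.

## Curation and alignment

* Read-through transcripts and recent human-lineage duplicates are dropped
  before anything else; the filter only removes records and logs reasons.
* One human representative isoform (the MANE transcript) anchors a greedy
  centroid clustering of all non-human isoforms at 80% protein identity
  (identity = identical positions / aligned columns of a global affine-gap
  alignment, dual-gap columns excluded; match +1, mismatch 0, gap open 2,
  extend 0.5). The human-containing cluster is kept, one isoform per
  species (ties: identity to human, then length, then lexicographic id).
  Whether the original screen's 80% threshold applied to nucleotide or
  protein identity is not derivable from its description; protein identity
  is used here and stated as unresolved. Genes with fewer than three
  species cannot support a branch-site test and are dropped.
* The species tree (27 primates by default, human `Hsap`; foreground either
  the human terminal branch, "Hominina", or the great-ape stem,
  "Hominidae") is pruned per gene with `ape`'s drop-tip machinery; the
  foreground mark is stored symbolically and re-resolved after pruning.
  Printed sources for the topology do not publish branch lengths, so the
  default tree takes a uniform per-edge length (0.05 neutral-equivalent
  substitutions per codon, a mid-depth mammalian scale chosen once) and any
  Newick with lengths can be supplied instead.
* Proteins are aligned progressively along the guide tree (BLOSUM62, gap
  open 10 / extend 0.5, profile columns scored by mean pairwise
  substitution score); the aligner's contract is determinism and optimal
  two-sequence scores, not fidelity to any external program. Codon
  alignments are produced by back-translation (each residue replaced by its
  source codon, gaps by `---`), which must round-trip every CDS exactly.
* Manual alignment curation is inherently non-reproducible; it is replaced
  by explicit, loggable column masks plus a gap-fraction auto-mask (drop
  codon columns where fewer than half the taxa have a non-gap codon).
  In-frame stop codons are rejected upstream; `N`-containing codons are
  missing data, never silently altered.

## The verification cascade

Candidate sites surviving the two-method consensus are screened against
population variation, in a fixed rule order (`classify_pss()`):

1. no recorded modern-human polymorphism → **true PSS**;
2. ancestral allele present but rare in every population (max frequency
   ≤ 0.10) and no haplo-block membership → **true PSS** (rare independent
   back-variant);
3. derived allele is the minor allele (ancestral frequency ≥ 0.50), no
   haplo-block → **minor allele** (reference-genome artifact / unfixed
   variant);
4. ancestral allele common in ≥ 1 population and/or membership in an LD
   block of candidates (any $r^2 \ge 0.5$) → **false positive**.

A site whose SNP id is recorded without frequency data is reported
UNRESOLVED, never guessed. LD ($r^2 = D^2 / p_A p_a p_B p_b$) is computed
from phased haplotype columns and only among sites of the same gene. The
source screen reports exemplar frequencies (kept back-variants at 0.02 and
0.06; a ruled-out minor allele at ancestral frequency ~0.75; ruled-out
standing variation at 0.80–0.90) but no explicit cut-offs; the defaults
0.10 / 0.50 / 0.50 / 0.5 reproduce every reported decision and are exposed
in `verification_thresholds()`. Archaic dating is separate: a true PSS
whose every non-missing archaic genotype (Vindija, Altai, Denisova) is
derived predates the archaic–modern split; any ancestral or heterozygous
archaic genotype flags a post-split candidate; missing archaic data never
blocks a true-PSS call, only its dating. Great-ape panels (111 chimpanzees,
17 bonobos, 42 gorillas, 10 orangutans) are summarised per taxon; a site
monomorphic-ancestral in every covered taxon carries the note that no
incomplete-lineage-sorting signal is present.

The packaged worked example (`table2_fixture()`, `table2_variants()`)
encodes the twelve both-method candidate codons in MAMLD1, PRDM9 and
ZNF860 with their reported SNPs, frequencies, the ZNF860 348–464–609
haplo-block and archaic states. Two of its entries deserve flags. First,
the source table's caption counts eleven sites while its body (and the
accompanying text) lists twelve; the fixture follows the body. Second, no
frequency is printed for the two rare PRDM9 back-variants at codons 629 and
657 ("rare" only); the fixture uses a synthetic 0.01, below the
rare-back-variant threshold, and says so in its documentation. The
haplotype panel for the ZNF860 block is a deterministic comonotone
construction at ancestral frequencies 0.80/0.90/0.85, which places the
block-partner correlations inside the reported 0.5–1 range.

## The synthetic-data generator

`simulate_codon_alignment()` draws each site's latent class from the
mixture, the ancestral codon from $\pi$, and evolves codons along each
branch by sampling from the exact transition matrices of the likelihood
engine — no Gillespie simulation, hence exact model/simulator consistency.
`simulate_variant_table()` draws phased haplotype panels; sites inside an
LD block mix a comonotone background (a shared uniform drives all sites)
with independent draws, at coupling $c = \sqrt{r^2_\text{target} /
r^2_\text{max}}$, which achieves the target $r^2$ in closed form and
errors when the target exceeds what the frequencies allow.
`simulate_archaic_and_ape_genotypes()` produces the archaic trio and the
180-individual ape panel. All generators are bit-reproducible under a
fixed seed.

What the generator does *not* emulate: indels and alignment error (codon
alignments are simulated gap-free), recombination within a gene,
sequencing error and coverage gaps, population structure beyond
block-level LD, and non-stationary codon frequencies. Passing calibration
on these simulations therefore demonstrates internal statistical
correctness of the tests under the model family — not robustness to the
alignment artifacts that motivate the masking and dual-method consensus
steps on real data.

## Calibration, problem sizes and known limitations

The test suite calibrates the tests at these scales (chosen as the
package's study conditions): branch-site LRT size on 200 null simulations
(27 taxa, 300 codons; empirical size must stay ≤ 0.08 at $\alpha = 0.05$),
power on 20 simulations at $\omega_2 = 8$, $p_2 = 0.15$, 500 codons
(≥ 0.5), MEME-style site-level size on 100 × 100-codon replicates run on
the 10-taxon catarrhine subtree containing the foreground, and parameter
recovery ($\kappa$ within ±20%, $\omega_2$ within ±40% of truth on
2,000-codon simulations, averaged over 10 replicates — $\omega_2$ sits on
a likelihood ridge against $p_2$, so single-replicate estimates are noisy
and the average is the meaningful quantity). Calibration harnesses run the
fitters with a single optimizer start; this is conservative for size, and
the alternative fit adds a deterministic strong-selection start so power is
not lost to the $\omega_2$/$p_2$ ridge.

Known limitations, stated plainly: no gamma rate variation or synonymous
rate variation; ambiguity codes other than `N` unsupported; branch lengths
rescaled, not re-estimated per edge; the aBSREL simplification fixes two
foreground rate classes; the MEME-style grid profile bounds $\omega^+$ at
30 (a site with a huge true $\omega^+$ still registers, at a slightly
deflated statistic); and at primate-like divergences the branch-site test
has modest power for single genes — which is precisely why the screen that
motivated this package leaned on 27 genomes, dual methods and downstream
population verification.
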