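---
title: "Methods: haplotype-block detection, sweep scanning and pedigree classification"
author: "hapblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-block detection, sweep scanning and pedigree classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapblocks)
```

# Scope and model of the data

`hapblocks` analyses panels of near-fully homozygous crop lines (inbred or
allohaploid derivatives) genotyped at biallelic SNPs, organised around a
breeding pedigree: two parents, a focal cultivar bred from their cross, and
progeny cultivars bred from the focal line and unrelated co-parents.
Because each line is effectively homozygous, one sample contributes one
haplotype per locus, and genotypes are coded haploid (0 = reference, 1 =
alternate, -1 = missing). Residual heterozygous calls are treated as
genotyping noise and recoded missing rather than phased; the per-sample
heterozygosity rate is reported so that a genuinely heterogeneous sample is
visible. All computations use pairwise-complete observations: a sample
missing at a site is dropped from that site's statistics only.

The package answers three questions about such a panel:

1. which runs of adjacent SNPs travel together as **haplotype blocks**;
2. which genomic regions show the **selective-sweep** signature of
   elevated differentiation and reduced diversity in a trait-tolerant
   group relative to a sensitive group;
3. how blocks move through the pedigree — **family-shared**,
   **parent-specific inherited**, or **recombined** into a mosaic of the
   two parental haplotypes.

# Haplotype blocks

For two biallelic sites with alternate-allele frequencies $p_A$, $p_B$ and
joint haplotype frequency $p_{AB}$ (directly countable in a haploid-coded
panel — no EM phasing is needed), the linkage-disequilibrium coefficient is
$D = p_{AB} - p_A p_B$, normalised as

$$D' = D / D_{\max}, \qquad
D_{\max} = \begin{cases}
\min\{p_A(1-p_B),\,(1-p_A)p_B\} & D \ge 0\\
\min\{p_A p_B,\,(1-p_A)(1-p_B)\} & D < 0,
\end{cases}$$

together with $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$.

Following the Gabriel-style criterion, a pair is in **strong LD** when the
one-sided confidence bounds on $|D'|$ satisfy $CU \ge 0.98$ (consistent
with no historical recombination) and $CL \ge 0.7$. The bounds come from a
fixed-margin grid likelihood (the Haploview approach, chosen over a
bootstrap because it is deterministic): allele frequencies are fixed at
their observed values, haplotype frequencies are reconstructed from each
grid value of $|D'|$ (step 0.001, observed sign of $D$), the multinomial
likelihood of the four observed haplotype counts is evaluated on the grid
and normalised to a distribution, and $CL$/$CU$ are its 5th and 95th
percentiles.

`partition_blocks()` then scans each chromosome once over *adjacent*
filtered SNPs: the current block extends across pair $(i, i+1)$ iff the
pair passes the strong-LD test (and the point estimate $|D'| \ge 0.7$,
the break rule phrased on the point estimate; it is almost always implied
by $CL \ge 0.7$); otherwise the block closes and the next begins at
$i+1$. This is the $O(S)$ procedure that the block-definition sentence
itself describes, not Haploview's exhaustive all-pairs "spine of LD"
search; on panels whose LD is genuinely block-structured with sharp
breaks the two coincide, and the adjacent-pair scan is what the
generator's ground truth validates. Single-SNP blocks are discarded: a
one-SNP "haplotype" carries no linkage information. Monomorphic sites
(undefined LD) always break a block.

**Power at small panel sizes.** The grid-likelihood bounds are
conservative when few haplotypes are observed. At $n = 20$ haplotypes a
pair in *complete* LD (no recombinant haplotypes at all) reaches
$CL \ge 0.7$ only when the two haplotype classes are reasonably balanced
— splits between 7:13 and 13:7; the maximum attainable $CL$ at 10:10 is
about 0.735. Rare haplotypes therefore cannot form detectable blocks in a
20-line panel no matter how perfect their association. This drives two
design choices below (balanced founder pools in the generator) and is a
caveat for real data: block counts from small panels under-represent
blocks carried by rare haplotypes.

# Sweep scan

Within each trait group, per-site diversity is the mean number of pairwise
allele differences between two *distinct* haplotypes,
$2 n_0 n_1 / (n(n-1))$ for $n = n_0 + n_1$ non-missing calls; the
between-group term uses all cross-group pairs,
$(n_0^R n_1^S + n_1^R n_0^S)/(n^R n^S)$. Sliding windows (default 100 kb
at 10 kb steps) sum these site contributions and divide by the window
span in bp (per-bp normalisation by physical span, not by SNP count;
windows truncated at a chromosome end keep their actual span).
Then, per window,

$$F_{ST} = \frac{\pi_{\text{Between}} - \pi_{\text{Within}}}{\pi_{\text{Between}}},
\qquad \pi_{\text{Within}} = \tfrac12(\pi_R + \pi_S),$$

and the log diversity ratio $\ln(\pi_R/\pi_S)$, where $R$ is the tolerant
and $S$ the sensitive group. The unweighted mean for
$\pi_{\text{Within}}$ is the symmetric Hudson-style reading of "two
individuals sampled from the same population". Two consequences of using
distinct-pair (unbiased) within-group estimators are deliberate: under
random relabelling of samples the expected $F_{ST}$ is 0 (the
with-replacement estimator would be biased upward by roughly $1/n$), and
two *identical* groups give a small exactly-computable negative value
($1 - n/(n-1)$), not 0 — negative $F_{ST}$ estimates are reported as
computed, never clipped. Windows with $\pi_{\text{Between}} = 0$ or an
undefined ratio are flagged `NA` and excluded from ranking.

`select_candidates()` takes the windows simultaneously in the top `tail`
fraction (default 1%) of $F_{ST}$ and in the bottom `tail` fraction of
$\ln(\pi_R/\pi_S)$ — reduced diversity in the tolerant group is the sweep
signature; the direction and an absolute-ratio alternative are exposed as
options because the "< 0.01" phrasing of the published filter is
ambiguous between a tail fraction and an absolute ratio threshold, and we
adopt the tail reading. The cutoff is the $k$-th most extreme defined
value with $k = \lceil \text{tail} \cdot n \rceil$; ties at the cutoff
are all included, so selection is monotone in `tail`. Selected windows
that overlap or are book-ended merge into candidate regions. Candidate
regions map to genes by $\ge 1$ bp overlap (configurable minimum), and
per-trait gene sets may share genes; both the duplicate-counting sum and
the union are reported.

# Pedigree classification

Blocks are detected once on the pooled panel, so per-sample haplotype
strings over a block's SNPs live on common coordinates; "shared" means
string identity, and a sample with any missing allele in the block gets a
null string that never matches. Per block, in priority order:

1. **family_shared** — all family members (parents, focal, progeny) carry
   identical strings;
2. **parentA/B_inherited** — the focal string equals exactly one parent's
   and all required progeny match the focal string;
3. **recombined** — the focal string matches neither parent but splits at
   one or more SNP boundaries into contiguous segments that alternate
   between the two parents, each matching that parent's sub-string, with
   all required progeny matching. The breakpoint search is a dynamic
   programme over split positions returning the minimal-breakpoint
   mosaic, leftmost breakpoints on ties (blocks are short, so the search
   is exact);
4. **other** — anything else, with the reason recorded (missing strings,
   progeny mismatch, no mosaic).

By default all progeny must match (`min_progeny` relaxes this), mirroring
the published accounting in which recombined blocks were required to
reach all five progeny. The accounting report divides the family-shared
count by the total block count, but the parent-specific counts by the
*family-shared* count — an unusual convention retained deliberately
because it is how the published fractions (4.22% = 1003/23 752,
14.40% = 3420/23 752, against 40.87% = 23 752/58 116) are constructed;
the denominator is an explicit argument. Percentages use half-up rounding
to two decimals and always recompute from the integer counts. The
subgenome tally maps chromosomes named `A*`/`D*` to the At/Dt subgenomes
of allotetraploid cotton by default.

# The synthetic-panel generator

`simulate_panel()` produces the panel the analysis assumes, plus full
ground truth, and is the package's validation instrument. Defaults
emulate a 20-line resequencing panel: 2 parents, 1 focal line, 5 progeny
and 12 unrelated elite lines, on 2 chromosomes (`A01`, `D01`, one per
subgenome) of 5 Mb with 25 planted blocks each.

* **Blocks.** Each planted block carries two complementary founder
  haplotypes assigned to exactly half of the 14 founder lines. Balance is
  deliberate: given the power analysis above, a 20-haplotype panel can
  only certify strong LD for splits in 7:13..13:7, so balanced pools make
  every planted block detectable *in principle* and detection failures
  attributable to the method. Complementary haplotypes keep every block
  SNP polymorphic (a monomorphic SNP would split the adjacent-pair scan).
  A consequence is that planted-block SNPs segregate at common
  frequencies (MAF 0.35-0.5), which also keeps them clear of the default
  MAF filter.
* **Background SNPs** every 10 kb in inter-block gaps segregate
  independently with founder frequencies Uniform(0.1, 0.9). They emulate
  the dense background variation of a resequencing panel (the real data
  carry a SNP roughly every 0.8 kb) and ensure every scan window is
  informative; without them most windows hold no SNPs, the defined-window
  count collapses, and the joint 1% tail becomes so small that a genuine
  sweep can be missed purely by rank-tie geometry.
* **Pedigree.** The focal line is one recombinant gamete of
  parentA x parentB per chromosome — crossover count Poisson
  (`crossover_rate`, default 1 per chromosome per meiosis), positions
  uniform — instantly fixed to homozygosity (selfing of a near-homozygous
  line is modelled as gamete duplication). Progeny are independent
  gametes of focal x one random elite co-parent. By default crossover
  positions snap to the midpoints of inter-block gaps so that every
  planted block is transmitted intact and ground-truth categories are
  unambiguous; `intra_block_crossovers = TRUE` lets crossovers fall
  inside blocks to exercise recombined-mosaic classification.
* **Sweep region.** A 100 kb interval on `A01` (block-free; its SNPs are
  its own) where tolerant-group and sensitive-group allele frequencies
  differ by `sweep_freq_delta` (default 0.8) with the tolerant group's
  expected heterozygosity reduced `sweep_pi_reduction`-fold (default 5);
  the two frequencies are solved from these two constraints
  ($p_t \approx 0.029$, $p_s \approx 0.829$ at the defaults).
  `sweep_freq_delta = 0` disables the differentiation for null
  calibration. The 5 Mb chromosome length makes the sweep about 2% of
  all windows — tail selection of a "top 1%" is only meaningful when the
  true sweep is a small fraction of the genome, which is the regime of
  the real data.
* **Determinism.** All draws derive from the single `seed`; equal seeds
  give byte-identical VCF output.

What the generator does **not** emulate: coalescent genealogies and LD
decay within blocks, mutation during the pedigree, genotyping error and
missingness (inputs may contain them; simulated panels are complete),
homoeologous exchange between subgenomes, and realistic site-frequency
spectra inside planted blocks. Tests passing on this generator therefore
show that the estimators and the detection/classification logic are
correct under the model's own assumptions, not that the thresholds are
optimal for any particular real panel.

# Numerical and interface choices

* Grid step for the $|D'|$ likelihood is 0.001; bounds are grid
  percentiles, so a point estimate may differ from a bound by at most the
  grid resolution.
* Window tiling starts at 1 bp and advances by `step`; a truncated
  terminal window is added only when the tiling does not land exactly on
  the chromosome end (a 1 Mb chromosome at 100 kb/10 kb yields 91
  windows).
* Internal coordinates are 1-based inclusive throughout (VCF/GFF
  convention); BED-style outputs convert to 0-based half-open at the
  boundary.
* Default site filters are MAF $\ge$ 0.05 and missingness $\le$ 0.2
  (the published pipeline states neither; both are arguments).
* Rounding of reported percentages is half-up to 2 decimals
  (`round_half_up()`), so printed proportions recompute exactly from
  counts.
* `run_pipeline()` writes every intermediate as TSV/BED plus a JSON
  manifest (input checksums, parameters, version, per-stage record
  counts — no timestamps, so reruns are byte-identical); failures abort
  with the stage name and leave a `.partial` marker.

# Problem sizes used in validation

The shipped test-suite and the acceptance script run the generator at its
default scale — 20 samples, 2 x 5 Mb chromosomes, 50 planted blocks,
roughly 1300 SNPs — with 100 seed replicates for sweep recovery and its
null calibration, 1000 random tables for the LD brute-force
cross-checks, 10 000 meioses for the crossover-rate calibration, and a
handful of seeds for block-boundary recovery and pedigree-classification
agreement. These sizes exercise every code path while keeping a full run
in well under a minute per component.

# Known limitations

* The adjacent-pair scan cannot bridge a single weak pair inside an
  otherwise strong block (Haploview's exhaustive search can); on sharply
  block-structured LD this does not arise.
* Strong-LD power at 20 haplotypes restricts detectable blocks to
  common haplotype splits (see above); block counts from small panels
  are underestimates.
* The recombined category requires exact string mosaics; genotyping
  error inside a block sends it to `other` rather than fuzzily matching.
* $F_{ST}$ is reported without significance testing, and no
  haplotype-based sweep statistics (XP-CLR, XP-EHH) are implemented.
* Heterozygous genotypes are never phased; panels of outbred material
  are out of scope.
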