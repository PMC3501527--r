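---
title: "Methods: tag-based digital gene expression analysis with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression analysis with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay and its model

Tag-based digital gene expression (DGE, the SAGE lineage of protocols)
represents each transcript by a single short sequence tag. The anchoring
enzyme NlaIII cuts cDNA at every `CATG`; the tagging enzyme MmeI then
cuts 17 bp downstream of the recognition site, so the observable unit is
a 21-base tag: `CATG` plus 17 downstream bases. Because the cDNA is
bead-bound at its 3' end, the fragment that is actually sequenced comes
from the **3'-most** `CATG` site that has at least 17 bases downstream —
the *canonical* tag of the transcript. Expression is measured by
counting how many times each tag is sequenced in a library.

`tagdge` implements the complete analysis around this assay:

1. **Reference construction** (`build_tag_library()`): in-silico
   digestion of a reference transcriptome. Deliberately, the reference
   holds *all* qualifying sites of every gene, not only the canonical
   one, mirroring how reference tag libraries are built in practice
   (partial digestion and internal priming make non-canonical tags
   observable). The simulator, by contrast, emits only canonical tags —
   the mismatch is intentional and mirrors the chemistry.
2. **Cleaning** (`filter_tags()`): removal of adapter-only reads, reads
   containing `N`, and tags with a library-wide copy number of 1
   (overwhelmingly sequencing errors: a 21-mer one error away from a
   true tag is almost surely unique).
3. **Mapping** (`assign_tags()`): each clean tag species is matched
   against the reference allowing at most one base mismatch. Tags
   matching reference tags of exactly one gene are *unambiguous* and are
   the only evidence used for quantification; tags matching two or more
   genes are counted in the mapped totals but contribute to no gene.
4. **Normalization** (`tpm_normalize()`): transcripts per million,
   `1e6 * count / denominator`.
5. **Differential expression** (`dge_test()`): the Audic–Claverie exact
   test between two libraries, Benjamini–Hochberg FDR, and the joint
   significance criterion FDR <= 0.001 and |log2 ratio| >= 1.
6. **Enrichment** (`enrich_terms()`): hypergeometric upper-tail test of
   term membership in the DEG set against the annotated background.

## The Audic–Claverie statistic

For a tag with `x` counts in library 1 (total `N1`) and `y` counts in
library 2 (total `N2`), the conditional probability of `y` given `x` is

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

the posterior predictive of a Poisson rate under a flat prior. It is
algebraically a negative binomial with size $x+1$ and success
probability $N_1/(N_1+N_2)$ — `tagdge` uses that identity only as an
independent cross-check in its tests; the implementation itself works in
log space with `lgamma`, so counts up to $10^6$ are handled without
overflow. Subtracting the two `lgamma` terms in canonical (max, min)
order makes the evaluation bitwise symmetric in $(x, y)$ when
$N_1 = N_2$. Note the formula itself is *not* symmetric under the full
swap $(x, N_1) \leftrightarrow (y, N_2)$ when $N_1 \neq N_2$ — swapping
multiplies it by $N_2/N_1$ — which is easy to verify with exact rational
arithmetic.

**Two-sided p-value.** The literature does not fix a two-sided
construction; `tagdge` uses the conventional doubled smaller tail,
capped at 1: $p = \min(1,\, 2\min(P(Y \le y), P(Y \ge y)))$. The lower
tail is a log-space sum over $k = 0..y$. For the upper tail the naive
complement $1 - P(Y \le y-1)$ loses all relative precision exactly when
the tail is small and interesting, so it is summed directly from
$k = y$ with the multiplicative recurrence
$t_{k+1} = t_k \cdot q\,(x+k+1)/(k+1)$, $q = r/(1+r)$, stopping when a
term falls below $10^{-16}$ of the running sum. A useful identity keeps
this cheap: the two tails overlap in the point mass at $y$ and sum to
$1 + p(y|x) > 1$, so whenever the lower tail is below $1/2$ it *is* the
smaller tail and the upper tail need not be summed at all; when the
lower tail is at least $1/2$, $y$ sits at or past the mode and the
direct upper sum terminates after $O(\sqrt{x+y})$ terms.

Genes with $x = y = 0$ carry no evidence and are excluded before
multiple-testing correction (they would only inflate the BH divisor).
The doubled-tail construction conditions on $x$, which is why the
resulting p-value is not symmetric under the library swap even at
$N_1 = N_2$; this is a property of the construction, not a defect of
the implementation.

**Log ratios with zero counts.** The reported effect size is
$\log_2(\mathrm{TPM}_2/\mathrm{TPM}_1)$ with each TPM floored at the TPM
of a single tag in its library ($10^6/N$). The floor keeps ratios
finite and order-preserving; it is configurable (`tpm_floor`).

**TPM denominator.** "Per million tags" is ambiguous between clean and
unambiguously mapped totals; the package defaults to the clean total
(`denominator_mode = "clean_total"`) and offers `"unambiguous_total"`,
under which TPM sums to exactly $10^6$.

## Hypergeometric enrichment

With `N` annotated background genes, `n` DEGs among them, `M` genes
annotated to a term and `m` DEGs annotated to it, the enrichment
p-value is the upper tail

$$P(X \ge m) = \sum_{i=m}^{\min(n,M)}
\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

summed directly in log-gamma form (again avoiding the $1-\cdot$
cancellation; impossible terms with $n-i > N-M$ vanish through
`lchoose`). `m = 0` returns exactly 1. The "corrected p-value" used for
the significance flag is Benjamini–Hochberg by default (Bonferroni by
flag); the pathway-style q-value column is always BH. Terms annotating
fewer than `min_term_size = 2` genes are skipped as degenerate. No GO
graph propagation is performed: term assignments are tested flat, as
consumed.

## One-mismatch mapping

Each 21-mer has exactly 63 Hamming-distance-1 neighbors. Mapping
enumerates them (in chunks, to bound memory) and looks both the tag and
its neighbors up in a hash of the reference; the contract — verified
against an all-pairs brute-force Hamming oracle in the tests — is:
exact match preempts the mismatch search (a tag matching gene A exactly
and gene B at distance 1 is unambiguous for A; parsimony favors the
better match, and `exact_preempts = FALSE` pools both if desired);
otherwise all reference tags at distance exactly 1 are matched; gene
status is decided solely by the number of distinct genes among the
matched reference tags.

## Coordinates and conventions

Site positions are 1-based positions of the `C` of `CATG`, the
R/Bioconductor convention; a site qualifies iff `pos + 20 <= length`,
and the tag is `substring(seq, pos, pos + 20)`. The reference excludes
tags containing `N` (clean tags are N-free, so such reference entries
could never be matched). `strand_mode = "sense_only"` is the default —
assembled unigenes have a determined sense — with `"both"` available
because assembly orientation is imperfect in practice.

## The synthetic-data generator

Every stage is validated against simulated data with known truth, so no
sequencing download is required. The generator emulates:

* **Transcriptome** (`sim_transcriptome()`): log-normal transcript
  lengths (default meanlog `log(400)`, sdlog 0.45, floor 60 bp —
  matching the few-hundred-bp unigenes typical of de novo insect
  assemblies), GC fraction 0.42, and a configurable fraction (default
  5%) of *untaggable* genes carrying no qualifying `CATG` site, as real
  transcriptomes do. Taggable genes are guaranteed at least one site (a
  `CATG` is planted when the random sequence lacks one); untaggable
  genes have every qualifying site broken by iterated point mutation.
* **Expression truth** (`sim_expression()`): log-normal relative
  abundances (sdlog 1.5, giving the strong heterogeneity/redundancy
  structure tag libraries show: a few tags carry most of the reads), a
  configurable DE fraction (default 5%) with known log2 fold changes
  (default ±2) applied to library 2 before renormalization.
* **Libraries** (`sim_library()`): multinomial sampling of canonical
  tags at library sizes in the $10^5$–$10^6$ range (defaults scaled to
  desk size, $2 \times 10^5$), iid per-base substitution errors
  (default 0.5%), plus the three contaminant classes the filter removes:
  adapter-only sentinel reads (1%), reads with an `N` (0.5%), and unique
  random 21-mers arriving as singletons (0.5%). The four classes sum to
  the library size exactly, read for read. Untaggable genes with
  assigned abundance are zeroed with a warning and the mass
  redistributed — such transcripts produce no tag in the real protocol.
  Substitution errors are sampled exactly (a binomial draw of the number
  of mutated bases, then uniform positions), not per-read
  approximations; there are no indels, since tags have fixed length.
* **Annotations** (`sim_annotations()`): Bernoulli gene–term membership
  at a background rate (5%) with one planted term annotating a target
  set at an enriched rate (80%), giving the enrichment test a known
  positive.

What the simulator does *not* model: 49-bp raw reads with adapter
context and quality strings, PCR amplification bias, partial digestion,
SNPs destroying `CATG` sites, or biological replicates (the classic
design this package targets has one library per condition — which is
also why no replicate-aware dispersion model, such as a negative
binomial, is fitted). Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under multinomial sampling, not
robustness to those real-data artifacts.

## Numerical and design choices

* **Cleaning order**: adapter-only reads first, then N-containing
  reads, then copy-number-1 tags computed on the *remaining* counts.
  The published protocols do not state the order; fixing it makes the
  conservation identity `clean = raw - adapter - N - singletons` exact
  and testable on every input.
* **Percentages** in report tables are rounded half-up to 2 decimals
  (the convention of published summary tables); multi-library averages
  are means of the per-library values, counts rounded half-up to
  integers and percentage rows averaged over the already-rounded
  per-library percentages — the convention that reproduces published
  tables of this kind exactly. A zero denominator reports 0.
* **Copy-number bins** default to `[2,5] [6,10] [11,20] [21,50]
  [51,100] [>=101]`, the customary view of tag-library redundancy;
  bins are configurable as a strictly increasing break vector, which
  makes overlap impossible by construction.
* **Seeds**: every generator takes an explicit seed and restores the
  caller's RNG state; `simulate_dge_experiment()` derives per-stage
  sub-seeds from one master seed, so whole experiments are reproducible
  to the byte.
* **Problem sizes in the tests**: oracle equivalence is checked at
  1,000 tags × 1,000 references (mapping) and 500 sequences
  (digestion); calibration at 5,000 genes × $10^5$ tags over 20 seeds;
  recovery at 20,000 genes × $10^6$ tags — sizes chosen so the whole
  suite runs in well under a minute per property while keeping the
  statistical assertions sharp.

## Known limitations

* Single-library-per-condition design: no dispersion estimation, so
  biological variability is attributed to sampling noise — the known
  limitation of the Audic–Claverie framework.
* Ambiguous tags are discarded rather than probabilistically rescued;
  genes whose canonical tag is shared with another gene are
  systematically under-quantified.
* The one-mismatch neighborhood is exact but fixed; no two-mismatch
  rescue.
* Enrichment treats terms independently; correlated terms inflate the
  BH-corrected significant set as they do in any flat enrichment test.
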