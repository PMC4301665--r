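---
title: "Methods: ortholog pairing and transcriptome divergence in orthodiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog pairing and transcriptome divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`orthodiverge` implements a comparative transcriptome-divergence analysis
between two species for which only transcript sets (one possibly a draft
454-style assembly) are available: ortholog identification by reciprocal
best hit (RBH) with a translated rescue pass, ORF-based partitioning of
transcripts into 5'UTR / CDS / 3'UTR, codon-aware pairwise alignment,
per-site classification by codon degeneracy and CpG context,
region-by-context divergence statistics, and Ka/Ks estimation with
positive-selection binning and sliding-window scans. A codon-level
simulator with recorded truth makes the whole pipeline testable without
any external data.

# Orthology model

Orthologs are defined operationally as reciprocal best hits between the two
transcript sets. Hits come from a self-contained seeded local aligner
rather than an external BLAST installation: a candidate query/subject pair
must share at least two exact 11-mers (nucleotide level) or two amino-acid
4-mers within a reading-frame pair (translated level, all 6 x 6 frame
combinations considered, best reported, at most the four seed-richest frame
pairs aligned). Candidates are scored by Smith-Waterman local alignment
(match 2 / mismatch -3, gap open 5 / extend 2; BLOSUM62 with gap open 10 /
extend 0.5 for proteins) and retained when the Karlin-Altschul E-value
against the subject set is at most `1e-10` — the conventional BLASTn cutoff
for cross-species transcript matching. The E-value uses standard ungapped
parameters (nucleotide: lambda 0.625, K 0.41; BLOSUM62: lambda 0.267,
K 0.041); these are approximations for our slightly different gap
penalties, which is acceptable because the cutoff separates scores
differing by hundreds of bits in practice.

Three filters mirror the analysis this package operationalizes:

* **50% continuous-region rule** — a hit survives only if its aligned
  continuous region covers at least half of the query, applied on the
  query side of each search direction.
* **250-bp translation cutoff** — queries with no nucleotide-level hit are
  re-searched at the translated level only if they are at least 250 bp;
  shorter ones are tallied as "too short".
* **150-bp pair rule** — pairs whose gap-free CDS alignment is shorter than
  150 bp are excluded from Ka/Ks estimation.

A pair is `one_to_one` only when neither member is the best hit of any
third transcript; otherwise it is flagged `many` (paralog-involved). The
per-query inventory (`one_to_one`, `many`, `species_specific`,
`too_short`) always partitions the query set exactly, so record counts can
be audited the way assembly papers account for their unigene totals. With
exactly two species and pairwise data, speciation-node detection by
gene-tree species overlap reduces to RBH, which is why no tree machinery
is included; this is an approximation for histories with differential
paralog loss.

# Transcript partitioning

CDSs are taken from the longest ATG-to-stop ORF across both strands (ties:
plus strand, then leftmost), with 3'-incomplete ORFs accepted and clipped
to the last full codon — 454-style transcripts are often truncated.
Minus-strand calls trigger reverse complementation so stored coordinates
are always forward. The default minimum ORF length is 150 nt, matching the
pair rule above. The partition is deterministic given the ORF call; no
attempt is made to recover UTRs by homology. Supplied CDS coordinates (TSV
`id, cds_start, cds_end, strand`, 0-based half-open) override prediction.

# Site classification

CDS pairs are aligned through their proteins (global BLOSUM62 alignment,
back-mapped to nucleotides) so gaps fall in codon-sized blocks at codon
boundaries; UTRs are aligned directly as nucleotides. All gap columns are
then removed — the trimAL-style convention — leaving columns that are
comparable unless either base is `N`.

* **Degeneracy.** A column is *fourfold* iff it is a third codon position,
  the first two codon positions agree between the species, and all four
  third-position variants encode the same amino acid. It is *nd*
  (non-degenerate) iff in both codon contexts every non-stop
  single-nucleotide change alters the amino acid (changes to stops are
  excluded from consideration, the PAML convention). Everything else is
  *other*, including columns whose two codon contexts disagree — this
  makes nd + fourfold + other sum exactly to the comparable CDS columns
  rather than double-counting ambiguous sites.
* **CpG context.** No ancestor is available, so a column is in CpG context
  iff in *either* extant sequence the base participates in a CG
  dinucleotide, evaluated on the original ungapped neighbours. The union
  rule keeps the flag symmetric between species; a stricter
  "both-sequences" mode is available as a switch (`classify_cpg(mode =
  "both")`).

# Divergence statistics

For each region (5'UTR, CDS, nd, 4d, 3'UTR) and context (ALL, non-CpG,
CpG), the table reports percent difference, compared kb, transition and
transversion counts and their ratio, and pooled GC / CpG content.
Two averaging modes exist because summary tables of this kind are
ambiguous about them: `per_pair` (default) takes the unweighted mean of
per-pair percentages with the standard error of that mean across pairs —
which reproduces the characteristic non-additivity of an ALL row relative
to its CpG / non-CpG rows — while `pooled` divides summed differences by
summed compared sites and satisfies ALL = CpG + non-CpG exactly. Pairs
contributing zero comparable columns to a cell are excluded from that
cell, not imputed as zero. The dispersion column is explicitly the
standard error of the mean across pairs, not a standard deviation.

# Ka/Ks estimation

Two estimators are always emitted so they can cross-check each other:

* **NG86** — per-position synonymous-site fractions (synonymous non-stop
  neighbours over non-stop neighbours), site counts averaged over the two
  sequences, differences averaged over all minimal mutational pathways
  between each codon pair with stop-crossing pathways discarded, and
  Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`. When every pathway
  crosses a stop the differences are counted with stops allowed and the
  pair is flagged (`stop_fallback`) rather than left undefined. This
  estimator doubles as the in-house oracle baseline: the test suite checks
  it exactly against an independent exhaustive-enumeration implementation.
* **YN** — a Yang-Nielsen-style approximate method, written for this
  package rather than ported: kappa is estimated from fourfold-degenerate
  and non-degenerate columns via K80 correction (weighted by their site
  counts), synonymous/nonsynonymous site counts weight each possible
  change by kappa and the F3x4 position-specific base composition, and the
  synonymous and nonsynonymous proportions are corrected with the
  two-parameter K80 formula using their observed transition/transversion
  split. When kappa cannot be estimated (no informative columns, or
  saturation makes the K80 logs undefined) the method falls back to NG86
  with an `ng86_fallback` flag and a warning.

Saturation (p >= 3/4, or K80 logs undefined) leaves the affected component
`NA` with a `saturated` flag. `omega = Ka/Ks` is reported as `Inf` with a
`ks_zero` flag when `Ks = 0 < Ka`; binning counts such pairs separately
and never coerces them into the finite bins. Bin edges are right-closed:
`>2`, `(1,2]`, `(0.5,1]`, `<=0.5`.

The Fisher exact test uses the 2x2 table `[[round(Sd), round(S-Sd)],
[round(Nd), round(N-Nd)]]` with half-up rounding (`floor(x + 0.5)`),
two-sided — the convention of the widely used Ka/Ks calculators whose
p-values this field reports.

Sliding-window scans default to 57-bp windows advanced in 6-bp steps (both
multiples of 3, so windows stay codon-aligned) positioned on the
gap-column-removed alignment, 0-based half-open; a 300-bp alignment
therefore yields exactly 41 windows. Windows with omega > 1 are flagged as
candidate positively selected loci. Alignments shorter than one window
produce a single whole-alignment window with a warning.

# The simulator

`simulate_ortholog_pairs()` draws an ancestral transcript per pair — i.i.d.
UTRs and a CDS of stop-free codons at the configured base frequencies,
with a fixed ATG start and stop codon — and evolves two descendant
lineages independently. Each lineage receives `Poisson(t/2 * L)` proposed
point mutations (`t` is the expected neutral substitutions per site summed
over both branches); a proposal picks a site and target base with
probability proportional to rate, transitions weighted `kappa` and
CpG-context transitions further multiplied by `cpg_mult`, with CpG context
evaluated on the current sequence state (hypermutability is
context-dependent, not ancestral). Stop-creating CDS changes are rejected.

Selection is acceptance thinning: nonsynonymous proposals are accepted
with probability `min(1, omega)` and synonymous proposals with
`min(1, 1/omega)`. For `omega <= 1` this is plain nonsynonymous thinning;
the synonymous side of the rule extends the same mechanism to `omega > 1`
(adaptive regimes), since relative acceptance is what fixes realized
dN/dS at `omega` on both sides of 1. A consequence worth noting: realized
Ks is `t * min(1, 1/omega)`, so simulations targeting a given Ks at
`omega > 1` scale `t` by `max(1, omega)`. The start and stop codons are
frozen so the reading frame remains recoverable by the annotator.

Defaults describe a plausible insect-transcriptome comparison at the
divergence scale this pipeline targets: 200-codon CDSs with 100/150-bp
UTRs (~850-bp transcripts), `kappa = 2`, `omega = 0.2` (purifying),
`t = 0.1` (Ks near 0.1), slightly AT-rich base composition
(A = T = 0.3), `cpg_mult = 1` unless CpG effects are under study. Decoys
are unrelated random transcripts; paralogs duplicate existing genes with
one extra round of divergence.

What the simulator does *not* emulate: indels (UTR alignment gaps arise
only between genuinely diverged random flanks), rate heterogeneity across
sites and genes, codon-usage selection, assembly artifacts (chimeras,
fragmentation), and sequencing error. Passing tests therefore demonstrate
correctness of the estimators and bookkeeping under the stated model, not
robustness to misassembly or annotation error in real data. Truth
bookkeeping records every accepted substitution; because multiple hits
can collapse, observed differences are at most the recorded event counts,
and this inequality is what the round-trip audit tests check. Estimator
caveat: when two synonymous events land in one codon, pathway averaging
can attribute fractional nonsynonymous steps, so Ka estimates on
synonymous-only histories are near zero rather than exactly zero.

# Numerical and testing choices

Test and validation problem sizes were chosen to give stable statistics at
interactive runtimes: oracle equivalence on 1,000 random alignments of up
to 30 codons; omega recovery on 200 pairs per regime at 500 codons
(medians within 20% of truth; the YN estimator is the one this check
targets, since NG86 carries the known downward omega bias when kappa > 1);
ts/tv recovery on 25-30 pairs of 800-bp UTRs at `t = 0.04`, where the
`kappa = 2`, equal-frequency expectation for the ts/tv *count* ratio is
`kappa/2 = 1` (one transition target versus two transversion targets per
site); window localization on 100 single-pair replicates with five
nonsynonymous changes implanted in a 57-bp window on a synonymous-only
background, judged successful when the maximum-omega window overlaps the
implant extended by one step. All randomness flows from explicit seeds;
identical seeds reproduce FASTA outputs byte for byte.

# Known limitations

* RBH is blind to differential paralog loss and reports such cases only
  through the `many` flag.
* The YN implementation is an approximate-method family member, not a
  numerical clone of any particular released calculator; its estimates
  agree with NG86 in the kappa = 1 limit and recover simulated parameters,
  but third-decimal agreement with specific software versions is out of
  scope.
* Karlin-Altschul parameters are ungapped approximations.
* UTR divergence is reported uncorrected (observed percent difference),
  so UTR rows are not distance estimates.
* The annotator picks a single ORF per transcript; polycistronic or
  chimeric transcripts are mis-partitioned by construction.
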