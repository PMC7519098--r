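---
title: "Methods and design of plastcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

`plastcomp` implements the standard comparative workflow for chloroplast
genomes as a set of small, testable operations plus a synthetic-data module
that generates every input with known truth. This vignette documents the
models behind each stage, the tunable parameters and their defaults, the
numerical conventions, and the design choices made where the problem was
genuinely open.

## Coordinates and containers

All internal coordinates are 0-based half-open, and positions on a genome
are interpreted modulo its length (plastomes are circles). Human-readable
reports (BED, TSV) follow each format's own convention. Sequences are plain
upper-case strings over `{A,C,G,T,N}`; Biostrings handles FASTA/FASTQ I/O
and supplies the plastid/bacterial genetic code (translation table 11),
rtracklayer/GenomicRanges handle GFF3.

## Quadripartite structure

The inverted-repeat pair is defined as the maximal-length pair of disjoint
circular intervals whose sequences are reverse complements up to
`max_mismatch` substitutions. Detection is exact seed-and-extend: k-mers
shared between the doubled forward strand and the doubled reverse
complement are chained along diagonals, which yields every maximal exact
match of length at least k (the absence of a neighbouring anchor on a
diagonal implies a mismatching character, so chained runs cannot be
extended). With `max_mismatch > 0`, exact runs on a diagonal are greedily
merged while the bridged characters stay within budget. Plastid IR copies
are near-perfect, so the default is `max_mismatch = 0` and the default
`min_ir_len = 1000` is far above the longest inverted match expected in
random sequence (about `log4(n^2)` bp).

LSC is the longer single-copy arc; IRa is the IR copy immediately
downstream of the LSC, so the circle reads LSC, IRa, SSC, IRb. Input FASTA
may start anywhere on the circle; `rotate_to_lsc()` canonicalises. If the
two single-copy arcs tie in length, the arc following the
lexicographically first IR interval is called LSC — a documented
tie-break that cannot occur on realistic plastomes.

Junction genes are those whose exon span strictly contains a region
boundary; features may wrap the origin (recorded with `end` beyond the
genome length). GC content by annotation class resolves overlaps with the
priority exon > intron > UTR > intergenic. Plastome annotations do not
delimit UTRs, so the UTR class is operationalised as a fixed window of
`utr_len` bp (default 50) flanking each gene span, exposed as a parameter
rather than hard-coded.

## Repeat censuses

`scan_ssrs()` reports maximal perfect tandem repeats of 1–6 bp motifs with
the conventional plastome thresholds (10, 5, 4, 3, 3, 3 copies for mono-
through hexanucleotides). The reported locus covers whole units only
(`end - start = unit x count`); a motif that is a self-repetition of a
shorter motif is reported once at the smallest unit. Overlapping candidates
of different unit sizes are resolved in favour of the smaller unit, then
the longer run, then the leftmost start — a deterministic rule mirrored by
the brute-force oracle in the tests. Loci separated by at most
`compound_gap` bp (default 100) are additionally grouped as compound, and
the census summary reports both the per-locus total and the
compound-grouped total, since published totals do not always state which
tally they use.

`find_maximal_repeats()` reports exact repeat pairs of length at least
`min_len` (default 18) for four relations: direct copy, reversed copy
(inverted), complemented copy, and reverse-complemented copy
(palindromic). Maximality is two-sided. Pairs are canonicalised with
`pos1 <= pos2`; a location equal to its own image under the relation (for
example a poly-A run under reversal) is reported once with `pos1 == pos2`.
The trivial whole-sequence self identity is excluded. Only exact repeats
are scanned — published census parameters state a minimum length but no
mismatch tolerance, and the exact dialect keeps the oracle equivalence
testable. On a plastome the IR pair itself surfaces as the longest
palindromic hit; passing the partition flags pairs whose copies both lie
inside the IRs, since the duplicated IR doubles many hits.

## Pairwise divergence

The divergence module consumes an existing pairwise alignment (production
of the alignment is delegated to an external aligner such as MAFFT; the
module's contract starts at aligned FASTA so truth alignments can be
injected). Every column with two differing unambiguous bases is one SNP;
every maximal single-row gap run is one indel event. Two windowed views
follow the conventions of the tools they emulate: sliding divergence
(default 600 bp window, 200 bp step) excludes gapped columns from both
numerator and denominator (DnaSP-like), while low-identity regions count
gaps as mismatches and charge query insertions to the following reference
position (mVISTA-like), merging consecutive windows below the 50% identity
threshold. Windows with zero compared sites are flagged undefined rather
than reported as zero. Because the IR duplicates every variant it contains,
`call_snps_indels()` optionally reports a second tally with IRb masked.

## Codon usage

Statistics are computed from complete in-frame CDS longer than 300 nt
(terminal stop removed). RSCU divides a codon's count by its family mean;
families with zero counts are omitted with a warning. CAI uses
relative-adaptiveness weights `w = RSCU / max RSCU in family` from a
reference set; reference codons with zero count receive a 0.5 pseudo-count.
No reference set is canonical for plastomes, so the default reference is
the pooled counts of the photosynthesis-gene class (genes are classed
photo / genet / other by an editable name-prefix map), consistent with how
plastome codon studies contrast those classes. ENC follows Wright: family
homozygosity `F = (n sum p^2 - 1)/(n - 1)` over families with n >= 2,
averaged within degeneracy classes, `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`
clamped to [20, 61]; a missing 3-fold class (no isoleucine observed) is
interpolated as the mean of the 2- and 4-fold class averages, the usual
codonW behaviour, while a missing 2-, 4- or 6-fold class leaves ENC
undefined. The neutrality view regresses GC12 on GC3 by ordinary least
squares; degenerate inputs (zero variance) are returned flagged instead of
fitted.

## Ka/Ks

`ng86_pairwise()` implements Nei–Gojobori counting. Synonymous site
fractions classify the three possible changes at each codon position;
changes creating stop codons are excluded and the position renormalised, so
every counted codon contributes exactly 3 sites and `S + N = 3 x codons`
holds identically. Multi-hit codons average synonymous/nonsynonymous steps
with equal weight over all minimal mutational pathways, excluding pathways
through stops (if every pathway is blocked, all are used — a documented
fallback for a vanishingly rare case). Proportions are Jukes–Cantor
corrected; `p >= 3/4` leaves the distance undefined and the result flagged
rather than fabricated. Note that a single codon with one synonymous
difference already yields `pS = 3`, so meaningful distances require genes,
not codons. Mid-alignment stop codons (plastid pseudogenes) skip the codon
with a warning. The genome summary reports uncorrected pN/pS alongside the
corrected values for comparability across correction choices, the mean over
defined ratios, and a per-gene reason for every excluded ratio (`Ks = 0`
being the common one).

## RNA editing

Input is per-replicate site evidence (VCF-derived or simulated): position,
alleles, quality, depth and DP4 strand counts. The hard filters are
quality >= 20 and depth strictly greater than 10 — the strict reading of
the conventional "depth > 10" filter, exposed as `strict_depth` because the
notation is ambiguous in the literature. Only C→T (forward) and G→A
(reverse) single-nucleotide changes encode C-to-U in transcript
orientation. A site becomes a call when it passes the filters in at least
2 of the replicates. Efficiency is edited reads over total reads from DP4;
across replicates the primary aggregate is the unweighted mean of
per-replicate efficiencies (how per-site values are usually plotted), with
the depth-weighted pooled ratio also reported since the averaging
convention is rarely stated. No multiple-testing correction is applied —
the procedure is hard filtering, not hypothesis testing. Codon effects are
annotated strand-aware (an edit in a minus-strand gene is a genomic G→A),
including recognition of ACG→ATG start repair, synonymy, and a
polar-to-nonpolar change flag.

## Structural haplotypes

The two forms differ only in SSC orientation. A subtle consequence drives
the classifier design: each IR–SSC junction of one form is locally the
reverse complement of the other form's opposite junction, and on the minus
strand of form B the arrangement IRa + SSC + IRb appears intact. Spanning
an IR–SSC junction alone therefore never distinguishes the forms — only
the relative orientation of LSC and SSC does. Classification consequently
requires both (i) a single contiguous diagonal match spanning an
informative junction (IRa/SSC or SSC/IRb) with `min_flank` context on each
side and (ii) a matched-base score margin of at least `min_margin` over
the rival form, which is only achievable when the read also reaches into
the LSC across a full IR copy. This is why real-data workflows restrict to
reads longer than 30 kb when the IR is ~26 kb; `min_read_len` defaults to
30000 accordingly and is scaled down alongside the synthetic genomes in
tests. Matching is exact k-mer anchoring (default k = 16) chained per
diagonal on the doubled reference, so reads may cross the circular origin;
substitution errors fragment but do not displace the diagonal, and at 10%
error the expected gap to the next clean 16-mer is a few bases, which the
flank requirement absorbs.

The circular-LSC screen builds the diagnostic query LSC-end + LSC-start.
A read qualifies only when one diagonal spans the end-to-start junction
with flanking context: reads matching a single part lack the span, and
reads covering the normal LSC place the two parts on diagonals separated
by the LSC interior, so they are excluded structurally.

## Indel cladistics

An indel event is a maximal gap block with identical boundary columns
across its carriers; overlapping blocks with different extents are distinct
events — the conservative identity that matches how discrete shared indels
are counted, with ragged-boundary merging deliberately not performed.
Polarity is read against an outgroup when provided (gap where the outgroup
has bases = deletion; bases where the outgroup has a gap = insertion), else
against the majority state; events the outgroup covers only partially are
left unpolarised and dropped. Group specificity is strict: the carrier set
must equal exactly one group's full membership. The same strictness applies
to group-specific SNPs (derived state carried by exactly one full group).
A terminal-conservation report (mean pairwise identity over the first 605
and last 100 columns by default) echoes the primer-design rationale for
such marker genes.

## Synthetic data: what it emulates and what it does not

The generator builds the circle LSC + IRa + SSC + revcomp(IRa) from i.i.d.
nucleotides at a specified GC (default 0.37, the typical plastome value) —
the simplest null that exercises every scanner — then plants SSRs, repeat
pairs, annotation (including a gene spanning the IRb/LSC junction, the
rps19-style case) and adjusts the two single-base IR flanks so the planted
IR pair is exactly maximal, making region-size recovery a construction
property rather than a sampling one. Divergence simulation applies a
specified number of substitutions and indel events and returns the implied
true alignment; by default substitutions drawn in IRa are mirrored into
IRb, preserving the quadripartite invariant, with the mirrored hit counted
against the same substitution budget (an `independent` policy exists for
stress-testing near-exact IR detection; indel events are applied at their
stated positions and never mirrored). Long-read simulation draws circularly
wrapped substrings from a mixture of the two forms on random strands with
i.i.d. substitution errors only — indel-free errors keep the truth
alignment trivial while still stressing the classifiers — and can
constrain reads to the haplotype-informative LSC–IR–SSC span. Pileup
simulation draws per-site depth from a Poisson and edited reads from
Binomial(depth, efficiency), split binomially across strands, emitting
evidence rows only when at least one alternate read exists, as a variant
caller would.

None of this emulates real ONT error profiles, coverage biases, chimeric
reads, mapping ambiguity, or RNA-seq read-level artefacts. Passing tests
therefore demonstrate the correctness of the computations under their
stated models, not robustness to every artefact of real instruments; the
module boundaries (aligned FASTA in, VCF-style evidence in) are where real
data, produced by external aligners and callers, plugs in.

## Problem sizes and determinism

The test and acceptance workloads use reduced-scale plastomes chosen to
exercise every code path comfortably within a default test run: a
1/10-scale genome (LSC 8800, IR 2600, SSC 1800 bp) for the end-to-end
quantities, 100 plastomes spanning IR lengths 100 bp–5 kb for partition
recovery, 50 random 2 kb sequences for the census-oracle equivalences,
all 1830 sense-codon pairs for the Ka/Ks pathway oracle, 46 editing sites
at planted efficiencies spanning 0.28–0.98 (mean 0.63) at depth 100 with
4 replicates, and 200 junction-spanning reads at an equimolar mixture with
and without 10% substitution error. The editing efficiencies are a fixed
evenly spaced grid rather than random draws so the planted mean is exact.
Every stochastic step takes an explicit seed, generators restore the
caller's RNG state, and identical seeds give byte-identical outputs
(tabular outputs are sorted and printed at fixed precision).

## Known limitations

- Repeat and SSR scans are linear in the presented sequence; features
  spanning the circular origin are only found after canonical rotation.
- Mismatch-tolerant IR extension is greedy and is a convenience for
  slightly decayed IRs, not an optimal alignment.
- NG86 is the only Ka/Ks model implemented; likelihood models and
  site-model selection tests are out of scope.
- The read classifier assumes substitution-dominated errors; true indel
  noise shifts diagonals and would require gapped chaining.
- CAI class means depend on the gene-class map, which is a configurable
  convention, not an inference.
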