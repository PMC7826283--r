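---
title: "m5Cmap: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m5Cmap: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

NSUN6 is a cytosine-5 RNA methyltransferase that deposits 5-methylcytidine
(m5C) on mRNA at a strict consensus element: the methylated cytosine is the
first base of a CTC[CT]A motif, the element sits predominantly in 3'UTRs,
and the target cytosine lies in the loop of a stem-loop structure close to
translation termination sites. m5Cmap implements the computational pipeline
needed to map and interpret such sites from three complementary assay
types — miCLIP (crosslink-truncation sequencing of a trapped enzyme-RNA
intermediate), RNA bisulfite sequencing, and ribosome profiling paired with
RNA-seq — and ships a synthetic-data generator with planted ground truth so
that every stage can be validated end to end at desk scale.

Every internal coordinate in the package is 0-based half-open. GTF input
and output is 1-based closed on disk; BED/bedGraph are 0-based half-open.
This single convention is load-bearing: the methods here are sensitive to
single-nucleotide offsets (truncation-site assignment, P-site registers,
profile steps), and the conversion helpers are property-tested as exact
inverse bijections.

# miCLIP truncation-site calling

Reverse transcription stops at the crosslinked cytosine, so a read's 5'
end sits immediately 3' of the methylated base. The pipeline:

1. **Demultiplex and deduplicate.** Reads carry a 10-nt header: positions
   1–3 and 8–10 are a 6-nt random barcode, positions 4–7 the sample
   barcode. Within a sample, reads with identical (random barcode, insert)
   are PCR products and collapse to one; the cDNA count of a unique insert
   is the number of distinct random barcodes seen for it.
2. **Align.** Unique inserts are aligned by seed-and-verify (two 17-mer
   seeds, so one mismatch cannot hide an alignment) with at most one
   mismatch and a unique best hit required; multi-mapped inserts are
   discarded. This mirrors `-m1 -v1 --best --strata`-style unique mapping
   at transcriptome scale.
3. **Assign truncations.** The truncation position is the base immediately
   5' of the insert's first aligned base. The cDNA count goes to the
   closest strand-matched C within ±2 nt, searching distance 0, 1, 2 and
   preferring the upstream C on ties. The tie rule is a package decision —
   the ±2 nt window convention does not define one — chosen to be
   deterministic and biased toward the side where the crosslink chemistry
   acts; it is configurable and logged.
4. **Normalize and filter.** Counts become RPM (per million uniquely
   mapped, post-deduplication cDNAs; whether the library size is pre- or
   post-dedup was an open convention — we use post-dedup, the quantity the
   dedup step is designed to produce). High-confidence sites need RPM
   strictly above 50 in at least two of three replicates.

Count conservation (assigned + discarded = input) is asserted at every
filter, and every reported site's reference base is checked to be a C on
its strand.

# Bisulfite quantification

Alignment happens in three-letter space: both read and reference have C
collapsed to T, which makes alignment invariant to conversion status. Up
to two collapsed-space mismatches are allowed; reads failing the first
pass are retried after removing a potential tRNA CCA tail (three 3'
bases, minimum 18 nt retained). tRNA references are built from first gene
copies only (the `-1` suffix in GtRNAdb names), introns spliced out, CCA
appended and two N flanking bases added; multi-mapping tRNA reads keep one
alignment chosen uniformly at random among those with fewest mismatches.

Two read-level filters implement the method's actual computation:

* **Conversion-resistant artifacts**: a read whose methylated fraction
  over the reference cytosines it covers exceeds 1/3 (strictly) is
  discarded. The denominator is cytosines *covered* by the read — the
  alternative (cytosines called) was an open reading; covered is the
  conservative choice and is documented here.
* **Methylation extraction**: at each covered reference C, read C counts
  as methylated, read T as unmethylated, anything else as a mismatch (not
  evidence).

Site-level quantification around a site list: sites within ±2 nt of a
motif's methylated C are shifted onto it (the "next to a motif" distance
is unstated in the underlying method; ±2 matches the miCLIP assignment
window) and duplicates removed; motif and non-motif sites are profiled
separately. For each cytosine within ±10 nt, per-site counts with more
than 5 reads are rescaled to 5 total, *preserving the methylated fraction
exactly*: the cap is a weight, not a resampling. The capped methylated
count is carried both as a double and as an exact integer
numerator/denominator pair (`cap * n_meth`, `total`), so the identity
capped fraction = raw fraction is provable in exact rational arithmetic
and is asserted as such in the tests. The aggregated level per offset is
`sum(capped_meth) / sum(capped_total)`.

# Ribosome profiling

Footprints of length 27–29 show the strongest triplet periodicity and are
the only lengths analyzed. Reads must overlap the coding span by at least
50% of their length and have the expected 5'-end frame for their length
(learned as the modal frame, or fixed). One deliberate convention departs
from a literal reading of the upstream method: **the coding span for the
overlap filter includes the annotated stop codon**. With a stop-exclusive
CDS, a footprint holding the stop codon in its P-site overlaps only 12 of
27 nt and would always be filtered out — yet such post-termination
footprints are precisely what the stop-codon-at-P-site analyses measure.
Including the stop codon (termination is part of translation) makes the
analysis chain self-consistent; the flag (`include_stop_codon`) is
exposed.

The codon register reads the P-site offset of 12 as 0-based: read
positions 1–27 (1-based) split into nine codons at positions −5..+3 with
0 the A-site, so codon 5 (read positions 13–15) is the P-site and codon 6
(16–18) the A-site. The underlying description mixes "offset of 12" with
"positions 12–14", which differ by one base under a 1-based reading; the
0-based resolution makes the two statements agree and is configurable.

Codon profiles store raw counts (64 × 9), per-position fractions, and
normalized counts (fraction over the per-codon mean fraction across the
nine positions); both normalization identities are asserted exactly.
Enrichment between conditions is the log2 ratio of normalized counts
after adding a pseudocount of 0.5 to raw counts (avoids division by zero
for rare codons; standard practice; configurable). P-site coverage tracks
place one unit at 5' end + 12 per read, strands separate, bin size 1.

# Occupancy classification around sites

Coverage matrices take the track slice ±1500 nt around each site in the
site's 5'→3' orientation, missing data as zero. Classification follows
the difference d = (covered positions upstream) − (covered positions
downstream), where "covered" means nonzero coverage (the phrase "number
of covered bases" supports counting positions, not summing depth; a
depth-sum variant is available). The standard error of d is the
population SD across all sites divided by √n — computed once globally,
not per class (the iterative alternative was unstated) — and sites are
higher/lower/unchanged at ±1.96·SE. The randomized motif control redraws
site-sized sets from all 3'UTR motif occurrences 1000 times and reports
the mean with a 2.5–97.5 percentile envelope (the confidence level was
unstated; 95% assumed).

# Translation efficiency and overlap statistics

Genes below mean 1 CPM are non-expressed. The package deliberately does
not re-implement GLM dispersion machinery: the defined computation is the
T statistic on per-gene (log2FC, SE) pairs,

  T = |log2FC_Ribo − log2FC_RNA| / sqrt(SE²_Ribo + SE²_RNA),

with two-tailed standard-normal p (no degrees-of-freedom correction, as
the normality assumption states) and Benjamini–Hochberg q. The (log2FC,
SE) inputs may come from external tools' output tables for real data; for
synthetic tests the package provides a documented simplified estimator:
library-normalized, pseudocounted group means give log2FC, and the SE
comes from a delta method under a negative-binomial model with one common
dispersion estimated by a pooled moment ratio, φ = Σ(v−μ)/Σμ² across
genes and groups. The pooled ratio matters: a per-gene variance with four
replicates makes T heavy-tailed (null type-I ≈ 0.09 at nominal 0.05),
and a trimmed-mean common estimate is biased low; the pooled ratio is
nearly unbiased and restores the normal calibration the T statistic
assumes (measured null type-I 0.043–0.062 across seeds). Total-count
normalization means a fold change shared by all genes is invisible
(compositionality); `normalize = FALSE` declares depth-matched libraries.

Target-vs-DE overlap uses Fisher's exact test per RPM threshold
(0, 0.5, 1, 3, 5, 10, 50 — strict `>`, matching the miCLIP filter's
strict threshold) and direction, with the sample OR (ad)/(bc), a Wald 95%
CI, and a Haldane 0.5 correction applied to OR/CI only when a cell is
zero. The p-value is the standard two-sided hypergeometric sum; the test
suite checks it exhaustively against an explicit binomial-coefficient
oracle over all 2×2 tables with margins up to 50.

# Sequence-structure element screening

Motif scanning reports all (overlapping) CTC[CT]A matches with the
methylated C at the match start. The hairpin screen is a *documented
simplified* nearest-neighbour model, not a full thermodynamic folder:
contiguous stems of Watson-Crick and GU pairs with a four-class stack
table (GC/GC −3.3, GC with AU −2.2, AU/AU −1.1, any GU −1.0 kcal/mol), a
linear terminal-loop penalty 5.0 + 0.3·(L−3), and at most one
single-nucleotide bulge per arm at +3.0, minimized over all hairpin
registers in a 51-nt window (window size unstated upstream; 51 nt is the
package default and configurable). The scale is calibrated so a 6-bp GC
stem with a 5-nt loop scores below −5 kcal/mol, which keeps the
−5 kcal/mol stem-loop threshold meaningful; two model properties are
asserted (no negative energy without ≥3 stackable pairs; energy invariant
under reverse-complementing the stem arms). For real data an external
folding engine can be substituted upstream of the thresholding — the
thresholding, not the folding engine, is the method.

Readthrough analysis counts in-frame stop codons (continuing the ORF's
frame) between the annotated stop and a 3'UTR site, against a control
region of equal codon count immediately downstream of the site; "frequency"
is returned as a count with the region size, from which a rate is
derivable. Stop-codon context is the base immediately downstream of the
stop; genes with k annotated stops contribute each with weight 1/k.

# The synthetic world

The generator's defaults state the world the tests run in:

* transcripts of 600–1200 nt with a 30–50 nt 5'UTR, a CDS built from the
  61 sense codons (real ORFs carry no premature in-frame stops — with
  uniform random codons the 3/64 stop rate would dominate the stop-codon
  rows of the codon profile), an annotated stop codon, and a 100–150 nt
  3'UTR;
* a motif_fraction of transcripts carries exactly one planted CTCCA in
  the 3'UTR; a hairpin_fraction of those sits in the loop of an explicit
  8-bp GC stem with a 7-nt loop (explicit complementary stems, because
  ground-truth structure must be known exactly, not sampled);
* planted stoichiometries cycle through {0.1, 0.5, 0.9}, spanning the
  low-stoichiometry regime the assays operate in;
* miCLIP depth 100 unique cDNAs per site, PCR duplicate rate 0.5, 5%
  noise reads, fixed 35-nt inserts (insert-length distribution unstated
  upstream; fixed and configurable);
* bisulfite conversion 0.995, 5% fully unconverted artifact reads,
  coverage 200 per site;
* footprints with P-site offset 12, lengths 27–29, a post-termination
  dwell class (stop in P-site) whose doubling emulates the knockout, and
  an optional readthrough class extending in frame to the planted motif;
* negative-binomial counts (dispersion 0.1, four replicates) with a
  de_fraction of genes given a nonzero ΔTE ~ N(0, 1).

What a green test does and does not establish: the simulations are
transcript-space, plus-strand, splice-free, with no sequencing-error
model beyond bisulfite conversion and no expression heterogeneity across
transcripts. A green run certifies the *computations* — conventions,
filters, statistics, registers — against planted truth; it does not
certify genome-scale alignment, liftover between assemblies (the
real-data mixture of hg19/hg38 coordinates is out of scope), splice
junctions, or the behaviour of external aligners this package replaces at
desk scale.

# Numerical choices and degenerate inputs

* Capping uses exact integer numerators/denominators; aggregation across
  sites is double-precision (documented rounding).
* The Fisher p uses the relative tolerance (1 + 1e-7) when summing
  probabilities "at least as extreme", the standard guard against
  floating-point ties.
* classify_sites requires ≥2 sites (SE undefined otherwise); z = 0
  classifies everything with d ≠ 0; unchanged counts grow monotonically
  with z.
* Sites with no covered cytosine in context are flagged and contribute an
  empty profile rather than zeros-as-data.
* Reads shorter than the barcode header (10 nt), than the minimum length
  after CCA trimming (18 nt), or than the 27-nt codon window are
  discarded with counts logged, never silently.
* All generators accept a seed and are byte-reproducible under it; seeded
  randomness never touches the caller's RNG state.

# Known limitations

Plus-strand transcript-space alignment only (minus-strand handling exists
in the site/track/matrix code paths); no BAM/CRAM I/O (a SAM-subset text
format is the exchange format, importable from real BAMs by an adapter);
no GLM-based differential machinery (import external (log2FC, SE) tables
for that); the hairpin model is a screen, not a folder; no splice-aware
alignment pass. These are scope boundaries, not accidents — each replaces
an external tool whose behaviour is not the method under study.
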