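# m5Cmap

Mapping and interpreting NSUN6-dependent 5-methylcytidine (m5C) sites in
mRNA.

NSUN6 methylates mRNA cytosines at a strict consensus element — the
methylated C is the first base of a `CTC[CT]A` motif — predominantly in
3'UTRs, inside the loops of stem-loop structures, near sites of
translation termination. Detecting and interpreting these sites requires
stitching together three assay types, each with its own single-nucleotide
bookkeeping:

* **miCLIP**: a catalytically trapped enzyme crosslinks to its substrate
  cytosine, and cDNA truncation positions mark methylation sites. The
  pipeline demultiplexes the 10-nt barcode layout (random 1–3/8–10,
  sample 4–7), collapses PCR duplicates, aligns unique inserts, assigns
  each truncation to the closest cytosine within ±2 nt, normalizes to
  RPM, and keeps sites with >50 RPM in ≥2 of 3 replicates.
* **RNA bisulfite sequencing**: unmethylated C reads as T; methylated C
  resists. Alignment is conversion-aware (three-letter space, ≤2
  mismatches, CCA-trim retry for tRNA tails), reads with >1/3 methylated
  cytosines are discarded as conversion-resistant artifacts, and
  site-level methylation is quantified in a ±10 nt context with per-site
  evidence capped at 5 reads — a weight that provably preserves each
  site's methylated fraction (exact rational arithmetic).
* **Ribosome profiling + RNA-seq**: footprints of length 27–29 are frame-
  filtered, split into nine codons (−5..+3, 0 = A-site, P-site offset 12),
  and compared between conditions as normalized codon enrichments;
  single-nucleotide P-site tracks feed coverage matrices (±1500 nt) and an
  upstream/downstream occupancy classifier (±1.96·SE). Differential
  translation efficiency is tested per gene with

  `T = |log2FC_Ribo − log2FC_RNA| / sqrt(SE²_Ribo + SE²_RNA)`,

  two-tailed normal p, and Benjamini–Hochberg FDR; target/DE overlap uses
  Fisher's exact test with odds ratios across an RPM-threshold sweep.
* **Sequence-structure screening**: overlapping motif scans, a documented
  simplified hairpin free-energy model with the −5 kcal/mol stem-loop
  threshold, transcriptome-wide predicted-element enumeration, in-frame
  stop-codon counts between annotated stops and 3'UTR sites (readthrough
  analysis), and stop-codon context distributions.

A first-class synthetic-data module generates transcriptomes, miCLIP/BS
reads, footprints and count matrices with planted ground truth, so the
whole pipeline is validated end to end — see the methods vignette
(`vignettes/m5Cmap-methods.Rmd`) for the model, conventions, parameter
choices, and what a green test does and does not establish.

## Worked example

```r
library(m5Cmap)

tr <- make_transcriptome(n_genes = 200, motif_fraction = 1,
                         hairpin_fraction = 0.5, seed = 7)
tr
#> Transcriptome: 200 transcripts, 200 planted sites (100 in hairpins)

## miCLIP: 3 replicates, 100 unique cDNAs/site, 50% PCR duplicates, 5% noise
reps <- lapply(1:3, function(r)
  simulate_miclip_reads(tr, depth = 100, pcr_dup_rate = 0.5,
                        noise_rate = 0.05, seed = 7 + r))
res <- miclip_call(reps, tr$sequences)
hc <- res$sites[res$sites$high_confidence, ]
#> 200 high-confidence sites from 4642 candidates
#> precision 1.000, recall 1.000 against the planted truth
head(hc[, c("contig", "pos", "strand", "mean_rpm")], 3)
#>  contig pos strand mean_rpm
#>  tx_001 504      + 4545.455
#>  tx_002 839      + 4545.455
#>  tx_003 731      + 4545.455

## bisulfite quantification at the called sites
rd <- simulate_bs_reads(tr, coverage = 200, conversion_rate = 0.995,
                        artifact_fraction = 0.05, seed = 11)
bs <- bsseq_run(rd, tr$sequences, data.frame(contig = hc$contig, pos = hc$pos))
#> artifact filter removed 1978 of 40000 aligned reads   (~5%, as planted)
#> aggregate motif-site level at offset 0: 0.494         (planted mean 0.5)
head(bs$quant$per_site[, c("contig", "pos", "n_meth", "n_total", "level")], 3)
#>  contig pos n_meth n_total      level   # planted stoichiometry
#>  tx_001 504     16     196 0.08163265   # 0.1
#>  tx_002 839     96     186 0.51612903   # 0.5
#>  tx_003 731    180     196 0.91836735   # 0.9

## ribosome footprints: perfect triplet periodicity by construction
fp <- simulate_ribo_footprints(tr, reads_per_codon = 2, seed = 13)
periodicity_report(fp, tr$models)
#>  length frame0 frame1 frame2 dominant_fraction
#>      27  32083      0      0                 1
#>      28  32659      0      0                 1
#>      29  32384      0      0                 1
```

The RPM values are per-site cDNA counts scaled by the library size
(100 cDNAs at a ~22k-cDNA library ≈ 4545 RPM); the per-site bisulfite
levels recover the planted stoichiometries within binomial error; the
frame table is the periodicity evidence used to select footprint lengths.

## Command line

A thin CLI over the same functions ships in `inst/scripts/m5cmap`
(`simulate`, `miclip call`, `bsseq quantify`, `ribo track|periodicity`,
`seq scan|predict`, `diff te`); see the script header for usage.
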