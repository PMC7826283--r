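## Synthetic transcriptomes, reads and count matrices with planted ground
## truth. The generator states a fixed world: motif-bearing 3'UTR sites in
## hairpin loops, truncation-type miCLIP reads with PCR-duplicate barcodes,
## bisulfite reads with per-site stoichiometry plus conversion-resistant
## artifact reads, triplet-periodic footprints that stop at termination (with
## an optional readthrough class), and negative-binomial count matrices.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.splice <- function(s, at0, replacement) {
  # overwrite s at 0-based offset at0 with replacement
  paste0(substring(s, 1L, at0), replacement,
         substring(s, at0 + nchar(replacement) + 1L, nchar(s)))
}

#' Generate a synthetic transcriptome with planted methylation sites
#'
#' Each gene is a single-exon transcript on its own contig with a 5'UTR, a
#' CDS (length divisible by three) and a 3'UTR; the annotated stop codon
#' occupies the three bases immediately after the CDS. A `motif_fraction`
#' subset of transcripts carries exactly one planted CTCCA element in its
#' 3'UTR (the methylated cytosine is the first base of the motif); a
#' `hairpin_fraction` subset of those embeds the motif in the loop of a
#' planted stem-loop (8-bp GC stem, 7-nt loop). Planted sites receive
#' methylation stoichiometries by recycling `stoichiometries`, and a
#' `readthrough_fraction` subset of motif transcripts is flagged for
#' stop-codon readthrough in the footprint simulator.
#'
#' @param n_genes number of genes (>= 1).
#' @param length_range transcript length range in nt.
#' @param motif_fraction fraction of transcripts with a planted motif site.
#' @param hairpin_fraction fraction of motif sites embedded in a stem-loop.
#' @param stoichiometries methylation stoichiometries recycled over planted
#'   sites.
#' @param readthrough_fraction fraction of motif transcripts flagged for
#'   readthrough.
#' @param seed integer seed; the same seed reproduces the transcriptome
#'   byte-identically.
#' @return object of class `Transcriptome`: list with `sequences` (named
#'   character), `models` (named list of [transcript_model()]), and `truth`
#'   (planted sites, incidental motif occurrences, seed).
#' @export
make_transcriptome <- function(n_genes = 50L, length_range = c(600L, 1200L),
                               motif_fraction = 0.8, hairpin_fraction = 0.5,
                               stoichiometries = c(0.1, 0.5, 0.9),
                               readthrough_fraction = 0.1, seed = 1L) {
  stopifnot(n_genes >= 1L, motif_fraction >= 0, motif_fraction <= 1,
            hairpin_fraction >= 0, hairpin_fraction <= 1)
  .with_seed(seed, {
    n_motif <- round(n_genes * motif_fraction)
    motif_idx <- if (n_motif) sort(sample.int(n_genes, n_motif)) else integer(0)
    n_hp <- round(n_motif * hairpin_fraction)
    hp_idx <- if (n_hp) sort(sample(motif_idx, n_hp)) else integer(0)
    n_rt <- round(n_motif * readthrough_fraction)
    rt_idx <- if (n_rt) sort(sample(motif_idx, n_rt)) else integer(0)

    seqs <- character(n_genes)
    models <- vector("list", n_genes)
    planted <- list()
    stoi_i <- 0L
    for (g in seq_len(n_genes)) {
      tid <- sprintf("tx_%03d", g)
      gid <- sprintf("gene_%03d", g)
      tlen <- sample(seq.int(length_range[1L], length_range[2L]), 1L)
      utr5 <- sample(30:50, 1L)
      utr3 <- sample(100:150, 1L)
      cds_len <- tlen - utr5 - 3L - utr3
      cds_len <- cds_len - (cds_len %% 3L)
      if (cds_len < 30L) {
        stop("transcript too short to host UTRs + CDS: ", tid)
      }
      cds_start <- utr5
      cds_end <- utr5 + cds_len
      s <- .rand_seq(tlen)
      # a real ORF has no premature in-frame stop: draw CDS codons from the
      # 61 sense codons, then plant the annotated stop right after the CDS
      sense <- setdiff(.ALL_CODONS, c("TAA", "TAG", "TGA"))
      cds_seq <- paste(sample(sense, cds_len %/% 3L, replace = TRUE),
                       collapse = "")
      s <- .splice(s, cds_start, cds_seq)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
      s <- .splice(s, cds_end, stop_codon)

      site <- NULL
      if (g %in% motif_idx) {
        # motif C at p; need 10 nt upstream context and 40 nt downstream
        lo <- cds_end + 3L + 15L
        hi <- tlen - 41L
        stopifnot(hi > lo)
        p <- sample(seq.int(lo, hi), 1L)
        if (g %in% hp_idx) {
          arm <- paste(sample(c("G", "C"), 8L, replace = TRUE), collapse = "")
          hair <- paste0(arm, "A", "CTCCA", "A", revcomp(arm))
          h0 <- p - 9L  # motif C sits at hairpin offset 9 (arm 8 + "A")
          if (h0 < cds_end + 3L) { h0 <- cds_end + 3L; p <- h0 + 9L }
          s <- .splice(s, h0, hair)
        } else {
          s <- .splice(s, p, "CTCCA")
        }
        stoi_i <- stoi_i + 1L
        site <- data.frame(
          transcript_id = tid, pos = p,
          stoichiometry = stoichiometries[((stoi_i - 1L) %%
                                             length(stoichiometries)) + 1L],
          motif_present = TRUE, in_hairpin = g %in% hp_idx,
          readthrough = g %in% rt_idx, stringsAsFactors = FALSE)
        planted[[length(planted) + 1L]] <- site
      }
      seqs[g] <- s
      names(seqs)[g] <- tid
      models[[g]] <- transcript_model(
        tid, gid, tid, "+", s, cds_start, cds_end,
        stop_codons = data.frame(offset = cds_end, codon = stop_codon,
                                 stringsAsFactors = FALSE))
    }
    names(models) <- names(seqs)
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(transcript_id = character(0), pos = integer(0),
                 stoichiometry = numeric(0), motif_present = logical(0),
                 in_hairpin = logical(0), readthrough = logical(0))
    # record incidental (non-planted) motif occurrences
    inc <- list()
    for (g in seq_len(n_genes)) {
      hits <- scan_motif(seqs[[g]])
      if (!nrow(hits)) next
      pl <- planted$pos[planted$transcript_id == names(seqs)[g]]
      extra <- hits[!hits$start %in% pl, , drop = FALSE]
      if (nrow(extra)) {
        inc[[length(inc) + 1L]] <- data.frame(
          transcript_id = names(seqs)[g], pos = extra$start,
          pattern_matched = extra$pattern_matched, stringsAsFactors = FALSE)
      }
    }
    incidental <- if (length(inc)) do.call(rbind, inc) else
      data.frame(transcript_id = character(0), pos = integer(0),
                 pattern_matched = character(0))
    structure(list(
      sequences = seqs, models = models,
      truth = list(planted_sites = planted, incidental_motifs = incidental,
                   seed = seed)
    ), class = "Transcriptome")
  })
}

#' @export
print.Transcriptome <- function(x, ...) {
  cat(sprintf("Transcriptome: %d transcripts, %d planted sites (%d in hairpins)\n",
              length(x$sequences), nrow(x$truth$planted_sites),
              sum(x$truth$planted_sites$in_hairpin)))
  invisible(x)
}

#' Write a synthetic transcriptome to disk
#'
#' Emits FASTA + GTF + a JSON truth file into `dir`.
#'
#' @param tr a `Transcriptome`.
#' @param dir output directory (created if absent).
#' @return character vector of the three paths, invisibly.
#' @export
write_transcriptome <- function(tr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcriptome.fa")
  gtf <- file.path(dir, "transcriptome.gtf")
  truth <- file.path(dir, "truth.json")
  write_fasta(tr$sequences, fa)
  write_annotation(tr$models, gtf)
  jsonlite::write_json(tr$truth, truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gtf = gtf, truth = truth))
}

.rand_barcodes <- function(n, len = 6L, unique_set = TRUE) {
  if (unique_set) {
    # sample without replacement from the 4^len barcode space
    idx <- sample.int(4L^len, n)
    vapply(idx - 1L, function(k) {
      paste(c("A", "C", "G", "T")[(k %/% 4L^(seq_len(len) - 1L)) %% 4L + 1L],
            collapse = "")
    }, character(1L))
  } else {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1L))
  }
}

#' Simulate miCLIP reads with barcodes and PCR duplicates
#'
#' Reads follow the 10-nt header layout: positions 1-3 random barcode,
#' 4-7 experimental barcode, 8-10 random barcode, then the insert. cDNA
#' truncates at the crosslinked cytosine, so each signal insert begins at
#' the nucleotide immediately 3' of a planted site's C. `depth` unique
#' cDNAs are generated per site; the raw read number is inflated to
#' `depth / (1 - pcr_dup_rate)` by emitting exact duplicates (same random
#' barcode and insert). A `noise_rate` fraction of raw reads starts at
#' random non-site positions.
#'
#' @param tr a `Transcriptome`.
#' @param depth unique cDNAs per planted site.
#' @param pcr_dup_rate fraction of raw reads that are PCR duplicates.
#' @param noise_rate fraction of raw reads starting at random positions.
#' @param experimental_barcode 4-nt sample barcode used for all reads.
#' @param insert_length insert length in nt.
#' @param seed integer seed.
#' @return data.frame(read_id, sequence); signal and noise reads shuffled.
#' @export
simulate_miclip_reads <- function(tr, depth = 100L, pcr_dup_rate = 0.5,
                                  noise_rate = 0.05,
                                  experimental_barcode = "ACGT",
                                  insert_length = 35L, seed = 1L) {
  stopifnot(depth >= 1L, pcr_dup_rate >= 0, pcr_dup_rate < 1,
            noise_rate >= 0, noise_rate < 1, nchar(experimental_barcode) == 4L)
  .with_seed(seed, {
    sites <- tr$truth$planted_sites
    out <- list()
    for (i in seq_len(nrow(sites))) {
      tid <- sites$transcript_id[i]
      p <- sites$pos[i]
      s <- tr$sequences[[tid]]
      ins <- substring(s, p + 2L, p + 1L + insert_length)
      rbs <- .rand_barcodes(depth)
      uniq <- paste0(substring(rbs, 1L, 3L), experimental_barcode,
                     substring(rbs, 4L, 6L), ins)
      n_raw <- round(depth / (1 - pcr_dup_rate))
      dups <- if (n_raw > depth)
        sample(uniq, n_raw - depth, replace = TRUE) else character(0)
      out[[length(out) + 1L]] <- c(uniq, dups)
    }
    signal <- unlist(out)
    n_noise <- round(noise_rate * length(signal))
    noise <- character(0)
    if (n_noise > 0L) {
      site_key <- paste(sites$transcript_id, sites$pos + 1L)
      noise <- vapply(seq_len(n_noise), function(i) {
        repeat {
          tid <- sample(names(tr$sequences), 1L)
          tlen <- nchar(tr$sequences[[tid]])
          start0 <- sample.int(tlen - insert_length - 1L, 1L)  # >= 1
          if (!paste(tid, start0) %in% site_key) break
        }
        rb <- .rand_barcodes(1L, unique_set = FALSE)
        paste0(substring(rb, 1L, 3L), experimental_barcode,
               substring(rb, 4L, 6L),
               substring(tr$sequences[[tid]], start0 + 1L,
                         start0 + insert_length))
      }, character(1L))
    }
    reads <- sample(c(signal, noise))
    data.frame(read_id = sprintf("mic_%06d", seq_along(reads)),
               sequence = reads, stringsAsFactors = FALSE)
  })
}

#' Simulate bisulfite-converted reads over planted sites
#'
#' Reads are drawn so that each covers the full +/-10 nt context of its
#' site. Unmethylated cytosines convert (read T) with probability
#' `conversion_rate`; the planted-site cytosine reads C with probability
#' equal to its stoichiometry. An `artifact_fraction` of reads emulates
#' conversion-resistant regions: ALL their cytosines stay unconverted.
#'
#' @param tr a `Transcriptome`.
#' @param coverage reads per planted site.
#' @param conversion_rate bisulfite conversion probability, in (0.9, 1].
#' @param artifact_fraction fraction of fully unconverted reads.
#' @param read_length read length in nt.
#' @param stoichiometry_override if not NULL, overrides every site's
#'   stoichiometry (e.g. 0 for a knockout run).
#' @param seed integer seed.
#' @return data.frame(read_id, sequence, true_contig, true_pos, artifact);
#'   `true_pos` is the 0-based position the read was drawn from.
#' @export
simulate_bs_reads <- function(tr, coverage = 200L, conversion_rate = 0.995,
                              artifact_fraction = 0.05, read_length = 50L,
                              stoichiometry_override = NULL, seed = 1L) {
  stopifnot(conversion_rate > 0.9, conversion_rate <= 1, coverage >= 1L)
  .with_seed(seed, {
    sites <- tr$truth$planted_sites
    rows <- list()
    for (i in seq_len(nrow(sites))) {
      tid <- sites$transcript_id[i]
      p <- sites$pos[i]
      stoi <- if (is.null(stoichiometry_override)) sites$stoichiometry[i]
              else stoichiometry_override
      s <- tr$sequences[[tid]]
      tlen <- nchar(s)
      lo <- max(0L, p + 10L - (read_length - 1L))
      hi <- min(p - 10L, tlen - read_length)
      stopifnot(hi >= lo)
      starts <- sample(seq.int(lo, hi), coverage, replace = TRUE)
      frag <- substring(s, starts + 1L, starts + read_length)
      artifact <- runif(coverage) < artifact_fraction
      conv <- vapply(seq_len(coverage), function(k) {
        if (artifact[k]) return(frag[k])  # all Cs unconverted
        v <- strsplit(frag[k], "", fixed = TRUE)[[1L]]
        cpos <- which(v == "C")
        if (!length(cpos)) return(frag[k])
        site_in_read <- p - starts[k] + 1L  # 1-based within read
        u <- runif(length(cpos))
        is_site <- cpos == site_in_read
        to_t <- (is_site & u >= stoi) | (!is_site & u < conversion_rate)
        v[cpos[to_t]] <- "T"
        paste(v, collapse = "")
      }, character(1L))
      rows[[i]] <- data.frame(
        read_id = sprintf("bs_%s_%04d", tid, seq_len(coverage)),
        sequence = conv, true_contig = tid, true_pos = starts,
        artifact = artifact, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate ribosome footprints walking the CDS
#'
#' Footprints are placed so the P-site nucleotide (read position
#' `psite_offset`, 0-based) walks codon starts within the CDS. Coverage
#' stops at termination: the most 3' elongating footprint has the annotated
#' stop codon in its A-site. A post-termination dwell class (stop codon in
#' the P-site) is emitted with multiplicity `terminal_dwell` x
#' `reads_per_codon`; doubling it emulates the knockout's stalled
#' termination. Transcripts flagged for readthrough continue in frame
#' through the 3'UTR up to the planted motif and stop there.
#'
#' @param tr a `Transcriptome`.
#' @param reads_per_codon footprints per codon position.
#' @param lengths footprint lengths, a subset of 26..31.
#' @param psite_offset 5'-end-to-P-site offset (0-based nucleotides).
#' @param terminal_dwell multiplier for the post-termination dwell class.
#' @param include_readthrough emit readthrough footprints on flagged
#'   transcripts.
#' @param seed integer seed.
#' @return data.frame of aligned reads (read_id, contig, pos, strand,
#'   length, mismatches, query) with 0-based `pos`.
#' @export
simulate_ribo_footprints <- function(tr, reads_per_codon = 1L,
                                     lengths = 27:29, psite_offset = 12L,
                                     terminal_dwell = 1L,
                                     include_readthrough = TRUE, seed = 1L) {
  stopifnot(psite_offset >= 0L, all(lengths >= 26L & lengths <= 31L))
  .with_seed(seed, {
    rows <- list()
    sites <- tr$truth$planted_sites
    for (m in tr$models) {
      if (m$cds_end <= m$cds_start) next
      s <- m$sequence
      tlen <- nchar(s)
      psites <- seq.int(m$cds_start, m$cds_end - 3L, by = 3L)
      reps <- rep(reads_per_codon, length(psites))
      # post-termination dwell: stop codon in the P-site
      psites <- c(psites, m$cds_end)
      reps <- c(reps, round(reads_per_codon * terminal_dwell))
      rt <- sites[sites$transcript_id == m$transcript_id &
                    sites$readthrough, , drop = FALSE]
      if (include_readthrough && nrow(rt)) {
        p <- rt$pos[1L]
        last <- m$cds_end + 3L * ((p - 3L - m$cds_end) %/% 3L)
        if (last >= m$cds_end + 3L) {
          rt_ps <- seq.int(m$cds_end + 3L, last, by = 3L)
          psites <- c(psites, rt_ps)
          reps <- c(reps, rep(reads_per_codon, length(rt_ps)))
        }
      }
      ps_all <- rep(psites, reps)
      if (!length(ps_all)) next
      len <- sample(lengths, length(ps_all), replace = TRUE)
      start <- ps_all - psite_offset
      ok <- start >= 0L & start + len <= tlen
      start <- start[ok]; len <- len[ok]
      if (!length(start)) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("fp_%s_%05d", m$transcript_id, seq_along(start)),
        contig = m$contig, pos = start, strand = "+", length = len,
        mismatches = 0L,
        query = substring(s, start + 1L, start + len),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate RNA-seq and Ribo-seq count matrices with known fold changes
#'
#' Negative-binomial counts for two conditions (control vs knockout) and
#' two assays. A `de_fraction` of genes receives a nonzero true
#' differential translation efficiency delta = log2FC_Ribo - log2FC_RNA
#' (drawn N(0, `lfc_sd`)); RNA log2 fold changes are zero so delta is the
#' Ribo-side change.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per condition (>= 2).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param de_fraction fraction of genes with nonzero delta-TE.
#' @param lfc_sd standard deviation of the true delta-TE.
#' @param mean_log2_range log2 range of baseline gene means.
#' @param seed integer seed.
#' @return list(rna, ribo) count matrices (genes x 2*n_reps, control
#'   columns first), `groups` factor, and `truth` data.frame(gene_id,
#'   lfc_rna, lfc_ribo, delta).
#' @export
simulate_counts <- function(n_genes = 2000L, n_reps = 4L, dispersion = 0.1,
                            de_fraction = 0.1, lfc_sd = 1,
                            mean_log2_range = c(4, 10), seed = 1L) {
  stopifnot(n_reps >= 2L, dispersion >= 0)
  .with_seed(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    mu <- 2^runif(n_genes, mean_log2_range[1L], mean_log2_range[2L])
    delta <- numeric(n_genes)
    n_de <- round(n_genes * de_fraction)
    if (n_de > 0L) {
      idx <- sample.int(n_genes, n_de)
      delta[idx] <- stats::rnorm(n_de, 0, lfc_sd)
    }
    lfc_rna <- numeric(n_genes)
    lfc_ribo <- lfc_rna + delta
    draw <- function(mu_vec) {
      if (dispersion == 0) {
        matrix(stats::rpois(n_genes * n_reps, rep(mu_vec, n_reps)),
               nrow = n_genes)
      } else {
        matrix(rnbinom(n_genes * n_reps, mu = rep(mu_vec, n_reps),
                       size = 1 / dispersion), nrow = n_genes)
      }
    }
    rna <- cbind(draw(mu), draw(mu * 2^lfc_rna))
    ribo <- cbind(draw(mu), draw(mu * 2^lfc_ribo))
    dimnames(rna) <- list(gene_id, c(sprintf("ctrl_%d", seq_len(n_reps)),
                                     sprintf("ko_%d", seq_len(n_reps))))
    dimnames(ribo) <- dimnames(rna)
    list(rna = rna, ribo = ribo,
         groups = factor(rep(c("ctrl", "ko"), each = n_reps),
                         levels = c("ctrl", "ko")),
         truth = data.frame(gene_id = gene_id, lfc_rna = lfc_rna,
                            lfc_ribo = lfc_ribo, delta = delta,
                            stringsAsFactors = FALSE))
  })
}
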