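## miCLIP truncation-site inference: demultiplex, deduplicate, align,
## assign truncation positions to cytosines, normalize to RPM, and apply
## the replicate-consensus filter.
##
## Conventions. The cDNA truncates AT the crosslinked cytosine, so an
## insert's 5'-most aligned base sits immediately 3' of it: the truncation
## position is the base immediately 5' of the read start, and the read's
## cDNA count is assigned to the closest strand-matched C within +/-2 nt
## (search order distance 0, 1, 2; ties broken upstream).

#' Demultiplex miCLIP reads and collapse PCR duplicates
#'
#' Reads carry a 10-nt header: positions 1-3 random barcode, 4-7
#' experimental (sample) barcode, 8-10 random barcode. Within a sample,
#' reads with identical (random barcode, insert) are PCR products and
#' collapse to one; the cDNA count of a unique insert is the number of
#' distinct random barcodes observed for it.
#'
#' @param reads data.frame(read_id, sequence).
#' @param experimental_barcodes character vector whitelist of 4-nt sample
#'   barcodes.
#' @return list with `samples` (named list of data.frame(insert, count)),
#'   `undetermined` (same shape, off-whitelist barcodes) and `stats`
#'   (n_input, n_short, n_undetermined).
#' @export
demultiplex_dedup <- function(reads, experimental_barcodes) {
  stopifnot(all(nchar(experimental_barcodes) == 4L))
  n_input <- nrow(reads)
  len <- nchar(reads$sequence)
  short <- len < 10L
  n_short <- sum(short)
  sq <- reads$sequence[!short]
  dt <- data.table::data.table(
    random_barcode = paste0(substring(sq, 1L, 3L), substring(sq, 8L, 10L)),
    expbc = substring(sq, 4L, 7L),
    insert = substring(sq, 11L))
  dt[, sample_id := ifelse(expbc %in% experimental_barcodes, expbc,
                           "undetermined")]
  # collapse exact PCR duplicates, then count distinct random barcodes
  uniq <- unique(dt, by = c("sample_id", "random_barcode", "insert"))
  counts <- uniq[, .(count = .N), by = .(sample_id, insert)]
  split_df <- function(d) {
    out <- as.data.frame(d[, .(insert, count)])
    out[order(out$insert), , drop = FALSE]
  }
  samples <- lapply(
    stats::setNames(nm = experimental_barcodes),
    function(b) split_df(counts[sample_id == b]))
  und <- split_df(counts[sample_id == "undetermined"])
  list(samples = samples, undetermined = und,
       stats = list(n_input = n_input, n_short = n_short,
                    n_undetermined = sum(und$count)))
}

#' Align inserts to a small reference transcriptome
#'
#' Seed-and-verify alignment mirroring unique-best mapping with at most one
#' mismatch: two 17-mer seeds (so a single mismatch cannot break both),
#' full-length verification, and rejection of inserts with more than one
#' best hit. Plus-strand transcript-space only.
#'
#' @param inserts data.frame(insert, count) from [demultiplex_dedup()].
#' @param reference named character vector of contig sequences.
#' @param max_mismatches maximum mismatches for a valid alignment.
#' @return list with `aligned` data.frame(insert, contig, pos, strand,
#'   mismatches, count) (0-based `pos`) and `stats` (n_input, n_unaligned,
#'   n_multimapped; in unique inserts).
#' @export
align_inserts <- function(inserts, reference, max_mismatches = 1L) {
  hits <- .batch_align(inserts$insert, reference, k = 17L,
                       max_mismatches = max_mismatches, report = "unique")
  n <- nrow(inserts)
  aligned <- if (nrow(hits$aligned)) {
    i <- hits$aligned$seq_idx
    data.frame(insert = inserts$insert[i], contig = hits$aligned$contig,
               pos = hits$aligned$pos, strand = "+",
               mismatches = hits$aligned$mismatches,
               count = inserts$count[i], stringsAsFactors = FALSE)
  } else {
    data.frame(insert = character(0), contig = character(0),
               pos = integer(0), strand = character(0),
               mismatches = integer(0), count = integer(0))
  }
  list(aligned = aligned,
       stats = list(n_input = n, n_unaligned = length(hits$unaligned_idx),
                    n_multimapped = length(hits$ambiguous_idx)))
}

# Batched seed-and-verify alignment shared by the miCLIP and bisulfite
# aligners. Seeds of width k are placed at k-grid offsets plus the read
# end, so `max_mismatches` mismatches cannot break all seeds of a read
# that is long enough; candidates are verified full-length. `transform`
# (e.g. C->T collapse) is applied to reads and reference before matching.
.batch_align <- function(sequences, reference, k, max_mismatches,
                         report = c("unique", "all"),
                         transform = identity) {
  report <- match.arg(report)
  seqs_t <- transform(sequences)
  ref_t <- transform(reference)
  idx <- .kmer_index(ref_t, k)
  n <- length(sequences)
  L <- nchar(seqs_t)
  ref_len <- setNames(nchar(reference), names(reference))

  seed_rows <- lapply(seq_len(n), function(i) {
    if (L[i] < k) return(NULL)
    offs <- unique(c(seq(0L, L[i] - k, by = k)[seq_len(max_mismatches + 1L)],
                     L[i] - k))
    offs <- offs[!is.na(offs)]
    data.table::data.table(seq_idx = i, off = offs,
                           kmer = substring(seqs_t[i], offs + 1L,
                                            offs + k))
  })
  seed_dt <- data.table::rbindlist(seed_rows)
  empty <- data.frame(seq_idx = integer(0), contig = character(0),
                      pos = integer(0), mismatches = integer(0))
  unaligned <- setdiff(seq_len(n), if (nrow(seed_dt)) unique(seed_dt$seq_idx)
                       else integer(0))
  if (!nrow(seed_dt)) {
    return(list(aligned = empty, unaligned_idx = unaligned,
                ambiguous_idx = integer(0)))
  }
  cand <- idx[seed_dt, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  cand[, pos := pos - off]
  cand <- unique(cand[pos >= 0L, .(seq_idx, contig, pos)])
  cand <- cand[pos + L[seq_idx] <= ref_len[contig]]
  if (!nrow(cand)) {
    return(list(aligned = empty, unaligned_idx = seq_len(n),
                ambiguous_idx = integer(0)))
  }
  # verify candidates in collapsed/transformed space
  ref_sub <- substring(ref_t[cand$contig], cand$pos + 1L,
                       cand$pos + L[cand$seq_idx])
  cand[, mismatches := mapply(.count_mismatches, seqs_t[seq_idx], ref_sub,
                              USE.NAMES = FALSE)]
  cand <- cand[mismatches <= max_mismatches]
  hit_idx <- if (nrow(cand)) unique(cand$seq_idx) else integer(0)
  unaligned <- setdiff(seq_len(n), hit_idx)
  if (report == "all") {
    out <- as.data.frame(cand[order(seq_idx, contig, pos)])
    return(list(aligned = out, unaligned_idx = unaligned,
                ambiguous_idx = integer(0)))
  }
  cand <- cand[cand[, .I[mismatches == min(mismatches)], by = seq_idx]$V1]
  nbest <- cand[, .N, by = seq_idx]
  ambiguous <- nbest$seq_idx[nbest$N > 1L]
  best <- cand[!seq_idx %in% ambiguous]
  list(aligned = as.data.frame(best[order(seq_idx)]),
       unaligned_idx = unaligned, ambiguous_idx = ambiguous)
}

.kmer_index <- function(reference, k) {
  parts <- lapply(names(reference), function(nm) {
    s <- reference[[nm]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           contig = nm, pos = starts - 1L)
  })
  idx <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1L))])
  data.table::setkey(idx, kmer)
  idx
}

.count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Assign truncation read counts to cytosines
#'
#' The truncation position is the nucleotide immediately 5' of the insert's
#' 5'-most aligned base. Each insert's cDNA count goes to the closest
#' strand-matched C within +/-2 nt of the truncation position, searching
#' distance 0, then 1, then 2, preferring the upstream C on ties. Inserts
#' with no C in the window, or aligned at contig position 0 (no upstream
#' base), are discarded and counted.
#'
#' @param aligned data.frame(contig, pos, strand, count) of uniquely
#'   aligned inserts (0-based `pos` of the 5'-most aligned base).
#' @param reference named character vector of contig sequences.
#' @param window maximum distance from the truncation position to a C.
#' @return list with `sites` data.frame(contig, pos, strand, count)
#'   aggregated per cytosine, and `stats` (n_input, n_assigned, n_no_c,
#'   n_edge; in reads, i.e. summed cDNA counts).
#' @export
call_truncation_sites <- function(aligned, reference, window = 2L) {
  n_input <- sum(aligned$count)
  n_no_c <- 0L; n_edge <- 0L
  rows <- list()
  for (i in seq_len(nrow(aligned))) {
    contig <- aligned$contig[i]
    p5 <- aligned$pos[i]
    strand <- aligned$strand[i]
    cnt <- aligned$count[i]
    if (p5 == 0L) { n_edge <- n_edge + cnt; next }
    trunc <- p5 - 1L
    ref <- reference[[contig]]
    target <- if (strand == "+") "C" else "G"
    hit <- NA_integer_
    for (d in 0:window) {
      for (q in unique(c(trunc - d, trunc + d))) {  # upstream first
        if (q < 0L || q >= nchar(ref)) next
        if (substring(ref, q + 1L, q + 1L) == target) { hit <- q; break }
      }
      if (!is.na(hit)) break
    }
    if (is.na(hit)) { n_no_c <- n_no_c + cnt; next }
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, pos = hit, strand = strand, count = cnt,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) {
    dt <- data.table::rbindlist(rows)
    as.data.frame(dt[, .(count = sum(count)), by = .(contig, pos, strand)])
  } else {
    data.frame(contig = character(0), pos = integer(0),
               strand = character(0), count = integer(0))
  }
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites,
       stats = list(n_input = n_input, n_assigned = sum(sites$count),
                    n_no_c = n_no_c, n_edge = n_edge))
}

#' Normalize site counts per million uniquely mapping reads
#'
#' @param counts numeric vector of site read counts.
#' @param library_unique_reads number of uniquely mapping reads in the
#'   library (post-deduplication cDNA count); must be positive.
#' @return RPM values, `counts * 1e6 / library_unique_reads`.
#' @export
normalize_rpm <- function(counts, library_unique_reads) {
  if (length(library_unique_reads) != 1L || library_unique_reads <= 0) {
    stop("library_unique_reads must be a single positive number")
  }
  counts * 1e6 / library_unique_reads
}

#' Replicate-consensus high-confidence site filter
#'
#' A site is retained iff its RPM is strictly greater than `rpm_threshold`
#' in at least `min_replicates` of the `n_replicates` replicates.
#'
#' @param rpm_by_replicate numeric matrix, sites x replicates.
#' @param rpm_threshold RPM cutoff (strict).
#' @param min_replicates minimum number of passing replicates.
#' @param n_replicates expected number of replicate columns.
#' @return logical vector over rows (TRUE = high confidence).
#' @export
filter_high_confidence <- function(rpm_by_replicate, rpm_threshold = 50,
                                   min_replicates = 2L, n_replicates = 3L) {
  rpm_by_replicate <- as.matrix(rpm_by_replicate)
  if (ncol(rpm_by_replicate) != n_replicates) {
    stop("expected ", n_replicates, " replicate columns, got ",
         ncol(rpm_by_replicate))
  }
  rowSums(rpm_by_replicate > rpm_threshold) >= min_replicates
}

#' Run the full miCLIP site-calling pipeline over replicates
#'
#' Demultiplexes and deduplicates each replicate's raw reads, aligns the
#' unique inserts, infers truncation sites, normalizes to RPM per
#' replicate, and applies the replicate-consensus filter across the site
#' union. Asserts that every reported site's reference base is C on its
#' strand.
#'
#' @param reads_by_replicate list of data.frame(read_id, sequence), one per
#'   replicate.
#' @param reference named character vector of contig sequences.
#' @param experimental_barcode the sample's 4-nt barcode.
#' @param rpm_threshold,min_replicates see [filter_high_confidence()].
#' @param max_mismatches see [align_inserts()].
#' @return list with `sites` (data.frame contig, pos, strand, per-replicate
#'   count and rpm columns, mean_rpm, high_confidence) and `per_replicate`
#'   stats.
#' @export
miclip_call <- function(reads_by_replicate, reference,
                        experimental_barcode = "ACGT", rpm_threshold = 50,
                        min_replicates = 2L, max_mismatches = 1L) {
  n_rep <- length(reads_by_replicate)
  per_rep <- vector("list", n_rep)
  tables <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    dmx <- demultiplex_dedup(reads_by_replicate[[r]], experimental_barcode)
    ins <- dmx$samples[[experimental_barcode]]
    aln <- align_inserts(ins, reference, max_mismatches)
    lib <- sum(aln$aligned$count)
    ts <- call_truncation_sites(aln$aligned, reference)
    st <- ts$sites
    st$rpm <- normalize_rpm(st$count, lib)
    tables[[r]] <- st
    per_rep[[r]] <- list(demux = dmx$stats, align = aln$stats,
                         truncation = ts$stats, library_unique_reads = lib)
  }
  key <- unique(do.call(rbind, lapply(tables, function(x)
    x[, c("contig", "pos", "strand")])))
  key <- key[order(key$contig, key$pos), , drop = FALSE]
  rownames(key) <- NULL
  count_m <- matrix(0, nrow(key), n_rep)
  rpm_m <- matrix(0, nrow(key), n_rep)
  kk <- paste(key$contig, key$pos, key$strand)
  for (r in seq_len(n_rep)) {
    tk <- paste(tables[[r]]$contig, tables[[r]]$pos, tables[[r]]$strand)
    ix <- match(tk, kk)
    count_m[ix, r] <- tables[[r]]$count
    rpm_m[ix, r] <- tables[[r]]$rpm
  }
  colnames(count_m) <- sprintf("count_%d", seq_len(n_rep))
  colnames(rpm_m) <- sprintf("rpm_%d", seq_len(n_rep))
  hc <- filter_high_confidence(rpm_m, rpm_threshold, min_replicates, n_rep)
  # hard assertion: the reference base at every site is C on its strand
  base <- vapply(seq_len(nrow(key)), function(i) {
    substring(reference[[key$contig[i]]], key$pos[i] + 1L, key$pos[i] + 1L)
  }, character(1L))
  want <- ifelse(key$strand == "+", "C", "G")
  if (nrow(key) && !all(base == want)) stop("non-cytosine site reported")
  sites <- cbind(key, count_m, rpm_m,
                 mean_rpm = rowMeans(rpm_m), high_confidence = hc)
  list(sites = sites, per_replicate = per_rep)
}

#' Annotate sites with transcript features and 50-nt window counts
#'
#' Labels each site 5'UTR / CDS / 3'UTR / noncoding (or intergenic when no
#' transcript matches), using the half-open CDS: a site at `cds_end` is
#' 3'UTR. Sites are also counted within non-overlapping fixed 50-nt
#' windows per transcript.
#'
#' @param sites data.frame(contig, pos, ...).
#' @param models named list of transcript models (contig = transcript id).
#' @param window_size tiling window width in nt.
#' @return list with `sites` (input plus `feature` column), `windows`
#'   (data.frame transcript_id, window, n_sites) and `singleton_fraction`
#'   (fraction of occupied windows holding exactly one site).
#' @export
annotate_sites <- function(sites, models, window_size = 50L) {
  feature <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- models[[sites$contig[i]]]
    if (is.null(m)) { feature[i] <- "intergenic"; next }
    p <- sites$pos[i]
    feature[i] <- if (m$cds_end <= m$cds_start) "noncoding"
      else if (p < m$cds_start) "5UTR"
      else if (p < m$cds_end) "CDS"
      else "3UTR"
  }
  sites$feature <- feature
  inside <- sites[feature != "intergenic", , drop = FALSE]
  windows <- if (nrow(inside)) {
    dt <- data.table::data.table(transcript_id = inside$contig,
                                 window = inside$pos %/% window_size)
    as.data.frame(dt[, .(n_sites = .N), by = .(transcript_id, window)])
  } else {
    data.frame(transcript_id = character(0), window = integer(0),
               n_sites = integer(0))
  }
  list(sites = sites, windows = windows,
       singleton_fraction = if (nrow(windows))
         mean(windows$n_sites == 1L) else NA_real_)
}
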