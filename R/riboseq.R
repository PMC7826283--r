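## Ribosome-profiling analysis: periodicity and frame filtering, nine-codon
## position profiles (-5..+3, 0 = A-site), codon enrichment at the active
## sites, single-nucleotide P-site tracks, and motif positioning within
## footprints.
##
## Register. Reading the P-site offset of 12 as 0-based, read positions
## 1-27 (1-based) split into nine codons: codon 5 (read positions 13-15) is
## the P-site (-1) and codon 6 (16-18) the A-site (0).

.ALL_CODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1L,
                          paste, collapse = ""))
.PROFILE_POSITIONS <- -5:3

# 3' end of the coding span used by the overlap filter: the CDS extended by
# the annotated stop codon (when one sits right at cds_end)
.coding_end <- function(m, include_stop_codon = TRUE) {
  e <- m$cds_end
  if (include_stop_codon && nrow(m$stop_codons) &&
      any(m$stop_codons$offset == m$cds_end)) {
    e <- min(e + 3L, nchar(m$sequence))
  }
  as.integer(e)
}

#' Select periodic footprints by length, CDS overlap and frame
#'
#' Keeps reads whose length is in `lengths`, that overlap an annotated CDS
#' by at least `min_cds_overlap` of the read length, and whose 5'-end frame
#' (relative to the CDS start) equals the expected frame for that read
#' length. Expected frames are learned as the modal frame per length unless
#' supplied.
#'
#' The coding span used for the overlap filter includes the annotated stop
#' codon (`include_stop_codon = TRUE`): footprints dwelling at termination
#' with the stop codon in the P- or A-site are part of translation and must
#' survive selection for the active-site codon analyses.
#'
#' @param alignments data.frame of aligned footprints (contig, pos, length).
#' @param models named list of transcript models, keyed by contig.
#' @param lengths retained footprint lengths.
#' @param min_cds_overlap minimum CDS overlap as a fraction of read length.
#' @param expected_frames optional named integer vector (names = lengths).
#' @param include_stop_codon extend the coding span by the annotated stop
#'   codon for the overlap computation.
#' @return list(kept, stats, expected_frames); stats counts drops at every
#'   filter so kept + dropped = input.
#' @export
select_periodic_reads <- function(alignments, models, lengths = 27:29,
                                  min_cds_overlap = 0.5,
                                  expected_frames = NULL,
                                  include_stop_codon = TRUE) {
  n_input <- nrow(alignments)
  len_ok <- alignments$length %in% lengths
  a <- alignments[len_ok, , drop = FALSE]
  cds_start <- vapply(a$contig, function(ct) {
    m <- models[[ct]]
    if (is.null(m) || m$cds_end <= m$cds_start) NA_integer_ else m$cds_start
  }, integer(1L))
  cds_end <- vapply(a$contig, function(ct) {
    m <- models[[ct]]
    if (is.null(m) || m$cds_end <= m$cds_start) return(NA_integer_)
    .coding_end(m, include_stop_codon)
  }, integer(1L))
  no_cds <- is.na(cds_start)
  ov <- pmax(0L, pmin(a$pos + a$length, cds_end) - pmax(a$pos, cds_start))
  ov_ok <- !no_cds & ov >= min_cds_overlap * a$length
  b <- a[ov_ok, , drop = FALSE]
  frame <- (b$pos - cds_start[ov_ok]) %% 3L
  if (is.null(expected_frames)) {
    expected_frames <- vapply(split(frame, b$length), function(f) {
      as.integer(names(which.max(table(f))))
    }, integer(1L))
  }
  frame_ok <- frame == expected_frames[as.character(b$length)]
  kept <- b[frame_ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       stats = list(n_input = n_input, n_bad_length = sum(!len_ok),
                    n_no_cds = sum(no_cds), n_low_overlap = sum(!ov_ok & !no_cds),
                    n_bad_frame = sum(!frame_ok), n_kept = nrow(kept)),
       expected_frames = expected_frames)
}

#' Per-length frame distribution of footprint 5' ends
#'
#' For each read length, counts 5' ends per frame (0/1/2) relative to the
#' CDS start, over CDS-overlapping reads, and reports the dominant-frame
#' fraction — the periodicity evidence used to pick footprint lengths.
#'
#' @param alignments data.frame of aligned footprints.
#' @param models named list of transcript models.
#' @param min_cds_overlap minimum CDS overlap fraction.
#' @param include_stop_codon see [select_periodic_reads()].
#' @return data.frame(length, frame0, frame1, frame2, dominant_fraction).
#' @export
periodicity_report <- function(alignments, models, min_cds_overlap = 0.5,
                               include_stop_codon = TRUE) {
  empty <- data.frame(length = integer(0), frame0 = integer(0),
                      frame1 = integer(0), frame2 = integer(0),
                      dominant_fraction = numeric(0))
  if (!nrow(alignments)) return(empty)
  cds_start <- vapply(alignments$contig, function(ct) {
    m <- models[[ct]]
    if (is.null(m) || m$cds_end <= m$cds_start) NA_integer_ else m$cds_start
  }, integer(1L))
  cds_end <- vapply(alignments$contig, function(ct) {
    m <- models[[ct]]
    if (is.null(m) || m$cds_end <= m$cds_start) return(NA_integer_)
    .coding_end(m, include_stop_codon)
  }, integer(1L))
  ov <- pmax(0L, pmin(alignments$pos + alignments$length, cds_end) -
               pmax(alignments$pos, cds_start))
  keep <- !is.na(cds_start) & ov >= min_cds_overlap * alignments$length
  if (!any(keep)) return(empty)
  frame <- (alignments$pos[keep] - cds_start[keep]) %% 3L
  len <- alignments$length[keep]
  out <- lapply(sort(unique(len)), function(L) {
    f <- tabulate(frame[len == L] + 1L, nbins = 3L)
    data.frame(length = L, frame0 = f[1L], frame1 = f[2L], frame2 = f[3L],
               dominant_fraction = max(f) / sum(f))
  })
  do.call(rbind, out)
}

#' Nine-codon position profile from frame-validated footprints
#'
#' Read positions 1-27 are split into nine codons at positions -5..+3
#' (0 = A-site); codon identities are read from the transcript sequence
#' under the footprint. Reads shorter than 27 nt are skipped and counted.
#'
#' @param filtered_reads data.frame from [select_periodic_reads()].
#' @param models named list of transcript models.
#' @return object of class `CodonProfile`: list with `counts` (64 x 9),
#'   `fraction` (per-position fractions summing to 1), `normalized`
#'   (fraction over per-codon mean fraction), `n_reads`, `n_skipped`.
#' @export
extract_codon_profile <- function(filtered_reads, models) {
  counts <- matrix(0L, 64L, 9L,
                   dimnames = list(.ALL_CODONS,
                                   as.character(.PROFILE_POSITIONS)))
  ok <- filtered_reads$length >= 27L
  n_skipped <- sum(!ok)
  fr <- filtered_reads[ok, , drop = FALSE]
  if (nrow(fr)) {
    # vectorized: one substring call per codon position over all reads
    seq_by_contig <- vapply(models, `[[`, "", "sequence")
    s <- seq_by_contig[fr$contig]
    for (j in seq_len(9L)) {
      st <- fr$pos + 3L * (j - 1L)
      cod <- substring(s, st + 1L, st + 3L)
      tab <- table(factor(cod, levels = .ALL_CODONS))
      counts[, j] <- counts[, j] + as.integer(tab)
    }
  }
  fraction <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  rowm <- rowMeans(fraction)
  normalized <- fraction / ifelse(rowm > 0, rowm, NA_real_)
  structure(list(counts = counts, fraction = fraction,
                 normalized = normalized, n_reads = nrow(fr),
                 n_skipped = n_skipped), class = "CodonProfile")
}

#' @export
print.CodonProfile <- function(x, ...) {
  cat(sprintf("CodonProfile: %d reads, positions %s (0 = A-site)\n",
              x$n_reads, paste(range(.PROFILE_POSITIONS), collapse = "..")))
  invisible(x)
}

#' Codon enrichment between two conditions at the ribosome active sites
#'
#' log2 ratio of normalized codon counts (knockout over control), computed
#' after adding a pseudocount to the raw counts. Codons with zero raw
#' counts in both profiles at a position are NA. The E/P/A slice (positions
#' -2/-1/0) is returned as the headline view.
#'
#' @param profile_ko,profile_ctrl `CodonProfile` objects built identically.
#' @param pseudocount added to raw counts before fractions.
#' @return list with `enrichment` (64 x 9 matrix of log2 ratios) and `epa`
#'   (the positions -2..0 slice).
#' @export
codon_enrichment <- function(profile_ko, profile_ctrl, pseudocount = 0.5) {
  renorm <- function(counts) {
    cts <- counts + pseudocount
    fraction <- sweep(cts, 2L, colSums(cts), "/")
    fraction / rowMeans(fraction)
  }
  e <- log2(renorm(profile_ko$counts) / renorm(profile_ctrl$counts))
  both_zero <- profile_ko$counts == 0L & profile_ctrl$counts == 0L
  e[both_zero] <- NA_real_
  list(enrichment = e, epa = e[, c("-2", "-1", "0"), drop = FALSE])
}

#' Single-nucleotide P-site coverage track
#'
#' Each footprint contributes 1 at its 5' end plus `offset` (0-based, on
#' the read's strand); reads shorter than the offset are skipped. Strands
#' are kept separate.
#'
#' @param alignments data.frame of aligned footprints.
#' @param offset 5'-end-to-P-site offset in nt.
#' @return data.frame(contig, pos, strand, value) — a per-position track.
#' @export
psite_coverage_track <- function(alignments, offset = 12L) {
  ok <- alignments$length > offset
  a <- alignments[ok, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), value = numeric(0)))
  }
  psite <- ifelse(a$strand == "+", a$pos + offset,
                  a$pos + a$length - 1L - offset)
  dt <- data.table::data.table(contig = a$contig, pos = psite,
                               strand = a$strand)
  agg <- dt[, .(value = as.numeric(.N)), by = .(contig, pos, strand)]
  data.table::setorder(agg, contig, strand, pos)
  as.data.frame(agg)[, c("contig", "pos", "strand", "value")]
}

#' Motif start positions within footprints
#'
#' For each frame-validated footprint, records the read positions (1-based,
#' 1..27) where the motif begins, and normalizes counts by the number of
#' reads.
#'
#' @param filtered_reads data.frame from [select_periodic_reads()] with a
#'   `query` column (footprint sequence).
#' @param pattern motif regular expression.
#' @return data.frame(position, count, fraction) over positions 1..27.
#' @export
motif_position_in_footprint <- function(filtered_reads, pattern = "CTCCA") {
  counts <- integer(27L)
  n <- nrow(filtered_reads)
  for (i in seq_len(n)) {
    hits <- scan_motif(filtered_reads$query[i], pattern)
    if (!nrow(hits)) next
    p1 <- hits$start + 1L
    p1 <- p1[p1 <= 27L]
    counts[p1] <- counts[p1] + 1L
  }
  data.frame(position = 1:27, count = counts,
             fraction = if (n > 0L) counts / n else rep(0, 27L))
}

#' Compare motif positioning between two footprint sets
#'
#' Per read position, a two-proportion test of motif occurrence between
#' conditions, Benjamini-Hochberg corrected.
#'
#' @param tab_a,tab_b data.frames from [motif_position_in_footprint()].
#' @param n_a,n_b number of reads in each set.
#' @return data.frame(position, fraction_a, fraction_b, p, q).
#' @export
compare_motif_positions <- function(tab_a, tab_b, n_a, n_b) {
  p <- vapply(seq_len(27L), function(i) {
    x <- c(tab_a$count[i], tab_b$count[i])
    if (sum(x) == 0L) return(NA_real_)
    suppressWarnings(prop.test(x, c(n_a, n_b))$p.value)
  }, numeric(1L))
  data.frame(position = 1:27, fraction_a = tab_a$fraction,
             fraction_b = tab_b$fraction, p = p,
             q = p.adjust(p, method = "BH"))
}
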