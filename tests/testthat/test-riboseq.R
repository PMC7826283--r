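test_that("periodic read selection filters length, overlap and frame", {
  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, include_readthrough = FALSE, seed = 81L)
  sel <- select_periodic_reads(fp, tr$models)
  # clean simulation: every in-length read passes overlap + frame
  expect_identical(sel$stats$n_bad_frame, 0L)
  expect_identical(nrow(sel$kept) + sel$stats$n_bad_length +
                     sel$stats$n_no_cds + sel$stats$n_low_overlap +
                     sel$stats$n_bad_frame, nrow(fp))
  expect_true(all(sel$expected_frames == 0L))

  # a read overlapping the coding span by less than half is dropped
  m <- tr$models[[1L]]
  low <- data.frame(read_id = "x", contig = m$transcript_id,
                    pos = m$cds_start - 14L, strand = "+", length = 27L,
                    mismatches = 0L, query = strrep("A", 27L))
  sel2 <- select_periodic_reads(low, tr$models,
                                expected_frames = c(`27` = 0L))
  expect_identical(nrow(sel2$kept), 0L)
  expect_identical(sel2$stats$n_low_overlap, 1L)

  # frame-shuffled placement: about a third survives the frame filter
  set.seed(82)
  n <- 3000L
  pos <- m$cds_start + sample(0:(m$cds_end - m$cds_start - 30L), n,
                              replace = TRUE)
  shuf <- data.frame(read_id = sprintf("s%d", seq_len(n)),
                     contig = m$transcript_id, pos = pos, strand = "+",
                     length = 27L, mismatches = 0L, query = strrep("A", 27L))
  sel3 <- select_periodic_reads(shuf, tr$models,
                                expected_frames = c(`27` = 0L))
  expect_lt(abs(nrow(sel3$kept) / n - 1 / 3), 3 * sqrt(2 / 9 / n))
})

test_that("periodicity_report measures frame dominance", {
  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, include_readthrough = FALSE, seed = 83L)
  rep1 <- periodicity_report(fp, tr$models)
  expect_setequal(rep1$length, 27:29)
  expect_true(all(rep1$dominant_fraction == 1))

  # uniform placement: dominant fraction near 1/3
  m <- tr$models[[2L]]
  set.seed(84)
  n <- 3000L
  unif <- data.frame(read_id = sprintf("u%d", seq_len(n)),
                     contig = m$transcript_id,
                     pos = m$cds_start + sample(0:(m$cds_end - m$cds_start -
                                                     30L), n, replace = TRUE),
                     strand = "+", length = 28L, mismatches = 0L,
                     query = strrep("A", 28L))
  rep2 <- periodicity_report(unif, tr$models)
  expect_lt(rep2$dominant_fraction, 0.38)
  expect_identical(nrow(periodicity_report(fp[0, ], tr$models)), 0L)
})

test_that("codon profile identities hold and register is correct", {
  # a transcript that is AAA codons throughout
  seq27 <- strrep("AAA", 30L)
  m <- transcript_model("t", "g", "t", "+", seq27, 12L, 72L,
                        stop_codons = data.frame(offset = integer(0),
                                                 codon = character(0)))
  rd <- data.frame(read_id = "r", contig = "t", pos = 12L, strand = "+",
                   length = 27L, mismatches = 0L,
                   query = substring(seq27, 13L, 39L))
  prof <- extract_codon_profile(rd, list(t = m))
  expect_identical(sum(prof$counts["AAA", ]), 9L)
  expect_true(all(prof$counts["AAA", ] == 1L))
  # conservation: per-position column sums equal contributing reads
  expect_true(all(colSums(prof$counts) == prof$n_reads))
  # reads shorter than 27 nt are skipped with a count
  rd$length <- 26L
  expect_identical(extract_codon_profile(rd, list(t = m))$n_skipped, 1L)

  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, include_readthrough = FALSE, seed = 85L)
  sel <- select_periodic_reads(fp, tr$models)
  prof <- extract_codon_profile(sel$kept, tr$models)
  expect_equal(colSums(prof$fraction), rep(1, 9L), ignore_attr = TRUE)
  rm <- rowMeans(prof$normalized)
  expect_equal(rm[is.finite(rm)], rep(1, sum(is.finite(rm))),
               ignore_attr = TRUE)

  # terminating footprints (A-site at the annotated stop) read a stop codon
  # at position 0, and the codon 5' of the stop at position -1
  stops <- c("TAA", "TAG", "TGA")
  term <- sel$kept[mapply(function(ct, p) {
    p == tr$models[[ct]]$cds_end - 15L
  }, sel$kept$contig, sel$kept$pos), , drop = FALSE]
  expect_gt(nrow(term), 0L)
  a_codon <- substring(tr$sequences[term$contig], term$pos + 16L,
                       term$pos + 18L)
  expect_true(all(a_codon %in% stops))
  p_codon <- substring(tr$sequences[term$contig], term$pos + 13L,
                       term$pos + 15L)
  before_stop <- substring(tr$sequences[term$contig],
                           vapply(term$contig,
                                  function(ct) tr$models[[ct]]$cds_end - 2L,
                                  integer(1L)),
                           vapply(term$contig,
                                  function(ct) tr$models[[ct]]$cds_end,
                                  integer(1L)))
  expect_identical(p_codon, before_stop)
})

test_that("codon enrichment is zero on identity and antisymmetric on swap", {
  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, seed = 86L)
  sel <- select_periodic_reads(fp, tr$models)
  prof <- extract_codon_profile(sel$kept, tr$models)
  e_same <- codon_enrichment(prof, prof)$enrichment
  expect_true(all(e_same[!is.na(e_same)] == 0))

  fp2 <- simulate_ribo_footprints(tr, terminal_dwell = 3L, seed = 87L)
  prof2 <- extract_codon_profile(select_periodic_reads(fp2, tr$models)$kept,
                                 tr$models)
  e12 <- codon_enrichment(prof2, prof)$enrichment
  e21 <- codon_enrichment(prof, prof2)$enrichment
  expect_equal(e12, -e21)
})

test_that("P-site track arithmetic and conservation", {
  aln <- data.frame(read_id = "r", contig = "c", pos = 100L, strand = "+",
                    length = 28L, mismatches = 0L, query = strrep("A", 28L))
  tr1 <- psite_coverage_track(aln)
  expect_identical(tr1$pos, 112L)
  expect_identical(tr1$value, 1)

  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, include_readthrough = FALSE, seed = 88L)
  track <- psite_coverage_track(fp)
  expect_identical(sum(track$value), as.numeric(nrow(fp)))
  # no P-site signal strictly downstream of the dwell position
  for (ct in unique(track$contig)) {
    expect_lte(max(track$pos[track$contig == ct]),
               tr$models[[ct]]$cds_end)
  }
  # a read shorter than the offset is skipped
  expect_identical(nrow(psite_coverage_track(
    data.frame(read_id = "x", contig = "c", pos = 0L, strand = "+",
               length = 10L, mismatches = 0L, query = strrep("A", 10L)),
    offset = 12L)), 0L)
})

test_that("motif positioning within footprints is counted and compared", {
  rd <- data.frame(read_id = c("a", "b"), contig = "c", pos = 0L,
                   strand = "+", length = 27L, mismatches = 0L,
                   query = c(strrep("A", 27L),
                             paste0("ACTCCA", strrep("G", 21L))))
  tab <- motif_position_in_footprint(rd)
  expect_identical(tab$count[tab$position == 2L], 1L)
  expect_identical(sum(tab$count), 1L)
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  none <- motif_position_in_footprint(rd[1L, , drop = FALSE])
  expect_true(all(none$count == 0L))

  cmp <- compare_motif_positions(tab, none, 2L, 1L)
  expect_identical(nrow(cmp), 27L)
  expect_true(all(is.na(cmp$p) | (cmp$q >= cmp$p - 1e-12)))
})
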