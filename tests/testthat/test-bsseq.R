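test_that("three-letter alignment is conversion-invariant", {
  ref <- c(r = paste0("GATTACAGGCCTTACGGATCCAGTACCGGTTAACCGTA",
                      "GGCTTACGATCAGGTACCATGGCA"))
  frag <- substring(ref[["r"]], 11L, 40L)
  fully <- chartr("C", "T", frag)
  reads <- data.frame(read_id = c("full", "one_c", "bad"),
                      sequence = c(fully, frag, fully), stringsAsFactors = FALSE)
  # three true mismatches (in collapsed space) on the third read
  v <- strsplit(reads$sequence[3L], "")[[1L]]
  swap <- c(2L, 12L, 25L)
  v[swap] <- chartr("AGT", "GAA", v[swap])
  reads$sequence[3L] <- paste(v, collapse = "")
  res <- align_bs_reads(reads, ref)
  expect_setequal(res$aligned$read_id, c("full", "one_c"))
  expect_true(all(res$aligned$mismatches == 0L))
  expect_true(all(res$aligned$pos == 10L))
  expect_identical(res$unaligned$read_id, "bad")
  # conservation: aligned + unaligned + ambiguous = input
  expect_identical(res$stats$n_aligned + res$stats$n_unaligned +
                     res$stats$n_ambiguous, res$stats$n_input)
})

test_that("the CCA-trim retry rescues tail-bearing reads only", {
  body <- "GGATTACCGTAGGCTAACGGATCAGGTACC"
  ref <- c(t = body)
  reads <- data.frame(read_id = c("cca", "junk"),
                      sequence = c(paste0(chartr("C", "T", body), "CCA"),
                                   strrep("ACGT", 10L)),
                      stringsAsFactors = FALSE)
  p1 <- align_bs_reads(reads, ref)
  expect_identical(nrow(p1$aligned), 0L)
  p2 <- retry_cca_trim(p1$unaligned, ref)
  expect_identical(p2$aligned$read_id, "cca")
  expect_true(all(p2$aligned$cca_trimmed))
  expect_identical(p2$unaligned$read_id, "junk")
  # too-short reads after trimming are discarded
  shorty <- data.frame(read_id = "s", sequence = strrep("A", 20L))
  expect_identical(retry_cca_trim(shorty, ref)$stats$n_too_short, 1L)
})

test_that("the >1/3 artifact filter uses a strict boundary", {
  ref <- c(r = "ACACACACAC")  # Cs at 0-based 1,3,5,7,9
  mk <- function(q) data.frame(read_id = "x", contig = "r", pos = 0L,
                               strand = "+", length = nchar(q),
                               mismatches = 0L, query = q,
                               stringsAsFactors = FALSE)
  # 4 Cs covered, 2 unconverted: 0.5 > 1/3 -> discarded
  r <- filter_conversion_artifacts(mk("ACATACATA"), ref)
  expect_identical(nrow(r$kept), 0L)
  # 3 Cs covered, 1 unconverted: exactly 1/3 -> kept
  r <- filter_conversion_artifacts(mk("ACATAT"), ref)
  expect_identical(nrow(r$kept), 1L)
  # no C covered -> kept
  ref2 <- c(r = "AGAGAGAG")
  r <- filter_conversion_artifacts(mk("AGAG"), ref2)
  expect_identical(nrow(r$kept), 1L)
})

test_that("simulated artifact reads are all removed; others mostly kept", {
  tr <- small_transcriptome()
  rd <- simulate_bs_reads(tr, coverage = 30L, conversion_rate = 0.995,
                          artifact_fraction = 0.2, seed = 61L)
  aln <- align_bs_reads(rd, tr$sequences)
  flt <- filter_conversion_artifacts(aln$aligned, tr$sequences)
  art_ids <- rd$read_id[rd$artifact]
  # every aligned artifact read (they all span the motif, so >= 2 Cs) drops
  expect_true(all(!flt$kept$read_id %in% art_ids))
  expect_identical(flt$stats$n_kept + flt$stats$n_discarded,
                   flt$stats$n_input)
})

test_that("extract_methylation counts reference cytosines", {
  ref <- c(r = "AACGTACGTA")
  reads <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(read_id = sprintf("r%d", i), contig = "r", pos = 0L,
               strand = "+", length = 10L, mismatches = 0L,
               query = "AACGTACGTA", stringsAsFactors = FALSE)
  }))
  out <- extract_methylation(reads, ref)
  expect_identical(out$pos, c(2L, 6L))
  expect_true(all(out$n_meth == 10L & out$n_unmeth == 0L & out$level == 1))
  # converted reads count as unmethylated; uncovered positions are absent
  reads$query <- "AATGTACGTA"
  out <- extract_methylation(reads[1:4, ], ref)
  expect_identical(out$n_unmeth[out$pos == 2L], 4L)
  expect_identical(out$n_meth[out$pos == 6L], 4L)
  short <- reads[1L, ]; short$query <- "AACGT"; short$length <- 5L
  expect_false(6L %in% extract_methylation(short, ref)$pos)
})

test_that("build_trna_reference filters copies and assembles contigs", {
  models <- list(
    list(name = "tRNA-Ala-AGC-9-1", sequence = "GGGACG", introns = NULL),
    list(name = "tRNA-Ala-AGC-9-2", sequence = "GGGACG", introns = NULL))
  out <- build_trna_reference(models)
  expect_length(out, 1L)
  expect_identical(out[["tRNA-Ala-AGC-9-1"]], "NNGGGACGCCANN")

  # intron splicing: final length = exons + 3 (CCA) + 4 (N flanks)
  withint <- list(list(name = "tRNA-Thr-ACG-1-1",
                       sequence = paste0(strrep("A", 10L), "GTGTG",
                                         strrep("G", 10L)),
                       introns = list(c(10L, 15L))))
  out <- build_trna_reference(withint)
  expect_identical(nchar(out[[1L]]), 20L + 3L + 4L)
  expect_identical(out[[1L]], paste0("NN", strrep("A", 10L), strrep("G", 10L),
                                     "CCA", "NN"))
  expect_warning(build_trna_reference(list(list(name = "oops",
                                                sequence = "AAA",
                                                introns = NULL))),
                 "malformed")
})

test_that("tRNA multi-mapper resolution picks fewest mismatches, then random", {
  aln <- data.frame(read_id = c("r", "r", "r"), contig = c("a", "b", "c"),
                    pos = 0L, mismatches = c(1L, 0L, 2L),
                    stringsAsFactors = FALSE)
  expect_identical(resolve_trna_multimappers(aln, seed = 1L)$contig, "b")
  one <- aln[1L, ]
  expect_identical(resolve_trna_multimappers(one, seed = 1L), one)

  # two equal-best alignments: ~50% each over many seeded reads
  n <- 4000L
  big <- data.frame(read_id = rep(sprintf("r%04d", seq_len(n)), each = 2L),
                    contig = rep(c("a", "b"), n), pos = 0L, mismatches = 0L,
                    stringsAsFactors = FALSE)
  res <- resolve_trna_multimappers(big, seed = 2L)
  frac_a <- mean(res$contig == "a")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / n))
})

test_that("site quantification shifts, dedups, caps, and partitions", {
  ref <- c(r = paste0(strrep("A", 10L), "CTCCA", strrep("A", 10L)))
  cc <- data.frame(contig = "r", pos = 10L, strand = "+", n_meth = 6L,
                   n_unmeth = 4L, level = 0.6, stringsAsFactors = FALSE)
  # one site, 10 reads 6 methylated, cap 5 -> contributes (3, 5), level 0.6
  q <- quantify_site_methylation(data.frame(contig = "r", pos = 10L), cc, ref)
  expect_identical(q$per_site$capped_meth, 3)
  expect_identical(q$per_site$capped_total, 5L)
  expect_identical(q$per_site$capped_level, 0.6)
  expect_identical(q$per_site$level, 0.6)

  # two sites near the same motif collapse to one after shift + dedup
  q2 <- quantify_site_methylation(data.frame(contig = "r", pos = c(9L, 11L)),
                                  cc, ref)
  expect_identical(nrow(q2$sites), 1L)
  expect_identical(q2$sites$pos, 10L)
  expect_true(q2$sites$motif)

  # motif / non-motif subsets partition the input sites
  ref2 <- c(r = paste0(strrep("A", 10L), "CTCCA", strrep("A", 10L),
                       "CAAAA", strrep("G", 5L)))
  cc2 <- rbind(cc, data.frame(contig = "r", pos = 25L, strand = "+",
                              n_meth = 1L, n_unmeth = 3L, level = 0.25))
  q3 <- quantify_site_methylation(
    data.frame(contig = "r", pos = c(10L, 25L)), cc2, ref2)
  expect_identical(sort(q3$sites$motif), c(FALSE, TRUE))
  expect_setequal(unique(q3$profile$motif), c(FALSE, TRUE))

  # a site with no covered C in context is flagged with an empty profile
  q4 <- quantify_site_methylation(data.frame(contig = "r", pos = 25L),
                                  cc[0, ], ref2)
  expect_true(q4$sites$flagged)
})

test_that("capping preserves every site's methylated fraction exactly", {
  set.seed(71)
  for (i in 1:200) {
    n_meth <- sample(0:60, 1L)
    n_unmeth <- sample(0:60, 1L)
    total <- n_meth + n_unmeth
    if (total == 0L) next
    ref <- c(r = paste0(strrep("A", 10L), "CTCCA", strrep("A", 10L)))
    cc <- data.frame(contig = "r", pos = 10L, strand = "+",
                     n_meth = n_meth, n_unmeth = n_unmeth,
                     level = n_meth / total)
    q <- quantify_site_methylation(data.frame(contig = "r", pos = 10L),
                                   cc, ref)
    ps <- q$per_site
    # exact rational identity: capped_meth/(den * capped_total) == m/t
    expect_identical(ps$capped_meth_num * total,
                     n_meth * ps$capped_meth_den * ps$capped_total)
    expect_identical(ps$capped_level, ps$level)
    expect_lte(ps$capped_total, 5L)
  }
})
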