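test_that("make_transcriptome plants exactly one 3'UTR motif per transcript", {
  tr <- make_transcriptome(n_genes = 10L, motif_fraction = 1, seed = 1L)
  ps <- tr$truth$planted_sites
  expect_identical(nrow(ps), 10L)
  for (i in seq_len(nrow(ps))) {
    m <- tr$models[[ps$transcript_id[i]]]
    expect_identical(substring(m$sequence, ps$pos[i] + 1L, ps$pos[i] + 5L),
                     "CTCCA")
    expect_gte(ps$pos[i], m$cds_end + 3L)  # in the 3'UTR, past the stop
  }
  # CDS invariants: length divisible by 3, annotated stop right after
  for (m in tr$models) {
    expect_identical((m$cds_end - m$cds_start) %% 3L, 0L)
    expect_true(substring(m$sequence, m$cds_end + 1L, m$cds_end + 3L) %in%
                  c("TAA", "TAG", "TGA"))
    # ORF carries no premature in-frame stop
    starts <- seq.int(m$cds_start, m$cds_end - 3L, by = 3L)
    codons <- substring(m$sequence, starts + 1L, starts + 3L)
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("motif_fraction 0 plants nothing; incidental hits are recorded", {
  tr <- make_transcriptome(n_genes = 10L, motif_fraction = 0, seed = 2L)
  expect_identical(nrow(tr$truth$planted_sites), 0L)
  # incidental occurrences (if any) are exactly the scan hits
  for (tid in names(tr$sequences)) {
    hits <- scan_motif(tr$sequences[[tid]])
    inc <- tr$truth$incidental_motifs
    expect_setequal(hits$start, inc$pos[inc$transcript_id == tid])
  }
})

test_that("generators are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_transcriptome(make_transcriptome(n_genes = 6L, seed = 9L), d1)
  write_transcriptome(make_transcriptome(n_genes = 6L, seed = 9L), d2)
  for (f in c("transcriptome.fa", "transcriptome.gtf", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  tr <- make_transcriptome(n_genes = 6L, seed = 9L)
  expect_identical(simulate_miclip_reads(tr, depth = 20L, seed = 3L),
                   simulate_miclip_reads(tr, depth = 20L, seed = 3L))
  expect_identical(simulate_bs_reads(tr, coverage = 10L, seed = 3L),
                   simulate_bs_reads(tr, coverage = 10L, seed = 3L))
  expect_identical(simulate_ribo_footprints(tr, seed = 3L),
                   simulate_ribo_footprints(tr, seed = 3L))
  s1 <- simulate_counts(n_genes = 50L, seed = 3L)
  s2 <- simulate_counts(n_genes = 50L, seed = 3L)
  expect_identical(s1$rna, s2$rna)
  expect_identical(s1$ribo, s2$ribo)
})

test_that("miCLIP reads follow the truncation and duplication model", {
  tr <- small_transcriptome()
  ps <- tr$truth$planted_sites
  # pcr_dup_rate 0.5: raw reads ~ 2x depth, brute-force dedup recovers depth
  reads <- simulate_miclip_reads(tr, depth = 40L, pcr_dup_rate = 0.5,
                                 noise_rate = 0, seed = 5L)
  expect_identical(nrow(reads), 80L * nrow(ps))
  expect_identical(oracle_dedup(reads$sequence), 40L * nrow(ps))

  # pcr_dup_rate 0: dedup is the identity
  reads0 <- simulate_miclip_reads(tr, depth = 25L, pcr_dup_rate = 0,
                                  noise_rate = 0, seed = 6L)
  expect_identical(oracle_dedup(reads0$sequence), nrow(reads0))

  # noise_rate 0: every insert starts 1 nt downstream of a planted C
  ins <- substring(reads0$sequence, 11L)
  expected <- unlist(lapply(seq_len(nrow(ps)), function(i) {
    substring(tr$sequences[[ps$transcript_id[i]]], ps$pos[i] + 2L,
              ps$pos[i] + 36L)
  }))
  expect_true(all(ins %in% expected))
})

test_that("bisulfite reads encode stoichiometry and artifacts", {
  tr <- small_transcriptome()
  ps <- tr$truth$planted_sites
  # full conversion, full stoichiometry, no artifacts
  rd <- simulate_bs_reads(tr, coverage = 5L, conversion_rate = 1,
                          artifact_fraction = 0,
                          stoichiometry_override = 1, seed = 7L)
  for (i in seq_len(nrow(rd))) {
    orig <- substring(tr$sequences[[rd$true_contig[i]]], rd$true_pos[i] + 1L,
                      rd$true_pos[i] + 50L)
    p <- ps$pos[ps$transcript_id == rd$true_contig[i]][1L]
    in_read <- p - rd$true_pos[i] + 1L
    v <- strsplit(rd$sequence[i], "")[[1L]]
    o <- strsplit(orig, "")[[1L]]
    cpos <- which(o == "C")
    expect_true(all(v[setdiff(cpos, in_read)] == "T"))
    expect_identical(v[in_read], "C")
  }
  # stoichiometry 0.5 at high coverage: binomial recovery at the site
  tr1 <- make_transcriptome(n_genes = 2L, motif_fraction = 1,
                            stoichiometries = 0.5, seed = 8L)
  rd <- simulate_bs_reads(tr1, coverage = 1000L, conversion_rate = 1,
                          artifact_fraction = 0, seed = 9L)
  p <- tr1$truth$planted_sites$pos[1L]
  tid <- tr1$truth$planted_sites$transcript_id[1L]
  sub <- rd[rd$true_contig == tid, ]
  site_base <- substring(sub$sequence, p - sub$true_pos + 1L,
                         p - sub$true_pos + 1L)
  frac <- mean(site_base == "C")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))

  # artifact reads keep every C
  rd <- simulate_bs_reads(tr1, coverage = 200L, artifact_fraction = 0.5,
                          seed = 10L)
  art <- rd[rd$artifact, ]
  orig <- substring(tr1$sequences[art$true_contig], art$true_pos + 1L,
                    art$true_pos + 50L)
  expect_identical(gsub("[^C]", "", art$sequence),
                   unname(gsub("[^C]", "", orig)))
  expect_lt(abs(mean(rd$artifact) - 0.5), 3 * sqrt(0.25 / nrow(rd)))
})

test_that("ribosome footprints respect the P-site walk and termination", {
  tr <- small_transcriptome()
  fp <- simulate_ribo_footprints(tr, include_readthrough = FALSE, seed = 3L)
  psite <- fp$pos + 12L
  cds_end <- vapply(fp$contig, function(ct) tr$models[[ct]]$cds_end,
                    integer(1L))
  cds_start <- vapply(fp$contig, function(ct) tr$models[[ct]]$cds_start,
                      integer(1L))
  expect_true(all(psite <= cds_end))  # nothing beyond the dwell position
  expect_true(all((psite - cds_start) %% 3L == 0L))

  # fixed length 28: a single 5'-end frame class
  fp28 <- simulate_ribo_footprints(tr, lengths = 28L,
                                   include_readthrough = FALSE, seed = 4L)
  frames <- (fp28$pos - cds_start[1L]) %% 3L
  expect_identical(length(unique((fp28$pos -
    vapply(fp28$contig, function(ct) tr$models[[ct]]$cds_start, integer(1L))
  ) %% 3L)), 1L)

  # readthrough transcripts: 3'UTR P-site coverage up to (not past) the motif
  fp_rt <- simulate_ribo_footprints(tr, include_readthrough = TRUE, seed = 5L)
  ps <- tr$truth$planted_sites
  rt <- ps[ps$readthrough, ]
  expect_gt(nrow(rt), 0L)
  for (i in seq_len(nrow(rt))) {
    m <- tr$models[[rt$transcript_id[i]]]
    sub <- fp_rt[fp_rt$contig == m$transcript_id, ]
    psites <- sub$pos + 12L
    utr <- psites[psites > m$cds_end]
    expect_gt(length(utr), 0L)                 # upstream 3'UTR coverage
    expect_true(all(psites < rt$pos[i]))       # nothing downstream of motif
  }
})

test_that("count matrices approach the planted fold changes", {
  sim <- simulate_counts(n_genes = 300L, de_fraction = 0, seed = 12L)
  expect_true(all(sim$truth$delta == 0))
  # Poisson limit: low dispersion + large means recover the true log2FC
  sim <- simulate_counts(n_genes = 400L, n_reps = 6L, dispersion = 1e-4,
                         de_fraction = 0.5, lfc_sd = 1,
                         mean_log2_range = c(11, 13), seed = 13L)
  ko <- sim$ribo[, sim$groups == "ko", drop = FALSE]
  ctrl <- sim$ribo[, sim$groups == "ctrl", drop = FALSE]
  est <- log2(rowMeans(ko) / rowMeans(ctrl))
  expect_lt(stats::median(abs(est - sim$truth$lfc_ribo)), 0.05)
})
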