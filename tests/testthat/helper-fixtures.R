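# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# small transcriptome used by several module tests
small_transcriptome <- function() {
  if (is.null(.fixture_env$tr)) {
    .fixture_env$tr <- make_transcriptome(
      n_genes = 20L, motif_fraction = 1, hairpin_fraction = 0.5,
      readthrough_fraction = 0.25, seed = 42L)
  }
  .fixture_env$tr
}

# brute-force miCLIP dedup oracle: unique (random barcode, insert) pairs
oracle_dedup <- function(sequences) {
  rb <- paste0(substring(sequences, 1, 3), substring(sequences, 8, 10))
  ins <- substring(sequences, 11)
  length(unique(paste(rb, ins)))
}

# brute-force truncation assignment oracle: enumerate the +/-2 window
oracle_truncation <- function(ref, p5, window = 2L) {
  if (p5 == 0L) return(NA_integer_)
  trunc <- p5 - 1L
  cand <- c(trunc, trunc - 1L, trunc + 1L, trunc - 2L, trunc + 2L)
  cand <- cand[seq_len(2L * window + 1L)]
  for (q in cand) {
    if (q < 0L || q >= nchar(ref)) next
    if (substring(ref, q + 1L, q + 1L) == "C") return(q)
  }
  NA_integer_
}

# brute-force overlapping motif scan oracle
oracle_scan <- function(s, words = c("CTCCA", "CTCTA")) {
  n <- nchar(s)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - 4L))) {
    if (substring(s, i, i + 4L) %in% words) hits <- c(hits, i - 1L)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
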