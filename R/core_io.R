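#' @import data.table
#' @importFrom stats sd quantile rnbinom rbinom runif setNames p.adjust pnorm
#'   dhyper phyper prop.test t.test
#' @importFrom utils head tail write.table read.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "contig", "pos", "strand", "value", "count", "kmer",
  "read_id", "mismatches", "insert", "random_barcode", "sample_id", "N",
  "codon", "position", "gene_id", "transcript_id", "rpm", "site_id",
  "run", "idx", "start", "end", "expbc", "meth", "n_meth", "n_unmeth",
  "capped_meth", "capped_total", "level", "offset", "motif", "window",
  "off", "seq_idx"
))

## ---------------------------------------------------------------------------
## Sequence utilities
## ---------------------------------------------------------------------------

#' Reverse complement of a DNA string
#'
#' Plain character implementation used everywhere internally; IUPAC codes
#' beyond ACGTN are left untouched by complementation.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Convert between 1-based closed and 0-based half-open intervals
#'
#' All internal coordinates are 0-based half-open. GTF on disk is 1-based
#' closed; BED/bedGraph are already 0-based half-open. These two helpers are
#' exact inverses of each other.
#'
#' @param start,end interval bounds in the source convention.
#' @return two-column matrix with converted `start`, `end`.
#' @export
gtf_to_internal <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname gtf_to_internal
#' @export
internal_to_gtf <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is normalized to `T`; duplicated
#' contig names are an error. Names are truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return named character vector, one element per record (possibly empty).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(setNames(character(0), character(0)))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- chartr("u", "t", toupper(as.character(seqs)))
  out <- chartr("U", "T", out)
  setNames(out, nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript model is the coordinate frame every downstream stage works
#' in: the spliced sequence in transcript orientation, half-open CDS offsets
#' within it, and the gene's annotated stop codons.
#'
#' @param transcript_id,gene_id,contig identifiers.
#' @param strand `"+"` or `"-"` (genomic strand of the transcript).
#' @param sequence spliced transcript sequence, transcript orientation.
#' @param cds_start,cds_end 0-based half-open CDS offsets in transcript
#'   coordinates; equal offsets denote a non-coding transcript.
#' @param stop_codons data.frame with columns `offset` (0-based transcript
#'   offset of the stop codon's first base) and `codon`.
#' @param cds_ok logical; FALSE flags a CDS whose length is not a multiple
#'   of three (kept, but warned about at parse time).
#' @return object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, sequence,
                             cds_start = 0L, cds_end = 0L,
                             stop_codons = data.frame(offset = integer(0),
                                                      codon = character(0)),
                             cds_ok = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(sequence)
  if (!(cds_start >= 0L && cds_start <= cds_end && cds_end <= n)) {
    stop("invalid CDS offsets for ", transcript_id)
  }
  if (nrow(stop_codons) &&
      !all(stop_codons$codon %in% c("TAA", "TAG", "TGA"))) {
    stop("stop codon not in {TAA, TAG, TGA} for ", transcript_id)
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, contig = contig,
    strand = strand, sequence = sequence,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    stop_codons = stop_codons, cds_ok = isTRUE(cds_ok)
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s, %s%s) %d nt, CDS [%d,%d), %d stop codon(s)\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nchar(x$sequence), x$cds_start, x$cds_end, nrow(x$stop_codons)))
  invisible(x)
}

#' Read transcript models from a GTF annotation and reference FASTA
#'
#' Understands `exon`, `CDS` and `stop_codon` features (1-based closed on
#' disk) and assembles transcript-space models with 0-based half-open
#' internal coordinates; minus-strand features are reverse-complemented into
#' transcript orientation. A CDS whose length is not divisible by three
#' triggers a warning and the model is flagged via `cds_ok = FALSE`.
#'
#' @param gtf_path GTF file path.
#' @param fasta reference sequences: a named character vector (as returned
#'   by [read_fasta()]) or a FASTA path.
#' @return named list of [transcript_model()] objects, keyed by transcript id.
#' @export
read_annotation <- function(gtf_path, fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fasta <- read_fasta(fasta)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  keep <- df$type %in% c("exon", "CDS", "stop_codon")
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(list())
  out <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    contig <- sub$seqnames[1L]
    strand <- sub$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    gid <- if ("gene_id" %in% names(sub)) sub$gene_id[1L] else tid
    if (!contig %in% names(fasta)) {
      stop("contig ", contig, " for transcript ", tid, " missing from FASTA")
    }
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    if (!nrow(ex)) ex <- data.frame(start = min(sub$start), end = max(sub$end))
    ex <- ex[order(ex$start), , drop = FALSE]
    # to internal 0-based half-open
    ex0 <- gtf_to_internal(ex$start, ex$end)
    seq_fwd <- paste(substring(fasta[[contig]], ex0[, 1L] + 1L, ex0[, 2L]),
                     collapse = "")
    tseq <- if (strand == "+") seq_fwd else revcomp(seq_fwd)

    g2t <- .genomic_to_transcript_fun(ex0, strand)
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    cds_ok <- TRUE
    if (nrow(cds)) {
      cds0 <- gtf_to_internal(cds$start, cds$end)
      cds_len <- sum(cds0[, 2L] - cds0[, 1L])
      # transcript offsets of all CDS bases' extremes
      t_lo <- min(g2t(cds0[, 1L]), g2t(cds0[, 2L] - 1L))
      t_hi <- max(g2t(cds0[, 1L]), g2t(cds0[, 2L] - 1L)) + 1L
      if (cds_len %% 3L != 0L) {
        warning("CDS length of ", tid, " not divisible by 3; flagged")
        cds_ok <- FALSE
      }
      cds_start <- t_lo; cds_end <- t_hi
    } else {
      cds_start <- cds_end <- 0L
    }
    sc <- sub[sub$type == "stop_codon", , drop = FALSE]
    stop_df <- data.frame(offset = integer(0), codon = character(0))
    if (nrow(sc)) {
      sc0 <- gtf_to_internal(sc$start, sc$end)
      offs <- vapply(seq_len(nrow(sc0)), function(i) {
        min(g2t(sc0[i, 1L]), g2t(sc0[i, 2L] - 1L))
      }, integer(1L))
      stop_df <- data.frame(
        offset = offs,
        codon = substring(tseq, offs + 1L, offs + 3L),
        stringsAsFactors = FALSE
      )
    }
    out[[tid]] <- transcript_model(tid, gid, contig, strand, tseq,
                                   cds_start, cds_end, stop_df, cds_ok)
  }
  out
}

# Returns a vectorized mapper genomic 0-based pos -> transcript 0-based offset
# for exons `ex0` (0-based half-open matrix, genomic order) on `strand`.
.genomic_to_transcript_fun <- function(ex0, strand) {
  widths <- ex0[, 2L] - ex0[, 1L]
  cum <- c(0L, cumsum(widths))
  total <- sum(widths)
  function(g) {
    vapply(g, function(p) {
      i <- which(p >= ex0[, 1L] & p < ex0[, 2L])
      if (!length(i)) stop("genomic position ", p, " outside exons")
      fwd <- cum[i] + (p - ex0[i, 1L])
      if (strand == "+") as.integer(fwd) else as.integer(total - 1L - fwd)
    }, integer(1L))
  }
}

#' Write transcript models to GTF
#'
#' Emits the exon/CDS/stop_codon dialect this package reads back (1-based
#' closed coordinates on disk). For the synthetic transcriptome each
#' transcript is a single exon spanning its own contig.
#'
#' @param models named list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                     m$transcript_id)
    n <- nchar(m$sequence)
    fmt <- function(type, s0, e0) {
      se <- internal_to_gtf(s0, e0)
      sprintf("%s\tm5Cmap\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$contig, type, se[1L], se[2L], m$strand, attr9)
    }
    lines <- c(lines, fmt("exon", 0L, n))
    if (m$cds_end > m$cds_start) {
      lines <- c(lines, fmt("CDS", m$cds_start, m$cds_end))
    }
    if (nrow(m$stop_codons)) {
      for (i in seq_len(nrow(m$stop_codons))) {
        o <- m$stop_codons$offset[i]
        lines <- c(lines, fmt("stop_codon", o, o + 3L))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## bedGraph (stands in for bigWig: textual, diffable, desk scale)
## ---------------------------------------------------------------------------

#' Write a per-position track as bedGraph
#'
#' The in-memory track representation throughout the package is a
#' data.frame with columns `contig`, `pos` (0-based), `value`. Adjacent
#' equal-valued positions are merged into half-open intervals on disk.
#'
#' @param track data.frame(contig, pos, value).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("contig", "pos", "value") %in% names(track)))
  dt <- data.table::as.data.table(track)[value != 0]
  data.table::setorder(dt, contig, pos)
  if (anyDuplicated(dt[, .(contig, pos)])) {
    stop("duplicate positions in track")
  }
  lines <- character(0)
  if (nrow(dt)) {
    dt[, run := cumsum(c(1L, (diff(pos) != 1L) | (head(value, -1L) != tail(value, -1L)))),
       by = contig]
    runs <- dt[, .(start = min(pos), end = max(pos) + 1L, value = value[1L]),
               by = .(contig, run)]
    lines <- sprintf("%s\t%d\t%d\t%s", runs$contig, runs$start, runs$end,
                     format(runs$value, trim = TRUE, scientific = FALSE))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a per-position track
#'
#' Intervals are expanded back to single positions; overlapping intervals
#' are an error.
#'
#' @param path bedGraph path.
#' @return data.frame(contig, pos, value), ordered by contig then position.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      value = numeric(0)))
  }
  parts <- data.table::fread(text = lines, header = FALSE,
                             col.names = c("contig", "start", "end", "value"))
  data.table::setorder(parts, contig, start)
  ov <- parts[, any(start[-1L] < head(end, -1L)), by = contig]$V1
  if (any(ov)) stop("overlapping intervals in bedGraph")
  out <- parts[, .(pos = seq.int(start, end - 1L), value = value),
               by = .(contig, idx = seq_len(nrow(parts)))]
  res <- as.data.frame(out[, .(contig, pos = as.integer(pos),
                               value = as.numeric(value))])
  res[order(res$contig, res$pos), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## SAM subset
## ---------------------------------------------------------------------------

#' Read a minimal SAM-subset alignment file
#'
#' Tab-separated SAM with header lines (`@`) ignored; only QNAME, FLAG
#' (bit 0x10 for minus strand, 0x4 for unmapped), RNAME, POS, SEQ and the
#' `NM:i:` tag are interpreted. CIGAR is assumed full-length match.
#'
#' @param path SAM path.
#' @return data.frame(read_id, contig, pos, strand, length, mismatches,
#'   query) with 0-based `pos`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.frame(read_id = character(0), contig = character(0),
                      pos = integer(0), strand = character(0),
                      length = integer(0), mismatches = integer(0),
                      query = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  recs <- lapply(fields, function(f) {
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)
    nm <- 0L
    tags <- f[-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (length(hit)) nm <- as.integer(sub("^NM:i:", "", hit[1L]))
    data.frame(read_id = f[1L], contig = f[3L],
               pos = as.integer(f[4L]) - 1L,
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
               length = nchar(f[10L]), mismatches = nm, query = f[10L],
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (!length(recs)) return(empty)
  do.call(rbind, recs)
}

#' Write alignments as a minimal SAM-subset file
#'
#' @param aln data.frame as returned by [read_sam()].
#' @param path output path.
#' @param contig_lengths optional named integer vector for `@SQ` headers.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  }
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       aln$read_id, flag, aln$contig, aln$pos + 1L,
                       nchar(aln$query), aln$query, aln$mismatches), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED6 sites
## ---------------------------------------------------------------------------

#' Read / write single-nucleotide site lists as BED6
#'
#' BED is 0-based half-open on disk; every interval must be 1 nt wide.
#'
#' @param sites data.frame(contig, pos, strand, name, score).
#' @param path file path.
#' @return for the reader, a data.frame(contig, pos, strand, name, score).
#' @export
write_bed_sites <- function(sites, path) {
  if (!nrow(sites)) { writeLines(character(0), path); return(invisible(path)) }
  name <- if ("name" %in% names(sites)) sites$name else "."
  score <- if ("score" %in% names(sites)) sites$score else 0
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", sites$contig, sites$pos,
                     sites$pos + 1L, name,
                     format(score, trim = TRUE, scientific = FALSE),
                     sites$strand), path)
  invisible(path)
}

#' @rdname write_bed_sites
#' @export
read_bed_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), name = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(text = lines, header = FALSE)
  if (any(dt[[3L]] - dt[[2L]] != 1L)) {
    stop("BED site intervals must be single-nucleotide")
  }
  data.frame(contig = as.character(dt[[1L]]), pos = as.integer(dt[[2L]]),
             strand = as.character(dt[[6L]]), name = as.character(dt[[4L]]),
             score = as.numeric(dt[[5L]]), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## FASTQ (constant placeholder qualities) and TSV count matrices
## ---------------------------------------------------------------------------

#' Read / write reads as FASTQ
#'
#' The simulators carry no quality model, so qualities are written as a
#' constant placeholder and ignored on read.
#'
#' @param reads data.frame(read_id, sequence).
#' @param path file path.
#' @return for the reader, a data.frame(read_id, sequence).
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      strrep("I", nchar(reads$sequence))), con)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(read_id = character(0), sequence = character(0)))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ")
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
             sequence = lines[c(FALSE, TRUE, FALSE, FALSE)],
             stringsAsFactors = FALSE)
}

#' Read / write gene count matrices as TSV
#'
#' Layout: a `gene_id` column followed by one column per sample.
#'
#' @param counts integer matrix with gene rownames.
#' @param path file path.
#' @return for the reader, a matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
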