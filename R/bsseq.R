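## Conversion-aware alignment, artifact filtering, methylation extraction,
## tRNA reference handling, and capped site-level quantification.
##
## Alignment happens in three-letter space (C collapsed to T in both read
## and reference), which makes it invariant to bisulfite conversion status;
## the original read is retained for the methylation calls.

.collapse_ct <- function(x) chartr("Cc", "Tt", x)

#' Align bisulfite reads to a small reference in three-letter space
#'
#' Seed-and-verify: reads and reference are C-to-T collapsed, candidate
#' positions come from 16-mer seeds placed so that `max_mismatches`
#' mismatches cannot break all of them, and candidates are verified over
#' the full read in collapsed space. A unique best alignment is required
#' unless `report = "all"` (used for the tRNA multi-mapper path).
#'
#' @param reads data.frame(read_id, sequence, ...); extra columns are
#'   carried through to the unaligned output.
#' @param reference named character vector of contig sequences
#'   (transcriptome scale).
#' @param max_mismatches maximum mismatches in collapsed space.
#' @param report `"unique"` (default) or `"all"` valid alignments.
#' @return list with `aligned` data.frame(read_id, contig, pos, strand,
#'   length, mismatches, query) where `query` is the ORIGINAL read;
#'   `unaligned` (input rows that found no valid alignment);
#'   `ambiguous` (rows dropped for multiple best hits, `report = "unique"`);
#'   and `stats`.
#' @export
align_bs_reads <- function(reads, reference, max_mismatches = 2L,
                           report = c("unique", "all")) {
  report <- match.arg(report)
  hits <- .batch_align(reads$sequence, reference, k = 16L,
                       max_mismatches = max_mismatches, report = report,
                       transform = .collapse_ct)
  i <- hits$aligned$seq_idx
  aligned <- if (length(i)) {
    data.frame(read_id = reads$read_id[i], contig = hits$aligned$contig,
               pos = hits$aligned$pos, strand = "+",
               length = nchar(reads$sequence[i]),
               mismatches = hits$aligned$mismatches,
               query = reads$sequence[i], stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(0), contig = character(0),
               pos = integer(0), strand = character(0), length = integer(0),
               mismatches = integer(0), query = character(0))
  }
  list(aligned = aligned,
       unaligned = reads[hits$unaligned_idx, , drop = FALSE],
       ambiguous = reads[hits$ambiguous_idx, , drop = FALSE],
       stats = list(n_input = nrow(reads),
                    n_aligned = length(unique(aligned$read_id)),
                    n_unaligned = length(hits$unaligned_idx),
                    n_ambiguous = length(hits$ambiguous_idx)))
}

#' Retry unaligned reads after trimming a potential tRNA CCA tail
#'
#' Removes the last three bases and realigns; reads shorter than
#' `min_length` after trimming are discarded. Never applied to reads that
#' aligned in the first pass.
#'
#' @param unaligned data.frame(read_id, sequence) of first-pass failures.
#' @param reference named character vector.
#' @param max_mismatches see [align_bs_reads()].
#' @param min_length minimum read length after trimming.
#' @return as [align_bs_reads()], with a `cca_trimmed` column on `aligned`
#'   and `n_too_short` in `stats`.
#' @export
retry_cca_trim <- function(unaligned, reference, max_mismatches = 2L,
                           min_length = 18L) {
  trimmed <- unaligned
  trimmed$sequence <- substring(trimmed$sequence, 1L,
                                pmax(0L, nchar(trimmed$sequence) - 3L))
  keep <- nchar(trimmed$sequence) >= min_length
  res <- align_bs_reads(trimmed[keep, , drop = FALSE], reference,
                        max_mismatches)
  if (nrow(res$aligned)) res$aligned$cca_trimmed <- TRUE
  res$stats$n_too_short <- sum(!keep)
  res
}

# per-read methylation tally against the reference: list(n_c, n_meth)
.read_meth_state <- function(query, ref_seq, pos) {
  L <- nchar(query)
  refs <- substring(ref_seq, pos + 1L, pos + L)
  rv <- strsplit(refs, "", fixed = TRUE)[[1L]]
  qv <- strsplit(query, "", fixed = TRUE)[[1L]]
  cpos <- which(rv == "C")
  list(cpos = cpos,
       meth = qv[cpos] == "C",
       unmeth = qv[cpos] == "T")
}

#' Discard likely conversion-resistant artifact reads
#'
#' A read is discarded iff the fraction of methylated (unconverted)
#' cytosines among the reference cytosines it covers is strictly greater
#' than `max_meth_fraction`. Reads covering no cytosine are kept.
#'
#' @param aligned data.frame from [align_bs_reads()].
#' @param reference named character vector.
#' @param max_meth_fraction discard threshold (strict >); default 1/3.
#' @return list(kept, discarded, stats).
#' @export
filter_conversion_artifacts <- function(aligned, reference,
                                        max_meth_fraction = 1 / 3) {
  drop <- logical(nrow(aligned))
  for (i in seq_len(nrow(aligned))) {
    st <- .read_meth_state(aligned$query[i], reference[[aligned$contig[i]]],
                           aligned$pos[i])
    n_c <- length(st$cpos)
    if (n_c == 0L) next
    drop[i] <- sum(st$meth) / n_c > max_meth_fraction
  }
  list(kept = aligned[!drop, , drop = FALSE],
       discarded = aligned[drop, , drop = FALSE],
       stats = list(n_input = nrow(aligned), n_kept = sum(!drop),
                    n_discarded = sum(drop)))
}

#' Extract per-cytosine methylation counts
#'
#' For every reference cytosine covered by a kept read: read C increments
#' `n_meth`, read T increments `n_unmeth`, other bases are treated as
#' mismatches and ignored. Positions never covered are absent.
#'
#' @param kept data.frame of filtered alignments.
#' @param reference named character vector.
#' @return data.frame(contig, pos, strand, n_meth, n_unmeth, level) with
#'   0-based `pos`, ordered by contig and position.
#' @export
extract_methylation <- function(kept, reference) {
  ctg <- list(); pp <- list(); mm <- list()
  for (i in seq_len(nrow(kept))) {
    st <- .read_meth_state(kept$query[i], reference[[kept$contig[i]]],
                           kept$pos[i])
    use <- st$meth | st$unmeth
    if (!any(use)) next
    ctg[[i]] <- rep(kept$contig[i], sum(use))
    pp[[i]] <- kept$pos[i] + st$cpos[use] - 1L
    mm[[i]] <- st$meth[use]
  }
  if (!length(ctg)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), n_meth = integer(0),
                      n_unmeth = integer(0), level = numeric(0)))
  }
  dt <- data.table::data.table(contig = unlist(ctg), pos = unlist(pp),
                               meth = unlist(mm))
  agg <- dt[, .(n_meth = sum(meth), n_unmeth = sum(!meth)),
            by = .(contig, pos)]
  data.table::setorder(agg, contig, pos)
  out <- as.data.frame(agg)
  out$strand <- "+"
  out$level <- out$n_meth / (out$n_meth + out$n_unmeth)
  out[, c("contig", "pos", "strand", "n_meth", "n_unmeth", "level")]
}

#' Build a per-tRNA reference from annotated tRNA gene models
#'
#' Keeps only first gene copies (a '1' in the fifth dash-separated field of
#' the GtRNAdb-style name), splices out introns, appends the CCA tail, and
#' adds two flanking N on each side.
#'
#' @param trna_models list of `list(name, sequence, introns)` where
#'   `introns` is a list of 0-based half-open `c(start, end)` spans in the
#'   gene body (or NULL).
#' @return named character vector of per-tRNA contigs.
#' @export
build_trna_reference <- function(trna_models) {
  out <- character(0)
  for (m in trna_models) {
    fields <- strsplit(m$name, "-", fixed = TRUE)[[1L]]
    if (length(fields) < 5L) {
      warning("malformed tRNA name (kept): ", m$name)
    } else if (fields[5L] != "1") {
      next
    }
    s <- m$sequence
    if (!is.null(m$introns) && length(m$introns)) {
      keep_mask <- rep(TRUE, nchar(s))
      for (iv in m$introns) keep_mask[(iv[1L] + 1L):iv[2L]] <- FALSE
      s <- paste(strsplit(s, "", fixed = TRUE)[[1L]][keep_mask],
                 collapse = "")
    }
    out[m$name] <- paste0("NN", s, "CCA", "NN")
  }
  out
}

#' Resolve tRNA multi-mapping reads to one alignment each
#'
#' Restricts each read's alignments to those with the fewest mismatches and
#' picks one uniformly at random (seeded), so every read is counted once.
#'
#' @param alignments data.frame with at least read_id, contig, pos,
#'   mismatches (e.g. from `align_bs_reads(report = "all")`).
#' @param seed integer seed.
#' @return data.frame with one row per read.
#' @export
resolve_trna_multimappers <- function(alignments, seed = 1L) {
  if (!nrow(alignments)) return(alignments)
  .with_seed(seed, {
    picked <- lapply(split(seq_len(nrow(alignments)), alignments$read_id),
                     function(ix) {
                       mm <- alignments$mismatches[ix]
                       ix <- ix[mm == min(mm)]
                       if (length(ix) == 1L) ix else sample(ix, 1L)
                     })
    out <- alignments[unlist(picked, use.names = FALSE), , drop = FALSE]
    out <- out[order(out$read_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

## ---------------------------------------------------------------------------
## Capped site-level quantification around the motif
## ---------------------------------------------------------------------------

#' Quantify methylation around a site list with read-cap normalization
#'
#' Sites within `shift_window` nt of a motif's methylated C are shifted
#' onto it and duplicates removed; motif and non-motif sites are profiled
#' separately. For each cytosine offset within `-context..context` of a
#' site, the per-site (methylated, total) counts are rescaled to at most
#' `cap` total reads preserving the methylated fraction exactly (the cap is
#' a weight, not a resampling: capped_meth = cap * n_meth / total computed
#' as one exact-integer division). The aggregated level per offset is
#' sum(capped_meth) / sum(capped_total).
#'
#' @param sites data.frame(contig, pos, ...) of candidate sites.
#' @param cytosine_counts data.frame from [extract_methylation()].
#' @param reference named character vector.
#' @param pattern motif regular expression (methylated C = match start).
#' @param context half-width of the profiled window in nt.
#' @param cap per-site read cap.
#' @param shift_window motif-shift search distance in nt.
#' @return list with `sites` (shifted, deduplicated, with `motif` flag and
#'   `flagged` for sites with no covered C in context), `per_site`
#'   (offset-0 site-level counts and level), and `profile` (per subset x
#'   offset: capped_meth, capped_total, level).
#' @export
quantify_site_methylation <- function(sites, cytosine_counts, reference,
                                      pattern = "CTC[CT]A", context = 10L,
                                      cap = 5L, shift_window = 2L) {
  width <- 5L
  shifted <- sites[, c("contig", "pos"), drop = FALSE]
  motif <- logical(nrow(shifted))
  for (i in seq_len(nrow(shifted))) {
    ref <- reference[[shifted$contig[i]]]
    p <- shifted$pos[i]
    best <- NA_integer_
    for (d in 0:shift_window) {
      for (q in unique(c(p - d, p + d))) {
        if (q < 0L || q + width > nchar(ref)) next
        if (grepl(paste0("^", pattern, "$"),
                  substring(ref, q + 1L, q + width))) { best <- q; break }
      }
      if (!is.na(best)) break
    }
    if (!is.na(best)) { shifted$pos[i] <- best; motif[i] <- TRUE }
  }
  shifted$motif <- motif
  shifted <- shifted[!duplicated(shifted[, c("contig", "pos")]), ,
                     drop = FALSE]
  rownames(shifted) <- NULL

  cc_key <- paste(cytosine_counts$contig, cytosine_counts$pos)
  per_site <- list(); prof <- list()
  flagged <- logical(nrow(shifted))
  for (i in seq_len(nrow(shifted))) {
    ref <- reference[[shifted$contig[i]]]
    p <- shifted$pos[i]
    any_cov <- FALSE
    for (off in seq.int(-context, context)) {
      q <- p + off
      if (q < 0L || q >= nchar(ref)) next
      if (substring(ref, q + 1L, q + 1L) != "C") next
      j <- match(paste(shifted$contig[i], q), cc_key)
      if (is.na(j)) next
      n_meth <- cytosine_counts$n_meth[j]
      total <- n_meth + cytosine_counts$n_unmeth[j]
      if (total == 0L) next
      any_cov <- TRUE
      # the cap is a weight, not a resampling: capped_meth is the exact
      # rational cap * n_meth / total, carried as integer num/den so the
      # per-site methylated fraction is provably unchanged
      if (total > cap) {
        cm_num <- cap * n_meth; cm_den <- total; ct <- cap
      } else {
        cm_num <- n_meth; cm_den <- 1L; ct <- total
      }
      cm <- cm_num / cm_den
      prof[[length(prof) + 1L]] <- data.frame(
        site = i, offset = off, motif = shifted$motif[i],
        n_meth = n_meth, n_total = total,
        capped_meth = cm, capped_meth_num = cm_num, capped_meth_den = cm_den,
        capped_total = ct, stringsAsFactors = FALSE)
      if (off == 0L) {
        per_site[[length(per_site) + 1L]] <- data.frame(
          contig = shifted$contig[i], pos = p, motif = shifted$motif[i],
          n_meth = n_meth, n_total = total, capped_meth = cm,
          capped_meth_num = cm_num, capped_meth_den = cm_den,
          capped_total = ct, level = n_meth / total,
          # single exact-integer division: provably equal to n_meth/total
          capped_level = cm_num / (cm_den * ct), stringsAsFactors = FALSE)
      }
    }
    flagged[i] <- !any_cov
  }
  shifted$flagged <- flagged
  per_site <- if (length(per_site)) do.call(rbind, per_site) else
    data.frame(contig = character(0), pos = integer(0), motif = logical(0),
               n_meth = integer(0), n_total = integer(0),
               capped_meth = numeric(0), capped_meth_num = numeric(0),
               capped_meth_den = numeric(0), capped_total = numeric(0),
               level = numeric(0), capped_level = numeric(0))
  profile <- if (length(prof)) {
    dt <- data.table::rbindlist(prof)
    out <- dt[, .(capped_meth = sum(capped_meth),
                  capped_total = sum(capped_total)),
              by = .(motif, offset)]
    out[, level := capped_meth / capped_total]
    data.table::setorder(out, motif, offset)
    as.data.frame(out)
  } else {
    data.frame(motif = logical(0), offset = integer(0),
               capped_meth = numeric(0), capped_total = numeric(0),
               level = numeric(0))
  }
  list(sites = shifted, per_site = per_site, profile = profile)
}

#' Run the bisulfite pipeline end to end on raw reads
#'
#' Convenience wrapper: align (with CCA-trim retry), artifact-filter,
#' extract, and quantify around a site list.
#'
#' @param reads data.frame(read_id, sequence).
#' @param reference named character vector.
#' @param sites data.frame(contig, pos).
#' @param max_mismatches,max_meth_fraction,context,cap,pattern
#'   passed through to the stage functions.
#' @return list(alignment_stats, filter_stats, cytosines, quant).
#' @export
bsseq_run <- function(reads, reference, sites, max_mismatches = 2L,
                      max_meth_fraction = 1 / 3, context = 10L, cap = 5L,
                      pattern = "CTC[CT]A") {
  pass1 <- align_bs_reads(reads, reference, max_mismatches)
  pass2 <- retry_cca_trim(pass1$unaligned, reference, max_mismatches)
  aligned <- pass1$aligned
  if (nrow(pass2$aligned)) {
    p2 <- pass2$aligned[, names(aligned), drop = FALSE]
    aligned <- rbind(aligned, p2)
  }
  flt <- filter_conversion_artifacts(aligned, reference, max_meth_fraction)
  cyt <- extract_methylation(flt$kept, reference)
  quant <- quantify_site_methylation(sites, cyt, reference, pattern,
                                     context, cap)
  list(alignment_stats = list(pass1 = pass1$stats, pass2 = pass2$stats),
       filter_stats = flt$stats, cytosines = cyt, quant = quant)
}
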