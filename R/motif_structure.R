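## Motif scanning, hairpin screening, and readthrough sequence analyses.
##
## The methyltransferase's consensus element is CTC[CT]A with the methylated
## cytosine as the FIRST base of the match; target cytosines sit in the loop
## of a stem-loop. The hairpin screen uses a documented simplified
## nearest-neighbour model (see hairpin_energy) whose scale is calibrated so
## the -5 kcal/mol stem-loop threshold is meaningful on synthetic data.

#' Scan a sequence for the methylation consensus motif
#'
#' Finds all (possibly overlapping) matches of `pattern`; the methylated
#' cytosine is the first base of the match.
#'
#' @param sequence character scalar, transcript orientation.
#' @param pattern regular expression; default the CTC\[CT\]A consensus.
#' @return data.frame with `start` (0-based position of the methylated C)
#'   and `pattern_matched` (the matched word).
#' @export
scan_motif <- function(sequence, pattern = "CTC[CT]A") {
  stopifnot(length(sequence) == 1L)
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), pattern_matched = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  # motif word length: assume fixed-width pattern; take 5 for the default,
  # otherwise re-match at each start
  width <- attr(regexpr(pattern, "CTCCA"), "match.length")
  if (is.na(width) || width < 1L) width <- 5L
  data.frame(start = starts,
             pattern_matched = substring(sequence, starts + 1L, starts + width),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Simplified hairpin free-energy model
## ---------------------------------------------------------------------------

.pair_class <- function(a, b) {
  # 0 = not paired, 3 = GC, 2 = AT, 1 = GT wobble
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3L)
  if (key %in% c("AT", "TA")) return(2L)
  if (key %in% c("GT", "TG")) return(1L)
  0L
}

# stack energy between two consecutive pairs, by pair class (kcal/mol)
.stack_energy <- function(c1, c2) {
  if (c1 == 3L && c2 == 3L) return(-3.3)   # GC on GC
  if (c1 == 1L || c2 == 1L) return(-1.0)   # any wobble involved
  if (c1 == 3L || c2 == 3L) return(-2.2)   # GC on AT
  -1.1                                     # AT on AT
}

.loop_penalty <- function(len) 5.0 + 0.3 * (len - 3L)

# best (most negative) additional energy from extending a stem outward from
# positions (a, b) given the previous pair's class; at most one single-nt
# bulge per arm, charged `bulge_penalty`.
.stem_extend <- function(v, a, b, prev_class, bulge_l, bulge_r,
                         bulge_penalty) {
  n <- length(v)
  best <- 0
  if (a >= 1L && b <= n) {
    cl <- .pair_class(v[a], v[b])
    if (cl > 0L) {
      e <- .stack_energy(prev_class, cl) +
        .stem_extend(v, a - 1L, b + 1L, cl, bulge_l, bulge_r, bulge_penalty)
      if (e < best) best <- e
    }
  }
  if (bulge_l > 0L && a >= 2L && b <= n) {
    cl <- .pair_class(v[a - 1L], v[b])
    if (cl > 0L) {
      e <- bulge_penalty + .stack_energy(prev_class, cl) +
        .stem_extend(v, a - 2L, b + 1L, cl, bulge_l - 1L, bulge_r,
                     bulge_penalty)
      if (e < best) best <- e
    }
  }
  if (bulge_r > 0L && b + 1L <= n && a >= 1L) {
    cl <- .pair_class(v[a], v[b + 1L])
    if (cl > 0L) {
      e <- bulge_penalty + .stack_energy(prev_class, cl) +
        .stem_extend(v, a - 1L, b + 2L, cl, bulge_l, bulge_r - 1L,
                     bulge_penalty)
      if (e < best) best <- e
    }
  }
  best
}

#' Score a window for stem-loop (hairpin) formation
#'
#' A documented simplified nearest-neighbour model: contiguous stems built
#' from Watson-Crick and GU pairs with stack energies by pair class, a
#' linear terminal-loop penalty, and at most one single-nucleotide bulge per
#' stem arm (penalized). The minimum energy over all hairpin registers is
#' reported. The absolute scale is calibrated so that a 6-bp GC stem closed
#' by a 5-nt loop scores below -5 kcal/mol, making the -5 kcal/mol
#' stem-loop threshold meaningful. This is a screening statistic, not a
#' complete thermodynamic folding; an external folding engine can be
#' substituted upstream for real data.
#'
#' @param window sequence window (DNA alphabet; U accepted) centred on the
#'   candidate cytosine. Typically `2 * flank + 1` nt with flank 25.
#' @param energy_threshold stem-loop call threshold in kcal/mol.
#' @param min_loop,max_loop allowed terminal loop lengths.
#' @param bulge_penalty energy charge per bulged nucleotide.
#' @return object of class `HairpinCall`: list with `window`, `energy`
#'   (kcal/mol; 0 when no hairpin is possible), `is_stem_loop`,
#'   `motif_in_loop` (is the central base inside the unpaired terminal loop
#'   of the best hairpin), and `loop` (0-based half-open loop span, or NULL).
#' @export
hairpin_energy <- function(window, energy_threshold = -5,
                           min_loop = 3L, max_loop = 10L,
                           bulge_penalty = 3.0) {
  window <- chartr("Uu", "Tt", toupper(window))
  v <- strsplit(window, "", fixed = TRUE)[[1L]]
  n <- length(v)
  center <- (n - 1L) %/% 2L  # 0-based
  best_e <- 0
  best_loop <- NULL
  if (n >= min_loop + 2L * 3L) {  # need stem >= 3 + loop >= min_loop
    for (i in seq_len(n - min_loop - 1L)) {        # 1-based closing pair 5' idx
      for (loop_len in min_loop:max_loop) {
        j <- i + loop_len + 1L
        if (j > n) break
        cl <- .pair_class(v[i], v[j])
        if (cl == 0L) next
        e <- .loop_penalty(loop_len) +
          .stem_extend(v, i - 1L, j + 1L, cl, 1L, 1L, bulge_penalty)
        if (e < best_e) {
          best_e <- e
          best_loop <- c(i, j - 1L)  # 0-based half-open (i..j-2 inclusive)
        }
      }
    }
  }
  motif_in_loop <- !is.null(best_loop) &&
    center >= best_loop[1L] && center < best_loop[2L]
  structure(list(window = window, energy = best_e,
                 is_stem_loop = best_e <= energy_threshold,
                 motif_in_loop = motif_in_loop,
                 loop = best_loop), class = "HairpinCall")
}

#' @export
print.HairpinCall <- function(x, ...) {
  cat(sprintf("HairpinCall: energy %.2f kcal/mol, stem-loop: %s, motif in loop: %s\n",
              x$energy, x$is_stem_loop, x$motif_in_loop))
  invisible(x)
}

#' Enumerate predicted sequence-structure elements transcriptome-wide
#'
#' A predicted element is a motif hit whose surrounding window passes the
#' stem-loop screen. The overlap with an observed site list quantifies what
#' fraction of predicted elements is actually targeted.
#'
#' @param models named list of transcript models.
#' @param observed_sites data.frame(contig, pos) of observed methylation
#'   sites (transcript coordinates), or NULL.
#' @param pattern motif regular expression.
#' @param energy_threshold stem-loop threshold (kcal/mol); `Inf` disables
#'   the structure screen.
#' @param flank half-window for folding (window = 2 * flank + 1 nt).
#' @param region `"all"` or `"3utr"` to restrict hits to 3'UTRs.
#' @return list with `predicted` (data.frame contig, pos, energy),
#'   `n_predicted`, `n_overlap` and `fraction_observed`.
#' @export
predict_transcriptome_sites <- function(models, observed_sites = NULL,
                                        pattern = "CTC[CT]A",
                                        energy_threshold = -5, flank = 25L,
                                        region = c("all", "3utr")) {
  region <- match.arg(region)
  rows <- list()
  for (m in models) {
    hits <- scan_motif(m$sequence, pattern)
    if (region == "3utr") hits <- hits[hits$start >= m$cds_end, , drop = FALSE]
    if (!nrow(hits)) next
    for (p in hits$start) {
      lo <- max(0L, p - flank)
      hi <- min(nchar(m$sequence), p + flank + 1L)
      win <- substring(m$sequence, lo + 1L, hi)
      hp <- hairpin_energy(win, energy_threshold = energy_threshold)
      pass <- if (is.infinite(energy_threshold)) TRUE else hp$is_stem_loop
      if (pass) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = m$contig, pos = p, energy = hp$energy,
          stringsAsFactors = FALSE)
      }
    }
  }
  predicted <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), energy = numeric(0))
  n_overlap <- 0L
  if (!is.null(observed_sites) && nrow(predicted) && nrow(observed_sites)) {
    key_p <- paste(predicted$contig, predicted$pos)
    key_o <- paste(observed_sites$contig, observed_sites$pos)
    n_overlap <- sum(key_p %in% key_o)
  }
  list(predicted = predicted, n_predicted = nrow(predicted),
       n_overlap = n_overlap,
       fraction_observed = if (nrow(predicted)) n_overlap / nrow(predicted)
                           else NA_real_)
}

## ---------------------------------------------------------------------------
## Readthrough sequence analyses
## ---------------------------------------------------------------------------

#' Count in-frame stop codons between an annotated stop and a 3'UTR site
#'
#' Walks codons in the frame continued from the annotated ORF, counts stop
#' codons between the annotated stop codon and the site, and the same count
#' in a control region of equal size immediately downstream of the site.
#'
#' @param sequence transcript sequence (or a `TranscriptModel`).
#' @param annotated_stop_offset 0-based offset of the annotated stop codon's
#'   first base.
#' @param site_offset 0-based offset of the 3'UTR methylation site; must be
#'   downstream of the stop codon.
#' @return list(n_between, n_control, n_codons, control_truncated).
#' @export
inframe_stop_frequency <- function(sequence, annotated_stop_offset,
                                   site_offset) {
  if (inherits(sequence, "TranscriptModel")) sequence <- sequence$sequence
  if (site_offset <= annotated_stop_offset) {
    stop("site must be downstream of the annotated stop codon")
  }
  stops <- c("TAA", "TAG", "TGA")
  # codons strictly after the stop codon, fully contained in (stop, site]
  starts <- seq.int(annotated_stop_offset + 3L, by = 3L,
                    length.out = max(0L, (site_offset - annotated_stop_offset - 2L) %/% 3L))
  starts <- starts[starts + 2L <= site_offset]
  n_codons <- length(starts)
  codon_at <- function(s) substring(sequence, s + 1L, s + 3L)
  n_between <- if (n_codons) sum(vapply(starts, codon_at, "") %in% stops) else 0L
  # control: the next n_codons codons in the same frame
  truncated <- FALSE
  n_control <- 0L
  if (n_codons) {
    ctrl <- max(starts) + 3L * seq_len(n_codons)
    fit <- ctrl + 3L <= nchar(sequence)
    if (!all(fit)) truncated <- TRUE
    ctrl <- ctrl[fit]
    n_control <- if (length(ctrl)) sum(vapply(ctrl, codon_at, "") %in% stops) else 0L
  }
  list(n_between = as.integer(n_between), n_control = as.integer(n_control),
       n_codons = n_codons, control_truncated = truncated)
}

#' Stop-codon context distribution
#'
#' The stop-codon context is the base immediately downstream of the stop
#' codon. Genes with multiple annotated stop codons contribute each stop
#' with weight 1/k so per-gene weights sum to 1; a stop at the transcript
#' end (no next base) falls in category `"end"`.
#'
#' @param models named list of transcript models.
#' @param target_genes optional character vector of gene ids defining a
#'   subset (e.g. methylation targets) reported alongside the overall
#'   distribution.
#' @return list with `weights` (data.frame gene_id, codon, next_base,
#'   weight), `overall` and (if requested) `target` aggregated
#'   (codon, next_base, weight, fraction) tables.
#' @export
stop_codon_context <- function(models, target_genes = NULL) {
  rows <- list()
  genes <- split(models, vapply(models, `[[`, "", "gene_id"))
  for (gid in names(genes)) {
    stops <- list()
    for (m in genes[[gid]]) {
      if (!nrow(m$stop_codons)) next
      for (i in seq_len(nrow(m$stop_codons))) {
        o <- m$stop_codons$offset[i]
        nb <- if (o + 4L <= nchar(m$sequence))
          substring(m$sequence, o + 4L, o + 4L) else "end"
        stops[[length(stops) + 1L]] <- data.frame(
          gene_id = gid, codon = m$stop_codons$codon[i], next_base = nb,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(stops)) next
    df <- unique(do.call(rbind, stops))
    df$weight <- 1 / nrow(df)
    rows[[gid]] <- df
  }
  weights <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), codon = character(0),
               next_base = character(0), weight = numeric(0))
  rownames(weights) <- NULL
  agg <- function(w) {
    if (!nrow(w)) return(data.frame(codon = character(0),
                                    next_base = character(0),
                                    weight = numeric(0),
                                    fraction = numeric(0)))
    a <- stats::aggregate(weight ~ codon + next_base, data = w, FUN = sum)
    a$fraction <- a$weight / sum(a$weight)
    a[order(-a$weight), , drop = FALSE]
  }
  out <- list(weights = weights, overall = agg(weights))
  if (!is.null(target_genes)) {
    out$target <- agg(weights[weights$gene_id %in% target_genes, , drop = FALSE])
  }
  out
}
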