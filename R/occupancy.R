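## Coverage matrices around sites, upstream/downstream occupancy
## classification, the coding-sequence profile, and the randomized motif
## control.

# dense per-contig coverage vectors from a (contig, pos, value) track
.dense_track <- function(track, contig_lengths = NULL) {
  out <- list()
  for (ct in unique(track$contig)) {
    sub <- track[track$contig == ct, , drop = FALSE]
    n <- if (!is.null(contig_lengths) && ct %in% names(contig_lengths)) {
      contig_lengths[[ct]]
    } else {
      max(sub$pos) + 1L
    }
    v <- numeric(n)
    v[sub$pos + 1L] <- sub$value
    out[[ct]] <- v
  }
  out
}

#' Build a coverage matrix around sites
#'
#' One row per site: the track slice `[pos - flank, pos + flank)` in the
#' 5'-to-3' orientation of the site's strand (minus-strand rows reversed);
#' positions outside the contig are zero. Column `flank + 1` aligns to the
#' site nucleotide.
#'
#' @param track data.frame(contig, pos, value) with optional `strand`
#'   column (matched against site strands when present).
#' @param sites data.frame(contig, pos) with optional `strand`.
#' @param flank half-window size in nt.
#' @param contig_lengths optional named lengths (else inferred from track).
#' @return numeric matrix, sites x 2*flank, with attribute `sites`.
#' @export
matrix_around_sites <- function(track, sites, flank = 1500L,
                                contig_lengths = NULL) {
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  mat <- matrix(0, nrow(sites), 2L * flank)
  for (st in unique(strand)) {
    tr <- track
    if ("strand" %in% names(track)) tr <- track[track$strand == st, ,
                                                drop = FALSE]
    dense <- .dense_track(tr, contig_lengths)
    for (i in which(strand == st)) {
      v <- dense[[sites$contig[i]]]
      if (is.null(v)) next
      cols <- seq.int(sites$pos[i] - flank, sites$pos[i] + flank - 1L)
      ok <- cols >= 0L & cols < length(v)
      row <- numeric(2L * flank)
      row[ok] <- v[cols[ok] + 1L]
      if (st == "-") row <- rev(row)
      mat[i, ] <- row
    }
  }
  colnames(mat) <- as.character(seq.int(-flank, flank - 1L))
  attr(mat, "sites") <- sites
  mat
}

#' Classify sites by upstream vs downstream footprint signal
#'
#' For each site, `d` is the number of covered (nonzero) positions upstream
#' minus the number covered downstream. With SE the standard error of `d`
#' across all sites (population SD / sqrt(n)), a site is `higher` if
#' `d > z * SE`, `lower` if `d < -z * SE`, else `unchanged`.
#'
#' @param mat matrix from [matrix_around_sites()] (equal flanks).
#' @param z classification threshold in SE units.
#' @return list with `class` (factor per site), `d`, `se`, and `counts`.
#' @export
classify_sites <- function(mat, z = 1.96) {
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 sites to estimate the SE")
  flank <- ncol(mat) %/% 2L
  up <- mat[, seq_len(flank), drop = FALSE]
  down <- mat[, flank + seq_len(flank), drop = FALSE]
  d <- rowSums(up > 0) - rowSums(down > 0)
  se <- sqrt(mean((d - mean(d))^2)) / sqrt(n)  # population SD / sqrt(n)
  cls <- ifelse(d > z * se, "higher", ifelse(d < -z * se, "lower",
                                             "unchanged"))
  cls <- factor(cls, levels = c("lower", "unchanged", "higher"))
  list(class = cls, d = d, se = se, counts = table(cls))
}

#' Fraction of positions annotated as coding around sites
#'
#' Per column of the site-centred window, the fraction of sites whose
#' aligned position falls inside any merged CDS interval.
#'
#' @param models named list of transcript models (CDS intervals merged per
#'   contig).
#' @param sites data.frame(contig, pos) with optional `strand`.
#' @param flank half-window size.
#' @return data.frame(offset, fraction) over offsets -flank..flank-1.
#' @export
cds_profile_around_sites <- function(models, sites, flank = 1500L) {
  cds <- list()
  for (m in models) {
    if (m$cds_end > m$cds_start) {
      cds[[m$contig]] <- rbind(cds[[m$contig]],
                               c(m$cds_start, m$cds_end))
    }
  }
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  acc <- numeric(2L * flank)
  for (i in seq_len(nrow(sites))) {
    iv <- cds[[sites$contig[i]]]
    if (is.null(iv)) next
    cols <- seq.int(sites$pos[i] - flank, sites$pos[i] + flank - 1L)
    inside <- rep(FALSE, length(cols))
    for (r in seq_len(nrow(iv))) {
      inside <- inside | (cols >= iv[r, 1L] & cols < iv[r, 2L])
    }
    if (strand[i] == "-") inside <- rev(inside)
    acc <- acc + inside
  }
  data.frame(offset = seq.int(-flank, flank - 1L),
             fraction = if (nrow(sites)) acc / nrow(sites) else acc)
}

#' Randomized motif control profile with confidence envelope
#'
#' Draws `n_draws` site sets of the observed size from a candidate pool
#' (all 3'UTR motif occurrences) without replacement, recomputes the
#' profile for each, and returns the mean and the 2.5/97.5 percentile
#' envelope.
#'
#' @param sites observed site data.frame (defines the draw size).
#' @param pool data.frame(contig, pos) of candidate motif positions; must
#'   be at least as large as `sites`.
#' @param profile_fun function(sites_df) -> numeric profile vector.
#' @param n_draws number of resamples.
#' @param seed integer seed.
#' @return list(mean, lower, upper) numeric vectors of the profile length.
#' @export
random_motif_control <- function(sites, pool, profile_fun, n_draws = 1000L,
                                 seed = 1L) {
  if (nrow(pool) < nrow(sites)) {
    stop("candidate pool smaller than the site set")
  }
  .with_seed(seed, {
    draws <- matrix(NA_real_, n_draws, 0L)
    first <- profile_fun(pool[sample.int(nrow(pool), nrow(sites)), ,
                              drop = FALSE])
    draws <- matrix(NA_real_, n_draws, length(first))
    draws[1L, ] <- first
    for (b in seq_len(n_draws)[-1L]) {
      draws[b, ] <- profile_fun(pool[sample.int(nrow(pool), nrow(sites)), ,
                                     drop = FALSE])
    }
    list(mean = colMeans(draws),
         lower = apply(draws, 2L, quantile, probs = 0.025, names = FALSE),
         upper = apply(draws, 2L, quantile, probs = 0.975, names = FALSE))
  })
}
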