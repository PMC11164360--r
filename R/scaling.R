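#' Strand-oriented contact-frequency scaling P(s)
#'
#' Bins cis pairs by genomic separation `s = pos2 - pos1` into geometric
#' (log-spaced) bins and counts them separately for the four strand
#' orientations `++`, `+-`, `-+`, `--`.  Counts are also normalised by bin
#' width in bp, the form in which the decay of contact frequency with
#' distance (the P(s) curve) is usually inspected.  Trans pairs contribute to
#' an average trans contact frequency: the trans pair count divided by the
#' total number of inter-chromosomal locus pairs, `sum_{i<j} L_i * L_j`.
#'
#' @param pairs Flipped `.pairs` record `data.table`; only records uniquely
#'   mapped on both sides contribute.
#' @param chromsizes Named vector (or [pairs_header]) of chromosome lengths.
#' @param min_dist Smallest separation binned (bp, > 0).
#' @param max_dist Largest separation binned; defaults to the longest
#'   chromosome.
#' @param bins_per_decade Number of log-spaced bins per factor 10.
#' @return Object of class `scaling_curve`: a list with `bins` (a
#'   `data.table` with `bin_start`, `bin_end`, one count column and one
#'   `norm_` column per orientation, and `total`), `avg_trans_frequency`,
#'   `n_cis_binned`, `n_trans` and the binning parameters.
#' @export
compute_scaling <- function(pairs, chromsizes, min_dist = 10,
                            max_dist = NULL, bins_per_decade = 8) {
  if (inherits(chromsizes, "pairs_header")) chromsizes <- chromsizes$chromsizes
  if (min_dist <= 0) stop("min_dist must be > 0")
  if (is.null(max_dist)) max_dist <- max(chromsizes)
  if (max_dist <= min_dist) stop("max_dist must exceed min_dist")
  n_edges <- ceiling(log10(max_dist / min_dist) * bins_per_decade) + 1L
  edges <- min_dist * 10^(seq(0L, n_edges - 1L) / bins_per_decade)
  edges[length(edges)] <- max(edges[length(edges)], max_dist)
  nb <- length(edges) - 1L

  c1 <- substr(pairs$pair_type, 1L, 1L)
  c2 <- substr(pairs$pair_type, 2L, 2L)
  mapped <- c1 %in% c("U", "R") & c2 %in% c("U", "R") &
    pairs$chrom1 != .NULL_CHROM & pairs$chrom2 != .NULL_CHROM
  cis <- mapped & pairs$chrom1 == pairs$chrom2
  trans <- mapped & !cis
  s <- pairs$pos2[cis] - pairs$pos1[cis]
  orient <- paste0(pairs$strand1[cis], pairs$strand2[cis])
  inrange <- s >= edges[1] & s < edges[length(edges)]
  bin <- findInterval(s[inrange], edges, rightmost.closed = FALSE)
  orientations <- c("++", "+-", "-+", "--")
  counts <- matrix(0L, nrow = nb, ncol = 4L,
                   dimnames = list(NULL, orientations))
  tab <- table(factor(bin, levels = seq_len(nb)),
               factor(orient[inrange], levels = orientations))
  counts[] <- as.integer(tab)
  widths <- diff(edges)
  bins <- data.table::data.table(bin_start = edges[-length(edges)],
                                 bin_end = edges[-1])
  for (o in orientations) {
    bins[, (paste0("n_", o)) := counts[, o]]
  }
  bins[, total := as.integer(rowSums(counts))]
  for (o in orientations) {
    bins[, (paste0("norm_", o)) := counts[, o] / widths]
  }
  lens <- as.numeric(chromsizes)
  trans_possible <- (sum(lens)^2 - sum(lens^2)) / 2
  structure(
    list(bins = bins[], orientations = orientations,
         avg_trans_frequency = sum(trans) / trans_possible,
         n_cis_binned = sum(inrange), n_trans = sum(trans),
         min_dist = min_dist, max_dist = max_dist,
         bins_per_decade = bins_per_decade),
    class = "scaling_curve"
  )
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat("<scaling_curve> ", nrow(x$bins), " bins in [",
      format(x$min_dist), ", ", format(x$max_dist), ") bp, ",
      x$n_cis_binned, " cis pairs binned, avg trans frequency ",
      format(x$avg_trans_frequency, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Orientation convergence distance
#'
#' At short range, ligation by-products (dangling ends, self-circles, mirror
#' artefacts) inflate specific strand orientations, so the four oriented
#' P(s) curves disagree; at larger separations genuine contacts dominate and
#' the orientations converge.  Scanning from the largest separation down,
#' this returns the upper edge of the right-most bin whose orientations are
#' *not* similar — pairs below this distance may be by-products.
#'
#' A bin is similar when the relative spread `(max - min) / mean` of its four
#' per-orientation densities is at most `rel_tol`; only bins holding at least
#' `min_count` pairs are judged (sparser bins are too noisy to call).  When
#' every judged bin is similar the first bin edge is returned (no by-product
#' zone detected); when every judged bin is dissimilar the curve never
#' converges and `NA` is returned.
#'
#' @param curve A [compute_scaling()] result.
#' @param rel_tol Relative spread below which orientations count as similar.
#' @param min_count Minimum pairs per bin for the bin to be judged.
#' @return Convergence distance in bp, or `NA` (not converged).
#' @export
convergence_distance <- function(curve, rel_tol = 0.25, min_count = 100) {
  bins <- curve$bins
  norm <- as.matrix(bins[, paste0("norm_", curve$orientations),
                         with = FALSE])
  judged <- bins$total >= min_count
  if (!any(judged)) return(bins$bin_start[1])
  mean_ <- rowMeans(norm)
  spread <- (apply(norm, 1, max) - apply(norm, 1, min)) /
    ifelse(mean_ > 0, mean_, 1)
  dissimilar <- judged & spread > rel_tol
  if (!any(dissimilar)) return(bins$bin_start[1])
  if (all(dissimilar[judged])) return(NA_real_)
  bins$bin_end[max(which(dissimilar))]
}
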