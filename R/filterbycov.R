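#' Filter pairs from anomalously covered regions (single-cell QC)
#'
#' In single-cell 3C+ data the contact count of a locus is bounded by its
#' copy number, so genomic bins with irregularly high coverage flag
#' amplification artefacts or copy-number changes.  This computes genome-wide
#' coverage as the number of pair *sides* falling in each fixed-width bin
#' (both sides of every mapped record are counted) and removes every record
#' with at least one side in a bin whose coverage exceeds `max_coverage`
#' (strictly).  Two passes: count, then filter — the result is independent
#' of record order.
#'
#' @param pairs Deduplicated `.pairs` record `data.table`.
#' @param bin_size Bin width in bp.
#' @param max_coverage Highest tolerated side count per bin.
#' @return List with `kept` and `removed` record tables and `coverage`, a
#'   `data.table` of (chrom, bin_start, count) for non-empty bins.
#' @export
filter_by_coverage <- function(pairs, bin_size = 1000L, max_coverage = 10L) {
  stopifnot(bin_size >= 1L, max_coverage >= 1L)
  sides <- data.table::rbindlist(list(
    data.table::data.table(chrom = pairs$chrom1, pos = pairs$pos1,
                           row = seq_len(nrow(pairs))),
    data.table::data.table(chrom = pairs$chrom2, pos = pairs$pos2,
                           row = seq_len(nrow(pairs)))
  ))
  sides <- sides[chrom != .NULL_CHROM]
  sides[, bin := (pos - 1L) %/% as.integer(bin_size)]
  coverage <- sides[, .(count = .N), by = .(chrom, bin)]
  high <- coverage[count > max_coverage]
  bad_rows <- unique(sides[high, on = c("chrom", "bin")]$row)
  keep <- !(seq_len(nrow(pairs)) %in% bad_rows)
  coverage[, bin_start := bin * as.integer(bin_size) + 1L]
  data.table::setorder(coverage, chrom, bin_start)
  list(kept = pairs[keep],
       removed = pairs[!keep],
       coverage = coverage[, .(chrom, bin_start, count)])
}
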