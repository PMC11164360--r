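#' Chromosome ranks for canonical pair ordering
#'
#' Chromosomes rank in the order of the chromsizes file (not lexicographic),
#' so that sorted pairs form blocks per chromosome pair compatible with
#' downstream binning.  The null sentinel `!` ranks after every real
#' chromosome, clustering unmapped classes at the end of a sorted file.
#'
#' @param chroms Character vector of chromosome names (may include `!`).
#' @param chromsizes Named vector of chromosome lengths in canonical order.
#' @return Integer ranks.
#' @export
chrom_rank <- function(chroms, chromsizes) {
  r <- match(chroms, names(chromsizes))
  isnull <- chroms == .NULL_CHROM
  if (anyNA(r[!isnull])) {
    bad <- unique(chroms[!isnull & is.na(r)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  r[isnull] <- length(chromsizes) + 1L
  r
}

# per-side extras come in matched pairs foo1/foo2; swapping a pair swaps them
.sided_extra_pairs <- function(cols) {
  base1 <- grep("1$", cols, value = TRUE)
  base <- sub("1$", "", base1)
  keep <- paste0(base, "2") %in% cols
  cbind(col1 = base1[keep], col2 = paste0(base[keep], "2"))
}

#' Flip pairs into canonical (upper-triangular) orientation
#'
#' Arranges each pair so the side with the genomically lower coordinate
#' (chromosome rank, then position) comes first.  Pairs with an unmapped or
#' multi-mapped side are instead ordered by mapping class (N before M before
#' mapped), the convention used by pair-type codes such as `NU` and `MU`.
#' Swapping a pair consistently swaps chromosomes, positions, strands, the
#' two pair-type characters and all per-side extra columns (`mapq1`/`mapq2`,
#' ...).  Idempotent.
#'
#' @param pairs `.pairs` record `data.table`.
#' @param chromsizes Named vector defining the chromosome order (or a
#'   [pairs_header], whose chromsizes are used).
#' @return A flipped copy of `pairs`.
#' @export
flip_pairs <- function(pairs, chromsizes) {
  if (inherits(chromsizes, "pairs_header")) chromsizes <- chromsizes$chromsizes
  pairs <- data.table::copy(pairs)
  if (!nrow(pairs)) return(pairs)
  r1 <- chrom_rank(pairs$chrom1, chromsizes)
  r2 <- chrom_rank(pairs$chrom2, chromsizes)
  c1 <- substr(pairs$pair_type, 1L, 1L)
  c2 <- substr(pairs$pair_type, 2L, 2L)
  t1 <- .class_tier(c1)
  t2 <- .class_tier(c2)
  swap <- (t1 > t2) |
    (t1 == t2 & (r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)))
  if (any(swap)) {
    cols <- .sided_extra_pairs(setdiff(names(pairs), "pair_type"))
    for (k in seq_len(nrow(cols))) {
      a <- cols[k, "col1"]
      b <- cols[k, "col2"]
      tmp <- pairs[[a]][swap]
      data.table::set(pairs, which(swap), a, pairs[[b]][swap])
      data.table::set(pairs, which(swap), b, tmp)
    }
    data.table::set(pairs, which(swap), "pair_type",
                    paste0(c2[swap], c1[swap]))
  }
  pairs[]
}

# full deterministic sort order: (rank1, rank2, pos1, pos2, strand1, strand2,
# serialized line) — the final tie-break makes the order total
.pairs_order <- function(pairs, chromsizes) {
  order(
    chrom_rank(pairs$chrom1, chromsizes),
    chrom_rank(pairs$chrom2, chromsizes),
    pairs$pos1, pairs$pos2, pairs$strand1, pairs$strand2,
    .pairs_lines(pairs),
    method = "radix"
  )
}

#' Sort pairs by genomic position
#'
#' Total, deterministic order on (chrom1 rank, chrom2 rank, pos1, pos2,
#' strand1, strand2, whole serialized record).  Input is expected to be
#' flipped; records with chrom1 ranking after chrom2 are rejected unless
#' `auto_flip` is set.
#'
#' @param pairs `.pairs` record `data.table`.
#' @param chromsizes Named vector (or [pairs_header]) defining chromosome
#'   order.
#' @param auto_flip Flip unflipped records instead of erroring.
#' @return A sorted copy of `pairs`.
#' @export
sort_pairs <- function(pairs, chromsizes, auto_flip = FALSE) {
  if (inherits(chromsizes, "pairs_header")) chromsizes <- chromsizes$chromsizes
  if (!nrow(pairs)) return(data.table::copy(pairs))
  r1 <- chrom_rank(pairs$chrom1, chromsizes)
  r2 <- chrom_rank(pairs$chrom2, chromsizes)
  # class-flipped pairs put a null side first; only both-mapped pairs are
  # subject to the coordinate convention
  unflipped <- r1 > r2 & pairs$chrom1 != .NULL_CHROM &
    pairs$chrom2 != .NULL_CHROM
  if (any(unflipped)) {
    if (!auto_flip) {
      stop("record ", which(unflipped)[1],
           " is not flipped (chrom1 ranks after chrom2); ",
           "flip first or use auto_flip = TRUE")
    }
    pairs <- flip_pairs(pairs, chromsizes)
  }
  pairs[.pairs_order(pairs, chromsizes)]
}

#' Merge sorted pairs inputs
#'
#' Combines sorted datasets sharing one chromosome order into a single sorted
#' output equal to the full sort of their concatenation.  Headers must agree
#' on chromsizes and columns; provenance entries are concatenated in input
#' order.
#'
#' @param inputs List of `list(header=, pairs=)` objects (as returned by
#'   [read_pairs()] or [parse_pairs()]).
#' @return `list(header=, pairs=)` with the merged records.
#' @export
merge_pairs <- function(inputs) {
  stopifnot(length(inputs) >= 1L)
  h0 <- inputs[[1]]$header
  for (i in seq_along(inputs)) {
    h <- inputs[[i]]$header
    if (!identical(h$chromsizes, h0$chromsizes)) {
      stop("input ", i, " has a different chromosome order/sizes")
    }
    if (!identical(h$columns, h0$columns)) {
      stop("input ", i, " has different columns")
    }
    p <- inputs[[i]]$pairs
    if (nrow(p)) {
      ord <- .pairs_order(p, h0$chromsizes)
      if (is.unsorted(ord)) {
        stop("input ", i, " is not sorted (first out-of-order record at line ",
             which(ord != seq_along(ord))[1], ")")
      }
    }
  }
  merged <- data.table::rbindlist(lapply(inputs, `[[`, "pairs"))
  merged <- sort_pairs(merged, h0$chromsizes)
  header <- h0
  header$provenance <- unlist(lapply(inputs, function(x) x$header$provenance))
  list(header = header, pairs = merged)
}
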