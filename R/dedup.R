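#' Label duplicate clusters by fixed-radius neighbour search
#'
#' Two records are neighbours iff they share chrom1, chrom2, strand1, strand2
#' and every column in `match_extras`, and their positions differ by at most
#' `max_mismatch` bp on both sides.  Clusters are the connected components of
#' the neighbour graph (transitive closure), so chains of near-identical
#' copies collapse together.  Labels are deterministic: clusters are numbered
#' by their first member in sort order.
#'
#' Because the input is position-sorted, neighbours are found with a sorted
#' sliding window over `pos1` rather than a spatial tree; the result is
#' defined by the neighbour relation above, not by the search strategy.
#'
#' @param pairs Sorted, flipped `.pairs` record `data.table`.
#' @param max_mismatch Matching radius in bp per side (0 = exact).
#' @param match_extras Extra column names that must also match exactly.
#' @return Integer vector of cluster labels (1-based, in order of first
#'   appearance).
#' @export
find_duplicate_clusters <- function(pairs, max_mismatch = 3L,
                                    match_extras = NULL) {
  n <- nrow(pairs)
  if (!n) return(integer())
  keyparts <- c(list(pairs$chrom1, pairs$chrom2, pairs$strand1,
                     pairs$strand2),
                lapply(match_extras, function(cn) pairs[[cn]]))
  grp <- do.call(paste, c(keyparts, sep = "\r"))
  blk <- paste(pairs$chrom1, pairs$chrom2, sep = "\r")
  pos1 <- pairs$pos1
  pos2 <- pairs$pos2
  edges_from <- list()
  edges_to <- list()
  k <- 1L
  ne <- 0L
  while (k < n) {
    i <- seq_len(n - k)
    j <- i + k
    # window continuation is judged within (chrom1, chrom2) blocks, where
    # pos1 is non-decreasing; the full key is only needed for actual edges
    near <- blk[i] == blk[j] & (pos1[j] - pos1[i]) <= max_mismatch
    if (!any(near)) break
    hit <- near & grp[i] == grp[j] & abs(pos2[j] - pos2[i]) <= max_mismatch
    if (any(hit)) {
      ne <- ne + 1L
      edges_from[[ne]] <- i[hit]
      edges_to[[ne]] <- j[hit]
    }
    k <- k + 1L
  }
  if (!ne) return(seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(unlist(edges_from), unlist(edges_to)))
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in sort order
  match(comp, unique(comp))
}

#' Remove PCR/optical duplicates from a sorted pairs stream
#'
#' Candidates for deduplication are records mapped uniquely on both sides
#' (pair types composed of `U`/`R`); all other records pass through untouched
#' to the `unmapped` stream.  Within each duplicate cluster
#' (see [find_duplicate_clusters()]) the first record in sort order is kept;
#' the others are emitted on the duplicate stream with their pair type
#' rewritten to `DD`.
#'
#' Processing is chunked: records are handled `chunk_size` at a time, and all
#' clusters that still have a member within `max_mismatch` of the chunk's
#' trailing (chrom1, chrom2, pos1) key are carried over, so the output is
#' identical for every chunk size.
#'
#' @param pairs Sorted, flipped `.pairs` record `data.table`.
#' @param chromsizes Named vector (or [pairs_header]) defining chromosome
#'   order, used to verify sortedness.
#' @param max_mismatch Matching radius in bp per side.
#' @param match_extras Extra columns that must match for two records to be
#'   duplicates (e.g. a phase column).
#' @param chunk_size Records per processing block (`Inf` = whole input).
#' @return List with `unique`, `duplicates` and `unmapped` record tables,
#'   and `stats`: counts plus the library [complexity
#'   estimate][estimate_complexity].
#' @export
dedup_pairs <- function(pairs, chromsizes, max_mismatch = 3L,
                        match_extras = NULL, chunk_size = Inf) {
  if (inherits(chromsizes, "pairs_header")) chromsizes <- chromsizes$chromsizes
  n <- nrow(pairs)
  if (n) {
    ord <- .pairs_order(pairs, chromsizes)
    if (is.unsorted(ord)) {
      stop("input is not sorted (first out-of-order record at row ",
           which(ord != seq_along(ord))[1], ")")
    }
  }
  c1 <- substr(pairs$pair_type, 1L, 1L)
  c2 <- substr(pairs$pair_type, 2L, 2L)
  cand <- pairs$chrom1 != .NULL_CHROM & pairs$chrom2 != .NULL_CHROM &
    c1 %in% c("U", "R") & c2 %in% c("U", "R")
  body <- pairs[cand]
  passed <- pairs[!cand]
  m <- nrow(body)
  rep_of <- integer(m)
  if (m) {
    body[, idx := .I]
    carry <- body[0]
    carry[, rep_idx := integer()]
    chunk_size <- max(1L, min(chunk_size, m))
    starts <- seq(1L, m, by = chunk_size)
    for (s in seq_along(starts)) {
      lo <- starts[s]
      hi <- min(lo + chunk_size - 1L, m)
      buf <- data.table::rbindlist(list(carry, body[lo:hi, ]),
                                   fill = TRUE)
      lab <- find_duplicate_clusters(buf, max_mismatch, match_extras)
      # cluster representative: smallest original row index seen so far
      buf[is.na(rep_idx), rep_idx := idx]
      rep_global <- vapply(split(buf$rep_idx, lab), min, integer(1))
      buf[, rep_idx := rep_global[as.character(lab)]]
      if (hi < m) {
        last <- buf[.N]
        tailing <- buf$chrom1 == last$chrom1 & buf$chrom2 == last$chrom2 &
          buf$pos1 >= last$pos1 - max_mismatch
        carry_clusters <- unique(lab[tailing])
        keep_mask <- lab %in% carry_clusters
        flush <- buf[!keep_mask]
        carry <- buf[keep_mask]
      } else {
        flush <- buf
        carry <- buf[0]
      }
      if (nrow(flush)) rep_of[flush$idx] <- flush$rep_idx
    }
    body[, idx := NULL]
  }
  is_dup <- rep_of != seq_len(m)
  uniq <- body[!is_dup]
  dups <- body[is_dup]
  if (nrow(dups)) dups[, pair_type := "DD"]
  stats <- list(
    total = n,
    candidates = m,
    unique = nrow(uniq),
    duplicates = nrow(dups),
    passed_through = nrow(passed),
    complexity = estimate_complexity(m, nrow(uniq))
  )
  list(unique = uniq[], duplicates = dups[], unmapped = passed,
       stats = stats)
}

#' Estimate library complexity from duplicate counts
#'
#' Under the standard model that each sequencing read is drawn with
#' replacement from a finite pool of `C` distinct molecules, the expected
#' number of distinct molecules observed after `T` draws is
#' `U = C * (1 - exp(-T / C))`.  The estimate inverts this relation for the
#' observed `(T, U)` by bracketed root finding to a relative tolerance of
#' 1e-6.  With no duplicates observed (`U = T`) the pool size is unbounded
#' and the estimate is undefined (`NA`); with heavy saturation the estimate
#' approaches `U`.
#'
#' @param n_total Total reads observed (`T`).
#' @param n_unique Distinct molecules observed (`U`).
#' @return List of class `complexity_estimate` with `n_total`, `n_unique`
#'   and `estimate` (`NA` when undefined).
#' @export
#' @examples
#' estimate_complexity(200, 100)  # ~125.6
estimate_complexity <- function(n_total, n_unique) {
  if (n_unique > n_total) stop("n_unique cannot exceed n_total")
  est <- NA_real_
  if (n_total > 0 && n_unique < n_total) {
    f <- function(C) C * (1 - exp(-n_total / C)) - n_unique
    lo <- max(n_unique, 1)
    hi <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    est <- stats::uniroot(f, c(lo, hi), tol = lo * 1e-8)$root
  }
  structure(
    list(n_total = n_total, n_unique = n_unique, estimate = est),
    class = "complexity_estimate"
  )
}

#' @export
print.complexity_estimate <- function(x, ...) {
  cat("library complexity: T =", x$n_total, ", U =", x$n_unique,
      ", C =", if (is.na(x$estimate)) "undefined (no duplicates)"
      else format(x$estimate, digits = 6), "\n")
  invisible(x)
}
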