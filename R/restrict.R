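#' Digest a genome with a restriction enzyme recognition site
#'
#' Computes the restriction fragment map of each chromosome: fragment
#' boundaries are placed at position 1 and at the first base of every match
#' of the recognition pattern on either strand (the pattern and its reverse
#' complement are both searched; palindromic sites are counted once).
#' IUPAC ambiguity codes are honoured.  Fragment `i` spans the half-open
#' interval `[start_i, start_{i+1})`, the last fragment ending at
#' chromosome length + 1.
#'
#' @param sequences Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @param site Recognition sequence (IUPAC alphabet), e.g. `"GATC"`.
#' @return Object of class `fragment_map`: list with `starts` (named list of
#'   sorted 1-based fragment start vectors) and `lengths` (named integer
#'   vector of chromosome lengths).
#' @export
#' @examples
#' digest_genome(c(chrT = "AAGATCAA"), "GATC")  # starts 1, 3
digest_genome <- function(sequences, site) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  site <- toupper(site)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) {
    stop("recognition site contains non-IUPAC letters: ", site)
  }
  pat <- Biostrings::DNAString(site)
  rc <- Biostrings::reverseComplement(pat)
  palindrome <- as.character(pat) == as.character(rc)
  starts <- lapply(seq_along(sequences), function(i) {
    subj <- sequences[[i]]
    hits <- IRanges::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
    if (!palindrome) {
      hits <- c(hits,
                IRanges::start(Biostrings::matchPattern(rc, subj,
                                                        fixed = FALSE)))
    }
    sort(unique(c(1L, as.integer(hits))))
  })
  names(starts) <- names(sequences)
  structure(
    list(starts = starts,
         lengths = stats::setNames(Biostrings::width(sequences),
                                   names(sequences))),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map>", length(x$starts), "chromosome(s),",
      sum(lengths(x$starts)), "fragments\n")
  invisible(x)
}

#' Write / read a fragment map as BED3-compatible TSV
#'
#' One line per fragment: chromosome, 0-based start, 0-based-exclusive end.
#' @param frags A [digest_genome()] result.
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  lines <- unlist(lapply(names(frags$starts), function(ch) {
    st <- frags$starts[[ch]]
    en <- c(st[-1], frags$lengths[[ch]] + 1L)
    sprintf("%s\t%d\t%d", ch, st - 1L, en - 1L)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fragments
#' @return `read_fragments`: a `fragment_map`.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end"))
  starts <- lapply(split(dt, by = "chrom", sorted = FALSE),
                   function(d) sort(as.integer(d$start + 1L)))
  lens <- vapply(split(dt, by = "chrom", sorted = FALSE),
                 function(d) as.integer(max(d$end)), integer(1))
  structure(list(starts = starts, lengths = lens), class = "fragment_map")
}

#' Annotate pairs with their restriction fragments
#'
#' Locates each mapped side in the fragment map by binary search on the
#' fragment starts and appends six extra columns: `rfrag1`, `rfrag_start1`,
#' `rfrag_end1`, and the side-2 triple.  Fragment indices are 0-based
#' ordinals per chromosome; ends are the exclusive fragment bound.  Null
#' sides are annotated with the sentinel -1.
#'
#' @param pairs `.pairs` record `data.table`.
#' @param frags A [digest_genome()] / [read_fragments()] result covering the
#'   record chromosomes.
#' @return A copy of `pairs` with the six annotation columns.
#' @export
annotate_restriction <- function(pairs, frags) {
  pairs <- data.table::copy(pairs)
  for (s in 1:2) {
    chrom <- pairs[[paste0("chrom", s)]]
    pos <- pairs[[paste0("pos", s)]]
    idx <- rep(-1L, nrow(pairs))
    fs <- rep(-1L, nrow(pairs))
    fe <- rep(-1L, nrow(pairs))
    for (ch in unique(chrom)) {
      if (ch == .NULL_CHROM) next
      if (is.null(frags$starts[[ch]])) {
        stop("fragment map does not cover chromosome '", ch, "'")
      }
      st <- frags$starts[[ch]]
      en <- c(st[-1], frags$lengths[[ch]] + 1L)
      sel <- which(chrom == ch)
      p <- pos[sel]
      if (any(p > frags$lengths[[ch]])) {
        stop("position beyond chromosome '", ch, "' length")
      }
      k <- findInterval(p, st)
      idx[sel] <- k - 1L
      fs[sel] <- st[k]
      fe[sel] <- en[k]
    }
    pairs[, (paste0("rfrag", s)) := idx]
    pairs[, (paste0("rfrag_start", s)) := fs]
    pairs[, (paste0("rfrag_end", s)) := fe]
  }
  pairs[]
}

#' Classify restriction ligation by-products
#'
#' Pairs on two different restriction fragments are regular (`valid`)
#' ligation products.  Pairs whose two sides fall on the *same* fragment are
#' protocol by-products, told apart by strand orientation (on flipped pairs,
#' side 1 is the leftmost): convergent `+-` pairs are unligated dangling
#' ends, divergent `-+` pairs are self-circles, and same-strand pairs are
#' mirror artefacts (putative PCR by-products).
#'
#' @param pairs Flipped pairs annotated by [annotate_restriction()].
#' @return Character vector: `"valid"`, `"dangling_end"`, `"self_circle"` or
#'   `"mirror"` (`NA` for pairs with an unannotated side).
#' @export
classify_byproduct <- function(pairs) {
  need <- c("rfrag1", "rfrag2")
  if (!all(need %in% names(pairs))) {
    stop("pairs lack restriction annotations; run annotate_restriction()")
  }
  same <- pairs$chrom1 == pairs$chrom2 &
    pairs$rfrag1 == pairs$rfrag2 & pairs$rfrag1 >= 0L
  orient <- paste0(pairs$strand1, pairs$strand2)
  out <- rep("valid", nrow(pairs))
  out[same & orient == "+-"] <- "dangling_end"
  out[same & orient == "-+"] <- "self_circle"
  out[same & (orient == "++" | orient == "--")] <- "mirror"
  out[pairs$rfrag1 < 0L | pairs$rfrag2 < 0L] <- NA_character_
  out
}
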