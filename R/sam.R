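#' Read SAM text alignments
#'
#' Distills SAM alignment lines into a table of alignment records.  Only the
#' text SAM dialect is accepted; BAM input should be converted externally
#' (e.g. `samtools view`).  The reference span is computed by walking the
#' CIGAR string over its reference-consuming operations, and the aligned
#' portion of the read is reported as a 0-based half-open interval in the
#' orientation of the original read (clips, including hard clips, count
#' towards read coordinates).
#'
#' @param x Path to a SAM text file, or a character vector of SAM lines.
#' @return List with `samheader` (the `@`-prefixed lines) and `alignments`,
#'   a `data.table` with one row per alignment record: `qname`, `flag`,
#'   `chrom`, `pos`, `mapq`, `cigar`, `is_mapped`, `is_secondary`,
#'   `is_supplementary`, `side` (1/2 from the mate flags), `strand`,
#'   `ref_start`/`ref_end` (1-based closed), `read_start`/`read_end`
#'   (0-based half-open, read orientation), `read_len`, `score` (AS tag)
#'   and `xb` (suboptimal-alignment tag, see [phase_pairs()]).
#' @export
read_sam <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    con <- .open_read(x)
    on.exit(close(con))
    readLines(con)
  } else {
    x
  }
  is_head <- startsWith(lines, "@")
  list(
    samheader = lines[is_head],
    alignments = parse_sam_alignments(lines[!is_head])
  )
}

#' Parse SAM alignment lines into a table
#'
#' Vectorised workhorse behind [read_sam()]; see there for the columns.
#'
#' @param lines Character vector of SAM alignment lines (no `@` headers).
#' @return `data.table` of alignments, in input order.
#' @export
parse_sam_alignments <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.table::data.table(
      qname = character(), flag = integer(), chrom = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      is_mapped = logical(), is_secondary = logical(),
      is_supplementary = logical(), side = integer(), strand = character(),
      ref_start = integer(), ref_end = integer(), read_start = integer(),
      read_end = integer(), read_len = integer(), score = integer(),
      xb = character()
    ))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 11L || anyNA(fields[[11]])) {
    bad <- if (length(fields) < 11L) 1L else which(is.na(fields[[11]]))[1]
    stop("not a SAM alignment line (fewer than 11 fields): '",
         substr(lines[bad], 1, 60), "'")
  }
  flag <- suppressWarnings(as.integer(fields[[2]]))
  if (anyNA(flag)) {
    stop("non-numeric FLAG field: '",
         substr(lines[which(is.na(flag))[1]], 1, 60), "'")
  }
  aln <- data.table::data.table(
    qname = fields[[1]],
    flag = flag,
    chrom = fields[[3]],
    pos = as.integer(fields[[4]]),
    mapq = as.integer(fields[[5]]),
    cigar = fields[[6]]
  )
  aln[, is_mapped := bitwAnd(flag, 4L) == 0L]
  # a mapped record with CIGAR "*" carries no span information
  star <- aln$is_mapped & aln$cigar == "*"
  if (any(star)) {
    warning(sum(star), " mapped record(s) with CIGAR '*' treated as unmapped")
    aln[star, is_mapped := FALSE]
  }
  aln[, is_secondary := bitwAnd(flag, 256L) != 0L]
  aln[, is_supplementary := bitwAnd(flag, 2048L) != 0L]
  aln[, side := data.table::fifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L)]
  aln[, strand := data.table::fifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]

  cw <- .cigar_walk(aln$cigar)
  aln[, `:=`(
    ref_start = data.table::fifelse(is_mapped, pos, NA_integer_),
    ref_end = data.table::fifelse(is_mapped, pos + cw$ref_len - 1L,
                                  NA_integer_),
    read_len = cw$read_len,
    read_start = data.table::fifelse(strand == "+", cw$lead, cw$trail),
    read_end = data.table::fifelse(strand == "+", cw$lead, cw$trail) +
      cw$query_aln
  )]
  aln[is_mapped == FALSE, `:=`(
    chrom = .NULL_CHROM, ref_start = NA_integer_, ref_end = NA_integer_,
    read_start = NA_integer_, read_end = NA_integer_
  )]

  # optional tags: AS (alignment score), XB (suboptimal placements)
  tagpart <- vapply(
    strsplit(lines, "\t", fixed = TRUE),
    function(f) paste(f[-seq_len(11L)], collapse = "\t"),
    character(1)
  )
  aln[, score := NA_integer_]
  has_as <- grepl("AS:i:", tagpart, fixed = TRUE)
  aln[has_as, score := as.integer(sub("AS:i:", "",
                                      regmatches(tagpart, regexpr("AS:i:-?[0-9]+", tagpart))))]
  aln[, xb := NA_character_]
  has_xb <- grepl("XB:Z:", tagpart, fixed = TRUE)
  if (any(has_xb)) {
    aln[has_xb, xb := sub("XB:Z:", "",
                          regmatches(tagpart, regexpr("XB:Z:[^\t]+", tagpart)))]
  }
  aln[]
}

#' Parse a single SAM record
#'
#' @param line One SAM alignment line.
#' @return One-row `data.table`; see [parse_sam_alignments()].
#' @export
parse_sam_record <- function(line) parse_sam_alignments(line)

# CIGAR accounting.  ref-consuming ops: M D N = X; query-consuming: M I = X;
# clips S and H are part of the original read but not of the alignment.
.cigar_walk <- function(cigars) {
  n <- length(cigars)
  ref_len <- integer(n)
  query_aln <- integer(n)
  lead <- integer(n)
  trail <- integer(n)
  read_len <- integer(n)
  ok <- cigars != "*" & !is.na(cigars)
  if (any(ok)) {
    toks <- regmatches(cigars[ok], gregexpr("[0-9]+[MIDNSHP=X]", cigars[ok]))
    bad <- vapply(toks, function(t) length(t) == 0L, logical(1)) |
      vapply(toks, function(t) sum(nchar(t)), integer(1)) !=
        nchar(cigars[ok])
    if (any(bad)) {
      stop("malformed CIGAR string: '", cigars[ok][which(bad)[1]], "'")
    }
    res <- vapply(toks, function(t) {
      len <- as.integer(sub("[MIDNSHP=X]", "", t))
      op <- substr(t, nchar(t), nchar(t))
      nref <- sum(len[op %in% c("M", "D", "N", "=", "X")])
      nq <- sum(len[op %in% c("M", "I", "=", "X")])
      clip <- op %in% c("S", "H")
      aligned_at <- which(!clip)
      nlead <- if (length(aligned_at)) {
        sum(len[seq_len(aligned_at[1] - 1L)][clip[seq_len(aligned_at[1] - 1L)]])
      } else sum(len[clip])
      ntrail <- if (length(aligned_at)) {
        rest <- seq_along(len) > aligned_at[length(aligned_at)]
        sum(len[rest & clip])
      } else 0L
      c(nref, nq, nlead, ntrail)
    }, numeric(4))
    ref_len[ok] <- as.integer(res[1, ])
    query_aln[ok] <- as.integer(res[2, ])
    lead[ok] <- as.integer(res[3, ])
    trail[ok] <- as.integer(res[4, ])
    read_len[ok] <- query_aln[ok] + lead[ok] + trail[ok]
  }
  list(ref_len = ref_len, query_aln = query_aln, lead = lead,
       trail = trail, read_len = read_len)
}

#' Group alignments into per-read bundles
#'
#' Splits a name-grouped alignment table into one bundle per read id,
#' preserving the input order of reads.  A read id that reappears after a
#' different id indicates that the input was not produced read-by-read and is
#' rejected.
#'
#' @param alignments `data.table` from [parse_sam_alignments()].
#' @return List of `data.table`s, one per read id, each carrying all
#'   alignments of that read (secondary/supplementary included but flagged).
#' @export
group_by_read <- function(alignments) {
  if (!nrow(alignments)) return(list())
  run <- data.table::rleid(alignments$qname)
  firsts <- alignments$qname[!duplicated(run)]
  if (anyDuplicated(firsts)) {
    dup <- firsts[duplicated(firsts)][1]
    stop("input not name-grouped: read id '", dup,
         "' reappears after a different id")
  }
  split(alignments, run)
}
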