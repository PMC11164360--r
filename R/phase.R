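#' Phasing configuration
#'
#' Haplotype-resolved protocols map reads against a combined diploid
#' reference whose chromosome names carry a haplotype suffix
#' (`name<sep><suffix>`, e.g. `chr1#0` / `chr1#1`).  Phasing compares the
#' best alignment score of a side with the scores of reported suboptimal
#' placements to decide whether the side is confidently assigned to one
#' haplotype, unresolved (the homologous position scores equally — no
#' distinguishing variant), or a genuine multi-mapper.
#'
#' @param suffixes Two distinct haplotype suffixes, in haplotype order.
#' @param sep Separator between base chromosome name and suffix.
#' @param score_tie_margin Score difference (inclusive) within which a
#'   suboptimal alignment counts as tied with the best one.  The default 0
#'   treats only exact ties as ambiguous.
#' @return List of class `phase_config`.
#' @export
phase_config <- function(suffixes = c("0", "1"), sep = "#",
                         score_tie_margin = 0) {
  stopifnot(length(suffixes) == 2L, suffixes[1] != suffixes[2],
            score_tie_margin >= 0)
  structure(list(suffixes = suffixes, sep = sep,
                 score_tie_margin = score_tie_margin),
            class = "phase_config")
}

# split "chr1#0" into base "chr1" and suffix "0"; error on unknown suffix
.split_haplotype <- function(chrom, config) {
  pat <- paste0(
    "^(.*)", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", config$sep),
    "(", paste(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", config$suffixes),
               collapse = "|"), ")$"
  )
  ok <- grepl(pat, chrom)
  list(ok = ok,
       base = sub(pat, "\\1", chrom),
       suffix = sub(pat, "\\2", chrom))
}

#' Phase one aligned side
#'
#' A side resolves to the haplotype of its best alignment unless a
#' suboptimal alignment ties with it (within `score_tie_margin`): a tie on
#' the homologous chromosome (same base name, other haplotype) means the
#' read covers no distinguishing variant and the side is `unresolved`; a tie
#' anywhere else marks a true `multi`-mapper (multi takes precedence over an
#' additional homologous tie).
#'
#' @param chrom Suffixed chromosome name of the best alignment.
#' @param score Best alignment score.
#' @param xb Suboptimal alignments as `"chrom,pos,strand,score"` entries
#'   joined by `;` (`NA` or `""` = none reported).
#' @param config A [phase_config()].
#' @return List with `status` (`"hap1"`, `"hap2"`, `"unresolved"`,
#'   `"multi"`) and `base` (chromosome name without suffix).
#' @export
phase_side <- function(chrom, score, xb, config = phase_config()) {
  sp <- .split_haplotype(chrom, config)
  if (!sp$ok) {
    stop("chromosome '", chrom, "' carries no recognised haplotype suffix")
  }
  status <- if (sp$suffix == config$suffixes[1]) "hap1" else "hap2"
  if (!is.na(xb) && nzchar(xb) && !is.na(score)) {
    entries <- strsplit(strsplit(xb, ";", fixed = TRUE)[[1]], ",",
                        fixed = TRUE)
    homolog_tie <- FALSE
    other_tie <- FALSE
    for (e in entries) {
      if (length(e) < 4L) next
      sub_score <- suppressWarnings(as.numeric(e[4]))
      if (is.na(sub_score) || score - sub_score > config$score_tie_margin) {
        next
      }
      sub_sp <- .split_haplotype(e[1], config)
      if (sub_sp$ok && sub_sp$base == sp$base &&
          sub_sp$suffix != sp$suffix) {
        homolog_tie <- TRUE
      } else {
        other_tie <- TRUE
      }
    }
    if (other_tie) status <- "multi"
    else if (homolog_tie) status <- "unresolved"
  }
  list(status = status, base = sp$base)
}

.PHASE_CODES <- c(hap1 = "0", hap2 = "1", unresolved = ".", multi = "!")

#' Phase a pairs table
#'
#' Applies [phase_side()] to both sides of every mapped record, appends
#' `phase1`/`phase2` columns (haplotype suffix, `.` for unresolved, `!` for
#' multi-mappers), rewrites chromosome names to their base (suffix-free)
#' form, and re-flips against the base chromosome order.  Requires the
#' score/suboptimal columns emitted by [parse_pairs()] with
#' `extra_columns = c("score1","score2","XB1","XB2")`.
#'
#' @param pairs `.pairs` record `data.table` with score and XB columns.
#' @param header A [pairs_header] whose chromsizes are the suffixed diploid
#'   reference.
#' @param config A [phase_config()].
#' @return `list(header=, pairs=)` with base-name chromosomes, phase columns
#'   declared in the header, and records re-flipped.
#' @export
phase_pairs <- function(pairs, header, config = phase_config()) {
  for (cn in c("score1", "score2", "XB1", "XB2")) {
    if (!cn %in% names(pairs)) {
      stop("phasing requires column '", cn,
           "'; re-run parse with the score/XB extra columns")
    }
  }
  pairs <- data.table::copy(pairs)
  n <- nrow(pairs)
  for (s in 1:2) {
    chrom <- pairs[[paste0("chrom", s)]]
    score <- as.numeric(pairs[[paste0("score", s)]])
    xb <- as.character(pairs[[paste0("XB", s)]])
    phase <- rep(.NULL_STRAND, n)
    base <- chrom
    mapped <- chrom != .NULL_CHROM
    for (i in which(mapped)) {
      r <- phase_side(chrom[i], score[i], xb[i], config)
      phase[i] <- .PHASE_CODES[[r$status]]
      base[i] <- r$base
    }
    pairs[, (paste0("chrom", s)) := base]
    pairs[, (paste0("phase", s)) := phase]
  }
  # base-name chromosome sizes: homologs may differ (indels); keep the max
  sp <- .split_haplotype(names(header$chromsizes), config)
  if (!all(sp$ok)) {
    stop("header chromosome '", names(header$chromsizes)[!sp$ok][1],
         "' carries no recognised haplotype suffix")
  }
  base_names <- unique(sp$base)
  base_sizes <- vapply(base_names, function(b) {
    max(header$chromsizes[sp$base == b])
  }, integer(1))
  new_header <- header
  new_header$chromsizes <- stats::setNames(base_sizes, base_names)
  new_header$columns <- union(header$columns, c("phase1", "phase2"))
  data.table::setcolorder(pairs, new_header$columns)
  list(header = new_header,
       pairs = flip_pairs(pairs, new_header$chromsizes))
}
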