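#' Read a `.pairs` file
#'
#' Reads the `#`-prefixed header and the tab-separated body of a 4DN `.pairs`
#' file.  Files ending in `.gz` are decompressed transparently.  In strict
#' mode every record is checked against the header: correct column count,
#' declared chromosome names (or the `!` null sentinel with position 0 and
#' strand `.`), and positions within the declared chromosome lengths.
#'
#' @param path Path to a `.pairs`/`.pairs.gz` file, or a text connection.
#' @param strict Validate every record against the header invariants.
#' @return A list with elements `header` (a [pairs_header]) and `pairs`
#'   (a `data.table`, one row per contact).
#' @export
read_pairs <- function(path, strict = FALSE) {
  con <- .open_read(path)
  if (!inherits(path, "connection")) on.exit(close(con))
  lines <- readLines(con)
  is_head <- grepl("^#", lines)
  # header must be a prefix of the file
  n_head <- if (any(!is_head)) which(!is_head)[1] - 1L else length(lines)
  if (any(is_head[-seq_len(n_head)])) {
    bad <- which(is_head & seq_along(lines) > n_head)[1]
    stop("header line after body at line ", bad)
  }
  header <- .parse_header_lines(lines[seq_len(n_head)])
  if (is.null(header$columns)) {
    if (strict) stop("header lacks a '#columns:' line")
    header$columns <- .PAIRS_CORE_COLUMNS
  }
  body <- lines[seq_along(lines) > n_head]
  pairs <- .parse_pairs_body(body, header, strict = strict,
                             line_offset = n_head)
  list(header = header, pairs = pairs)
}

.parse_pairs_body <- function(body, header, strict = FALSE, line_offset = 0L) {
  ncol <- length(header$columns)
  if (!length(body)) {
    pairs <- data.table::as.data.table(
      stats::setNames(rep(list(character()), ncol), header$columns)
    )
    pairs[, `:=`(pos1 = integer(), pos2 = integer())]
    return(pairs[])
  }
  split <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(split) != ncol) {
    widths <- lengths(strsplit(body, "\t", fixed = TRUE))
    bad <- which(widths != ncol)[1]
    stop(sprintf(
      "record at line %d has %d fields, header declares %d",
      line_offset + bad, widths[bad], ncol
    ))
  } else if (anyNA(split[[ncol]])) {
    bad <- which(is.na(split[[ncol]]))[1]
    stop(sprintf(
      "record at line %d has fewer fields than the %d declared",
      line_offset + bad, ncol
    ))
  }
  pairs <- data.table::setDT(stats::setNames(split, header$columns))
  pairs[, `:=`(pos1 = as.integer(pos1), pos2 = as.integer(pos2))]
  if (strict) .validate_records(pairs, header, line_offset)
  pairs[]
}

# strict per-record invariants; errors name the first offending line
.validate_records <- function(pairs, header, line_offset = 0L) {
  known <- c(names(header$chromsizes), .NULL_CHROM)
  for (s in 1:2) {
    chrom <- pairs[[paste0("chrom", s)]]
    pos <- pairs[[paste0("pos", s)]]
    strand <- pairs[[paste0("strand", s)]]
    bad <- which(!(chrom %in% known))
    if (length(bad)) {
      stop(sprintf("unknown chromosome '%s' at line %d",
                   chrom[bad[1]], line_offset + bad[1]))
    }
    isnull <- chrom == .NULL_CHROM
    bad <- which(isnull & (pos != .NULL_POS | strand != .NULL_STRAND))
    if (length(bad)) {
      stop(sprintf("null side with non-null pos/strand at line %d",
                   line_offset + bad[1]))
    }
    bad <- which(!isnull & (is.na(pos) | pos < 1L))
    if (length(bad)) {
      stop(sprintf("mapped side with position < 1 at line %d",
                   line_offset + bad[1]))
    }
    lens <- header$chromsizes[chrom]
    bad <- which(!isnull & pos > lens)
    if (length(bad)) {
      stop(sprintf("position beyond chromosome end at line %d",
                   line_offset + bad[1]))
    }
    bad <- which(!isnull & !(strand %in% c("+", "-", ".")))
    if (length(bad)) {
      stop(sprintf("invalid strand '%s' at line %d",
                   strand[bad[1]], line_offset + bad[1]))
    }
  }
  invisible(TRUE)
}

#' Write a `.pairs` file
#'
#' Emits the header (with an optional provenance entry appended for the
#' current command) followed by one tab-separated line per record.  Reading
#' the result back with [read_pairs()] reproduces the records exactly and the
#' header up to the appended provenance entry.
#'
#' @param header A [pairs_header].
#' @param pairs `data.table` of records whose columns match
#'   `header$columns`.
#' @param path Output path (gzip-compressed if it ends in `.gz`) or a
#'   writable text connection.
#' @param command Optional provenance string recorded as a `#command:` entry.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(header, pairs, path, command = NULL) {
  problems <- validate_pairs_header(header)
  if (length(problems)) {
    stop("invalid header: ", paste(problems, collapse = "; "))
  }
  if (!identical(names(pairs), header$columns)) {
    stop(sprintf(
      "record columns (%s) do not match header columns (%s)",
      paste(names(pairs), collapse = ","),
      paste(header$columns, collapse = ",")
    ))
  }
  if (!is.null(command)) header$provenance <- c(header$provenance, command)
  con <- .open_write(path)
  if (!inherits(path, "connection")) on.exit(close(con))
  writeLines(.format_header(header), con)
  if (nrow(pairs)) {
    writeLines(do.call(paste, c(as.list(pairs), sep = "\t")), con)
  }
  invisible(path)
}

# serialize records to body lines without touching a file (sorting tie-breaks,
# byte-exact comparisons)
.pairs_lines <- function(pairs) {
  if (!nrow(pairs)) return(character())
  do.call(paste, c(as.list(pairs), sep = "\t"))
}
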