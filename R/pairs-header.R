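#' Construct a `.pairs` file header
#'
#' The header of a `.pairs` file carries the chromosome order and sizes of the
#' reference assembly, the names of the body columns (the first eight of which
#' are fixed by the 4DN specification), the SAM header of the alignments the
#' pairs were derived from, and a provenance trail with one entry per command
#' that touched the file.
#'
#' @param chromsizes Named integer vector, or two-column data.frame
#'   (name, length), giving chromosomes in their canonical order.
#' @param columns Character vector of column names; must start with the eight
#'   reserved names `readID chrom1 pos1 chrom2 pos2 strand1 strand2 pair_type`.
#' @param samheader Character vector of SAM header lines (`@`-prefixed).
#' @param provenance Character vector of command-line records.
#' @param version Format version string.
#' @param other Verbatim `#`-prefixed header lines not otherwise interpreted.
#'
#' @return An object of class `pairs_header`.
#' @export
#' @examples
#' h <- pairs_header(c(chr1 = 10000L, chr2 = 8000L))
#' validate_pairs_header(h)
pairs_header <- function(chromsizes,
                         columns = .PAIRS_CORE_COLUMNS,
                         samheader = character(),
                         provenance = character(),
                         version = "1.0",
                         other = character()) {
  chromsizes <- .as_chromsizes(chromsizes)
  h <- structure(
    list(
      version = version,
      chromsizes = chromsizes,
      columns = columns,
      samheader = samheader,
      provenance = provenance,
      other = other
    ),
    class = "pairs_header"
  )
  problems <- validate_pairs_header(h)
  if (length(problems)) {
    stop("invalid pairs header: ", paste(problems, collapse = "; "))
  }
  h
}

.as_chromsizes <- function(x) {
  if (is.data.frame(x)) {
    cs <- as.integer(x[[2]])
    names(cs) <- as.character(x[[1]])
    return(cs)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("chromsizes must be named (chromosome name -> length)")
  }
  stats::setNames(as.integer(x), names(x))
}

#' Validate a `.pairs` header
#'
#' Checks the structural invariants of the header (reserved leading columns,
#' unique chromosome names, positive lengths) and returns a character vector
#' of violations; an empty vector means the header is valid.  Validation
#' never throws.
#'
#' @param header A `pairs_header` (or any list with the same fields).
#' @return Character vector of human-readable violations (possibly empty).
#' @export
validate_pairs_header <- function(header) {
  problems <- character()
  if (is.null(header$columns) || length(header$columns) < 8L) {
    problems <- c(problems, "missing or short '#columns' declaration")
  } else if (!identical(header$columns[1:8], .PAIRS_CORE_COLUMNS)) {
    problems <- c(problems, paste0(
      "first eight columns must be '",
      paste(.PAIRS_CORE_COLUMNS, collapse = " "), "'"
    ))
  }
  if (anyDuplicated(header$columns)) {
    problems <- c(problems, "duplicated column names")
  }
  cs <- header$chromsizes
  if (is.null(cs) || length(cs) == 0L) {
    problems <- c(problems, "no '#chromsize' entries")
  } else {
    if (anyDuplicated(names(cs))) {
      problems <- c(problems, "duplicated chromosome names")
    }
    if (any(is.na(cs)) || any(cs <= 0L)) {
      problems <- c(problems, "chromosome lengths must be positive")
    }
    if (.NULL_CHROM %in% names(cs)) {
      problems <- c(problems, "'!' is reserved for null sides")
    }
  }
  problems
}

#' @export
print.pairs_header <- function(x, ...) {
  cat("<pairs_header> format v", x$version, "\n", sep = "")
  cat("  chromosomes: ", length(x$chromsizes), " (",
      paste(head(names(x$chromsizes), 4), collapse = ", "),
      if (length(x$chromsizes) > 4) ", ..." else "", ")\n", sep = "")
  cat("  columns:", paste(x$columns, collapse = " "), "\n")
  if (length(x$provenance)) {
    cat("  provenance entries:", length(x$provenance), "\n")
  }
  invisible(x)
}

# serialize header to "#"-prefixed lines; columns line goes last so that the
# body follows its declaration immediately
.format_header <- function(header) {
  c(
    paste0("## pairs format v", header$version),
    "#shape: upper triangle",
    sprintf("#chromsize: %s %d", names(header$chromsizes), header$chromsizes),
    if (length(header$samheader)) paste0("#samheader: ", header$samheader),
    if (length(header$provenance)) paste0("#command: ", header$provenance),
    header$other,
    paste0("#columns: ", paste(header$columns, collapse = " "))
  )
}

# parse "#"-prefixed lines into a pairs_header; strict structure errors name
# the offending line
.parse_header_lines <- function(lines) {
  version <- "1.0"
  chrom_names <- character()
  chrom_lens <- integer()
  columns <- NULL
  samheader <- character()
  provenance <- character()
  other <- character()
  for (ln in lines) {
    if (grepl("^## pairs format", ln)) {
      version <- sub("^## pairs format v?", "", ln)
    } else if (grepl("^#chromsize:", ln)) {
      fields <- strsplit(trimws(sub("^#chromsize:", "", ln)), "[ \t]+")[[1]]
      if (length(fields) != 2L || is.na(suppressWarnings(as.integer(fields[2])))) {
        stop("malformed header line: '", ln, "'")
      }
      chrom_names <- c(chrom_names, fields[1])
      chrom_lens <- c(chrom_lens, as.integer(fields[2]))
    } else if (grepl("^#columns:", ln)) {
      columns <- strsplit(trimws(sub("^#columns:", "", ln)), "[ \t]+")[[1]]
    } else if (grepl("^#samheader:", ln)) {
      samheader <- c(samheader, sub("^#samheader:[ ]?", "", ln))
    } else if (grepl("^#command:", ln)) {
      provenance <- c(provenance, sub("^#command:[ ]?", "", ln))
    } else if (grepl("^#shape:", ln)) {
      # implied by flipping; kept implicit
    } else if (grepl("^#", ln)) {
      other <- c(other, ln)
    } else {
      stop("malformed header line: '", ln, "'")
    }
  }
  structure(
    list(
      version = version,
      chromsizes = stats::setNames(chrom_lens, chrom_names),
      columns = columns,
      samheader = samheader,
      provenance = provenance,
      other = other
    ),
    class = "pairs_header"
  )
}

#' Generate, validate, transfer or modify a `.pairs` header
#'
#' A single dispatcher mirroring the `header` command of the CLI.
#'
#' * `generate`: build a minimal valid header from `chromsizes` (+ `columns`).
#' * `validate`: return the character vector of violations for `header`
#'   (empty when valid); never throws.
#' * `transfer`: attach `donor`'s header to a body with `body_ncol` columns;
#'   errors when the widths disagree.  Unknown `#` lines of the donor are
#'   preserved verbatim.
#' * `set_columns`: replace the column names of `header` by `columns`.
#'
#' @param action One of `"generate"`, `"validate"`, `"transfer"`,
#'   `"set_columns"`.
#' @param header Target header (for validate / set_columns).
#' @param donor Donor header (for transfer).
#' @param columns Column names (generate / set_columns).
#' @param chromsizes Chromosome sizes (generate).
#' @param body_ncol Number of columns of the recipient body (transfer).
#' @return A `pairs_header`, or a character vector of violations for
#'   `action = "validate"`.
#' @export
header_update <- function(action = c("generate", "validate", "transfer",
                                     "set_columns"),
                          header = NULL, donor = NULL, columns = NULL,
                          chromsizes = NULL, body_ncol = NULL) {
  action <- match.arg(action)
  switch(action,
    generate = {
      if (is.null(chromsizes)) stop("generate requires chromsizes")
      pairs_header(chromsizes, columns = columns %||% .PAIRS_CORE_COLUMNS)
    },
    validate = {
      validate_pairs_header(header)
    },
    transfer = {
      if (is.null(donor)) stop("transfer requires a donor header")
      if (!is.null(body_ncol) && body_ncol != length(donor$columns)) {
        stop(sprintf(
          "donor header declares %d columns but body has %d",
          length(donor$columns), body_ncol
        ))
      }
      donor
    },
    set_columns = {
      if (is.null(header) || is.null(columns)) {
        stop("set_columns requires header and columns")
      }
      if (length(columns) != length(header$columns)) {
        stop("set_columns must preserve the column count (",
             length(header$columns), ")")
      }
      header$columns <- columns
      problems <- validate_pairs_header(header)
      if (length(problems)) {
        stop("invalid columns: ", paste(problems, collapse = "; "))
      }
      header
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with chromosome name and length columns.
#' @return Named integer vector of chromosome lengths, in file order.
#' @export
read_chromsizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("name", "length"))
  stats::setNames(as.integer(dt$length), dt$name)
}

#' Write a chromosome-sizes file
#' @param chromsizes Named integer vector.
#' @param path Output path.
#' @export
write_chromsizes <- function(chromsizes, path) {
  writeLines(sprintf("%s\t%d", names(chromsizes), chromsizes), path)
  invisible(path)
}
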