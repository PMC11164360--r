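#' Split a pairs table by a filter expression
#'
#' Partitions records into those matching a boolean expression over the
#' declared columns and the rest, preserving order in both outputs.  The
#' expression is parsed and checked against a restricted grammar — column
#' names, literals, comparisons (`==`, `!=`, `<`, `<=`, `>`, `>=`),
#' arithmetic (`+`, `-`, `*`, `/`, `abs`), boolean connectives (`&`, `|`,
#' `!`, with `and`/`or`/`not` and `True`/`False` accepted as synonyms), set
#' membership (`%in%`, `c`) and regular-expression matching (`grepl`) — so
#' no arbitrary code can run.  Position columns compare numerically.
#'
#' @param pairs `.pairs` record `data.table`.
#' @param expr Filter expression as a string, e.g.
#'   `"(chrom1 != chrom2) or (abs(pos1 - pos2) >= 2000)"`; alternatively a
#'   function taking the record table and returning a logical vector (API
#'   hook for arbitrary predicates).
#' @param header Optional [pairs_header]; when given, column references are
#'   validated against its declared columns before streaming.
#' @return List with `selected` and `rest` record tables.
#' @export
select_pairs <- function(pairs, expr, header = NULL) {
  if (is.function(expr)) {
    keep <- expr(pairs)
  } else {
    e <- .compile_filter(expr, header %||% list(columns = names(pairs)))
    keep <- eval(e, envir = pairs, enclos = .filter_env())
  }
  if (!is.logical(keep)) stop("filter expression is not boolean")
  if (length(keep) == 1L) keep <- rep(keep, nrow(pairs))
  if (length(keep) != nrow(pairs)) {
    stop("filter expression returned ", length(keep), " values for ",
         nrow(pairs), " records")
  }
  keep[is.na(keep)] <- FALSE
  list(selected = pairs[keep], rest = pairs[!keep])
}

.FILTER_FUNS <- c("==", "!=", "<", "<=", ">", ">=", "+", "-", "*", "/",
                  "abs", "&", "|", "!", "&&", "||", "(", "%in%", "c",
                  "grepl", "min", "max", "xor")

.filter_env <- function() {
  env <- new.env(parent = emptyenv())
  for (f in .FILTER_FUNS) assign(f, get(f, envir = baseenv()), envir = env)
  env
}

.compile_filter <- function(expr, header) {
  # pythonic synonyms accepted for CLI parity
  expr <- gsub("\\band\\b", "&", expr)
  expr <- gsub("\\bor\\b", "|", expr)
  expr <- gsub("\\bnot\\b", "!", expr)
  expr <- gsub("\\bTrue\\b", "TRUE", expr)
  expr <- gsub("\\bFalse\\b", "FALSE", expr)
  e <- tryCatch(str2lang(expr),
                error = function(err) stop("cannot parse filter expression: ",
                                           conditionMessage(err)))
  .check_filter_ast(e, header$columns)
  e
}

.check_filter_ast <- function(e, columns) {
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .FILTER_FUNS) {
      stop("function '", fn, "' is not allowed in filter expressions")
    }
    for (arg in as.list(e)[-1]) .check_filter_ast(arg, columns)
  } else if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% c(columns, "TRUE", "FALSE", "T", "F")) {
      stop("unknown column '", nm, "' in filter expression")
    }
  } else if (!(is.numeric(e) || is.character(e) || is.logical(e))) {
    stop("literal of unsupported type in filter expression")
  }
  invisible(TRUE)
}

#' Randomly subsample a pairs table
#'
#' Fraction mode makes an independent keep-decision per record with the
#' given probability; count mode draws a uniform without-replacement subset
#' of exactly `count` records.  Both are deterministic for a given seed,
#' preserve record order, and leave the caller's RNG state untouched.
#'
#' @param pairs `.pairs` record `data.table`.
#' @param fraction Keep probability in `[0, 1]` (exclusive with `count`).
#' @param count Exact subset size (exclusive with `fraction`).
#' @param seed Integer seed.
#' @return Subset record table, in input order.
#' @export
sample_pairs <- function(pairs, fraction = NULL, count = NULL, seed = 1L) {
  if (is.null(fraction) == is.null(count)) {
    stop("give exactly one of fraction or count")
  }
  n <- nrow(pairs)
  if (!is.null(fraction)) {
    stopifnot(fraction >= 0, fraction <= 1)
    keep <- .with_seed(seed, runif(n) < fraction)
    pairs[keep]
  } else {
    if (count > n) stop("count (", count, ") exceeds input size (", n, ")")
    idx <- .with_seed(seed, sort(sample.int(n, count)))
    pairs[idx]
  }
}
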