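#' Summary statistics of a pairs dataset
#'
#' Single-pass quality-control summary: totals by mapping category, the
#' pair-type histogram, cis/trans counts, cis counts above a ladder of
#' separation thresholds, per-chromosome-pair counts, the strand-oriented
#' scaling with its orientation convergence distance, and the library
#' complexity estimate (when duplicates are marked, i.e. after
#' [dedup_pairs()]).
#'
#' Sides are classed from the pair-type code: `U`/`R` count as uniquely
#' mapped; `N` and masked-walk `W` as unmapped; `M` as multi-mapped.  `DD`
#' records are duplicates of both-unique pairs.  Cis/trans and the distance
#' tiers are computed on mapped, deduplicated records.
#'
#' @param pairs Flipped `.pairs` record `data.table` (deduplication
#'   optional).
#' @param header A [pairs_header] (chromosome order and sizes).
#' @param with_scaling Include the oriented scaling and convergence distance.
#' @param min_dist,max_dist,bins_per_decade Binning, see [compute_scaling()].
#' @param rel_tol,min_count Convergence call, see [convergence_distance()].
#' @param dist_tiers Cis separation thresholds (bp) for the `cis_*kb+`
#'   counters.
#' @return Nested list of class `pairs_stats`.
#' @export
compute_stats <- function(pairs, header, with_scaling = TRUE,
                          min_dist = 10, max_dist = NULL,
                          bins_per_decade = 8, rel_tol = 0.25,
                          min_count = 100,
                          dist_tiers = c(1e3, 2e3, 4e3, 1e4, 2e4, 4e4)) {
  chromsizes <- header$chromsizes
  n <- nrow(pairs)
  c1 <- substr(pairs$pair_type, 1L, 1L)
  c2 <- substr(pairs$pair_type, 2L, 2L)
  mapped1 <- c1 %in% c("U", "R", "D")
  mapped2 <- c2 %in% c("U", "R", "D")
  is_dup <- pairs$pair_type == "DD"
  both_mapped <- mapped1 & mapped2
  nodups <- both_mapped & !is_dup
  cis <- nodups & pairs$chrom1 == pairs$chrom2 &
    pairs$chrom1 != .NULL_CHROM
  trans <- nodups & !cis
  dist <- abs(pairs$pos2 - pairs$pos1)

  type_tab <- table(pairs$pair_type)
  pair_types <- stats::setNames(as.list(as.integer(type_tab)),
                                names(type_tab))

  tiers <- stats::setNames(
    lapply(dist_tiers, function(d) sum(cis & dist >= d)),
    sprintf("cis_%skb+", format(dist_tiers / 1e3, trim = TRUE,
                                drop0trailing = TRUE))
  )

  chrom_freq <- list()
  if (any(nodups)) {
    cf <- data.table::data.table(
      chrom1 = pairs$chrom1[nodups], chrom2 = pairs$chrom2[nodups]
    )[, .N, by = .(chrom1, chrom2)]
    for (i in seq_len(nrow(cf))) {
      chrom_freq[[cf$chrom1[i]]][[cf$chrom2[i]]] <- cf$N[i]
    }
  }

  stats <- list(
    total = n,
    total_unmapped = sum(c1 %in% c("N", "W") & c2 %in% c("N", "W")),
    total_single_sided_mapped = sum(xor(mapped1, mapped2)),
    total_mapped = sum(both_mapped),
    total_dups = sum(is_dup),
    total_nodups = sum(nodups),
    cis = sum(cis),
    trans = sum(trans),
    pair_types = pair_types
  )
  stats <- c(stats, tiers)
  stats$chrom_freq <- chrom_freq

  conv <- NA_real_
  if (with_scaling && n) {
    curve <- compute_scaling(pairs, chromsizes, min_dist = min_dist,
                             max_dist = max_dist,
                             bins_per_decade = bins_per_decade)
    conv <- convergence_distance(curve, rel_tol = rel_tol,
                                 min_count = min_count)
    dist_freq <- list()
    for (o in curve$orientations) {
      dist_freq[[o]] <- stats::setNames(
        as.list(curve$bins[[paste0("n_", o)]]),
        format(curve$bins$bin_start, trim = TRUE, digits = 6)
      )
    }
    stats$dist_freq <- dist_freq
    stats$avg_trans_frequency <- curve$avg_trans_frequency
  }

  complexity <- NA_real_
  if (stats$total_dups > 0L) {
    complexity <- estimate_complexity(stats$total_mapped,
                                      stats$total_nodups)$estimate
  }
  stats$summary <- list(
    frac_cis = if (stats$total_nodups) stats$cis / stats$total_nodups else 0,
    frac_dups = if (stats$total_mapped) {
      stats$total_dups / stats$total_mapped
    } else 0,
    dist_freq_convergence = list(
      convergence_dist = conv,
      rel_tol = rel_tol,
      min_count = min_count
    ),
    complexity_naive = complexity
  )
  structure(stats, class = "pairs_stats")
}

# flatten a nested list into "a/b/c" paths with scalar leaves
.flatten_stats <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    path <- c(prefix, nm)
    if (is.list(v)) {
      out <- c(out, .flatten_stats(v, path))
    } else if (length(v) == 1L) {
      out[[paste(path, collapse = "/")]] <- v
    }
  }
  out
}

#' Write a statistics summary as YAML or flattened TSV
#'
#' YAML output is the nested mapping itself.  TSV output is a two-column
#' `path<TAB>value` table with `/`-joined key paths (e.g.
#' `summary/dist_freq_convergence/convergence_dist`), convenient for
#' `grep`/`cut` pipelines.  Both forms round-trip through [read_stats()].
#'
#' @param stats A [compute_stats()] result.
#' @param path Output file path or writable connection.
#' @param format `"yaml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_stats <- function(stats, path, format = c("yaml", "tsv")) {
  format <- match.arg(format)
  con <- .open_write(path)
  if (!inherits(path, "connection")) on.exit(close(con))
  if (format == "yaml") {
    writeLines(yaml::as.yaml(unclass(stats)), con)
  } else {
    flat <- .flatten_stats(unclass(stats))
    vals <- vapply(flat, function(v) {
      if (is.numeric(v)) format(v, digits = 17, trim = TRUE,
                                scientific = FALSE)
      else as.character(v)
    }, character(1))
    writeLines(paste(names(flat), vals, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a statistics summary written by [write_stats()]
#'
#' @param path File path or connection.
#' @param format `"yaml"` or `"tsv"`.
#' @return A `pairs_stats` nested list (TSV leaves are numeric where they
#'   parse as numbers).
#' @export
read_stats <- function(path, format = c("yaml", "tsv")) {
  format <- match.arg(format)
  if (format == "yaml") {
    out <- yaml::read_yaml(path)
  } else {
    con <- .open_read(path)
    if (!inherits(path, "connection")) on.exit(close(con))
    lines <- readLines(con)
    out <- list()
    assign_path <- function(x, keys, val) {
      if (length(keys) == 1L) {
        x[[keys]] <- val
      } else {
        if (is.null(x[[keys[1]]])) x[[keys[1]]] <- list()
        x[[keys[1]]] <- assign_path(x[[keys[1]]], keys[-1], val)
      }
      x
    }
    for (ln in lines[nzchar(lines)]) {
      kv <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      keys <- strsplit(kv[1], "/", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.numeric(kv[2]))
      if (is.na(val) && !identical(kv[2], "NA")) val <- kv[2]
      out <- assign_path(out, keys, val)
    }
  }
  structure(out, class = "pairs_stats")
}

#' @export
print.pairs_stats <- function(x, ...) {
  cat("<pairs_stats> total:", x$total,
      " mapped:", x$total_mapped,
      " dups:", x$total_dups,
      " cis:", x$cis, " trans:", x$trans, "\n")
  if (!is.null(x$summary$dist_freq_convergence$convergence_dist)) {
    cat("  convergence distance:",
        x$summary$dist_freq_convergence$convergence_dist, "bp\n")
  }
  invisible(x)
}
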