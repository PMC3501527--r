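# Raw-tag cleaning and the library-statistics / copy-number reports.

#' Clean a raw tag library
#'
#' Applies the standard DGE cleaning rules, in order: remove adapter-only
#' reads (the [adapter_sentinel()] placeholder), then reads containing an
#' `N`, then every tag whose remaining total copy number is exactly 1
#' (likely sequencing errors). The surviving clean set therefore contains
#' only N-free tags with count >= 2.
#'
#' @param raw a `sim_library`, a character vector of reads, or a named
#'   count vector (tag -> count).
#' @return list with `clean` (named integer count vector, every count >=
#'   2) and `stats` (a [filter_stats()] object).
#' @examples
#' filter_tags(c("CATGAAAAAAAAAAAAAAAAA", "CATGAAAAAAAAAAAAAAAAA",
#'               "CATGCCCCCCCCCCCCCCCCC"))$stats
#' @export
filter_tags <- function(raw) {
  if (inherits(raw, "sim_library")) raw <- raw$reads
  counts <- as_tag_counts(raw)
  raw_total <- sum(counts)
  raw_distinct <- length(counts)

  is_adapter <- names(counts) == adapter_sentinel()
  n_adapter <- sum(counts[is_adapter])
  counts <- counts[!is_adapter]

  has_n <- grepl("N", names(counts), fixed = TRUE)
  n_with_n <- sum(counts[has_n])
  counts <- counts[!has_n]

  single <- counts == 1L
  n_single <- sum(counts[single])
  clean <- counts[!single]

  stats <- filter_stats(raw_total = raw_total, raw_distinct = raw_distinct,
                        n_adapter_only = n_adapter,
                        n_containing_N = n_with_n,
                        n_copy_number_1 = n_single,
                        clean_total = sum(clean),
                        clean_distinct = length(clean))
  list(clean = clean, stats = stats)
}

#' Filtering statistics for one library
#'
#' Constructor for the cleaning report. The conservation identity
#' `clean_total = raw_total - n_adapter_only - n_containing_N -
#' n_copy_number_1` is enforced; `clean_pct_of_raw` is computed as a
#' percentage rounded half-up to 2 decimals.
#'
#' @param raw_total,raw_distinct total and distinct raw reads.
#' @param n_adapter_only,n_containing_N,n_copy_number_1 reads removed by
#'   each rule.
#' @param clean_total,clean_distinct total and distinct clean tags.
#' @return object of class `filter_stats`.
#' @export
filter_stats <- function(raw_total, raw_distinct, n_adapter_only = 0,
                         n_containing_N = 0, n_copy_number_1 = 0,
                         clean_total, clean_distinct) {
  vals <- c(raw_total, raw_distinct, n_adapter_only, n_containing_N,
            n_copy_number_1, clean_total, clean_distinct)
  stopifnot(all(vals >= 0))
  if (clean_total !=
      raw_total - n_adapter_only - n_containing_N - n_copy_number_1)
    stop("filter counts violate the conservation identity", call. = FALSE)
  structure(list(raw_total = raw_total, raw_distinct = raw_distinct,
                 n_adapter_only = n_adapter_only,
                 n_containing_N = n_containing_N,
                 n_copy_number_1 = n_copy_number_1,
                 clean_total = clean_total,
                 clean_distinct = clean_distinct,
                 clean_pct_of_raw = pct2(clean_total, raw_total)),
            class = "filter_stats")
}

#' @export
print.filter_stats <- function(x, ...) {
  cat("Tag filtering\n")
  cat(sprintf("  raw:      %d (%d distinct)\n", x$raw_total, x$raw_distinct))
  cat(sprintf("  removed:  %d adapter-only, %d containing N, %d copy-number-1\n",
              x$n_adapter_only, x$n_containing_N, x$n_copy_number_1))
  cat(sprintf("  clean:    %d (%d distinct), %.2f%% of raw\n",
              x$clean_total, x$clean_distinct, x$clean_pct_of_raw))
  invisible(x)
}

#' Library statistics report (one library)
#'
#' Assembles the standard DGE sequencing summary for one library: raw and
#' clean totals, mapped and unambiguous tag counts with their
#' percentages of the clean set, tag-mapped gene counts with their
#' percentages of the reference genes, and unknown tags. All percentages
#' are rounded half-up to 2 decimals; when a denominator is zero the
#' percentage is reported as 0.
#'
#' @param filter a [filter_stats()] object.
#' @param mapping a [mapping_stats()] object.
#' @param genes_total number of reference genes (for the gene
#'   percentages).
#' @param library_id label used as the value column name.
#' @return data frame with columns `statistic`, `value`; class
#'   `library_stats`.
#' @export
library_stats <- function(filter, mapping, genes_total,
                          library_id = "library") {
  stopifnot(inherits(filter, "filter_stats"),
            inherits(mapping, "mapping_stats"))
  f <- filter
  m <- mapping
  rows <- c(
    "Raw Data" = f$raw_total,
    "Distinct Raw Data" = f$raw_distinct,
    "Clean Tag" = f$clean_total,
    "Distinct Clean Tag" = f$clean_distinct,
    "Clean Tag/Raw Tag (%)" = pct2(f$clean_total, f$raw_total),
    "All Tag Mapping to Gene" = m$all_mapped_total,
    "All Tag Mapping to Gene (% of clean)" =
      pct2(m$all_mapped_total, f$clean_total),
    "Distinct All Tag Mapping to Gene" = m$all_mapped_distinct,
    "Distinct All Tag Mapping to Gene (% of distinct clean)" =
      pct2(m$all_mapped_distinct, f$clean_distinct),
    "Unambiguous Tag Mapping to Gene" = m$unambiguous_total,
    "Unambiguous Tag Mapping to Gene (% of clean)" =
      pct2(m$unambiguous_total, f$clean_total),
    "Distinct Unambiguous Tag Mapping to Gene" = m$unambiguous_distinct,
    "Distinct Unambiguous Tag Mapping to Gene (% of distinct clean)" =
      pct2(m$unambiguous_distinct, f$clean_distinct),
    "All Tag-mapped Genes" = m$genes_mapped_all,
    "All Tag-mapped Genes (% of reference genes)" =
      pct2(m$genes_mapped_all, genes_total),
    "Unambiguous Tag-mapped Genes" = m$genes_mapped_unambiguous,
    "Unambiguous Tag-mapped Genes (% of reference genes)" =
      pct2(m$genes_mapped_unambiguous, genes_total),
    "Unknown Tag" = m$unknown_total,
    "Unknown Tag (% of clean)" = pct2(m$unknown_total, f$clean_total),
    "Distinct Unknown Tag" = m$unknown_distinct,
    "Distinct Unknown Tag (% of distinct clean)" =
      pct2(m$unknown_distinct, f$clean_distinct)
  )
  out <- data.frame(statistic = names(rows), value = unname(rows),
                    stringsAsFactors = FALSE)
  names(out)[2L] <- library_id
  class(out) <- c("library_stats", "data.frame")
  out
}

#' Combine per-library statistics into one table with averages
#'
#' Joins several [library_stats()] reports column-wise and appends an
#' `Averages` column: the mean of the per-library values, counts rounded
#' half-up to integers and percentage rows (computed from the already
#' rounded per-library percentages) rounded half-up to 2 decimals.
#'
#' @param ... `library_stats` objects (or a single list of them).
#' @return data frame with one column per library plus `Averages`.
#' @export
library_stats_table <- function(...) {
  libs <- list(...)
  if (length(libs) == 1L && !inherits(libs[[1L]], "library_stats"))
    libs <- libs[[1L]]
  stopifnot(length(libs) >= 1L,
            all(vapply(libs, inherits, TRUE, "library_stats")))
  out <- libs[[1L]]
  class(out) <- "data.frame"
  for (x in libs[-1L]) {
    stopifnot(identical(x$statistic, out$statistic))
    out[[names(x)[2L]]] <- x[[2L]]
  }
  vals <- as.matrix(out[, -1L, drop = FALSE])
  avg <- rowMeans(vals)
  is_pct <- grepl("%", out$statistic, fixed = TRUE)
  avg[is_pct] <- round_half_up(avg[is_pct], 2L)
  avg[!is_pct] <- round_half_up(avg[!is_pct], 0L)
  out$Averages <- avg
  class(out) <- c("library_stats", "data.frame")
  out
}

#' Copy-number distribution of a clean tag set
#'
#' Assigns every clean tag species to one copy-number bin and reports,
#' per bin, the total tag count, the distinct tag count and their
#' percentages of the clean totals. This is the report used to judge the
#' heterogeneity/redundancy structure of a library (few tags at very high
#' copy number carrying most of the reads, many distinct tags at low
#' copy number).
#'
#' @param clean named count vector of clean tags (counts >= 2), as
#'   returned by [filter_tags()].
#' @param breaks increasing integer vector of bin lower bounds; bin `i`
#'   covers `[breaks[i], breaks[i+1] - 1]` and the last bin is
#'   open-ended. The default bins are `[2,5] [6,10] [11,20] [21,50]
#'   [51,100] [>=101]`.
#' @return data frame of class `copy_number_dist` with columns `bin`,
#'   `lower`, `upper`, `total`, `distinct`, `pct_of_total`,
#'   `pct_of_distinct`.
#' @export
copy_number_distribution <- function(clean,
                                     breaks = c(2, 6, 11, 21, 51, 101)) {
  if (is.list(clean) && !is.null(clean$clean)) clean <- clean$clean
  counts <- as_tag_counts(clean)
  if (any(counts < 2L))
    stop("clean tag counts must all be >= 2", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1L] > 2)
    stop("breaks must be strictly increasing and start at or below 2",
         call. = FALSE)
  lower <- breaks
  upper <- c(breaks[-1L] - 1L, Inf)
  bin_idx <- findInterval(counts, breaks)
  total <- vapply(seq_along(breaks), function(i)
    sum(counts[bin_idx == i]), numeric(1))
  distinct <- vapply(seq_along(breaks), function(i)
    sum(bin_idx == i), numeric(1))
  lab <- sprintf(">=%d", lower)
  fin <- is.finite(upper)
  lab[fin] <- sprintf("[%d,%d]", lower[fin], as.integer(upper[fin]))
  out <- data.frame(bin = lab, lower = lower, upper = upper,
                    total = total, distinct = distinct,
                    pct_of_total = pct2(total, sum(counts)),
                    pct_of_distinct = pct2(distinct, length(counts)),
                    stringsAsFactors = FALSE)
  class(out) <- c("copy_number_dist", "data.frame")
  out
}
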