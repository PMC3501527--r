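# Tag-to-gene mapping (exact or one-base mismatch), mapping statistics,
# unambiguous gene counting and TPM normalization.

# all Hamming-distance-1 neighbors of the query tags; returns a data
# frame (query_idx, neighbor)
hamming1_neighbors <- function(tags) {
  n <- length(tags)
  if (n == 0L)
    return(data.frame(query_idx = integer(0), neighbor = character(0)))
  width <- nchar(tags[1L])
  rep_q <- rep(tags, each = width * 4L)
  pos <- rep(rep(seq_len(width), each = 4L), times = n)
  base <- rep(rep(DNA_BASES, times = width), times = n)
  cur <- substring(rep_q, pos, pos)
  keep <- base != cur
  nb <- rep_q[keep]
  substr(nb, pos[keep], pos[keep]) <- base[keep]
  data.frame(query_idx = rep(seq_len(n), each = width * 4L)[keep],
             neighbor = nb, stringsAsFactors = FALSE)
}

#' Match one clean tag against the reference library
#'
#' An exact occurrence in the reference preempts the mismatch search;
#' otherwise every reference tag at Hamming distance exactly 1 is a
#' match. A tag matching no reference tag within one mismatch is
#' unknown.
#'
#' @param tag a single 21-mer over `{A,C,G,T}`.
#' @param library a [build_tag_library()] object.
#' @param exact_preempts if `TRUE` (default) an exact hit suppresses the
#'   one-mismatch candidates; if `FALSE` exact and one-mismatch hits are
#'   pooled.
#' @return list with `match_class` (`"exact"`, `"one_mismatch"` or
#'   `"unknown"`), `matched_tags` (reference tag sequences) and
#'   `matched_genes` (union of their gene ids).
#' @export
match_tag <- function(tag, library, exact_preempts = TRUE) {
  stopifnot(inherits(library, "tag_library"))
  if (!is.character(tag) || length(tag) != 1L || nchar(tag) != 21L)
    stop("tag must be a single 21-base string", call. = FALSE)
  check_dna(tag, allow_n = FALSE, what = "tag")
  a <- assign_tags(setNames(2L, tag), library,
                   exact_preempts = exact_preempts)
  row <- a$assignments
  list(match_class = row$match_class,
       matched_tags = if (nzchar(row$matched_tags))
         strsplit(row$matched_tags, ";", fixed = TRUE)[[1L]] else character(0),
       matched_genes = if (nzchar(row$genes))
         strsplit(row$genes, ";", fixed = TRUE)[[1L]] else character(0))
}

#' Map a clean tag set to genes
#'
#' Classifies every clean tag species as exact, one-mismatch or unknown
#' against the reference library, takes the union of the gene ids of the
#' matched reference tags, and derives the per-tag status: unambiguous
#' (exactly one gene), ambiguous (two or more) or unknown (none).
#' Aggregated mapping statistics are computed over read counts (totals)
#' and over tag species (distinct).
#'
#' @param clean named count vector of clean tags (or the list returned by
#'   [filter_tags()]).
#' @inheritParams match_tag
#' @return list with `assignments` (data frame `tag`, `count`,
#'   `match_class`, `n_genes`, `genes`, `matched_tags`, `status`) and
#'   `stats` (a `mapping_stats` object).
#' @export
assign_tags <- function(clean, library, exact_preempts = TRUE) {
  stopifnot(inherits(library, "tag_library"))
  if (is.list(clean) && !is.null(clean$clean)) clean <- clean$clean
  counts <- as_tag_counts(clean)
  q <- names(counts)
  if (length(q) > 0L) {
    if (any(nchar(q) != 21L))
      stop("clean tags must all be 21 bases long", call. = FALSE)
    check_dna(q, allow_n = FALSE, what = "clean tag")
  }
  ref <- library$tags

  match_class <- rep("unknown", length(q))
  genes <- character(length(q))
  mtags <- character(length(q))

  ex <- match(q, ref$tag)
  hit_ex <- !is.na(ex)
  match_class[hit_ex] <- "exact"
  genes[hit_ex] <- ref$gene_ids[ex[hit_ex]]
  mtags[hit_ex] <- q[hit_ex]

  todo <- if (exact_preempts) which(!hit_ex) else seq_along(q)
  # chunked neighbor enumeration bounds memory at large query counts
  for (chunk in split(todo, ceiling(seq_along(todo) / 20000L))) {
    nb <- hamming1_neighbors(q[chunk])
    hit <- match(nb$neighbor, ref$tag)
    ok <- !is.na(hit)
    if (!any(ok)) next
    qi <- chunk[nb$query_idx[ok]]
    gene_hit <- ref$gene_ids[hit[ok]]
    tag_hit <- ref$tag[hit[ok]]
    add_genes <- vapply(split(gene_hit, qi), function(g)
      paste(unique(unlist(strsplit(g, ";", fixed = TRUE))), collapse = ";"),
      "")
    add_tags <- vapply(split(tag_hit, qi), paste, "", collapse = ";")
    ii <- as.integer(names(add_genes))
    mm <- !hit_ex[ii]  # exact hits keep their class when pooling
    match_class[ii[mm]] <- "one_mismatch"
    if (exact_preempts) {
      genes[ii] <- add_genes
      mtags[ii] <- add_tags
    } else {
      sep <- ifelse(nzchar(genes[ii]), ";", "")
      both <- paste0(genes[ii], sep, add_genes)
      genes[ii] <- vapply(strsplit(both, ";", fixed = TRUE), function(g)
        paste(unique(g), collapse = ";"), "")
      mtags[ii] <- paste0(mtags[ii], sep, add_tags)
    }
  }

  n_genes <- ifelse(nzchar(genes),
                    lengths(strsplit(genes, ";", fixed = TRUE)), 0L)
  status <- ifelse(n_genes == 0L, "unknown",
                   ifelse(n_genes == 1L, "unambiguous", "ambiguous"))
  assignments <- data.frame(tag = q, count = as.integer(counts),
                            match_class = match_class,
                            n_genes = as.integer(n_genes),
                            genes = genes, matched_tags = mtags,
                            status = status, stringsAsFactors = FALSE)
  rownames(assignments) <- NULL

  mapped <- status != "unknown"
  unamb <- status == "unambiguous"
  stats <- mapping_stats(
    clean_total = sum(counts), clean_distinct = length(counts),
    all_mapped_total = sum(counts[mapped]),
    all_mapped_distinct = sum(mapped),
    unambiguous_total = sum(counts[unamb]),
    unambiguous_distinct = sum(unamb),
    genes_mapped_all = length(unique(unlist(
      strsplit(genes[mapped], ";", fixed = TRUE)))),
    genes_mapped_unambiguous = length(unique(genes[unamb])),
    unknown_total = sum(counts[!mapped]),
    unknown_distinct = sum(!mapped)
  )
  list(assignments = assignments, stats = stats)
}

#' Mapping statistics for one library
#'
#' Constructor; the conservation identity `all_mapped_total +
#' unknown_total = clean_total` (and its distinct counterpart) is
#' enforced.
#'
#' @param clean_total,clean_distinct clean tag totals.
#' @param all_mapped_total,all_mapped_distinct tags mapped to any gene
#'   (ambiguous included).
#' @param unambiguous_total,unambiguous_distinct tags mapped to exactly
#'   one gene.
#' @param genes_mapped_all,genes_mapped_unambiguous genes hit by any /
#'   by unambiguous tags.
#' @param unknown_total,unknown_distinct unmapped tags.
#' @param check enforce the conservation identity (default). Set to
#'   `FALSE` only when transcribing externally published summaries,
#'   which sometimes exclude reads dropped by unlisted criteria and so
#'   need not balance.
#' @return object of class `mapping_stats`.
#' @export
mapping_stats <- function(clean_total, clean_distinct,
                          all_mapped_total, all_mapped_distinct,
                          unambiguous_total, unambiguous_distinct,
                          genes_mapped_all, genes_mapped_unambiguous,
                          unknown_total, unknown_distinct, check = TRUE) {
  if (check &&
      (all_mapped_total + unknown_total != clean_total ||
       all_mapped_distinct + unknown_distinct != clean_distinct))
    stop("mapped + unknown must equal clean (totals and distinct)",
         call. = FALSE)
  stopifnot(unambiguous_total <= all_mapped_total,
            genes_mapped_unambiguous <= genes_mapped_all)
  structure(list(clean_total = clean_total, clean_distinct = clean_distinct,
                 all_mapped_total = all_mapped_total,
                 all_mapped_distinct = all_mapped_distinct,
                 unambiguous_total = unambiguous_total,
                 unambiguous_distinct = unambiguous_distinct,
                 genes_mapped_all = genes_mapped_all,
                 genes_mapped_unambiguous = genes_mapped_unambiguous,
                 unknown_total = unknown_total,
                 unknown_distinct = unknown_distinct),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat("Tag mapping\n")
  cat(sprintf("  clean:       %d (%d distinct)\n",
              x$clean_total, x$clean_distinct))
  cat(sprintf("  mapped:      %d (%.2f%%), unambiguous %d (%.2f%%)\n",
              x$all_mapped_total, pct2(x$all_mapped_total, x$clean_total),
              x$unambiguous_total, pct2(x$unambiguous_total, x$clean_total)))
  cat(sprintf("  genes hit:   %d (unambiguously %d)\n",
              x$genes_mapped_all, x$genes_mapped_unambiguous))
  cat(sprintf("  unknown:     %d (%.2f%%)\n",
              x$unknown_total, pct2(x$unknown_total, x$clean_total)))
  invisible(x)
}

#' Per-gene unambiguous tag counts
#'
#' Sums the counts of each gene's unambiguous tags. Ambiguous tags
#' contribute to no gene; reference genes with no unambiguous tag are
#' included with count 0.
#'
#' @param assignments result of [assign_tags()] (the list or its
#'   `assignments` data frame).
#' @param library the `tag_library` the assignment was made against.
#' @return data frame `(gene_id, count)` covering every reference gene.
#' @export
count_genes <- function(assignments, library) {
  stopifnot(inherits(library, "tag_library"))
  if (is.list(assignments) && !is.null(assignments$assignments))
    assignments <- assignments$assignments
  un <- assignments[assignments$status == "unambiguous", , drop = FALSE]
  counts <- setNames(numeric(length(library$gene_ids)), library$gene_ids)
  if (nrow(un) > 0L) {
    agg <- tapply(un$count, un$genes, sum)
    counts[names(agg)] <- agg
  }
  data.frame(gene_id = names(counts), count = as.numeric(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' TPM normalization
#'
#' `tpm = 1e6 * count / denominator`. The conventional denominator for
#' tag libraries is the clean tag total ("per million clean tags");
#' the unambiguous total is offered as an alternative, under which the
#' TPM column sums to 1e6 exactly.
#'
#' @param counts data frame `(gene_id, count)` from [count_genes()].
#' @param denominator normalization total (> 0), e.g.
#'   `stats$clean_total` or `sum(counts$count)`.
#' @return the input data frame with a `tpm` column added.
#' @export
tpm_normalize <- function(counts, denominator) {
  stopifnot(is.data.frame(counts), "count" %in% names(counts))
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      denominator <= 0)
    stop("denominator must be a single positive number", call. = FALSE)
  counts$tpm <- 1e6 * counts$count / denominator
  counts
}

#' Quantify one library against a reference tag library
#'
#' Convenience wrapper running [assign_tags()], [count_genes()] and
#' [tpm_normalize()] for one clean tag set.
#'
#' @inheritParams assign_tags
#' @param denominator_mode `"clean_total"` (default) or
#'   `"unambiguous_total"`; which library total the TPM scales by.
#' @return object of class `tag_expression`: data frame `(gene_id,
#'   count, tpm)` with attributes `mapping_stats`, `denominator` and
#'   `denominator_mode`.
#' @export
quantify_library <- function(clean, library,
                             denominator_mode = c("clean_total",
                                                  "unambiguous_total"),
                             exact_preempts = TRUE) {
  denominator_mode <- match.arg(denominator_mode)
  a <- assign_tags(clean, library, exact_preempts = exact_preempts)
  denom <- switch(denominator_mode,
                  clean_total = a$stats$clean_total,
                  unambiguous_total = a$stats$unambiguous_total)
  tab <- tpm_normalize(count_genes(a, library), denom)
  structure(tab, mapping_stats = a$stats, denominator = denom,
            denominator_mode = denominator_mode,
            class = c("tag_expression", "data.frame"))
}

#' @export
print.tag_expression <- function(x, ...) {
  cat(sprintf("Gene expression table: %d genes, %d with evidence (denominator %s = %g)\n",
              nrow(x), sum(x$count > 0), attr(x, "denominator_mode"),
              attr(x, "denominator")))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
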