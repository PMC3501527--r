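# Hypergeometric term enrichment of a DEG set against the annotated
# background.

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability that at least `m` of the `n` DEGs are annotated to a term
#' covering `M` of the `N` annotated background genes:
#' `P(X >= m) = sum_{i=m}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)`
#' (equivalently `1 - sum_{i=0}^{m-1}` of the same terms). Terms with
#' `n - i > N - M` are impossible and contribute zero. Computed by
#' summing the upper tail directly in log-gamma form, which keeps small
#' p-values at full relative precision.
#'
#' @param N number of annotated background genes.
#' @param n number of DEGs within `N`.
#' @param M genes annotated to the term.
#' @param m DEGs annotated to the term (`0 <= m <= min(n, M)`).
#' @return upper-tail probability (vectorized over `m` and `M`).
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_pvalue <- function(N, n, M, m) {
  len <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, len); n <- rep_len(n, len)
  M <- rep_len(M, len); m <- rep_len(m, len)
  if (any(n > N) || any(M > N) || any(m > pmin(n, M)) || any(m < 0))
    stop("need 0 <= m <= min(n, M) and n, M <= N", call. = FALSE)
  vapply(seq_len(len), function(j) {
    if (m[j] == 0) return(1)  # empty subtracted sum: certain event
    i <- m[j]:min(n[j], M[j])
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(1, exp(logsumexp(lt)))
  }, numeric(1))
}

#' Term enrichment of a DEG set
#'
#' For every annotation term, assembles the `(N, n, M, m)` contingency
#' inputs from the gene-to-term table, computes the hypergeometric
#' upper-tail p-value, and corrects across all tested terms. In `"go"`
#' mode a term is significant when its corrected p-value is at most
#' `alpha`; in `"pathway"` mode when its q-value (BH) is at most
#' `alpha`. DEGs without annotation are dropped from `n` (with a
#' message); genes are counted once per term regardless of duplicate
#' annotation rows.
#'
#' @param deg_genes character vector of differentially expressed gene
#'   ids.
#' @param annotation data frame with columns `gene_id` and `term_id`
#'   (extra columns ignored).
#' @param mode `"go"` or `"pathway"`; chooses which corrected value the
#'   significance flag uses.
#' @param correction multiple-testing correction for `p_corrected`:
#'   `"BH"` (default) or `"bonferroni"`. The `q_value` column is always
#'   BH.
#' @param alpha significance threshold (default 0.05).
#' @param min_term_size terms annotating fewer than this many genes are
#'   skipped (default 2).
#' @return object of class `enrichment`: data frame `(term_id, N, n, M,
#'   m, p_raw, p_corrected, q_value, significant)` sorted by `p_raw`.
#' @export
enrich_terms <- function(deg_genes, annotation,
                         mode = c("go", "pathway"),
                         correction = c("BH", "bonferroni"),
                         alpha = 0.05, min_term_size = 2) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  stopifnot(is.data.frame(annotation))
  if (!all(c("gene_id", "term_id") %in% names(annotation)))
    stop("annotation needs 'gene_id' and 'term_id' columns", call. = FALSE)
  ann <- unique(annotation[, c("gene_id", "term_id")])
  if (nrow(ann) == 0L) stop("annotation table is empty", call. = FALSE)

  universe <- unique(ann$gene_id)
  N <- length(universe)
  degs <- unique(deg_genes)
  dropped <- sum(!degs %in% universe)
  if (dropped > 0L)
    message(dropped, " DEG(s) without annotation dropped from the test")
  degs <- degs[degs %in% universe]
  n <- length(degs)

  term_genes <- split(ann$gene_id, ann$term_id)
  M <- lengths(term_genes)
  keep <- M >= min_term_size
  term_genes <- term_genes[keep]
  M <- M[keep]
  if (length(M) == 0L)
    stop("no term reaches min_term_size = ", min_term_size, call. = FALSE)
  m <- vapply(term_genes, function(g) sum(degs %in% g), numeric(1))

  p_raw <- hypergeom_pvalue(N, n, M, m)
  p_corrected <- p.adjust(p_raw,
                          method = if (correction == "BH") "BH"
                                   else "bonferroni")
  q_value <- p.adjust(p_raw, method = "BH")
  significant <- if (mode == "go") p_corrected <= alpha else q_value <= alpha

  out <- data.frame(term_id = names(term_genes), N = N, n = n,
                    M = as.integer(M), m = as.integer(m),
                    p_raw = p_raw, p_corrected = p_corrected,
                    q_value = q_value, significant = significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mode = mode, correction = correction, alpha = alpha,
            dropped_degs = dropped,
            class = c("enrichment", "data.frame"))
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("Term enrichment (%s mode, %s correction): %d terms tested, %d significant at alpha = %g\n",
              attr(x, "mode"), attr(x, "correction"), nrow(x),
              sum(x$significant), attr(x, "alpha")))
  print.data.frame(head(as.data.frame(x), 8L), digits = 4)
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}
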