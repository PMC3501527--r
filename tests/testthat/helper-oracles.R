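# Independent oracles used across the suite. All are deliberately naive:
# they define the contract the fast implementations must match.

# sliding-window CATG scan (1-based positions of the 'C')
naive_catg_scan <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(integer(0))
  which(vapply(seq_len(n - 3L), function(p)
    substr(seq, p, p + 3L) == "CATG", logical(1)))
}

# naive tag extraction: every qualifying site's 21-mer, N-free
naive_extract <- function(seq) {
  pos <- naive_catg_scan(seq)
  pos <- pos[pos + 20L <= nchar(seq)]
  tags <- vapply(pos, function(p) substr(seq, p, p + 20L), "")
  keep <- !grepl("N", tags, fixed = TRUE)
  data.frame(pos = pos[keep], tag = tags[keep], stringsAsFactors = FALSE)
}

# all-pairs Hamming classification of queries against a tag_library:
# exact hit preempts; otherwise all reference tags at distance exactly 1
brute_match <- function(query, library) {
  ref <- library$tags$tag
  qc <- strsplit(query, "")[[1L]]
  d <- vapply(ref, function(r)
    sum(qc != strsplit(r, "")[[1L]]), numeric(1))
  genes_of <- function(idx) sort(unique(unlist(
    strsplit(library$tags$gene_ids[idx], ";", fixed = TRUE))))
  if (any(d == 0)) {
    list(match_class = "exact", matched_genes = genes_of(which(d == 0)))
  } else if (any(d == 1)) {
    list(match_class = "one_mismatch",
         matched_genes = genes_of(which(d == 1)))
  } else {
    list(match_class = "unknown", matched_genes = character(0))
  }
}

# vectorized all-pairs brute force for large query sets: classify every
# query against every reference tag by full Hamming distance
brute_match_all <- function(queries, library) {
  ref <- library$tags$tag
  ref_mat <- do.call(rbind, strsplit(ref, ""))
  lapply(queries, function(q) {
    qc <- strsplit(q, "")[[1L]]
    d <- rowSums(ref_mat != matrix(qc, nrow(ref_mat), length(qc),
                                   byrow = TRUE))
    genes_of <- function(idx) sort(unique(unlist(
      strsplit(library$tags$gene_ids[idx], ";", fixed = TRUE))))
    if (any(d == 0))
      list(match_class = "exact", matched_genes = genes_of(which(d == 0)))
    else if (any(d == 1))
      list(match_class = "one_mismatch",
           matched_genes = genes_of(which(d == 1)))
    else list(match_class = "unknown", matched_genes = character(0))
  })
}

# hand-applied Benjamini-Hochberg step-up
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# direct full-summation two-sided Audic-Claverie p-value (no early
# stopping; terms via dnbinom, an independent closed form of the same pmf)
ac_pvalue_bruteforce <- function(x, y, N1, N2, kmax = 10000L) {
  pr <- N1 / (N1 + N2)
  pk <- stats::dnbinom(0:kmax, size = x + 1, prob = pr)
  lower <- sum(pk[1:(y + 1L)])
  upper <- sum(pk[(y + 1L):(kmax + 1L)])
  min(1, 2 * min(lower, upper))
}

random_dna <- function(n, len, letters = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(letters, len, replace = TRUE), collapse = ""), "")
}

read_fixture <- function(name) {
  read.delim(test_path(name), stringsAsFactors = FALSE)
}

rel_err <- function(got, want) {
  ifelse(want == 0, abs(got), abs(got - want) / abs(want))
}
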