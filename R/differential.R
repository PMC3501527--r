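# Differential expression between two tag libraries: the Audic-Claverie
# exact statistic, two-sided p-values, BH FDR, and the joint
# FDR / log2-ratio significance call. Also the ddCt qRT-PCR utility.

# log p(y|x) for the Audic-Claverie posterior predictive:
# p(y|x) = (N2/N1)^y (x+y)! / ( x! y! (1+N2/N1)^(x+y+1) )
ac_log_prob <- function(x, y, N1, N2) {
  r <- N2 / N1
  # subtracting the lgamma terms in canonical (max, min) order keeps the
  # evaluation bitwise symmetric in (x, y) when N1 = N2
  y * log(r) + lgamma(x + y + 1) - lgamma(pmax(x, y) + 1) -
    lgamma(pmin(x, y) + 1) - (x + y + 1) * log1p(r)
}

#' Audic-Claverie tag-count probability
#'
#' Probability of observing `y` copies of a tag in library 2 given `x`
#' copies in library 1, for library totals `N1` and `N2`:
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`, evaluated in
#' log space with `lgamma` so that counts up to 1e6 are handled without
#' overflow. Equivalent to a negative binomial with size `x+1` and
#' success probability `N1/(N1+N2)`.
#'
#' @param x,y nonnegative tag counts (vectorized).
#' @param N1,N2 positive library totals.
#' @return probabilities in `(0, 1]`.
#' @examples
#' ac_probability(0, 0, 1e5, 1e5)  # exactly 1/2
#' @export
ac_probability <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be > 0",
                                         call. = FALSE)
  exp(ac_log_prob(x, y, N1, N2))
}

#' Audic-Claverie two-sided p-value
#'
#' Doubled smaller tail of the conditional distribution of `y` given
#' `x`: `p = min(1, 2 * min(P(Y <= y), P(Y >= y)))`. The lower tail is a
#' log-space sum over `k = 0..y`; the upper tail is summed directly from
#' `k = y` with a multiplicative recurrence, stopping once a term falls
#' below `1e-16` of the running sum, which keeps tiny tails accurate to
#' full double precision (no `1 - lower` cancellation).
#'
#' @inheritParams ac_probability
#' @return two-sided p-values in `(0, 1]` (vectorized over `x`, `y`).
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be > 0",
                                         call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i)
    ac_pvalue_one(x[i], y[i], N1[i], N2[i]), numeric(1))
}

ac_pvalue_one <- function(x, y, N1, N2) {
  r <- N2 / N1
  q <- r / (1 + r)
  k <- 0:y
  lp <- ac_log_prob(x, k, N1, N2)
  lower <- exp(logsumexp(lp))
  # lower + upper = 1 + p(y|x) > 1, so if lower < 1/2 the smaller tail is
  # the lower one and the upper tail never needs summing
  if (lower < 0.5) return(min(1, 2 * lower))
  # upper tail from y upward; lower >= 1/2 puts y at or past the mode, so
  # the terms decay and the sum is short
  s <- 1
  term <- 1
  kk <- y
  repeat {
    term <- term * q * (x + kk + 1) / (kk + 1)
    if (!(term > s * 1e-16)) break
    s <- s + term
    kk <- kk + 1
  }
  upper <- exp(lp[y + 1L] + log(s))
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across the supplied p-values (delegating to
#' [stats::p.adjust()]); Benjamini-Yekutieli available for dependent
#' tests.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Call differentially expressed genes between two libraries
#'
#' Per gene, the Audic-Claverie two-sided p-value for counts `x` vs `y`
#' given totals `N1`, `N2`, BH-adjusted across all tested genes, and the
#' log2 expression ratio of the TPM values (each TPM floored at the TPM
#' of a single tag in its library, so that zero counts give finite,
#' order-preserving ratios). A gene is significant when `fdr <=
#' fdr_threshold` and `|log2_ratio| >= log2_threshold`; genes with `x =
#' y = 0` carry no evidence and are excluded from testing.
#'
#' @param x,y unambiguous tag counts in libraries 1 and 2 (equal-length
#'   vectors; names, if present, are used as gene ids).
#' @param N1,N2 normalization totals of the two libraries (the same
#'   denominators used for TPM).
#' @param gene_ids optional gene ids.
#' @param fdr_threshold,log2_threshold joint significance criteria
#'   (defaults 0.001 and 1).
#' @param fdr_method [bh_fdr()] method.
#' @param tpm_floor floor applied to each TPM before the ratio; default
#'   `1e6/N`, the TPM of one tag, per library.
#' @return object of class `dge_test`: list with `table` (data frame
#'   `gene_id, x, y, tpm1, tpm2, log2_ratio, p_value, fdr, significant,
#'   direction`), `n_excluded`, and the call parameters. Has `print`,
#'   `summary` and `plot` methods.
#' @examples
#' res <- dge_test(c(a = 100, b = 50), c(a = 400, b = 52),
#'                 N1 = 1e5, N2 = 1e5)
#' res$table
#' @export
dge_test <- function(x, y, N1 = sum(x), N2 = sum(y), gene_ids = NULL,
                     fdr_threshold = 0.001, log2_threshold = 1,
                     fdr_method = c("BH", "BY"), tpm_floor = NULL) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(length(x) == length(y), fdr_threshold > 0, log2_threshold > 0)
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (N1 <= 0 || N2 <= 0) stop("library totals must be > 0", call. = FALSE)
  gene_ids <- gene_ids %||% names(x) %||%
    sprintf("gene%05d", seq_along(x))

  keep <- x + y > 0
  n_excluded <- sum(!keep)
  gx <- x[keep]; gy <- y[keep]; ids <- gene_ids[keep]

  tpm1 <- 1e6 * gx / N1
  tpm2 <- 1e6 * gy / N2
  floor1 <- (tpm_floor %||% (1e6 / N1))
  floor2 <- (tpm_floor %||% (1e6 / N2))
  log2_ratio <- log2(pmax(tpm2, floor2) / pmax(tpm1, floor1))

  p <- ac_pvalue(gx, gy, N1, N2)
  fdr <- bh_fdr(p, method = fdr_method)
  significant <- fdr <= fdr_threshold & abs(log2_ratio) >= log2_threshold
  direction <- ifelse(!significant, "none",
                      ifelse(log2_ratio > 0, "up", "down"))

  tab <- data.frame(gene_id = ids, x = gx, y = gy,
                    tpm1 = tpm1, tpm2 = tpm2, log2_ratio = log2_ratio,
                    p_value = p, fdr = fdr, significant = significant,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, n_excluded = n_excluded,
                 N1 = N1, N2 = N2,
                 fdr_threshold = fdr_threshold,
                 log2_threshold = log2_threshold,
                 fdr_method = fdr_method),
            class = "dge_test")
}

#' @export
print.dge_test <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Audic-Claverie differential expression: %d genes tested (%d excluded with x = y = 0)\n",
              nrow(tab), x$n_excluded))
  cat(sprintf("  criteria: FDR <= %g (%s) and |log2 ratio| >= %g\n",
              x$fdr_threshold, x$fdr_method, x$log2_threshold))
  cat(sprintf("  significant: %d (%d up, %d down in library 2)\n",
              sum(tab$significant), sum(tab$direction == "up"),
              sum(tab$direction == "down")))
  invisible(x)
}

#' @export
summary.dge_test <- function(object, ...) {
  tab <- object$table
  out <- list(
    n_tested = nrow(tab),
    n_excluded = object$n_excluded,
    n_significant = sum(tab$significant),
    n_up = sum(tab$direction == "up"),
    n_down = sum(tab$direction == "down"),
    top = head(tab[order(tab$fdr, tab$p_value), ], 10L)
  )
  class(out) <- "summary.dge_test"
  out
}

#' @export
print.summary.dge_test <- function(x, ...) {
  cat(sprintf("%d genes tested (%d excluded); %d significant (%d up, %d down)\n",
              x$n_tested, x$n_excluded, x$n_significant, x$n_up, x$n_down))
  cat("Top genes by FDR:\n")
  print.data.frame(x$top, digits = 4)
  invisible(x)
}

#' @export
plot.dge_test <- function(x, ...) {
  tab <- x$table
  col <- ifelse(tab$direction == "up", "red2",
                ifelse(tab$direction == "down", "green4", "grey60"))
  plot(tab$log2_ratio, -log10(pmax(tab$fdr, 1e-300)), col = col,
       pch = 20, cex = 0.5,
       xlab = "log2 ratio (library 2 / library 1)",
       ylab = "-log10 FDR", ...)
  graphics::abline(v = c(-1, 1) * x$log2_threshold, lty = 2)
  graphics::abline(h = -log10(x$fdr_threshold), lty = 2)
  invisible(x)
}

#' Relative qRT-PCR fold change (delta-delta-Ct)
#'
#' `fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator))`, the standard relative
#' quantification against an internal reference gene and a calibrator
#' sample.
#'
#' @param ct_target_sample,ct_ref_sample threshold cycles of the target
#'   and reference gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator the same in the
#'   calibrator sample.
#' @return fold change (vectorized).
#' @examples
#' ddct_fold_change(20, 15, 22, 15)  # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
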