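# Synthetic-data generators: transcriptomes with CATG tag sites,
# log-normal expression truths, multinomially sampled tag libraries with
# the contaminant read classes the cleaning step removes, and planted
# term annotations for the enrichment test.

#' Sentinel sequence used for adapter-only reads
#'
#' Adapter-only ("empty") reads carry no tag; the simulator represents
#' them with a reserved sentinel that can never collide with a valid
#' 21-mer, so the cleaning filter can be tested unambiguously.
#'
#' @return the sentinel string.
#' @export
adapter_sentinel <- function() "ADAPTER_ONLY"

#' Simulate a reference transcriptome
#'
#' Generates `n_genes` random transcript sequences with log-normally
#' distributed lengths and a fixed GC fraction. Exactly
#' `round(fraction_untaggable * n_genes)` genes are made untaggable (no
#' CATG site with 17 or more downstream bases); every other gene is
#' guaranteed at least one qualifying site, planting a CATG when the
#' random sequence happens to lack one.
#'
#' @param n_genes number of genes (>= 1).
#' @param length_meanlog,length_sdlog log-normal parameters of transcript
#'   length in bases.
#' @param min_length lower bound on transcript length (>= 25).
#' @param gc GC fraction in `[0, 1]`.
#' @param fraction_untaggable fraction of genes carrying no extractable
#'   tag, in `[0, 1]`.
#' @param seed integer seed; identical inputs regenerate a byte-identical
#'   transcriptome.
#' @return an object of class `transcriptome`: a named character vector
#'   of sequences with attributes `untaggable` (gene ids) and `params`.
#' @examples
#' tx <- sim_transcriptome(5, seed = 1)
#' nchar(tx)
#' @export
sim_transcriptome <- function(n_genes,
                              length_meanlog = log(400),
                              length_sdlog = 0.45,
                              min_length = 60,
                              gc = 0.42,
                              fraction_untaggable = 0.05,
                              seed = NULL) {
  stopifnot(n_genes >= 1, min_length >= 25,
            gc >= 0, gc <= 1, length_sdlog >= 0)
  if (fraction_untaggable < 0 || fraction_untaggable > 1)
    stop("fraction_untaggable must be in [0, 1]", call. = FALSE)
  with_rng_seed(seed, {
    lens <- pmax(min_length,
                 round(rlnorm(n_genes, length_meanlog, length_sdlog)))
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(l)
      paste(sample(DNA_BASES, l, replace = TRUE, prob = probs),
            collapse = ""), "")
    ids <- sprintf("gene%05d", seq_len(n_genes))
    names(seqs) <- ids

    n_unt <- round(fraction_untaggable * n_genes)
    unt <- if (n_unt > 0) sample(ids, n_unt) else character(0)

    qualifying <- function(s) {
      p <- find_catg_sites(s)
      p[p + 20L <= nchar(s)]
    }
    for (g in ids) {
      s <- seqs[[g]]
      if (g %in% unt) {
        # break every qualifying site; re-scan because a substitution can
        # create a new CATG in the surrounding window
        repeat {
          p <- qualifying(s)
          if (length(p) == 0L) break
          substr(s, p[1L], p[1L]) <- sample(c("A", "G", "T"), 1L)
        }
      } else if (length(qualifying(s)) == 0L) {
        at <- sample.int(nchar(s) - 20L, 1L)
        substr(s, at, at + 3L) <- "CATG"
      }
      seqs[[g]] <- s
    }
    structure(seqs, untaggable = unt,
              params = list(n_genes = n_genes,
                            length_meanlog = length_meanlog,
                            length_sdlog = length_sdlog,
                            min_length = min_length, gc = gc,
                            fraction_untaggable = fraction_untaggable,
                            seed = seed),
              class = "transcriptome")
  })
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("Synthetic transcriptome: %d genes (%d untaggable), lengths %d-%d\n",
              length(x), length(attr(x, "untaggable")),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

unclass_transcriptome <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Assign a ground-truth expression profile
#'
#' Per-gene relative abundances for each library, drawn from a log-normal
#' base distribution. Library 1 is the reference; a chosen fraction of
#' genes is truly differentially expressed in library 2, their reference
#' abundance multiplied by `2^log2fc` before renormalization. Any further
#' libraries replicate the reference profile.
#'
#' @param transcriptome a `transcriptome`, or a character vector of gene
#'   ids.
#' @param n_libraries number of libraries (>= 2 when `de_fraction > 0`).
#' @param meanlog,sdlog log-normal parameters of the base abundance.
#' @param de_fraction fraction of genes truly differentially expressed in
#'   library 2, in `[0, 1]`.
#' @param log2fc_values pool of true log2 fold changes sampled (with
#'   replacement) for the DE genes; all nonzero.
#' @param seed integer seed.
#' @return object of class `expression_truth`: list with `abundance`
#'   (genes x libraries matrix, columns `lib1`, `lib2`, ..., each summing
#'   to 1), `true_log2fc` (named vector, 0 for non-DE genes), `de_genes`.
#' @export
sim_expression <- function(transcriptome,
                           n_libraries = 2,
                           meanlog = 0,
                           sdlog = 1.5,
                           de_fraction = 0.05,
                           log2fc_values = c(-2, 2),
                           seed = NULL) {
  ids <- if (is.character(transcriptome) && is.null(names(transcriptome)))
    transcriptome else names(as_sequence_vector(transcriptome))
  n <- length(ids)
  stopifnot(n >= 1, n_libraries >= 1)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  if (de_fraction > 0 && length(log2fc_values) == 0L)
    stop("log2fc_values must be nonempty when de_fraction > 0",
         call. = FALSE)
  if (any(log2fc_values == 0))
    stop("true log2 fold changes must be nonzero", call. = FALSE)
  with_rng_seed(seed, {
    base <- rlnorm(n, meanlog, sdlog)
    w1 <- base / sum(base)
    n_de <- round(de_fraction * n)
    de <- if (n_de > 0) sample(ids, n_de) else character(0)
    lfc <- setNames(numeric(n), ids)
    if (n_de > 0)
      lfc[de] <- sample(log2fc_values, n_de, replace = TRUE)
    w2 <- w1 * 2^lfc
    w2 <- w2 / sum(w2)
    ab <- matrix(w1, nrow = n, ncol = n_libraries,
                 dimnames = list(ids, paste0("lib", seq_len(n_libraries))))
    if (n_libraries >= 2) ab[, 2L] <- w2
    structure(list(abundance = ab, true_log2fc = lfc, de_genes = de,
                   params = list(meanlog = meanlog, sdlog = sdlog,
                                 de_fraction = de_fraction,
                                 log2fc_values = log2fc_values,
                                 seed = seed)),
              class = "expression_truth")
  })
}

#' Simulate one raw DGE tag library
#'
#' Tag reads are the canonical tags (3'-most qualifying CATG site) of the
#' genes, drawn multinomially from the truth abundances; each emitted
#' base is independently substituted with probability `error_rate`. On
#' top of the tag reads the simulator emits the three contaminant classes
#' the cleaning filter removes: adapter-only sentinel reads, reads
#' carrying an `N`, and unique random 21-mers that end up with copy
#' number 1. The four classes sum to `library_size` exactly.
#'
#' @param transcriptome a `transcriptome` (or named sequence vector).
#' @param truth an `expression_truth` for the same genes.
#' @param library_id column of `truth$abundance` to sample from.
#' @param library_size total number of raw reads (>= 1).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param adapter_fraction,n_fraction,singleton_noise_fraction proportions
#'   of adapter-only, N-containing and singleton-noise reads; together
#'   with sampling they must sum to < 1.
#' @param seed integer seed.
#' @return object of class `sim_library`: list with `reads` (character
#'   vector of length `library_size`), `library_id`, `library_size`,
#'   `emission` (ground-truth per-class counts and per-gene emitted tag
#'   counts, before sequencing error) and `params`.
#' @export
sim_library <- function(transcriptome, truth,
                        library_id = "lib1",
                        library_size = 2e5,
                        error_rate = 0.005,
                        adapter_fraction = 0.01,
                        n_fraction = 0.005,
                        singleton_noise_fraction = 0.005,
                        seed = NULL) {
  stopifnot(library_size >= 1, error_rate >= 0, error_rate < 1,
            adapter_fraction >= 0, n_fraction >= 0,
            singleton_noise_fraction >= 0)
  if (adapter_fraction + n_fraction + singleton_noise_fraction >= 1)
    stop("contaminant fractions must sum to < 1", call. = FALSE)
  seqs <- as_sequence_vector(transcriptome)
  stopifnot(inherits(truth, "expression_truth"))
  if (!library_id %in% colnames(truth$abundance))
    stop("library_id '", library_id, "' not found in truth", call. = FALSE)
  w <- truth$abundance[, library_id]
  if (!identical(names(w), names(seqs)))
    stop("truth and transcriptome gene ids disagree", call. = FALSE)

  with_rng_seed(seed, {
    canon <- vapply(seqs, canonical_tag, "")
    dead <- is.na(canon) & w > 0
    if (any(dead)) {
      warning(sum(dead), " untaggable gene(s) with nonzero abundance; ",
              "abundance reassigned to zero and redistributed")
      w[dead] <- 0
      w <- w / sum(w)
    }

    n_adapter <- as.integer(round(adapter_fraction * library_size))
    n_n <- as.integer(round(n_fraction * library_size))
    n_noise <- as.integer(round(singleton_noise_fraction * library_size))
    n_tag <- as.integer(library_size) - n_adapter - n_n - n_noise
    stopifnot(n_tag >= 0L)

    gene_counts <- as.vector(rmultinom(1L, n_tag, w))
    names(gene_counts) <- names(w)
    reads <- rep(canon, gene_counts)

    if (error_rate > 0 && n_tag > 0) {
      # exact iid per-base substitution: draw the number of mutated bases,
      # then their positions uniformly without replacement
      n_bases <- n_tag * 21L
      k <- rbinom(1L, n_bases, error_rate)
      if (k > 0) {
        idx <- sample(n_bases, k)
        ri <- (idx - 1L) %/% 21L + 1L
        pos <- (idx - 1L) %% 21L + 1L
        cur <- substring(reads[ri], pos, pos)
        alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                       G = c("A", "C", "T"), T = c("A", "C", "G"))
        alt <- vapply(seq_len(k), function(j)
          alt_of[[cur[j]]][sample.int(3L, 1L)], "")
        # reads hit more than once must be mutated in rounds, or the
        # second vectorized assignment would discard the first change
        rk <- stats::ave(ri, ri, FUN = seq_along)
        for (round_i in seq_len(max(rk))) {
          sel <- rk == round_i
          tmp <- reads[ri[sel]]
          substr(tmp, pos[sel], pos[sel]) <- alt[sel]
          reads[ri[sel]] <- tmp
        }
      }
    }

    if (n_n > 0) {
      src <- rep(canon, as.vector(rmultinom(1L, n_n, w)))
      p <- sample.int(21L, n_n, replace = TRUE)
      substr(src, p, p) <- "N"
      n_reads <- src
    } else n_reads <- character(0)

    noise <- character(0)
    if (n_noise > 0) {
      repeat {
        need <- n_noise - length(noise)
        if (need <= 0L) break
        cand <- vapply(seq_len(need), function(i)
          paste(sample(DNA_BASES, 21L, replace = TRUE), collapse = ""), "")
        cand <- setdiff(unique(cand), c(canon[!is.na(canon)], noise))
        noise <- c(noise, cand)
      }
    }

    all_reads <- c(reads, n_reads, noise,
                   rep(adapter_sentinel(), n_adapter))
    all_reads <- all_reads[sample.int(length(all_reads))]
    stopifnot(length(all_reads) == library_size)

    structure(list(
      library_id = library_id,
      reads = all_reads,
      library_size = library_size,
      emission = list(n_tag = n_tag, n_adapter = n_adapter, n_n = n_n,
                      n_noise = n_noise, gene_counts = gene_counts,
                      canonical_tags = canon),
      params = list(error_rate = error_rate,
                    adapter_fraction = adapter_fraction,
                    n_fraction = n_fraction,
                    singleton_noise_fraction = singleton_noise_fraction,
                    seed = seed)
    ), class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  e <- x$emission
  cat(sprintf("Simulated DGE library '%s': %d reads (%d tag, %d adapter, %d with N, %d noise)\n",
              x$library_id, x$library_size, e$n_tag, e$n_adapter, e$n_n,
              e$n_noise))
  invisible(x)
}

#' Simulate a gene-to-term annotation table with one planted term
#'
#' Every term annotates genes independently at `background_rate`, except
#' `enriched_term_id`, which annotates the `target_genes` at
#' `enriched_rate` (and the remaining genes at `background_rate`). Used
#' to give the enrichment test a known positive.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_terms number of terms; ids are `T001`, `T002`, ...
#' @param enriched_term_id id of the planted term; must belong to the
#'   term universe.
#' @param target_genes genes enriched for the planted term.
#' @param background_rate,enriched_rate annotation probabilities with
#'   `0 <= background_rate < enriched_rate <= 1`.
#' @param seed integer seed.
#' @return data frame `(gene_id, term_id)`, one row per annotation.
#' @export
sim_annotations <- function(gene_ids,
                            n_terms = 20,
                            enriched_term_id = "T001",
                            target_genes = character(0),
                            background_rate = 0.05,
                            enriched_rate = 0.8,
                            seed = NULL) {
  stopifnot(n_terms >= 1)
  if (!(background_rate >= 0 && background_rate < enriched_rate &&
        enriched_rate <= 1))
    stop("need 0 <= background_rate < enriched_rate <= 1", call. = FALSE)
  terms <- sprintf("T%03d", seq_len(n_terms))
  if (!enriched_term_id %in% terms)
    stop("enriched_term_id '", enriched_term_id,
         "' is not in the term universe", call. = FALSE)
  if (!all(target_genes %in% gene_ids))
    stop("target_genes must be a subset of gene_ids", call. = FALSE)
  with_rng_seed(seed, {
    rows <- lapply(terms, function(tm) {
      rate <- rep(background_rate, length(gene_ids))
      if (tm == enriched_term_id)
        rate[gene_ids %in% target_genes] <- enriched_rate
      hit <- runif(length(gene_ids)) < rate
      if (!any(hit)) return(NULL)
      data.frame(gene_id = gene_ids[hit], term_id = tm,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write or read raw tag reads
#'
#' Two on-disk forms are supported: one read per line (`format =
#' "reads"`), or a two-column tab-separated `tag` / `count` table
#' (`format = "counts"`). `read_raw_tags()` auto-detects the form and
#' always returns a named count vector.
#'
#' @param x a `sim_library`, a character vector of reads, or a named
#'   count vector.
#' @param path file path.
#' @param format output form.
#' @return `read_raw_tags()`: named integer vector of counts.
#' @export
write_raw_tags <- function(x, path, format = c("counts", "reads")) {
  format <- match.arg(format)
  if (inherits(x, "sim_library")) x <- x$reads
  if (format == "reads") {
    if (!is.null(names(x)) && is.numeric(x)) x <- rep(names(x), x)
    writeLines(x, path)
  } else {
    counts <- as_tag_counts(x)
    counts <- counts[order(names(counts))]
    write.table(data.frame(tag = names(counts), count = as.integer(counts)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_raw_tags
#' @export
read_raw_tags <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("tag", "count") %in% names(tab)))
      names(tab)[1:2] <- c("tag", "count")
    setNames(as.integer(tab$count), tab$tag)
  } else {
    as_tag_counts(readLines(path))
  }
}

#' Write an expression truth table as TSV
#'
#' Long table `(gene_id, library_id, abundance, true_log2fc)`.
#'
#' @param truth an `expression_truth`.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "expression_truth"))
  ab <- truth$abundance
  out <- data.frame(
    gene_id = rep(rownames(ab), ncol(ab)),
    library_id = rep(colnames(ab), each = nrow(ab)),
    abundance = as.vector(ab),
    true_log2fc = rep(truth$true_log2fc[rownames(ab)], ncol(ab)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
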