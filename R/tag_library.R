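#' Locate NlaIII recognition sites in a sequence
#'
#' Returns the 1-based positions of the 'C' of every `CATG` occurrence on
#' the given strand. `CATG` cannot overlap itself, but the scan is
#' exhaustive over every position.
#'
#' @param sequence a single DNA string over `{A,C,G,T,N}` (case
#'   insensitive).
#' @return integer vector of strictly increasing 1-based positions
#'   (empty when no site is present).
#' @examples
#' find_catg_sites("CATGCATG")  # 1, 5
#' @export
find_catg_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_dna(sequence)
  hit <- gregexpr("CATG", sequence, fixed = TRUE)[[1L]]
  if (hit[1L] == -1L) integer(0) else as.integer(hit)
}

#' Extract all candidate 21-base tags from a sequence
#'
#' In the DGE protocol, NlaIII cuts at `CATG` and MmeI cuts 17 bp
#' downstream, so each qualifying site yields a 21-mer: `CATG` plus the 17
#' following bases. A site qualifies only when at least 17 bases follow
#' the `CATG` (i.e. `position + 20 <= length`). Tags containing `N` are
#' dropped: they can never be matched by clean tags, which are N-free.
#'
#' @inheritParams find_catg_sites
#' @return data frame with columns `pos` (1-based position of the 'C')
#'   and `tag` (21-mer); zero rows when no site qualifies.
#' @export
extract_tags <- function(sequence) {
  sequence <- toupper(sequence)
  pos <- find_catg_sites(sequence)
  pos <- pos[pos + 20L <= nchar(sequence)]
  if (length(pos) == 0L)
    return(data.frame(pos = integer(0), tag = character(0),
                      stringsAsFactors = FALSE))
  tags <- substring(sequence, pos, pos + 20L)
  keep <- !grepl("N", tags, fixed = TRUE)
  data.frame(pos = pos[keep], tag = tags[keep], stringsAsFactors = FALSE)
}

#' Canonical tag of a transcript
#'
#' The tag the bead-based protocol actually sequences: after digestion the
#' 3'-most fragment stays bound, so the observable tag comes from the
#' 3'-most `CATG` site with at least 17 downstream bases.
#'
#' @inheritParams find_catg_sites
#' @return the 21-mer of the 3'-most qualifying site, or `NA_character_`
#'   when the sequence has no qualifying site (an untaggable transcript).
#' @export
canonical_tag <- function(sequence) {
  tg <- extract_tags(sequence)
  if (nrow(tg) == 0L) NA_character_ else tg$tag[nrow(tg)]
}

#' Build the reference tag library from a transcriptome
#'
#' In-silico digestion of every gene: all `CATG` sites with 17 downstream
#' bases contribute a 21-mer to the reference, each annotated with its
#' gene of origin, site position and strand. A tag shared by several
#' genes is kept once with all origins recorded and flagged as not
#' gene-unique; clean tags mapping to such a tag are ambiguous and do not
#' contribute to any gene's expression.
#'
#' @param transcriptome named character vector of gene sequences (names
#'   are gene ids), a `Biostrings::DNAStringSet`, or a `transcriptome`
#'   object from [sim_transcriptome()].
#' @param strand_mode `"sense_only"` (default; assembled unigenes have a
#'   determined sense) or `"both"` to also digest the reverse complement
#'   of each gene.
#' @return an object of class `tag_library`: list with `tags` (data frame
#'   `tag`, `n_genes`, `gene_ids` semicolon-joined, `is_gene_unique`),
#'   `origins` (long data frame `tag`, `gene_id`, `pos`, `strand`),
#'   `gene_ids`, `genes_total`, `genes_taggable`, `strand_mode`.
#' @examples
#' lib <- build_tag_library(c(g1 = paste0("CATG", strrep("A", 17))))
#' lib$tags$tag
#' @export
build_tag_library <- function(transcriptome,
                              strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  seqs <- as_sequence_vector(transcriptome)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("transcriptome records must be named by gene id", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene_id in transcriptome: ",
         names(seqs)[anyDuplicated(names(seqs))], call. = FALSE)
  seqs <- toupper(seqs)

  scan_one <- function(seq, gene, strand) {
    tg <- extract_tags(seq)
    if (nrow(tg) == 0L) return(NULL)
    data.frame(tag = tg$tag, gene_id = gene, pos = tg$pos,
               strand = strand, stringsAsFactors = FALSE)
  }
  pieces <- vector("list", length(seqs) * (1L + (strand_mode == "both")))
  k <- 0L
  for (i in seq_along(seqs)) {
    k <- k + 1L
    pieces[[k]] <- scan_one(seqs[[i]], names(seqs)[i], "+")
  }
  if (strand_mode == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
    for (i in seq_along(seqs)) {
      k <- k + 1L
      pieces[[k]] <- scan_one(rc[[i]], names(seqs)[i], "-")
    }
  }
  origins <- do.call(rbind, pieces)
  if (is.null(origins))
    origins <- data.frame(tag = character(0), gene_id = character(0),
                          pos = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
  # stable order so the build is independent of input record order
  origins <- origins[order(origins$tag, origins$gene_id, origins$strand,
                           origins$pos), , drop = FALSE]
  rownames(origins) <- NULL

  if (nrow(origins) > 0L) {
    gene_by_tag <- lapply(split(origins$gene_id, origins$tag), unique)
    tags <- data.frame(
      tag = names(gene_by_tag),
      n_genes = lengths(gene_by_tag),
      gene_ids = vapply(gene_by_tag, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
    tags$is_gene_unique <- tags$n_genes == 1L
    rownames(tags) <- NULL
  } else {
    tags <- data.frame(tag = character(0), n_genes = integer(0),
                       gene_ids = character(0), is_gene_unique = logical(0),
                       stringsAsFactors = FALSE)
  }

  structure(list(
    tags = tags,
    origins = origins,
    gene_ids = names(seqs),
    genes_total = length(seqs),
    genes_taggable = length(unique(origins$gene_id)),
    strand_mode = strand_mode
  ), class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Reference tag library (", x$strand_mode, ")\n", sep = "")
  cat(sprintf("  genes: %d total, %d taggable\n",
              x$genes_total, x$genes_taggable))
  cat(sprintf("  tags:  %d distinct (%d gene-unique), %d site origins\n",
              nrow(x$tags), sum(x$tags$is_gene_unique), nrow(x$origins)))
  invisible(x)
}

#' Write / read a reference tag library as TSV
#'
#' One row per distinct tag: tag sequence, semicolon-joined gene ids,
#' site positions, strands and the gene-unique flag.
#'
#' @param library a `tag_library`.
#' @param path output file path.
#' @return `write_tag_library()` returns `path` invisibly.
#' @export
write_tag_library <- function(library, path) {
  stopifnot(inherits(library, "tag_library"))
  o <- library$origins
  per_tag <- function(col) vapply(split(o[[col]], o$tag),
                                  paste, "", collapse = ";")
  out <- library$tags
  if (nrow(out) > 0L) {
    out$positions <- per_tag("pos")[out$tag]
    out$strands <- per_tag("strand")[out$tag]
  } else {
    out$positions <- character(0)
    out$strands <- character(0)
  }
  write.table(out[, c("tag", "gene_ids", "positions", "strands",
                      "is_gene_unique")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcriptome FASTA
#'
#' Multi-record FASTA, wrapped or unwrapped, case-insensitive; record
#' names are truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return named uppercase character vector of sequences.
#' @export
read_transcriptome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a transcriptome FASTA
#'
#' @param transcriptome named character vector or `transcriptome` object.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(transcriptome, path) {
  seqs <- as_sequence_vector(transcriptome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

as_sequence_vector <- function(x) {
  if (inherits(x, "transcriptome")) return(unclass_transcriptome(x))
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a transcriptome", call. = FALSE)
}
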