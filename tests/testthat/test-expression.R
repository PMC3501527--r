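# One-mismatch tag mapping, status classification, gene counting and TPM.

tagA <- paste0("CATG", strrep("A", 17))
tagC <- paste0("CATG", strrep("C", 17))

test_that("exact hits preempt the one-mismatch search", {
  lib <- build_tag_library(c(g1 = tagA, g2 = tagC))
  m <- match_tag(tagA, lib)
  expect_identical(m$match_class, "exact")
  expect_identical(m$matched_genes, "g1")

  off <- paste0("CATG", "T", strrep("A", 16))
  m1 <- match_tag(off, lib)
  expect_identical(m1$match_class, "one_mismatch")
  expect_identical(m1$matched_genes, "g1")

  far <- paste0("CATG", strrep("G", 17))
  expect_identical(match_tag(far, lib)$match_class, "unknown")
  expect_error(match_tag("CATG", lib), "21")
})

test_that("a tag matching one gene exactly and another at distance 1 is
          unambiguous unless exact and mismatch hits are pooled", {
  near <- paste0("CATG", "T", strrep("A", 16))  # distance 1 from tagA
  lib <- build_tag_library(c(gA = tagA, gB = near))
  pre <- match_tag(tagA, lib, exact_preempts = TRUE)
  expect_identical(pre$match_class, "exact")
  expect_identical(pre$matched_genes, "gA")
  pooled <- match_tag(tagA, lib, exact_preempts = FALSE)
  expect_identical(pooled$match_class, "exact")
  expect_setequal(pooled$matched_genes, c("gA", "gB"))
})

test_that("gene-status classification follows the matched gene count", {
  # one query whose two 1-mismatch neighbors live in different genes
  q <- paste0("CATG", "G", strrep("A", 16))
  nb1 <- paste0("CATG", "T", strrep("A", 16))
  nb2 <- paste0("CATG", "C", strrep("A", 16))
  lib <- build_tag_library(c(g1 = nb1, g2 = nb2))
  a <- assign_tags(setNames(5L, q), lib)
  expect_identical(a$assignments$status, "ambiguous")
  expect_identical(a$assignments$match_class, "one_mismatch")
  expect_identical(a$stats$unambiguous_total, 0L)
  expect_identical(a$stats$all_mapped_total, 5L)

  nowhere <- assign_tags(setNames(c(3L, 4L), c(tagA, tagC)),
                         build_tag_library(c(g = paste0("CATG", strrep("T", 17)))))
  expect_identical(nowhere$stats$unknown_total, 7L)
  expect_identical(nowhere$stats$unknown_total, nowhere$stats$clean_total)
})

test_that("mapping equals the brute-force Hamming oracle", {
  set.seed(100)
  genes <- setNames(paste0("CATG", random_dna(200, 17)),
                    sprintf("g%03d", 1:200))
  lib <- build_tag_library(genes)
  # queries: reference tags, 1- and 2-base mutants, random tags
  mutate <- function(tag, k) {
    pos <- sample(21, k)
    for (p in pos) {
      cur <- substr(tag, p, p)
      substr(tag, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    tag
  }
  queries <- unique(c(
    sample(lib$tags$tag, 50),
    vapply(sample(lib$tags$tag, 50, replace = TRUE), mutate, "", k = 1),
    vapply(sample(lib$tags$tag, 50, replace = TRUE), mutate, "", k = 2),
    random_dna(50, 21)))
  a <- assign_tags(setNames(rep(2L, length(queries)), queries), lib)
  for (i in seq_along(queries)) {
    want <- brute_match(queries[i], lib)
    expect_identical(a$assignments$match_class[i], want$match_class)
    got_genes <- if (nzchar(a$assignments$genes[i]))
      sort(strsplit(a$assignments$genes[i], ";")[[1]]) else character(0)
    expect_identical(got_genes, want$matched_genes)
  }
  # conservation over counts and species
  expect_identical(a$stats$all_mapped_total + a$stats$unknown_total,
                   a$stats$clean_total)
  expect_identical(a$stats$all_mapped_distinct + a$stats$unknown_distinct,
                   a$stats$clean_distinct)
})

test_that("an error-free library maps completely onto its own reference", {
  tx <- sim_transcriptome(150, fraction_untaggable = 0, seed = 110)
  truth <- sim_expression(tx, de_fraction = 0, seed = 111)
  sl <- sim_library(tx, truth, "lib1", 50000, error_rate = 0,
                    adapter_fraction = 0, n_fraction = 0,
                    singleton_noise_fraction = 0, seed = 112)
  fl <- filter_tags(sl)
  lib <- build_tag_library(tx)
  a <- assign_tags(fl$clean, lib)
  expect_identical(a$stats$unknown_total, 0L)
  # every gene whose canonical tag survived filtering is recovered
  counts <- count_genes(a, lib)
  emitted <- sl$emission$gene_counts
  canon <- sl$emission$canonical_tags
  surviving <- names(emitted)[emitted >= 2 & canon %in% names(fl$clean)]
  gene_unique_canon <- surviving[canon[surviving] %in%
                                   lib$tags$tag[lib$tags$is_gene_unique]]
  got <- setNames(counts$count, counts$gene_id)
  expect_true(all(got[gene_unique_canon] > 0))
})

test_that("gene counts sum unambiguous evidence only", {
  t2 <- paste0("CATG", strrep("G", 17))
  shared <- paste0("CATG", strrep("T", 17))
  lib <- build_tag_library(c(
    g1 = paste0(tagA, t2),                  # two unambiguous tags
    g2 = paste0(shared, "AA"),
    g3 = paste0("CC", shared)))             # shared -> ambiguous
  clean <- setNames(c(10L, 5L, 99L), c(tagA, t2, shared))
  a <- assign_tags(clean, lib)
  counts <- count_genes(a, lib)
  got <- setNames(counts$count, counts$gene_id)
  expect_identical(unname(got["g1"]), 15)
  expect_identical(unname(got["g2"]), 0)   # ambiguous contributes nothing
  expect_identical(unname(got["g3"]), 0)
  expect_identical(sum(counts$count), as.numeric(a$stats$unambiguous_total))
})

test_that("TPM scales counts by the chosen denominator", {
  counts <- data.frame(gene_id = c("a", "b"), count = c(50, 0))
  out <- tpm_normalize(counts, 5e5)
  expect_equal(out$tpm, c(100, 0))
  expect_error(tpm_normalize(counts, 0), "positive")
  # with the unambiguous-total denominator TPM sums to one million
  tx <- sim_transcriptome(100, fraction_untaggable = 0, seed = 120)
  truth <- sim_expression(tx, de_fraction = 0, seed = 121)
  sl <- sim_library(tx, truth, "lib1", 20000, seed = 122)
  fl <- filter_tags(sl)
  lib <- build_tag_library(tx)
  ex <- quantify_library(fl$clean, lib,
                         denominator_mode = "unambiguous_total")
  expect_equal(sum(ex$tpm), 1e6)
})

test_that("TPM recovers the truth ranking on error-free data", {
  tx <- sim_transcriptome(2000, fraction_untaggable = 0, seed = 130)
  truth <- sim_expression(tx, de_fraction = 0, seed = 131)
  sl <- sim_library(tx, truth, "lib1", 3e5, error_rate = 0,
                    adapter_fraction = 0, n_fraction = 0,
                    singleton_noise_fraction = 0, seed = 132)
  fl <- filter_tags(sl)
  lib <- build_tag_library(tx)
  ex <- quantify_library(fl$clean, lib)
  rho <- cor(ex$tpm, truth$abundance[ex$gene_id, "lib1"],
             method = "spearman")
  expect_gte(rho, 0.99)
})
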