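# Synthetic-data generators: seed determinism, designed untaggability,
# expression truths, read-class conservation and annotation planting.

test_that("transcriptome generation is seed deterministic", {
  a <- sim_transcriptome(100, seed = 42)
  b <- sim_transcriptome(100, seed = 42)
  expect_identical(a, b)
  c <- sim_transcriptome(100, seed = 43)
  expect_false(identical(as.character(a), as.character(c)))
})

test_that("exactly the requested fraction of genes is untaggable", {
  tx <- sim_transcriptome(50, fraction_untaggable = 0.2, seed = 1)
  # independent check by naive scan: a gene is untaggable iff no CATG
  # site has >= 17 downstream bases
  untag <- names(tx)[vapply(unclass(tx), function(s) {
    p <- naive_catg_scan(s)
    !any(p + 20L <= nchar(s))
  }, logical(1))]
  expect_length(untag, 10L)
  expect_setequal(untag, attr(tx, "untaggable"))
  # the degenerate all-untaggable case
  one <- sim_transcriptome(1, fraction_untaggable = 1, seed = 7)
  expect_true(is.na(canonical_tag(as.character(one))))
  # taggable genes always carry at least one qualifying site
  tx2 <- sim_transcriptome(80, fraction_untaggable = 0, min_length = 25,
                           length_meanlog = log(40), seed = 2)
  expect_true(all(vapply(unclass(tx2), function(s)
    any(naive_catg_scan(s) + 20L <= nchar(s)), logical(1))))
  expect_true(all(nchar(tx2) >= 25))
  expect_error(sim_transcriptome(10, fraction_untaggable = 1.5),
               "fraction_untaggable")
})

test_that("expression truth is a simplex with the assigned fold changes", {
  tx <- sim_transcriptome(300, seed = 5)
  truth <- sim_expression(tx, de_fraction = 0.1, log2fc_values = c(-2, 2),
                          seed = 6)
  expect_equal(colSums(truth$abundance), c(lib1 = 1, lib2 = 1),
               tolerance = 1e-9)
  expect_length(truth$de_genes, 30L)
  expect_true(all(abs(truth$true_log2fc[truth$de_genes]) > 0))
  # renormalization preserves the assigned ratio relative to non-DE genes
  ratio <- truth$abundance[, "lib2"] / truth$abundance[, "lib1"]
  nonde <- setdiff(names(tx), truth$de_genes)
  rel <- ratio[truth$de_genes] / ratio[nonde[1]]
  expect_equal(unname(rel), 2^truth$true_log2fc[truth$de_genes],
               tolerance = 1e-12, ignore_attr = TRUE)

  null <- sim_expression(tx, de_fraction = 0, seed = 7)
  expect_equal(null$abundance[, "lib1"], null$abundance[, "lib2"])
  expect_error(sim_expression(tx, de_fraction = 1.5), "de_fraction")
  expect_error(sim_expression(tx, de_fraction = 0.5,
                              log2fc_values = numeric(0)), "nonempty")
})

test_that("simulated libraries conserve read classes exactly", {
  tx <- sim_transcriptome(100, fraction_untaggable = 0, seed = 10)
  truth <- sim_expression(tx, de_fraction = 0, seed = 11)
  sl <- sim_library(tx, truth, "lib1", library_size = 20000,
                    error_rate = 0.01, adapter_fraction = 0.05,
                    n_fraction = 0.02, singleton_noise_fraction = 0.01,
                    seed = 12)
  e <- sl$emission
  expect_identical(length(sl$reads), 20000L)
  expect_identical(e$n_tag + e$n_adapter + e$n_n + e$n_noise, 20000L)
  expect_identical(sum(sl$reads == adapter_sentinel()), as.integer(e$n_adapter))
  expect_identical(sum(e$gene_counts), e$n_tag)
  # determinism
  sl2 <- sim_library(tx, truth, "lib1", library_size = 20000,
                     error_rate = 0.01, adapter_fraction = 0.05,
                     n_fraction = 0.02, singleton_noise_fraction = 0.01,
                     seed = 12)
  expect_identical(sl$reads, sl2$reads)
})

test_that("with no error or contamination every read is a canonical tag", {
  tx <- sim_transcriptome(50, fraction_untaggable = 0, seed = 20)
  truth <- sim_expression(tx, de_fraction = 0, seed = 21)
  sl <- sim_library(tx, truth, "lib1", 5000, error_rate = 0,
                    adapter_fraction = 0, n_fraction = 0,
                    singleton_noise_fraction = 0, seed = 22)
  canon <- vapply(unclass(tx), canonical_tag, "")
  expect_true(all(sl$reads %in% canon))
})

test_that("a single expressed gene yields a degenerate multinomial", {
  tx <- sim_transcriptome(3, fraction_untaggable = 0, seed = 30)
  truth <- sim_expression(tx, de_fraction = 0, seed = 31)
  truth$abundance[, ] <- 0
  truth$abundance[1, ] <- 1
  sl <- sim_library(tx, truth, "lib1", 1000, error_rate = 0,
                    adapter_fraction = 0, n_fraction = 0,
                    singleton_noise_fraction = 0, seed = 32)
  expect_identical(unname(sl$emission$gene_counts[1]), 1000L)
  expect_identical(unique(sl$reads), canonical_tag(as.character(tx)[1]))
})

test_that("untaggable genes with abundance are zeroed with a warning", {
  tx <- sim_transcriptome(20, fraction_untaggable = 0.5, seed = 40)
  truth <- sim_expression(tx, de_fraction = 0, seed = 41)
  expect_warning(
    sl <- sim_library(tx, truth, "lib1", 2000, error_rate = 0,
                      adapter_fraction = 0, n_fraction = 0,
                      singleton_noise_fraction = 0, seed = 42),
    "untaggable")
  expect_identical(
    sum(sl$emission$gene_counts[attr(tx, "untaggable")]), 0L)
})

test_that("empirical tag frequencies converge to the truth abundances", {
  g <- 500
  size <- 1e5
  tx <- sim_transcriptome(g, fraction_untaggable = 0, seed = 50)
  truth <- sim_expression(tx, de_fraction = 0, seed = 51)
  sl <- sim_library(tx, truth, "lib1", size, error_rate = 0,
                    adapter_fraction = 0, n_fraction = 0,
                    singleton_noise_fraction = 0, seed = 52)
  emp <- sl$emission$gene_counts / size
  tv <- sum(abs(emp - truth$abundance[, "lib1"])) / 2
  expect_lt(tv, 3 * sqrt(g / size))
})

test_that("annotation planting hits the target set at the planted rate", {
  genes <- sprintf("g%04d", 1:400)
  target <- genes[1:40]
  # degenerate rates give exactly the target set
  ann <- sim_annotations(genes, n_terms = 3, enriched_term_id = "T002",
                         target_genes = target, background_rate = 0,
                         enriched_rate = 1, seed = 60)
  expect_setequal(ann$gene_id[ann$term_id == "T002"], target)
  expect_identical(sum(ann$term_id != "T002"), 0L)
  # determinism
  ann2 <- sim_annotations(genes, n_terms = 3, enriched_term_id = "T002",
                          target_genes = target, background_rate = 0,
                          enriched_rate = 1, seed = 60)
  expect_identical(ann, ann2)
  # realized rate within 3 binomial standard errors of the planted rate
  big_target <- genes[1:200]
  ann3 <- sim_annotations(genes, n_terms = 2, enriched_term_id = "T001",
                          target_genes = big_target,
                          background_rate = 0.05, enriched_rate = 0.8,
                          seed = 61)
  hit <- sum(ann3$gene_id[ann3$term_id == "T001"] %in% big_target)
  rate <- hit / length(big_target)
  se <- sqrt(0.8 * 0.2 / length(big_target))
  expect_lt(abs(rate - 0.8), 3 * se)
  expect_error(sim_annotations(genes, n_terms = 2,
                               enriched_term_id = "T099"), "universe")
  expect_error(sim_annotations(genes, background_rate = 0.9,
                               enriched_rate = 0.8), "background_rate")
})

test_that("raw tag files round-trip in both formats", {
  tx <- sim_transcriptome(20, fraction_untaggable = 0, seed = 70)
  truth <- sim_expression(tx, de_fraction = 0, seed = 71)
  sl <- sim_library(tx, truth, "lib1", 500, seed = 72)
  counts <- as.integer(table(sl$reads))
  names(counts) <- names(table(sl$reads))

  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_raw_tags(sl, p1, format = "counts")
  expect_identical(read_raw_tags(p1), counts[order(names(counts))])

  p2 <- withr::local_tempfile(fileext = ".txt")
  write_raw_tags(sl, p2, format = "reads")
  back <- read_raw_tags(p2)
  expect_identical(back[order(names(back))], counts[order(names(counts))])
})
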