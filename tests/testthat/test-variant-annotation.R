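test_that("novelty classes follow exact-over-same-codon dominance", {
  cat <- data.frame(catalog_name = "COSMIC-standin", c_pos = 818L,
                    ref = "T", alt = "G", protein_label = "F273C")
  r <- classify_novelty(817, "T", "C", cat)
  expect_identical(r$novelty, "same_codon_different_change")
  expect_identical(r$sources, "COSMIC-standin")
  cat2 <- data.frame(catalog_name = "COSMIC-standin", c_pos = 755L,
                     ref = "G", alt = "T", protein_label = "S252I")
  expect_identical(classify_novelty(755, "G", "A", cat2)$novelty,
                   "same_codon_different_change")
  expect_identical(classify_novelty(755, "G", "A", NULL)$novelty, "novel")
  # exact match dominates a same-codon record in another catalog
  both <- rbind(cat, data.frame(catalog_name = "dbSNP-standin",
                                c_pos = 817L, ref = "T", alt = "C",
                                protein_label = "F273L"))
  rb <- classify_novelty(817, "T", "C", both)
  expect_identical(rb$novelty, "known_exact")
  expect_identical(rb$sources, "dbSNP-standin")
})

test_that("novelty classes are mutually exclusive and exhaustive", {
  set.seed(11)
  cats <- make_catalog_standins(n_decoys = 10, seed = 3)
  for (k in 1:60) {
    pos <- sample(740:980, 1)
    ba <- sample(c("A", "C", "G", "T"), 2)
    r <- classify_novelty(pos, ba[1], ba[2], cats)
    expect_true(r$novelty %in%
                  c("novel", "known_exact", "same_codon_different_change"))
    if (r$novelty == "known_exact") {
      expect_true(any(cats$c_pos == pos & cats$ref == ba[1] &
                        cats$alt == ba[2]))
      expect_gt(length(r$sources), 0)
    }
    if (r$novelty == "novel") {
      expect_false(any((cats$c_pos + 2L) %/% 3L == (pos + 2L) %/% 3L))
    }
  }
})

test_that("annotation combines consequence, domains, epitopes and novelty", {
  model <- default_reference()$model
  v <- data.frame(c_pos = 823L, ref = "C", alt = "T")
  a <- annotate_variants(v, model)
  expect_identical(a$protein_label, "P275S")
  expect_setequal(strsplit(a$domains, ",")[[1]], c("M9", "TPNO1_core"))
  expect_identical(a$epitope, "epitope1")
  expect_identical(a$novelty, "novel")
  a2 <- annotate_variants(data.frame(c_pos = 922L, ref = "T", alt = "C"),
                          model, catalogs = make_catalog_standins())
  expect_identical(a2$protein_label, "S308P")
  expect_identical(a2$domains, "C_terminal")
  expect_identical(a2$novelty, "known_exact")
  expect_identical(a2$sources, "dbSNP-standin")
  expect_error(annotate_variants(
    data.frame(c_pos = 823L, ref = "G", alt = "T"), model),
    "reference mismatch")
})

test_that("re-annotating the event table reproduces printed labels except on the documented discrepancy list", {
  ref <- default_reference()
  vp <- validate_printed_pairs(table1_events(), ref$model)
  flagged <- vp[!vp$consistent, ]
  documented <- c("c.817T>G", "c.898C>T", "c.922T>G")
  expect_setequal(flagged$hgvs_c, documented)
  expect_setequal(
    paste(flagged$hgvs_c, flagged$computed_p),
    c("c.817T>G F273V", "c.898C>T R300*", "c.922T>G S308A"))
  # consistent + flagged rows are exhaustive
  expect_equal(sum(vp$consistent) + nrow(flagged), nrow(vp))
  # the generator's discrepancy report agrees with the validator
  expect_setequal(
    paste0("c.", ref$discrepancies$c_pos, ref$discrepancies$ref, ">",
           ref$discrepancies$alt),
    documented)
})

test_that("printed-pair validation judges individual rows", {
  model <- default_reference()$model
  one <- function(c_pos, ref, alt, printed) {
    validate_printed_pairs(
      data.frame(c_pos = c_pos, ref = ref, alt = alt,
                 printed_p = printed), model)
  }
  expect_true(one(841, "T", "C", "F281L")$consistent)
  expect_false(one(817, "T", "G", "F273L")$consistent)
  expect_identical(one(922, "T", "G", "S308P")$computed_p, "S308A")
})

test_that("FUS mapping follows the packaged alignment columns", {
  py <- pynls_alignment()
  expect_identical(map_to_fus(275, py), 510L)
  expect_identical(map_to_fus(284, py), 522L)
  expect_identical(map_to_fus(285, py), NA_integer_)  # FUS gap column
  expect_identical(map_to_fus(300, py), NA_integer_)  # outside window
  # strictly increasing, hence injective, on doubly-aligned columns
  both <- py[!is.na(py$a1_pos) & !is.na(py$fus_pos), ]
  expect_true(!is.unsorted(both$fus_pos, strictly = TRUE))
  expect_true(!is.unsorted(both$a1_pos, strictly = TRUE))
})

test_that("epitope tags follow the configured PY-NLS intervals", {
  expect_identical(epitope_of(273), "epitope1")
  expect_identical(epitope_of(276), "epitope1")
  expect_setequal(epitope_of(284), c("epitope2", "epitope3"))
  expect_identical(epitope_of(287), "epitope3")
  expect_length(epitope_of(290), 0)
})

test_that("FUS-mutation overlap supports both table readings", {
  snv_res <- unique(annotated_table1()$aa_index)
  starred <- fus_mutation_overlap(snv_res)
  strict <- fus_mutation_overlap(snv_res, criterion = "mutation_row")
  expect_identical(starred, c(275L, 284L))
  expect_true(all(starred %in% strict))
})

test_that("annotated output writes valid TSV and VCF", {
  ref <- default_reference()
  ann <- annotated_table1()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(ann, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(ann))
  expect_identical(back$hgvs_c, ann$hgvs_c)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_minimal_vcf(ann, ref$amplicon, vcf)
  parsed <- VariantAnnotation::readVcf(vcf)
  expect_equal(length(parsed), nrow(ann))
  expect_identical(
    as.character(VariantAnnotation::ref(parsed)), ann$ref)
  expect_identical(
    unlist(VariantAnnotation::info(parsed)$NOVELTY, use.names = FALSE),
    ann$novelty)
  pos <- BiocGenerics::start(SummarizedExperiment::rowRanges(parsed))
  expect_equal(pos, ann$g_pos - ref$amplicon$g_start + 1L)
})

test_that("catalog files round-trip and enforce uniqueness", {
  cats <- make_catalog_standins(n_decoys = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(cats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_catalog(path)
  expect_equal(nrow(back), nrow(cats))
  dup <- rbind(cats, cats[1, ])
  expect_error(as_catalog(dup), "unique")
  expect_error(as_catalog(data.frame(c_pos = 1)), "lacks column")
})
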