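test_that("the built reference satisfies every printed constraint", {
  ref <- default_reference()
  expect_equal(nchar(ref$amplicon$sequence), 611L)
  expect_equal(length(ref$model$g_exonic), 212L)
  codons <- ref$codons
  # forced codons
  expect_identical(codons$codon[codons$residue == 276], "ATG")
  expect_identical(codons$codon[codons$residue == 300], "CGA")
  expect_identical(codons$codon[codons$residue == 321], "TAA")
  expect_identical(codons$codon[codons$residue == 273], "TTT")
  # protein anchors from the PY-NLS alignment (residues 262-289)
  py <- pynls_alignment()
  al <- py[!is.na(py$a1_pos), ]
  for (i in seq_len(nrow(al))) {
    expect_identical(codons$aa[codons$residue == al$a1_pos[i]],
                     al$a1_aa[i])
  }
  # PCR primer footprints embedded verbatim
  expect_identical(substr(ref$amplicon$sequence, 1, 21),
                   "CAGATAAAGGCCCTCTTTCCC")
  down <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CTCAGCTACATTAGGGTTATTGGG")))
  expect_identical(substr(ref$amplicon$sequence, 611 - 23, 611), down)
  # editable fill avoids the EcoRI motif
  expect_false(grepl("GAATTC", ref$amplicon$sequence, fixed = TRUE))
})

test_that("reference construction is deterministic in the seed", {
  a <- build_reference(seed = 7L)
  b <- build_reference(seed = 7L)
  c <- build_reference(seed = 8L)
  expect_identical(a$amplicon$sequence, b$amplicon$sequence)
  expect_false(identical(a$amplicon$sequence, c$amplicon$sequence))
  # constrained coding positions never move with the seed
  expect_identical(a$codons, c$codons)
})

test_that("jointly unsatisfiable codon constraints are excluded and reported", {
  ev <- data.frame(subject = "X-1", group = "PPMS", c_pos = 817L,
                   ref = "T", alt = "G", printed_p = "F273L",
                   stringsAsFactors = FALSE)
  ev$hgvs_c <- "c.817T>G"
  cons <- reference_constraints(events = ev, primers = NULL, pynls = NULL,
                                catalogs = NULL)
  ref <- build_reference(cons)
  expect_equal(nrow(ref$discrepancies), 1L)
  expect_identical(ref$discrepancies$label, "F273L")
  # a satisfiable variant of the same row builds cleanly
  ev2 <- ev
  ev2$alt <- "C"
  ev2$hgvs_c <- "c.817T>C"
  cons2 <- reference_constraints(events = ev2, primers = NULL,
                                 pynls = NULL, catalogs = NULL)
  ref2 <- build_reference(cons2)
  expect_equal(nrow(ref2$discrepancies), 0L)
  expect_identical(translate_codon(ref_codon(ref2$model, 273)), "F")
})

test_that("a zero-probability simulation returns faithful clones", {
  ref <- default_reference()
  sim <- simulate_clone_set(ref, n_clones = 8, somatic_prob = 0,
                            pcr_error_prob = 0, seed = 3)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(sim$reads == ref$amplicon$sequence))
  expect_identical(names(sim$reads)[1], "S1|clone0001")
})

test_that("simulated events are consistent with their truth records", {
  ref <- default_reference()
  sim <- simulate_clone_set(ref, n_clones = 400, subject = "SPMS-1",
                            somatic_prob = 0.1, region = "M9",
                            pcr_error_prob = 0.01, seed = 42)
  tr <- sim$truth
  expect_gt(sum(tr$kind == "somatic"), 0)
  expect_gt(sum(tr$kind == "pcr_error"), 0)
  som <- tr[tr$kind == "somatic", ]
  # somatic events live in full codons of the region and change the protein
  expect_true(all(in_region(som$residue, "M9")))
  for (i in seq_len(nrow(som))) {
    cq <- consequence(ref$model, som$c_pos[i], som$ref[i], som$alt[i])
    expect_true(cq$cls %in% c("missense", "nonsense"))
  }
  # every truth record matches the planted base in the read
  for (i in seq_len(nrow(tr))) {
    off <- tr$g_pos[i] - ref$amplicon$g_start + 1L
    expect_identical(unname(substr(sim$reads[tr$clone_id[i]], off, off)),
                     tr$alt[i])
  }
  # reproducible from the seed
  sim2 <- simulate_clone_set(ref, n_clones = 400, subject = "SPMS-1",
                             somatic_prob = 0.1, region = "M9",
                             pcr_error_prob = 0.01, seed = 42)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("clone FASTA and truth TSV exports are byte-stable", {
  ref <- default_reference()
  sim <- simulate_clone_set(ref, n_clones = 5, somatic_prob = 0.5,
                            pcr_error_prob = 0, seed = 11)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clone_set(sim, fasta = fa, truth_tsv = tsv)
  reads <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(reads), sim$reads)
  truth <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(truth$g_pos, sim$truth$g_pos)
})

test_that("catalog stand-ins carry the cited records plus harmless decoys", {
  cats <- make_catalog_standins(n_decoys = 30, seed = 5)
  cited <- catalog_standin_entries()
  for (i in seq_len(nrow(cited))) {
    expect_true(any(cats$c_pos == cited$c_pos[i] &
                      cats$ref == cited$ref[i] &
                      cats$alt == cited$alt[i]))
  }
  decoys <- cats[is.na(cats$protein_label), ]
  expect_true(all(decoys$c_pos <= 700))  # outside the amplicon window
  expect_identical(classify_novelty(817, "T", "C", cats)$novelty,
                   "same_codon_different_change")
  expect_identical(make_catalog_standins(10, seed = 9),
                   make_catalog_standins(10, seed = 9))
})

test_that("ortholog fixtures plant exactly the requested differences", {
  ref <- default_reference()
  aln <- make_ortholog_fixture(ref, distant = integer(0))
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  human <- m["Homo sapiens", ]
  rhesus <- m["Macaca mulatta", ]
  expect_equal(which(human != rhesus) + 267L, c(269, 271, 278, 300, 303))
  expect_identical(m["Pan troglodytes", ], human)
  expect_error(
    make_ortholog_fixture(ref, diff_spec = list("Macaca mulatta" = 400)),
    "outside the aligned region")
  # human row is the reference translation of the region
  want <- vapply(268:305, function(r) {
    translate_codon(ref_codon(ref$model, r))
  }, "")
  expect_identical(human, want)
})

test_that("the insert screen construct rejects inserts with internal sites", {
  expect_error(ecori_construct(paste0(strrep("A", 300), "GAATTC",
                                      strrep("A", 305))),
               "internal EcoRI site")
})
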