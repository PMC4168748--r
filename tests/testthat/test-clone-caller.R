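test_that("identical and single-substitution reads align as forced", {
  ref <- default_reference()
  amp <- ref$amplicon
  a0 <- align_clone(amp$sequence, amp)
  expect_identical(a0$identity, 1)
  expect_identical(a0$n_gap_cols, 0L)
  expect_true(a0$accepted)
  expect_equal(nrow(call_snvs(a0, amp)), 0L)

  g826 <- c_to_g(ref$model, 826L)
  read <- amp$sequence
  off <- g826 - amp$g_start + 1L
  substr(read, off, off) <- "C"
  a1 <- align_clone(read, amp, clone_id = "c1")
  expect_identical(a1$n_gap_cols, 0L)
  calls <- call_snvs(a1, amp)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$g_pos, g826)
  expect_identical(calls$ref, "A")
  expect_identical(calls$alt, "C")
  expect_identical(g_to_c(ref$model, calls$g_pos), 826L)
})

test_that("primer-masked and N-bearing mismatch columns never produce calls", {
  amp <- default_reference()$amplicon
  read <- amp$sequence
  # substitution inside the upstream primer footprint (g.3080-3100)
  substr(read, 6, 6) <- setdiff(c("A", "C", "G", "T"),
                                substr(read, 6, 6))[1]
  a <- align_clone(read, amp)
  expect_equal(nrow(call_snvs(a, amp)), 0L)

  read2 <- amp$sequence
  substr(read2, 300, 300) <- "N"
  a2 <- align_clone(read2, amp)
  expect_equal(nrow(call_snvs(a2, amp)), 0L)
})

test_that("alignment scores match the brute-force affine DP oracle", {
  set.seed(41)
  cfg <- caller_config(check_orientation = FALSE, length_bounds = c(0, 10))
  for (k in 1:120) {
    m <- sample(8:30, 1)
    ref_seq <- random_seq(m)
    read <- if (k %% 3 == 0) random_seq(sample(8:30, 1)) else
      mutated_copy(ref_seq, n_sub = sample(0:3, 1), n_indel = sample(0:2, 1))
    amp <- toy_amplicon(ref_seq)
    got <- align_clone(read, amp, cfg)$score
    want <- affine_align_score(read, ref_seq)
    expect_equal(got, want, info = sprintf("read=%s ref=%s", read, ref_seq))
  }
  # an alternate scoring scheme
  cfg2 <- caller_config(match = 2, mismatch = -3, gap_open = 4,
                        gap_extend = 1, check_orientation = FALSE,
                        length_bounds = c(0, 10))
  for (k in 1:40) {
    ref_seq <- random_seq(sample(10:25, 1))
    read <- mutated_copy(ref_seq, 2, 1)
    got <- align_clone(read, toy_amplicon(ref_seq), cfg2)$score
    expect_equal(got, affine_align_score(read, ref_seq, 2, -3, 4, 1))
  }
})

test_that("calls are invariant to read orientation", {
  ref <- default_reference()
  amp <- ref$amplicon
  read <- amp$sequence
  substr(read, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, 250, 250))[1]
  fwd <- align_clone(read, amp, clone_id = "f")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  rev <- align_clone(rc, amp, clone_id = "r")
  expect_identical(rev$orientation, "reverse")
  cf <- call_snvs(fwd, amp)
  cr <- call_snvs(rev, amp)
  expect_identical(cf[c("g_pos", "ref", "alt")], cr[c("g_pos", "ref", "alt")])
})

test_that("acceptance policy handles length, identity and indel clones", {
  amp <- default_reference()$amplicon
  short <- substr(amp$sequence, 1, 200)
  a <- align_clone(short, amp)
  expect_false(a$accepted)
  expect_identical(a$reason, "length")

  noisy <- amp$sequence
  set.seed(5)
  pos <- sample(30:580, 20)
  for (p in pos) {
    substr(noisy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(noisy, p, p))[1]
  }
  a2 <- align_clone(noisy, amp)
  expect_false(a2$accepted)
  expect_identical(a2$reason, "identity")

  del <- paste0(substr(amp$sequence, 1, 300), substr(amp$sequence, 304, 611))
  a3 <- align_clone(del, amp)                       # mask_calls default
  expect_true(a3$accepted)
  expect_gt(a3$n_gap_cols, 0L)
  expect_equal(nrow(call_snvs(a3, amp)), 0L)
  a4 <- align_clone(del, amp, caller_config(indel_policy = "drop_clone"))
  expect_false(a4$accepted)
  expect_identical(a4$reason, "indel")
})

test_that("restriction digest fragment arithmetic is exact", {
  # no site
  expect_identical(digest_fragments("ACGTACGT", topology = "circular"), 8L)
  expect_identical(digest_fragments("ACGTACGT", topology = "linear"), 8L)
  # single site, linear: cut after the G at offset p
  seqlin <- paste0(strrep("A", 10), "GAATTC", strrep("C", 4))
  expect_equal(digest_fragments(seqlin, topology = "linear"), c(9L, 11L))
  # single site, circular: one cut -> one full-length fragment
  expect_equal(digest_fragments(seqlin, topology = "circular"), 20L)
  # two sites, linear: three pieces
  seq2 <- paste0("GAATTC", strrep("T", 10), "GAATTC", strrep("T", 3))
  expect_equal(digest_fragments(seq2, topology = "linear"),
               sort(c(1L, 16L, 8L)))
  # the cloning construct releases the printed band sizes
  amp <- default_reference()$amplicon
  construct <- ecori_construct(amp$sequence)
  expect_equal(nchar(construct), 4511L)
  expect_equal(digest_fragments(construct, topology = "circular"),
               c(611L, 3900L))
})

test_that("clone-set driver recovers simulated truth and reports QC", {
  ref <- default_reference()
  sim <- simulate_clone_set(ref, n_clones = 30, subject = "PPMS-1",
                            somatic_prob = 0.3, pcr_error_prob = 0,
                            seed = 99)
  res <- call_clone_set(sim$reads, ref, cohort = cohort_config())
  truth <- sim$truth[order(sim$truth$clone_id, sim$truth$g_pos), ]
  calls <- res$calls[order(res$calls$clone_id, res$calls$g_pos), ]
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls$g_pos, truth$g_pos)
  expect_identical(calls$alt, truth$alt)
  expect_identical(calls$clone_id, truth$clone_id)
  expect_equal(res$qc$n_reads, 30L)
  expect_equal(res$qc$accepted, 30L)

  # all-reference clone set yields zero calls
  clean <- simulate_clone_set(ref, n_clones = 10, subject = "HC-1",
                              somatic_prob = 0, pcr_error_prob = 0,
                              seed = 1)
  res0 <- call_clone_set(clean$reads, ref)
  expect_equal(nrow(res0$calls), 0L)

  # indel-bearing clone under mask_calls: no calls, still in denominator
  reads <- clean$reads[1:3]
  reads[2] <- paste0(substr(reads[2], 1, 100), substr(reads[2], 104, 611))
  res1 <- call_clone_set(reads, ref)
  expect_equal(res1$qc$accepted, 3L)
  expect_equal(nrow(res1$calls), 0L)

  # unknown subject id is a configuration error
  bad <- clean$reads[1]
  names(bad) <- "GHOST-1|clone0001"
  expect_error(call_clone_set(bad, ref, cohort = cohort_config()),
               "unknown subject")
  expect_error(call_clone_set(setNames(bad, "noseparator"), ref),
               "subject\\|clone")
})
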