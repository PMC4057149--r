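mir122 <- mirna("miR-122", "UGGAGUGUGACAAUGGUGUUUG")

test_that("seed patterns are reverse complements of the stated positions", {
  pats <- seed_target_patterns(mir122)
  expect_equal(pats[["6mer"]], "CACUCC")
  expect_equal(pats[["7mer-m8"]], "ACACUCC")
  expect_equal(pats[["7mer-A1"]], "CACUCCA")
  expect_equal(pats[["8mer"]], "ACACUCCA")

  # poly-A seed complements to poly-U
  m <- mirna("polyA", paste0("G", "AAAAAA", strrep("C", 15)))
  expect_equal(seed_target_patterns(m)[["6mer"]], "UUUUUU")

  expect_error(seed_target_patterns("ACGUACG"), "shorter than 8")
  expect_error(mirna("short", "ACGUACGUACG"), "shorter than 18")
})

test_that("a transcript containing the 8mer pattern yields one 8mer site", {
  sm <- scan_seed_matches(list(id = "t1", sequence = "AAACACUCCAAA"), mir122)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$site_class, "8mer")
  expect_equal(sm$t_start, 2L)
  expect_equal(sm$t_end, 10L)
})

test_that("a single planted 6mer in a clean background is found exactly once", {
  panel <- data.frame(id = mir122$id, sequence = mir122$sequence,
                      biotype = "miRNA", stringsAsFactors = FALSE)
  pl <- data.frame(mirna_id = "miR-122", site_class = "6mer", position = 100)
  fx <- make_transcript_with_planted_sites(plant_spec(500, pl, rng_seed = 9),
                                           panel)
  sm <- scan_seed_matches(fx$record, mir122)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$t_start, 100L)
  expect_equal(sm$site_class, "6mer")

  # brute-force all-offsets oracle agrees
  orc <- oracle_scan(fx$record$sequence, mir122$sequence)
  expect_equal(site_key(sm), site_key(orc))
})

test_that("no pattern occurrence means no sites", {
  # rejection-sampled background with zero plants
  panel <- make_mirna_panel(4, rng_seed = 3)
  fx <- make_transcript_with_planted_sites(
    plant_spec(400, data.frame(mirna_id = character(),
                               site_class = character(),
                               position = integer()), rng_seed = 5),
    panel)
  sites <- predict_all(fx$record, panel, mismatch_mode = "all")
  expect_equal(nrow(sites), 0L)
})

test_that("mismatch sites require the perfect 13-18 compensatory block", {
  panel <- make_mirna_panel(1, rng_seed = 21)
  m <- mirna(panel$id[1], panel$sequence[1])
  pl <- data.frame(mirna_id = panel$id[1],
                   site_class = "mismatch-compensatory", position = 60)
  fx <- make_transcript_with_planted_sites(plant_spec(160, pl, rng_seed = 8),
                                           panel)
  hit <- find_target_sites(fx$record, m, allow_mismatch = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$site_class, "mismatch-compensatory")
  expect_equal(hit$t_start, fx$truth$t_start)
  expect_equal(hit$n_seed_mismatches, 1L)

  # scrambling the block region removes the site
  seq2 <- fx$record$sequence
  block_rc <- revcomp_rna(m$three_prime_block)
  broken <- sub(block_rc, strrep("A", 6), seq2, fixed = TRUE)
  expect_false(identical(broken, seq2))
  hit2 <- find_target_sites(list(id = "t", sequence = broken), m,
                            allow_mismatch = TRUE)
  expect_equal(sum(hit2$site_class == "mismatch-compensatory"), 0L)

  # without the mismatch search the site is not reported at all
  hit3 <- find_target_sites(fx$record, m, allow_mismatch = FALSE)
  expect_equal(nrow(hit3), 0L)
})

test_that("alignment of a perfect duplex scores every position Watson-Crick", {
  rc <- revcomp_rna(mir122$sequence)
  tseq <- paste0("GGGG", rc, "GGGG")
  sm <- scan_seed_matches(list(id = "t", sequence = tseq), mir122)
  res <- align_window(tseq, sm[1, ], mir122)
  p <- alignment_params()
  expect_equal(res$score, 22 * p$match_score)
  expect_true(all(res$paired_positions == "wc"))
})

test_that("anchored seed columns alone give the seed score", {
  # miRNA whose 3' half is poly-A cannot pair an all-A/C upstream window,
  # so only the six anchored seed columns contribute
  m <- mirna("artificial", paste0("U", "GGGGGG", "G", strrep("A", 14)))
  tseq <- paste0(strrep("A", 20), "CCCCCC", "U")
  sm <- scan_seed_matches(list(id = "t", sequence = tseq), m)
  expect_equal(sm$site_class, "6mer")
  res <- align_window(tseq, sm[1, ], m)
  expect_equal(res$score, 6 * alignment_params()$match_score)
})

test_that("extending Watson-Crick pairing in the 3' window is monotone", {
  set.seed(33)
  for (rep in 1:5) {
    # miRNA whose 3' half uses only {A,C}: an all-A upstream window can pair
    # nothing (no U/G partner, no wobble), so overwriting it with the true
    # complement strictly extends pairing without disturbing anything else
    tail14 <- paste(sample(c("A", "C"), 14, replace = TRUE), collapse = "")
    m <- mirna("m", paste0("U", "GGGGGG", "G", tail14))
    rc3 <- revcomp_rna(substr(m$sequence, 8, 22))   # 15 nt, ends at the seed
    base <- paste0(strrep("A", 19), "CCCCCC", "U")
    prev_score <- -Inf
    for (k in 0:15) {
      tchars <- strsplit(base, "")[[1]]
      if (k > 0) {
        tchars[(19 - k + 1):19] <- strsplit(substr(rc3, 16 - k, 15), "")[[1]]
      }
      tseq <- paste(tchars, collapse = "")
      sm_k <- scan_seed_matches(list(id = "t", sequence = tseq), m)
      row <- sm_k[sm_k$core_start == 19 & sm_k$n_seed_mismatches == 0L, ]
      expect_equal(nrow(row), 1L)
      score <- align_window(tseq, row[1, ], m)$score
      expect_gte(score, prev_score)
      # every extension step adds exactly one Watson-Crick column
      expect_equal(score, 30 + 5 * k)
      prev_score <- score
    }
  }
})

test_that("finder equals the naive all-offsets oracle on random inputs", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:25) {
    tlen <- sample(200:800, 1)
    tseq <- random_rna_str(tlen)
    mseq <- random_mirna_seq()
    m <- mirna(paste0("m", i), mseq)
    got <- find_target_sites(list(id = "t", sequence = tseq), m,
                             allow_mismatch = TRUE)
    orc <- oracle_scan(tseq, mseq, allow_mismatch = TRUE)
    expect_equal(site_key(got), site_key(orc), info = paste("case", i))
    n_checked <- n_checked + nrow(orc)
  }
  expect_gt(n_checked, 0L)  # the sweep must have exercised real sites
})

test_that("class dominance: collapsed loci report only the most specific class", {
  pats <- seed_target_patterns(mir122)
  # one locus per class, separated by non-pairing spacers; the 8mer locus
  # contains the 6mer/7mer patterns but must be reported once, as 8mer only
  tseq <- paste0("GGG", pats[["8mer"]], "GGG", pats[["7mer-m8"]], "GGG",
                 pats[["7mer-A1"]], "GGG", pats[["6mer"]], "GGG")
  sm <- scan_seed_matches(list(id = "t", sequence = tseq), mir122)
  expect_equal(nrow(sm), 4L)
  expect_equal(sm$site_class, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  expect_equal(anyDuplicated(sm$core_start), 0L)
  # no reported 6mer overlaps the 8mer locus
  eight <- sm[sm$site_class == "8mer", ]
  six <- sm[sm$site_class == "6mer", ]
  expect_true(six$t_start >= eight$t_end | six$t_end <= eight$t_start)
})

test_that("predict_all is deterministic and respects the cross product", {
  panel <- make_mirna_panel(3, rng_seed = 12)
  pl1 <- data.frame(mirna_id = panel$id[1], site_class = "8mer", position = 40)
  pl2 <- data.frame(mirna_id = panel$id[2], site_class = "7mer-m8", position = 90)
  fx1 <- make_transcript_with_planted_sites(plant_spec(200, pl1, rng_seed = 1),
                                            panel, id = "tx1")
  fx2 <- make_transcript_with_planted_sites(plant_spec(200, pl2, rng_seed = 2),
                                            panel, id = "tx2")
  transcripts <- rbind(fx1$record, fx2$record)
  s1 <- predict_all(transcripts, panel)
  s2 <- predict_all(transcripts, panel)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2L)
  expect_equal(s1$site_class, c("8mer", "7mer-m8"))

  expect_equal(nrow(predict_all(transcripts, panel[0, ])), 0L)
})
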