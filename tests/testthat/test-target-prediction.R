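MIRNA <- "GGCUGGACUGAAUCGGAUCCA"  # 21 nt

test_that("a perfect reverse-complement site scores 0 and cleaves", {
  w <- facing_window(MIRNA)
  sc <- score_site(MIRNA, w)
  expect_equal(sc$expectation, 0)
  expect_equal(classify_mode(sc), "cleavage")
})

test_that("hand-scored alignments match the scoring table exactly", {
  cases <- list(
    # G:U wobble at position 1 (outside the 2-13 seed): 0.5
    list(subs = list(list(pos = 1, base = "T")), exp = 0.5),
    # same wobble inside the seed (position 5): doubled to 1.0
    list(subs = list(list(pos = 5, base = "T")), exp = 1.0),
    # mismatch at position 10 (seed): 2.0
    list(subs = list(list(pos = 10, base = "A")), exp = 2.0),
    # mismatch at 14 (1.0) plus wobble at 1 (0.5)
    list(subs = list(list(pos = 14, base = "C"), list(pos = 1, base = "T")),
         exp = 1.5),
    # two seed mismatches (2.0 each): rejected by the 3.0 threshold
    list(subs = list(list(pos = 6, base = "A"), list(pos = 11, base = "C")),
         exp = 4.0))
  for (cs in cases) {
    sc <- score_site(MIRNA, facing_window(MIRNA, cs$subs))
    expect_equal(sc$expectation, cs$exp)
  }
})

test_that("adding a mismatch never decreases the expectation", {
  w0 <- facing_window(MIRNA)
  e0 <- score_site(MIRNA, w0)$expectation
  for (pos in c(1, 5, 9, 13, 17, 21)) {
    w1 <- facing_window(MIRNA, list(list(pos = pos, base = "A")))
    e1 <- score_site(MIRNA, w1)$expectation
    expect_gte(e1, e0)
    # and a second mismatch on top of the first
    for (pos2 in c(3, 15)) {
      if (pos2 == pos) next
      w2 <- facing_window(MIRNA, list(list(pos = pos, base = "A"),
                                      list(pos = pos2, base = "A")))
      expect_gte(score_site(MIRNA, w2)$expectation, e1)
    }
  }
})

test_that("central mismatches call translational inhibition", {
  mm_base <- c("9" = "C", "10" = "A", "11" = "C")  # true mismatches
  for (pos in 9:11) {
    sc <- score_site(MIRNA, facing_window(
      MIRNA, list(list(pos = pos, base = mm_base[[as.character(pos)]]))))
    expect_equal(classify_mode(sc), "translational_inhibition")
  }
  sc14 <- score_site(MIRNA, facing_window(
    MIRNA, list(list(pos = 14, base = "C"))))
  expect_equal(classify_mode(sc14), "cleavage")
  # a central wobble still pairs: cleavage
  scw <- score_site(MIRNA, facing_window(
    MIRNA, list(list(pos = 10, base = "T"))))  # G10 faces U
  expect_equal(classify_mode(scw), "cleavage")
})

test_that("single-gap alignments are penalized and positioned", {
  w <- facing_window(MIRNA)
  # extra target base outside the seed region
  w_ins <- paste0(substr(w, 1, 2), "A", substr(w, 3, nchar(w)))
  sc <- score_site(MIRNA, w_ins)
  expect_equal(sc$expectation, 2.0)   # one gap, weight 1 outside seed
  # deleted target base facing the seed: gap penalty doubled
  w_del <- paste0(substr(w, 1, 11), substr(w, 13, nchar(w)))
  sc2 <- score_site(MIRNA, w_del)
  expect_lte(sc2$expectation, 4.0)
  expect_gte(sc2$expectation, 2.0)
})

test_that("transcript scanning finds exactly the planted site", {
  withr::with_seed(21, {
    tx <- random_ctx <- paste(sample(c("A", "C", "G", "T"), 500,
                                     replace = TRUE), collapse = "")
  })
  site <- facing_window(MIRNA)
  tx_planted <- paste0(substr(tx, 1, 200), site, substr(tx, 201, 500))
  sites <- scan_transcripts(c(mir = MIRNA), c(tx1 = tx_planted),
                            target_params(use_upe = FALSE))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 201)
  expect_equal(sites$end, 200 + nchar(site))
  expect_equal(sites$expectation, 0)
  expect_equal(sites$mode, "cleavage")
  # a random 21-mer against the random transcript: no hits at 3.0
  withr::with_seed(33, {
    rnd <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                 collapse = "")
  })
  none <- scan_transcripts(c(r = rnd), c(tx1 = tx),
                           target_params(use_upe = FALSE))
  expect_equal(nrow(none), 0)
})

test_that("overlapping candidate windows collapse to the best site", {
  # two perfect sites side by side plus a tandem overlap-inducing repeat
  site <- facing_window(MIRNA)
  tx <- paste0(strrep("C", 30), site, strrep("C", 30), site, strrep("C", 30))
  sites <- scan_transcripts(c(mir = MIRNA), c(tx1 = tx),
                            target_params(use_upe = FALSE))
  expect_equal(nrow(sites), 2)
  expect_true(all(sites$expectation == 0))
})

test_that("UPE reflects site accessibility and degenerate flanks", {
  site <- "GGATCCGATTCAGTCCAGCC"
  # site buried in a hairpin stem vs the same site in poly-A context
  buried <- paste0(site, "TTTTT", rc_oracle(site), strrep("A", 10))
  open <- paste0(site, strrep("A", 35))
  upe_buried <- compute_upe(buried, 1, nchar(site))
  upe_open <- compute_upe(open, 1, nchar(site))
  expect_gt(upe_buried, upe_open)
  # zero-length flanks equal the site-only opening energy
  u0 <- compute_upe(buried, 1, nchar(site), flank_up = 0, flank_down = 0)
  expect_equal(u0, unpairing_energy(site, 1, nchar(site)))
})

test_that("every reported site satisfies the thresholds", {
  site <- facing_window(MIRNA)
  near <- facing_window(MIRNA, list(list(pos = 6, base = "A"),
                                    list(pos = 10, base = "A")))  # 4.0
  tx <- paste0(strrep("A", 20), site, strrep("A", 20), near, strrep("A", 20))
  sites <- scan_transcripts(c(mir = MIRNA), c(tx1 = tx),
                            target_params(use_upe = FALSE))
  expect_true(all(sites$expectation <= 3.0))
  expect_equal(nrow(sites), 1)
})
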