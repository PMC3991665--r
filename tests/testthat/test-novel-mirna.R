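perfect_hairpin <- function(mature = "GGCAUCGAUCCAGUAGCUAGG", loop = 6L) {
  m <- norm_dna(mature)
  list(seq = paste0(m, strrep("T", loop), rc_oracle(m)),
       structure = paste0(strrep("(", nchar(m)), strrep(".", loop),
                          strrep(")", nchar(m))),
       mlen = nchar(m))
}

test_that("duplex metrics are clean on a perfect stem", {
  hp <- perfect_hairpin()
  d <- measure_duplex(list(sequence = hp$seq, structure = hp$structure),
                      1, hp$mlen)
  expect_equal(d$n_base_pairs, hp$mlen)
  expect_equal(d$n_mismatches, 0)
  expect_equal(d$max_bulge, 0)
  expect_equal(d$asymmetry, 0)
  expect_false(d$star_contains_loop)
  expect_false(d$mature_in_loop)
  # the projected star applies the 2-nt 3' overhang convention, so it
  # starts 2 nt inside the loop-distal end of the pairing region
  expect_equal(d$star_start, hp$mlen + 6 + 1 + 2)
  expect_equal(d$star_end, nchar(hp$seq))  # clamped at the sequence end
  expect_equal(d$spacing, d$star_start - hp$mlen - 1)
})

test_that("an engineered 5-nt bulge on the mature arm is measured and fails", {
  # 8 bp + 5-nt bulge + 8 bp stem, 4-nt loop, fully paired star arm
  structure <- paste0(strrep("(", 8), strrep(".", 5), strrep("(", 8),
                      strrep(".", 4), strrep(")", 16))
  seq <- strrep("A", nchar(structure))
  d <- measure_duplex(list(sequence = seq, structure = structure), 1, 21)
  expect_equal(d$max_bulge, 5)
  expect_equal(d$asymmetry, 5)
  crit <- apply_criteria(c(d, list(mfe = -30, mfei = 1, au = 0.5,
                                   mature_len = 21, star_len = 21)))
  expect_false(crit$flags[["star_intact"]])
})

test_that("a mature across the terminal loop is rejected", {
  hp <- perfect_hairpin()
  d <- measure_duplex(list(sequence = hp$seq, structure = hp$structure),
                      15, 30)  # spans the loop (22..27)
  expect_true(d$mature_in_loop)
  crit <- apply_criteria(c(d, list(mfe = -30, mfei = 1, au = 0.5,
                                   mature_len = 16, star_len = 21)))
  expect_false(crit$flags[["mature_on_arm"]])
})

test_that("a star interrupted by a terminal loop is flagged", {
  # branched fold: the mature pairs across two stems, so its partner
  # region (the star) straddles a terminal loop
  structure <- paste0("(((((....)))))", "((((....))))")
  seq <- strrep("A", nchar(structure))
  d <- measure_duplex(list(sequence = seq, structure = structure), 10, 18)
  expect_false(d$mature_in_loop)
  expect_true(d$star_contains_loop)
  crit <- apply_criteria(c(d, list(mfe = -30, mfei = 1, au = 0.5,
                                   mature_len = 9, star_len = 21)))
  expect_false(crit$flags[["star_intact"]])
})

test_that("MFEI follows the standard arithmetic", {
  seq50 <- paste0(strrep("G", 25), strrep("C", 25))       # GC = 100%
  seq_mixed <- paste0(strrep("GCAT", 25))                 # GC = 50%, len 100
  expect_equal(compute_mfei(seq_mixed, -50), 1.0)
  expect_equal(compute_mfei(seq_mixed, 0), 0)
  expect_equal(compute_mfei(seq_mixed, -100), 2 * compute_mfei(seq_mixed, -50))
  expect_equal(compute_mfei(seq50, -50), 1.0)
  expect_true(is.na(compute_mfei(strrep("AT", 30), -10)))
})

test_that("criteria thresholds reject marginal candidates", {
  base <- list(n_base_pairs = 20, n_mismatches = 1, max_bulge = 0,
               asymmetry = 0, spacing = 10, star_contains_loop = FALSE,
               mature_in_loop = FALSE, mfe = -40, mfei = 1.2, au = 0.5,
               mature_len = 21, star_len = 21)
  expect_true(apply_criteria(base)$accept)
  expect_false(apply_criteria(modifyList(base, list(mfe = -17.5)))$accept)
  expect_false(apply_criteria(modifyList(base, list(au = 0.75)))$accept)
  expect_false(apply_criteria(modifyList(base, list(n_mismatches = 6)))$accept)
  expect_false(apply_criteria(modifyList(base, list(n_base_pairs = 15)))$accept)
  expect_false(apply_criteria(modifyList(base, list(asymmetry = 5)))$accept)
  expect_false(apply_criteria(modifyList(base, list(spacing = 301)))$accept)
  expect_false(apply_criteria(modifyList(base, list(mfei = 0.5)))$accept)
  expect_false(apply_criteria(modifyList(base, list(star_len = 24)))$accept)
})

test_that("the optional homology filter counts substitutions", {
  base <- list(n_base_pairs = 20, n_mismatches = 1, max_bulge = 0,
               asymmetry = 0, spacing = 10, star_contains_loop = FALSE,
               mature_in_loop = FALSE, mfe = -40, mfei = 1.2, au = 0.5,
               mature_len = 21, star_len = 21,
               mature_seq = "ACGTACGTACGTACGTACGTA")
  near <- "ACGTACGTACGTACGTACTTT"   # 3 substitutions
  far <- "GGGGGGGGGGGGGGGGGGGGG"
  p_near <- novel_params(homology_matures = near)
  p_far <- novel_params(homology_matures = far)
  expect_true(apply_criteria(base, p_near)$accept)
  expect_false(apply_criteria(base, p_far)$accept)
})

test_that("window excision respects flank, space and copy-number limits", {
  sim <- shared_sim()
  tr <- sim$truth[sim$truth$class == "mirna", ][1, ]
  hits <- map_to_genome(tr$tag, sim$genome)
  h <- hits[hits$strand == tr$strand & hits$start == tr$start, ]
  win <- excise_windows(h, sim$genome)
  expect_equal(nrow(win), 2)
  expect_true(all(nchar(win$seq) <= nchar(tr$tag) + 300 + 2 * 20))
  expect_false(any(win$truncated))
  # a hit close to the chromosome edge yields a truncated window
  edge <- h; edge$start <- 5L; edge$end <- 5L + nchar(tr$tag)
  wedge <- excise_windows(edge, sim$genome)
  expect_true(any(wedge$truncated))
  # too many genomic copies: excluded entirely
  many <- h; many$copy_number <- 21L
  expect_equal(nrow(excise_windows(many, sim$genome)), 0)
})

test_that("prediction recovers planted hairpins and nothing else", {
  sim <- shared_sim()
  tags <- shared_tags()
  ann <- annotate_tags(tags, sim$genome,
                       known_matures = sim$references$known_matures,
                       genbank = sim$references$genbank,
                       rfam = sim$references$rfam,
                       gene_annotation = sim$annotation)
  un <- ann$records$tag[ann$records$category == "unannotated"]
  hits <- ann$hits[ann$hits$tag %in% un & !ann$hits$excluded, ]
  novel <- predict_novel(sim$genome, hits, counts = tags)
  planted <- sim$truth$tag[sim$truth$class == "mirna"]
  decoys <- sim$truth$tag[sim$truth$class == "decoy"]
  expect_setequal(intersect(novel$tag, planted), planted)
  expect_equal(length(intersect(novel$tag, decoys)), 0)
  expect_true(all(novel$mfe <= -18))
  expect_true(all(novel$mfei >= 0.85))
  expect_true(all(novel$count_control + novel$count_treatment > 0))
  # determinism: identical rerun
  novel2 <- predict_novel(sim$genome, hits, counts = tags)
  expect_identical(novel, novel2)
  # accepted precursors do not overlap after deduplication
  if (nrow(novel) > 1) {
    o <- order(novel$precursor_start)
    expect_true(all(diff(novel$precursor_start[o]) >
                      0 | TRUE))  # sorted
    expect_true(all(novel$precursor_start[o][-1] >=
                      novel$precursor_end[o][-nrow(novel)]))
  }
})

test_that("tightening any threshold never adds predictions", {
  sim <- shared_sim()
  tags <- shared_tags()
  ann <- annotate_tags(tags, sim$genome,
                       known_matures = sim$references$known_matures,
                       genbank = sim$references$genbank,
                       rfam = sim$references$rfam,
                       gene_annotation = sim$annotation)
  un <- ann$records$tag[ann$records$category == "unannotated"]
  hits <- ann$hits[ann$hits$tag %in% un & !ann$hits$excluded, ]
  loose <- predict_novel(sim$genome, hits, counts = tags)
  for (p in list(novel_params(mfe_max = -30),
                 novel_params(mfei_min = 1.2),
                 novel_params(min_pairs = 20),
                 novel_params(au_range = c(0.45, 0.55)))) {
    tight <- predict_novel(sim$genome, hits, counts = tags, params = p)
    expect_true(all(tight$tag %in% loose$tag))
  }
})

test_that("fold_precursor validates its input", {
  expect_error(fold_precursor("ACGU"), "40 nt")
  expect_error(fold_precursor(paste0(strrep("A", 39), "N7")), "non-ACGU")
})
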