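test_that("genome generation is deterministic and honours GC", {
  cfg <- simulation_config(genome_length = 100000L, gc_fraction = 0.5,
                           seed = 3L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  # binomial: GC count ~ Bin(1e5, 0.5), 0.48-0.52 is +/- 12.6 sd
  expect_gt(gc_fraction(g1$genome[["chr1"]]), 0.48)
  expect_lt(gc_fraction(g1$genome[["chr1"]]), 0.52)
})

test_that("no miRNA slots are reserved when none are requested", {
  cfg <- simulation_config(n_planted_mirnas = 0L, seed = 5L)
  g <- generate_genome(cfg)
  expect_false("mirna" %in% g$slots$class)
  sim <- build_simulation(cfg)
  expect_false("mirna" %in% sim$truth$class)
})

test_that("slot demand beyond genome capacity raises a sizing error", {
  cfg <- simulation_config(genome_length = 12000L, n_planted_mirnas = 30L,
                           n_decoy_tags = 30L)
  expect_error(generate_genome(cfg), "capacity")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(simulation_config(genome_length = 5000L), "10 kb")
  expect_error(simulation_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(simulation_config(
    contaminant_fractions = c(low_quality = 0.6, polyA = 0.5)), "sum below 1")
  expect_error(simulation_config(de_spec = c(mir_999 = 2)), "unplanted")
})

test_that("planted hairpins satisfy the candidate criteria (round trip)", {
  sim <- shared_sim()
  mir <- sim$truth[sim$truth$class == "mirna", ]
  prec <- sim$precursors
  expect_equal(nrow(prec), nrow(mir))
  for (i in seq_len(nrow(prec))) {
    off <- sim$config$stem_ext + 1L
    ev <- evaluate_hairpin(prec$sequence[i], off, sim$config$mature_length)
    expect_true(ev$accept, label = paste("hairpin", prec$locus_id[i]))
    expect_lt(ev$fold$mfe, 0)
    # perfect-stem construction: clean duplex
    expect_equal(ev$metrics$n_mismatches, 0)
    expect_equal(ev$metrics$max_bulge, 0)
    expect_equal(ev$metrics$asymmetry, 0)
    expect_false(ev$metrics$star_contains_loop)
  }
  # and the precursor truly sits in the genome at the recorded interval
  for (i in seq_len(nrow(prec))) {
    sub <- substr(sim$genome[["chr1"]], prec$start[i] + 1L, prec$end[i])
    expected <- if (prec$strand[i] == "+") prec$sequence[i] else
      rc_oracle(prec$sequence[i])
    expect_identical(sub, expected)
  }
})

test_that("a mismatch-saturated decoy fails the duplex mismatch criterion", {
  sim <- shared_sim()
  mature <- sim$truth$tag[sim$truth$class == "mirna"][1]
  # star arm replaced by the mature itself: no complementarity at all
  bad <- paste0(mature, "CAUUCGAAUC", mature)
  ev <- evaluate_hairpin(paste0(strrep("A", 15), bad, strrep("A", 15)),
                         16L, nchar(mature))
  expect_false(ev$accept)
  expect_gte(ev$metrics$n_mismatches, 6)
  expect_false(ev$flags[["duplex_mismatch"]])
})

test_that("library simulation is deterministic and truth-consistent", {
  libs1 <- shared_libs()
  libs2 <- simulate_libraries(shared_sim())
  expect_identical(libs1$reads, libs2$reads)
  # truth counts equal reads emitted from planted loci
  for (lib in c("control", "treatment")) {
    lab <- table(libs1$reads[[lib]]$label)
    tr <- libs1$truth
    cnt <- tr[[paste0("count_", lib)]]
    for (i in seq_len(nrow(tr))) {
      emitted <- if (tr$locus_id[i] %in% names(lab))
        as.integer(lab[[tr$locus_id[i]]]) else 0L
      expect_equal(unname(cnt[i]), emitted, label = tr$locus_id[i])
    }
  }
})

test_that("a planted fold change is realized within sampling error", {
  cfg <- small_config(de_spec = c(mir_001 = 4), error_rate = 0, seed = 77L)
  libs <- simulate_libraries(build_simulation(cfg))
  row <- libs$truth[libs$truth$locus_id == "mir_001", ]
  x <- row$count_control; y <- row$count_treatment
  # Poisson sampling: log ratio sd = sqrt(1/x + 1/y)
  se <- sqrt(1 / x + 1 / y)
  expect_lt(abs(log(y / x) - log(4)), 4 * se)
})

test_that("a null fold change keeps the libraries balanced", {
  libs <- shared_libs()
  tr <- libs$truth[libs$truth$class == "mirna", ]
  for (i in seq_len(nrow(tr))) {
    x <- tr$count_control[i]; y <- tr$count_treatment[i]
    se <- sqrt(1 / max(x, 1) + 1 / max(y, 1))
    expect_lt(abs(log(max(y, 1) / max(x, 1))), 5 * se)
  }
})

test_that("zero contaminant fractions give reads that all survive cleaning", {
  cfg <- small_config(contaminant_fractions = setNames(
    rep(0, 6), mirseed:::CONTAMINANT_CLASSES), error_rate = 0, seed = 9L)
  libs <- simulate_libraries(build_simulation(cfg))
  cl <- clean_reads(libs$reads$control, cfg$adapter_5p, cfg$adapter_3p)
  expect_true(all(cl$fates == "clean"))
  expect_true(all(cl$report$removed == 0))
})

test_that("plant_hairpin rejects out-of-range matures", {
  g <- c(chr1 = strrep("A", 2000))
  expect_error(plant_hairpin(g, strrep("ACG", 10), at = 100), "\\[18, 25\\]")
})

test_that("written simulation files round-trip", {
  dir <- withr::local_tempdir()
  libs <- shared_libs()
  paths <- write_simulation(shared_sim(), libs, dir)
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(unname(g["chr1"]), unname(shared_sim()$genome[["chr1"]]))
  fq <- read_fastq(file.path(dir, "reads_control.fastq"))
  expect_equal(nrow(fq), nrow(libs$reads$control))
  expect_identical(fq$seq, libs$reads$control$seq)
})
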