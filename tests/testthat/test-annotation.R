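test_that("planted tags map back to their truth intervals", {
  sim <- shared_sim()
  tr <- sim$truth
  hits <- map_to_genome(tr$tag, sim$genome)
  for (i in seq_len(nrow(tr))) {
    h <- hits[hits$tag == tr$tag[i] & hits$start == tr$start[i], ]
    expect_equal(nrow(h), 1, label = tr$locus_id[i])
    expect_equal(h$strand, tr$strand[i], label = tr$locus_id[i])
    expect_equal(h$end, tr$end[i])
  }
})

test_that("every reported hit substring equals the tag (strand-aware)", {
  sim <- shared_sim()
  hits <- map_to_genome(sim$truth$tag, sim$genome)
  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(hits))) {
    sub <- substr(g, hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") sub <- rc_oracle(sub)
    expect_identical(sub, hits$tag[i])
  }
})

test_that("a scrambled tag has zero hits and empty genomes are rejected", {
  sim <- shared_sim()
  hits <- map_to_genome("GTCAGTCAGGCAATCCGGATCCA", sim$genome)
  expect_equal(nrow(hits), 0)
  expect_error(map_to_genome("ACGTACGTACGTACGTACGT", character(0)), "empty")
})

test_that("high-copy tags are flagged for exclusion", {
  tag <- "ACGTTGCAACGGATCCATGCA"
  genome <- c(chr1 = paste0(paste(rep(c(tag, strrep("T", 30)), 25),
                                  collapse = ""), strrep("C", 100)))
  hits <- map_to_genome(tag, genome, max_copies = 20)
  expect_equal(unique(hits$copy_number), 25)
  expect_true(all(hits$excluded))
})

test_that("known miRNA assignment requires a perfect match", {
  ref <- c(kmir1 = "UGGAGCUCCCUUCAUUCCAAU")
  hit <- match_known_mirnas("TGGAGCTCCCTTCATTCCAAT", ref)  # U/T normalized
  expect_true(hit$known_miRNA)
  expect_equal(hit$family, "kmir1")
  near <- match_known_mirnas("TGGAGCTCCCTTCATTCCAAA", ref)  # one mismatch
  expect_false(near$known_miRNA)
  # exact substring of a precursor also qualifies
  prec <- c(pre1 = paste0("AAGGA", "TGCACTGGATCCGATGCACACC", "TTGGA"))
  sub <- match_known_mirnas("TGCACTGGATCCGATGCACACC", character(0), prec)
  expect_true(sub$known_miRNA)
  expect_error(match_known_mirnas("ACGT", c(a = "A", a = "C")), "duplicate")
})

test_that("ncRNA, exon and intron classification recover the planted classes", {
  sim <- shared_sim()
  tr <- sim$truth
  hits <- map_to_genome(tr$tag, sim$genome)
  cats <- classify_other(tr$tag, hits,
                         genbank = sim$references$genbank,
                         rfam = sim$references$rfam,
                         gene_annotation = sim$annotation,
                         genome_lengths = nchar(sim$genome))
  expect_true(all(cats$rRNA_etc_genbank[tr$class %in% c("rRNA", "tRNA")]))
  expect_true(all(cats$rRNA_etc_rfam[tr$class %in% c("snoRNA", "snRNA")]))
  expect_true(all(cats$exon[tr$class == "exon"]))
  expect_true(all(cats$intron[tr$class == "intron"]))
  # intergenic hairpin matures match nothing
  mir <- tr$class == "mirna"
  expect_false(any(cats$rRNA_etc_genbank[mir] | cats$rRNA_etc_rfam[mir] |
                     cats$exon[mir] | cats$intron[mir]))
  expect_error(
    classify_other(tr$tag, hits,
                   gene_annotation = data.frame(chrom = "chr1", start = 0,
                                                end = 1e7, strand = "+",
                                                type = "exon"),
                   genome_lengths = nchar(sim$genome)),
    "outside genome")
})

test_that("siRNA duplex detection requires the 2-nt 3' overhang geometry", {
  base <- strrep("C", 60)
  mk_genome <- function(offset) {
    locus <- "ATTGACGGATCCAGTTGCAGGA"  # 22 nt plus-strand tag
    g <- paste0(base, locus, base)
    plus <- locus
    s_plus <- nchar(base)            # 0-based start of the plus tag
    minus_iv <- c(s_plus - offset, s_plus - offset + 22)
    minus <- rc_oracle(substr(g, minus_iv[1] + 1, minus_iv[2]))
    list(genome = c(chr1 = g), tags = c(plus, minus))
  }
  ok <- mk_genome(2)
  pairs <- identify_sirna_candidates(map_to_genome(ok$tags, ok$genome))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$start_minus, pairs$start_plus - 2)

  off3 <- mk_genome(3)
  expect_equal(nrow(identify_sirna_candidates(
    map_to_genome(off3$tags, off3$genome))), 0)

  # 21-nt tags never form a candidate pair
  short <- mk_genome(2)
  short$tags <- substr(short$tags, 1, 21)
  expect_equal(nrow(identify_sirna_candidates(
    map_to_genome(short$tags, short$genome))), 0)
})

test_that("priority resolution picks the highest-priority category", {
  df <- data.frame(tag = c("t1", "t2", "t3"),
                   rRNA_etc_genbank = c(TRUE, FALSE, FALSE),
                   known_miRNA = c(TRUE, FALSE, FALSE),
                   exon = c(FALSE, TRUE, FALSE),
                   intron = c(FALSE, TRUE, FALSE))
  res <- resolve_priority(df)
  expect_equal(as.character(res$category),
               c("rRNA_etc_genbank", "exon", "unannotated"))
  # permutation invariance: column order is irrelevant
  res2 <- resolve_priority(df[, c("tag", "intron", "exon", "known_miRNA",
                                  "rRNA_etc_genbank")])
  expect_equal(res2$category, res$category)
})

test_that("annotation recovers every planted class through the full stack", {
  sim <- shared_sim()
  tags <- shared_tags()
  ann <- annotate_tags(tags, sim$genome,
                       known_matures = sim$references$known_matures,
                       genbank = sim$references$genbank,
                       rfam = sim$references$rfam,
                       gene_annotation = sim$annotation)
  rec <- ann$records
  tr <- shared_libs()$truth
  cat_of <- setNames(as.character(rec$category), rec$tag)
  expected <- c(known_mirna = "known_miRNA", rRNA = "rRNA_etc_genbank",
                tRNA = "rRNA_etc_genbank", snoRNA = "rRNA_etc_rfam",
                snRNA = "rRNA_etc_rfam", exon = "exon", intron = "intron",
                mirna = "unannotated", decoy = "unannotated")
  for (i in seq_len(nrow(tr))) {
    if (tr$count_control[i] + tr$count_treatment[i] == 0) next
    expect_equal(unname(cat_of[[tr$tag[i]]]),
                 unname(expected[[tr$class[i]]]),
                 label = tr$locus_id[i])
  }
  # category partition covers all tags exactly once
  expect_equal(sum(ann$summary$unique_tags), nrow(tags))
  expect_equal(sum(ann$summary$total_reads),
               sum(tags$count_control + tags$count_treatment))
})
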