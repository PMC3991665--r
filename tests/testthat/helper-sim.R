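# Shared small simulated experiment, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 42L, ...) {
  simulation_config(read_depth = 4000L, n_planted_mirnas = 4L,
                    n_known_mirnas = 3L, n_decoy_loci = 2L, n_genes = 2L,
                    n_decoy_tags = 4L, seed = seed, ...)
}

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- build_simulation(small_config())
  .sim_cache$sim
}

shared_libs <- function() {
  if (is.null(.sim_cache$libs)) .sim_cache$libs <- simulate_libraries(shared_sim())
  .sim_cache$libs
}

shared_clean <- function() {
  if (is.null(.sim_cache$clean)) {
    cfg <- shared_sim()$config
    libs <- shared_libs()
    .sim_cache$clean <- lapply(libs$reads, clean_reads,
                               adapter5 = cfg$adapter_5p,
                               adapter3 = cfg$adapter_3p)
  }
  .sim_cache$clean
}

shared_tags <- function() {
  if (is.null(.sim_cache$tags)) {
    cl <- shared_clean()
    .sim_cache$tags <- collapse_unique(cl$control$inserts$seq,
                                       cl$treatment$inserts$seq)
  }
  .sim_cache$tags
}

# reverse complement without Biostrings, for oracle checks
rc_oracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Build a target window facing a miRNA: start from the perfect reverse
# complement, then substitute the target base facing selected miRNA
# positions. This is an independent construction used to hand-score sites.
facing_window <- function(mirna, subs = list()) {
  comp <- c(A = "T", C = "G", G = "C", U = "A", T = "A")
  m <- strsplit(norm_rna(mirna), "")[[1]]
  facing <- unname(comp[m])      # facing[i] pairs miRNA position i
  for (s in subs) facing[s$pos] <- s$base
  paste(rev(facing), collapse = "")
}
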