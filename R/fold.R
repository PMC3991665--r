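# Thermodynamic folding engine interface.
#
# All secondary-structure prediction goes through this narrow contract
# (sequence in, dot-bracket + MFE out) so the engine is swappable. The
# default engine is ViennaRNA's RNAfold executable.

#' Is the folding engine available?
#'
#' @return TRUE if the `RNAfold` executable is on the PATH.
#' @export
folding_engine_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

require_folding_engine <- function() {
  if (!folding_engine_available()) {
    stopf(paste(
      "RNAfold (ViennaRNA) was not found on the PATH;",
      "secondary-structure prediction is unavailable."
    ))
  }
}

#' Predict minimum-free-energy secondary structures
#'
#' Folds one or more sequences with the thermodynamic engine (RNAfold) and
#' returns the MFE dot-bracket structure and free energy for each. Folding
#' is deterministic: the same sequence always yields the same structure and
#' energy. T is treated as U.
#'
#' @param seqs character vector of nucleotide sequences (A/C/G/T/U).
#' @param constraints optional character vector (same length as `seqs`) of
#'   hard structure constraints in RNAfold syntax; `x` forces a position to
#'   stay unpaired, `.` leaves it unconstrained.
#' @return data.frame with columns `sequence`, `structure`, `mfe`
#'   (kcal/mol).
#' @export
rna_fold <- function(seqs, constraints = NULL) {
  require_folding_engine()
  seqs <- as.character(seqs)
  if (length(seqs) == 0) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  bad <- grepl("[^ACGUTacgut]", seqs)
  if (any(bad)) {
    stopf("rna_fold: sequence %d contains non-ACGU characters", which(bad)[1])
  }
  rna <- norm_rna(seqs)
  ids <- sprintf("s%06d", seq_along(rna))
  if (is.null(constraints)) {
    input <- as.vector(rbind(paste0(">", ids), rna))
    args <- c("--noPS")
  } else {
    stopifnot(length(constraints) == length(seqs))
    if (any(nchar(constraints) != nchar(seqs))) {
      stopf("rna_fold: constraint length must equal sequence length")
    }
    input <- as.vector(rbind(paste0(">", ids), rna, constraints))
    args <- c("--noPS", "-C")
  }
  out <- system2("RNAfold", args, input = input, stdout = TRUE, stderr = FALSE)
  parse_rnafold_output(out, rna)
}

parse_rnafold_output <- function(lines, rna) {
  hdr <- grep("^>", lines)
  if (length(hdr) != length(rna)) {
    stopf("rna_fold: engine returned %d records for %d sequences",
          length(hdr), length(rna))
  }
  structure <- character(length(rna))
  mfe <- numeric(length(rna))
  for (i in seq_along(hdr)) {
    sl <- lines[hdr[i] + 2L]
    m <- regmatches(sl, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", sl))[[1]]
    if (length(m) != 3) stopf("rna_fold: unparseable engine output: '%s'", sl)
    structure[i] <- m[2]
    mfe[i] <- as.numeric(m[3])
    if (nchar(structure[i]) != nchar(rna[i])) {
      stopf("rna_fold: structure length mismatch for record %d", i)
    }
  }
  data.frame(sequence = rna, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Base-pairing table of a dot-bracket structure
#'
#' @param structure a single dot-bracket string.
#' @return integer vector `pt` with `pt[i]` the partner of position `i`, or
#'   0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stopf("pair_table: unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stopf("pair_table: unbalanced brackets")
  pt
}

# Terminal (hairpin) loops: pairs (i, j) with no paired position strictly
# inside. Returns a matrix with columns start, end of each loop interval.
hairpin_loops <- function(pt) {
  loops <- NULL
  n <- length(pt)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) {
      inside <- if (j - i > 1) pt[(i + 1):(j - 1)] else integer(0)
      if (all(inside == 0)) loops <- rbind(loops, c(i + 1L, j - 1L))
    }
  }
  if (is.null(loops)) loops <- matrix(integer(0), ncol = 2)
  colnames(loops) <- c("start", "end")
  loops
}

#' Energy to open (unpair) a subsequence
#'
#' Computes the unpairing energy of `[site_start, site_end]` within `seq`
#' as the free-energy difference between the MFE fold with the site forced
#' single-stranded and the unconstrained MFE fold. Non-negative by
#' construction; large values mean the site is buried in stable structure.
#'
#' @param seq a single nucleotide sequence (the local context to fold).
#' @param site_start,site_end 1-based inclusive site coordinates in `seq`.
#' @return opening energy in kcal/mol.
#' @export
unpairing_energy <- function(seq, site_start, site_end) {
  n <- nchar(seq)
  stopifnot(site_start >= 1, site_end <= n, site_start <= site_end)
  con <- strrep(".", n)
  substr(con, site_start, site_end) <- strrep("x", site_end - site_start + 1)
  free <- rna_fold(seq)$mfe
  open <- rna_fold(seq, constraints = con)$mfe
  max(open - free, 0)
}
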