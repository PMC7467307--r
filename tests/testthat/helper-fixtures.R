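# Shared fixtures and independent oracles.

# Deterministic random DNA (independent of package internals).
fixture_dna <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

fixture_reference <- function(seqs) {
  Biostrings::DNAStringSet(seqs)
}

# Brute-force oracle for arm occurrence counting: scans every offset of
# every sequence on both strands; positions hit by both strands (palindromic
# arms) count once.
naive_arm_count <- function(arm, seqs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  total <- 0L
  for (s in as.character(seqs)) {
    L <- nchar(arm)
    n <- nchar(s)
    if (n < L) next
    for (i in seq_len(n - L + 1L)) {
      sub <- substr(s, i, i + L - 1L)
      if (sub == arm || sub == rc) total <- total + 1L
    }
  }
  total
}

# Closed-form minimal window count.
min_windows <- function(L, gmax = 230, v = 20) {
  if (L <= gmax) 1L else as.integer(ceiling((L - v) / (gmax - v)))
}

# A small standard design fixture: 3 genes x 3 exons (memoised per seed).
.fixture_cache <- new.env(parent = emptyenv())
design_fixture <- function(seed = 7) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ref <- make_reference(n_genes = 3, exons_per_gene = 3,
                        exon_len_range = c(120L, 300L), seed = seed)
  targets <- pad_and_merge_targets(ref$targets, pad = 20, reference = ref$reference)
  panel <- suppressWarnings(design_panel(ref$reference, targets))
  fx <- list(reference = ref$reference, raw_targets = ref$targets,
             targets = targets, panel = panel)
  .fixture_cache[[key]] <- fx
  fx
}

# Build an error-free read pair for a probe, from first principles.
manual_read_pair <- function(probe, reference, umi = "ACGTA", read_len = 150L,
                             gap_seq = NULL) {
  if (is.null(gap_seq)) {
    gap_seq <- as.character(Biostrings::subseq(
      reference[[probe$chrom]], probe$gap_start + 1L, probe$gap_end))
  }
  r1 <- paste0(umi, probe$ext_seq,
               substr(gap_seq, 1L, read_len - nchar(umi) - nchar(probe$ext_seq)))
  sfx_len <- read_len - nchar(probe$lig_seq)
  Lg <- nchar(gap_seq)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0(substr(gap_seq, Lg - sfx_len + 1L, Lg), probe$lig_seq))))
  list(read1 = r1, read2 = r2)
}

# Substitute one base at a 1-based offset of a string.
sub_base <- function(s, at, base) {
  paste0(substr(s, 1, at - 1L), base, substr(s, at + 1L, nchar(s)))
}

# Distinct 5-mer UMIs.
umi_pool <- function(n) {
  stopifnot(n <= 1024)
  grid <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T"), b4 = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  paste0("A", grid$b1, grid$b2, grid$b3, grid$b4)[seq_len(n)]
}

# A coverage_profile built directly from a depth vector (for threshold ops).
manual_profile <- function(depths, chrom = "chr1") {
  targets <- data.frame(chrom = chrom, start = 0L, end = length(depths),
                        gene = "G", exon = "e", stringsAsFactors = FALSE)
  structure(list(depth = stats::setNames(list(S4Vectors::Rle(as.integer(depths))), chrom),
                 per_probe = data.frame(probe_id = character(0),
                                        n_families = integer(0)),
                 per_target = targets, targets = targets),
            class = "coverage_profile")
}
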