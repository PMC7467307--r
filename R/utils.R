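#' @importFrom data.table data.table as.data.table setDT setkey := .N .SD rbindlist fwrite fread setorder setnames setattr melt
#' @import Biostrings
#' @import IRanges
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom S4Vectors Rle DataFrame mcols runValue queryHits subjectHits
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom stats rpois rgeom rbinom runif setNames
NULL

# Percentages throughout are reported to one decimal, half-up (so 94.15 -> 94.2),
# matching the usual presentation of panel QC tables.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- vapply(gregexpr("[GCgc]", x), function(m) sum(m > 0L), integer(1))
  gc / n
}

# Extract [start0, end0) (0-based half-open) from a named DNAStringSet.
ref_subseq <- function(reference, chrom, start0, end0) {
  if (!chrom %in% names(reference)) {
    stop("sequence '", chrom, "' not present in reference", call. = FALSE)
  }
  len <- Biostrings::width(reference[chrom])
  if (start0 < 0L || end0 > len) {
    stop("interval [", start0, ",", end0, ") out of bounds for '", chrom,
         "' (length ", len, ")", call. = FALSE)
  }
  as.character(Biostrings::subseq(reference[[chrom]], start0 + 1L, end0))
}

# 0-based half-open intervals -> IRanges (1-based closed).
as_iranges0 <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# Run `expr` under a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n_bases, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n_bases, replace = TRUE, prob = p), collapse = "")
}

# Longest common prefix/suffix lengths between two strings; "N" matches anything.
lcp_len <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  ok <- ca[seq_len(n)] == cb[seq_len(n)] | ca[seq_len(n)] == "N" | cb[seq_len(n)] == "N"
  mis <- which(!ok)
  if (length(mis) == 0L) n else mis[1L] - 1L
}

lcs_len <- function(a, b) {
  ca <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  ok <- ca[seq_len(n)] == cb[seq_len(n)] | ca[seq_len(n)] == "N" | cb[seq_len(n)] == "N"
  mis <- which(!ok)
  if (length(mis) == 0L) n else mis[1L] - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
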