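#' Normalize a variant to left-aligned, parsimonious form
#'
#' Applies the standard normalization: shared trailing bases are trimmed
#' (extending to the left along the reference when an allele empties, which
#' left-aligns indels in repeat tracts), then shared leading bases are
#' trimmed down to the single anchor base. SNVs are returned unchanged.
#'
#' @param reference named `DNAStringSet`.
#' @param chrom sequence name.
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt allele strings (VCF convention).
#' @return list with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(reference, chrom, pos, ref, alt) {
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L, ref != alt)
  base_at <- function(p) ref_subseq(reference, chrom, p - 1L, p)
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 1L && na >= 1L &&
        substr(ref, nr, nr) == substr(alt, na, na) && (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (!nzchar(ref) || !nzchar(alt)) {
        pos <- pos - 1L
        b <- base_at(pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
      changed <- TRUE
    }
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 2L && na >= 2L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nr)
      alt <- substr(alt, 2L, na)
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

# Classify a family fragment against the reference gap fill. Returns NULL
# for uninformative fragments, otherwise a list with the L-length aligned
# string ("-" marks deleted positions, inserted bases removed) and an
# optional indel allele (normalized).
align_fragment <- function(frag, refseq, reference, chrom, gs0, max_indel = 3L) {
  L <- nchar(refseq)
  Lf <- nchar(frag)
  if (Lf == L) return(list(aligned = frag, indel = NULL))
  if (abs(Lf - L) > max_indel) return(NULL)
  p <- lcp_len(frag, refseq)
  s <- lcs_len(frag, refseq)
  if (p + s < min(L, Lf)) return(NULL)  # not a clean single indel
  if (Lf < L) {  # deletion of d bases
    d <- L - Lf
    q0 <- max(0L, Lf - s)
    q0 <- min(q0, p)
    if (q0 >= 1L) {
      pos1 <- gs0 + q0
      refA <- ref_subseq(reference, chrom, gs0 + q0 - 1L, gs0 + q0 + d)
    } else {
      pos1 <- gs0  # anchor on the base preceding the gap fill
      refA <- ref_subseq(reference, chrom, gs0 - 1L, gs0 + d)
    }
    altA <- substr(refA, 1L, 1L)
    aligned <- paste0(substr(frag, 1L, q0), strrep("-", d),
                      substr(frag, q0 + 1L, Lf))
  } else {       # insertion of k bases
    k <- Lf - L
    q0 <- max(0L, L - s)
    q0 <- min(q0, p)
    ins <- substr(frag, q0 + 1L, q0 + k)
    if (grepl("N", ins)) return(list(aligned = NULL, indel = NULL))
    if (q0 >= 1L) {
      pos1 <- gs0 + q0
      refA <- ref_subseq(reference, chrom, gs0 + q0 - 1L, gs0 + q0)
    } else {
      pos1 <- gs0
      refA <- ref_subseq(reference, chrom, gs0 - 1L, gs0)
    }
    altA <- paste0(refA, ins)
    aligned <- paste0(substr(frag, 1L, q0), substr(frag, q0 + k + 1L, Lf))
  }
  nv <- normalize_variant(reference, chrom, pos1, refA, altA)
  list(aligned = aligned,
       indel = data.frame(chrom = chrom, pos = nv$pos, ref = nv$ref,
                          alt = nv$alt, stringsAsFactors = FALSE))
}

#' Call variants from one sample's UMI families
#'
#' Builds a unique-molecule pileup from the family consensus fragments
#' (bases from probes overlapping the same position are pooled), calls
#' substitutions from per-position base counts and short indels (up to 3
#' bp) by exact alternate-fragment matching within the gap fill, and
#' applies the depth and allele-fraction filters. Consensus `N` bases are
#' excluded from depth. A site is reported when any non-reference allele
#' reaches the minimum alternate fraction; sub-threshold alleles at such
#' sites are emitted flagged `LOW_VAF`, and all calls at sites below the
#' depth minimum are flagged `LOW_DEPTH`. The alternate fraction also sets
#' zygosity: at or above the het/hom boundary is homozygous, below it
#' heterozygous.
#'
#' @param families a [dedup()] result for one sample.
#' @param panel a `mip_panel` data.frame.
#' @param reference named `DNAStringSet`.
#' @param config a [filter_config()].
#' @param sample_id sample label.
#' @return data.frame with `sample_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `depth`, `alt_count`, `alt_fraction`, `zygosity`, `filter`
#'   (comma-joined flags or `"PASS"`).
#' @export
call_sample <- function(families, panel, reference, config = filter_config(),
                        sample_id = "S1") {
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      alt_fraction = numeric(0), zygosity = character(0),
                      filter = character(0), stringsAsFactors = FALSE)
  if (is.null(families) || nrow(families) == 0L) return(empty)
  counts <- list()
  indels <- list()
  for (pidx in seq_len(nrow(panel))) {
    pr <- panel[pidx, ]
    fams <- families[families$probe_id == pr$probe_id, , drop = FALSE]
    if (nrow(fams) == 0L) next
    gs0 <- pr$gap_start
    L <- pr$gap_end - pr$gap_start
    refseq <- ref_subseq(reference, pr$chrom, gs0, pr$gap_end)
    aligned <- character(0)
    for (f in seq_len(nrow(fams))) {
      al <- align_fragment(fams$frag[f], refseq, reference, pr$chrom, gs0)
      if (is.null(al)) next
      if (!is.null(al$aligned)) aligned <- c(aligned, al$aligned)
      if (!is.null(al$indel)) indels[[length(indels) + 1L]] <- al$indel
    }
    if (!length(aligned)) next
    m <- matrix(unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
                nrow = L)
    base_counts <- vapply(c("A", "C", "G", "T"),
                          function(b) as.integer(rowSums(m == b)),
                          integer(L))
    counts[[length(counts) + 1L]] <- data.table::data.table(
      chrom = pr$chrom, pos = gs0 + seq_len(L),
      A = base_counts[, "A"], C = base_counts[, "C"],
      G = base_counts[, "G"], T = base_counts[, "T"])
  }
  if (!length(counts)) return(empty)
  pile <- data.table::rbindlist(counts)[
    , lapply(.SD, sum), by = c("chrom", "pos"),
    .SDcols = c("A", "C", "G", "T")]
  pile[, depth := A + C + G + T]
  # reference base per position
  pile[, ref := {
    ch <- strsplit(ref_subseq(reference, chrom[1], min(pos) - 1L, max(pos)),
                   "", fixed = TRUE)[[1]]
    ch[pos - min(pos) + 1L]
  }, by = "chrom"]

  # substitution candidate alleles
  long <- data.table::melt(pile, id.vars = c("chrom", "pos", "depth", "ref"),
                           measure.vars = c("A", "C", "G", "T"),
                           variable.name = "alt", value.name = "alt_count",
                           variable.factor = FALSE)
  cand <- long[alt != ref & alt_count > 0L]
  cand[, alt := as.character(alt)]

  # indel candidate alleles (depth taken at the anchor position)
  if (length(indels)) {
    idt <- data.table::rbindlist(indels)
    idt <- idt[, list(alt_count = .N), by = c("chrom", "pos", "ref", "alt")]
    idt[, depth := pile$depth[match(paste(chrom, pos), paste(pile$chrom, pile$pos))]]
    idt[is.na(depth) | depth < alt_count, depth := alt_count]
    cand <- rbind(cand[, c("chrom", "pos", "ref", "alt", "depth", "alt_count")],
                  idt[, c("chrom", "pos", "ref", "alt", "depth", "alt_count")])
  } else {
    cand <- cand[, c("chrom", "pos", "ref", "alt", "depth", "alt_count")]
  }
  if (nrow(cand) == 0L) return(empty)
  cand[, alt_fraction := alt_count / depth]
  cand[, site_max := max(alt_fraction), by = c("chrom", "pos")]
  cand <- cand[site_max >= config$min_alt_fraction]
  if (nrow(cand) == 0L) return(empty)
  cand[, site_max := NULL]
  cand[, zygosity := ifelse(alt_fraction >= config$het_hom_boundary, "hom", "het")]
  flags <- mapply(function(d, f) {
    fl <- character(0)
    if (d < config$min_depth) fl <- c(fl, "LOW_DEPTH")
    if (f < config$min_alt_fraction) fl <- c(fl, "LOW_VAF")
    if (length(fl)) paste(fl, collapse = ",") else "PASS"
  }, cand$depth, cand$alt_fraction)
  cand[, filter := flags]
  res <- as.data.frame(cand)
  res <- cbind(sample_id = sample_id, res, stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag cohort-level systematic artifacts
#'
#' A unique variant (`chrom`, `pos`, `ref`, `alt`) observed in strictly
#' more than `max_cohort_fraction` of the cohort's samples receives the
#' `COHORT_ARTIFACT` flag in every sample. The operation is
#' permutation-invariant in the sample order.
#'
#' @param calls combined call table over the cohort ([call_sample()] rows).
#' @param n_samples number of samples in the cohort (must be at least the
#'   number of distinct `sample_id`s in `calls`).
#' @param config a [filter_config()].
#' @return `calls` with updated `filter`.
#' @export
cohort_filter <- function(calls, n_samples, config = filter_config()) {
  stopifnot(n_samples >= 1L)
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  n_carriers <- vapply(split(calls$sample_id, key),
                       function(x) length(unique(x)), integer(1))
  flagged_keys <- names(n_carriers)[n_carriers > config$max_cohort_fraction * n_samples]
  hit <- key %in% flagged_keys
  calls$filter[hit] <- ifelse(calls$filter[hit] == "PASS", "COHORT_ARTIFACT",
                              paste0(calls$filter[hit], ",COHORT_ARTIFACT"))
  calls
}

#' Write calls as VCF
#'
#' Emits a VCF 4.2 file for one sample: filters in the FILTER column
#' (comma-joined flags become semicolon-separated), genotype, unique-molecule
#' depth, alternate-molecule count and alternate fraction in the FORMAT
#' fields (GT, DP, AD, VF). Input is sorted internally; indels are expected
#' in the normalized (left-aligned, parsimonious) representation that
#' [call_sample()] produces.
#'
#' @param calls a [call_sample()] result (single sample).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(calls, path) {
  sid <- unique(calls$sample_id)
  if (length(sid) > 1L) stop("write_vcf expects calls of a single sample", call. = FALSE)
  if (length(sid) == 0L) sid <- "SAMPLE"
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  n <- nrow(calls)
  vr <- VariantAnnotation::VRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos, width = nchar(calls$ref)),
    ref = calls$ref, alt = calls$alt,
    totalDepth = as.integer(calls$depth),
    altDepth = as.integer(calls$alt_count),
    sampleNames = rep(sid, n))
  v <- VariantAnnotation::asVCF(vr)
  hdr <- VariantAnnotation::header(v)
  m <- VariantAnnotation::meta(hdr)
  m$fileformat <- S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  VariantAnnotation::meta(hdr) <- m
  VariantAnnotation::fixed(hdr)$FILTER <- S4Vectors::DataFrame(
    Description = c("All filters passed",
                    "Unique-molecule depth below the minimum",
                    "Supporting-molecule fraction below the minimum",
                    "Present in more than the allowed fraction of cohort samples"),
    row.names = c("PASS", "LOW_DEPTH", "LOW_VAF", "COHORT_ARTIFACT"))
  geno_hdr <- VariantAnnotation::geno(hdr)
  geno_hdr <- rbind(geno_hdr, S4Vectors::DataFrame(
    Number = c("1", "1"), Type = c("String", "Float"),
    Description = c("Genotype", "Alternate-allele molecule fraction"),
    row.names = c("GT", "VF")))
  VariantAnnotation::geno(hdr) <- geno_hdr
  VariantAnnotation::header(v) <- hdr
  VariantAnnotation::fixed(v)$FILTER <- gsub(",", ";", calls$filter)
  VariantAnnotation::geno(v)$GT <- matrix(
    ifelse(calls$zygosity == "hom", "1/1", "0/1"), ncol = 1,
    dimnames = list(NULL, sid))
  VariantAnnotation::geno(v)$VF <- matrix(
    round(calls$alt_fraction, 4), ncol = 1, dimnames = list(NULL, sid))
  VariantAnnotation::writeVcf(v, path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a call table
#'
#' @param path VCF path.
#' @return data.frame in [call_sample()] layout.
#' @export
read_vcf_calls <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  sid <- colnames(v)[1] %||% "SAMPLE"
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], character(1))
  ad <- VariantAnnotation::geno(v)$AD
  alt_count <- if (length(dim(ad)) == 3L) {
    as.integer(ad[, 1, dim(ad)[3]])
  } else {
    vapply(seq_len(nrow(v)), function(i) {
      x <- ad[i, 1][[1]]
      as.integer(x[length(x)])
    }, integer(1))
  }
  gt <- as.character(VariantAnnotation::geno(v)$GT[, 1])
  data.frame(
    sample_id = sid,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    depth = as.integer(VariantAnnotation::geno(v)$DP[, 1]),
    alt_count = alt_count,
    alt_fraction = as.numeric(VariantAnnotation::geno(v)$VF[, 1]),
    zygosity = ifelse(gt == "1/1", "hom", "het"),
    filter = gsub(";", ",", as.character(rr$FILTER)),
    stringsAsFactors = FALSE)
}

#' Write / read a call table as TSV
#'
#' Plain-text exchange format for cohort-merged call sets.
#'
#' @param calls a call table.
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character", chrom = "character",
                                   ref = "character", alt = "character"))
}
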