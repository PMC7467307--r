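#' Load target regions from a BED file
#'
#' Reads a 4+ column BED file of exon targets, pads every record
#' symmetrically (by default the 20 bp of flanking intron sequence captured
#' alongside each exon), and merges overlapping or bookended padded records
#' on the same sequence. The BED name column is interpreted as
#' `gene|exon`; merged regions keep the comma-joined unique gene and exon
#' labels of their constituents.
#'
#' Coordinates are BED convention throughout: 0-based, half-open.
#'
#' @param bed_path path to a BED file (tab-separated, at least 4 columns).
#' @param pad non-negative padding in bp applied to both sides of each record.
#' @param reference optional named `DNAStringSet`; when supplied, regions are
#'   checked against sequence bounds (padding is clipped at position 0 and at
#'   the sequence end).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `gene`,
#'   `exon` (class `mip_targets`).
#' @export
load_targets <- function(bed_path, pad = 20L, reference = NULL) {
  stopifnot(file.exists(bed_path), pad >= 0L)
  lines <- readLines(bed_path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  recs <- which(keep)
  if (length(recs) == 0L) stop("no BED records in ", bed_path, call. = FALSE)
  fields <- strsplit(lines[recs], "\t", fixed = TRUE)
  parse_rec <- function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("malformed BED line ", recs[i], ": fewer than 3 fields", call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
      stop("malformed BED line ", recs[i], ": bad interval [", f[2], ",", f[3], ")",
           call. = FALSE)
    }
    name <- if (length(f) >= 4L) f[4] else paste0("region", i)
    parts <- strsplit(name, "|", fixed = TRUE)[[1]]
    data.frame(chrom = f[1], start = start, end = end,
               gene = parts[1],
               exon = if (length(parts) >= 2L) parts[2] else name,
               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(seq_along(recs), parse_rec))
  pad_and_merge_targets(df, pad = pad, reference = reference)
}

#' Pad and merge target records
#'
#' In-memory counterpart of [load_targets()]: applies a symmetric pad and
#' merges overlapping or bookended padded records per sequence.
#'
#' @param df data.frame with `chrom`, `start`, `end`, `gene`, `exon`
#'   (0-based half-open).
#' @inheritParams load_targets
#' @return A `mip_targets` data.frame.
#' @export
pad_and_merge_targets <- function(df, pad = 20L, reference = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$gene)) df$gene <- paste0("region", seq_len(nrow(df)))
  if (is.null(df$exon)) df$exon <- df$gene
  df$start <- pmax(0L, as.integer(df$start) - as.integer(pad))
  df$end <- as.integer(df$end) + as.integer(pad)
  if (!is.null(reference)) {
    lens <- stats::setNames(Biostrings::width(reference), names(reference))
    bad <- !(df$chrom %in% names(lens))
    if (any(bad)) {
      stop("target sequence(s) absent from reference: ",
           paste(unique(df$chrom[bad]), collapse = ", "), call. = FALSE)
    }
    over <- df$end > lens[df$chrom]
    df$end[over] <- as.integer(lens[df$chrom[over]])
  }
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- as_iranges0(d$start, d$end)
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    data.frame(
      chrom = d$chrom[1],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      gene = vapply(seq_along(red), function(i)
        paste(unique(d$gene[grp == i]), collapse = ","), character(1)),
      exon = vapply(seq_along(red), function(i)
        paste(unique(d$exon[grp == i]), collapse = ","), character(1)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  class(res) <- c("mip_targets", "data.frame")
  res
}

#' Write target regions as BED
#'
#' @param targets a `mip_targets` data.frame.
#' @param path output path.
#' @export
write_targets_bed <- function(targets, path) {
  bed <- data.frame(targets$chrom, targets$start, targets$end,
                    paste(targets$gene, targets$exon, sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a common-SNP table
#'
#' Accepts either a VCF (allele frequency taken from the `AF` INFO field) or
#' a tab-separated table with columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `maf`. Used by the probe designer to avoid placing targeting arms
#' over common polymorphisms.
#'
#' @param path path to a `.vcf` file or a TSV.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `maf`.
#' @export
read_snp_table <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    af <- VariantAnnotation::info(v)$AF
    if (is.null(af)) stop("VCF has no AF INFO field: ", path, call. = FALSE)
    af <- vapply(af, function(x) as.numeric(x)[1], numeric(1))
    alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], character(1))
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = alt,
      maf = af,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "maf")
    if (!all(need %in% names(df))) {
      stop("SNP table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df <- df[need]
  }
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  df
}
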