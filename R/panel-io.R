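PANEL_COLUMNS <- c(
  "probe_id", "gene", "exon", "chrom", "strand",
  "ext_seq", "ext_start", "ext_end",
  "lig_seq", "lig_start", "lig_end",
  "gap_start", "gap_end",
  "oligo", "oligo_len", "oligo_in_range",
  "umi_len", "dosage",
  "ext_copies", "lig_copies", "snp_in_arm", "allele_note"
)

#' Export a probe panel
#'
#' Writes the probe table as a TSV (one probe per row, documented column
#' set, intervals in 0-based half-open coordinates) and optionally a BED
#' file of the gap fills. The TSV round-trips losslessly through
#' [read_panel()]; given identical inputs and parameters the designer
#' produces a byte-identical file.
#'
#' @param panel a `mip_panel` data.frame.
#' @param probe_tsv_path output TSV path.
#' @param bed_path optional output BED path for the gap fills (name column
#'   = probe id, strand column = probe strand).
#' @return invisibly, `probe_tsv_path`.
#' @export
export_panel <- function(panel, probe_tsv_path, bed_path = NULL) {
  df <- as.data.frame(panel)[, PANEL_COLUMNS]
  tryCatch(
    utils::write.table(df, probe_tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA"),
    error = function(e) stop("cannot write panel TSV to '", probe_tsv_path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (!is.null(bed_path)) {
    bed <- data.frame(df$chrom, df$gap_start, df$gap_end, df$probe_id,
                      0L, df$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(probe_tsv_path)
}

#' Read a probe panel TSV
#'
#' Inverse of [export_panel()].
#'
#' @param probe_tsv_path path to a panel TSV.
#' @return a `mip_panel` data.frame.
#' @export
read_panel <- function(probe_tsv_path) {
  stopifnot(file.exists(probe_tsv_path))
  df <- utils::read.table(probe_tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = c(allele_note = "character"))
  missing <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing)) {
    stop("panel TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, PANEL_COLUMNS]
  int_cols <- c("ext_start", "ext_end", "lig_start", "lig_end",
                "gap_start", "gap_end", "oligo_len", "umi_len",
                "ext_copies", "lig_copies")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$dosage <- as.numeric(df$dosage)
  df$oligo_in_range <- as.logical(df$oligo_in_range)
  df$snp_in_arm <- as.logical(df$snp_in_arm)
  class(df) <- c("mip_panel", "data.frame")
  df
}
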