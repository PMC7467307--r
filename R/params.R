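#' Panel design parameters
#'
#' Bundles the geometric and exclusion constraints of the probe designer:
#' arm-length search ranges, the common linker and UMI lengths, the gap-fill
#' (capture insert) size range, the tiling overlap between adjacent probes,
#' the maximum tolerated genomic copy count of a targeting arm, and the
#' population allele-frequency threshold above which a SNP under an arm
#' disqualifies it.
#'
#' Defaults describe a 220-230 nt gap-fill design with 16-20 nt extension
#' arms, 20-24 nt ligation arms, a 30 nt linker carrying a 5 nt UMI, 20 bp
#' tiling overlap, exclusion of arms with more than 5 exact genomic copies,
#' and exclusion of arms overlapping SNPs with minor allele frequency
#' above 1%.
#'
#' @param ext_arm_len_range integer(2), extension-arm length range in nt.
#' @param lig_arm_len_range integer(2), ligation-arm length range in nt.
#' @param linker_len linker length in nt (UMI excluded).
#' @param umi_len UMI length in nt.
#' @param gap_fill_range integer(2), gap-fill length range in nt.
#' @param tile_overlap minimum overlap between consecutive gap fills, bp.
#' @param max_arm_copy_count maximum exact genomic occurrences of an arm
#'   (counting both strands) before the probe is excluded.
#' @param snp_maf_threshold arms overlapping SNPs with minor allele frequency
#'   strictly above this value are avoided or duplicated per allele.
#' @param oligo_len_range intended assembled-oligo length range; totals
#'   outside it are flagged with a warning, not rejected.
#' @return An object of class `design_params` (a validated list).
#' @export
design_params <- function(ext_arm_len_range = c(16L, 20L),
                          lig_arm_len_range = c(20L, 24L),
                          linker_len = 30L,
                          umi_len = 5L,
                          gap_fill_range = c(220L, 230L),
                          tile_overlap = 20L,
                          max_arm_copy_count = 5L,
                          snp_maf_threshold = 0.01,
                          oligo_len_range = c(77L, 80L)) {
  stopifnot(
    length(ext_arm_len_range) == 2L, ext_arm_len_range[1] <= ext_arm_len_range[2],
    length(lig_arm_len_range) == 2L, lig_arm_len_range[1] <= lig_arm_len_range[2],
    length(gap_fill_range) == 2L, gap_fill_range[1] <= gap_fill_range[2],
    gap_fill_range[1] >= 1L,
    linker_len >= 0L, umi_len >= 1L,
    tile_overlap >= 0L, tile_overlap < gap_fill_range[1],
    max_arm_copy_count >= 1L,
    snp_maf_threshold > 0, snp_maf_threshold < 1
  )
  structure(list(
    ext_arm_len_range = as.integer(ext_arm_len_range),
    lig_arm_len_range = as.integer(lig_arm_len_range),
    linker_len = as.integer(linker_len),
    umi_len = as.integer(umi_len),
    gap_fill_range = as.integer(gap_fill_range),
    tile_overlap = as.integer(tile_overlap),
    max_arm_copy_count = as.integer(max_arm_copy_count),
    snp_maf_threshold = snp_maf_threshold,
    oligo_len_range = as.integer(oligo_len_range)
  ), class = "design_params")
}

#' Capture / sequencing noise model for the read simulator
#'
#' @param mean_molecules mean number of unique captured molecules per probe
#'   per sample (Poisson rate, before dosage and GC effects).
#' @param pcr_dup_mean mean number of additional PCR copies per molecule;
#'   each molecule is emitted `1 + Geometric(pcr_dup_mean)` times.
#' @param error_rate per-base substitution error rate (applies to every read
#'   base, UMI included). Must be below 0.01.
#' @param gc_multiplier capture-efficiency multiplier applied to probes whose
#'   gap-fill GC fraction exceeds `gc_threshold`; 1 disables the effect, 0
#'   reproduces complete dropout of GC-rich targets.
#' @param gc_threshold GC fraction above which `gc_multiplier` applies.
#' @param read_len read length of each mate (2 x `read_len` sequencing).
#' @param seed RNG seed used by [simulate_reads()].
#' @return An object of class `capture_model`.
#' @export
capture_model <- function(mean_molecules = 100,
                          pcr_dup_mean = 1,
                          error_rate = 0.002,
                          gc_multiplier = 1,
                          gc_threshold = 0.5,
                          read_len = 150L,
                          seed = 1L) {
  stopifnot(
    mean_molecules > 0,
    pcr_dup_mean >= 0,
    error_rate >= 0, error_rate < 0.01,
    gc_multiplier >= 0, gc_multiplier <= 1,
    read_len >= 50L
  )
  structure(list(
    mean_molecules = mean_molecules,
    pcr_dup_mean = pcr_dup_mean,
    error_rate = error_rate,
    gc_multiplier = gc_multiplier,
    gc_threshold = gc_threshold,
    read_len = as.integer(read_len),
    seed = as.integer(seed)
  ), class = "capture_model")
}

#' Variant filter thresholds
#'
#' The three-part artifact filter applied to unique-molecule variant calls:
#' minimum unique-molecule depth (30), minimum fraction of molecules
#' supporting the alternate allele (20%), and the cohort-frequency cutoff
#' (variants present in more than 90% of batch samples are flagged as
#' systematic artifacts). The heterozygous/homozygous boundary on the
#' alternate fraction is configurable and defaults to 0.80.
#'
#' @param min_depth minimum unique-molecule depth; sites below it are
#'   flagged `LOW_DEPTH` (strict: depth < min_depth fails).
#' @param min_alt_fraction minimum supporting-molecule fraction; alleles
#'   below it are flagged `LOW_VAF`.
#' @param max_cohort_fraction variants present in strictly more than this
#'   fraction of cohort samples are flagged `COHORT_ARTIFACT`.
#' @param het_hom_boundary alternate fractions at or above this are called
#'   homozygous, below it heterozygous.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 30L,
                          min_alt_fraction = 0.20,
                          max_cohort_fraction = 0.90,
                          het_hom_boundary = 0.80) {
  stopifnot(
    min_depth >= 1L,
    min_alt_fraction > 0,
    min_alt_fraction < het_hom_boundary,
    het_hom_boundary <= 1,
    max_cohort_fraction > 0, max_cohort_fraction <= 1
  )
  structure(list(
    min_depth = as.integer(min_depth),
    min_alt_fraction = min_alt_fraction,
    max_cohort_fraction = max_cohort_fraction,
    het_hom_boundary = het_hom_boundary
  ), class = "filter_config")
}

#' Default linker sequence with UMI placeholder
#'
#' The assembled probe oligo is `extension arm + linker + ligation arm`,
#' where the linker is a fixed 30 nt sequence carrying two universal PCR
#' primer sites, plus a 5 nt degenerate UMI (`NNNNN`). The UMI placeholder
#' sits between the linker halves.
#'
#' @param umi_len number of `N` placeholder positions.
#' @return A character scalar of length 30 + `umi_len`.
#' @export
default_linker <- function(umi_len = 5L) {
  left <- "CTTCAGCTTCCCGAT"   # 15 nt universal primer site
  right <- "TACACGACGCTCTTC"  # 15 nt universal primer site
  paste0(left, strrep("N", umi_len), right)
}
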