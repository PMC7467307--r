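#' Capture efficiency
#'
#' Percentage of panel probes that produce usable sequence reads.
#'
#' @param n_working number of probes with reads.
#' @param n_total total probes in the panel.
#' @return percentage, rounded to 1 decimal (half-up).
#' @export
capture_efficiency <- function(n_working, n_total) {
  if (n_total <= 0) stop("total probe count must be positive", call. = FALSE)
  stopifnot(n_working >= 0, n_working <= n_total)
  pct(n_working, n_total)
}

#' Probe failure rate
#'
#' Percentage of panel probes with no sequence reads.
#'
#' @param n_failed number of probes without reads.
#' @param n_total total probes in the panel.
#' @return percentage, rounded to 1 decimal (half-up).
#' @export
probe_failure_rate <- function(n_failed, n_total) {
  if (n_total <= 0) stop("total probe count must be positive", call. = FALSE)
  stopifnot(n_failed >= 0, n_failed <= n_total)
  pct(n_failed, n_total)
}

variant_key <- function(df, with_sample = TRUE) {
  cols <- c(if (with_sample && "sample_id" %in% names(df)) "sample_id",
            "chrom", "pos", "ref", "alt")
  do.call(paste, c(df[cols], sep = ":"))
}

in_mask <- function(df, mask) {
  if (is.null(mask)) return(rep(TRUE, nrow(df)))
  ok <- logical(nrow(df))
  for (ch in unique(df$chrom)) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    sel <- df$chrom == ch
    if (nrow(m) == 0L) { ok[sel] <- FALSE; next }
    ir <- as_iranges0(m$start, m$end)
    pos_ir <- IRanges::IRanges(start = df$pos[sel], width = 1L)
    ok[sel] <- IRanges::overlapsAny(pos_ir, ir)
  }
  ok
}

#' Sensitivity against a truth set
#'
#' Compares a call set to a truth set of variants under identical
#' normalization. Overall sensitivity counts every truth variant;
#' covered-only sensitivity excludes truth variants whose site falls
#' outside the coverage mask. Zygosity agreement is computed over the
#' jointly detected variants; the false-positive rate is the fraction of
#' calls absent from the truth set (restricted to the mask when one is
#' given). Percentages with zero denominator are `NA` (not applicable).
#'
#' @param truth data.frame of truth variants (`chrom`, `pos`, `ref`,
#'   `alt`, optionally `sample_id` and `zygosity`).
#' @param calls data.frame of calls (same columns; typically PASS-filtered).
#' @param coverage_mask optional data.frame of covered regions (`chrom`,
#'   `start`, `end`, 0-based half-open).
#' @return list of class `concordance_result`: `n_truth`, `n_detected`,
#'   `n_missed_in_uncovered`, `sensitivity_pct`,
#'   `sensitivity_covered_only_pct`, `zygosity_agreement_pct`,
#'   `false_positive_rate_pct`.
#' @export
sensitivity <- function(truth, calls, coverage_mask = NULL) {
  n_truth <- nrow(truth)
  if (n_truth == 0L) {
    return(structure(list(n_truth = 0L, n_detected = 0L,
                          n_missed_in_uncovered = 0L,
                          sensitivity_pct = NA_real_,
                          sensitivity_covered_only_pct = NA_real_,
                          zygosity_agreement_pct = NA_real_,
                          false_positive_rate_pct = NA_real_),
                     class = "concordance_result"))
  }
  with_sample <- "sample_id" %in% names(truth) && "sample_id" %in% names(calls)
  tk <- variant_key(truth, with_sample)
  ck <- variant_key(calls, with_sample)
  detected <- tk %in% ck
  covered <- in_mask(truth, coverage_mask)
  n_detected <- sum(detected)
  n_missed_uncov <- sum(!detected & !covered)
  n_cov <- sum(covered)
  zyg <- NA_real_
  if ("zygosity" %in% names(truth) && "zygosity" %in% names(calls) &&
      n_detected > 0L) {
    tz <- truth$zygosity[detected]
    cz <- calls$zygosity[match(tk[detected], ck)]
    zyg <- pct(sum(tz == cz), n_detected)
  }
  fp <- NA_real_
  if (nrow(calls) > 0L) {
    cin <- in_mask(calls, coverage_mask)
    n_calls <- sum(cin)
    if (n_calls > 0L) fp <- pct(sum(!(ck[cin] %in% tk)), n_calls)
  }
  structure(list(
    n_truth = n_truth,
    n_detected = n_detected,
    n_missed_in_uncovered = n_missed_uncov,
    sensitivity_pct = pct(n_detected, n_truth),
    sensitivity_covered_only_pct = if (n_cov > 0L)
      pct(sum(detected & covered), n_cov) else NA_real_,
    zygosity_agreement_pct = zyg,
    false_positive_rate_pct = fp
  ), class = "concordance_result")
}

#' Cross-platform concordance of two call sets
#'
#' Counts calls (keyed by sample, position and alleles) made by both
#' platforms versus by exactly one, and reports the true-positive
#' percentage `100 * concordant / (concordant + dissimilar)`. When
#' coverage profiles are supplied, each dissimilar call is annotated with
#' its cause: `low_coverage` when the other platform's unique-molecule
#' depth at the site is below `min_depth`, otherwise `below_threshold`.
#'
#' @param calls_a,calls_b call tables filtered with the same thresholds.
#' @param profile_a,profile_b optional [coverage_profile()]s of the two
#'   platforms (single representative sample), used for cause annotation.
#' @param min_depth depth boundary for the `low_coverage` cause.
#' @return list of class `cross_comparison`: `n_concordant`,
#'   `n_dissimilar`, `true_positive_pct`, `dissimilar_pct`,
#'   `disagreements` (data.frame with `platform`, key columns, `cause`).
#' @export
cross_compare <- function(calls_a, calls_b, profile_a = NULL, profile_b = NULL,
                          min_depth = 30L) {
  ka <- variant_key(calls_a)
  kb <- variant_key(calls_b)
  n_concordant <- sum(ka %in% kb)
  only_a <- calls_a[!(ka %in% kb), , drop = FALSE]
  only_b <- calls_b[!(kb %in% ka), , drop = FALSE]
  n_dissimilar <- nrow(only_a) + nrow(only_b)
  depth_at <- function(profile, chrom, pos) {
    if (is.null(profile) || !chrom %in% names(profile$depth)) return(NA_integer_)
    d <- profile$depth[[chrom]]
    if (pos > length(d)) return(0L)
    as.integer(d[pos])
  }
  annotate <- function(df, other_profile, platform) {
    if (nrow(df) == 0L) {
      return(data.frame(platform = character(0), sample_id = character(0),
                        chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        cause = character(0), stringsAsFactors = FALSE))
    }
    cause <- vapply(seq_len(nrow(df)), function(i) {
      d <- depth_at(other_profile, df$chrom[i], df$pos[i])
      if (is.na(d)) NA_character_
      else if (d < min_depth) "low_coverage"
      else "below_threshold"
    }, character(1))
    data.frame(platform = platform,
               sample_id = if ("sample_id" %in% names(df)) df$sample_id else NA,
               chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               cause = cause, stringsAsFactors = FALSE)
  }
  disagreements <- rbind(annotate(only_a, profile_b, "A"),
                         annotate(only_b, profile_a, "B"))
  total <- n_concordant + n_dissimilar
  structure(list(
    n_concordant = n_concordant,
    n_dissimilar = n_dissimilar,
    true_positive_pct = if (total > 0L) pct(n_concordant, total) else NA_real_,
    dissimilar_pct = if (total > 0L) pct(n_dissimilar, total) else NA_real_,
    disagreements = disagreements
  ), class = "cross_comparison")
}

#' Per-gene coverage table
#'
#' Builds the per-gene performance rows (targeted bp, probe count,
#' percentage of bases above the depth threshold, probes with no reads)
#' from a panel and one or more per-sample coverage profiles (percentages
#' are averaged over samples).
#'
#' @param panel a `mip_panel` data.frame.
#' @param profiles a [coverage_profile()] or list of them.
#' @param targets a `mip_targets` data.frame.
#' @param threshold depth threshold for the coverage percentage.
#' @return data.frame with `gene`, `targeted_bp`, `n_probes`,
#'   `pct_over_threshold`, `probes_no_reads`.
#' @export
gene_coverage_table <- function(panel, profiles, targets, threshold = 30L) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  genes <- unique(unlist(strsplit(targets$gene, ",", fixed = TRUE)))
  first_gene <- function(x) strsplit(x, ",", fixed = TRUE)[[1]][1]
  rows <- lapply(genes, function(g) {
    tg <- targets[vapply(targets$gene, function(x)
      g %in% strsplit(x, ",", fixed = TRUE)[[1]], logical(1)), , drop = FALSE]
    pg <- panel[vapply(panel$gene, function(x)
      g %in% strsplit(x, ",", fixed = TRUE)[[1]], logical(1)), , drop = FALSE]
    bp <- sum(tg$end - tg$start)
    pcts <- vapply(profiles, function(pf) {
      sub <- pf
      sub$targets <- tg
      pct_covered(sub, threshold)
    }, numeric(1))
    failed <- vapply(profiles, function(pf) {
      sum(pf$per_probe$n_families[match(pg$probe_id, pf$per_probe$probe_id)] == 0L)
    }, numeric(1))
    data.frame(gene = g, targeted_bp = bp, n_probes = nrow(pg),
               pct_over_threshold = round_half_up(mean(pcts)),
               probes_no_reads = as.integer(round(mean(failed))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene report with totals row
#'
#' Appends a totals row to a per-gene table: base pairs, probe counts and
#' failed probes are summed; the coverage percentage is averaged weighted
#' by targeted bp. Totals are exact column sums.
#'
#' @param per_gene a [gene_coverage_table()]-style data.frame (columns
#'   `gene`, `targeted_bp`, `n_probes`, and optionally
#'   `pct_over_threshold`, `probes_no_reads`).
#' @return the table with a final `Total` row.
#' @export
gene_report <- function(per_gene) {
  tot <- data.frame(gene = "Total",
                    targeted_bp = sum(per_gene$targeted_bp),
                    n_probes = sum(per_gene$n_probes),
                    stringsAsFactors = FALSE)
  if ("pct_over_threshold" %in% names(per_gene)) {
    tot$pct_over_threshold <- round_half_up(
      sum(per_gene$pct_over_threshold * per_gene$targeted_bp) /
        sum(per_gene$targeted_bp))
  }
  if ("probes_no_reads" %in% names(per_gene)) {
    tot$probes_no_reads <- sum(per_gene$probes_no_reads)
  }
  rbind(per_gene[names(tot)], tot)
}

#' Bases requiring Sanger follow-up
#'
#' Totals the bases in regions flagged as uncovered or unreliable (supplied
#' as an explicit region list, or directly as a base count) and expresses
#' them as a percentage of the targeted panel.
#'
#' @param regions data.frame of flagged regions (`chrom`, `start`, `end`,
#'   0-based half-open), or a numeric base count.
#' @param targets a `mip_targets` data.frame, or a numeric total targeted
#'   base count.
#' @return list with `bp`, `total_bp`, `percentage` (1 decimal, half-up).
#' @export
sanger_followup <- function(regions, targets) {
  bp <- if (is.numeric(regions)) regions else {
    sum(IRanges::width(IRanges::reduce(as_iranges0(regions$start, regions$end))))
  }
  total_bp <- if (is.numeric(targets)) targets else sum(targets$end - targets$start)
  stopifnot(total_bp > 0)
  list(bp = as.integer(bp), total_bp = as.integer(total_bp),
       percentage = pct(bp, total_bp))
}

#' Cost-model parameters
#'
#' Per-sample cost accounting for a probe-based targeted panel: a one-off
#' probe synthesis cost (`n_probes * probe_unit_cost`) plus a fixed
#' rebalancing/optimisation/validation cost are amortised over the cohort;
#' reagents are per sample; sequencing is charged per run of up to
#' `samples_per_run` samples.
#'
#' @param probe_unit_cost cost per probe (currency units).
#' @param n_probes probes in the panel.
#' @param reagent_cost_per_sample reagent cost per sample.
#' @param fixed_setup_cost one-off panel setup cost.
#' @param sequencing_run_cost cost of one sequencing run.
#' @param samples_per_run samples multiplexed per run.
#' @return list of class `cost_params`.
#' @export
cost_params <- function(probe_unit_cost = 5.6, n_probes = 276L,
                        reagent_cost_per_sample = 1.8,
                        fixed_setup_cost = 1575,
                        sequencing_run_cost = 1073,
                        samples_per_run = 384L) {
  stopifnot(probe_unit_cost >= 0, n_probes >= 0, reagent_cost_per_sample >= 0,
            fixed_setup_cost >= 0, sequencing_run_cost >= 0,
            samples_per_run >= 1L)
  structure(list(probe_unit_cost = probe_unit_cost,
                 n_probes = as.integer(n_probes),
                 reagent_cost_per_sample = reagent_cost_per_sample,
                 fixed_setup_cost = fixed_setup_cost,
                 sequencing_run_cost = sequencing_run_cost,
                 samples_per_run = as.integer(samples_per_run)),
            class = "cost_params")
}

#' Per-sample cost
#'
#' `(n_probes * probe_unit_cost + fixed_setup_cost) / n_samples +
#' reagent_cost_per_sample +
#' sequencing_run_cost * ceiling(n_samples / samples_per_run) / n_samples`.
#' Monotone non-increasing in the cohort size between run boundaries; the
#' large-cohort limit is `reagent_cost_per_sample + sequencing_run_cost /
#' samples_per_run`.
#'
#' @param params a [cost_params()].
#' @param n_samples cohort size.
#' @return cost per sample (same currency as the parameters).
#' @export
per_sample_cost <- function(params, n_samples) {
  stopifnot(n_samples >= 1L)
  (params$n_probes * params$probe_unit_cost + params$fixed_setup_cost) / n_samples +
    params$reagent_cost_per_sample +
    params$sequencing_run_cost * ceiling(n_samples / params$samples_per_run) / n_samples
}
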