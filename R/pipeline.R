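#' Build an arm index for read-to-probe assignment
#'
#' Indexes each probe's extension arm (keyed at the read-1 offset just
#' after the UMI) and the reverse complement of its ligation arm (the
#' read-2 prefix). Duplicate arm sequences across probes are recorded as
#' ambiguous keys; lookups return all candidates and assignment falls to
#' the disambiguation rule in [assign_and_trim()].
#'
#' @param panel a `mip_panel` data.frame with unique probe ids.
#' @return an object of class `arm_index`.
#' @export
build_arm_index <- function(panel) {
  stopifnot(!anyDuplicated(panel$probe_id))
  df <- as.data.frame(panel)
  df$ext_len <- nchar(df$ext_seq)
  df$lig_len <- nchar(df$lig_seq)
  df$lig_rc <- if (nrow(df)) revcomp(df$lig_seq) else character(0)
  df$gap_len <- df$gap_end - df$gap_start
  structure(list(
    probes = df,
    ext_lens = sort(unique(df$ext_len)),
    ambiguous_ext = unique(df$ext_seq[duplicated(df$ext_seq)])
  ), class = "arm_index")
}

# Hamming distances between equal-length strings `xs` and one pattern.
hamming_to_pattern <- function(xs, pattern) {
  n <- length(xs)
  if (n == 0L) return(integer(0))
  L <- nchar(pattern)
  m <- matrix(unlist(strsplit(xs, "", fixed = TRUE), use.names = FALSE), nrow = L)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  as.integer(colSums(m != p))
}

#' Assign reads to probes and trim arms and UMIs
#'
#' The UMI is the first `umi_len` bases of read 1. A read pair is assigned
#' to a probe when the extension arm matches read 1 (immediately after the
#' UMI) and the ligation arm matches the start of read 2, each within
#' `max_mismatch` substitutions; pairs whose two arms match different
#' probes (chimeras) and pairs matching no probe are left unassigned.
#' Arm and UMI bases are removed, and the two mate fragments are merged
#' into a single gap-fill fragment by exact overlap (insert lengths within
#' 3 bp of the probe's gap fill are tried, nearest first); when no exact
#' overlap exists the expected insert length is used and disagreeing
#' overlap bases are masked to `N`. No gapped alignment is performed.
#'
#' Assignment is deterministic and order-independent: ties between probes
#' with identical arms are broken by total arm mismatch count, then by
#' panel order.
#'
#' @param read1,read2 character vectors of mate sequences.
#' @param index an [build_arm_index()] result.
#' @param max_mismatch maximum substitutions tolerated per arm.
#' @return data.table with one row per assigned pair: `read`, `probe_id`,
#'   `umi`, `frag`; unassigned count in `attr(, "n_unassigned")`.
#' @export
assign_and_trim <- function(read1, read2, index, max_mismatch = 1L) {
  probes <- index$probes
  n <- length(read1)
  stopifnot(length(read2) == n)
  if (n == 0L || nrow(probes) == 0L) {
    out <- data.table::data.table(read = integer(0), probe_id = character(0),
                                  umi = character(0), frag = character(0))
    data.table::setattr(out, "n_unassigned", n)
    return(out)
  }
  umi_len <- probes$umi_len[1]
  umi <- substr(read1, 1L, umi_len)
  assigned <- integer(n)  # probe row or 0

  # Pass 1: exact arm matches.
  cand <- list()
  for (el in index$ext_lens) {
    key <- substr(read1, umi_len + 1L, umi_len + el)
    rows <- which(probes$ext_len == el)
    hit <- match(key, probes$ext_seq[rows])
    ok <- which(!is.na(hit))
    if (!length(ok)) next
    cand[[as.character(el)]] <- data.table::data.table(
      read = ok, probe = rows[hit[ok]])
  }
  if (length(cand)) {
    cd <- data.table::rbindlist(cand)
    # ambiguous extension arms: expand to all probes sharing the arm sequence
    if (length(index$ambiguous_ext)) {
      amb <- cd[probes$ext_seq[cd$probe] %in% index$ambiguous_ext]
      if (nrow(amb)) {
        extra <- lapply(seq_len(nrow(amb)), function(i) {
          shared <- which(probes$ext_seq == probes$ext_seq[amb$probe[i]])
          data.table::data.table(read = amb$read[i], probe = shared)
        })
        cd <- unique(data.table::rbindlist(c(list(cd), extra)))
      }
    }
    lig_ok <- substr(read2[cd$read], 1L, probes$lig_len[cd$probe]) ==
      probes$lig_rc[cd$probe]
    cd <- cd[lig_ok]
    if (nrow(cd)) {
      cd <- cd[order(cd$read, cd$probe)]
      first <- !duplicated(cd$read)
      assigned[cd$read[first]] <- cd$probe[first]
    }
  }

  # Pass 2: mismatch-tolerant rescue for still-unassigned reads.
  if (max_mismatch > 0L) {
    left <- which(assigned == 0L)
    if (length(left)) {
      best_mm <- rep(Inf, length(left))
      best_probe <- integer(length(left))
      for (p in seq_len(nrow(probes))) {
        el <- probes$ext_len[p]; ll <- probes$lig_len[p]
        mm1 <- hamming_to_pattern(substr(read1[left], umi_len + 1L, umi_len + el),
                                  probes$ext_seq[p])
        mm2 <- hamming_to_pattern(substr(read2[left], 1L, ll), probes$lig_rc[p])
        ok <- mm1 <= max_mismatch & mm2 <= max_mismatch
        tot <- mm1 + mm2
        better <- ok & tot < best_mm
        best_mm[better] <- tot[better]
        best_probe[better] <- p
      }
      got <- best_probe > 0L
      assigned[left[got]] <- best_probe[got]
    }
  }

  hit <- which(assigned > 0L)
  out <- data.table::data.table(read = hit, probe = assigned[hit])
  out[, `:=`(probe_id = probes$probe_id[probe], umi = umi[hit])]

  # Trim arms and merge mates into the gap-fill fragment.
  frag <- character(nrow(out))
  for (p in unique(out$probe)) {
    sel <- which(out$probe == p)
    rl <- nchar(read1[out$read[sel][1]])
    el <- probes$ext_len[p]; ll <- probes$lig_len[p]
    L <- probes$gap_len[p]
    prefix <- substr(read1[out$read[sel]], umi_len + el + 1L, rl)
    sfx <- revcomp(substr(read2[out$read[sel]], ll + 1L, rl))
    lp <- rl - umi_len - el
    ls <- rl - ll
    merged <- rep(NA_character_, length(sel))
    remaining <- seq_along(sel)
    for (delta in c(0L, -1L, 1L, -2L, 2L, -3L, 3L)) {
      if (!length(remaining)) break
      Lp <- L + delta
      ov <- lp + ls - Lp
      if (ov < 1L || ov > min(lp, ls)) next
      match_ok <- substr(prefix[remaining], lp - ov + 1L, lp) ==
        substr(sfx[remaining], 1L, ov)
      take <- remaining[match_ok]
      if (length(take)) {
        merged[take] <- paste0(prefix[take], substr(sfx[take], ov + 1L, ls))
        remaining <- remaining[!match_ok]
      }
    }
    if (length(remaining)) {
      # No overlap is error-free at any candidate insert length (sequencing
      # errors in the overlap): take the length with the fewest overlap
      # mismatches (ties prefer the smallest length shift), masking
      # disagreeing overlap bases to N.
      deltas <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L)
      best_mm <- rep(Inf, length(remaining))
      best_delta <- rep(NA_integer_, length(remaining))
      for (delta in deltas) {
        ov <- lp + ls - (L + delta)
        if (ov < 1L || ov > min(lp, ls)) next
        a <- substr(prefix[remaining], lp - ov + 1L, lp)
        b <- substr(sfx[remaining], 1L, ov)
        am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE), nrow = ov)
        bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE), nrow = ov)
        mm <- colSums(am != bm)
        better <- mm < best_mm
        best_mm[better] <- mm[better]
        best_delta[better] <- delta
      }
      for (delta in deltas) {
        take <- remaining[!is.na(best_delta) & best_delta == delta]
        if (!length(take)) next
        ov <- lp + ls - (L + delta)
        a <- substr(prefix[take], lp - ov + 1L, lp)
        b <- substr(sfx[take], 1L, ov)
        am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE), nrow = ov)
        bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE), nrow = ov)
        am[am != bm] <- "N"
        cons <- apply(am, 2L, paste, collapse = "")
        merged[take] <- paste0(substr(prefix[take], 1L, lp - ov),
                               cons, substr(sfx[take], ov + 1L, ls))
      }
      still <- remaining[is.na(best_delta)]
      if (length(still)) merged[still] <- prefix[still]
    }
    frag[sel] <- merged
  }
  out[, frag := frag]
  out[, probe := NULL]
  res <- out[, c("read", "probe_id", "umi", "frag")]
  data.table::setattr(res, "n_unassigned", n - length(hit))
  res[]
}

#' Collapse assigned fragments into UMI families
#'
#' One family per distinct `(probe_id, UMI)`. The family consensus is the
#' strict per-position majority of non-`N` bases over the family's reads
#' (ties give `N`); reads whose merged fragment length differs from the
#' family's modal length are counted in `read_count` but excluded from the
#' consensus. UMIs are never error-corrected: families differing by one
#' UMI mismatch stay separate.
#'
#' @param assigned an [assign_and_trim()] result.
#' @return data.table with `probe_id`, `umi`, `read_count`, `frag`
#'   (consensus sequence).
#' @export
dedup <- function(assigned) {
  if (nrow(assigned) == 0L) {
    return(data.table::data.table(probe_id = character(0), umi = character(0),
                                  read_count = integer(0), frag = character(0)))
  }
  dt <- data.table::as.data.table(assigned)[, c("probe_id", "umi", "frag")]
  fam <- dt[, list(read_count = .N, n_distinct = data.table::uniqueN(frag),
                   frag = frag[1L]),
            by = c("probe_id", "umi")]
  slow <- fam[fam$n_distinct > 1L, c("probe_id", "umi")]
  if (nrow(slow)) {
    sub <- dt[slow, on = c("probe_id", "umi")]
    cons <- sub[, list(frag = consensus_strings(frag)), by = c("probe_id", "umi")]
    i.frag <- NULL  # appease R CMD check; data.table join prefix
    fam[cons, on = c("probe_id", "umi"), frag := i.frag]
  }
  fam[, n_distinct := NULL]
  data.table::setorder(fam, probe_id, umi)
  fam[]
}

# Strict-majority consensus; reads at non-modal fragment lengths (indel
# disagreements) are dropped, N never votes, ties (and all-N columns) give N.
consensus_strings <- function(xs) {
  lens <- nchar(xs)
  ul <- unique(lens)
  if (length(ul) > 1L) {
    cnt <- vapply(ul, function(l) sum(lens == l), integer(1))
    modal <- min(ul[cnt == max(cnt)])
    xs <- xs[lens == modal]
  }
  if (length(unique(xs)) == 1L) return(xs[1])
  L <- nchar(xs[1])
  m <- matrix(unlist(strsplit(xs, "", fixed = TRUE), use.names = FALSE), nrow = L)
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) rowSums(m == b), numeric(L))
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, bases))
  mx <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
  out <- bases[max.col(cnt, ties.method = "first")]
  out[mx == 0 | rowSums(cnt == mx) > 1L] <- "N"
  paste(out, collapse = "")
}

#' Unique-molecule coverage profile
#'
#' Per-base unique-molecule depth over the target regions (a family covers
#' its probe's gap fill) plus per-probe family counts and per-target mean
#' and median depth.
#'
#' @param families a [dedup()] result (one sample).
#' @param panel a `mip_panel` data.frame.
#' @param targets a `mip_targets` data.frame.
#' @return list of class `coverage_profile` with `depth` (per-chrom integer
#'   `Rle` over full chromosome coordinates), `per_probe`, `per_target`,
#'   `targets`.
#' @export
coverage_profile <- function(families, panel, targets) {
  counts <- table(factor(families$probe_id, levels = panel$probe_id))
  per_probe <- data.frame(probe_id = panel$probe_id,
                          n_families = as.integer(counts),
                          stringsAsFactors = FALSE)
  depth <- list()
  for (ch in unique(targets$chrom)) {
    p <- panel[panel$chrom == ch, , drop = FALSE]
    reps <- per_probe$n_families[match(p$probe_id, per_probe$probe_id)]
    ir <- as_iranges0(rep(p$gap_start, reps), rep(p$gap_end, reps))
    maxend <- max(targets$end[targets$chrom == ch],
                  if (nrow(p)) max(p$gap_end) else 0L)
    depth[[ch]] <- IRanges::coverage(ir, width = maxend)
  }
  per_target <- targets
  per_target$mean_depth <- NA_real_
  per_target$median_depth <- NA_real_
  for (i in seq_len(nrow(targets))) {
    d <- depth[[targets$chrom[i]]]
    v <- as.integer(IRanges::Views(d, as_iranges0(targets$start[i], targets$end[i]))[[1]])
    per_target$mean_depth[i] <- mean(v)
    per_target$median_depth[i] <- stats::median(v)
  }
  structure(list(depth = depth, per_probe = per_probe,
                 per_target = per_target, targets = targets),
            class = "coverage_profile")
}

#' Percentage of target bases above a depth threshold
#'
#' Strictly-greater comparison: a base at exactly the threshold does not
#' count (">30x" is read literally).
#'
#' @param profile a [coverage_profile()] result.
#' @param threshold unique-molecule depth threshold.
#' @return percentage in `[0, 100]` (unrounded).
#' @export
pct_covered <- function(profile, threshold = 30L) {
  tot <- 0L
  over <- 0L
  for (i in seq_len(nrow(profile$targets))) {
    t <- profile$targets[i, ]
    v <- as.integer(IRanges::Views(profile$depth[[t$chrom]],
                                   as_iranges0(t$start, t$end))[[1]])
    tot <- tot + length(v)
    over <- over + sum(v > threshold)
  }
  if (tot == 0L) return(0)
  100 * over / tot
}

#' Uncovered target regions
#'
#' Maximal disjoint intervals of target bases whose unique-molecule depth
#' is at or below a threshold (default: no coverage at all). These are the
#' regions that would need orthogonal (e.g. Sanger) follow-up.
#'
#' @param profile a [coverage_profile()] result.
#' @param threshold bases with depth less than or equal to this are reported.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
uncovered_regions <- function(profile, threshold = 0L) {
  out <- list()
  for (ch in unique(profile$targets$chrom)) {
    d <- profile$depth[[ch]]
    low <- IRanges::slice(d, upper = threshold, rangesOnly = TRUE)
    tir <- with(profile$targets[profile$targets$chrom == ch, ],
                as_iranges0(start, end))
    hit <- IRanges::intersect(low, IRanges::reduce(tir))
    if (length(hit)) {
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(hit) - 1L,
                              end = IRanges::end(hit), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify probe performance and recommend rebalancing
#'
#' From a pilot batch's per-probe unique-read counts: probes with no reads
#' are `failed` and should be replaced; probes with 1-30 reads are `poor`
#' and are boosted by adding a 5-fold concentration to the pool (the
#' original 1x stays, so the boosted dosage is 6x; with
#' `mode = "replace"` the original is replaced and the new dosage is 5x);
#' probes with more than 30 reads are `adequate`.
#'
#' @param per_probe data.frame with `probe_id` and `n_families` (or a
#'   `coverage_profile`).
#' @param panel optional panel; when given, current dosages are used as the
#'   base for the recommended new dosage.
#' @param mode `"augment"` (default) or `"replace"`: whether the 5-fold
#'   addition augments or replaces the original concentration.
#' @return data.frame with `probe_id`, `unique_reads`, `category`,
#'   `recommendation`, `new_dosage`.
#' @export
probe_performance <- function(per_probe, panel = NULL, mode = c("augment", "replace")) {
  mode <- match.arg(mode)
  if (inherits(per_probe, "coverage_profile")) per_probe <- per_probe$per_probe
  counts <- per_probe$n_families
  if (any(counts < 0L)) stop("negative probe read counts", call. = FALSE)
  category <- ifelse(counts == 0L, "failed",
                     ifelse(counts <= 30L, "poor", "adequate"))
  recommendation <- c(failed = "replace", poor = "boost_5x",
                      adequate = "none")[category]
  base <- if (!is.null(panel)) {
    panel$dosage[match(per_probe$probe_id, panel$probe_id)]
  } else rep(1, length(counts))
  factor5 <- if (mode == "augment") 6 else 5
  new_dosage <- ifelse(category == "poor", base * factor5, base)
  data.frame(probe_id = per_probe$probe_id, unique_reads = counts,
             category = category, recommendation = unname(recommendation),
             new_dosage = new_dosage, stringsAsFactors = FALSE)
}

#' Apply a rebalancing report to a panel
#'
#' @param panel a `mip_panel` data.frame.
#' @param performance a [probe_performance()] result.
#' @return the panel with updated `dosage`.
#' @export
rebalance_panel <- function(panel, performance) {
  i <- match(panel$probe_id, performance$probe_id)
  upd <- !is.na(i)
  panel$dosage[upd] <- performance$new_dosage[i[upd]]
  panel
}

#' Run the read-processing core for one sample
#'
#' Convenience wrapper: read (or accept) paired reads, assign and trim,
#' de-duplicate by UMI, and compute the coverage profile.
#'
#' @param panel a `mip_panel` data.frame.
#' @param targets a `mip_targets` data.frame.
#' @param read1,read2 character vectors of reads, or paths to FASTQ files.
#' @param max_mismatch per-arm mismatch tolerance.
#' @return list with `families`, `profile`, `n_unassigned`, `n_reads`.
#' @export
run_sample <- function(panel, targets, read1, read2, max_mismatch = 1L) {
  if (length(read1) == 1L && file.exists(read1[1])) {
    rd <- read_fastq_pair(read1, read2)
    read1 <- rd$read1; read2 <- rd$read2
  }
  index <- build_arm_index(panel)
  assigned <- assign_and_trim(read1, read2, index, max_mismatch)
  families <- dedup(assigned)
  profile <- coverage_profile(families, panel, targets)
  list(families = families, profile = profile,
       n_unassigned = attr(assigned, "n_unassigned"), n_reads = length(read1))
}
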