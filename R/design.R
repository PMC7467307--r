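#' Tile a target region with gap-fill windows
#'
#' Computes the minimal number of gap-fill windows (probe capture inserts)
#' that cover a region, with every window length inside the allowed gap-fill
#' range and consecutive windows overlapping by at least the tiling overlap.
#' Regions shorter than the minimum gap fill are covered by a single window
#' centred on the region, extending into flanking sequence.
#'
#' For a region of length `L`, maximum gap fill `g` and overlap `v`, the
#' minimal window count is `1` when `L <= g` and `ceiling((L - v)/(g - v))`
#' otherwise. Windows are spread evenly so the first starts at the region
#' start and the last ends at the region end.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`
#'   in 0-based half-open coordinates.
#' @param params a [design_params()] object.
#' @return data.frame of windows with columns `chrom`, `start`, `end`.
#' @export
tile_region <- function(region, params = design_params()) {
  start <- as.integer(region$start)
  end <- as.integer(region$end)
  stopifnot(end > start)
  L <- end - start
  gmin <- params$gap_fill_range[1]
  gmax <- params$gap_fill_range[2]
  v <- params$tile_overlap
  if (L <= gmax) {
    w <- max(gmin, L)
    left_ext <- (w - L) %/% 2L
    s <- start - left_ext
    wins <- data.frame(start = s, end = s + w)
  } else {
    n <- as.integer(ceiling((L - v) / (gmax - v)))
    w <- max(gmin, as.integer(ceiling((L + v * (n - 1L)) / n)))
    s <- start + as.integer(floor((seq_len(n) - 1L) * (L - w) / (n - 1L)))
    wins <- data.frame(start = s, end = s + w)
  }
  wins$chrom <- region$chrom
  wins[, c("chrom", "start", "end")]
}

#' Count exact genomic occurrences of a targeting arm
#'
#' Counts exact matches of an arm sequence and of its reverse complement
#' over all sequences of the reference. A palindromic arm (equal to its own
#' reverse complement) matches both strands at the same positions; those
#' positions are counted once.
#'
#' @param arm_seq arm sequence (ACGT only).
#' @param reference a named `DNAStringSet`.
#' @return integer occurrence count.
#' @export
arm_copy_count <- function(arm_seq, reference) {
  stopifnot(nchar(arm_seq) > 0L)
  if (grepl("[^ACGT]", arm_seq)) {
    stop("arm sequence contains non-ACGT symbols: ", arm_seq, call. = FALSE)
  }
  fwd <- sum(Biostrings::vcountPattern(arm_seq, reference))
  rc <- revcomp(arm_seq)
  if (rc == arm_seq) {
    as.integer(fwd)
  } else {
    as.integer(fwd + sum(Biostrings::vcountPattern(rc, reference)))
  }
}

# SNPs (1-based pos) with maf strictly above the threshold that fall inside
# [start0, end0) of chrom.
snps_in_interval <- function(snps, chrom, start0, end0, maf_threshold) {
  if (is.null(snps) || nrow(snps) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      maf = numeric(0), stringsAsFactors = FALSE))
  }
  hit <- snps$chrom == chrom &
    snps$pos - 1L >= start0 & snps$pos - 1L < end0 &
    snps$maf > maf_threshold
  snps[hit, , drop = FALSE]
}

#' Choose targeting arms for a gap-fill window
#'
#' Searches the grid of allowed extension-arm (left flank) and ligation-arm
#' (right flank) lengths for the pair that (i) passes the genomic copy-count
#' limit, (ii) avoids common SNPs where possible, and (iii) among admissible
#' pairs minimises `|GC(ext) - 0.5| + |GC(lig) - 0.5|`, with ties broken by
#' longer total arm length, then by longer extension arm. This GC-balance
#' objective is a deterministic melting-temperature proxy.
#'
#' When every admissible arm pair overlaps a common SNP, the best pair is
#' returned together with allele-specific arm sequences so the caller can
#' emit one probe matching the reference allele and one matching the
#' alternate allele.
#'
#' @param window one-row data.frame with `chrom`, `start`, `end` (the gap
#'   fill, 0-based half-open).
#' @param reference named `DNAStringSet`.
#' @param params a [design_params()] object.
#' @param snps optional SNP table from [read_snp_table()].
#' @return A list with `status` one of `"ok"`, `"allele_duplicate"`,
#'   `"rejected"`. For accepted windows: `ext`/`lig` lists carrying `seq`,
#'   `start`, `end`, plus copy counts and SNP flags; for allele duplicates
#'   additionally `ext_alt`/`lig_alt` sequences. Rejections carry the
#'   failing constraints.
#' @export
pick_arms <- function(window, reference, params = design_params(), snps = NULL) {
  chrom <- window$chrom
  gs <- as.integer(window$start)
  ge <- as.integer(window$end)
  chrom_len <- Biostrings::width(reference[chrom])
  ext_lens <- seq(params$ext_arm_len_range[1], params$ext_arm_len_range[2])
  lig_lens <- seq(params$lig_arm_len_range[1], params$lig_arm_len_range[2])

  grid <- expand.grid(el = ext_lens, ll = lig_lens)
  cand <- lapply(seq_len(nrow(grid)), function(i) {
    el <- grid$el[i]; ll <- grid$ll[i]
    es <- gs - el; ee <- gs
    ls <- ge; le <- ge + ll
    if (es < 0L || le > chrom_len) return(NULL)
    ext_seq <- ref_subseq(reference, chrom, es, ee)
    lig_seq <- ref_subseq(reference, chrom, ls, le)
    if (grepl("[^ACGT]", ext_seq) || grepl("[^ACGT]", lig_seq)) return(NULL)
    ext_cc <- arm_copy_count(ext_seq, reference)
    lig_cc <- arm_copy_count(lig_seq, reference)
    ext_snps <- snps_in_interval(snps, chrom, es, ee, params$snp_maf_threshold)
    lig_snps <- snps_in_interval(snps, chrom, ls, le, params$snp_maf_threshold)
    list(el = el, ll = ll, es = es, ee = ee, ls = ls, le = le,
         ext_seq = ext_seq, lig_seq = lig_seq,
         ext_cc = ext_cc, lig_cc = lig_cc,
         n_snps = nrow(ext_snps) + nrow(lig_snps),
         ext_snps = ext_snps, lig_snps = lig_snps,
         score = abs(gc_fraction(ext_seq) - 0.5) + abs(gc_fraction(lig_seq) - 0.5))
  })
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0L) {
    return(list(status = "rejected", reason = "no_flank_sequence",
                window = window))
  }
  copy_ok <- vapply(cand, function(x)
    x$ext_cc <= params$max_arm_copy_count && x$lig_cc <= params$max_arm_copy_count,
    logical(1))
  if (!any(copy_ok)) {
    return(list(status = "rejected", reason = "arm_copy_count",
                window = window,
                max_copies = max(vapply(cand, function(x) max(x$ext_cc, x$lig_cc),
                                        integer(1)))))
  }
  adm <- cand[copy_ok]
  snp_free <- vapply(adm, function(x) x$n_snps == 0L, logical(1))
  pick_best <- function(xs) {
    sc <- vapply(xs, `[[`, numeric(1), "score")
    tot <- vapply(xs, function(x) x$el + x$ll, integer(1))
    el <- vapply(xs, `[[`, integer(1), "el")
    xs[[order(sc, -tot, -el)[1]]]
  }
  if (any(snp_free)) {
    best <- pick_best(adm[snp_free])
    return(c(list(status = "ok"), arm_fields(best)))
  }
  # Unavoidable common SNP: build allele-specific duplicate arm sequences.
  best <- pick_best(adm)
  out <- c(list(status = "allele_duplicate"), arm_fields(best))
  out$ext_alt <- substitute_alleles(best$ext_seq, best$es, best$ext_snps)
  out$lig_alt <- substitute_alleles(best$lig_seq, best$ls, best$lig_snps)
  out
}

arm_fields <- function(x) {
  list(ext = list(seq = x$ext_seq, start = x$es, end = x$ee,
                  copy_count = x$ext_cc, n_snps = nrow(x$ext_snps)),
       lig = list(seq = x$lig_seq, start = x$ls, end = x$le,
                  copy_count = x$lig_cc, n_snps = nrow(x$lig_snps)))
}

# Substitute single-base alternate alleles of the SNPs into an arm sequence.
substitute_alleles <- function(arm_seq, arm_start0, snp_df) {
  if (nrow(snp_df) == 0L) return(arm_seq)
  chars <- strsplit(arm_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(snp_df))) {
    if (nchar(snp_df$ref[i]) == 1L && nchar(snp_df$alt[i]) == 1L) {
      off <- snp_df$pos[i] - 1L - arm_start0 + 1L
      chars[off] <- snp_df$alt[i]
    }
  }
  paste(chars, collapse = "")
}

#' Assemble a probe oligo
#'
#' Concatenates extension arm, linker (carrying the degenerate UMI
#' placeholder) and ligation arm on the probe's encoding strand. The linker
#' must contain exactly `umi_len` `N` positions. Totals outside the intended
#' oligo length range are flagged (`in_range = FALSE`) but not rejected.
#'
#' @param ext_seq extension-arm sequence.
#' @param lig_seq ligation-arm sequence.
#' @param linker_seq linker sequence including the UMI placeholder; see
#'   [default_linker()].
#' @param params a [design_params()] object.
#' @return list with `oligo`, `length`, `in_range`.
#' @export
assemble_oligo <- function(ext_seq, lig_seq, linker_seq = default_linker(),
                           params = design_params()) {
  if (!nzchar(ext_seq) || !nzchar(lig_seq)) {
    stop("empty arm sequence", call. = FALSE)
  }
  n_placeholder <- lengths(regmatches(linker_seq, gregexpr("N", linker_seq)))
  if (n_placeholder != params$umi_len) {
    stop("linker must contain exactly ", params$umi_len,
         " N placeholder positions, found ", n_placeholder, call. = FALSE)
  }
  if (nchar(linker_seq) != params$linker_len + params$umi_len) {
    stop("linker length ", nchar(linker_seq), " != linker_len + umi_len = ",
         params$linker_len + params$umi_len, call. = FALSE)
  }
  oligo <- paste0(ext_seq, linker_seq, lig_seq)
  len <- nchar(oligo)
  list(oligo = oligo, length = len,
       in_range = len >= params$oligo_len_range[1] & len <= params$oligo_len_range[2])
}

#' Design a MIP panel
#'
#' Tiles every (padded, merged) target region with gap-fill windows, picks
#' targeting arms for each window under the copy-count and common-SNP
#' exclusion rules, assembles the oligos and returns the probe table.
#' Windows for which no admissible arm pair exists are recorded as
#' uncovered; windows whose arms unavoidably overlap a common SNP yield two
#' probes, one matching each allele.
#'
#' @param reference named `DNAStringSet`.
#' @param targets a `mip_targets` data.frame from [load_targets()] /
#'   [pad_and_merge_targets()].
#' @param params a [design_params()] object.
#' @param snps optional SNP table ([read_snp_table()]).
#' @param linker_seq linker sequence, see [default_linker()].
#' @return A `mip_panel` data.frame, one row per probe, with arm and
#'   gap-fill intervals in 0-based half-open coordinates, assembled oligo,
#'   `dosage` (default 1) and `allele_note` (`"wt"`/`"alt"` for
#'   allele-specific duplicates, `NA` otherwise). Rejected windows are kept
#'   in `attr(panel, "uncovered")`.
#' @export
design_panel <- function(reference, targets, params = design_params(),
                         snps = NULL, linker_seq = default_linker(params$umi_len)) {
  probes <- list()
  uncovered <- list()
  for (t in seq_len(nrow(targets))) {
    region <- targets[t, ]
    wins <- tile_region(region, params)
    for (w in seq_len(nrow(wins))) {
      res <- pick_arms(wins[w, ], reference, params, snps)
      if (res$status == "rejected") {
        uncovered[[length(uncovered) + 1L]] <- data.frame(
          chrom = region$chrom, start = wins$start[w], end = wins$end[w],
          gene = region$gene, reason = res$reason, stringsAsFactors = FALSE)
        next
      }
      base_id <- sprintf("%s_%03d", gsub(",", "-", region$gene),
                         length(probes) + 1L)
      mk <- function(ext_seq, lig_seq, note, id) {
        ol <- assemble_oligo(ext_seq, lig_seq, linker_seq, params)
        data.frame(
          probe_id = id, gene = region$gene, exon = region$exon,
          chrom = region$chrom, strand = "+",
          ext_seq = ext_seq, ext_start = res$ext$start, ext_end = res$ext$end,
          lig_seq = lig_seq, lig_start = res$lig$start, lig_end = res$lig$end,
          gap_start = wins$start[w], gap_end = wins$end[w],
          oligo = ol$oligo, oligo_len = ol$length, oligo_in_range = ol$in_range,
          umi_len = params$umi_len, dosage = 1,
          ext_copies = res$ext$copy_count, lig_copies = res$lig$copy_count,
          snp_in_arm = res$status == "allele_duplicate",
          allele_note = note, stringsAsFactors = FALSE)
      }
      if (res$status == "ok") {
        probes[[length(probes) + 1L]] <- mk(res$ext$seq, res$lig$seq, NA_character_, base_id)
      } else {
        probes[[length(probes) + 1L]] <- mk(res$ext$seq, res$lig$seq, "wt",
                                            paste0(base_id, ".wt"))
        probes[[length(probes) + 1L]] <- mk(res$ext_alt, res$lig_alt, "alt",
                                            paste0(base_id, ".alt"))
      }
    }
  }
  panel <- if (length(probes)) do.call(rbind, probes) else empty_panel()
  rownames(panel) <- NULL
  n_short <- sum(!panel$oligo_in_range)
  if (n_short > 0L) {
    warning(n_short, " probe oligo(s) outside the intended ",
            params$oligo_len_range[1], "-", params$oligo_len_range[2],
            " nt length range", call. = FALSE)
  }
  attr(panel, "uncovered") <- if (length(uncovered)) do.call(rbind, uncovered) else NULL
  attr(panel, "params") <- params
  class(panel) <- c("mip_panel", "data.frame")
  panel
}

empty_panel <- function() {
  data.frame(
    probe_id = character(), gene = character(), exon = character(),
    chrom = character(), strand = character(),
    ext_seq = character(), ext_start = integer(), ext_end = integer(),
    lig_seq = character(), lig_start = integer(), lig_end = integer(),
    gap_start = integer(), gap_end = integer(),
    oligo = character(), oligo_len = integer(), oligo_in_range = logical(),
    umi_len = integer(), dosage = numeric(),
    ext_copies = integer(), lig_copies = integer(),
    snp_in_arm = logical(), allele_note = character(),
    stringsAsFactors = FALSE)
}

#' Validate panel coverage of the targets
#'
#' Checks that every base of every target region lies under at least one
#' probe gap fill, and reports the covered-base fraction, the maximal
#' disjoint uncovered intervals, and the per-probe arm copy counts and
#' SNP-in-arm flags recorded at design time.
#'
#' @param panel a `mip_panel` data.frame.
#' @param targets a `mip_targets` data.frame.
#' @return list of class `panel_validation` with `covered_fraction`,
#'   `per_target` data.frame, `uncovered` data.frame, `arm_copy_counts`,
#'   `snp_flags`.
#' @export
validate_panel <- function(panel, targets) {
  total <- 0L
  covered <- 0L
  unc <- list()
  per_target <- targets
  per_target$covered_fraction <- 0
  for (ch in unique(targets$chrom)) {
    tir <- with(targets[targets$chrom == ch, ], as_iranges0(start, end))
    p <- panel[panel$chrom == ch, , drop = FALSE]
    gir <- if (nrow(p)) IRanges::reduce(as_iranges0(p$gap_start, p$gap_end))
           else IRanges::IRanges()
    cov_ir <- IRanges::intersect(tir, gir)
    unc_ir <- IRanges::setdiff(tir, gir)
    total <- total + sum(IRanges::width(tir))
    covered <- covered + sum(IRanges::width(cov_ir))
    if (length(unc_ir)) {
      unc[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(unc_ir) - 1L,
                              end = IRanges::end(unc_ir),
                              stringsAsFactors = FALSE)
    }
    idx <- which(targets$chrom == ch)
    for (k in seq_along(idx)) {
      ti <- tir[k]
      cw <- sum(IRanges::width(IRanges::intersect(ti, gir)))
      per_target$covered_fraction[idx[k]] <- cw / IRanges::width(ti)
    }
  }
  structure(list(
    covered_fraction = if (total > 0) covered / total else 0,
    per_target = per_target,
    uncovered = if (length(unc)) do.call(rbind, c(unc, make.row.names = FALSE)) else
      data.frame(chrom = character(), start = integer(), end = integer()),
    arm_copy_counts = panel[, c("probe_id", "ext_copies", "lig_copies")],
    snp_flags = panel[, c("probe_id", "snp_in_arm")]
  ), class = "panel_validation")
}
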