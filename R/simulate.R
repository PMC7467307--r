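#' Generate a synthetic multi-gene reference and exon targets
#'
#' Builds a single-contig reference in which `n_genes` genes, each with
#' `exons_per_gene` exons, are laid out with intronic and intergenic
#' spacers, and returns the matching exon BED-style target table
#' (`gene|exon` naming). Deterministic for a fixed seed.
#'
#' Exon base composition is uniform (GC 0.5) unless `first_exon_gc` is set,
#' in which case the first exon of every gene is drawn with that GC
#' fraction; GC-rich first exons emulate the promoter-proximal exons that
#' capture poorly in real panels.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene.
#' @param exon_len_range integer(2), exon length range in bp.
#' @param seed RNG seed.
#' @param chrom contig name.
#' @param intron_len_range,intergenic_len intron and intergenic spacer sizes.
#' @param first_exon_gc optional GC fraction for each gene's first exon.
#' @return list with `reference` (named `DNAStringSet`) and `targets`
#'   (unpadded exon records: `chrom`, `start`, `end`, `gene`, `exon`,
#'   0-based half-open).
#' @export
make_reference <- function(n_genes = 9L, exons_per_gene = 4L,
                           exon_len_range = c(120L, 300L), seed = 1L,
                           chrom = "chr1",
                           intron_len_range = c(300L, 600L),
                           intergenic_len = 800L,
                           first_exon_gc = NULL) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 1L,
            exon_len_range[1] >= 1L, exon_len_range[1] <= exon_len_range[2])
  with_seed(seed, {
    pieces <- character(0)
    rows <- list()
    pos <- 0L
    add <- function(seq) {
      pieces[[length(pieces) + 1L]] <<- seq
      pos <<- pos + nchar(seq)
    }
    add(random_dna(intergenic_len))
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%d", g)
      for (e in seq_len(exons_per_gene)) {
        if (e > 1L) add(random_dna(sample(intron_len_range[1]:intron_len_range[2], 1L)))
        len <- sample(exon_len_range[1]:exon_len_range[2], 1L)
        gc <- if (e == 1L && !is.null(first_exon_gc)) first_exon_gc else 0.5
        start <- pos
        add(random_dna(len, gc = gc))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = pos,
          gene = gene, exon = sprintf("ex%d", e), stringsAsFactors = FALSE)
      }
      add(random_dna(intergenic_len))
    }
    reference <- Biostrings::DNAStringSet(stats::setNames(
      paste(pieces, collapse = ""), chrom))
    targets <- do.call(rbind, rows)
    list(reference = reference, targets = targets)
  })
}

#' Write a reference to FASTA
#'
#' @param reference named `DNAStringSet`.
#' @param path output FASTA path.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return named `DNAStringSet` (names truncated at first whitespace).
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Plant diploid variants for a simulated cohort
#'
#' Draws per-sample variant sets at sites inside the panel's gap fills
#' (at least `margin` bp from gap-fill edges, so short indels stay fully
#' inside the capture insert), assigns het/hom zygosity, and returns the
#' cohort truth table in normalized VCF-style representation (1-based,
#' left-aligned, parsimonious).
#'
#' @param panel a `mip_panel` data.frame.
#' @param reference named `DNAStringSet`.
#' @param n_samples number of samples (`S01`, `S02`, ...).
#' @param variants_per_sample variants planted per sample.
#' @param indel_fraction fraction of planted variants that are short indels.
#' @param max_indel_len maximum indel length (<= 3 by design).
#' @param hom_fraction fraction of planted variants that are homozygous.
#' @param margin minimum distance of a planted site from gap-fill edges, bp.
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @export
plant_variants <- function(panel, reference, n_samples = 20L,
                           variants_per_sample = 3L, indel_fraction = 0.15,
                           max_indel_len = 3L, hom_fraction = 0.3,
                           margin = 10L, seed = 1L) {
  stopifnot(max_indel_len <= 3L)
  with_seed(seed, {
    out <- list()
    bases <- c("A", "C", "G", "T")
    for (s in seq_len(n_samples)) {
      sid <- sprintf("S%02d", s)
      used <- integer(0)
      made <- 0L
      guard <- 0L
      while (made < variants_per_sample && guard < 200L) {
        guard <- guard + 1L
        pr <- panel[sample(nrow(panel), 1L), ]
        off <- sample((pr$gap_start + margin):(pr$gap_end - margin - max_indel_len), 1L)
        if (any(abs(off - used) < 2L * margin)) next
        pos <- off + 1L  # 1-based
        refbase <- ref_subseq(reference, pr$chrom, off, off + 1L)
        is_indel <- stats::runif(1) < indel_fraction
        if (!is_indel) {
          ref <- refbase
          alt <- sample(setdiff(bases, refbase), 1L)
        } else if (stats::runif(1) < 0.5) {  # insertion after the anchor
          k <- sample(seq_len(max_indel_len), 1L)
          ref <- refbase
          alt <- paste0(refbase, paste(sample(bases, k, replace = TRUE), collapse = ""))
        } else {                             # deletion of k bases after the anchor
          k <- sample(seq_len(max_indel_len), 1L)
          ref <- ref_subseq(reference, pr$chrom, off, off + 1L + k)
          alt <- refbase
        }
        nv <- normalize_variant(reference, pr$chrom, pos, ref, alt)
        zyg <- if (stats::runif(1) < hom_fraction) "hom" else "het"
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, chrom = pr$chrom, pos = nv$pos, ref = nv$ref,
          alt = nv$alt, zygosity = zyg, stringsAsFactors = FALSE)
        used <- c(used, off)
        made <- made + 1L
      }
    }
    res <- do.call(rbind, out)
    res[order(res$sample_id, res$chrom, res$pos), , drop = FALSE]
  })
}

# Apply a set of VCF-style variants (rows of chrom/pos/ref/alt) to the
# gap-fill substring [gs0, ge0) of `chrom`. Variants must lie fully inside.
apply_variants_to_gap <- function(gap_seq, gs0, vars) {
  if (is.null(vars) || nrow(vars) == 0L) return(gap_seq)
  vars <- vars[order(-vars$pos), , drop = FALSE]
  for (i in seq_len(nrow(vars))) {
    off1 <- vars$pos[i] - gs0          # 1-based offset of the anchor in gap_seq
    nref <- nchar(vars$ref[i])
    stopifnot(substr(gap_seq, off1, off1 + nref - 1L) == vars$ref[i])
    gap_seq <- paste0(substr(gap_seq, 1L, off1 - 1L), vars$alt[i],
                      substr(gap_seq, off1 + nref, nchar(gap_seq)))
  }
  gap_seq
}

#' Simulate MIP capture reads for one sample
#'
#' For every probe, draws the number of unique captured molecules from
#' `Poisson(mean_molecules * dosage * gc_multiplier)`, where the GC
#' multiplier applies to probes whose gap-fill GC fraction exceeds the
#' model's threshold. Each molecule carries a distinct random UMI (collisions
#' are possible by chance and not prevented), its own draw of each
#' heterozygous variant (probability 0.5; homozygous variants always), and
#' is emitted `1 + Geometric(pcr_dup_mean)` times. Read 1 is
#' `UMI + extension arm + gap-fill prefix`; read 2 is the reverse complement
#' of `gap-fill suffix + ligation arm`; both are `read_len` bases.
#' Substitution errors are applied to every read base at the model's error
#' rate. Deterministic for a fixed model seed.
#'
#' @param panel a `mip_panel` data.frame.
#' @param reference named `DNAStringSet`.
#' @param variants data.frame of this sample's variants (`chrom`, `pos`,
#'   `ref`, `alt`, `zygosity`), or `NULL`.
#' @param model a [capture_model()].
#' @param sample_id sample label used in read names.
#' @return list with `read1`, `read2` (named character vectors),
#'   `molecules` (data.frame `probe_id`, `n_molecules`), `sample_id`.
#' @export
simulate_reads <- function(panel, reference, variants = NULL,
                           model = capture_model(), sample_id = "S1") {
  read_len <- model$read_len
  bases <- c("A", "C", "G", "T")
  with_seed(model$seed, {
    r1 <- list(); r2 <- list(); nm <- list(); ids <- list()
    for (p in seq_len(nrow(panel))) {
      pr <- panel[p, ]
      chrom_len <- Biostrings::width(reference[pr$chrom])
      if (pr$gap_start < 0L || pr$gap_end > chrom_len) {
        stop("probe ", pr$probe_id, " outside reference bounds", call. = FALSE)
      }
      gap_seq <- ref_subseq(reference, pr$chrom, pr$gap_start, pr$gap_end)
      mult <- if (gc_fraction(gap_seq) > model$gc_threshold) model$gc_multiplier else 1
      lambda <- model$mean_molecules * pr$dosage * mult
      nmol <- stats::rpois(1L, lambda)
      nm[[p]] <- data.frame(probe_id = pr$probe_id, n_molecules = nmol,
                            stringsAsFactors = FALSE)
      if (nmol == 0L) next
      pv <- if (is.null(variants)) NULL else
        variants[variants$chrom == pr$chrom &
                 variants$pos - 1L >= pr$gap_start &
                 variants$pos - 1L + nchar(variants$ref) <= pr$gap_end, , drop = FALSE]
      if (!is.null(pv) && nrow(pv) > 0L) {
        take <- matrix(FALSE, nmol, nrow(pv))
        for (v in seq_len(nrow(pv))) {
          take[, v] <- if (pv$zygosity[v] == "hom") TRUE else
            stats::rbinom(nmol, 1L, 0.5) == 1L
        }
        key <- apply(take, 1L, function(x) paste(as.integer(x), collapse = ""))
        mols <- character(nmol)
        for (k in unique(key)) {
          sel <- which(strsplit(k, "", fixed = TRUE)[[1]] == "1")
          mols[key == k] <- apply_variants_to_gap(gap_seq, pr$gap_start,
                                                  pv[sel, , drop = FALSE])
        }
      } else {
        mols <- rep(gap_seq, nmol)
      }
      umi_mat <- matrix(sample(bases, pr$umi_len * nmol, replace = TRUE),
                        ncol = pr$umi_len)
      umis <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))
      dup <- 1L + stats::rgeom(nmol, prob = 1 / (1 + model$pcr_dup_mean))
      Lp <- nchar(mols)
      p1 <- paste0(umis, pr$ext_seq,
                   substr(mols, 1L, read_len - pr$umi_len - nchar(pr$ext_seq)))
      sfx_len <- read_len - nchar(pr$lig_seq)
      p2 <- revcomp(paste0(substring(mols, pmax(1L, Lp - sfx_len + 1L), Lp),
                           pr$lig_seq))
      idx <- rep(seq_len(nmol), dup)
      dupn <- sequence(dup)
      r1[[p]] <- p1[idx]
      r2[[p]] <- p2[idx]
      ids[[p]] <- sprintf("%s:%s:m%05d:d%d", sample_id, pr$probe_id, idx, dupn)
    }
    read1 <- unlist(r1, use.names = FALSE) %||% character(0)
    read2 <- unlist(r2, use.names = FALSE) %||% character(0)
    nms <- unlist(ids, use.names = FALSE) %||% character(0)
    if (model$error_rate > 0 && length(read1)) {
      read1 <- inject_errors(read1, model$error_rate)
      read2 <- inject_errors(read2, model$error_rate)
    }
    names(read1) <- nms
    names(read2) <- nms
    list(read1 = read1, read2 = read2,
         molecules = do.call(rbind, nm), sample_id = sample_id)
  })
}

# Uniform per-base substitution errors at rate e (to one of the other bases).
inject_errors <- function(reads, e) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(reads)
  k <- stats::rbinom(length(reads), w, e)
  hit <- which(k > 0L)
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(w[i], k[i])
    for (j in at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a cohort
#'
#' Runs [simulate_reads()] for every sample in a cohort truth table,
#' deriving each sample's seed as `model$seed + sample index - 1`.
#'
#' @param panel,reference,model as in [simulate_reads()].
#' @param truth cohort truth table ([plant_variants()] output); sample ids
#'   are taken from its `sample_id` column. May also be a character vector
#'   of sample ids for variant-free samples.
#' @return named list of per-sample [simulate_reads()] results.
#' @export
simulate_cohort <- function(panel, reference, truth, model = capture_model()) {
  sids <- if (is.character(truth)) truth else unique(truth$sample_id)
  out <- vector("list", length(sids))
  names(out) <- sids
  for (i in seq_along(sids)) {
    vars <- if (is.character(truth)) NULL else
      truth[truth$sample_id == sids[i], , drop = FALSE]
    m <- model
    m$seed <- model$seed + i - 1L
    out[[i]] <- simulate_reads(panel, reference, vars, m, sample_id = sids[i])
  }
  out
}

#' Write simulated reads as paired FASTQ
#'
#' @param sim a [simulate_reads()] result.
#' @param dir output directory (created if needed).
#' @param gzip compress output.
#' @return character(2) of the two FASTQ paths.
#' @export
write_fastq <- function(sim, dir, gzip = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  f1 <- file.path(dir, paste0(sim$sample_id, "_R1", ext))
  f2 <- file.path(dir, paste0(sim$sample_id, "_R2", ext))
  s1 <- Biostrings::DNAStringSet(sim$read1)
  s2 <- Biostrings::DNAStringSet(sim$read2)
  Biostrings::writeXStringSet(s1, f1, format = "fastq",
                              compress = if (gzip) "gzip" else FALSE)
  Biostrings::writeXStringSet(s2, f2, format = "fastq",
                              compress = if (gzip) "gzip" else FALSE)
  c(f1, f2)
}

#' Read paired FASTQ into character vectors
#'
#' @param fastq1,fastq2 FASTQ paths (optionally gzipped).
#' @return list with `read1`, `read2` named character vectors.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  list(read1 = stats::setNames(as.character(r1), names(r1)),
       read2 = stats::setNames(as.character(r2), names(r2)))
}

#' Write a cohort truth table
#'
#' One record per planted variant, with zygosity; round-trips through
#' [read_truth()]. An empty truth table yields a header-only file.
#'
#' @param truth data.frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity")
  df <- if (is.null(truth) || nrow(truth) == 0L) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else truth[, cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table
#'
#' @param path TSV written by [write_truth()].
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character", chrom = "character",
                                   pos = "integer", ref = "character",
                                   alt = "character", zygosity = "character"))
}
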