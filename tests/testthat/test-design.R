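test_that("tile_region matches the closed-form minimal window count", {
  p <- design_params()
  r <- function(L) data.frame(chrom = "c", start = 1000L, end = 1000L + L)
  expect_equal(nrow(tile_region(r(220), p)), 1L)
  expect_equal(nrow(tile_region(r(440), p)), 2L)
  expect_equal(nrow(tile_region(r(650), p)), 3L)
  # a 220-long region is covered by exactly its own window
  w <- tile_region(r(220), p)
  expect_equal(w$start, 1000L)
  expect_equal(w$end, 1220L)
})

test_that("tilings cover the region with bounded windows and >=20 bp overlaps", {
  p <- design_params()
  set.seed(42)
  lens <- sample(1:2000, 300, replace = TRUE)
  for (L in lens) {
    reg <- data.frame(chrom = "c", start = 5000L, end = 5000L + L)
    w <- tile_region(reg, p)
    expect_equal(nrow(w), min_windows(L))
    expect_true(all(w$end - w$start >= 220 & w$end - w$start <= 230))
    expect_true(w$start[1] <= reg$start && w$end[nrow(w)] >= reg$end)
    if (nrow(w) > 1) {
      expect_true(all(diff(w$start) > 0))
      expect_true(all(w$end[-nrow(w)] - w$start[-1] >= 20))
    }
  }
})

test_that("arm_copy_count counts both strands and agrees with a naive scan", {
  # constructed fixture: arm planted once in otherwise AT-only sequence
  arm <- "GGCGTCAGCTACGGTC"
  ref1 <- fixture_reference(c(chr1 = paste0(strrep("AT", 50), arm, strrep("TA", 50))))
  expect_equal(arm_copy_count(arm, ref1), 1L)

  # arm repeated 6 times -> over the exclusion threshold
  ref6 <- fixture_reference(c(chr1 = paste0(rep(c(strrep("AT", 20), arm), 6), collapse = "")))
  expect_equal(arm_copy_count(arm, ref6), 6L)
  expect_gt(arm_copy_count(arm, ref6), design_params()$max_arm_copy_count)

  # palindromic arm occurring once: + and - strand hits coincide, counted once
  pal <- "ACGCGCGT"
  expect_equal(pal, as.character(Biostrings::reverseComplement(Biostrings::DNAString(pal))))
  refp <- fixture_reference(c(chr1 = paste0(strrep("AT", 30), pal, strrep("AT", 30))))
  expect_equal(arm_copy_count(pal, refp), naive_arm_count(pal, refp))
  expect_equal(arm_copy_count(pal, refp), 1L)

  expect_error(arm_copy_count("ACGTN", ref1), "non-ACGT")

  # property: agreement with the brute-force oracle on random references
  set.seed(7)
  ref <- fixture_reference(c(s1 = fixture_dna(3000, seed = 11),
                             s2 = fixture_dna(2000, seed = 12)))
  for (i in 1:20) {
    start <- sample(2900, 1)
    len <- sample(16:24, 1)
    arm <- substr(as.character(ref[["s1"]]), start, start + len - 1L)
    expect_equal(arm_copy_count(arm, ref), naive_arm_count(arm, ref))
  }
})

test_that("pick_arms returns the GC tie-break optimum over the length grid", {
  ref <- fixture_reference(c(chr1 = fixture_dna(3000, seed = 3)))
  win <- data.frame(chrom = "chr1", start = 1400L, end = 1625L)
  res <- pick_arms(win, ref, design_params())
  expect_equal(res$status, "ok")
  expect_equal(res$ext$end, 1400L)   # arms immediately flank the window
  expect_equal(res$lig$start, 1625L)

  # independent exhaustive oracle over the 5 x 5 grid
  s <- as.character(ref[["chr1"]])
  gc <- function(x) {
    ch <- strsplit(x, "")[[1]]
    mean(ch %in% c("G", "C"))
  }
  best <- NULL
  for (el in 16:20) for (ll in 20:24) {
    ext <- substr(s, 1400L - el + 1L, 1400L)
    lig <- substr(s, 1626L, 1625L + ll)
    score <- abs(gc(ext) - 0.5) + abs(gc(lig) - 0.5)
    cand <- list(el = el, ll = ll, ext = ext, lig = lig, score = score)
    if (is.null(best) || score < best$score ||
        (score == best$score && (el + ll > best$el + best$ll ||
          (el + ll == best$el + best$ll && el > best$el)))) {
      best <- cand
    }
  }
  expect_equal(res$ext$seq, best$ext)
  expect_equal(res$lig$seq, best$lig)
})

test_that("common SNPs in arms are avoided, tolerated below 1%, or duplicated", {
  ref <- fixture_reference(c(chr1 = fixture_dna(3000, seed = 5)))
  win <- data.frame(chrom = "chr1", start = 1400L, end = 1625L)
  base_at <- function(p) substr(as.character(ref[["chr1"]]), p, p)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

  # a rare SNP (0.5% < 1%) inside every candidate ligation arm is ignored
  rare <- data.frame(chrom = "chr1", pos = 1630L, ref = base_at(1630),
                     alt = other(base_at(1630)), maf = 0.005)
  expect_equal(pick_arms(win, ref, design_params(), rare)$status, "ok")

  # a common SNP (2%) in the first 20 bases of the ligation arm hits every
  # candidate -> allele-specific duplicate probes
  common <- data.frame(chrom = "chr1", pos = 1630L, ref = base_at(1630),
                       alt = other(base_at(1630)), maf = 0.02)
  res <- pick_arms(win, ref, design_params(), common)
  expect_equal(res$status, "allele_duplicate")
  expect_equal(res$ext_alt, res$ext$seq)        # extension arm untouched
  expect_false(res$lig_alt == res$lig$seq)      # ligation arm carries the alt
  off <- 1630L - res$lig$start                  # SNP offset within the arm
  expect_equal(substr(res$lig_alt, off, off), common$alt)
  expect_equal(sub_base(res$lig$seq, off, common$alt), res$lig_alt)

  # design_panel emits both probes with wt/alt notes at the same coordinates
  targets <- pad_and_merge_targets(
    data.frame(chrom = "chr1", start = 1420L, end = 1605L, gene = "G", exon = "e1"),
    pad = 20, reference = ref)
  panel <- suppressWarnings(design_panel(ref, targets, snps = common))
  dup <- panel[panel$snp_in_arm, ]
  expect_equal(nrow(dup), 2L)
  expect_setequal(dup$allele_note, c("wt", "alt"))
  expect_equal(unique(dup$gap_start), dup$gap_start[1])
})

test_that("probes whose arms exceed the copy-count limit are rejected", {
  # every candidate extension arm lies inside a 6x-repeated block
  block <- fixture_dna(300, seed = 21)
  uniq <- fixture_dna(600, seed = 22)
  ref <- fixture_reference(c(chr1 = paste0(strrep(block, 6), uniq)))
  win <- data.frame(chrom = "chr1", start = 6 * 300L, end = 6 * 300L + 225L)
  res <- pick_arms(win, ref, design_params())
  expect_equal(res$status, "rejected")
  expect_equal(res$reason, "arm_copy_count")
})

test_that("assemble_oligo concatenates segments and flags off-range totals", {
  p <- design_params()
  linker <- default_linker()
  expect_equal(nchar(linker), 35L)
  ol <- assemble_oligo(strrep("A", 20), strrep("G", 24), linker, p)
  expect_equal(ol$length, 79L)
  expect_true(ol$in_range)
  expect_equal(ol$oligo, paste0(strrep("A", 20), linker, strrep("G", 24)))

  short <- assemble_oligo(strrep("A", 16), strrep("G", 20), linker, p)
  expect_equal(short$length, 71L)
  expect_false(short$in_range)

  expect_error(assemble_oligo("", "ACGT", linker, p), "empty arm")
  bad <- sub("N", "A", linker)  # only 4 N placeholders left
  expect_error(assemble_oligo(strrep("A", 20), strrep("G", 24), bad, p), "N placeholder")
})

test_that("validate_panel reports covered fraction and uncovered intervals", {
  fx <- design_fixture()
  val <- validate_panel(fx$panel, fx$targets)
  expect_equal(val$covered_fraction, 1.0)
  expect_equal(nrow(val$uncovered), 0L)
  expect_true(all(fx$panel$gap_end - fx$panel$gap_start >= 220))
  expect_true(all(fx$panel$gap_end - fx$panel$gap_start <= 230))

  # deleting one probe uncovers its window minus the neighbours' contribution:
  # use the first target tiled by at least two probes
  n_over <- vapply(seq_len(nrow(fx$targets)), function(i) {
    t <- fx$targets[i, ]
    sum(fx$panel$gap_start < t$end & fx$panel$gap_end > t$start)
  }, integer(1))
  t1 <- fx$targets[which(n_over >= 2)[1], ]
  probes1 <- fx$panel[fx$panel$gap_start < t1$end & fx$panel$gap_end > t1$start, ]
  probes1 <- probes1[order(probes1$gap_start), ]
  expect_gte(nrow(probes1), 2L)
  drop_id <- probes1$probe_id[1]
  reduced <- fx$panel[fx$panel$probe_id != drop_id, ]
  class(reduced) <- class(fx$panel)
  val2 <- validate_panel(reduced, fx$targets)
  expect_lt(val2$covered_fraction, 1.0)
  # expected uncovered span: target start up to the next probe's gap start
  expect_equal(val2$uncovered$start[1], t1$start)
  expect_equal(val2$uncovered$end[1], probes1$gap_start[2])

  empty <- fx$panel[0, ]
  class(empty) <- class(fx$panel)
  expect_equal(validate_panel(empty, fx$targets)$covered_fraction, 0.0)
})

test_that("panel export round-trips and the design is deterministic", {
  fx <- design_fixture()
  tsv1 <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  export_panel(fx$panel, tsv1, bed)
  back <- read_panel(tsv1)
  expect_equal(as.data.frame(back), as.data.frame(fx$panel)[, names(back)])
  expect_equal(length(readLines(bed)), nrow(fx$panel))
  expect_true(all(back$dosage == 1))

  # byte-identical output on a repeated design run
  panel2 <- suppressWarnings(design_panel(fx$reference, fx$targets))
  tsv2 <- tempfile(fileext = ".tsv")
  export_panel(panel2, tsv2)
  expect_identical(readLines(tsv1), readLines(tsv2))
})

test_that("read_snp_table accepts TSV and VCF with AF", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tmaf", "chr1\t100\tA\tG\t0.02"), tsv)
  snp <- read_snp_table(tsv)
  expect_equal(snp$maf, 0.02)

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t.\t.\tAF=0.02"), vcf)
  snp2 <- read_snp_table(vcf)
  expect_equal(snp2$pos, 100L)
  expect_equal(snp2$maf, 0.02)
  expect_equal(snp2$alt, "G")
})
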