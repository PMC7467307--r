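# A hand-built single-probe fixture whose gap fill carries a known repeat
# (offsets 101..106 of the gap are C A A A A G), for indel normalization.
indel_fixture <- function() {
  set.seed(55)
  gap <- fixture_dna(225, seed = 56)
  while (substr(gap, 100, 100) == "A" || substr(gap, 107, 107) == "A") {
    gap <- fixture_dna(225, seed = 57)
  }
  gap <- paste0(substr(gap, 1, 100), "CAAAAG", substr(gap, 107, 225))
  substr(gap, 100, 100) <- "T"
  ref <- fixture_reference(c(chr1 = paste0(fixture_dna(300, seed = 58), gap,
                                           fixture_dna(300, seed = 59))))
  panel <- data.frame(
    probe_id = "P1", gene = "G", exon = "e", chrom = "chr1", strand = "+",
    ext_seq = "ACGTACGTACGTACGT", ext_start = 284L, ext_end = 300L,
    lig_seq = "ACGTACGTACGTACGTACGT", lig_start = 525L, lig_end = 545L,
    gap_start = 300L, gap_end = 525L,
    oligo = "x", oligo_len = 8L, oligo_in_range = FALSE, umi_len = 5L,
    dosage = 1, ext_copies = 1L, lig_copies = 1L, snp_in_arm = FALSE,
    allele_note = NA_character_, stringsAsFactors = FALSE)
  list(reference = ref, panel = panel, gap = gap)
}

fam_table <- function(frags) {
  data.frame(probe_id = rep("P1", length(frags)),
             umi = umi_pool(length(frags)),
             read_count = rep(1L, length(frags)),
             frag = frags, stringsAsFactors = FALSE)
}

test_that("substitution calls respect depth, fraction and zygosity rules", {
  fx <- indel_fixture()
  off <- 150L
  refbase <- substr(fx$gap, off, off)
  altbase <- setdiff(c("A", "C", "G", "T"), refbase)[1]
  mut <- sub_base(fx$gap, off, altbase)
  pos <- fx$panel$gap_start + off  # genomic 1-based

  # depth 40, alt 20 -> PASS het at fraction 0.5
  calls <- call_sample(fam_table(c(rep(mut, 20), rep(fx$gap, 20))),
                       fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, pos)
  expect_equal(calls$ref, refbase)
  expect_equal(calls$alt, altbase)
  expect_equal(calls$depth, 40L)
  expect_equal(calls$alt_fraction, 0.5)
  expect_equal(calls$zygosity, "het")
  expect_equal(calls$filter, "PASS")

  # depth 29, all alt -> LOW_DEPTH, hom
  calls2 <- call_sample(fam_table(rep(mut, 29)), fx$panel, fx$reference,
                        filter_config(), "S1")
  expect_equal(calls2$filter, "LOW_DEPTH")
  expect_equal(calls2$zygosity, "hom")
  expect_equal(calls2$depth, 29L)

  # depth 100, alt 19 (f = 0.19): below the 20% floor, no call at the site
  calls3 <- call_sample(fam_table(c(rep(mut, 19), rep(fx$gap, 81))),
                        fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(nrow(calls3), 0L)

  # sub-threshold second allele at a reportable site is emitted as LOW_VAF
  alt2 <- setdiff(c("A", "C", "G", "T"), c(refbase, altbase))[1]
  mut2 <- sub_base(fx$gap, off, alt2)
  calls4 <- call_sample(fam_table(c(rep(mut, 20), rep(mut2, 3), rep(fx$gap, 17))),
                        fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(calls4$filter[calls4$alt == altbase], "PASS")
  expect_equal(calls4$filter[calls4$alt == alt2], "LOW_VAF")

  # zygosity boundary: 80% is hom, 79% is het
  calls5 <- call_sample(fam_table(c(rep(mut, 80), rep(fx$gap, 20))),
                        fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(calls5$zygosity, "hom")
  calls6 <- call_sample(fam_table(c(rep(mut, 79), rep(fx$gap, 21))),
                        fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(calls6$zygosity, "het")

  # consensus N bases are excluded from depth
  nmask <- sub_base(fx$gap, off, "N")
  calls7 <- call_sample(fam_table(c(rep(mut, 20), rep(nmask, 10), rep(fx$gap, 20))),
                        fx$panel, fx$reference, filter_config(), "S1")
  expect_equal(calls7$depth, 40L)

  expect_equal(nrow(call_sample(fam_table(character(0)), fx$panel,
                                fx$reference, filter_config(), "S1")), 0L)
})

test_that("indels are called by exact fragment matching, left-aligned", {
  fx <- indel_fixture()
  # the gap carries CAAAAG at offsets 101..106; delete one A from the run
  del <- paste0(substr(fx$gap, 1, 102), substr(fx$gap, 104, 225))
  calls <- call_sample(fam_table(c(rep(del, 20), rep(fx$gap, 20))),
                       fx$panel, fx$reference, filter_config(), "S1")
  dcall <- calls[nchar(calls$ref) == 2L, ]
  expect_equal(nrow(dcall), 1L)
  expect_equal(dcall$pos, fx$panel$gap_start + 101L)  # anchored at the C
  expect_equal(dcall$ref, "CA")
  expect_equal(dcall$alt, "C")
  expect_equal(dcall$alt_count, 20L)
  expect_equal(dcall$zygosity, "het")

  # insert one A into the run: left-aligned to the same anchor
  ins <- paste0(substr(fx$gap, 1, 104), "A", substr(fx$gap, 105, 225))
  calls2 <- call_sample(fam_table(c(rep(ins, 35), rep(fx$gap, 5))),
                        fx$panel, fx$reference, filter_config(), "S1")
  icall <- calls2[nchar(calls2$alt) == 2L, ]
  expect_equal(icall$pos, fx$panel$gap_start + 101L)
  expect_equal(icall$ref, "C")
  expect_equal(icall$alt, "CA")
  expect_equal(icall$zygosity, "hom")
})

test_that("variant normalization trims and left-aligns against the reference", {
  ref <- fixture_reference(c(c1 = "TTCAAAAGTT"))
  # deletion inside the A-run shifts to the C anchor
  nv <- normalize_variant(ref, "c1", 6L, "AA", "A")
  expect_equal(nv, list(pos = 3L, ref = "CA", alt = "C"))
  # insertion likewise
  nv2 <- normalize_variant(ref, "c1", 6L, "A", "AA")
  expect_equal(nv2, list(pos = 3L, ref = "C", alt = "CA"))
  # shared leading base of an MNV is trimmed to a parsimonious SNV
  nv3 <- normalize_variant(ref, "c1", 3L, "CA", "CG")
  expect_equal(nv3, list(pos = 4L, ref = "A", alt = "G"))
  # SNVs pass through unchanged
  expect_equal(normalize_variant(ref, "c1", 3L, "C", "G"),
               list(pos = 3L, ref = "C", alt = "G"))
})

test_that("the cohort filter flags variants above 90% sample frequency", {
  mk_calls <- function(n_carriers) {
    data.frame(sample_id = sprintf("S%03d", seq_len(n_carriers)),
               chrom = "chr1", pos = 100L, ref = "A", alt = "G",
               depth = 50L, alt_count = 25L, alt_fraction = 0.5,
               zygosity = "het", filter = "PASS", stringsAsFactors = FALSE)
  }
  # 150/166 samples (90.4%) -> flagged everywhere
  out <- cohort_filter(mk_calls(150), 166)
  expect_true(all(out$filter == "COHORT_ARTIFACT"))
  # 149/166 (89.8%) -> kept
  out2 <- cohort_filter(mk_calls(149), 166)
  expect_true(all(out2$filter == "PASS"))
  # degenerate single-sample cohort: 100% > 90% -> flagged
  out3 <- cohort_filter(mk_calls(1), 1)
  expect_equal(out3$filter, "COHORT_ARTIFACT")
  # the flag appends to existing flags rather than replacing them
  calls <- mk_calls(150)
  calls$filter[1] <- "LOW_DEPTH"
  out4 <- cohort_filter(calls, 166)
  expect_equal(out4$filter[1], "LOW_DEPTH,COHORT_ARTIFACT")
  # permutation invariance
  calls5 <- mk_calls(150)
  out5 <- cohort_filter(calls5[rev(seq_len(150)), ], 166)
  expect_equal(sort(out5$sample_id), sort(out$sample_id))
  expect_true(all(out5$filter == "COHORT_ARTIFACT"))
})

test_that("raising thresholds never adds a PASS call", {
  fx <- design_fixture()
  truth <- plant_variants(fx$panel, fx$reference, n_samples = 1,
                          variants_per_sample = 3, seed = 19)
  sim <- simulate_reads(fx$panel, fx$reference, truth,
                        capture_model(mean_molecules = 60, error_rate = 0.002,
                                      seed = 23), "S01")
  rs <- run_sample(fx$panel, fx$targets, sim$read1, sim$read2)
  pass_keys <- function(cfg) {
    calls <- call_sample(rs$families, fx$panel, fx$reference, cfg, "S01")
    with(calls[calls$filter == "PASS", ], paste(chrom, pos, ref, alt))
  }
  base <- pass_keys(filter_config())
  expect_gt(length(base), 0L)
  stricter <- pass_keys(filter_config(min_depth = 50, min_alt_fraction = 0.3))
  expect_true(all(stricter %in% base))
})

test_that("VCF output carries filters, genotype and molecule counts", {
  calls <- data.frame(
    sample_id = "S1", chrom = "chr1",
    pos = c(150L, 120L, 410L),                    # deliberately unsorted
    ref = c("A", "C", "CA"), alt = c("G", "T", "C"),
    depth = c(40L, 35L, 50L), alt_count = c(20L, 33L, 25L),
    alt_fraction = c(0.5, 33 / 35, 0.5),
    zygosity = c("het", "hom", "het"),
    filter = c("PASS", "PASS", "PASS"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  recs <- lines[!grepl("^#", lines)]
  expect_equal(length(recs), 3L)
  expect_true(all(vapply(strsplit(recs, "\t"), `[`, "", 7) == "PASS"))
  # sorted internally
  expect_equal(as.integer(vapply(strsplit(recs, "\t"), `[`, "", 2)),
               c(120L, 150L, 410L))

  back <- read_vcf_calls(path)
  ord <- order(calls$pos)
  expect_equal(back$pos, calls$pos[ord])
  expect_equal(back$ref, calls$ref[ord])
  expect_equal(back$alt, calls$alt[ord])
  expect_equal(back$depth, calls$depth[ord])
  expect_equal(back$alt_count, calls$alt_count[ord])
  expect_equal(back$zygosity, calls$zygosity[ord])
  expect_equal(back$filter, calls$filter[ord])
  expect_equal(back$alt_fraction, calls$alt_fraction[ord], tolerance = 1e-4)

  # filter flags land in the FILTER column, semicolon-separated
  calls$filter <- c("LOW_DEPTH,LOW_VAF", "PASS", "COHORT_ARTIFACT")
  write_vcf(calls, path)
  recs2 <- readLines(path)
  recs2 <- recs2[!grepl("^#", recs2)]
  filt <- vapply(strsplit(recs2, "\t"), `[`, "", 7)
  expect_equal(filt, c("PASS", "LOW_DEPTH;LOW_VAF", "COHORT_ARTIFACT"))
})
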