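segs_fixture <- data.frame(
  segment_id = c("chr10:1-2e7:loss", "chr7:1-2e7:gain"),
  chrom = c("chr10", "chr7"), start = 1L, end = 2e7,
  direction = c("loss", "gain"), depth_ratio = c(0.5, 1.5),
  n_bins = 20L, whole_chrom = TRUE, stringsAsFactors = FALSE)

test_that("informative germline selection matches an exhaustive predicate oracle", {
  sites <- data.frame(
    chrom = c("chr10", "chr10", "chr7", "chr10", "chr3", "chr10"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = "A", alt = "G", kind = "germline",
    vaf_blood = c(0.50, 0.48, 0.55, 0.70, 0.50, 0.52),
    vaf_tumor = c(0.50, 0.15, 0.85, 0.10, 0.90, 0.60),
    stringsAsFactors = FALSE)
  got <- select_informative_germline(sites, segs_fixture,
                                     het_tol = 0.1, shift_min = 0.15)
  in_seg <- function(ch, p) any(segs_fixture$chrom == ch &
                                segs_fixture$start <= p & segs_fixture$end >= p)
  keep <- abs(sites$vaf_blood - 0.5) <= 0.1 &
          abs(sites$vaf_tumor - 0.5) >= 0.15 &
          mapply(in_seg, sites$chrom, sites$pos)
  expect_setequal(paste(got$chrom, got$pos), paste(sites$chrom, sites$pos)[keep])
  # site with no VAF shift is excluded
  expect_false("chr10:100" %in% paste0(got$chrom, ":", got$pos))
  # chr10 sites are inside the loss, chr7 inside the gain
  expect_identical(got$segment_direction[got$chrom == "chr10"],
                   rep("loss", sum(got$chrom == "chr10")))
  # invariant to input ordering
  perm <- sites[sample(nrow(sites)), ]
  got2 <- select_informative_germline(perm, segs_fixture, 0.1, 0.15)
  expect_identical(got, got2)
  # no segments: empty with warning
  expect_warning(none <- select_informative_germline(sites, segs_fixture[0, ]),
                 "no CNV segments")
  expect_equal(nrow(none), 0L)
})

test_that("allele-pattern calls follow the coverage and minor-allele rules", {
  info <- suppressWarnings(select_informative_germline(
    data.frame(chrom = "chr10", pos = c(100L, 200L), ref = "A", alt = "G",
               kind = "germline", vaf_blood = 0.5, vaf_tumor = 0.15,
               stringsAsFactors = FALSE), segs_fixture))
  counts <- data.frame(
    cell_id = c("c1", "c1", "c2", "c3", "c4"),
    chrom = "chr10", pos = c(100L, 200L, 100L, 100L, 200L),
    ref = "A", alt = "G",
    ref_count = c(5L, 3L, 0L, 0L, 1L),
    alt_count = c(0L, 4L, 0L, 6L, 1L), stringsAsFactors = FALSE)
  pat <- call_allele_pattern(counts, info, min_reads = 3, min_minor = 2)
  calls <- setNames(pat$sites$call, paste(pat$sites$cell_id, pat$sites$pos))
  expect_identical(unname(calls["c1 100"]), "ref_only")   # 5/0
  expect_identical(unname(calls["c1 200"]), "biallelic")  # 3/4
  expect_identical(unname(calls["c2 100"]), "no_coverage")
  expect_identical(unname(calls["c3 100"]), "alt_only")
  expect_identical(unname(calls["c4 200"]), "no_coverage") # 1+1 < 3 reads
  summaries <- setNames(pat$cells$summary, pat$cells$cell_id)
  expect_identical(unname(summaries["c1"]), "biallelic_observed")
  expect_identical(unname(summaries["c2"]), "uninformative")
  expect_identical(unname(summaries["c3"]), "monoallelic_consistent")
  # counts at unknown positions are rejected, naming the offender
  bad <- counts; bad$pos[1] <- 999L
  expect_error(call_allele_pattern(bad, info, 3, 2), "chr10:999")
})

test_that("somatic tallies match a brute-force count and are monotone in min_alt", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "T", kind = "somatic",
                      vaf_blood = NA_real_, vaf_tumor = 0.4,
                      stringsAsFactors = FALSE)
  set.seed(9)
  counts <- data.frame(
    cell_id = rep(c("c1", "c2", "c3"), each = 4),
    chrom = "chr1", pos = rep(sites$pos, 3), ref = "A", alt = "T",
    ref_count = rpois(12, 2), alt_count = rpois(12, 1),
    stringsAsFactors = FALSE)
  cells <- c("c1", "c2", "c3")
  prev <- NULL
  for (ma in 1:4) {
    t1 <- tally_somatic(counts, sites, min_alt = ma, cells = cells)
    expect_equal(t1$n_somatic_expressed,
                 unname(oracle_tally(counts, sites, ma, cells)))
    if (!is.null(prev)) expect_true(all(t1$n_somatic_expressed <= prev))
    prev <- t1$n_somatic_expressed
  }
  # all-zero alt: no tumor evidence anywhere
  zero <- transform(counts, alt_count = 0L)
  expect_true(all(tally_somatic(zero, sites, 1, cells)$n_somatic_expressed == 0L))
})
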