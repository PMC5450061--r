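test_that("configuration validation rejects infeasible settings", {
  expect_error(simulation_config(n_genes = 0L), "positive")
  expect_error(simulation_config(allelic_dropout = 1.5), "\\[0,1\\]")
  expect_error(simulation_config(n_germline_het_snvs = 2L,
                                 germline_in_loss = 5L), "exceeds")
  expect_error(simulation_config(nonsense = 1), "unknown")
  cfg <- simulation_config()
  expect_equal(cfg$n_chromosomes, 12L)
})

test_that("truth bookkeeping matches the configured populations", {
  b <- default_bundle()
  s <- summarize_truth(b)
  expect_equal(unname(s$class_counts["neoplastic"]), 180L)
  expect_equal(unname(s$class_counts["immune"]), 20L)
  expect_equal(s$carriage$n_cells, c(180L, 180L))
  # detected-site counts agree with direct counting on the allele table
  ac <- b$allele_counts
  sk <- paste0(b$somatic_sites$chrom, ":", b$somatic_sites$pos)
  direct <- sapply(sk, function(k) {
    rows <- ac[paste0(ac$chrom, ":", ac$pos) == k & ac$alt_count >= 1, ]
    length(unique(rows$cell_id))
  })
  expect_equal(s$somatic_detected$n_cells, unname(direct))
})

test_that("simulated per-gene CPM means track the generative means", {
  cfg <- simulation_config(seed = 77, n_control_cells = 500L,
                           n_tumor_cells = 5L, n_immune_cells = 0L)
  b <- simulate_bundle(cfg)
  cpm <- to_cpm(b$control)
  obs <- rowMeans(cpm$values)
  # expected CPM from the model: base mean thinned by dropout, normalized
  base <- local({
    set.seed(cfg$seed)
    stats::rlnorm(cfg$n_genes, cfg$base_mean_log, cfg$base_mean_sdlog)
  })
  pdrop <- 1 / (1 + (base / cfg$dropout_mid)^cfg$dropout_slope)
  exp_cpm <- base * (1 - pdrop) / sum(base * (1 - pdrop)) * 1e6
  # restrict to well-expressed genes where relative error is meaningful;
  # special genes (markers etc.) had their base means overridden
  plain <- grepl("^G\\d+$", rownames(cpm$values)) & exp_cpm > 200
  relerr <- abs(obs[plain] - exp_cpm[plain]) / exp_cpm[plain]
  expect_lt(median(relerr), 0.1)
})

test_that("germline allele counts respect the planted haplotypes", {
  b <- default_bundle()
  truth <- b$truth
  loss_sites <- truth$germline[truth$germline$in_loss, ]
  ac <- b$allele_counts
  neo <- truth$cells$cell_id[truth$cells$class == "neoplastic"]
  for (i in seq_len(nrow(loss_sites))) {
    rows <- ac[ac$chrom == loss_sites$chrom[i] & ac$pos == loss_sites$pos[i] &
               ac$cell_id %in% neo, ]
    if (nrow(rows) == 0L) next
    if (loss_sites$retained[i] == "ref") {
      expect_true(all(rows$alt_count == 0L))
    } else {
      expect_true(all(rows$ref_count == 0L))
    }
  }
})

test_that("a fold-1 'null' tumor shows control-like CNV call rates", {
  cfg <- simulation_config(
    seed = 300, n_tumor_cells = 100L, n_immune_cells = 0L,
    n_control_cells = 100L, n_germline_het_snvs = 1L, germline_in_loss = 1L,
    cnv_specs = list(list(chrom = "chr7", direction = "gain", fold = 1),
                     list(chrom = "chr10", direction = "loss", fold = 1)))
  b <- simulate_bundle(cfg)
  # depth ratios hover at 1: no segments called from the exome
  expect_equal(nrow(call_exome_segments(b$depth_bins)), 0L)
  # testing chr7 as if it were a gain calls ~alpha of null cells present
  tum <- to_cpm(b$tumor); ctl <- to_cpm(b$control)
  genes <- b$annotation$gene_id[b$annotation$chrom == "chr7"]
  res <- test_cnv_presence(segment_statistic(tum, genes),
                           segment_statistic(ctl, genes), "gain")
  expect_lt(mean(res$call == "present"), 0.15)
})

test_that("bundle files round-trip through the package readers", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  expect_no_warning(write_bundle(b, dir))
  expect_no_warning(b2 <- read_bundle(dir))
  expect_equal(b2$tumor$values, b$tumor$values)
  expect_identical(b2$tumor$unit, "counts")
  expect_equal(b2$annotation[, c("gene_id", "chrom", "start", "end")],
               b$annotation[, c("gene_id", "chrom", "start", "end")])
  expect_equal(b2$depth_bins$depth_ratio, b$depth_bins$depth_ratio)
  expect_equal(b2$germline_sites$pos, b$germline_sites$pos)
  expect_equal(b2$germline_sites$vaf_tumor, b$germline_sites$vaf_tumor,
               tolerance = 1e-4)
  expect_equal(b2$somatic_sites$pos, b$somatic_sites$pos)
  expect_equal(b2$allele_counts, b$allele_counts)
  expect_identical(paste(b2$lr_pairs$ligand, b2$lr_pairs$receptor),
                   paste(b$lr_pairs$ligand, b$lr_pairs$receptor))
})
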