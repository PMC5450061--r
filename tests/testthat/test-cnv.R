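test_that("exome segment calling finds whole-chromosome gain and loss", {
  bins <- rbind(
    data.frame(chrom = "chr7", start = seq(1, 2e7, 1e6),
               end = seq(1e6, 2e7 + 1e6 - 1, 1e6), depth_ratio = 1.5),
    data.frame(chrom = "chr10", start = seq(1, 2e7, 1e6),
               end = seq(1e6, 2e7 + 1e6 - 1, 1e6), depth_ratio = 0.5))
  segs <- call_exome_segments(bins, delta = 0.2, min_span = 1e7)
  expect_equal(nrow(segs), 2L)
  expect_identical(segs$direction[segs$chrom == "chr7"], "gain")
  expect_identical(segs$direction[segs$chrom == "chr10"], "loss")
  expect_true(all(segs$whole_chrom))

  neutral <- transform(bins, depth_ratio = 1.0)
  expect_equal(nrow(call_exome_segments(neutral, 0.2, 1e7)), 0L)
  expect_warning(call_exome_segments(bins[0, ], 0.2, 1e7), "empty")
})

test_that("segment run detection matches an exhaustive run-scan oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 10L
    starts <- seq(1, by = 1e6, length.out = n)
    ends <- starts + 1e6 - 1
    ratio <- sample(c(0.5, 1.0, 1.5), n, replace = TRUE)
    bins <- data.frame(chrom = "chr1", start = starts, end = ends,
                       depth_ratio = ratio)
    segs <- suppressWarnings(call_exome_segments(bins, 0.2, 3e6))
    orc <- oracle_runs(ratio, starts, ends, 0.2, 3e6)
    expect_equal(nrow(segs), length(orc))
    for (k in seq_along(orc)) {
      expect_equal(segs$start[k], orc[[k]]$start)
      expect_equal(segs$end[k], orc[[k]]$end)
      expect_identical(segs$direction[k], orc[[k]]$dir)
    }
  }
})

test_that("window log2FC matches hand computation and counts windows as n-w+1", {
  # one window: tumor mean 4, control mean 2, pseudocount 0 -> log2FC = 1
  tum <- make_cpm(matrix(4, 2, 1, dimnames = list(c("g01", "g02"), "t1")))
  ctl <- make_cpm(matrix(2, 2, 2, dimnames = list(c("g01", "g02"),
                                                  c("n1", "n2"))))
  go <- list(chr1 = c("g01", "g02"))
  wp <- window_log2fc(tum, ctl, go, w = 2, pseudocount = 0)
  expect_equal(nrow(wp$log2fc), 1L)
  expect_equal(unname(wp$log2fc[1, 1]), 1)

  set.seed(3)
  n <- 37L
  vals <- matrix(runif(n * 4, 0, 100), n,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("c%d", 1:4)))
  tum2 <- make_cpm(vals[, 1:2]); ctl2 <- make_cpm(vals[, 3:4])
  wp2 <- window_log2fc(tum2, ctl2, list(chr1 = rownames(vals)), w = 10,
                       pseudocount = 1)
  expect_equal(nrow(wp2$log2fc), n - 10L + 1L)
  # windows never span chromosomes; a short chromosome yields none
  go3 <- list(chr1 = rownames(vals)[1:20], chr2 = rownames(vals)[21:25])
  wp3 <- window_log2fc(tum2, ctl2, go3, w = 10)
  expect_equal(nrow(wp3$log2fc), 11L)
  expect_identical(wp3$skipped_chroms, "chr2")
})

test_that("self-normalization of control cells gives near-zero windows", {
  b <- default_bundle()
  ctl <- to_cpm(b$control)
  half <- ncol(ctl$values) %/% 2
  a <- expression_matrix(ctl$values[, seq_len(half)], unit = "CPM")
  c2 <- expression_matrix(ctl$values[, -seq_len(half)], unit = "CPM")
  go <- order_genes(b$annotation, rownames(ctl$values))
  wp <- window_log2fc(a, c2, go, w = 100)
  # every window is zero in expectation: the cell-averaged profile stays flat
  expect_lt(mean(abs(rowMeans(wp$log2fc))), 0.05)
})

test_that("empirical quantile test is exact against a rank-count oracle", {
  set.seed(11)
  ctrl <- rnorm(200)
  # cell below all controls, direction loss -> present with tiny quantile
  res <- test_cnv_presence(c(low = min(ctrl) - 1), ctrl, "loss")
  expect_identical(res$call, "present")
  expect_lt(res$quantile, 0.005)
  # central value -> absent at q = 0.5
  res2 <- test_cnv_presence(c(mid = 100), as.numeric(1:199), "loss")
  expect_identical(res2$call, "absent")
  expect_equal(res2$quantile, 0.5)
  # mid-rank quantiles equal brute-force rank counts
  cells <- rnorm(50)
  res3 <- test_cnv_presence(setNames(cells, paste0("c", 1:50)), ctrl, "gain")
  brute <- sapply(cells, function(s)
    (sum(ctrl < s) + 0.5 * sum(ctrl == s)) / length(ctrl))
  expect_equal(res3$quantile, brute, tolerance = 1e-15)
  expect_identical(res3$call, ifelse(brute > 0.95, "present", "absent"))
})

test_that("degenerate or undersized controls are handled explicitly", {
  expect_error(test_cnv_presence(c(a = 1), rep(1, 5), "gain"), "control cells")
  expect_warning(res <- test_cnv_presence(c(a = 1), rep(2, 30), "gain"),
                 "degenerate")
  expect_identical(res$call, "absent")
  expect_identical(res$flag, "degenerate_control")
})

test_that("uniformly increasing segment counts never lowers the gain quantile", {
  set.seed(5)
  base_counts <- matrix(rpois(50 * 30, 20), 50,
                        dimnames = list(sprintf("g%02d", 1:50),
                                        sprintf("c%02d", 1:30)))
  seg_genes <- sprintf("g%02d", 1:10)
  ctrl <- segment_statistic(to_cpm(make_counts(base_counts)), seg_genes)
  for (mult in c(1, 1.5, 2, 4)) {
    boosted <- base_counts
    boosted[seg_genes, 1] <- round(boosted[seg_genes, 1] * mult)
    stat <- segment_statistic(to_cpm(make_counts(boosted)), seg_genes)[1]
    q <- test_cnv_presence(stat, ctrl, "gain")$quantile
    if (mult == 1) q0 <- q else expect_gte(q, q0)
  }
})
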