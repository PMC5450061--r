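test_that("well-separated point clouds split perfectly at k = 2", {
  set.seed(1)
  markers <- sprintf("M%d", 1:5)
  a <- matrix(rnorm(5 * 10, 0, 0.1), 5)
  b <- matrix(rnorm(5 * 8, 50, 0.1), 5)
  vals <- 2^cbind(a, b) - 1  # so log2(CPM+1) recovers the clouds
  vals[vals < 0] <- 0
  dimnames(vals) <- list(markers, sprintf("c%02d", 1:18))
  m <- make_cpm(vals)
  labels <- cluster_cells(m, markers, k = 2)
  expect_equal(length(unique(labels[1:10])), 1L)
  expect_equal(length(unique(labels[11:18])), 1L)
  expect_false(labels[1] == labels[18])
  expect_error(cluster_cells(m, markers, k = 50), "exceeds")
})

test_that("complete-linkage merge heights match a manual agglomeration", {
  # 5 points in 1-D with hand-checkable dendrogram
  x <- matrix(c(0, 1, 3, 7, 20), ncol = 1)
  got <- hclust(dist(x), method = "complete")
  expect_equal(sort(got$height), sort(oracle_complete_linkage_heights(x)),
               tolerance = 1e-12)
  # merges: {0,1} at 1, {3}U{0,1} at 3, {7}U{0..3} at 7, {20} last at 20
  expect_equal(sort(got$height), c(1, 3, 7, 20))
})

test_that("the evidence decision table matches its exhaustive enumeration", {
  grid <- expand.grid(
    cnv = c("supports_tumor", "supports_normal", "uninformative"),
    somatic = c(0L, 2L),
    germline = c("biallelic_observed", "monoallelic_consistent", "uninformative"),
    bial_loss = c(FALSE, TRUE),
    immune = c(FALSE, TRUE), stringsAsFactors = FALSE)
  # a biallelic-in-present-loss flag implies a biallelic germline summary
  grid <- grid[!(grid$bial_loss & grid$germline != "biallelic_observed"), ]
  ev <- data.frame(cell_id = sprintf("c%03d", seq_len(nrow(grid))),
                   cnv_vote = grid$cnv, somatic_n = grid$somatic,
                   germline_summary = grid$germline,
                   biallelic_in_present_loss = grid$bial_loss,
                   in_immune_cluster = grid$immune, stringsAsFactors = FALSE)
  got <- integrate_evidence(ev)
  want <- mapply(oracle_verdict, grid$cnv, grid$somatic, grid$germline,
                 grid$bial_loss, grid$immune)
  expect_identical(got$class, unname(want))
  # purity: identical evidence -> identical verdicts
  expect_identical(integrate_evidence(ev), got)
  # totality: every row got a class
  expect_true(all(got$class %in% c("neoplastic", "non_neoplastic", "ambiguous")))
  # no somatic-positive cell is ever non_neoplastic
  expect_false(any(got$class == "non_neoplastic" & got$somatic_vote >= 1))
  # conflicting strong evidence is flagged, never silent
  conflict_rows <- got[ev$somatic_n >= 1 & ev$biallelic_in_present_loss, ]
  expect_true(all(conflict_rows$class == "ambiguous" & conflict_rows$conflict))
})

test_that("all-uninformative evidence yields ambiguous; the textbook immune cell yields non_neoplastic", {
  ev <- data.frame(
    cell_id = c("void", "immune"),
    cnv_vote = c("uninformative", "supports_normal"),
    somatic_n = c(0L, 0L),
    germline_summary = c("uninformative", "biallelic_observed"),
    biallelic_in_present_loss = FALSE,
    in_immune_cluster = c(FALSE, TRUE), stringsAsFactors = FALSE)
  got <- integrate_evidence(ev)
  expect_identical(got$class, c("ambiguous", "non_neoplastic"))
})

test_that("immune-majority cluster is the one with higher immune-marker expression", {
  b <- default_bundle()
  tum <- to_cpm(b$tumor)
  mk <- default_marker_genes()
  labels <- cluster_cells(tum, unlist(mk), k = 2)
  imm <- immune_majority_cluster(tum, labels, mk)
  truth <- b$truth$cells
  immune_cells <- truth$cell_id[truth$class == "immune"]
  expect_true(all(labels[immune_cells] == imm))
})
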