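# Independent brute-force oracles and tiny fixture builders.  These are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the implementation they check.

# sliding-window means by explicit loops
oracle_window_means <- function(V, w) {
  n <- nrow(V)
  out <- matrix(NA_real_, n - w + 1L, ncol(V))
  for (i in seq_len(n - w + 1L))
    for (j in seq_len(ncol(V)))
      out[i, j] <- mean(V[i:(i + w - 1L), j])
  out
}

# naive complete-linkage agglomeration; returns merge heights in order
oracle_complete_linkage_heights <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(D[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# literal transcription of the documented verdict decision table
oracle_verdict <- function(cnv, somatic_n, germline, bial_loss, immune_cl) {
  if (somatic_n >= 1 && bial_loss) return("ambiguous")
  if ((cnv == "supports_tumor" || somatic_n >= 1) && !bial_loss)
    return("neoplastic")
  if (cnv == "supports_normal" && somatic_n == 0 &&
      germline %in% c("biallelic_observed", "uninformative") && immune_cl)
    return("non_neoplastic")
  "ambiguous"
}

# crosstalk filter by explicit loops over cells and pairs
oracle_crosstalk <- function(sv, rv, db, pct_min = 20, mean_min = 2) {
  keep <- logical(nrow(db))
  for (i in seq_len(nrow(db))) {
    lig <- db$ligand[i]; rec <- db$receptor[i]
    l <- if (lig %in% rownames(sv)) sv[lig, ] else rep(0, ncol(sv))
    r <- if (rec %in% rownames(rv)) rv[rec, ] else rep(0, ncol(rv))
    lp <- 100 * sum(l > 0) / length(l); rp <- 100 * sum(r > 0) / length(r)
    keep[i] <- lp >= pct_min && mean(l) > mean_min &&
               rp >= pct_min && mean(r) > mean_min
  }
  db[keep, , drop = FALSE]
}

# per-cell somatic tallies by exhaustive counting
oracle_tally <- function(counts, sites, min_alt, cells) {
  sk <- paste0(sites$chrom, ":", sites$pos)
  sapply(cells, function(cl) {
    n <- 0L
    for (i in seq_len(nrow(counts))) {
      if (counts$cell_id[i] != cl) next
      if (!paste0(counts$chrom[i], ":", counts$pos[i]) %in% sk) next
      if (counts$alt_count[i] >= min_alt) n <- n + 1L
    }
    n
  })
}

# exhaustive maximal-run scan over depth-ratio bins of one chromosome
oracle_runs <- function(ratio, starts, ends, delta, min_span) {
  st <- ifelse(ratio > 1 + delta, 1L, ifelse(ratio < 1 - delta, -1L, 0L))
  segs <- list()
  i <- 1L
  while (i <= length(st)) {
    if (st[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < length(st) && st[j + 1L] == st[i]) j <- j + 1L
    if (ends[j] - starts[i] + 1 >= min_span)
      segs[[length(segs) + 1L]] <- list(start = starts[i], end = ends[j],
                                        dir = if (st[i] > 0) "gain" else "loss")
    i <- j + 1L
  }
  segs
}

# small CPM expression matrix from a plain matrix
make_cpm <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  expression_matrix(values, unit = "CPM")
}

make_counts <- function(values) {
  m <- make_cpm(values)
  expression_matrix(m$values, unit = "counts")
}

# cached default simulation bundle shared across test files
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle(simulation_config(seed = 20240917))
    cache
  }
})
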