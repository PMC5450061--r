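#' Call large-scale CNV segments from exome depth ratios
#'
#' Scans tumor/blood depth-ratio bins for maximal runs of consecutive bins
#' all above `1 + delta` (gain) or all below `1 - delta` (loss).  Runs
#' spanning at least `min_span` base pairs become segments; a segment
#' covering at least 90% of its chromosome's binned span is flagged as
#' whole-chromosome.  Only such large-scale events are reliable enough to
#' test per cell in scRNA-seq.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`,
#'   `depth_ratio` (tumor/blood, positive).
#' @param delta half-width of the neutral band around ratio 1 (default 0.2).
#' @param min_span minimum segment span in bp (default 10 Mb).
#' @return data.frame of segments: `segment_id`, `chrom`, `start`, `end`,
#'   `direction`, `depth_ratio` (mean over bins), `n_bins`, `whole_chrom`.
#' @export
call_exome_segments <- function(bins, delta = 0.2, min_span = 1e7) {
  cols <- c("chrom", "start", "end", "depth_ratio")
  if (!all(cols %in% names(bins))) stop("bins need columns ", paste(cols, collapse = ", "))
  empty <- data.frame(segment_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      direction = character(), depth_ratio = double(),
                      n_bins = integer(), whole_chrom = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(bins) == 0L) {
    warning("empty depth-ratio bin set; no segments called")
    return(empty)
  }
  out <- list()
  for (ch in natural_chrom_order(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    span_ch <- max(b$end) - min(b$start) + 1
    state <- ifelse(b$depth_ratio > 1 + delta, 1L,
                    ifelse(b$depth_ratio < 1 - delta, -1L, 0L))
    r <- rle(state)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      i <- idx_start[k]:idx_end[k]
      seg_start <- min(b$start[i]); seg_end <- max(b$end[i])
      if (seg_end - seg_start + 1 < min_span) next
      dir <- if (r$values[k] > 0L) "gain" else "loss"
      out[[length(out) + 1L]] <- data.frame(
        segment_id = sprintf("%s:%d-%d:%s", ch, seg_start, seg_end, dir),
        chrom = ch, start = seg_start, end = seg_end, direction = dir,
        depth_ratio = mean(b$depth_ratio[i]), n_bins = length(i),
        whole_chrom = (seg_end - seg_start + 1) >= 0.9 * span_ch,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes belonging to a CNV segment
#'
#' Membership is by transcription start: a gene is in the segment when its
#' annotated start falls inside the segment interval.  Whole-chromosome
#' segments take every annotated gene on the chromosome.
#'
#' @param segment one row of the [call_exome_segments()] table.
#' @param ann annotation data.frame.
#' @return character vector of gene ids.
#' @export
segment_genes <- function(segment, ann) {
  on_chrom <- ann[ann$chrom == segment$chrom, , drop = FALSE]
  if (isTRUE(segment$whole_chrom)) return(on_chrom$gene_id)
  on_chrom$gene_id[on_chrom$start >= segment$start & on_chrom$start <= segment$end]
}

#' Per-cell segment statistic: sum-total CPM over segment genes
#'
#' @param m CPM [expression_matrix()].
#' @param genes gene ids of the segment.
#' @return named numeric vector, one value per cell.
#' @export
segment_statistic <- function(m, genes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("segment statistic requires a CPM matrix")
  g <- intersect(genes, rownames(m$values))
  if (length(g) == 0L) stop("no segment genes present in the matrix")
  colSums(m$values[g, , drop = FALSE])
}

# internal: sliding window means over the rows of a genes x cells matrix,
# step 1, via cumulative sums; returns (n - w + 1) x cells
window_means <- function(V, w) {
  n <- nrow(V)
  cs <- apply(V, 2L, cumsum)
  if (n == 1L) cs <- matrix(cs, nrow = 1L, dimnames = dimnames(V))
  cs <- rbind(0, cs)
  (cs[(w + 1L):(n + 1L), , drop = FALSE] - cs[1L:(n - w + 1L), , drop = FALSE]) / w
}

#' Windowed expression log2 fold-change against a non-malignant control
#'
#' For each cell, mean CPM is computed in sliding windows of `w` adjacent
#' genes (step 1, windows never spanning chromosome boundaries) and
#' compared, as a log2 ratio, to the mean over control cells of the same
#' window statistic.  Large-scale CNVs appear as contiguous stretches of
#' shifted windows: a clonal single-copy loss is expected near -1, a
#' single-copy gain near +0.585.
#'
#' @param tumor,control CPM [expression_matrix()] objects sharing genes.
#' @param gene_order per-chromosome gene ordering from [order_genes()].
#' @param w window size in genes (default 100).
#' @param pseudocount CPM pseudocount added inside the ratio (default 1)
#'   so silent windows stay finite.
#' @return object of class `WindowProfile`: list with `log2fc` (windows x
#'   cells matrix), `windows` (data.frame `chrom`, `window_index`,
#'   `mid_gene`), `w`, `pseudocount`, `skipped_chroms`.
#' @export
window_log2fc <- function(tumor, control, gene_order, w = 100, pseudocount = 1) {
  stopifnot(inherits(tumor, "ExpressionMatrix"), inherits(control, "ExpressionMatrix"))
  if (tumor$unit != "CPM" || control$unit != "CPM")
    stop("window_log2fc requires CPM matrices")
  if (w < 2) stop("window size must be >= 2")
  common <- intersect(rownames(tumor$values), rownames(control$values))
  if (length(common) == 0L) stop("tumor and control share no genes")
  fc <- list(); meta <- list(); skipped <- character()
  for (ch in names(gene_order)) {
    genes <- intersect(gene_order[[ch]], common)
    n <- length(genes)
    if (n < w) {
      if (n > 0L) skipped <- c(skipped, ch)
      next
    }
    wt <- window_means(tumor$values[genes, , drop = FALSE], w)
    wc <- window_means(control$values[genes, , drop = FALSE], w)
    ctrl_mean <- rowMeans(wc)
    fc[[ch]] <- log2((wt + pseudocount) / (ctrl_mean + pseudocount))
    mid <- genes[seq_len(n - w + 1L) + (w - 1L) %/% 2L]
    meta[[ch]] <- data.frame(chrom = ch, window_index = seq_len(n - w + 1L),
                             mid_gene = mid, stringsAsFactors = FALSE)
  }
  if (length(fc) == 0L)
    stop("no chromosome holds at least one full window of ", w, " genes")
  structure(list(log2fc = do.call(rbind, fc),
                 windows = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 w = w, pseudocount = pseudocount, skipped_chroms = skipped),
            class = "WindowProfile")
}

#' @export
print.WindowProfile <- function(x, ...) {
  cat(sprintf("WindowProfile: %d windows (w = %d) x %d cells over %d chromosome(s)\n",
              nrow(x$log2fc), x$w, ncol(x$log2fc),
              length(unique(x$windows$chrom))))
  invisible(x)
}

#' Empirical per-cell test for CNV presence
#'
#' Places each cell's segment statistic within the empirical distribution
#' of the same statistic over control cells (mid-rank quantile for ties)
#' and calls the exome-defined CNV present when the cell falls outside the
#' one-sided `alpha` significance band of the control distribution: above
#' `1 - alpha` for a gain, below `alpha` for a loss.  Two-sided testing is
#' available via `sided = "two"` (band `alpha/2` in each tail).
#'
#' @param stat named numeric vector of per-cell segment statistics.
#' @param control_stats the same statistic over control cells.
#' @param direction `"gain"` or `"loss"` (from exome-seq).
#' @param alpha significance level of the control band (default 0.05).
#' @param min_controls minimum number of control cells required (default 20).
#' @param sided `"one"` (default, direction-aware) or `"two"`.
#' @return data.frame: `cell_id`, `statistic`, `quantile`, `call`
#'   (`"present"`/`"absent"`), `flag` (`"ok"` or `"degenerate_control"`).
#' @export
test_cnv_presence <- function(stat, control_stats,
                              direction = c("gain", "loss"),
                              alpha = 0.05, min_controls = 20,
                              sided = c("one", "two")) {
  direction <- match.arg(direction)
  sided <- match.arg(sided)
  n <- length(control_stats)
  if (n < min_controls)
    stop(sprintf("only %d control cells; need at least %d", n, min_controls))
  cells <- names(stat) %||% as.character(seq_along(stat))
  if (length(unique(control_stats)) == 1L) {
    warning("degenerate control distribution (all values equal); calling absent")
    return(data.frame(cell_id = cells, statistic = unname(stat),
                      quantile = NA_real_, call = "absent",
                      flag = "degenerate_control", stringsAsFactors = FALSE))
  }
  q <- vapply(stat, function(s)
    (sum(control_stats < s) + 0.5 * sum(control_stats == s)) / n, 0)
  present <- if (sided == "two") {
    a <- alpha / 2
    if (direction == "gain") q > 1 - a | q < a else q < a | q > 1 - a
  } else if (direction == "gain") q > 1 - alpha else q < alpha
  data.frame(cell_id = cells, statistic = unname(stat), quantile = unname(q),
             call = ifelse(present, "present", "absent"), flag = "ok",
             stringsAsFactors = FALSE)
}

#' Test every exome segment in every cell
#'
#' Convenience wrapper: computes the sum-total-CPM statistic of each
#' segment in tumor and control cells and applies [test_cnv_presence()].
#' Segments with no genes in the matrices are skipped with a warning.
#'
#' @param tumor,control CPM [expression_matrix()] objects.
#' @param segments segment table from [call_exome_segments()].
#' @param ann annotation data.frame.
#' @inheritParams test_cnv_presence
#' @return data.frame with one row per cell x segment: `cell_id`,
#'   `segment_id`, `chrom`, `direction`, `statistic`, `quantile`, `call`,
#'   `flag`.
#' @export
call_cnv_cells <- function(tumor, control, segments, ann, alpha = 0.05,
                           min_controls = 20, sided = "one") {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    genes <- segment_genes(seg, ann)
    genes <- intersect(genes, rownames(tumor$values))
    if (length(genes) == 0L) {
      warning("segment ", seg$segment_id, " has no genes in the matrix; skipped")
      next
    }
    calls <- test_cnv_presence(segment_statistic(tumor, genes),
                               segment_statistic(control, genes),
                               direction = seg$direction, alpha = alpha,
                               min_controls = min_controls, sided = sided)
    calls$segment_id <- seg$segment_id
    calls$chrom <- seg$chrom
    calls$direction <- seg$direction
    out[[length(out) + 1L]] <- calls
  }
  if (length(out) == 0L)
    stop("no segment could be tested")
  res <- do.call(rbind, out)
  res[, c("cell_id", "segment_id", "chrom", "direction",
          "statistic", "quantile", "call", "flag")]
}

#' Aggregate per-segment CNV calls into a per-cell vote
#'
#' A cell's CNV evidence `supports_tumor` when at least one exome-defined
#' segment is called present, `supports_normal` when every segment was
#' tested cleanly and called absent, and is `uninformative` otherwise
#' (e.g. degenerate control distribution).
#'
#' @param calls table from [call_cnv_cells()].
#' @return data.frame `cell_id`, `cnv_vote`.
#' @export
aggregate_cnv_votes <- function(calls) {
  split_calls <- split(calls, calls$cell_id)
  vote <- vapply(split_calls, function(d) {
    if (any(d$call == "present")) "supports_tumor"
    else if (all(d$call == "absent" & d$flag == "ok")) "supports_normal"
    else "uninformative"
  }, "")
  data.frame(cell_id = names(vote), cnv_vote = unname(vote),
             stringsAsFactors = FALSE)
}
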