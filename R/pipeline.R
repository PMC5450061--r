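#' Analysis parameters of the classification pipeline
#'
#' Central place for every tunable threshold, with the defaults the
#' methods vignette motivates.
#'
#' @param ... named overrides of any default.
#' @return a named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    window_size = 100L, pseudocount = 1, alpha = 0.05, sided = "one",
    min_controls = 20L,
    delta = 0.2, min_span = 1e7,
    het_tol = 0.1, shift_min = 0.15, min_reads = 3L, min_minor = 2L,
    min_alt = 1L,
    k = 2L, marker_genes = default_marker_genes(),
    cycle_gene_sets = default_cycle_genes(),
    cycle_threshold = 1.2, phase_margin = 0.3,
    sender_pct_min = 20, sender_mean_min = 2,
    receiver_pct_min = 20, receiver_mean_min = 2,
    receiver_any_expression = FALSE, expressed_floor = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full four-evidence classification pipeline
#'
#' Executes, in order: CPM normalization, genomic gene ordering, exome
#' segment calling, windowed CNV profiling, per-cell CNV testing,
#' informative-germline selection and allele-pattern calling, somatic
#' tallying, marker-space clustering, and evidence integration.  When a
#' ligand-receptor database is present and both verdict classes are
#' populated, candidate crosstalk from non-neoplastic (sender) to
#' neoplastic (receiver) cells is inferred as well.  Identical inputs and
#' parameters produce identical outputs.
#'
#' @param bundle input bundle: from [simulate_bundle()], [read_bundle()],
#'   or assembled by hand (`tumor`, `control`, `annotation`, `depth_bins`,
#'   `germline_sites`, `somatic_sites`, `allele_counts`, optional
#'   `lr_pairs`).
#' @param params a [pipeline_params()] list.
#' @return list of result tables: `verdicts`, `evidence`, `segments`,
#'   `windows` (a `WindowProfile`), `cnv_calls`, `informative_sites`,
#'   `allele_patterns` (list `sites`/`cells`), `somatic_tally`,
#'   `clusters`, `immune_cluster`, `cycle`, `interactions` (or NULL),
#'   `params`.
#' @export
run_pipeline <- function(bundle, params = pipeline_params()) {
  tumor <- run_stage("normalize", {
    if (bundle$tumor$unit == "counts") to_cpm(bundle$tumor) else bundle$tumor
  })
  control <- run_stage("normalize", {
    if (bundle$control$unit == "counts") to_cpm(bundle$control) else bundle$control
  })
  cells <- colnames(tumor$values)

  gene_order <- run_stage("order_genes",
    order_genes(bundle$annotation, rownames(tumor$values)))

  segments <- run_stage("call_exome_segments",
    call_exome_segments(bundle$depth_bins, delta = params$delta,
                        min_span = params$min_span))

  windows <- run_stage("window_log2fc",
    window_log2fc(tumor, control, gene_order, w = params$window_size,
                  pseudocount = params$pseudocount))

  cnv_calls <- run_stage("test_cnv_presence",
    call_cnv_cells(tumor, control, segments, bundle$annotation,
                   alpha = params$alpha, min_controls = params$min_controls,
                   sided = params$sided))
  cnv_votes <- aggregate_cnv_votes(cnv_calls)

  info_sites <- run_stage("select_informative_germline",
    select_informative_germline(bundle$germline_sites, segments,
                                het_tol = params$het_tol,
                                shift_min = params$shift_min))
  patterns <- run_stage("call_allele_pattern", {
    if (nrow(info_sites) == 0L) {
      list(sites = NULL,
           cells = data.frame(cell_id = character(), n_covered = integer(),
                              n_biallelic = integer(), summary = character(),
                              stringsAsFactors = FALSE))
    } else {
      keys <- site_key(info_sites$chrom, info_sites$pos)
      ac <- bundle$allele_counts
      call_allele_pattern(ac[site_key(ac$chrom, ac$pos) %in% keys, , drop = FALSE],
                          info_sites, min_reads = params$min_reads,
                          min_minor = params$min_minor)
    }
  })

  tally <- run_stage("tally_somatic",
    tally_somatic(bundle$allele_counts, bundle$somatic_sites,
                  min_alt = params$min_alt, cells = cells))

  all_markers <- unlist(params$marker_genes, use.names = FALSE)
  clusters <- run_stage("cluster_cells",
    cluster_cells(tumor, all_markers, k = params$k))
  immune_cluster <- run_stage("cluster_cells",
    immune_majority_cluster(tumor, clusters, params$marker_genes))

  evidence <- run_stage("integrate_evidence", {
    germ <- patterns$cells$summary[match(cells, patterns$cells$cell_id)]
    germ[is.na(germ)] <- "uninformative"
    # biallelic germline site inside a loss segment called present in
    # the same cell: the direct contradiction of carrying that loss
    bial <- rep(FALSE, length(cells))
    if (!is.null(patterns$sites)) {
      bs <- patterns$sites[patterns$sites$call == "biallelic" &
                           patterns$sites$segment_direction == "loss", ,
                           drop = FALSE]
      if (nrow(bs)) {
        present <- cnv_calls[cnv_calls$call == "present", , drop = FALSE]
        hit <- paste(bs$cell_id, bs$segment_id) %in%
          paste(present$cell_id, present$segment_id)
        bial[match(unique(bs$cell_id[hit]), cells)] <- TRUE
      }
    }
    data.frame(cell_id = cells,
               cnv_vote = cnv_votes$cnv_vote[match(cells, cnv_votes$cell_id)],
               somatic_n = tally$n_somatic_expressed[match(cells, tally$cell_id)],
               germline_summary = germ,
               biallelic_in_present_loss = bial,
               in_immune_cluster = unname(clusters[cells]) == immune_cluster,
               stringsAsFactors = FALSE)
  })
  verdicts <- run_stage("integrate_evidence", integrate_evidence(evidence))

  cycle <- run_stage("cycle_scores",
    cycle_scores(tumor, params$cycle_gene_sets,
                 threshold = params$cycle_threshold,
                 margin = params$phase_margin))

  interactions <- NULL
  if (!is.null(bundle$lr_pairs)) {
    senders <- verdicts$cell_id[verdicts$class == "non_neoplastic"]
    receivers <- verdicts$cell_id[verdicts$class == "neoplastic"]
    if (length(senders) > 0L && length(receivers) > 0L) {
      interactions <- run_stage("infer_interactions", {
        sub <- function(m, cc) expression_matrix(
          m$values[, cc, drop = FALSE], unit = "CPM")
        infer_interactions(sub(tumor, senders), sub(tumor, receivers),
                           bundle$lr_pairs,
                           sender_pct_min = params$sender_pct_min,
                           sender_mean_min = params$sender_mean_min,
                           receiver_pct_min = params$receiver_pct_min,
                           receiver_mean_min = params$receiver_mean_min,
                           receiver_any_expression = params$receiver_any_expression,
                           expressed_floor = params$expressed_floor)
      })
    }
  }

  list(verdicts = verdicts, evidence = evidence, segments = segments,
       windows = windows, cnv_calls = cnv_calls,
       informative_sites = info_sites, allele_patterns = patterns,
       somatic_tally = tally, clusters = clusters,
       immune_cluster = immune_cluster, cycle = cycle,
       interactions = interactions, params = params)
}

#' Write pipeline result tables and a JSON run summary
#'
#' One TSV per result table plus `run_summary.json` holding the
#' parameters, row counts and package version.  Output is deterministic
#' for identical results.
#'
#' @param res result list from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_plain(res$verdicts, p("verdicts.tsv"))
  write_tsv_plain(res$segments, p("segments.tsv"))
  write_tsv_plain(res$cnv_calls, p("cnv_calls.tsv"))
  wp <- res$windows
  win_long <- data.frame(
    wp$windows[rep(seq_len(nrow(wp$windows)), ncol(wp$log2fc)), ],
    cell_id = rep(colnames(wp$log2fc), each = nrow(wp$log2fc)),
    log2fc = as.vector(wp$log2fc), stringsAsFactors = FALSE)
  write_tsv_plain(win_long[, c("cell_id", "chrom", "window_index",
                               "mid_gene", "log2fc")], p("windows.tsv"))
  write_tsv_plain(res$informative_sites, p("informative_sites.tsv"))
  if (!is.null(res$allele_patterns$sites))
    write_tsv_plain(res$allele_patterns$sites, p("allele_pattern_sites.tsv"))
  write_tsv_plain(res$allele_patterns$cells, p("allele_pattern_cells.tsv"))
  write_tsv_plain(res$somatic_tally, p("somatic_tally.tsv"))
  write_tsv_plain(data.frame(cell_id = names(res$clusters),
                             cluster = as.integer(res$clusters)),
                  p("clusters.tsv"))
  write_tsv_plain(res$cycle, p("cycle_scores.tsv"))
  if (!is.null(res$interactions))
    write_tsv_plain(res$interactions, p("interactions.tsv"))
  summary <- list(
    package = "cellverdict",
    version = as.character(utils::packageVersion("cellverdict")),
    parameters = res$params[setdiff(names(res$params),
                                    c("marker_genes", "cycle_gene_sets"))],
    n_cells = nrow(res$verdicts),
    n_segments = nrow(res$segments),
    class_counts = as.list(table(res$verdicts$class)),
    n_interactions = if (is.null(res$interactions)) 0L
                     else nrow(res$interactions))
  jsonlite::write_json(summary, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
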