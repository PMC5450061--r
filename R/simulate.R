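#' Simulation configuration for a whole-tumor scRNA-seq dataset
#'
#' Builds the parameter list of the synthetic-data generator.  The default
#' scenario emulates the structure of a primary glioblastoma biopsy with a
#' matched blood/tumor exome: a clonal gain of chromosome 7 and loss of
#' chromosome 10 carried by every neoplastic cell, a minority (10%)
#' infiltrating immune population without CNVs, heterozygous germline SNVs
#' in the loss region expressed monoallelically in neoplastic cells,
#' sparsely expressed exome-validated somatic SNVs (about two thirds of
#' cells carry at least one), cycling tumor subpopulations, and
#' macrophage-expressed ligands paired with tumor-expressed receptors.
#' Counts follow a negative-binomial model with log-normal gene base
#' means, log-normal cell library factors and logistic mean-dependent
#' dropout.
#'
#' @param ... named overrides of any default listed below.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_genes = 2400L, genes_per_chrom = 200L,
    n_tumor_cells = 180L, n_immune_cells = 20L, n_control_cells = 120L,
    cnv_specs = list(list(chrom = "chr7", direction = "gain", fold = 1.5),
                     list(chrom = "chr10", direction = "loss", fold = 0.5)),
    n_somatic_snvs = 30L, somatic_expression_rate = 0.053,
    n_germline_het_snvs = 12L, germline_in_loss = 8L,
    allelic_dropout = 0.2, allele_site_depth = 8, somatic_site_depth = 2,
    nb_dispersion = 0.3,
    base_mean_log = log(3), base_mean_sdlog = 1.2,
    library_sdlog = 0.25,
    dropout_mid = 0.3, dropout_slope = 2,
    cycling_fraction = 0.2, cycle_boost = 8, cycle_offboost = 4,
    marker_boost = 6, marker_off = 0.2, tam_boost = 8, tam_off = 0.1,
    ligand_boost = 4, ligand_off = 0.3, receptor_boost = 3,
    n_lr_decoy = 50L, decoy_base_mean = 0.02,
    depth_bin_size = 1e6, depth_ratio_noise_sd = 0.03,
    gene_spacing = 1e5, gene_length = 1000L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  counts <- c("n_genes", "genes_per_chrom", "n_tumor_cells", "n_control_cells",
              "n_somatic_snvs", "n_germline_het_snvs")
  for (f in counts) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$n_immune_cells < 0) stop("n_immune_cells must be >= 0")
  for (s in cfg$cnv_specs) if (s$fold <= 0) stop("CNV folds must be > 0")
  probs <- c("somatic_expression_rate", "allelic_dropout", "cycling_fraction")
  for (f in probs) if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  if (cfg$germline_in_loss > cfg$n_germline_het_snvs)
    stop("germline_in_loss exceeds n_germline_het_snvs")
  if (cfg$germline_in_loss > cfg$genes_per_chrom)
    stop("more germline loss-region SNVs than genes on the loss chromosome")
  if (cfg$n_somatic_snvs > cfg$n_genes)
    stop("more somatic SNVs than genes")
  cfg$n_chromosomes <- as.integer(ceiling(cfg$n_genes / cfg$genes_per_chrom))
  class(cfg) <- "SimulationConfig"
  cfg
}

# logistic mean-dependent dropout probability
dropout_prob <- function(mu, mid, slope) 1 / (1 + (mu / mid)^slope)

# draw a counts matrix: NB noise on the mean matrix, then dropout
draw_counts <- function(mu, dispersion, mid, slope) {
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  keep <- matrix(stats::rbinom(length(mu), 1L,
                               1 - dropout_prob(mu, mid, slope)),
                 nrow = nrow(mu))
  counts * keep
}

#' Simulate a complete tumor/control dataset bundle
#'
#' Generates everything the pipeline consumes — tumor-biopsy and control
#' expression matrices, gene annotation, exome depth-ratio bins, germline
#' and somatic variant tables, per-cell allele counts at variant sites, a
#' ligand-receptor database with planted true pairs and decoys — plus
#' full truth labels.  Fully reproducible from `cfg$seed`.
#'
#' Generative model: counts for gene g in cell c are negative binomial
#' with mean `base_g * lib_c * fold_g(class) * boost_g(class, state)` and
#' dispersion `nb_dispersion`, thinned by logistic mean-dependent dropout.
#' Neoplastic cells carry every configured CNV (clonal); immune and
#' control cells carry none.  Germline heterozygous sites inside a loss
#' segment emit reads from a single retained haplotype in neoplastic
#' cells and from both haplotypes elsewhere, with per-allele dropout and
#' zero sequencing error; allele counts arise only at sites whose gene is
#' expressed in the cell.  Somatic sites emit alternate reads only in
#' neoplastic cells, at `somatic_expression_rate` per expressed site.
#'
#' @param cfg a [simulation_config()].
#' @return a bundle: list with `tumor`, `control`
#'   ([expression_matrix()] objects, raw counts), `annotation`,
#'   `depth_bins`, `germline_sites`, `somatic_sites`, `allele_counts`,
#'   `lr_pairs`, `truth` (list: `cells`, `cnv_specs`, `germline`,
#'   `lr_true`), `config`.
#' @export
simulate_bundle <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)

  ## genome layout: genes laid uniformly along synthetic chromosomes
  n_chr <- cfg$n_chromosomes
  chrom_of <- rep(paste0("chr", seq_len(n_chr)),
                  each = cfg$genes_per_chrom)[seq_len(cfg$n_genes)]
  idx_in_chr <- unlist(lapply(table(factor(chrom_of, unique(chrom_of))), seq_len),
                       use.names = FALSE)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ann <- data.frame(gene_id = gene_ids, chrom = chrom_of,
                    start = (idx_in_chr - 1L) * cfg$gene_spacing + 1L,
                    end = (idx_in_chr - 1L) * cfg$gene_spacing + cfg$gene_length,
                    strand = ".", stringsAsFactors = FALSE)

  ## base expression and special gene roles
  base <- stats::rlnorm(cfg$n_genes, cfg$base_mean_log, cfg$base_mean_sdlog)
  names(base) <- gene_ids
  med <- exp(cfg$base_mean_log)
  markers <- default_marker_genes()
  cyc <- default_cycle_genes()
  pick <- function(chrom, n, offset = 10L, by = 15L) {
    i <- which(chrom_of == chrom)[offset + by * (seq_len(n) - 1L)]
    if (anyNA(i)) stop("chromosome ", chrom, " too small for special genes")
    i
  }
  i_tum <- pick("chr3", length(markers$tumor))
  i_imm <- pick("chr4", length(markers$immune))
  i_g1s <- pick("chr11", length(cyc$g1s))
  i_g2m <- pick("chr12", length(cyc$g2m))
  lr_true <- data.frame(
    ligand = c("HBEGF", "IL6", "TGFB1", "PDGFB", "GAS6"),
    receptor = c("EGFR", "IL6ST", "TGFBR1", "PDGFRB", "AXL"),
    stringsAsFactors = FALSE)
  i_lig <- pick("chr5", nrow(lr_true))
  i_rec <- pick("chr6", nrow(lr_true))
  n_decoy <- cfg$n_lr_decoy
  lr_decoy <- data.frame(ligand = sprintf("LIG%03d", seq_len(n_decoy)),
                         receptor = sprintf("REC%03d", seq_len(n_decoy)),
                         stringsAsFactors = FALSE)
  i_dlig <- pick("chr1", n_decoy, offset = 5L, by = 3L)
  i_drec <- pick("chr2", n_decoy, offset = 5L, by = 3L)
  gene_ids[i_tum] <- markers$tumor;  gene_ids[i_imm] <- markers$immune
  gene_ids[i_g1s] <- cyc$g1s;        gene_ids[i_g2m] <- cyc$g2m
  gene_ids[i_lig] <- lr_true$ligand; gene_ids[i_rec] <- lr_true$receptor
  gene_ids[i_dlig] <- lr_decoy$ligand; gene_ids[i_drec] <- lr_decoy$receptor
  ann$gene_id <- gene_ids
  names(base) <- gene_ids
  # fixed moderate base means keep marker/cycle scores on a stable scale
  base[c(i_tum, i_imm, i_g1s, i_g2m, i_lig, i_rec)] <- med
  # decoys: first half fails on the ligand side, second half on the receptor
  half <- n_decoy %/% 2L
  fail_lig <- seq_len(half); fail_rec <- setdiff(seq_len(n_decoy), fail_lig)
  base[i_dlig[fail_lig]] <- cfg$decoy_base_mean
  base[i_dlig[fail_rec]] <- med
  base[i_drec[fail_lig]] <- med
  base[i_drec[fail_rec]] <- cfg$decoy_base_mean

  ## population multipliers
  mult_neo <- rep(1, cfg$n_genes)
  mult_imm <- rep(1, cfg$n_genes)
  mult_neo[i_tum] <- cfg$marker_boost;  mult_imm[i_tum] <- cfg$marker_off
  mult_neo[i_imm] <- cfg$tam_off;       mult_imm[i_imm] <- cfg$tam_boost
  mult_neo[i_rec] <- cfg$receptor_boost
  mult_neo[c(i_lig, i_dlig)] <- cfg$ligand_off
  mult_imm[c(i_lig, i_dlig)] <- cfg$ligand_boost
  mult_imm[i_drec] <- cfg$ligand_off

  ## CNV fold per gene (neoplastic cells only)
  fold <- rep(1, cfg$n_genes)
  for (s in cfg$cnv_specs) fold[chrom_of == s$chrom] <- s$fold

  ## cells
  n_bio <- cfg$n_tumor_cells + cfg$n_immune_cells
  bio_ids <- sprintf("cell_%03d", seq_len(n_bio))
  class <- sample(rep(c("neoplastic", "immune"),
                      c(cfg$n_tumor_cells, cfg$n_immune_cells)))
  cycling <- class == "neoplastic" &
    stats::runif(n_bio) < cfg$cycling_fraction
  phase <- ifelse(cycling, sample(c("G1/S", "G2/M"), n_bio, replace = TRUE),
                  "none")
  lib_bio <- stats::rlnorm(n_bio, 0, cfg$library_sdlog)
  ctrl_ids <- sprintf("ctrl_%03d", seq_len(cfg$n_control_cells))
  lib_ctrl <- stats::rlnorm(cfg$n_control_cells, 0, cfg$library_sdlog)

  ## mean matrices and counts
  mu_bio <- matrix(0, cfg$n_genes, n_bio, dimnames = list(gene_ids, bio_ids))
  for (c_i in seq_len(n_bio)) {
    g_mult <- if (class[c_i] == "neoplastic") mult_neo * fold else mult_imm
    if (cycling[c_i]) {
      on <- if (phase[c_i] == "G1/S") i_g1s else i_g2m
      off <- if (phase[c_i] == "G1/S") i_g2m else i_g1s
      g_mult <- g_mult * 1  # copy before modifying
      g_mult[on] <- g_mult[on] * cfg$cycle_boost
      g_mult[off] <- g_mult[off] * cfg$cycle_offboost
    }
    mu_bio[, c_i] <- base * g_mult * lib_bio[c_i]
  }
  tumor_counts <- draw_counts(mu_bio, cfg$nb_dispersion,
                              cfg$dropout_mid, cfg$dropout_slope)
  mu_ctrl <- outer(base, lib_ctrl)
  dimnames(mu_ctrl) <- list(gene_ids, ctrl_ids)
  ctrl_counts <- draw_counts(mu_ctrl, cfg$nb_dispersion,
                             cfg$dropout_mid, cfg$dropout_slope)

  ## exome depth-ratio bins
  bins <- list()
  for (ch in unique(chrom_of)) {
    span <- max(ann$end[ann$chrom == ch])
    starts <- seq(1, span, by = cfg$depth_bin_size)
    f <- fold[match(ch, chrom_of)]
    bins[[ch]] <- data.frame(
      chrom = ch, start = as.integer(starts),
      end = as.integer(pmin(starts + cfg$depth_bin_size - 1, span)),
      depth_ratio = f * exp(stats::rnorm(length(starts), 0,
                                         cfg$depth_ratio_noise_sd)),
      stringsAsFactors = FALSE)
  }
  depth_bins <- do.call(rbind, c(bins, list(make.row.names = FALSE)))

  ## germline heterozygous sites: most in the loss region (highest-expressed
  ## genes there, so single-cell coverage is realistic), the rest neutral
  loss_chroms <- vapply(Filter(function(s) s$direction == "loss",
                               cfg$cnv_specs), `[[`, "", "chrom")
  if (length(loss_chroms) == 0L && cfg$germline_in_loss > 0L)
    stop("config plants germline SNVs in a loss region but no loss is specified")
  bases4 <- c("A", "C", "G", "T")
  mk_sites <- function(gidx, vaf_tumor) {
    ref <- sample(bases4, length(gidx), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases4, r), 1L), "")
    data.frame(chrom = ann$chrom[gidx], pos = ann$start[gidx] + 50L,
               ref = ref, alt = unname(alt), kind = "germline",
               vaf_blood = pmin(pmax(
                 0.5 + stats::rnorm(length(gidx), 0, 0.005), 0.45), 0.55),
               vaf_tumor = vaf_tumor, gene_id = ann$gene_id[gidx],
               stringsAsFactors = FALSE)
  }
  in_loss_pool <- which(chrom_of %in% loss_chroms)
  g_loss <- in_loss_pool[order(-base[in_loss_pool])][seq_len(cfg$germline_in_loss)]
  retained <- sample(c("ref", "alt"), cfg$germline_in_loss, replace = TRUE)
  vt_loss <- ifelse(retained == "alt", 0.85, 0.15) +
    stats::rnorm(cfg$germline_in_loss, 0, 0.01)
  n_neutral <- cfg$n_germline_het_snvs - cfg$germline_in_loss
  neutral_pool <- which(chrom_of == "chr8")
  g_neut <- neutral_pool[order(-base[neutral_pool])][seq_len(n_neutral)]
  germline_sites <- rbind(
    mk_sites(g_loss, vt_loss),
    if (n_neutral > 0L)
      mk_sites(g_neut, 0.5 + stats::rnorm(n_neutral, 0, 0.01)))
  germline_truth <- data.frame(
    chrom = germline_sites$chrom, pos = germline_sites$pos,
    gene_id = germline_sites$gene_id,
    in_loss = c(rep(TRUE, cfg$germline_in_loss), rep(FALSE, n_neutral)),
    retained = c(retained, rep(NA_character_, n_neutral)),
    stringsAsFactors = FALSE)

  ## somatic sites on well-expressed, otherwise unremarkable genes
  special <- c(i_tum, i_imm, i_g1s, i_g2m, i_lig, i_rec, i_dlig, i_drec,
               g_loss, g_neut)
  pool <- setdiff(which(base >= stats::median(base)), special)
  if (length(pool) < cfg$n_somatic_snvs)
    stop("not enough eligible genes for the requested somatic SNVs")
  g_som <- sort(sample(pool, cfg$n_somatic_snvs))
  som_ref <- sample(bases4, cfg$n_somatic_snvs, replace = TRUE)
  somatic_sites <- data.frame(
    chrom = ann$chrom[g_som], pos = ann$start[g_som] + 25L,
    ref = som_ref,
    alt = unname(vapply(som_ref, function(r) sample(setdiff(bases4, r), 1L), "")),
    kind = "somatic", vaf_blood = NA_real_,
    vaf_tumor = stats::runif(cfg$n_somatic_snvs, 0.3, 0.45),
    gene_id = ann$gene_id[g_som], stringsAsFactors = FALSE)

  ## per-cell allele counts (zero sequencing error; reads only where the
  ## site's gene is expressed in that cell)
  ac <- list()
  emit <- function(cell, site, ref_n, alt_n) {
    data.frame(cell_id = cell, chrom = site$chrom, pos = site$pos,
               ref = site$ref, alt = site$alt,
               ref_count = ref_n, alt_count = alt_n,
               stringsAsFactors = FALSE)
  }
  for (s_i in seq_len(nrow(germline_sites))) {
    site <- germline_sites[s_i, ]
    mono <- germline_truth$in_loss[s_i]
    ret <- germline_truth$retained[s_i]
    expressed <- tumor_counts[site$gene_id, ] > 0
    for (c_i in which(expressed)) {
      n <- stats::rpois(1L, cfg$allele_site_depth)
      if (n == 0L) next
      if (mono && class[c_i] == "neoplastic") {
        if (stats::runif(1L) < cfg$allelic_dropout) next
        ref_n <- if (ret == "ref") n else 0L
        ac[[length(ac) + 1L]] <- emit(bio_ids[c_i], site, ref_n, n - ref_n)
      } else {
        keep_ref <- stats::runif(1L) >= cfg$allelic_dropout
        keep_alt <- stats::runif(1L) >= cfg$allelic_dropout
        if (!keep_ref && !keep_alt) next
        alt_n <- if (keep_ref && keep_alt) stats::rbinom(1L, n, 0.5)
                 else if (keep_alt) n else 0L
        ac[[length(ac) + 1L]] <- emit(bio_ids[c_i], site, n - alt_n, alt_n)
      }
    }
  }
  for (s_i in seq_len(nrow(somatic_sites))) {
    site <- somatic_sites[s_i, ]
    expressed <- tumor_counts[site$gene_id, ] > 0
    hit <- expressed & stats::runif(n_bio) < cfg$somatic_expression_rate
    for (c_i in which(hit)) {
      if (class[c_i] == "neoplastic") {
        ac[[length(ac) + 1L]] <- emit(bio_ids[c_i], site,
                                      stats::rpois(1L, cfg$somatic_site_depth),
                                      stats::rpois(1L, cfg$somatic_site_depth) + 1L)
      } else {
        ac[[length(ac) + 1L]] <- emit(bio_ids[c_i], site,
                                      stats::rpois(1L, cfg$somatic_site_depth) + 1L,
                                      0L)
      }
    }
  }
  allele_counts <- do.call(rbind, c(ac, list(make.row.names = FALSE)))

  lr_pairs <- rbind(lr_true, lr_decoy)
  truth_cells <- data.frame(cell_id = bio_ids, class = class,
                            cycling = cycling, phase = phase,
                            stringsAsFactors = FALSE)
  for (s in cfg$cnv_specs) {
    col <- paste0("carries_", s$chrom, "_", s$direction)
    truth_cells[[col]] <- class == "neoplastic"
  }
  germline_sites$gene_id <- NULL
  somatic_sites$gene_id <- NULL
  list(tumor = expression_matrix(tumor_counts, unit = "counts",
                                 group = rep("tumor_biopsy", n_bio)),
       control = expression_matrix(ctrl_counts, unit = "counts",
                                   group = rep("control", cfg$n_control_cells)),
       annotation = ann, depth_bins = depth_bins,
       germline_sites = germline_sites, somatic_sites = somatic_sites,
       allele_counts = allele_counts, lr_pairs = lr_pairs,
       truth = list(cells = truth_cells, cnv_specs = cfg$cnv_specs,
                    germline = germline_truth, lr_true = lr_true),
       config = cfg)
}

#' Deterministic tabulation of a bundle's truth labels
#'
#' @param bundle a bundle from [simulate_bundle()].
#' @return list: `class_counts`, `n_cycling`, `carriage` (per-segment
#'   carrier counts), `somatic_detected` (cells with >= 1 alt read per
#'   somatic site).
#' @export
summarize_truth <- function(bundle) {
  tc <- bundle$truth$cells
  carriage_cols <- grep("^carries_", names(tc), value = TRUE)
  carriage <- data.frame(segment = sub("^carries_", "", carriage_cols),
                         n_cells = vapply(carriage_cols,
                                          function(cl) sum(tc[[cl]]), 0L),
                         stringsAsFactors = FALSE, row.names = NULL)
  ac <- bundle$allele_counts
  skey <- site_key(bundle$somatic_sites$chrom, bundle$somatic_sites$pos)
  som <- ac[site_key(ac$chrom, ac$pos) %in% skey & ac$alt_count >= 1, ]
  somatic_detected <- data.frame(
    site = skey,
    n_cells = vapply(skey, function(k)
      length(unique(som$cell_id[site_key(som$chrom, som$pos) == k])), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(class_counts = table(tc$class),
       n_cycling = sum(tc$cycling),
       carriage = carriage,
       somatic_detected = somatic_detected)
}

#' Write a simulated bundle to disk in its external formats
#'
#' Emits exactly the files the analysis side consumes: expression TSVs,
#' BED annotation, depth-ratio TSV, germline/somatic VCFs, allele-count
#' TSV, ligand-receptor TSV, truth labels TSV and the configuration as
#' JSON.  Output is byte-deterministic for a given bundle.
#'
#' @param bundle a bundle from [simulate_bundle()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$tumor, p("expression_tumor.tsv"))
  write_expression(bundle$control, p("expression_control.tsv"))
  ann <- bundle$annotation
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start, ann$end),
                               strand = ifelse(ann$strand %in% c("+", "-"),
                                               ann$strand, "*"))
  gr$name <- ann$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, p("annotation.bed"), format = "bed")
  write_tsv_plain(bundle$depth_bins, p("depth_ratio.tsv"))
  write_snv_vcf(bundle$germline_sites, p("germline.vcf"))
  write_snv_vcf(bundle$somatic_sites, p("somatic.vcf"))
  write_allele_counts(bundle$allele_counts, p("allele_counts.tsv"))
  write_tsv_plain(bundle$lr_pairs, p("lr_pairs.tsv"))
  write_tsv_plain(bundle$truth$cells, p("truth_labels.tsv"))
  cfg <- bundle$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("sim_config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("expression_tumor.tsv", "expression_control.tsv",
             "annotation.bed", "depth_ratio.tsv", "germline.vcf",
             "somatic.vcf", "allele_counts.tsv", "lr_pairs.tsv",
             "truth_labels.tsv", "sim_config.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Read a bundle directory back through the package's format readers
#'
#' @param dir directory written by [write_bundle()] (or assembled by hand
#'   with the same file names).
#' @return a bundle list shaped like [simulate_bundle()] output; `truth`
#'   is included only when `truth_labels.tsv` is present.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  bundle <- list(
    tumor = read_expression(p("expression_tumor.tsv"), group = "tumor_biopsy"),
    control = read_expression(p("expression_control.tsv"), group = "control"),
    annotation = read_annotation(p("annotation.bed"), format = "bed"),
    depth_bins = read_tsv_plain(p("depth_ratio.tsv")),
    germline_sites = read_snv_vcf(p("germline.vcf"), kind = "germline"),
    somatic_sites = read_snv_vcf(p("somatic.vcf"), kind = "somatic"),
    allele_counts = read_allele_counts(p("allele_counts.tsv")),
    lr_pairs = if (file.exists(p("lr_pairs.tsv"))) read_lr_pairs(p("lr_pairs.tsv")))
  if (file.exists(p("truth_labels.tsv")))
    bundle$truth <- list(cells = read_tsv_plain(p("truth_labels.tsv")))
  bundle
}
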