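# End-to-end orchestration: preprocess -> clustering + clinical association
# -> stratified differential expression -> signature comparison ->
# correlation screens -> protein beta landscape -> target cross-referencing
# and over-representation. One config, seeded, every table written with a
# provenance header.

#' Samples from patients biopsied at all three time points
#'
#' @param ann sample annotation data.frame.
#' @return Character vector of sample ids belonging to patients with biopsies
#'   at weeks 0, 12 and 25 (empty when none).
#' @export
complete_case_subset <- function(ann) {
  if (!nrow(ann)) return(character(0))
  wk <- split(ann$week, ann$patient_id)
  full <- names(wk)[vapply(wk, function(w) all(.week_levels %in% w), logical(1))]
  ann$sample_id[ann$patient_id %in% full]
}

#' Pipeline run configuration
#'
#' Collects inputs (in-memory cohort or file paths), thresholds and stage
#' parameters for [run_all()]. Either `cohort` (a [generate_cohort()]-shaped
#' list) or the individual paths must be provided.
#'
#' @param cohort optional in-memory cohort list (`mirna`, `mrna`, `protein`,
#'   `annotation`, optionally `predictions`, `gene_sets`).
#' @param mirna_path,mrna_path,protein_path,annotation_path,predictions_path,gene_sets_path
#'   file-based inputs, used when `cohort` is `NULL`.
#' @param thr [thresholds()].
#' @param part list of PART controls: `k_max`, `n_ref`, `min_size`.
#' @param max_power mRNA polynomial degree of the protein model.
#' @param er ER stratum analyzed (`"pos"` by default; `NULL` = all patients).
#' @param seed integer master seed (recorded in every output header).
#' @param out_dir output directory for the report tables.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = NULL,
                       mirna_path = NULL, mrna_path = NULL, protein_path = NULL,
                       annotation_path = NULL, predictions_path = NULL,
                       gene_sets_path = NULL,
                       thr = thresholds(),
                       part = list(k_max = 10, n_ref = 20, min_size = 5),
                       max_power = 2, er = "pos",
                       seed = 1, out_dir = tempfile("neomir_run_")) {
  if (is.null(cohort)) {
    paths <- c(mirna_path, mrna_path, annotation_path)
    if (length(paths) < 3) stop("need `cohort` or at least miRNA, mRNA and annotation paths")
    missing_p <- paths[!file.exists(paths)]
    if (length(missing_p)) stop("input path(s) not found: ",
                                paste(missing_p, collapse = ", "))
  }
  structure(list(cohort = cohort, mirna_path = mirna_path,
                 mrna_path = mrna_path, protein_path = protein_path,
                 annotation_path = annotation_path,
                 predictions_path = predictions_path,
                 gene_sets_path = gene_sets_path,
                 thr = thr, part = part, max_power = max_power, er = er,
                 seed = seed, out_dir = out_dir), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (median centering + presence filter);
#' per-week PART clustering of samples with clinical association tests and of
#' features with cross-week persistence; pooled OR vs non-OR differential
#' expression at week 0 with the nomenclature-number summary; per-arm week-0
#' vs week-25 differential expression (all patients, then responders only)
#' with signature comparisons; miRNA-mRNA correlation of the
#' combination-arm-specific responder miRNAs and miRNA-proliferation
#' correlation per week and pooled; the protein beta landscape with hub
#' ranking and week-0/25 beta stability; and, when predictions/gene sets are
#' available, target cross-referencing and over-representation. Every output
#' table is written under `cfg$out_dir` with a provenance header (package
#' version, seed, config hash). Any stage failure aborts with the stage name;
#' tables written so far are retained.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with all stage results, the written `tables`
#'   (named file paths), and a `summary` of headline counts.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  thr <- cfg$thr
  seed <- cfg$seed
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  co <- cfg$cohort
  if (is.null(co)) {
    co <- list(
      mirna = read_matrix(cfg$mirna_path, "mirna"),
      mrna = read_matrix(cfg$mrna_path, "mrna"),
      protein = if (!is.null(cfg$protein_path)) read_matrix(cfg$protein_path, "protein"),
      annotation = read_annotation(cfg$annotation_path),
      predictions = if (!is.null(cfg$predictions_path)) read_predictions(cfg$predictions_path),
      gene_sets = if (!is.null(cfg$gene_sets_path)) read_gmt(cfg$gene_sets_path))
  }
  ann <- co$annotation
  check_samples_annotated(co$mirna, ann)
  hash <- config_hash(list(thr = thr, part = cfg$part,
                           max_power = cfg$max_power, er = cfg$er, seed = seed))
  tables <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    write_tsv_prov(df, path, seed = seed, hash = hash)
    tables[[name]] <<- path
    invisible(path)
  }
  log_stage <- function(...) message(sprintf(...))

  # ---- preprocess --------------------------------------------------------
  pp <- .stage("preprocess", {
    centered <- median_center(co$mirna)
    presence_filter(centered, thr$presence_min_fraction)
  })
  mir <- pp$matrix
  log_stage("preprocess: %d features retained, %d removed",
            nrow(mir$values), length(pp$removed_ids))
  emit(data.frame(feature_id = pp$removed_ids), "removed_features")
  emit(data.frame(feature_id = rownames(mir$values),
                  presence = rowMeans(!is.na(mir$values))), "retained_features")
  er_ann <- if (is.null(cfg$er)) ann else ann[ann$er_status == cfg$er, , drop = FALSE]

  # ---- clustering --------------------------------------------------------
  clus <- .stage("part_clustering", {
    res <- list(samples = list(), features = list(), assoc = list())
    for (w in .week_levels) {
      ids <- er_ann$sample_id[er_ann$week == w]
      mw <- subset_omics(mir, samples = ids)
      res$samples[[as.character(w)]] <-
        part_partition(mw, "samples", k_max = cfg$part$k_max,
                       n_ref = cfg$part$n_ref, min_size = cfg$part$min_size,
                       seed = seed + w)
      res$features[[as.character(w)]] <-
        part_partition(mw, "features", k_max = cfg$part$k_max,
                       n_ref = cfg$part$n_ref, min_size = cfg$part$min_size,
                       seed = seed + 100 + w)
      for (var in c("response", "pam50", "relapse")) {
        a <- tryCatch(cluster_clinical_association(
          res$samples[[as.character(w)]], er_ann, var, seed = seed),
          error = function(e) NULL)
        if (!is.null(a))
          res$assoc[[paste0("w", w, "_", var)]] <-
            data.frame(week = w, variable = var, p = a$p)
      }
    }
    res$persistence <- cluster_persistence(res$features)
    res
  })
  for (w in .week_levels) {
    cw <- clus$samples[[as.character(w)]]
    emit(data.frame(sample_id = names(cw$assignment), cluster = cw$assignment),
         paste0("clusters_samples_w", w))
    fw <- clus$features[[as.character(w)]]
    emit(data.frame(feature_id = names(fw$assignment), cluster = fw$assignment),
         paste0("clusters_features_w", w))
  }
  emit(do.call(rbind, clus$assoc), "cluster_clinical_associations")
  emit(clus$persistence, "cluster_persistence")
  log_stage("clustering: sample k per week = %s",
            paste(vapply(clus$samples, function(x) x$k, integer(1)), collapse = "/"))

  # ---- differential expression -------------------------------------------
  de <- .stage("differential", {
    out <- list()
    out$response_w0 <- run_de(mir, ann, "response", week = 0, er = cfg$er, thr = thr)
    for (a in .arm_levels) {
      out[[paste0("time_", a)]] <-
        run_de(mir, ann, "weeks", weeks = c(0, 25), arm = a, er = cfg$er, thr = thr)
      out[[paste0("time_", a, "_responders")]] <-
        run_de(mir, ann, "weeks", weeks = c(0, 25), arm = a, response = "OR",
               er = cfg$er, thr = thr)
    }
    out
  })
  for (nm in names(de)) emit(de[[nm]], paste0("de_", nm))
  nomen <- nomenclature_fraction(de_signature(de$response_w0),
                                 thr$nomenclature_cutoff)
  emit(nomen, "nomenclature_response_w0")
  venn_all <- compare_signatures(de_signature(de$time_bev),
                                 de_signature(de$time_chemo))
  venn_resp <- compare_signatures(de_signature(de$time_bev_responders),
                                  de_signature(de$time_chemo_responders))
  venn_df <- function(v, label) data.frame(
    comparison = label, n_a = length(v$set_a), n_b = length(v$set_b),
    overlap = length(v$overlap), a_only = length(v$a_only),
    b_only = length(v$b_only), concordant = v$concordant,
    discordant = v$discordant)
  emit(rbind(venn_df(venn_all, "bev_vs_chemo_all"),
             venn_df(venn_resp, "bev_vs_chemo_responders")),
       "signature_comparison")
  log_stage("differential: %d response-assoc.; time-course %d bev / %d chemo (overlap %d)",
            sum(de$response_w0$significant),
            length(venn_all$set_a), length(venn_all$set_b),
            length(venn_all$overlap))

  # ---- correlation screens -----------------------------------------------
  corr <- .stage("correlation", {
    bev_specific <- venn_resp$a_only
    if (!length(bev_specific))
      bev_specific <- utils::head(
        de$time_bev_responders$feature_id[order(de$time_bev_responders$q)], 5)
    cm <- pairwise_corr(mir, co$mrna, ann = er_ann, features_a = bev_specific)
    cm_sig <- filter_corr(cm, thr$corr_alpha, thr$corr_min_abs_r)
    prolif_genes <- intersect(co$truth$prolif_genes %||% character(0),
                              rownames(co$mrna$values))
    score <- if (length(prolif_genes))
      proliferation_score(co$mrna, prolif_genes)
    else stats::setNames(er_ann$proliferation_score, er_ann$sample_id)
    resp_sig <- de_signature(de$time_bev_responders)
    mir_sub <- if (length(resp_sig))
      subset_omics(mir, features = names(resp_sig)) else mir
    cp <- corr_with_score(mir_sub, score[names(score) %in% er_ann$sample_id],
                          ann = er_ann, per_week = TRUE,
                          score_name = "proliferation")
    list(mrna = cm, mrna_sig = cm_sig, prolif = cp,
         prolif_sig = filter_corr(cp, thr$corr_alpha, thr$corr_min_abs_r),
         bev_specific = bev_specific)
  })
  emit(corr$mrna_sig, "corr_mirna_mrna_significant")
  emit(corr$prolif, "corr_proliferation")
  log_stage("correlation: %d significant miRNA-mRNA pairs; %d prolif-correlated (pooled)",
            nrow(corr$mrna_sig),
            sum(corr$prolif_sig$week == "pooled"))

  # ---- protein model -----------------------------------------------------
  pm <- if (!is.null(co$protein)) .stage("protein_model", {
    land <- beta_landscape(co$protein, co$mrna, mir, er_ann,
                           weeks = .week_levels, max_power = cfg$max_power,
                           fdr = thr$de_fdr)
    list(landscape = land, hubs = rank_hubs(land),
         stability = beta_stability(land, 0, 25))
  }) else NULL
  if (!is.null(pm)) {
    emit(pm$landscape[pm$landscape$significant, , drop = FALSE],
         "beta_landscape_significant")
    emit(pm$hubs, "protein_hubs")
    emit(pm$stability$pairs, "beta_stability_w0_w25")
    log_stage("protein model: %d significant associations; stability r = %.3f",
              sum(pm$landscape$significant), pm$stability$r)
  }

  # ---- targets + enrichment ----------------------------------------------
  te <- if (!is.null(co$predictions)) .stage("targets_enrichment", {
    preds <- filter_predictions(co$predictions, thr)
    gene_de <- run_de(co$mrna, ann, "weeks", weeks = c(0, 25), arm = "bev",
                      response = "OR", er = cfg$er, thr = thr)
    matched <- match_targets(corr$mrna_sig, preds, gene_de = gene_de,
                             mirna_sign = de_signature(de$time_bev_responders))
    ora <- if (!is.null(co$gene_sets) && nrow(corr$mrna_sig))
      ora_fisher(unique(corr$mrna_sig$id_b), co$gene_sets,
                 universe = rownames(co$mrna$values), ora_fdr = thr$ora_fdr)
    list(predictions = preds, matched = matched, ora = ora)
  }) else NULL
  if (!is.null(te)) {
    emit(te$matched, "targets_matched")
    if (!is.null(te$ora)) emit(te$ora, "ora_enrichment")
    log_stage("targets: %d matched pairs (%d consistent)",
              nrow(te$matched), sum(te$matched$consistent))
  }

  summary <- list(
    n_features_retained = nrow(mir$values),
    sample_k_per_week = vapply(clus$samples, function(x) x$k, integer(1)),
    n_response_significant = sum(de$response_w0$significant),
    n_time_bev = length(venn_all$set_a),
    n_time_chemo = length(venn_all$set_b),
    n_time_overlap = length(venn_all$overlap),
    n_corr_mrna_significant = nrow(corr$mrna_sig),
    n_prolif_significant_pooled = sum(corr$prolif_sig$week == "pooled"),
    n_beta_significant = if (!is.null(pm)) sum(pm$landscape$significant) else NA,
    n_tables = length(tables))
  emit(data.frame(key = names(unlist(summary)), value = unlist(summary)),
       "run_summary")

  invisible(list(preprocess = pp, clustering = clus, de = de, corr = corr,
                 protein = pm, targets = te, tables = unlist(tables),
                 summary = summary, config = cfg))
}
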