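# Synthetic cohort generator: a full miRNA/mRNA/protein cohort with the
# longitudinal two-arm design and planted ground truth (clusters, response
# and time effects, miRNA-mRNA pairs, miRNA->protein betas), so that every
# downstream stage is testable without external data.

#' Configuration for the synthetic cohort
#'
#' Defaults mirror the study design the pipeline targets: 627 miRNAs profiled
#' at weeks 0/12/25 on 97/65/79 biopsies, objective-response splits 68:22,
#' 44:17 and 47:27 per week (the remaining samples carry unknown response),
#' two equally sized treatment arms, three planted miRNA clusters, 20
#' response-associated miRNAs at 1.5 log2 units, and arm-specific
#' time-course effects (139 in the combination arm, 251 in the chemotherapy
#' arm, 126 shared) realized by week 12 in the combination arm but only by
#' week 25 in the chemotherapy arm. Proteins are generated from the
#' polynomial-mRNA-plus-miRNA model with known betas for the planted triples.
#'
#' @param n_mirna,n_mrna,n_protein layer sizes.
#' @param samples_per_week biopsies at weeks 0, 12, 25.
#' @param or_nonor_per_week list of `c(OR, nonOR)` counts per week; the
#'   remainder of each week is coded `unknown`.
#' @param arm_split fraction of patients in the bevacizumab arm.
#' @param n_clusters,cluster_corr planted miRNA cluster count and
#'   within-cluster pairwise correlation.
#' @param n_response_de,response_effect response-associated miRNAs and their
#'   log2 shift in OR samples.
#' @param n_time_de_per_arm named vector `c(bev = ..., chemo = ...)` of
#'   time-course-affected miRNAs per arm.
#' @param n_time_de_shared how many of those are shared between arms.
#' @param time_effect log2 shift once the arm's effect is realized.
#' @param n_mirna_mrna_pairs,pair_corr planted miRNA-mRNA partner pairs
#'   (miRNA side drawn from the combination-arm time set) and their target
#'   Pearson correlation.
#' @param protein_beta_spec data.frame `mirna_id` (optional; indices drawn
#'   from unplanted miRNAs when omitted), `protein_index`, `beta` — raw-scale
#'   miRNA coefficients in the protein model. Default: 5 triples with betas
#'   0.8, -0.8, 0.6, -0.6, 0.7.
#' @param n_prolif_mirna,prolif_corr miRNAs tracking the latent proliferation
#'   factor and their correlation to it.
#' @param noise_sd protein-model residual standard deviation.
#' @param missing_rate completely-at-random missingness applied to the miRNA
#'   matrix (the presence filter's input).
#' @param baseline_mean,baseline_sd marginal log2 intensity distribution of
#'   the generated values (typical for log microarray data). The marginal
#'   spread decomposes into feature-level heterogeneity (`feature_sd`), a
#'   per-patient random intercept (`patient_sd`, the longitudinal link
#'   between a patient's biopsies) and a per-sample residual derived as
#'   `sqrt(baseline_sd^2 - feature_sd^2 - patient_sd^2)`.
#' @param feature_sd spread of feature-level mean expression.
#' @param patient_sd per-patient random-intercept scale.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_mirna = 627, n_mrna = 2000, n_protein = 210,
                          samples_per_week = c(97, 65, 79),
                          or_nonor_per_week = list(c(68, 22), c(44, 17), c(47, 27)),
                          arm_split = 0.5,
                          n_clusters = 3, cluster_corr = 0.5,
                          n_response_de = 20, response_effect = 1.5,
                          n_time_de_per_arm = c(bev = 139, chemo = 251),
                          n_time_de_shared = 126,
                          time_effect = 1.5,
                          n_mirna_mrna_pairs = 20, pair_corr = 0.8,
                          protein_beta_spec = NULL,
                          n_prolif_mirna = 2, prolif_corr = 0.6,
                          noise_sd = 0.5, missing_rate = 0.05,
                          baseline_mean = 8, baseline_sd = 1.5,
                          feature_sd = 1.2, patient_sd = 0.5, seed = 1) {
  stopifnot(length(samples_per_week) == 3, length(or_nonor_per_week) == 3)
  for (w in 1:3) {
    if (sum(or_nonor_per_week[[w]]) > samples_per_week[w])
      stop("OR + nonOR counts exceed samples at week ", .week_levels[w])
  }
  if (cluster_corr < 0 || cluster_corr >= 1) stop("cluster_corr must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (baseline_sd^2 <= feature_sd^2 + patient_sd^2)
    stop("baseline_sd^2 must exceed feature_sd^2 + patient_sd^2")
  if (is.null(protein_beta_spec))
    protein_beta_spec <- data.frame(protein_index = 1:5,
                                    beta = c(0.8, -0.8, 0.6, -0.6, 0.7))
  n_time_bev <- n_time_de_per_arm[["bev"]]
  n_time_chemo <- n_time_de_per_arm[["chemo"]]
  if (n_time_de_shared > min(n_time_bev, n_time_chemo))
    stop("n_time_de_shared exceeds an arm's time-DE count")
  n_planted <- n_response_de + n_time_bev + n_time_chemo - n_time_de_shared +
    n_prolif_mirna + nrow(protein_beta_spec)
  if (n_planted > n_mirna)
    stop("planted miRNA counts (", n_planted, ") exceed n_mirna (", n_mirna, ")")
  if (nrow(protein_beta_spec) > n_protein)
    stop("planted protein betas exceed n_protein")
  if (n_protein > n_mrna) stop("n_protein exceeds n_mrna (cis map is identity)")
  structure(as.list(environment()), class = "cohort_config")
}

# miRBase-flavoured feature names: a mix of low and high (>3000) family
# numbers plus a few let-7 members, so the nomenclature parser has real work.
.mirna_names <- function(n) {
  n_let <- min(5L, n)
  let <- paste0("hsa-let-7", letters[seq_len(n_let)], "-5p")
  n_rest <- n - n_let
  n_high <- round(0.4 * n_rest)
  nums <- c(sample.int(1500, n_rest - n_high),
            3000 + sample.int(5000, n_high))
  arms <- sample(c("-5p", "-3p", ""), n_rest, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
  c(sprintf("hsa-miR-%d%s", nums, arms), let)[seq_len(n)]
}

#' Generate a synthetic cohort with planted truth
#'
#' See [cohort_config()] for the design being emulated. All randomness is
#' driven by `config$seed`; two calls with the same config give identical
#' output.
#'
#' @param config a [cohort_config()].
#' @return list: `mirna`, `mrna`, `protein` ([omics_matrix()] layers),
#'   `annotation` (validated data.frame), `truth` (planted structure:
#'   `cluster_of_mirna`, `response_de`, `time_de`, `pairs`, `betas`,
#'   `prolif_mirnas`), `predictions` (synthetic target-prediction table
#'   covering the planted pairs plus decoys), `gene_sets` (one set enriched
#'   in the planted partner genes plus random sets), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  weeks <- .week_levels
  or_counts <- vapply(cfg$or_nonor_per_week, `[`, numeric(1), 1)
  non_counts <- vapply(cfg$or_nonor_per_week, `[`, numeric(1), 2)
  unk_counts <- cfg$samples_per_week - or_counts - non_counts

  # Patient pools sized by the largest per-week demand; "first k" nesting
  # makes later-week biopsy sets overlap earlier ones, as in a trial where
  # not every patient is sampled at every visit.
  pool <- c(OR = max(or_counts), nonOR = max(non_counts),
            unknown = max(unk_counts))
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(sum(pool))),
    response = rep(names(pool), pool),
    stringsAsFactors = FALSE)
  n_pat <- nrow(patients)
  n_bev <- round(cfg$arm_split * n_pat)
  patients$arm <- "chemo"
  for (grp in names(pool)) {   # balance arms within response groups
    idx <- which(patients$response == grp)
    patients$arm[idx[seq_along(idx) %% 2 == 1]] <- "bev"
  }
  patients$relapse <- stats::rbinom(n_pat, 1, 0.2) == 1
  patients$pcr <- stats::rbinom(n_pat, 1,
                                ifelse(patients$response == "OR", 0.3, 0.03)) == 1
  patients$t_stage <- sample(.tstage_levels, n_pat, replace = TRUE,
                             prob = c(0.6, 0.3, 0.1))
  pam_prob <- list(OR = c(0.30, 0.45, 0.08, 0.05, 0.12),
                   nonOR = c(0.55, 0.18, 0.08, 0.05, 0.14),
                   unknown = c(0.45, 0.30, 0.08, 0.05, 0.12))
  patients$pam50 <- vapply(patients$response, function(g)
    sample(.pam50_levels, 1, prob = pam_prob[[g]]), character(1))
  patients$er_status <- "pos"

  rows <- list()
  for (w in 1:3) {
    take <- character(0)
    for (grp in names(pool)) {
      want <- c(OR = or_counts[w], nonOR = non_counts[w],
                unknown = unk_counts[w])[[grp]]
      ids <- patients$patient_id[patients$response == grp]
      take <- c(take, ids[seq_len(want)])
    }
    rows[[w]] <- data.frame(patient_id = take, week = weeks[w],
                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- merge(ann, patients, by = "patient_id", sort = FALSE)
  ann$sample_id <- sprintf("%s_W%02d", ann$patient_id, ann$week)
  ann <- ann[order(ann$week, ann$patient_id), ]
  n_samp <- nrow(ann)
  pat_idx <- match(ann$patient_id, patients$patient_id)
  is_or <- ann$response == "OR"
  is_bev <- ann$arm == "bev"

  # Latent proliferation: patient level, declining under treatment, with a
  # steeper decline for responders on the combination arm.
  prolif_base <- stats::rnorm(n_pat)
  prolif <- prolif_base[pat_idx] - 0.5 * (ann$week / 25) -
    0.4 * (ann$week / 25) * (is_or & is_bev)
  ann$mitosis_count <- stats::rpois(n_samp, lambda = exp(2 + 0.7 * prolif))

  # ---- miRNA layer -------------------------------------------------------
  # marginal sd decomposes: baseline_sd^2 = feature_sd^2 + patient_sd^2 +
  # resid_sd^2; the cluster factor lives inside the per-sample residual
  resid_sd <- sqrt(cfg$baseline_sd^2 - cfg$feature_sd^2 - cfg$patient_sd^2)
  noise_scale <- sqrt(resid_sd^2 + cfg$patient_sd^2)  # within-feature sd
  nm <- cfg$n_mirna
  mir_ids <- unique(.mirna_names(nm))
  while (length(mir_ids) < nm) mir_ids <- unique(c(mir_ids, .mirna_names(nm)))
  mir_ids <- mir_ids[seq_len(nm)]
  cl <- rep(seq_len(cfg$n_clusters), length.out = nm)
  rho <- if (cfg$n_clusters > 1) cfg$cluster_corr else 0
  fac <- matrix(stats::rnorm(cfg$n_clusters * n_samp), cfg$n_clusters, n_samp)
  mu <- stats::rnorm(nm, cfg$baseline_mean, cfg$feature_sd)
  b_pat <- matrix(stats::rnorm(nm * n_pat, 0, cfg$patient_sd), nm, n_pat)
  eps <- matrix(stats::rnorm(nm * n_samp), nm, n_samp)
  mir <- mu + b_pat[, pat_idx] +
    resid_sd * (sqrt(rho) * fac[cl, , drop = FALSE] + sqrt(1 - rho) * eps)
  dimnames(mir) <- list(mir_ids, ann$sample_id)

  # planted index blocks (disjoint)
  i <- 0L
  idx_resp <- seq_len(cfg$n_response_de) + i; i <- i + cfg$n_response_de
  n_shared <- cfg$n_time_de_shared
  n_bev_only <- cfg$n_time_de_per_arm[["bev"]] - n_shared
  n_chemo_only <- cfg$n_time_de_per_arm[["chemo"]] - n_shared
  idx_shared <- seq_len(n_shared) + i; i <- i + n_shared
  idx_bev_only <- seq_len(n_bev_only) + i; i <- i + n_bev_only
  idx_chemo_only <- seq_len(n_chemo_only) + i; i <- i + n_chemo_only
  idx_prolif <- seq_len(cfg$n_prolif_mirna) + i; i <- i + cfg$n_prolif_mirna
  n_beta <- nrow(cfg$protein_beta_spec)
  idx_beta <- seq_len(n_beta) + i

  # response effects: OR samples shifted at every week (a patient-level trait)
  sign_resp <- rep(c(1, -1), length.out = cfg$n_response_de)
  if (cfg$n_response_de > 0)
    mir[idx_resp, is_or] <- mir[idx_resp, is_or] +
      sign_resp * cfg$response_effect

  # time effects: combination arm realized by week 12, chemo arm by week 25
  sign_shared <- rep(c(rep(1, 20), -1), length.out = max(n_shared, 0))
  sign_bev_only <- if (n_bev_only > 0) c(1, rep(-1, n_bev_only - 1)) else integer(0)
  sign_chemo_only <- rep(c(1, -1), length.out = n_chemo_only)
  bev_on <- is_bev & ann$week >= 12
  chemo_on <- !is_bev & ann$week >= 25
  add_time <- function(idx, sgn, cols) {
    if (length(idx) && any(cols))
      mir[idx, cols] <<- mir[idx, cols] + sgn * cfg$time_effect
  }
  add_time(idx_shared, sign_shared, bev_on)
  add_time(idx_shared, sign_shared, chemo_on)
  add_time(idx_bev_only, sign_bev_only, bev_on)
  add_time(idx_chemo_only, sign_chemo_only, chemo_on)

  # proliferation-tracking miRNAs (clean construction, no other effects)
  for (j in seq_along(idx_prolif)) {
    z <- (prolif - mean(prolif)) / stats::sd(prolif)
    mir[idx_prolif[j], ] <- mu[idx_prolif[j]] + noise_scale *
      (cfg$prolif_corr * z +
         sqrt(1 - cfg$prolif_corr^2) * stats::rnorm(n_samp))
  }

  # ---- mRNA layer --------------------------------------------------------
  ng <- cfg$n_mrna
  n_sig_genes <- 11L
  gene_ids <- c(sprintf("PROLIF%02d", seq_len(n_sig_genes)),
                sprintf("G%04d", seq_len(ng - n_sig_genes)))
  mu_g <- stats::rnorm(ng, cfg$baseline_mean, cfg$feature_sd)
  bg_pat <- matrix(stats::rnorm(ng * n_pat, 0, cfg$patient_sd), ng, n_pat)
  mrna <- mu_g + bg_pat[, pat_idx] +
    resid_sd * matrix(stats::rnorm(ng * n_samp), ng, n_samp)
  dimnames(mrna) <- list(gene_ids, ann$sample_id)
  zp <- (prolif - mean(prolif)) / stats::sd(prolif)
  for (g in seq_len(n_sig_genes))
    mrna[g, ] <- mu_g[g] + noise_scale *
      (0.9 * zp + sqrt(1 - 0.81) * stats::rnorm(n_samp))

  # planted miRNA-mRNA partners: miRNA side from the combination-arm time
  # set (falling back to background features), gene side outside the protein
  # panel and the proliferation signature
  protein_ids <- gene_ids[n_sig_genes + seq_len(cfg$n_protein)]
  pair_mirna_pool <- c(idx_bev_only, idx_shared,
                       setdiff(seq_len(nm), c(idx_resp, idx_shared, idx_bev_only,
                                              idx_chemo_only, idx_prolif, idx_beta)))
  pair_mir_idx <- pair_mirna_pool[seq_len(cfg$n_mirna_mrna_pairs)]
  pair_gene_idx <- n_sig_genes + cfg$n_protein + seq_len(cfg$n_mirna_mrna_pairs)
  if (length(pair_gene_idx) && max(pair_gene_idx) > ng)
    stop("not enough genes for planted pairs")
  for (k in seq_len(cfg$n_mirna_mrna_pairs)) {
    x <- mir[pair_mir_idx[k], ]
    zx <- (x - mean(x)) / stats::sd(x)
    mrna[pair_gene_idx[k], ] <- mu_g[pair_gene_idx[k]] + noise_scale *
      (cfg$pair_corr * zx +
         sqrt(1 - cfg$pair_corr^2) * stats::rnorm(n_samp))
  }

  ann$proliferation_score <- colMeans(
    (mrna[seq_len(n_sig_genes), ] - rowMeans(mrna[seq_len(n_sig_genes), ])) /
      apply(mrna[seq_len(n_sig_genes), ], 1, stats::sd))

  # ---- protein layer (generated FROM the bivariate model) ----------------
  np <- cfg$n_protein
  a0 <- stats::rnorm(np, 0, 0.3)
  a1 <- stats::runif(np, 0.4, 0.9)
  a2 <- stats::runif(np, -0.15, 0.15)
  prot <- matrix(NA_real_, np, n_samp, dimnames = list(protein_ids, ann$sample_id))
  beta_spec <- cfg$protein_beta_spec
  beta_mir_idx <- if ("mirna_id" %in% colnames(beta_spec))
    match(beta_spec$mirna_id, mir_ids) else idx_beta
  for (p in seq_len(np)) {
    mcis <- mrna[protein_ids[p], ]
    mc <- mcis - mean(mcis)
    y <- cfg$baseline_mean + a0[p] + a1[p] * mc + a2[p] * mc^2
    hit <- which(beta_spec$protein_index == p)
    for (h in hit) {
      x <- mir[beta_mir_idx[h], ]
      y <- y + beta_spec$beta[h] * (x - mean(x))
    }
    prot[p, ] <- y + stats::rnorm(n_samp, 0, cfg$noise_sd)
  }

  # MCAR missingness on the miRNA layer (the presence filter's consumer)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(nm * n_samp) < cfg$missing_rate, nm, n_samp)
    mir[mask] <- NA_real_
  }

  truth <- list(
    cluster_of_mirna = stats::setNames(cl, mir_ids),
    response_de = data.frame(
      mirna_id = mir_ids[idx_resp],
      effect = sign_resp * cfg$response_effect, stringsAsFactors = FALSE),
    time_de = rbind(
      if (n_shared) data.frame(mirna_id = mir_ids[idx_shared], arm = "both",
                               effect = sign_shared * cfg$time_effect,
                               stringsAsFactors = FALSE),
      if (n_bev_only) data.frame(mirna_id = mir_ids[idx_bev_only], arm = "bev",
                                 effect = sign_bev_only * cfg$time_effect,
                                 stringsAsFactors = FALSE),
      if (n_chemo_only) data.frame(mirna_id = mir_ids[idx_chemo_only], arm = "chemo",
                                   effect = sign_chemo_only * cfg$time_effect,
                                   stringsAsFactors = FALSE)),
    pairs = data.frame(mirna_id = mir_ids[pair_mir_idx],
                       gene_id = gene_ids[pair_gene_idx],
                       r = rep(cfg$pair_corr, length(pair_mir_idx)),
                       stringsAsFactors = FALSE),
    betas = data.frame(mirna_id = mir_ids[beta_mir_idx],
                       protein_id = protein_ids[beta_spec$protein_index],
                       beta = beta_spec$beta, stringsAsFactors = FALSE),
    prolif_mirnas = data.frame(mirna_id = mir_ids[idx_prolif],
                               r = rep(cfg$prolif_corr, length(idx_prolif)),
                               stringsAsFactors = FALSE),
    prolif_genes = gene_ids[seq_len(n_sig_genes)]
  )

  # synthetic target predictions: planted pairs strongly predicted by both
  # sources, plus weak and strong decoys
  n_pairs <- nrow(truth$pairs)
  planted_pred <- if (n_pairs) rbind(
    data.frame(mirna_id = truth$pairs$mirna_id, gene_id = truth$pairs$gene_id,
               source = rep("targetscan", n_pairs),
               score = stats::runif(n_pairs, -0.7, -0.36),
               stringsAsFactors = FALSE),
    data.frame(mirna_id = truth$pairs$mirna_id, gene_id = truth$pairs$gene_id,
               source = rep("microt", n_pairs),
               score = stats::runif(n_pairs, 0.72, 0.98),
               stringsAsFactors = FALSE)) else NULL
  n_decoy <- 150
  decoy <- data.frame(
    mirna_id = sample(mir_ids, n_decoy, replace = TRUE),
    gene_id = sample(gene_ids, n_decoy, replace = TRUE),
    source = sample(c("targetscan", "microt"), n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  decoy$score <- ifelse(decoy$source == "targetscan",
                        stats::runif(n_decoy, -0.34, -0.02),
                        stats::runif(n_decoy, 0.2, 0.69))
  strong_decoy <- data.frame(
    mirna_id = sample(mir_ids, 30, replace = TRUE),
    gene_id = sample(gene_ids, 30, replace = TRUE),
    source = "targetscan", score = stats::runif(30, -0.8, -0.4),
    stringsAsFactors = FALSE)
  predictions <- rbind(planted_pred, decoy, strong_decoy)
  predictions <- predictions[!duplicated(
    paste(predictions$mirna_id, predictions$gene_id, predictions$source)), ]

  gene_sets <- c(
    list(PLANTED_PARTNERS = unique(c(truth$pairs$gene_id,
                                     sample(gene_ids, 10)))),
    stats::setNames(lapply(1:9, function(i) sample(gene_ids, 30)),
                    sprintf("RANDOM_SET_%02d", 1:9)))

  ann_cols <- c("sample_id", "patient_id", "arm", "week", "response", "pcr",
                "pam50", "proliferation_score", "mitosis_count", "relapse",
                "t_stage", "er_status")
  ann <- validate_annotation(ann[, ann_cols])

  list(mirna = omics_matrix(mir, "mirna"),
       mrna = omics_matrix(mrna, "mrna"),
       protein = omics_matrix(prot, "protein"),
       annotation = ann, truth = truth, predictions = predictions,
       gene_sets = gene_sets, config = cfg)
}

#' Write a generated cohort to a directory
#'
#' Emits the three matrices, the annotation, the prediction table, the gene
#' sets (GMT) and the planted-truth tables as TSVs readable by the package's
#' readers.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_matrix(cohort$protein, file.path(dir, "protein.tsv"))
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$predictions, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  tr <- cohort$truth
  utils::write.table(data.frame(mirna_id = names(tr$cluster_of_mirna),
                                cluster = tr$cluster_of_mirna),
                     file.path(dir, "truth_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("response_de", "time_de", "pairs", "betas", "prolif_mirnas"))
    utils::write.table(tr[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
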