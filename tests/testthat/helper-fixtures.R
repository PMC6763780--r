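# Small fixtures built in code.

# Items x samples matrix with k planted clusters sharing a latent factor at
# within-cluster correlation rho; between-cluster correlation ~0.
make_cluster_matrix <- function(k = 3, per = 20, n = 90, rho = 0.8, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(k * n), k, n)
  cl <- rep(seq_len(k), each = per)
  x <- sqrt(rho) * f[cl, , drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(k * per * n), k * per, n)
  rownames(x) <- sprintf("f%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n))
  list(x = x, truth = cl)
}

# A reduced cohort config that keeps unit tests quick while preserving the
# longitudinal two-arm structure.
tiny_cohort_config <- function(seed = 1, ...) {
  defaults <- list(
    n_mirna = 80, n_mrna = 120, n_protein = 10,
    samples_per_week = c(40, 30, 34),
    or_nonor_per_week = list(c(26, 10), c(18, 8), c(20, 12)),
    n_clusters = 2, cluster_corr = 0.5,
    n_response_de = 8, response_effect = 1.5,
    n_time_de_per_arm = c(bev = 10, chemo = 16), n_time_de_shared = 8,
    time_effect = 1.5,
    n_mirna_mrna_pairs = 5, pair_corr = 0.8,
    protein_beta_spec = data.frame(protein_index = 1:3,
                                   beta = c(1.0, -1.0, 0.8)),
    n_prolif_mirna = 2, missing_rate = 0.05, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

make_omics <- function(values, layer = "mirna") {
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  omics_matrix(values, layer)
}

# Hand-built cluster_result for persistence tests.
fake_cluster_result <- function(assignment, axis = "features") {
  structure(list(axis = axis, assignment = assignment,
                 k = length(setdiff(unique(assignment), "OUTLIER")),
                 tree = NULL, params = list()), class = "cluster_result")
}
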