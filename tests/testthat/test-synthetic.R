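test_that("generation is deterministic under a seed and varies across seeds", {
  cfg <- tiny_cohort_config(seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$annotation, b$annotation)

  c2 <- generate_cohort(tiny_cohort_config(seed = 2))
  expect_false(identical(a$mirna$values, c2$mirna$values))
})

test_that("design sizes match the configuration", {
  co <- generate_cohort(cohort_config(seed = 2, n_mrna = 400))
  tab <- table(co$annotation$week)
  expect_equal(unname(as.vector(tab)), c(97, 65, 79))
  rt <- table(co$annotation$week, co$annotation$response)
  expect_equal(unname(rt[, "OR"]), c(68, 44, 47))
  expect_equal(unname(rt[, "nonOR"]), c(22, 17, 27))
  expect_true(all(co$annotation$week %in% c(0, 12, 25)))
  expect_equal(nrow(co$mirna$values), 627)
  expect_equal(nrow(co$protein$values), 210)
  # every planted id exists in the matrices
  expect_true(all(co$truth$response_de$mirna_id %in% rownames(co$mirna$values)))
  expect_true(all(co$truth$pairs$gene_id %in% rownames(co$mrna$values)))
  expect_true(all(co$truth$betas$protein_id %in% rownames(co$protein$values)))
})

test_that("planted counts exceeding the matrix dimensions are rejected", {
  expect_error(tiny_cohort_config(n_mirna = 20), "exceed")
})

test_that("non-planted features have week- and response-invariant means", {
  co <- generate_cohort(tiny_cohort_config(seed = 10, n_mirna = 300,
                                           missing_rate = 0))
  planted <- c(co$truth$response_de$mirna_id, co$truth$time_de$mirna_id,
               co$truth$prolif_mirnas$mirna_id, co$truth$betas$mirna_id)
  nulls <- setdiff(rownames(co$mirna$values), planted)
  ann <- co$annotation
  w0 <- ann$sample_id[ann$week == 0]; w25 <- ann$sample_id[ann$week == 25]
  dif_t <- rowMeans(co$mirna$values[nulls, w25]) -
    rowMeans(co$mirna$values[nulls, w0])
  or <- ann$sample_id[ann$response == "OR" & ann$week == 0]
  nr <- ann$sample_id[ann$response == "nonOR" & ann$week == 0]
  dif_r <- rowMeans(co$mirna$values[nulls, or]) -
    rowMeans(co$mirna$values[nulls, nr])
  # averaged over ~270 null features the mean difference shrinks toward 0
  expect_lt(abs(mean(dif_t)), 0.15)
  expect_lt(abs(mean(dif_r)), 0.15)
})

test_that("a null cohort yields ~no discoveries at BH 5%", {
  n_sig <- integer(3)
  for (s in 1:3) {
    co <- generate_cohort(tiny_cohort_config(
      seed = 100 + s, n_response_de = 0, n_prolif_mirna = 0,
      n_time_de_per_arm = c(bev = 0, chemo = 0), n_time_de_shared = 0,
      n_clusters = 1, cluster_corr = 0))
    de <- run_de(presence_filter(median_center(co$mirna), 0.8)$matrix,
                 co$annotation, "response", week = 0)
    n_sig[s] <- sum(de$significant)
  }
  expect_lte(sum(n_sig), 2)
})

test_that("noiseless protein generation is recovered exactly by refitting", {
  co <- generate_cohort(tiny_cohort_config(seed = 11, noise_sd = 0,
                                           missing_rate = 0))
  samp <- co$annotation$sample_id[co$annotation$week == 0]
  tr <- co$truth$betas
  for (i in seq_len(nrow(tr))) {
    x <- co$mirna$values[tr$mirna_id[i], samp]
    f <- fit_protein_model(co$protein$values[tr$protein_id[i], samp],
                           co$mrna$values[tr$protein_id[i], samp], x, 2)
    expect_equal(f$beta, tr$beta[i] * sd(x), tolerance = 1e-6)
  }
})

test_that("write_cohort round-trips matrices, annotation, and truth", {
  co <- generate_cohort(tiny_cohort_config(seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_matrix(file.path(dir, "mirna.tsv"), "mirna")
  expect_equal(back$values, co$mirna$values)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$sample_id, co$annotation$sample_id)
  expect_true(all(ann$week %in% c(0, 12, 25)))
  truth_resp <- read.delim(file.path(dir, "truth_response_de.tsv"))
  expect_equal(nrow(truth_resp), co$config$n_response_de)
  preds <- read_predictions(file.path(dir, "predictions.tsv"))
  expect_true(all(c("targetscan", "microt") %in% preds$source))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_true("PLANTED_PARTNERS" %in% names(sets))
})

test_that("planted prediction records survive the score filter", {
  co <- generate_cohort(tiny_cohort_config(seed = 14))
  kept <- filter_predictions(co$predictions)
  key <- paste(kept$mirna_id, kept$gene_id)
  planted <- paste(co$truth$pairs$mirna_id, co$truth$pairs$gene_id)
  expect_true(all(planted %in% key))
})
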