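test_that("Wilcoxon: exact path matches enumeration; degenerate inputs handled", {
  w <- wilcoxon_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p, 0.1, tolerance = 1e-12)          # 2 / choose(6, 3)
  expect_equal(w$statistic, 6)                        # ranks 1 + 2 + 3

  # identical groups (all ties): approximate path, symmetric, p = 1
  w2 <- wilcoxon_two_sample(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_false(w2$exact)
  expect_equal(w2$p, 1)

  expect_error(wilcoxon_two_sample(numeric(0), numeric(0)), "empty")
  expect_error(wilcoxon_two_sample(c(1, 2), numeric(0)), "observation")
})

test_that("exact Wilcoxon p equals full enumeration for small tie-free groups", {
  set.seed(42)
  for (nx in c(2, 4, 5)) for (ny in c(3, 5)) {
    x <- rnorm(nx); y <- rnorm(ny) + 0.5
    expect_equal(wilcoxon_two_sample(x, y)$p, wilcox_enum_oracle(x, y),
                 tolerance = 1e-12,
                 label = sprintf("enumeration n=%d m=%d", nx, ny))
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04, 0.05)),
               c(0.04, 0.05, 0.05, 0.05), tolerance = 1e-12)
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("fold changes are anti-logged group-mean ratios with NA flagging", {
  v <- rbind(f1 = c(4, 4, 2, 2),     # mean diff 2 -> FC 4
             f2 = c(3, 3, 3, 3),     # equal means -> FC 1
             f3 = c(NA, NA, 1, 2))   # absent in group a -> NA
  m <- make_omics(v)
  fc <- fold_change(m, c("s1", "s2"), c("s3", "s4"))
  expect_equal(unname(fc), c(4, 1, NaN))

  # the downregulation convention: FC 0.28 at week 25 vs 0 is a mean log2
  # drop of log2(0.28)
  v2 <- rbind(f = c(0, 0, log2(0.28), log2(0.28)))
  m2 <- make_omics(v2)
  fc2 <- fold_change(m2, c("s3", "s4"), c("s1", "s2"))
  expect_equal(unname(fc2), 0.28, tolerance = 1e-12)
  expect_error(fold_change(m, c("s1"), c("s1", "s2")), "disjoint")
})

test_that("run_de recovers planted response effects and respects the BH family", {
  co <- generate_cohort(tiny_cohort_config(seed = 3))
  pp <- presence_filter(median_center(co$mirna), 0.8)
  de <- run_de(pp$matrix, co$annotation, "response", week = 0)
  expect_equal(nrow(de), nrow(pp$matrix$values))
  hits <- de$feature_id[de$significant]
  expect_gte(mean(co$truth$response_de$mirna_id %in% hits), 0.8)
  # q recomputed over exactly the tested features
  expect_equal(de$q, bh_oracle(de$p), tolerance = 1e-12)
  # planted signs recovered
  sig <- merge(de[de$significant, ], co$truth$response_de, by.x = "feature_id",
               by.y = "mirna_id")
  expect_true(all(ifelse(sig$effect > 0, "up", "down") == sig$direction))
})

test_that("run_de is invariant to feature and sample order", {
  co <- generate_cohort(tiny_cohort_config(seed = 4, missing_rate = 0))
  m <- median_center(co$mirna)
  de1 <- run_de(m, co$annotation, "response", week = 0)
  perm_f <- sample(rownames(m$values))
  perm_s <- sample(colnames(m$values))
  m2 <- subset_omics(m, features = perm_f, samples = perm_s)
  de2 <- run_de(m2, co$annotation, "response", week = 0)
  de2 <- de2[match(de1$feature_id, de2$feature_id), ]
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  expect_equal(de1$q, de2$q, tolerance = 1e-12)
  expect_equal(de1$fold_change, de2$fold_change, tolerance = 1e-12)
})

test_that("undersized strata are skipped with a warning", {
  co <- generate_cohort(tiny_cohort_config(seed = 5))
  ann <- co$annotation
  ann$response[ann$response == "nonOR" & ann$week == 0][-1] <- "unknown"
  expect_warning(de <- run_de(co$mirna, ann, "response", week = 0), "< 3")
  expect_equal(nrow(de), 0)
})

test_that("signature comparison partitions and counts concordance", {
  a <- c(x = "up", y = "up", z = "down")
  b <- c(y = "up", z = "up", w = "down")
  v <- compare_signatures(a, b)
  expect_setequal(v$overlap, c("y", "z"))
  expect_equal(v$a_only, "x")
  expect_equal(v$b_only, "w")
  expect_equal(v$concordant, 1)
  expect_equal(v$discordant, 1)

  same <- compare_signatures(a, a)
  expect_equal(length(same$overlap), 3)
  expect_equal(same$concordant, 3)

  # cardinality conservation on random signed sets
  set.seed(9)
  for (i in 1:10) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    pool <- paste0("m", 1:60)
    sa <- setNames(sample(c("up", "down"), na, TRUE), sample(pool, na))
    sb <- setNames(sample(c("up", "down"), nb, TRUE), sample(pool, nb))
    v <- compare_signatures(sa, sb)
    expect_equal(length(v$set_a), length(v$overlap) + length(v$a_only))
    expect_equal(length(v$set_b), length(v$overlap) + length(v$b_only))
    expect_equal(v$concordant + v$discordant, length(v$overlap))
  }
})

test_that("miRNA nomenclature numbers parse across name forms", {
  ids <- mirna_numeric_id(c("hsa-miR-4465", "miR-125b-2-3p", "hsa-let-7a-5p",
                            "hsa-miR-21-5p", "not-a-mir"))
  expect_equal(unname(ids), c(4465L, 125L, NA, 21L, NA))
})

test_that("nomenclature fractions split by direction and handle degenerate sets", {
  sig <- c("hsa-miR-4465" = "up", "hsa-miR-21-5p" = "up", "hsa-miR-100-5p" = "down")
  nf <- nomenclature_fraction(sig, 3000)
  expect_equal(nf$fraction[nf$direction == "up"], 0.5)
  expect_equal(nf$fraction[nf$direction == "down"], 0)

  empty <- nomenclature_fraction(setNames(character(0), character(0)))
  expect_true(all(is.na(empty$fraction)))

  lets <- nomenclature_fraction(c("hsa-let-7a-5p" = "up", "hsa-let-7b-5p" = "up"))
  expect_true(is.na(lets$fraction[lets$direction == "up"]))
})
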