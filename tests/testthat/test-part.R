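test_that("Pearson distance: self 0, anti-correlation 2, orthogonality 1, constant item rejected", {
  x <- rbind(a = c(1, 2, 3, 4),
             b = c(4, 3, 2, 1),    # r = -1 with a
             c = c(1, 1, 2, 2))    # engineered r = 0 with d below
  d0 <- pearson_distance(x)
  expect_equal(unname(diag(d0)), rep(0, 3))
  expect_equal(d0["a", "b"], 2)

  y <- rbind(u = c(1, 2, 1, 2), v = c(1, 1, 2, 2))  # cor(u, v) = 0
  dy <- pearson_distance(y)
  expect_equal(dy["u", "v"], 1)

  z <- rbind(ok = c(1, 2, 3, 4), flatline = c(5, 5, 5, 5))
  expect_error(pearson_distance(z), "flatline")
})

test_that("distance is computed on pairwise-complete observations", {
  x <- rbind(a = c(1, 2, 3, 4, NA), b = c(2, 4, 6, NA, 1))
  d <- pearson_distance(x)   # complete pairs: first three -> r = 1
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
})

test_that("average linkage follows UPGMA: toy example and brute-force cophenetic oracle", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(1, 4))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # A,B merge first

  for (s in 1:5) {
    set.seed(s)
    n <- 6
    dm <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    hc <- average_linkage(dm)
    expect_equal(length(hc$height), n - 1)
    expect_true(all(diff(hc$height) >= -1e-12))
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- upgma_cophenetic_oracle(dm)
    dimnames(oracle) <- dimnames(coph)
    expect_equal(coph, oracle, tolerance = 1e-10)
  }
  expect_error(average_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("gap statistic: identical items give k = 1, two separated groups give k = 2", {
  x <- matrix(rep(c(1, 5, 2, 4), each = 6), 6, 4)
  rownames(x) <- paste0("f", 1:6)
  expect_equal(gap_best_k(x, seed = 1), 1L)

  mc <- make_cluster_matrix(k = 2, per = 15, n = 60, rho = 0.9, seed = 3)
  expect_equal(gap_best_k(mc$x, seed = 1), 2L)
})

test_that("PART recovers planted structure and flags displaced items as outliers", {
  mc <- make_cluster_matrix(k = 3, per = 15, n = 60, rho = 0.8, seed = 11)
  cr <- part_partition(mc$x, "features", seed = 11)
  expect_equal(cr$k, 3L)
  expect_gte(adjusted_rand_index(cr$assignment, mc$truth), 0.9)
  # partition covers all items exactly once
  expect_setequal(names(cr$assignment), rownames(mc$x))

  # two big groups + two strays (each stray on its own latent factor)
  set.seed(4)
  mc2 <- make_cluster_matrix(k = 2, per = 15, n = 60, rho = 0.9, seed = 4)
  strays <- make_cluster_matrix(k = 2, per = 1, n = 60, rho = 0.95, seed = 99)$x
  rownames(strays) <- c("stray1", "stray2")
  x <- rbind(mc2$x, strays)
  cr2 <- part_partition(x, "features", min_size = 5, seed = 5)
  expect_equal(cr2$k, 2L)
  expect_setequal(names(cr2$assignment)[cr2$assignment == "OUTLIER"],
                  c("stray1", "stray2"))
})

test_that("PART finds nested structure that a single flat cut misses", {
  # two super-clusters, each containing two sub-clusters: shared coarse
  # factor plus distinct fine factors
  set.seed(21)
  n <- 80
  coarse <- matrix(rnorm(2 * n), 2, n)
  fine <- matrix(rnorm(4 * n), 4, n)
  sub <- rep(1:4, each = 12)
  sup <- (sub + 1) %/% 2
  x <- sqrt(0.45) * coarse[sup, ] + sqrt(0.45) * fine[sub, ] +
    sqrt(0.10) * matrix(rnorm(48 * n), 48, n)
  rownames(x) <- paste0("f", seq_len(nrow(x)))
  cr <- part_partition(x, "features", seed = 2)
  expect_equal(cr$k, 4L)
  expect_gte(adjusted_rand_index(cr$assignment, sub), 0.9)
})

test_that("PART assignment is invariant to item order up to relabeling", {
  mc <- make_cluster_matrix(k = 3, per = 12, n = 70, rho = 0.8, seed = 31)
  cr1 <- part_partition(mc$x, "features", seed = 7)
  perm <- sample(nrow(mc$x))
  cr2 <- part_partition(mc$x[perm, ], "features", seed = 7)
  common <- names(cr1$assignment)
  expect_equal(adjusted_rand_index(cr1$assignment[common],
                                   cr2$assignment[common]), 1)
})

test_that("tiny inputs return a single cluster with a warning", {
  x <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("f", 1:3), NULL))
  expect_warning(cr <- part_partition(x, "features", min_size = 5, seed = 1),
                 "single cluster")
  expect_equal(cr$k, 1L)
})

test_that("cluster-clinical association matches exact Fisher arithmetic", {
  cr <- fake_cluster_result(
    setNames(rep(c("1", "2"), each = 3), paste0("s", 1:6)), axis = "samples")
  ann <- data.frame(sample_id = paste0("s", 1:6), patient_id = paste0("p", 1:6),
                    arm = "bev", week = 0L, er_status = "pos",
                    response = rep(c("OR", "nonOR"), each = 3))
  out <- cluster_clinical_association(cr, ann, "response")
  expect_equal(out$p, 0.1, tolerance = 1e-12)   # 2 / choose(6, 3)
  expect_equal(out$p, fisher22_oracle(out$table), tolerance = 1e-12)

  # balanced 2x2 table [[1,1],[1,1]] carries no association: p = 1
  ann2 <- ann[1:4, ]
  ann2$response <- c("OR", "nonOR", "OR", "nonOR")
  out2 <- cluster_clinical_association(
    fake_cluster_result(setNames(c("1", "1", "2", "2"), paste0("s", 1:4)),
                        "samples"), ann2, "response")
  expect_equal(out2$p, 1)

  ann$onelevel <- "same"
  expect_error(cluster_clinical_association(cr, ann, "onelevel"), "two")
})

test_that("outliers and unknown responses are excluded from association tables", {
  assign <- setNames(c("1", "1", "2", "2", "OUTLIER"), paste0("s", 1:5))
  ann <- data.frame(sample_id = paste0("s", 1:5), patient_id = paste0("p", 1:5),
                    arm = "bev", week = 0L, er_status = "pos",
                    response = c("OR", "OR", "nonOR", "unknown", "OR"))
  out <- cluster_clinical_association(fake_cluster_result(assign, "samples"),
                                      ann, "response")
  expect_equal(sum(out$table), 3)  # s4 unknown and s5 outlier dropped
})

test_that("cluster persistence: identity, single defection, and label invariance", {
  ids <- paste0("f", 1:8)
  w0 <- fake_cluster_result(setNames(rep(c("1", "2"), each = 4), ids))
  same <- list(w0 = w0, w12 = w0, w25 = w0)
  per <- cluster_persistence(same)
  expect_equal(per$persistence, c(1, 1))

  # one of 4 members moves at the last time point
  moved <- setNames(c("1", "1", "1", "2", "2", "2", "2", "2"), ids)
  per2 <- cluster_persistence(list(w0 = w0, w25 = fake_cluster_result(moved)))
  expect_setequal(per2$persistence, c(0.75, 1))

  # identical partitions under shuffled labels still give 100%
  relab <- setNames(rep(c("7", "3"), each = 4), ids)
  per3 <- cluster_persistence(list(w0 = w0, w25 = fake_cluster_result(relab)))
  expect_equal(per3$persistence, c(1, 1))

  other <- fake_cluster_result(setNames(rep("1", 3), paste0("g", 1:3)))
  expect_error(cluster_persistence(list(w0, other)), "universe")
})
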