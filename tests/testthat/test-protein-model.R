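test_that("noiseless planted polynomial models are recovered exactly", {
  set.seed(1)
  n <- 60
  m <- rnorm(n, 8, 1); x <- rnorm(n, 8, 1.5)
  y <- 1 + 0.5 * m + 0.3 * m^2 - 0.8 * x
  f <- fit_protein_model(y, m, x, max_power = 2)
  # standardized beta = raw beta * sd(miRNA)
  expect_equal(f$beta, -0.8 * sd(x), tolerance = 1e-8)
  expect_lt(f$p, 1e-12)

  # any max_power >= the planted degree recovers it too
  f3 <- fit_protein_model(y, m, x, max_power = 3)
  expect_equal(f3$beta, -0.8 * sd(x), tolerance = 1e-8)
})

test_that("beta and its p-value agree with an independent lm fit", {
  set.seed(2)
  n <- 80
  m <- rnorm(n, 8, 1); x <- rnorm(n, 8, 1.5)
  y <- 2 + 0.4 * m + 0.1 * m^2 + 0.25 * x + rnorm(n, 0, 0.5)
  f <- fit_protein_model(y, m, x, 2)
  mc <- m - mean(m)
  z1 <- as.vector(scale(mc)); z2 <- as.vector(scale(mc^2))
  xs <- as.vector(scale(x))
  lf <- summary(stats::lm(y ~ z1 + z2 + xs))
  expect_equal(f$beta, unname(coef(lf)["xs", "Estimate"]), tolerance = 1e-10)
  expect_equal(f$p, unname(coef(lf)["xs", "Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("with max_power = 1 beta solves the bivariate normal equations", {
  set.seed(3)
  n <- 40
  m <- rnorm(n); x <- rnorm(n)
  y <- 0.3 * m + 0.5 * x + rnorm(n, 0, 0.3)
  f <- fit_protein_model(y, m, x, max_power = 1)
  zm <- as.vector(scale(m - mean(m))); zx <- as.vector(scale(x))
  X <- cbind(1, zm, zx)
  coef <- solve(crossprod(X), crossprod(X, y))   # brute-force normal equations
  expect_equal(f$beta, coef[3], tolerance = 1e-10)
})

test_that("beta is invariant to affine rescaling of the raw miRNA", {
  set.seed(4)
  n <- 50
  m <- rnorm(n); x <- rnorm(n)
  y <- 0.2 * m - 0.4 * x + rnorm(n, 0, 0.4)
  f1 <- fit_protein_model(y, m, x, 2)
  f2 <- fit_protein_model(y, m, 100 * x + 3, 2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_protein_model(rnorm(20), rnorm(20), rep(1, 20), 2),
               "constant miRNA")
  expect_error(fit_protein_model(rnorm(4), rnorm(4), rnorm(4), 2),
               "complete triples")
})

test_that("beta landscape recovers planted betas and respects within-week BH", {
  co <- generate_cohort(tiny_cohort_config(seed = 6))
  land <- beta_landscape(co$protein, co$mrna, co$mirna, co$annotation)
  # one record per (miRNA, protein, week)
  expect_equal(nrow(land),
               nrow(co$mirna$values) * nrow(co$protein$values) * 3)
  truth <- co$truth$betas
  sig <- land[land$significant, ]
  hit <- merge(truth, sig, by = c("mirna_id", "protein_id"))
  expect_equal(nrow(hit), 3 * nrow(truth))     # every planted triple, every week
  expect_true(all(sign(hit$beta.x) == sign(hit$beta.y)))
  # q is BH within week over the fitted records
  for (w in c(0, 12, 25)) {
    sel <- land$week == w & !is.na(land$p)
    expect_equal(land$q[sel], bh_oracle(land$p[sel]), tolerance = 1e-12)
  }
})

test_that("landscape betas equal the scalar fit on complete data", {
  co <- generate_cohort(tiny_cohort_config(seed = 13, missing_rate = 0))
  land <- beta_landscape(co$protein, co$mrna, co$mirna, co$annotation, weeks = 0)
  pick <- land[c(3, 57, 101), ]
  samp <- co$annotation$sample_id[co$annotation$week == 0]
  for (i in seq_len(nrow(pick))) {
    f <- fit_protein_model(co$protein$values[pick$protein_id[i], samp],
                           co$mrna$values[pick$protein_id[i], samp],
                           co$mirna$values[pick$mirna_id[i], samp], 2)
    expect_equal(pick$beta[i], f$beta, tolerance = 1e-8)
    expect_equal(pick$p[i], f$p, tolerance = 1e-8)
  }
})

test_that("hub ranking computes shares per week", {
  rec <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m1"),
    protein_id = c("P1", "P1", "P1", "P2"),
    week = 0, significant = TRUE)
  hubs <- rank_hubs(rec)
  expect_equal(hubs$protein_id, c("P1", "P2"))
  expect_equal(hubs$share, c(0.75, 0.25))

  one <- rank_hubs(data.frame(mirna_id = "m", protein_id = "P", week = 25,
                              significant = TRUE))
  expect_equal(one$share, 1)
  expect_equal(nrow(rank_hubs(rec[0, ])), 0)
})

test_that("beta stability: identical weeks give the diagonal, r = 1", {
  rec0 <- data.frame(mirna_id = rep(paste0("m", 1:6), 2),
                     protein_id = "P1", week = rep(c(0, 25), each = 6),
                     beta = rep(c(0.5, -0.2, 0.9, 0.1, -0.6, 0.3), 2),
                     significant = TRUE)
  st <- beta_stability(rec0, 0, 25)
  expect_equal(st$pairs$beta_a, st$pairs$beta_b)
  expect_equal(st$r, 1)

  none <- rec0[rec0$week == 0, ]
  expect_warning(st2 <- beta_stability(none, 0, 25), "no common")
  expect_true(is.na(st2$r))
})
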