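# Bivariate miRNA + mRNA -> protein association model: protein expression
# regressed on polynomial terms of the in-cis mRNA plus a linear miRNA term;
# the miRNA coefficient ("beta") is the per-time-point association measure.

#' Fit the protein ~ polynomial(mRNA) + miRNA model
#'
#' Least-squares fit of
#' `protein ~ 1 + sum_{k=1..max_power} mRNA^k + miRNA` on complete triples.
#' The mRNA power terms absorb a flexible (polynomial) dependence of protein
#' on its own transcript; the miRNA enters linearly and its coefficient is
#' the beta value. Predictors are standardized before fitting (the mRNA
#' powers after centering the transcript, the miRNA to unit variance), so
#' beta is scale-free: invariant to affine rescaling of the raw miRNA.
#'
#' @param protein,mrna,mirna numeric vectors over the same samples.
#' @param max_power highest mRNA power (default 2).
#' @return list: `beta`, `se`, `t`, `p` (two-sided test of beta = 0), `n`,
#'   `df`, `coefficients` (full coefficient vector).
#' @export
fit_protein_model <- function(protein, mrna, mirna, max_power = 2) {
  stopifnot(length(protein) == length(mrna), length(mrna) == length(mirna),
            max_power >= 1)
  idx <- !(is.na(protein) | is.na(mrna) | is.na(mirna))
  n <- sum(idx)
  if (n < max_power + 3)
    stop(sprintf("need >= %d complete triples, have %d", max_power + 3, n))
  y <- protein[idx]; m <- mrna[idx]; x <- mirna[idx]
  if (stats::sd(x) == 0) stop("constant miRNA values: rank-deficient design")
  if (stats::sd(m) == 0) stop("constant mRNA values: rank-deficient design")
  mc <- m - mean(m)
  Z <- vapply(seq_len(max_power), function(k) {
    col <- mc^k
    (col - mean(col)) / stats::sd(col)
  }, numeric(n))
  xs <- (x - mean(x)) / stats::sd(x)
  X <- cbind(intercept = 1, Z, mirna = xs)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient design")
  dfree <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfree
  XtXinv <- chol2inv(fit$qr$qr[seq_len(ncol(X)), , drop = FALSE])
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- unname(fit$coefficients["mirna"])
  se_b <- unname(se[ncol(X)])
  tval <- if (se_b > 0) beta / se_b else sign(beta) * Inf
  p <- 2 * stats::pt(abs(tval), df = dfree, lower.tail = FALSE)
  list(beta = beta, se = se_b, t = tval, p = p, n = n, df = dfree,
       coefficients = fit$coefficients)
}

#' Beta landscape: every (miRNA, protein) pair at every time point
#'
#' Applies [fit_protein_model()] to one miRNA at a time for every protein
#' (with its in-cis mRNA) and every requested week, and BH-adjusts p-values
#' within week across all pairs. Weeks with too few samples are skipped with
#' a message.
#'
#' @param proteins,mrnas,mirnas [omics_matrix()] layers sharing sample ids.
#' @param ann sample annotation (defines the week of each sample).
#' @param cis_map named character vector `protein_id -> mrna_id`; defaults to
#'   identity on the protein ids present in the mRNA matrix.
#' @param weeks integer vector of time points.
#' @param max_power highest mRNA power.
#' @param fdr BH threshold marking `significant`.
#' @return data.frame: `mirna_id`, `protein_id`, `week`, `beta`, `se`, `p`,
#'   `n`, `q`, `significant`. Pairs that cannot be fit (too few complete
#'   triples, constant miRNA) carry `NA` and are excluded from the BH family.
#' @export
beta_landscape <- function(proteins, mrnas, mirnas, ann, cis_map = NULL,
                           weeks = c(0, 12, 25), max_power = 2, fdr = 0.05) {
  stopifnot(inherits(proteins, "omics_matrix"), inherits(mrnas, "omics_matrix"),
            inherits(mirnas, "omics_matrix"))
  if (is.null(cis_map)) {
    ids <- intersect(rownames(proteins$values), rownames(mrnas$values))
    if (!length(ids)) stop("empty cis map: no protein id matches an mRNA id")
    cis_map <- stats::setNames(ids, ids)
  }
  prot_ids <- intersect(rownames(proteins$values), names(cis_map))
  bad <- setdiff(cis_map[prot_ids], rownames(mrnas$values))
  if (length(bad)) stop("cis mRNA id(s) absent from mRNA matrix: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  shared <- Reduce(intersect, list(colnames(proteins$values),
                                   colnames(mrnas$values),
                                   colnames(mirnas$values)))
  mir_ids <- rownames(mirnas$values)
  n_par <- max_power + 2L   # intercept + powers + miRNA
  out <- list()
  for (w in weeks) {
    samp <- intersect(shared, ann$sample_id[ann$week == w])
    if (length(samp) < n_par + 2) {
      message("week ", w, " skipped: only ", length(samp), " samples")
      next
    }
    Xmir <- t(mirnas$values[, samp, drop = FALSE])       # samples x miRNAs
    obs <- !is.na(Xmir)
    n_s <- nrow(Xmir); n_m <- ncol(Xmir)
    for (prot in prot_ids) {
      y <- proteins$values[prot, samp]
      g <- mrnas$values[cis_map[[prot]], samp]
      base <- !(is.na(y) | is.na(g))
      if (sum(base) < n_par + 2) next
      mc <- g - mean(g[base])
      Zb <- cbind(1, vapply(seq_len(max_power), function(k) mc^k, numeric(n_s)))
      beta <- se <- pv <- rep(NA_real_, n_m)
      nn <- integer(n_m)
      for (j in seq_len(n_m)) {
        idx <- base & obs[, j]
        nj <- sum(idx)
        nn[j] <- nj
        if (nj < n_par + 1) next
        x <- Xmir[idx, j]
        sdx <- stats::sd(x)
        if (!is.finite(sdx) || sdx == 0) next
        W <- cbind(Zb[idx, , drop = FALSE], (x - mean(x)) / sdx)
        ys <- y[idx]
        XtX <- crossprod(W)
        R <- tryCatch(chol(XtX), error = function(e) NULL)
        if (is.null(R)) next
        Xty <- crossprod(W, ys)
        coef <- backsolve(R, forwardsolve(t(R), Xty))
        rss <- max(sum(ys^2) - sum(coef * Xty), 0)
        dfree <- nj - n_par
        sigma2 <- rss / dfree
        inv_last <- chol2inv(R)[n_par, n_par]
        se_b <- sqrt(sigma2 * inv_last)
        beta[j] <- coef[n_par]
        se[j] <- se_b
        pv[j] <- if (se_b > 0) 2 * stats::pt(abs(beta[j] / se_b), df = dfree,
                                             lower.tail = FALSE) else 0
      }
      out[[paste(prot, w)]] <- data.frame(
        mirna_id = mir_ids, protein_id = prot, week = w,
        beta = beta, se = se, p = pv, n = nn, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no week had enough samples")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- NA_real_
  for (w in unique(res$week)) {
    sel <- res$week == w
    res$q[sel] <- bh_adjust(res$p[sel])
  }
  res$significant <- !is.na(res$q) & res$q < fdr
  res
}

#' Rank protein hubs by number of associated miRNAs
#'
#' @param records significance-filtered (or `significant`-flagged)
#'   [beta_landscape()] records.
#' @return data.frame per (protein, week): `n_assoc_mirnas` (distinct
#'   significant miRNAs) and `share` of all significant associations at that
#'   week; sorted descending within week.
#' @export
rank_hubs <- function(records) {
  if ("significant" %in% colnames(records))
    records <- records[records$significant, , drop = FALSE]
  if (!nrow(records))
    return(data.frame(protein_id = character(0), week = integer(0),
                      n_assoc_mirnas = integer(0), share = numeric(0)))
  agg <- stats::aggregate(mirna_id ~ protein_id + week, data = records,
                          FUN = function(x) length(unique(x)))
  colnames(agg)[3] <- "n_assoc_mirnas"
  totals <- tapply(agg$n_assoc_mirnas, agg$week, sum)
  agg$share <- agg$n_assoc_mirnas / as.numeric(totals[as.character(agg$week)])
  agg <- agg[order(agg$week, -agg$n_assoc_mirnas), c("protein_id", "week",
                                                     "n_assoc_mirnas", "share")]
  rownames(agg) <- NULL
  agg
}

#' Pair betas between two weeks
#'
#' For every (miRNA, protein) pair, the beta at `week_a` against the beta at
#' `week_b`, restricted (by default) to pairs significant in at least one of
#' the two weeks; the Pearson correlation of the scatter summarizes how
#' stable the association landscape is over treatment.
#'
#' @param records [beta_landscape()] records.
#' @param week_a,week_b the two time points.
#' @param sig_in_either restrict to pairs significant in at least one week.
#' @return list: `pairs` (data.frame `mirna_id`, `protein_id`, `beta_a`,
#'   `beta_b`) and `r` (Pearson correlation; `NA` with a warning when no
#'   common pairs).
#' @export
beta_stability <- function(records, week_a = 0, week_b = 25,
                           sig_in_either = TRUE) {
  ra <- records[records$week == week_a & !is.na(records$beta), , drop = FALSE]
  rb <- records[records$week == week_b & !is.na(records$beta), , drop = FALSE]
  mg <- merge(ra[, c("mirna_id", "protein_id", "beta", "significant")],
              rb[, c("mirna_id", "protein_id", "beta", "significant")],
              by = c("mirna_id", "protein_id"), suffixes = c("_a", "_b"))
  if (sig_in_either)
    mg <- mg[mg$significant_a | mg$significant_b, , drop = FALSE]
  pairs <- mg[, c("mirna_id", "protein_id", "beta_a", "beta_b")]
  if (!nrow(pairs)) {
    warning("no common (miRNA, protein) pairs between the two weeks")
    return(list(pairs = pairs, r = NA_real_))
  }
  r <- if (nrow(pairs) >= 3) stats::cor(pairs$beta_a, pairs$beta_b) else NA_real_
  list(pairs = pairs, r = r)
}
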