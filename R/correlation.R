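# miRNA-mRNA correlation landscape and miRNA-proliferation correlation,
# with Bonferroni + |r| filters.

.corr_p <- function(r, n) {
  t <- abs(r) * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  ifelse(n >= 3, 2 * stats::pt(t, df = n - 2, lower.tail = FALSE), NA_real_)
}

#' Pairwise Pearson correlations between two expression layers
#'
#' Pearson `r` on pairwise-complete shared samples for every (feature of
#' `a`) x (feature of `b`) pair, with two-sided p-values from the t
#' transform and Bonferroni adjustment over the declared family (all
#' non-flagged pairs computed in this call). Zero-variance features and
#' pairs with fewer than 3 complete observations are flagged and excluded
#' from the family size.
#'
#' @param a,b [omics_matrix()] objects sharing sample ids (e.g. miRNA and
#'   mRNA layers).
#' @param ann optional sample annotation, required when `weeks` is given.
#' @param weeks optional integer vector restricting samples to these weeks.
#' @param features_a,features_b optional feature subsets.
#' @return data.frame: `id_a`, `id_b`, `r`, `n`, `p`, `p_adj`, `week`
#'   (`"pooled"` or the single week), `flagged`. Attribute `family_size`.
#' @export
pairwise_corr <- function(a, b, ann = NULL, weeks = NULL,
                          features_a = NULL, features_b = NULL) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  samples <- intersect(colnames(a$values), colnames(b$values))
  if (!is.null(weeks)) {
    if (is.null(ann)) stop("`ann` is required when `weeks` is given")
    samples <- intersect(samples, ann$sample_id[ann$week %in% weeks])
  }
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  va <- a$values[features_a %||% rownames(a$values), samples, drop = FALSE]
  vb <- b$values[features_b %||% rownames(b$values), samples, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(va), t(vb), use = "pairwise.complete.obs"))
  n <- tcrossprod((!is.na(va)) * 1, (!is.na(vb)) * 1)
  week_lab <- if (!is.null(weeks) && length(weeks) == 1) as.character(weeks)
              else "pooled"
  out <- data.frame(
    id_a = rep(rownames(va), times = ncol(r)),
    id_b = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), n = as.integer(as.vector(n)),
    stringsAsFactors = FALSE)
  out$flagged <- is.na(out$r) | out$n < 3
  out$p <- ifelse(out$flagged, NA_real_, .corr_p(out$r, out$n))
  m_family <- sum(!out$flagged)
  out$p_adj <- pmin(1, out$p * m_family)
  out$week <- week_lab
  attr(out, "family_size") <- m_family
  out
}

#' Filter correlation records on adjusted p and effect size
#'
#' Keeps records with `p_adj <= alpha` and `|r| >= min_abs_r`; both
#' boundaries inclusive. The family size must have been fixed upstream.
#'
#' @param records a [pairwise_corr()] / [corr_with_score()] result.
#' @param alpha Bonferroni-adjusted significance level.
#' @param min_abs_r minimal absolute Pearson correlation.
#' @return The significant subset of `records`.
#' @export
filter_corr <- function(records, alpha = 0.05, min_abs_r = 0.3) {
  keep <- !is.na(records$p_adj) & records$p_adj <= alpha &
    abs(records$r) >= min_abs_r
  records[keep, , drop = FALSE]
}

#' Proliferation score from a signature gene set
#'
#' Mean of per-gene standardized (z-scored across samples) expression over
#' the signature genes present in the matrix; invariant to per-gene affine
#' rescaling of the input.
#'
#' @param mrna mRNA [omics_matrix()].
#' @param genes character vector of signature gene ids.
#' @return Named numeric vector, one score per sample.
#' @export
proliferation_score <- function(mrna, genes) {
  stopifnot(inherits(mrna, "omics_matrix"))
  present <- intersect(genes, rownames(mrna$values))
  if (!length(present)) stop("no signature gene present in the matrix")
  v <- mrna$values[present, , drop = FALSE]
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  if (any(sdv == 0, na.rm = TRUE)) stop("constant signature gene(s)")
  z <- (v - mu) / sdv
  colMeans(z, na.rm = TRUE)
}

#' Correlate miRNAs with a per-sample score
#'
#' Pearson correlation of each miRNA with a per-sample score (proliferation
#' score, or a mitosis-count proxy), per week and/or pooled across weeks.
#' Bonferroni family = miRNAs tested x strata emitted in this call.
#'
#' @param mirna miRNA [omics_matrix()].
#' @param score named numeric vector (sample id -> score value).
#' @param ann sample annotation (needed for per-week strata).
#' @param per_week also emit one stratum per week in addition to pooled.
#' @param score_name label written into `id_b`.
#' @return data.frame like [pairwise_corr()], with `week` in
#'   `{"0","12","25","pooled"}`. Strata with fewer than 3 scored samples are
#'   skipped with a warning; constant-score strata are flagged.
#' @export
corr_with_score <- function(mirna, score, ann = NULL, per_week = TRUE,
                            score_name = "score") {
  stopifnot(inherits(mirna, "omics_matrix"))
  if (is.null(names(score))) stop("`score` must be named by sample id")
  samples <- intersect(colnames(mirna$values), names(score)[!is.na(score)])
  strata <- list(pooled = samples)
  if (per_week) {
    if (is.null(ann)) stop("`ann` is required for per-week strata")
    for (w in .week_levels)
      strata[[as.character(w)]] <- intersect(samples, ann$sample_id[ann$week == w])
  }
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (length(s) < 3) {
      warning("stratum '", nm, "' has fewer than 3 scored samples; skipped")
      next
    }
    v <- mirna$values[, s, drop = FALSE]
    sc <- score[s]
    const <- stats::sd(sc) == 0
    r <- if (const) rep(NA_real_, nrow(v)) else
      suppressWarnings(as.vector(stats::cor(t(v), sc, use = "pairwise.complete.obs")))
    n <- as.integer(rowSums(!is.na(v) & rep(!is.na(sc), each = nrow(v))))
    df <- data.frame(id_a = rownames(v), id_b = score_name, r = r, n = n,
                     flagged = const | is.na(r) | n < 3, stringsAsFactors = FALSE)
    df$p <- ifelse(df$flagged, NA_real_, .corr_p(df$r, df$n))
    df$week <- nm
    out[[nm]] <- df
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no stratum had enough scored samples")
  m_family <- sum(!out$flagged)
  out$p_adj <- pmin(1, out$p * m_family)
  rownames(out) <- NULL
  out <- out[, c("id_a", "id_b", "r", "n", "p", "p_adj", "week", "flagged")]
  attr(out, "family_size") <- m_family
  out
}
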