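# Stratified two-sample differential expression with BH control, fold
# changes, signature set comparison, and the nomenclature-number analysis.

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with midranks, tie
#' correction and continuity correction. The reported statistic is the
#' rank-sum of the first group.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @return list with `statistic` (rank-sum of `x`), `p`, and `exact` flag.
#' @export
wilcoxon_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) && !length(y)) stop("both groups are empty")
  if (!length(x) || !length(y)) stop("each group needs >= 1 observation")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
       p = wt$p.value, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, order-preserving); `NA` entries
#' propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-feature fold change between two sample groups
#'
#' `FC = 2^(mean_a - mean_b)` on the log2 matrix, missing values dropped per
#' group. A feature missing in an entire group gets `NA` (flagged, not an
#' error).
#'
#' @param m an [omics_matrix()].
#' @param a,b disjoint non-empty character vectors of sample ids.
#' @return Named numeric vector of linear-scale fold changes.
#' @export
fold_change <- function(m, a, b) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  va <- m$values[, a, drop = FALSE]
  vb <- m$values[, b, drop = FALSE]
  2^(rowMeans(va, na.rm = TRUE) - rowMeans(vb, na.rm = TRUE))
}

#' Stratified differential expression
#'
#' Two-sample Wilcoxon tests per feature between two strata defined on the
#' annotation, with BH adjustment over exactly the features tested in this
#' contrast and fold changes of group A over group B.
#'
#' Two contrast kinds are supported: `"weeks"` compares samples at
#' `weeks[2]` (group A) against `weeks[1]` (group B), optionally within one
#' arm and/or response group, so that a fold change below 1 reads as
#' downregulation over the course of treatment; `"response"` compares OR
#' (group A) against non-OR (group B) at a single `week` (samples with
#' unknown response are excluded).
#'
#' @param m an [omics_matrix()] (preprocessed).
#' @param ann sample annotation data.frame.
#' @param contrast `"weeks"` or `"response"`.
#' @param weeks length-2 integer vector `(from, to)` for the `"weeks"` contrast.
#' @param week single week for the `"response"` contrast.
#' @param arm restrict to one arm (`"chemo"`/`"bev"`), or `NULL` for both.
#' @param response restrict to one response group, or `NULL` for all.
#' @param er restrict to one ER status (default `"pos"`), or `NULL` for all.
#' @param thr [thresholds()]; `de_fdr` marks significance.
#' @return data.frame with one row per feature: `feature_id`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `statistic`, `p`, `q`, `fold_change`,
#'   `direction` (`up` = higher in group A), `significant`. Attributes
#'   `n_up`/`n_down` count significant features by direction. Empty (with a
#'   warning) when a stratum has fewer than 3 samples.
#' @export
run_de <- function(m, ann, contrast = c("weeks", "response"),
                   weeks = c(0, 25), week = 0,
                   arm = NULL, response = NULL, er = "pos",
                   thr = thresholds()) {
  stopifnot(inherits(m, "omics_matrix"))
  contrast <- match.arg(contrast)
  check_samples_annotated(m, ann)
  ann <- ann[ann$sample_id %in% colnames(m$values), , drop = FALSE]
  if (!is.null(er)) ann <- ann[ann$er_status == er, , drop = FALSE]
  if (!is.null(arm)) ann <- ann[ann$arm == arm, , drop = FALSE]
  if (contrast == "weeks") {
    stopifnot(length(weeks) == 2)
    if (!is.null(response)) ann <- ann[ann$response == response, , drop = FALSE]
    a <- ann$sample_id[ann$week == weeks[2]]
    b <- ann$sample_id[ann$week == weeks[1]]
    ga <- paste0("week", weeks[2]); gb <- paste0("week", weeks[1])
  } else {
    ann <- ann[ann$week == week & ann$response != "unknown", , drop = FALSE]
    a <- ann$sample_id[ann$response == "OR"]
    b <- ann$sample_id[ann$response == "nonOR"]
    ga <- paste0("OR@week", week); gb <- paste0("nonOR@week", week)
  }
  empty <- data.frame(feature_id = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0), n_b = integer(0),
                      statistic = numeric(0), p = numeric(0), q = numeric(0),
                      fold_change = numeric(0), direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(a) < 3 || length(b) < 3) {
    warning(sprintf("stratum with < 3 samples (%s: %d, %s: %d); skipped",
                    ga, length(a), gb, length(b)))
    return(empty)
  }
  va <- m$values[, a, drop = FALSE]
  vb <- m$values[, b, drop = FALSE]
  feats <- rownames(m$values)
  stat <- p <- rep(NA_real_, length(feats))
  n_a <- rowSums(!is.na(va)); n_b <- rowSums(!is.na(vb))
  for (i in seq_along(feats)) {
    if (n_a[i] < 1 || n_b[i] < 1) next
    w <- wilcoxon_two_sample(va[i, ], vb[i, ])
    stat[i] <- w$statistic; p[i] <- w$p
  }
  q <- bh_adjust(p)
  fc <- fold_change(m, a, b)
  direction <- ifelse(is.na(fc), NA_character_, ifelse(fc >= 1, "up", "down"))
  out <- data.frame(feature_id = feats, group_a = ga, group_b = gb,
                    n_a = n_a, n_b = n_b, statistic = stat, p = p, q = q,
                    fold_change = unname(fc), direction = direction,
                    significant = !is.na(q) & q < thr$de_fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$significant & out$direction == "up", na.rm = TRUE)
  attr(out, "n_down") <- sum(out$significant & out$direction == "down", na.rm = TRUE)
  out
}

#' Significant signed set from a differential-expression table
#'
#' @param de a [run_de()] result.
#' @return Named character vector `feature -> "up"/"down"` over the
#'   significant features.
#' @export
de_signature <- function(de) {
  sig <- de[de$significant & !is.na(de$direction), , drop = FALSE]
  stats::setNames(sig$direction, sig$feature_id)
}

#' Compare two signed signatures (Venn partition + direction concordance)
#'
#' @param a,b named character vectors `feature -> "up"/"down"`.
#' @return list of class `signature_comparison` with the overlap, exclusive
#'   sets, and concordant/discordant counts among the overlap.
#' @export
compare_signatures <- function(a, b) {
  stopifnot(all(a %in% c("up", "down")), all(b %in% c("up", "down")))
  ov <- intersect(names(a), names(b))
  structure(list(
    set_a = a, set_b = b,
    overlap = ov,
    a_only = setdiff(names(a), names(b)),
    b_only = setdiff(names(b), names(a)),
    concordant = sum(a[ov] == b[ov]),
    discordant = sum(a[ov] != b[ov])
  ), class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("<signature_comparison> |A|=%d |B|=%d overlap=%d (A-only %d, B-only %d); %d concordant / %d discordant\n",
              length(x$set_a), length(x$set_b), length(x$overlap),
              length(x$a_only), length(x$b_only), x$concordant, x$discordant))
  invisible(x)
}

#' Extract the miRBase family number from a miRNA name
#'
#' Parses forms like `hsa-miR-4465`, `miR-125b-2-3p` (duplicate-locus suffix
#' and arm ignored, the family number is kept) and returns `NA` for let-7
#' family members (which carry no number) and unparseable names.
#'
#' @param name character vector of miRBase-style names.
#' @return Integer vector of family numbers (`NA` where none), named by input.
#' @export
mirna_numeric_id <- function(name) {
  out <- rep(NA_integer_, length(name))
  mir <- regmatches(name, regexpr("(?i)(?:hsa-)?mir-([0-9]+)", name, perl = TRUE))
  has <- grepl("(?i)(?:hsa-)?mir-[0-9]+", name, perl = TRUE)
  is_let <- grepl("(?i)(?:hsa-)?let-7", name, perl = TRUE)
  out[has & !is_let] <- as.integer(sub("(?i).*mir-([0-9]+).*", "\\1",
                                       name[has & !is_let], perl = TRUE))
  stats::setNames(out, name)
}

#' Fraction of signature miRNAs with high nomenclature numbers, per direction
#'
#' miRBase numbers are assigned in discovery order, so a signature dominated
#' by numbers above the cutoff points at recently annotated (less
#' characterized) miRNAs.
#'
#' @param sig named character vector `mirna -> "up"/"down"`.
#' @param cutoff nomenclature number threshold (exclusive; default 3000).
#' @return data.frame per direction: number parseable, number above cutoff,
#'   fraction (`NA` when no name parses).
#' @export
nomenclature_fraction <- function(sig, cutoff = 3000) {
  res <- lapply(c(up = "up", down = "down"), function(dir) {
    ids <- mirna_numeric_id(names(sig)[sig == dir])
    n_parse <- sum(!is.na(ids))
    n_above <- sum(ids > cutoff, na.rm = TRUE)
    data.frame(direction = dir, n_parseable = n_parse, n_above = n_above,
               fraction = if (n_parse) n_above / n_parse else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
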