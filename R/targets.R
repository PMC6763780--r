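# Target-prediction score filtering, cross-referencing with correlation and
# differential regulation, and hypergeometric gene-set over-representation.

#' Filter target predictions by source-specific score thresholds
#'
#' TargetScan records are kept iff the context++ score is at most
#' `targetscan_max_context` (more negative = stronger predicted repression);
#' microT-CDS records iff the miTG score is at least `microt_min_score`
#' (higher = stronger). Both boundaries inclusive. `microt_invert` flips the
#' microT direction for compatibility with exports that store an eliminated-
#' confidence score instead.
#'
#' @param preds data.frame from [read_predictions()].
#' @param thr [thresholds()].
#' @param microt_invert keep microT records with score below the threshold
#'   instead (non-standard reading).
#' @return The retained records; idempotent and order-invariant.
#' @export
filter_predictions <- function(preds, thr = thresholds(), microt_invert = FALSE) {
  bad <- setdiff(unique(preds$source), c("targetscan", "microt"))
  if (length(bad)) stop("unknown prediction source(s): ",
                        paste(bad, collapse = ", "))
  keep_ts <- preds$source == "targetscan" & preds$score <= thr$targetscan_max_context
  keep_mt <- if (microt_invert)
    preds$source == "microt" & preds$score < thr$microt_min_score
  else
    preds$source == "microt" & preds$score >= thr$microt_min_score
  preds[keep_ts | keep_mt, , drop = FALSE]
}

#' Cross-reference correlations, predictions, and gene regulation
#'
#' Joins the miRNA-mRNA correlation records with the filtered prediction
#' tables and the gene-level differential regulation, and flags the canonical
#' repression pattern: a predicted target that is negatively correlated with
#' its miRNA and regulated in the direction opposite to the miRNA. Pairs are
#' never invented: the output is a subset of (correlation pairs) union
#' (prediction pairs).
#'
#' @param corr [pairwise_corr()] records (typically after [filter_corr()]).
#' @param preds filtered prediction records.
#' @param gene_de optional [run_de()] table for the genes (mRNA layer),
#'   supplying each gene's direction and fold change.
#' @param mirna_sign optional named character vector `mirna -> "up"/"down"`
#'   giving each miRNA's own regulation.
#' @return data.frame per (miRNA, gene): `r`, `p_adj`, prediction flags per
#'   source, `gene_direction`, `gene_fc`, `mirna_direction`, `consistent`,
#'   and a `category` label (`predicted_and_anticorrelated`,
#'   `predicted_positively_correlated`, `correlated_only`, `predicted_only`).
#' @export
match_targets <- function(corr, preds, gene_de = NULL, mirna_sign = NULL) {
  ckey <- paste(corr$id_a, corr$id_b, sep = "\r")
  pkey <- paste(preds$mirna_id, preds$gene_id, sep = "\r")
  keys <- union(ckey, pkey)
  split_keys <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(split_keys, `[`, character(1), 1),
    gene_id = vapply(split_keys, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  ci <- match(keys, ckey)
  out$r <- corr$r[ci]
  out$p_adj <- corr$p_adj[ci]
  out$predicted_targetscan <- keys %in% pkey[preds$source == "targetscan"]
  out$predicted_microt <- keys %in% pkey[preds$source == "microt"]
  predicted <- out$predicted_targetscan | out$predicted_microt
  if (!is.null(gene_de)) {
    gi <- match(out$gene_id, gene_de$feature_id)
    out$gene_direction <- gene_de$direction[gi]
    out$gene_fc <- gene_de$fold_change[gi]
  } else {
    out$gene_direction <- NA_character_
    out$gene_fc <- NA_real_
  }
  out$mirna_direction <- if (!is.null(mirna_sign))
    unname(mirna_sign[out$mirna_id]) else NA_character_
  out$consistent <- predicted & !is.na(out$r) & out$r < 0 &
    !is.na(out$gene_direction) & !is.na(out$mirna_direction) &
    out$gene_direction != out$mirna_direction
  correlated <- !is.na(out$r)
  out$category <- ifelse(predicted & correlated & out$r < 0,
                         "predicted_and_anticorrelated",
                  ifelse(predicted & correlated,
                         "predicted_positively_correlated",
                  ifelse(correlated, "correlated_only", "predicted_only")))
  out
}

#' Gene-set over-representation (one-sided Fisher / hypergeometric)
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and each
#' set (intersected with the universe), BH-adjusted across sets.
#'
#' @param gene_list character vector of genes of interest (intersected with
#'   the universe).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all considered genes.
#' @param ora_fdr BH threshold marking `significant`.
#' @return data.frame per set: `set_name`, `overlap`, `set_size`,
#'   `list_size`, `universe`, `p`, `q`, `significant`; sorted by `p`.
#' @export
ora_fisher <- function(gene_list, sets, universe, ora_fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- intersect(unique(gene_list), universe)
  nU <- length(universe); nL <- length(gene_list)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(s, gene_list))
    p <- stats::phyper(k - 1, length(s), nU - length(s), nL, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               list_size = nL, universe = nU, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < ora_fdr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
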