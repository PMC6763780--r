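# Hierarchical clustering with Pearson correlation distance and recursive
# gap-statistic thresholding (PART), plus cluster-clinical association and
# cross-time-point cluster persistence.

# Items in rows. Pairwise-complete Pearson distance d = 1 - r.
.pearson_dist <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 items for a distance matrix")
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  bad <- which(is.na(sds) | sds == 0)
  if (length(bad))
    stop("constant (zero-variance) item(s): ",
         paste(utils::head(rownames(x)[bad] %||% bad, 5), collapse = ", "))
  obs <- !is.na(x)
  npair <- tcrossprod(obs * 1)
  if (min(npair) < 3)
    stop("item pair(s) with fewer than 3 pairwise-complete observations")
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  if (anyNA(r)) stop("undefined correlation for some item pair (constant on the pairwise-complete subset)")
  d <- 1 - r
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Pearson correlation distance
#'
#' Distance `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation on
#' pairwise-complete observations; range \[0, 2\], zero diagonal. Items are
#' either the features (rows) or the samples (columns) of the matrix.
#'
#' @param m an [omics_matrix()] or a plain numeric matrix (items in rows).
#' @param axis cluster `"features"` or `"samples"` (ignored for plain matrices).
#' @return Symmetric distance matrix with item dimnames.
#' @export
pearson_distance <- function(m, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  x <- if (inherits(m, "omics_matrix")) {
    if (axis == "features") m$values else t(m$values)
  } else {
    as.matrix(m)
  }
  .pearson_dist(x)
}

#' Average-linkage (UPGMA) tree from a distance matrix
#'
#' @param d symmetric distance matrix (as from [pearson_distance()]).
#' @return An `stats::hclust` object; merge heights are non-decreasing.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(d), method = "average")
}

# Log within-cluster dispersion: pooled sum of squared deviations around
# cluster centroids (Tibshirani's W), tolerant of missing entries.
.log_wss <- function(x, labels) {
  w <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    sub <- x[idx, , drop = FALSE]
    ctr <- colMeans(sub, na.rm = TRUE)
    dev <- sweep(sub, 2, ctr)
    w <- w + sum(dev^2, na.rm = TRUE)
  }
  log(max(w, 1e-12))
}

.gap_tree <- function(x, distance) {
  if (distance == "pearson") average_linkage(.pearson_dist(x))
  else stats::hclust(stats::dist(x), method = "average")
}

.logw_curve <- function(x, hc, kmax) {
  vapply(seq_len(kmax), function(k) {
    labs <- if (k == 1) rep(1L, nrow(x)) else stats::cutree(hc, k = k)
    .log_wss(x, labs)
  }, numeric(1))
}

#' Gap-statistic choice of the number of clusters
#'
#' Computes the gap statistic over `k = 1..k_max` for the item matrix `x`
#' (items in rows): clusterings come from cutting an average-linkage tree
#' (Pearson correlation distance by default, as used throughout the
#' pipeline; Euclidean optionally) and the dispersion `W(k)` is the pooled
#' within-cluster sum of squares around cluster centroids. Reference
#' datasets are drawn uniformly over each observed dimension range. Returns
#' the smallest `k` with `Gap(k) >= Gap(k + 1) - s(k + 1)`, else 1.
#'
#' @param x numeric matrix, items in rows (may contain `NA`).
#' @param k_max maximum number of clusters considered.
#' @param n_ref number of reference datasets.
#' @param seed integer seed for the reference draws (`NULL` = current stream).
#' @param distance tree-building distance: `"pearson"` or `"euclidean"`.
#' @return Integer, the selected number of clusters.
#' @export
gap_best_k <- function(x, k_max = 10, n_ref = 20, seed = NULL,
                       distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  x <- x[, colSums(!is.na(x)) > 0, drop = FALSE]
  n <- nrow(x)
  if (n < 2) stop("need >= 2 items")
  if (distance == "pearson") {
    d <- .pearson_dist(x)
    if (max(d) < 1e-10) return(1L)   # all items effectively identical
  }
  kmax <- min(k_max, n - 1L)
  if (kmax < 2) return(1L)
  logw <- .logw_curve(x, .gap_tree(x, distance), kmax)
  rng_lo <- apply(x, 2, min, na.rm = TRUE)
  rng_hi <- apply(x, 2, max, na.rm = TRUE)
  ref_logw <- with_seed(seed, {
    t(vapply(seq_len(n_ref), function(b) {
      xb <- vapply(seq_len(ncol(x)),
                   function(j) stats::runif(n, rng_lo[j], rng_hi[j]),
                   numeric(n))
      .logw_curve(xb, .gap_tree(xb, distance), kmax)
    }, numeric(kmax)))
  })
  gap <- colMeans(ref_logw) - logw
  s <- apply(ref_logw, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  for (k in seq_len(kmax - 1L)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) return(as.integer(k))
  }
  1L
}

#' PART: recursive gap-thresholded partitioning
#'
#' Recursive cluster detection over a hierarchical tree: at each node the gap
#' statistic selects a number of clusters `k`; if `k > 1` the node is cut into
#' `k` parts and the procedure recurses into every part with at least
#' `min_size` items (smaller parts become outliers, labeled `"OUTLIER"`);
#' nodes where `k == 1` become final clusters. Nodes with fewer than
#' `2 * min_size` items are not split further. The result is deterministic
#' given `seed`.
#'
#' @param m an [omics_matrix()] or plain numeric matrix (items in rows).
#' @param axis cluster `"features"` or `"samples"`.
#' @param k_max,n_ref gap-statistic controls (see [gap_best_k()]).
#' @param min_size smallest admissible cluster.
#' @param seed integer seed driving the reference draws.
#' @return list of class `cluster_result` with fields `axis`, `assignment`
#'   (named character vector, cluster label or `"OUTLIER"` per item), `k`
#'   (number of non-outlier clusters), `tree` (root `hclust`), `params`.
#' @export
part_partition <- function(m, axis = c("features", "samples"),
                           k_max = 10, n_ref = 20, min_size = 5, seed = 1) {
  axis <- match.arg(axis)
  x <- if (inherits(m, "omics_matrix")) {
    if (axis == "features") m$values else t(m$values)
  } else as.matrix(m)
  n <- nrow(x)
  ids <- rownames(x) %||% as.character(seq_len(n))
  rownames(x) <- ids
  assignment <- stats::setNames(rep(NA_character_, n), ids)
  if (n < min_size) {
    warning("fewer than min_size items in total; returning a single cluster")
    assignment[] <- "1"
    return(structure(list(axis = axis, assignment = assignment, k = 1L,
                          tree = NULL,
                          params = list(k_max = k_max, n_ref = n_ref,
                                        min_size = min_size, seed = seed)),
                     class = "cluster_result"))
  }
  root_d <- .pearson_dist(x)
  root_tree <- average_linkage(root_d)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  counter$next_label <- 0L
  recurse <- function(items) {
    counter$i <- counter$i + 1L
    node_seed <- if (is.null(seed)) NULL else seed + 7919L * counter$i
    finalize <- function() {
      counter$next_label <- counter$next_label + 1L
      assignment[items] <<- as.character(counter$next_label)
    }
    if (length(items) < 2 * min_size) return(finalize())
    k <- gap_best_k(x[items, , drop = FALSE], k_max = k_max,
                    n_ref = n_ref, seed = node_seed)
    if (k == 1) return(finalize())
    d_sub <- .pearson_dist(x[items, , drop = FALSE])
    labs <- stats::cutree(average_linkage(d_sub), k = k)
    for (lv in sort(unique(labs))) {
      part <- items[labs == lv]
      if (length(part) < min_size) {
        assignment[part] <<- "OUTLIER"
      } else {
        recurse(part)
      }
    }
  }
  recurse(ids)
  k <- length(setdiff(unique(assignment), "OUTLIER"))
  structure(list(axis = axis, assignment = assignment, k = as.integer(k),
                 tree = root_tree,
                 params = list(k_max = k_max, n_ref = n_ref,
                               min_size = min_size, seed = seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("<cluster_result> axis=%s  k=%d  (%d items, %d outliers)\n",
              x$axis, x$k, length(x$assignment),
              sum(x$assignment == "OUTLIER")))
  print(tab)
  invisible(x)
}

#' Cluster-clinical association test
#'
#' Cross-tabulates cluster assignment (outliers excluded) against a
#' categorical clinical variable and tests independence with Fisher's exact
#' test. For tables where the exact network algorithm is infeasible, a seeded
#' Monte-Carlo p-value (1e5 draws) is used.
#'
#' @param cr a `cluster_result` over samples.
#' @param ann sample annotation data.frame (see [read_annotation()]).
#' @param var annotation column name; for `"response"`, `unknown` samples are
#'   excluded.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list with `table` (cluster x category contingency table) and `p`.
#' @export
cluster_clinical_association <- function(cr, ann, var, seed = 1) {
  stopifnot(inherits(cr, "cluster_result"))
  if (!var %in% colnames(ann)) stop("unknown annotation variable: ", var)
  keep <- names(cr$assignment)[cr$assignment != "OUTLIER"]
  idx <- match(keep, ann$sample_id)
  if (anyNA(idx)) stop("clustered sample(s) absent from annotation")
  val <- ann[[var]][idx]
  cl <- cr$assignment[keep]
  ok <- !is.na(val)
  if (identical(var, "response")) ok <- ok & val != "unknown"
  val <- as.character(val[ok]); cl <- cl[ok]
  if (length(unique(val)) < 2)
    stop("variable '", var, "' has fewer than two observed levels")
  tab <- table(cluster = cl, category = val)
  mc <- function() with_seed(seed,
    stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value)
  # exact network algorithm only for small tables (it is unstable beyond
  # that); otherwise seeded Monte-Carlo
  small <- all(dim(tab) == c(2, 2)) ||
    (prod(dim(tab)) <= 16 && sum(tab) <= 120)
  p <- if (small) tryCatch(stats::fisher.test(tab)$p.value,
                           error = function(e) mc()) else mc()
  list(table = tab, p = p)
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Cluster persistence across time points
#'
#' Matches the clusters of the first result to clusters at every later time
#' point by maximal Jaccard overlap (greedy, larger clusters first, one-to-one
#' within a time point) and reports, per matched chain, the fraction of
#' first-time-point members present in the matched cluster at every time
#' point. Label-invariant: identical partitions give 100% persistence.
#'
#' @param results list of `cluster_result` objects over the same item
#'   universe, in time order; names are used as time labels.
#' @return data.frame with one row per first-time-point cluster: label, size,
#'   matched label per later time point, `persistence` fraction.
#' @export
cluster_persistence <- function(results) {
  stopifnot(length(results) >= 2)
  universes <- lapply(results, function(r) sort(names(r$assignment)))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("cluster results must share one item universe")
  members <- function(r) {
    labs <- setdiff(unique(r$assignment), "OUTLIER")
    stats::setNames(lapply(labs, function(l) names(r$assignment)[r$assignment == l]), labs)
  }
  base <- members(results[[1]])
  later <- lapply(results[-1], members)
  ord <- order(-lengths(base))
  wk_names <- names(results)[-1] %||% paste0("t", seq_along(later))
  match_tab <- matrix(NA_character_, length(base), length(later),
                      dimnames = list(names(base), wk_names))
  for (w in seq_along(later)) {
    avail <- names(later[[w]])
    for (ci in ord) {
      if (!length(avail)) break
      jac <- vapply(avail, function(l) .jaccard(base[[ci]], later[[w]][[l]]),
                    numeric(1))
      sizes <- lengths(later[[w]][avail])
      best <- avail[order(-jac, -sizes)][1]
      match_tab[ci, w] <- best
      avail <- setdiff(avail, best)
    }
  }
  persistence <- vapply(seq_along(base), function(ci) {
    present <- rep(TRUE, length(base[[ci]]))
    for (w in seq_along(later)) {
      ml <- match_tab[ci, w]
      present <- present & if (is.na(ml)) FALSE else
        base[[ci]] %in% later[[w]][[ml]]
    }
    mean(present)
  }, numeric(1))
  out <- data.frame(cluster = names(base), size = lengths(base),
                    stringsAsFactors = FALSE)
  for (w in seq_along(wk_names)) out[[paste0("matched_", wk_names[w])]] <- match_tab[, w]
  out$persistence <- persistence
  rownames(out) <- NULL
  out[order(-out$size), , drop = FALSE]
}
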