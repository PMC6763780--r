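#' Per-sample median centering
#'
#' Subtracts from every sample column the median of its observed values, the
#' array-level location normalization applied before any statistics. The
#' missingness pattern is unchanged and the operation is idempotent.
#'
#' @param m an [omics_matrix()].
#' @return An `omics_matrix` whose every column has median (over observed
#'   values) equal to 0.
#' @export
median_center <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  omics_matrix(sweep(v, 2, med, "-"), m$layer)
}

#' Presence filter
#'
#' Removes features observed (non-missing) in less than `min_fraction` of
#' samples; the boundary is inclusive (a feature observed in exactly the
#' minimum fraction is retained). Feature order is preserved.
#'
#' @param m an [omics_matrix()].
#' @param min_fraction minimum observed fraction in (0, 1] (default: the 80%
#'   presence rule, see [thresholds()]).
#' @return list with elements `matrix` (the retained features) and
#'   `removed_ids` (character vector, original order).
#' @export
presence_filter <- function(m, min_fraction = 0.8) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  frac <- rowMeans(!is.na(m$values))
  keep <- frac >= min_fraction
  if (!any(keep))
    message("presence_filter: no features retained")
  list(matrix = omics_matrix(m$values[keep, , drop = FALSE], m$layer),
       removed_ids = rownames(m$values)[!keep])
}
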