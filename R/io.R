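#' Expression matrix container
#'
#' A thin S3 container for a features x samples matrix of log2 expression
#' values. Feature and sample identifiers live in the dimnames and must be
#' unique; missing entries are allowed (`NA`). The `layer` records which
#' molecular level the matrix holds and is fixed after construction.
#'
#' @param values numeric matrix with unique rownames (features) and unique
#'   colnames (samples); log2 scale.
#' @param layer one of `"mirna"`, `"mrna"`, `"protein"`.
#' @return An object of class `omics_matrix`.
#' @examples
#' m <- omics_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2"))), "mirna")
#' feature_ids(m)
#' @export
omics_matrix <- function(values, layer = c("mirna", "mrna", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature rownames and sample colnames")
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  structure(list(layer = layer, values = values), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples  (%.1f%% missing)\n",
              x$layer, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @rdname omics_matrix
#' @param m an `omics_matrix`.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an omics matrix by feature and/or sample ids
#'
#' @param m an `omics_matrix`.
#' @param features,samples character vectors of ids to keep (`NULL` keeps all).
#' @return An `omics_matrix` restricted to the requested ids, order as given.
#' @export
subset_omics <- function(m, features = NULL, samples = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(v))
    if (length(missing_f))
      stop("unknown feature id(s): ", paste(utils::head(missing_f, 5), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(v))
    if (length(missing_s))
      stop("unknown sample id(s): ", paste(utils::head(missing_s, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  omics_matrix(v, m$layer)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Empty cells and the token `NA` are read as missing. Any other non-numeric
#' cell is a format error reported with its row and column.
#'
#' @param path TSV file path.
#' @param layer molecular layer of the matrix (see [omics_matrix()]).
#' @return An `omics_matrix`; round-trips through [write_matrix()]
#'   value-exactly for finite entries.
#' @export
read_matrix <- function(path, layer = c("mirna", "mrna", "protein")) {
  layer <- match.arg(layer)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a feature-id column plus >=1 sample column")
  fid <- raw[[1]]
  if (anyDuplicated(fid))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sid <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(sid),
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    col <- raw[[j + 1]]
    is_missing <- is.na(col) | col == "" | col == "NA"
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is_missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (feature %s), column %s",
                   col[bad[1]], bad[1], fid[bad[1]], sid[j]))
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  omics_matrix(vals, layer)
}

#' Write an expression matrix to TSV
#'
#' Missing values are written as `NA`; see [read_matrix()] for the dialect.
#'
#' @param m an `omics_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.arm_levels <- c("chemo", "bev")
.week_levels <- c(0L, 12L, 25L)
.response_levels <- c("OR", "nonOR", "unknown")
.pam50_levels <- c("LumA", "LumB", "Basal", "Her2", "Normal")
.tstage_levels <- c("T2", "T3", "T4")

normalize_response <- function(x) {
  out <- rep("unknown", length(x))
  x0 <- tolower(gsub("[-_ ]", "", as.character(x)))
  out[!is.na(x0) & x0 == "or"] <- "OR"
  out[!is.na(x0) & x0 %in% c("nonor", "nr", "nonresponder")] <- "nonOR"
  out
}

validate_annotation <- function(ann) {
  req <- c("sample_id", "patient_id", "arm", "week", "er_status")
  miss <- setdiff(req, colnames(ann))
  if (length(miss)) stop("annotation misses required column(s): ",
                         paste(miss, collapse = ", "))
  ann$week <- suppressWarnings(as.integer(ann$week))
  if (any(is.na(ann$week) | !ann$week %in% .week_levels))
    stop("week values outside {0, 12, 25}: ",
         paste(unique(ann$week[!ann$week %in% .week_levels]), collapse = ", "))
  if (any(!ann$arm %in% .arm_levels))
    stop("arm values outside {chemo, bev}: ",
         paste(unique(ann$arm[!ann$arm %in% .arm_levels]), collapse = ", "))
  if (any(!ann$er_status %in% c("pos", "neg")))
    stop("er_status must be 'pos' or 'neg'")
  key <- paste(ann$patient_id, ann$week)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, week) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id(s)")
  if (!"response" %in% colnames(ann)) ann$response <- "unknown"
  ann$response <- normalize_response(ann$response)
  if ("pam50" %in% colnames(ann)) {
    bad <- !is.na(ann$pam50) & !ann$pam50 %in% .pam50_levels
    if (any(bad)) stop("invalid pam50 label(s): ",
                       paste(unique(ann$pam50[bad]), collapse = ", "))
  }
  if ("t_stage" %in% colnames(ann)) {
    bad <- !is.na(ann$t_stage) & !ann$t_stage %in% .tstage_levels
    if (any(bad)) stop("invalid t_stage label(s)")
  }
  for (col in c("pcr", "relapse"))
    if (col %in% colnames(ann)) ann[[col]] <- as.logical(ann[[col]])
  if ("proliferation_score" %in% colnames(ann))
    ann$proliferation_score <- as.numeric(ann$proliferation_score)
  if ("mitosis_count" %in% colnames(ann)) {
    ann$mitosis_count <- as.integer(ann$mitosis_count)
    if (any(!is.na(ann$mitosis_count) & ann$mitosis_count < 0))
      stop("mitosis_count must be non-negative")
  }
  rownames(ann) <- NULL
  ann
}

#' Read a sample annotation table
#'
#' TSV with required columns `sample_id`, `patient_id`, `arm` (chemo/bev),
#' `week` (0/12/25) and `er_status` (pos/neg). Optional columns: `response`
#' (OR / nonOR; anything else is coded `unknown` and excluded from
#' response-stratified tests), `pcr`, `pam50`, `proliferation_score`,
#' `mitosis_count`, `relapse`, `t_stage`. `(patient_id, week)` must be unique.
#'
#' @param path TSV file path.
#' @return A validated data.frame, one row per sample.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  validate_annotation(ann)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Descriptions are dropped, duplicate members deduplicated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(parts)))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    sets[[parts[1]]] <- members
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set name(s) in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target-prediction table
#'
#' TSV with columns `mirna_id`, `gene_id`, `score` and either a `source`
#' column or a single `source` supplied as an argument. Scores follow each
#' database's convention: TargetScan context++ (more negative = stronger),
#' microT-CDS miTG (higher = stronger).
#'
#' @param path TSV file path.
#' @param source `"targetscan"` or `"microt"` when the file has no source column.
#' @return data.frame with columns mirna_id, gene_id, source, score.
#' @export
read_predictions <- function(path, source = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("mirna_id", "gene_id", "score")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("prediction table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (!"source" %in% colnames(df)) {
    if (is.null(source)) stop("no source column and no `source` argument given")
    df$source <- source
  }
  if (any(!df$source %in% c("targetscan", "microt")))
    stop("unknown prediction source(s): ",
         paste(setdiff(unique(df$source), c("targetscan", "microt")), collapse = ", "))
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score))) stop("non-finite prediction score(s)")
  key <- paste(df$mirna_id, df$gene_id, df$source)
  df[!duplicated(key), c("mirna_id", "gene_id", "source", "score")]
}

#' Analysis thresholds
#'
#' One place for every cut-off the pipeline applies. Defaults follow the
#' study design: features observed in less than 80% of samples are removed,
#' differential expression is called at BH FDR < 5%, correlations are kept at
#' Bonferroni-adjusted p <= 0.05 with |r| >= 0.3, TargetScan predictions at
#' context++ score <= -0.35, microT-CDS at miTG score >= 0.7, fold-change
#' highlighting at 3x, the miRNA nomenclature-number split at 3000, and
#' over-representation at BH FDR < 5%.
#'
#' @param presence_min_fraction,de_fdr,corr_alpha,corr_min_abs_r
#'   preprocessing / testing cut-offs (see Description).
#' @param targetscan_max_context,microt_min_score prediction score cut-offs.
#' @param fold_highlight,nomenclature_cutoff,ora_fdr reporting cut-offs.
#' @return A named list of class `thresholds`.
#' @export
thresholds <- function(presence_min_fraction = 0.8,
                       de_fdr = 0.05,
                       corr_alpha = 0.05,
                       corr_min_abs_r = 0.3,
                       targetscan_max_context = -0.35,
                       microt_min_score = 0.7,
                       fold_highlight = 3.0,
                       nomenclature_cutoff = 3000L,
                       ora_fdr = 0.05) {
  for (p in c(presence_min_fraction, de_fdr, corr_alpha, ora_fdr))
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("probability thresholds must lie in (0, 1)")
  if (corr_min_abs_r < 0 || corr_min_abs_r > 1)
    stop("corr_min_abs_r must lie in [0, 1]")
  structure(list(
    presence_min_fraction = presence_min_fraction, de_fdr = de_fdr,
    corr_alpha = corr_alpha, corr_min_abs_r = corr_min_abs_r,
    targetscan_max_context = targetscan_max_context,
    microt_min_score = microt_min_score, fold_highlight = fold_highlight,
    nomenclature_cutoff = as.integer(nomenclature_cutoff), ora_fdr = ora_fdr
  ), class = "thresholds")
}

# Abort unless every matrix sample resolves to exactly one annotation row.
check_samples_annotated <- function(m, ann) {
  unknown <- setdiff(colnames(m$values), ann$sample_id)
  if (length(unknown))
    stop("sample id(s) absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  invisible(TRUE)
}
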