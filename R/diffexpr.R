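#' Construct an expression matrix with a two-group design
#'
#' @param values numeric matrix, features x samples, non-negative; row names
#'   are feature ids, column names sample ids.
#' @param condition named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @param unit `"TPM"` or `"counts"`.
#' @return An `expr_matrix` object.
#' @export
expression_matrix <- function(values, condition, unit = c("TPM", "counts")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids in expression matrix")
  if (any(values < 0)) stop("expression values must be non-negative")
  condition <- condition[colnames(values)]
  if (anyNA(condition)) stop("every sample needs a condition label")
  if (!all(condition %in% c("case", "control"))) {
    stop('conditions must be "case" or "control"')
  }
  structure(list(values = values, condition = condition, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples (%d case, %d control)\n",
              x$unit, nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' Convert raw counts to TPM
#'
#' Transcripts per million: per sample, each count is divided by the feature
#' length in kilobases and the resulting rates are rescaled to sum to 1e6.
#' A sample whose counts are all zero yields an all-zero TPM column (with a
#' warning) rather than NaN.
#'
#' @param expr an `expr_matrix` in counts.
#' @param lengths named numeric vector of feature lengths (nt) covering every
#'   feature, or a [feature_set()].
#' @return An `expr_matrix` in TPM.
#' @export
counts_to_tpm <- function(expr, lengths) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "counts") stop("counts_to_tpm expects an expr_matrix in counts")
  if (inherits(lengths, "feature_set")) {
    lengths <- stats::setNames(lengths$length_nt, lengths$feature_id)
  }
  len <- lengths[rownames(expr$values)]
  if (anyNA(len)) {
    stop("missing length for feature(s): ",
         paste(utils::head(rownames(expr$values)[is.na(len)], 5), collapse = ", "))
  }
  if (any(len < 1)) stop("feature lengths must be >= 1 nt")
  rate <- expr$values / (len / 1000)
  denom <- colSums(rate)
  zero_cols <- denom == 0
  if (any(zero_cols)) {
    warning("all-zero count column(s): ",
            paste(colnames(expr$values)[zero_cols], collapse = ", "),
            "; TPM set to zero for these samples")
    denom[zero_cols] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expression_matrix(tpm, expr$condition, unit = "TPM")
}

#' Classify differential expression from a statistics table
#'
#' Threshold classification in the DESeq2 reporting convention: a feature is
#' `up` when FDR < `alpha` (strict) and log2FC >= `min_abs_log2fc`
#' (inclusive), `down` when FDR < `alpha` and log2FC <= -`min_abs_log2fc`,
#' and `not_de` otherwise. Defaults mirror the usual FDR < 0.05,
#' |log2FC| >= 1 screen.
#'
#' @param stats data.frame with columns `feature_id`, `log2fc`, `fdr`.
#' @param alpha FDR threshold (strict).
#' @param min_abs_log2fc absolute log2 fold-change threshold (inclusive).
#' @return data.frame with columns `feature_id`, `log2fc`, `fdr`, `de_status`.
#' @export
classify_de <- function(stats, alpha = 0.05, min_abs_log2fc = 1.0) {
  stopifnot(all(c("feature_id", "log2fc", "fdr") %in% names(stats)))
  if (anyDuplicated(stats$feature_id)) {
    stop("duplicate feature_id in stats table: ",
         paste(unique(stats$feature_id[duplicated(stats$feature_id)]), collapse = ", "))
  }
  if (any(stats$fdr < 0 | stats$fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0, 1]")
  sig <- !is.na(stats$fdr) & stats$fdr < alpha
  status <- rep("not_de", nrow(stats))
  status[sig & stats$log2fc >= min_abs_log2fc] <- "up"
  status[sig & stats$log2fc <= -min_abs_log2fc] <- "down"
  out <- data.frame(feature_id = as.character(stats$feature_id),
                    log2fc = stats$log2fc, fdr = stats$fdr,
                    de_status = status, stringsAsFactors = FALSE)
  message(sprintf("classify_de: %d up, %d down, %d not DE",
                  sum(status == "up"), sum(status == "down"), sum(status == "not_de")))
  out
}

#' Naive two-group differential-expression test
#'
#' A deliberately simple stand-in for a count-model DE analysis, used to make
#' synthetic end-to-end runs self-contained; supply an external statistics
#' table (e.g. from DESeq2) for real data. Per feature: log2 fold change is
#' `log2((mean_case + 1) / (mean_control + 1))` on TPM with pseudo-count 1; a
#' two-sided Welch t-test is run on `log2(TPM + 1)`; p-values are adjusted by
#' Benjamini-Hochberg over all tested features.
#'
#' A feature with zero variance in both groups and equal means gets p = 1
#' (no evidence); zero variance with unequal means gets p = 0.
#'
#' @param expr an `expr_matrix` in TPM with >= 2 samples per condition.
#' @return data.frame with columns `feature_id`, `log2fc`, `p_value`, `fdr`.
#' @export
naive_de_test <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "TPM") stop("naive_de_test expects TPM (see counts_to_tpm)")
  case <- expr$values[, expr$condition == "case", drop = FALSE]
  ctrl <- expr$values[, expr$condition == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per condition")
  log2fc <- log2((rowMeans(case) + 1) / (rowMeans(ctrl) + 1))
  l1 <- log2(case + 1); l2 <- log2(ctrl + 1)
  m1 <- rowMeans(l1); m2 <- rowMeans(l2)
  v1 <- rowSums((l1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((l2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  data.frame(feature_id = rownames(expr$values),
             log2fc = log2fc,
             p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a DE statistics table (TSV: feature_id, log2fc, fdr)
#' @param path path to the TSV.
#' @return data.frame ready for [classify_de()].
#' @export
read_de_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "log2fc", "fdr") %in% names(df)))
  df
}

#' Read an expression matrix (TSV: first column feature_id, one column per sample)
#' @param path path to the TSV.
#' @param condition named vector mapping sample ids to case/control.
#' @param unit `"TPM"` or `"counts"`.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, condition, unit = c("TPM", "counts")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, condition, unit = match.arg(unit))
}

#' Write an expression matrix as TSV
#' @param expr an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
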