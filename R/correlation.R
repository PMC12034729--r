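#' Configuration for the pair correlation screen
#'
#' @param min_abs_r minimum absolute Pearson correlation (default 0.80).
#' @param alpha p-value threshold, strict (default 0.05).
#' @param sample_scope `"all_samples"` pools both conditions (default, what a
#'   plain TPM correlation of case+control profiles does); `"per_condition"`
#'   centres each feature within its condition before correlating, removing
#'   the group-shift component that differential expression alone induces.
#' @param transform `"none"` (raw TPM, default) or `"log2p1"`.
#' @param method `"t"` for the exact t-transform p-value (default) or
#'   `"permutation"` for a permutation p (useful at very small n).
#' @param n_perm permutations when `method = "permutation"`.
#' @param adjust_bh apply Benjamini-Hochberg across pair p-values before the
#'   alpha cut. Off by default: the screen uses raw p-values.
#' @return A `correlation_config` list.
#' @export
correlation_config <- function(min_abs_r = 0.80, alpha = 0.05,
                               sample_scope = c("all_samples", "per_condition"),
                               transform = c("none", "log2p1"),
                               method = c("t", "permutation"),
                               n_perm = 10000L, adjust_bh = FALSE) {
  stopifnot(min_abs_r >= 0, min_abs_r <= 1, alpha > 0, alpha < 1, n_perm >= 100)
  structure(list(min_abs_r = min_abs_r, alpha = alpha,
                 sample_scope = match.arg(sample_scope),
                 transform = match.arg(transform),
                 method = match.arg(method),
                 n_perm = as.integer(n_perm),
                 adjust_bh = isTRUE(adjust_bh)),
            class = "correlation_config")
}

#' Pearson correlation coefficient
#'
#' `r = sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`, clamped to `[-1, 1]` against rounding. Returns
#' `NA` (with a warning) when either vector has zero variance; such pairs
#' are excluded from the significance screen rather than silently dropped.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA_real_` for a degenerate input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  ssx <- sum(dx^2)
  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0) {
    warning("zero variance: Pearson r undefined")
    return(NA_real_)
  }
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  max(-1, min(1, r))
}

#' P-value for a Pearson correlation via the t-transform
#'
#' Two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against Student's t
#' with `n - 2` degrees of freedom; `p = 0` when `|r| = 1` exactly.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param n number of paired observations (>= 3).
#' @param df degrees of freedom; defaults to `n - 2`. Condition-centred
#'   correlations spend one extra df per additional group.
#' @return Two-sided p-value.
#' @export
pearson_p <- function(r, n, df = n - 2) {
  if (n < 3) stop("need n >= 3 for the correlation test")
  if (is.na(r)) return(NA_real_)
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided p estimated by permuting `y` `n_perm` times, with the add-one
#' correction `(1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations.
#' @return Estimated two-sided p-value, or `NA` for degenerate input.
#' @export
permutation_p <- function(x, y, n_perm = 10000L) {
  r_obs <- suppressWarnings(pearson_r(x, y))
  if (is.na(r_obs)) return(NA_real_)
  n <- length(x)
  idx <- matrix(0L, n, n_perm)
  for (j in seq_len(n_perm)) idx[, j] <- sample.int(n)
  yperm <- matrix(y[idx], nrow = n)
  rp <- as.vector(stats::cor(x, yperm))
  (1 + sum(abs(rp) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
}

#' Score cis pairs by Pearson correlation of expression profiles
#'
#' Each pair is annotated with the Pearson correlation `r` between its
#' lncRNA and mRNA expression profiles across samples, a p-value, and the
#' joint screen verdict: `significant` when `|r| >= min_abs_r` **and**
#' `p < alpha` (raw p by default). `sign` is `positive` when r > 0,
#' `negative` when r < 0, `undefined` when r could not be computed
#' (zero-variance profile); undefined pairs are never significant.
#'
#' @param pairs cis-pair data.frame.
#' @param expr_lnc `expr_matrix` containing the lncRNA profiles.
#' @param expr_mrna `expr_matrix` containing the mRNA profiles; defaults to
#'   `expr_lnc` when one matrix holds both. Sample columns must be aligned.
#' @param config a [correlation_config()].
#' @return The pairs with `r`, `p_value`, `significant` and `sign` filled in.
#' @export
screen_pairs <- function(pairs, expr_lnc, expr_mrna = expr_lnc,
                         config = correlation_config()) {
  stopifnot(inherits(expr_lnc, "expr_matrix"), inherits(expr_mrna, "expr_matrix"),
            inherits(config, "correlation_config"))
  if (!identical(colnames(expr_lnc$values), colnames(expr_mrna$values))) {
    stop("sample columns of the two expression matrices are not aligned")
  }
  if (nrow(pairs) == 0) return(pairs)
  miss_l <- setdiff(pairs$lncrna_id, rownames(expr_lnc$values))
  miss_m <- setdiff(pairs$mrna_id, rownames(expr_mrna$values))
  if (length(miss_l) || length(miss_m)) {
    stop("pair member(s) absent from expression matrix: ",
         paste(utils::head(c(miss_l, miss_m), 5), collapse = ", "))
  }
  X <- expr_lnc$values[pairs$lncrna_id, , drop = FALSE]
  Y <- expr_mrna$values[pairs$mrna_id, , drop = FALSE]
  if (config$transform == "log2p1") {
    X <- log2(X + 1); Y <- log2(Y + 1)
  }
  n <- ncol(X)
  df <- n - 2
  if (config$sample_scope == "per_condition") {
    cond <- expr_lnc$condition
    for (g in unique(cond)) {
      cols <- cond == g
      X[, cols] <- X[, cols, drop = FALSE] - rowMeans(X[, cols, drop = FALSE])
      Y[, cols] <- Y[, cols, drop = FALSE] - rowMeans(Y[, cols, drop = FALSE])
    }
    df <- n - 2 - (length(unique(cond)) - 1)
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(pearson_r(X[i, ], Y[i, ]))
  }, numeric(1))
  p <- if (config$method == "permutation") {
    vapply(seq_len(nrow(pairs)), function(i) {
      if (is.na(r[i])) NA_real_ else permutation_p(X[i, ], Y[i, ], config$n_perm)
    }, numeric(1))
  } else {
    vapply(r, pearson_p, numeric(1), n = n, df = df)
  }
  p_screen <- if (config$adjust_bh) stats::p.adjust(p, method = "BH") else p
  pairs$r <- r
  pairs$p_value <- p
  pairs$significant <- !is.na(r) & abs(r) >= config$min_abs_r &
    !is.na(p_screen) & p_screen < config$alpha
  pairs$sign <- ifelse(is.na(r), "undefined",
                       ifelse(r > 0, "positive", "negative"))
  pairs
}
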