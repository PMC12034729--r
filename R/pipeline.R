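#' Run the full cis-regulatory lncRNA-mRNA target screen
#'
#' End-to-end pipeline over an annotated two-condition expression dataset:
#'
#' 1. lncRNA candidate selection: features with biotype `lncRNA` or
#'    `candidate`, strictly longer than `min_lncrna_nt`, and (when a verdict
#'    table is supplied) called non-coding by at least `min_votes` of the
#'    four coding-potential predictors.
#' 2. TPM conversion when the expression matrix holds raw counts.
#' 3. Differential expression: an external statistics table when supplied
#'    (the recommended route for real data), otherwise the built-in
#'    [naive_de_test()]; threshold classification at FDR < `de_alpha`,
#'    |log2FC| >= `de_min_abs_log2fc`.
#' 4. Window pairing of lncRNA anchors (differentially expressed lncRNAs by
#'    default) against all mRNA loci within `window_bp`.
#' 5. Concordance annotation, restriction to pairs whose members are both
#'    DE, and the Pearson correlation screen on those pairs.
#' 6. Summary rollup.
#'
#' @param features [feature_set()] with biotypes.
#' @param expr `expr_matrix` (counts or TPM) covering all features.
#' @param coding_calls optional verdict table for [consensus_noncoding()].
#' @param de_stats optional external DE table (`feature_id`, `log2fc`, `fdr`).
#' @param window_bp cis window in bp.
#' @param anchor `"gene_body"` or `"tss"` distance anchoring.
#' @param de_alpha,de_min_abs_log2fc DE thresholds.
#' @param cor_config a [correlation_config()].
#' @param min_lncrna_nt strict lower length bound for lncRNA candidates.
#' @param min_votes consensus non-coding vote threshold.
#' @param anchor_lncrnas `"de_only"` pairs only differentially expressed
#'   lncRNAs (default); `"all"` pairs every retained lncRNA.
#' @return A `cis_pipeline_result` list: `lncrnas`, `mrnas`, `de`, `tpm`,
#'   `pairs` (all window pairs, screened ones annotated), `summary`.
#' @export
cis_pipeline <- function(features, expr, coding_calls = NULL, de_stats = NULL,
                         window_bp = 100000L, anchor = c("gene_body", "tss"),
                         de_alpha = 0.05, de_min_abs_log2fc = 1.0,
                         cor_config = correlation_config(),
                         min_lncrna_nt = 200L, min_votes = 3L,
                         anchor_lncrnas = c("de_only", "all")) {
  anchor <- match.arg(anchor)
  anchor_lncrnas <- match.arg(anchor_lncrnas)
  stopifnot(inherits(features, "feature_set"), inherits(expr, "expr_matrix"))

  cand <- subset_features(features, features$biotype %in% c("lncRNA", "candidate"))
  cand <- filter_by_length(cand, min_lncrna_nt)
  if (!is.null(coding_calls)) {
    keep <- consensus_noncoding(coding_calls, min_votes)
    cand <- subset_features(cand, cand$feature_id %in% keep)
  }
  mrnas <- subset_features(features, features$biotype == "mRNA")

  tpm <- if (expr$unit == "counts") counts_to_tpm(expr, features) else expr
  if (is.null(de_stats)) de_stats <- naive_de_test(tpm)
  de <- classify_de(de_stats, alpha = de_alpha, min_abs_log2fc = de_min_abs_log2fc)

  lnc_anchors <- if (anchor_lncrnas == "de_only") {
    de_ids <- de$feature_id[de$de_status != "not_de"]
    subset_features(cand, cand$feature_id %in% de_ids)
  } else cand

  pairs <- find_cis_pairs(lnc_anchors, mrnas, window_bp = window_bp, anchor = anchor)
  pairs <- annotate_concordance(pairs, de)
  both_de <- pairs$concordance != "not_both_de"
  if (any(both_de)) {
    screened <- screen_pairs(pairs[both_de, , drop = FALSE], tpm, tpm, cor_config)
    pairs[both_de, c("r", "p_value", "significant", "sign")] <-
      screened[, c("r", "p_value", "significant", "sign")]
  }
  structure(list(lncrnas = cand, mrnas = mrnas, de = de, tpm = tpm,
                 pairs = pairs, summary = summarize_pairs(pairs)),
            class = "cis_pipeline_result")
}

#' @export
print.cis_pipeline_result <- function(x, ...) {
  cat(sprintf("cis_pipeline_result: %d lncRNA candidates, %d mRNAs, %d DE features\n",
              nrow(x$lncrnas), nrow(x$mrnas), sum(x$de$de_status != "not_de")))
  print(x$summary)
  invisible(x)
}
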