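#' Summarize a screened cis-pair table
#'
#' Produces the standard result surface of a cis-target screen: how many
#' pairs fell in the genomic window, how many involved two differentially
#' expressed members, how many passed the correlation screen, the
#' positive/negative split among significant pairs, the concordance
#' breakdown (both up / both down / discordant) among significant pairs, and
#' the number of unique genes (lncRNAs and mRNAs counted in one set) in the
#' concordant-up subset.
#'
#' @param pairs fully annotated cis-pair data.frame (after
#'   [annotate_concordance()] and [screen_pairs()]; pairs never screened may
#'   carry `NA` in `significant`).
#' @return A `pair_summary` list; `positive_fraction` is `NA` when no pair is
#'   significant.
#' @export
summarize_pairs <- function(pairs) {
  sig <- !is.na(pairs$significant) & pairs$significant
  n_sig <- sum(sig)
  n_pos <- sum(sig & pairs$sign == "positive")
  n_neg <- sum(sig & pairs$sign == "negative")
  conc <- pairs$concordance
  both_de <- !is.na(conc) & conc != "not_both_de"
  n_both_up <- sum(sig & conc == "both_up", na.rm = TRUE)
  ids_up <- c(pairs$lncrna_id[sig & conc == "both_up"],
              pairs$mrna_id[sig & conc == "both_up"])
  out <- list(
    n_pairs_window = nrow(pairs),
    n_pairs_both_de = sum(both_de),
    n_significant = n_sig,
    n_positive = n_pos,
    n_negative = n_neg,
    n_both_up = n_both_up,
    n_both_down = sum(sig & conc == "both_down", na.rm = TRUE),
    n_discordant = sum(sig & conc == "discordant", na.rm = TRUE),
    n_unique_genes_both_up = length(unique(ids_up)),
    positive_fraction = if (n_sig > 0) n_pos / n_sig else NA_real_
  )
  class(out) <- "pair_summary"
  out
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("cis-pair screen summary\n")
  cat(sprintf("  pairs within window:        %d\n", x$n_pairs_window))
  cat(sprintf("  pairs with both members DE: %d\n", x$n_pairs_both_de))
  cat(sprintf("  significant pairs:          %d\n", x$n_significant))
  if (!is.na(x$positive_fraction)) {
    cat(sprintf("  positive / negative:        %d / %d (%.3f positive, %d%%)\n",
                x$n_positive, x$n_negative, x$positive_fraction,
                round(100 * x$positive_fraction)))
  }
  cat(sprintf("  both up / both down / discordant: %d / %d / %d\n",
              x$n_both_up, x$n_both_down, x$n_discordant))
  cat(sprintf("  unique genes in both-up pairs:    %d\n", x$n_unique_genes_both_up))
  invisible(x)
}

#' Write a pair summary as JSON (plus an optional text rendering)
#' @param summary a `pair_summary`.
#' @param path output JSON path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Score recovery of planted cis couplings
#'
#' Compares the significant pairs against the simulator's planted truth.
#' Sensitivity is the fraction of planted coupled pairs recovered as
#' significant; the false discovery rate is the fraction of significant
#' pairs that were not planted (`NA` when nothing is significant).
#'
#' @param pairs screened cis-pair data.frame.
#' @param truth a `synthetic_truth` (see [simulate_layout()]), or any list
#'   with a `planted_pairs` data.frame carrying `lncrna_id` and `mrna_id`.
#' @param features optional [feature_set()]; when given, truth ids are
#'   checked against it and an unknown id is an error.
#' @return A `recovery_report` list with `sensitivity`,
#'   `false_discovery_rate`, `n_planted`, `n_recovered`, `n_significant`.
#' @export
score_recovery <- function(pairs, truth, features = NULL) {
  planted <- truth$planted_pairs
  stopifnot(is.data.frame(planted),
            all(c("lncrna_id", "mrna_id") %in% names(planted)))
  if (!is.null(features)) {
    unknown <- setdiff(c(planted$lncrna_id, planted$mrna_id), features$feature_id)
    if (length(unknown) > 0) {
      stop("truth references unknown feature id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  key <- function(l, m) paste(l, m, sep = "\r")
  planted_keys <- key(planted$lncrna_id, planted$mrna_id)
  sig <- pairs[!is.na(pairs$significant) & pairs$significant, , drop = FALSE]
  sig_keys <- key(sig$lncrna_id, sig$mrna_id)
  n_recovered <- sum(planted_keys %in% sig_keys)
  n_sig <- nrow(sig)
  out <- list(
    sensitivity = if (length(planted_keys) > 0) n_recovered / length(planted_keys) else NA_real_,
    false_discovery_rate = if (n_sig > 0) sum(!sig_keys %in% planted_keys) / n_sig else NA_real_,
    n_planted = length(planted_keys),
    n_recovered = n_recovered,
    n_significant = n_sig
  )
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: %d/%d planted pairs recovered (sensitivity %.3f), FDR %s over %d significant\n",
              x$n_recovered, x$n_planted, x$sensitivity,
              ifelse(is.na(x$false_discovery_rate), "NA",
                     sprintf("%.3f", x$false_discovery_rate)),
              x$n_significant))
  invisible(x)
}
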