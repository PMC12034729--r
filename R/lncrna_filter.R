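#' Filter candidate transcripts by length
#'
#' Long non-coding RNAs are conventionally defined as transcripts exceeding
#' 200 nt, so the cutoff is a strict inequality: a feature of exactly
#' `min_exclusive_nt` nucleotides is removed.
#'
#' @param features a [feature_set()] with `length_nt` populated.
#' @param min_exclusive_nt retain features strictly longer than this (nt).
#' @return The retained [feature_set()], input order preserved.
#' @export
filter_by_length <- function(features, min_exclusive_nt = 200L) {
  stopifnot(inherits(features, "feature_set"))
  subset_features(features, features$length_nt > min_exclusive_nt)
}

predictor_names <- c("CPC2", "CNCI", "Pfam", "FEElnc")

#' Read a coding-potential verdict table
#'
#' TSV with columns `feature_id`, `CPC2`, `CNCI`, `Pfam`, `FEElnc`; cell
#' values `NC` (non-coding), `C` (coding) or `NA` (not assessed).
#'
#' @param path path to the TSV.
#' @return data.frame with one column per predictor holding
#'   `"noncoding"` / `"coding"` / `"missing"`.
#' @export
read_coding_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = character(0))
  normalize_coding_calls(df)
}

normalize_coding_calls <- function(df) {
  if (!"feature_id" %in% names(df)) stop("verdict table needs a feature_id column")
  extra <- setdiff(names(df), c("feature_id", predictor_names))
  if (length(extra) > 0) {
    stop("unknown predictor name(s): ", paste(extra, collapse = ", "),
         " (expected ", paste(predictor_names, collapse = ", "), ")")
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id in verdict table: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  }
  map <- c(NC = "noncoding", C = "coding", "NA" = "missing",
           noncoding = "noncoding", coding = "coding", missing = "missing")
  for (p in intersect(predictor_names, names(df))) {
    v <- as.character(df[[p]])
    v[is.na(v)] <- "NA"
    if (any(!v %in% names(map))) {
      stop("invalid verdict value(s) for ", p, ": ",
           paste(setdiff(unique(v), names(map)), collapse = ", "))
    }
    df[[p]] <- unname(map[v])
  }
  for (p in setdiff(predictor_names, names(df))) df[[p]] <- "missing"
  df[, c("feature_id", predictor_names)]
}

#' Consensus non-coding vote over four coding-potential predictors
#'
#' A transcript is retained as non-coding when at least `min_votes` of the
#' four predictors (CPC2, CNCI, Pfam, FEElnc) call it non-coding. A
#' `"missing"` verdict never counts toward the non-coding tally: an
#' unassessed transcript is not promoted.
#'
#' @param calls verdict table as returned by [read_coding_calls()] (or a
#'   data.frame in the same shape, raw `NC`/`C`/`NA` cells accepted).
#' @param min_votes minimum number of non-coding verdicts, between 1 and 4.
#' @return Character vector of retained feature ids (input order).
#' @export
consensus_noncoding <- function(calls, min_votes = 3L) {
  stopifnot(min_votes >= 1L, min_votes <= length(predictor_names))
  calls <- normalize_coding_calls(calls)
  votes <- Reduce(`+`, lapply(predictor_names,
                              function(p) as.integer(calls[[p]] == "noncoding")))
  calls$feature_id[votes >= min_votes]
}
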