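#' Construct a feature set of gene-level genomic loci
#'
#' A feature set is the package's container for gene loci: one row per
#' feature with a unique id, 1-based fully-closed genomic coordinates
#' (GTF convention), a strand, a biotype and a feature length in
#' nucleotides. All downstream distance arithmetic assumes these
#' conventions.
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, and optionally `strand` (default `"."`), `biotype` (default
#'   `"other"`) and `length_nt` (default the genomic span `end - start + 1`).
#' @param genome_name optional genome label stored as an attribute.
#' @return A `feature_set`: a validated data.frame sorted by chromosome and
#'   start coordinate.
#' @examples
#' fs <- feature_set(data.frame(
#'   feature_id = c("lnc1", "g1"), chrom = "chr1",
#'   start = c(1000L, 5000L), end = c(2000L, 9000L),
#'   biotype = c("lncRNA", "mRNA")))
#' @export
feature_set <- function(features, genome_name = NA_character_) {
  stopifnot(is.data.frame(features))
  required <- c("feature_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    feature_id = as.character(features$feature_id),
    chrom = as.character(features$chrom),
    start = as.integer(features$start),
    end = as.integer(features$end),
    strand = if ("strand" %in% names(features)) as.character(features$strand) else ".",
    biotype = if ("biotype" %in% names(features)) as.character(features$biotype) else "other",
    stringsAsFactors = FALSE
  )
  df$length_nt <- if ("length_nt" %in% names(features)) {
    as.integer(features$length_nt)
  } else {
    df$end - df$start + 1L
  }
  df$strand[is.na(df$strand) | df$strand == "*"] <- "."
  bad_strand <- !df$strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    stop("invalid strand value(s): ", paste(unique(df$strand[bad_strand]), collapse = ", "))
  }
  known <- c("lncRNA", "mRNA", "candidate", "other")
  df$biotype[is.na(df$biotype) | !df$biotype %in% known] <- "other"
  validate_features(df)
  df <- df[order(df$chrom, df$start, df$end, df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "genome_name") <- genome_name
  class(df) <- c("feature_set", "data.frame")
  df
}

validate_features <- function(df) {
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup) > 0) {
    stop("duplicate feature_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  if (length(bad) > 0) {
    stop("end < start (or missing coordinate) for feature(s): ",
         paste(df$feature_id[bad], collapse = ", "))
  }
  if (any(df$start < 1L)) {
    stop("coordinates must be >= 1 after normalization (1-based closed intervals)")
  }
  if (any(is.na(df$length_nt) | df$length_nt < 1L)) {
    stop("length_nt must be a positive integer for every feature")
  }
  invisible(df)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d features on %d chromosome(s)",
              nrow(x), length(unique(x$chrom))))
  gn <- attr(x, "genome_name")
  if (!is.na(gn)) cat(sprintf(" [%s]", gn))
  cat("\n")
  tab <- table(x$biotype)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}

# Convert to GRanges for interval machinery; strand "." maps to "*".
# seqlevels can be widened so two sets compare without seqlevel warnings.
as_granges <- function(fs, seqlevels = unique(fs$chrom)) {
  strand <- ifelse(fs$strand == ".", "*", fs$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(fs$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = fs$start, end = fs$end),
    strand = strand
  )
  names(gr) <- fs$feature_id
  gr
}

# Subset a feature_set preserving class and attributes.
subset_features <- function(fs, keep) {
  out <- fs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_name") <- attr(fs, "genome_name")
  class(out) <- c("feature_set", "data.frame")
  out
}
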