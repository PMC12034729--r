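#' Read a genomic annotation into a feature set
#'
#' Parses GTF 2.2 or BED6 annotations into gene-level loci with coordinates
#' normalized to 1-based fully-closed intervals (the GTF convention; BED's
#' half-open 0-based starts are shifted by +1). Multi-transcript genes in a
#' GTF are collapsed to their union interval (minimum start, maximum end),
#' because pairing operates on gene-level loci.
#'
#' Biotype precedence: an explicit `biotype_table` overrides anything in the
#' file; otherwise the GTF attributes `gene_biotype` / `transcript_biotype` /
#' `biotype` are used; features with no recognisable biotype are labelled
#' `"other"`. BED files carry no biotype, so a sidecar table is the only way
#' to assign one there.
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed"`.
#' @param biotype_table optional data.frame (or path to a TSV) with columns
#'   `feature_id` and `biotype`; takes precedence over file attributes.
#' @param genome_name optional genome label.
#' @return A [feature_set()].
#' @export
read_annotation <- function(path, format = c("gtf", "bed"), biotype_table = NULL,
                            genome_name = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fs <- switch(format,
    gtf = read_gtf_features(path),
    bed = read_bed_features(path)
  )
  if (!is.null(biotype_table)) {
    if (is.character(biotype_table)) {
      biotype_table <- utils::read.delim(biotype_table, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("feature_id", "biotype") %in% names(biotype_table)))
    idx <- match(fs$feature_id, biotype_table$feature_id)
    fs$biotype[!is.na(idx)] <- biotype_table$biotype[idx[!is.na(idx)]]
  }
  feature_set(fs, genome_name = genome_name)
}

# Line-level validation so malformed input is reported with its line number;
# rtracklayer then does the actual parsing.
read_gtf_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  content <- which(!grepl("^\\s*(#|$)", lines))
  for (i in content) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                   i, length(fields)))
    }
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i))
    }
    if (end < start) {
      stop(sprintf("malformed GTF line %d: end (%d) < start (%d)", i, end, start))
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) stop("GTF has no gene_id attribute")
  biotype <- rep(NA_character_, length(gr))
  for (attr_name in c("gene_biotype", "transcript_biotype", "biotype")) {
    if (attr_name %in% names(meta)) {
      val <- as.character(meta[[attr_name]])
      biotype <- ifelse(is.na(biotype), val, biotype)
    }
  }
  df <- data.frame(
    feature_id = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  # Collapse all records of a gene to the union interval.
  collapse_to_genes(df)
}

collapse_to_genes <- function(df) {
  split_rows <- split(seq_len(nrow(df)), df$feature_id)
  rows <- lapply(split_rows, function(idx) {
    sub <- df[idx, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1) {
      stop("feature ", sub$feature_id[1], " spans multiple chromosomes")
    }
    bt <- sub$biotype[!is.na(sub$biotype)]
    data.frame(
      feature_id = sub$feature_id[1],
      chrom = sub$chrom[1],
      start = min(sub$start),
      end = max(sub$end),
      strand = if (length(unique(sub$strand)) == 1) sub$strand[1] else ".",
      biotype = if (length(bt) > 0) bt[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_bed_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  content <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  for (i in content) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 4) {
      stop(sprintf("malformed BED line %d: expected >= 4 tab-separated fields", i))
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed BED line %d: non-numeric coordinates", i))
    }
    if (end < start + 1L) {
      stop(sprintf("malformed BED line %d: empty or inverted interval", i))
    }
  }
  gr <- rtracklayer::import(path, format = "bed")  # import gives 1-based closed
  ids <- names(gr)
  if (is.null(ids) && "name" %in% names(S4Vectors::mcols(gr))) {
    ids <- as.character(S4Vectors::mcols(gr)$name)
  }
  if (is.null(ids) || anyNA(ids)) stop("BED records must carry a name field (column 4)")
  data.frame(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write a feature set as BED6
#'
#' Starts are converted back to BED's 0-based half-open convention, so a
#' BED -> feature_set -> BED round trip reproduces the original intervals.
#'
#' @param fs a [feature_set()].
#' @param path output path.
#' @export
write_bed <- function(fs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   fs$chrom, fs$start - 1L, fs$end, fs$feature_id, 0L, fs$strand)
  writeLines(lines, path)
  invisible(path)
}

pairs_columns <- c("lncrna_id", "mrna_id", "chrom", "distance_bp", "r",
                   "p_value", "significant", "sign", "concordance")

#' Write a cis-pair table to TSV
#'
#' Columns: lncRNA_id, mRNA_id, chrom, distance_bp, r, p_value, significant,
#' sign, concordance. Missing values are written as `"."`. Numeric columns are
#' serialized at full double precision so that [read_pairs_table()] is an
#' exact inverse and repeated runs are byte-identical.
#'
#' @param pairs a cis-pair data.frame (see [find_cis_pairs()]).
#' @param path output path.
#' @export
write_pairs_table <- function(pairs, path) {
  stopifnot(all(pairs_columns %in% names(pairs)))
  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
  fmt_int <- function(x) ifelse(is.na(x), ".", sprintf("%d", as.integer(x)))
  fmt_chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  fmt_lgl <- function(x) ifelse(is.na(x), ".", ifelse(x, "TRUE", "FALSE"))
  header <- paste(c("lncRNA_id", "mRNA_id", "chrom", "distance_bp", "r",
                    "p_value", "significant", "sign", "concordance"),
                  collapse = "\t")
  body <- paste(fmt_chr(pairs$lncrna_id), fmt_chr(pairs$mrna_id),
                fmt_chr(pairs$chrom), fmt_int(pairs$distance_bp),
                fmt_num(pairs$r), fmt_num(pairs$p_value),
                fmt_lgl(pairs$significant), fmt_chr(pairs$sign),
                fmt_chr(pairs$concordance), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a cis-pair table written by [write_pairs_table()]
#'
#' @param path path to the TSV.
#' @return A cis-pair data.frame with `"."` decoded back to `NA`.
#' @export
read_pairs_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                          colClasses = "character")
  expected <- c("lncRNA_id", "mRNA_id", "chrom", "distance_bp", "r", "p_value",
                "significant", "sign", "concordance")
  if (!identical(names(df), expected)) {
    stop("not a cis-pair table: expected columns ", paste(expected, collapse = ", "))
  }
  out <- data.frame(
    lncrna_id = df$lncRNA_id,
    mrna_id = df$mRNA_id,
    chrom = df$chrom,
    distance_bp = as.integer(df$distance_bp),
    r = as.numeric(df$r),
    p_value = as.numeric(df$p_value),
    significant = as.logical(df$significant),
    sign = df$sign,
    concordance = df$concordance,
    stringsAsFactors = FALSE
  )
  out
}
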