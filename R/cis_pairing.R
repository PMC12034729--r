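#' Enumerate candidate cis lncRNA-mRNA pairs within a genomic window
#'
#' A pair is emitted when both loci lie on the same chromosome and the
#' closest-edge gap between the two gene intervals is at most `window_bp`
#' (default 100 kb). The gap is `max(0, start2 - end1, start1 - end2)` on
#' 1-based closed intervals: 0 for overlapping loci, 1 for book-ended loci.
#' Strand is ignored — the window extends both upstream and downstream of
#' the lncRNA locus, so orientation cannot change membership. With
#' `anchor = "tss"` the distance is instead measured between the two
#' transcription start sites (strand-aware 5' ends).
#'
#' @param lncrnas [feature_set()] of lncRNA loci (the window anchors).
#' @param mrnas [feature_set()] of mRNA loci.
#' @param window_bp maximum gap in bp (>= 0).
#' @param anchor `"gene_body"` (closest-edge gap, default) or `"tss"`.
#' @return A cis-pair data.frame ordered by (chrom, lncRNA start, mRNA
#'   start), with correlation fields (`r`, `p_value`, `significant`, `sign`,
#'   `concordance`) left `NA` for [screen_pairs()] to fill.
#' @export
find_cis_pairs <- function(lncrnas, mrnas, window_bp = 100000L,
                           anchor = c("gene_body", "tss")) {
  stopifnot(inherits(lncrnas, "feature_set"), inherits(mrnas, "feature_set"))
  anchor <- match.arg(anchor)
  if (window_bp < 0) stop("window_bp must be >= 0")
  if (nrow(lncrnas) == 0 || nrow(mrnas) == 0) return(empty_pairs())

  lev <- union(lncrnas$chrom, mrnas$chrom)
  if (anchor == "tss") {
    lg <- tss_granges(lncrnas, lev)
    mg <- tss_granges(mrnas, lev)
  } else {
    lg <- as_granges(lncrnas, lev)
    mg <- as_granges(mrnas, lev)
  }
  # findOverlaps' maxgap counts positions strictly between ranges, which is
  # one less than the closest-edge gap; query with maxgap = window_bp to get
  # a superset, then apply the exact gap predicate.
  hits <- GenomicRanges::findOverlaps(lg, mg, maxgap = window_bp,
                                      ignore.strand = TRUE)
  li <- S4Vectors::queryHits(hits)
  mi <- S4Vectors::subjectHits(hits)
  if (anchor == "tss") {
    ls <- GenomicRanges::start(lg)[li]; le <- ls
    ms <- GenomicRanges::start(mg)[mi]; me <- ms
  } else {
    ls <- lncrnas$start[li]; le <- lncrnas$end[li]
    ms <- mrnas$start[mi]; me <- mrnas$end[mi]
  }
  gap <- pmax(0L, ms - le, ls - me)
  keep <- gap <= window_bp
  li <- li[keep]; mi <- mi[keep]; gap <- gap[keep]
  k <- length(li)
  out <- data.frame(
    lncrna_id = lncrnas$feature_id[li],
    mrna_id = mrnas$feature_id[mi],
    chrom = lncrnas$chrom[li],
    distance_bp = as.integer(gap),
    r = rep(NA_real_, k), p_value = rep(NA_real_, k),
    significant = rep(NA, k),
    sign = rep(NA_character_, k), concordance = rep(NA_character_, k),
    stringsAsFactors = FALSE
  )
  ord <- order(out$chrom, lncrnas$start[li], mrnas$start[mi],
               out$lncrna_id, out$mrna_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(lncrna_id = character(0), mrna_id = character(0),
             chrom = character(0), distance_bp = integer(0), r = numeric(0),
             p_value = numeric(0), significant = logical(0),
             sign = character(0), concordance = character(0),
             stringsAsFactors = FALSE)
}

# 1-bp ranges at the strand-aware 5' end; unstranded features use start.
tss_granges <- function(fs, seqlevels = unique(fs$chrom)) {
  pos <- ifelse(fs$strand == "-", fs$end, fs$start)
  gr <- GenomicRanges::GRanges(factor(fs$chrom, levels = seqlevels),
                               IRanges::IRanges(pos, pos))
  names(gr) <- fs$feature_id
  gr
}

#' Annotate pairs with direction concordance of their members
#'
#' Every pair gets a `concordance` label: `both_up`, `both_down`,
#' `discordant` (both members differentially expressed but in opposite
#' directions) or `not_both_de` (at least one member not DE).
#'
#' @param pairs cis-pair data.frame from [find_cis_pairs()].
#' @param de DE classification from [classify_de()].
#' @return The pairs with `concordance` filled in.
#' @export
annotate_concordance <- function(pairs, de) {
  status <- stats::setNames(de$de_status, de$feature_id)
  ids <- unique(c(pairs$lncrna_id, pairs$mrna_id))
  unknown <- setdiff(ids, names(status))
  if (length(unknown) > 0) {
    stop("no DE record for pair member(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  sl <- unname(status[pairs$lncrna_id])
  sm <- unname(status[pairs$mrna_id])
  conc <- rep("not_both_de", nrow(pairs))
  both <- sl != "not_de" & sm != "not_de"
  conc[both & sl == "up" & sm == "up"] <- "both_up"
  conc[both & sl == "down" & sm == "down"] <- "both_down"
  conc[both & sl != sm] <- "discordant"
  pairs$concordance <- conc
  pairs
}

#' Restrict pairs to those whose members are both differentially expressed
#'
#' @inheritParams annotate_concordance
#' @return The retained pairs with `concordance` set to `both_up`,
#'   `both_down` or `discordant`.
#' @export
restrict_to_de <- function(pairs, de) {
  ann <- annotate_concordance(pairs, de)
  out <- ann[ann$concordance != "not_both_de", , drop = FALSE]
  rownames(out) <- NULL
  out
}
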