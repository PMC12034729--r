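#' Simulation configuration for planted cis-coupling benchmarks
#'
#' Defines a two-condition exosome-scale RNA-seq experiment with known
#' ground truth: designated lncRNA-mRNA pairs placed within the cis window
#' whose expression is coupled through a latent Gaussian copula, in-window
#' null pairs (no coupling, no differential expression), distal decoy pairs
#' placed beyond twice the window, short candidate decoys that fail the
#' length filter, and planted log2 fold-change effects.
#'
#' Defaults describe a desk-scale benchmark: 5 vs 5 samples, two 50 Mb
#' chromosomes, 200 lncRNAs and 600 mRNAs, 100 coupled pairs at latent
#' rho = 0.9 with |log2FC| = 2 effects, negative-binomial dispersion 0.1,
#' baseline means log-uniform between 50 and 1000 counts.
#'
#' @param n_case,n_control samples per condition (>= 2).
#' @param n_chromosomes,chrom_length_bp genome geometry.
#' @param n_lncrna,n_mrna feature counts by class.
#' @param n_coupled_pairs in-window pairs with copula coupling and DE.
#' @param n_null_pairs in-window pairs with neither coupling nor DE.
#' @param n_distal_pairs coupled+DE pairs placed > 2 x window apart.
#' @param n_short_decoys candidate transcripts <= 200 nt.
#' @param n_de_singleton_mrna unpaired mRNAs given a DE effect (half up,
#'   half down).
#' @param n_background non-differential background genes (biotype `"other"`,
#'   never paired). They keep the differential features a minority of the
#'   library mass, as in a real transcriptome; without them the TPM
#'   renormalization would compress every planted fold change by the bulk
#'   composition shift.
#' @param background_mean_log_range natural-log mean-count range for the
#'   background genes; the default makes them abundant (housekeeping-like),
#'   so they dominate library mass without inflating the gene count.
#' @param window_bp the cis window the geometry is built around.
#' @param rho latent Gaussian correlation of coupled pairs, in (-1, 1).
#' @param de_log2fc planted absolute log2 fold change.
#' @param both_up_fraction fraction of coupled pairs whose members are both
#'   upregulated (the rest are both downregulated).
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp * mu^2).
#' @param baseline_mean_log_range range of natural-log baseline mean counts.
#' @param flip_prob per-predictor probability of a wrong coding-potential
#'   verdict.
#' @param seed integer seed; every simulation stage derives its stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 5L, n_control = 5L,
                       n_chromosomes = 2L, chrom_length_bp = 5e7,
                       n_lncrna = 200L, n_mrna = 600L,
                       n_coupled_pairs = 100L, n_null_pairs = 50L,
                       n_distal_pairs = 50L, n_short_decoys = 20L,
                       n_de_singleton_mrna = 100L, n_background = 1200L,
                       window_bp = 100000L, rho = 0.9, de_log2fc = 2,
                       both_up_fraction = 0.9, nb_dispersion = 0.1,
                       baseline_mean_log_range = c(log(50), log(1000)),
                       background_mean_log_range = c(log(200), log(4000)),
                       flip_prob = 0.05, seed = 17L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
              n_coupled_pairs = as.integer(n_coupled_pairs),
              n_null_pairs = as.integer(n_null_pairs),
              n_distal_pairs = as.integer(n_distal_pairs),
              n_short_decoys = as.integer(n_short_decoys),
              n_de_singleton_mrna = as.integer(n_de_singleton_mrna),
              n_background = as.integer(n_background),
              window_bp = as.integer(window_bp), rho = rho,
              de_log2fc = de_log2fc, both_up_fraction = both_up_fraction,
              nb_dispersion = nb_dispersion,
              baseline_mean_log_range = baseline_mean_log_range,
              background_mean_log_range = background_mean_log_range,
              flip_prob = flip_prob, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_case >= 2, n_control >= 2, n_chromosomes >= 1,
              window_bp >= 0, nb_dispersion > 0,
              flip_prob >= 0, flip_prob < 0.5,
              both_up_fraction >= 0, both_up_fraction <= 1,
              length(baseline_mean_log_range) == 2,
              baseline_mean_log_range[1] <= baseline_mean_log_range[2])
    if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
    if (n_coupled_pairs + n_null_pairs + n_distal_pairs > n_lncrna) {
      stop("pair budget exceeds n_lncrna")
    }
    if (n_coupled_pairs + n_null_pairs + n_distal_pairs + n_de_singleton_mrna > n_mrna) {
      stop("pair + singleton-DE budget exceeds n_mrna")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a genome layout with planted cis geometry
#'
#' Places gene loci on the configured chromosomes so that every planted
#' (coupled or null) pair has a closest-edge gap drawn uniformly in
#' `[0, window_bp]`, every distal pair has a gap in
#' `(2 * window_bp, 3 * window_bp]`, and all other inter-feature gaps exceed
#' `window_bp` — so the planted geometry is the only in-window structure and
#' recovery metrics are unambiguous. True lncRNAs and short decoys are
#' emitted with biotype `"candidate"` (novel transcripts carry no trusted
#' biotype); mRNAs with biotype `"mRNA"`.
#'
#' @param cfg a [sim_config()].
#' @return list with `features` (a [feature_set()]) and `truth` (a
#'   `synthetic_truth`: `planted_pairs`, `null_pairs`, `distal_pairs`,
#'   `planted_de` named log2FC vector, `true_lncrna` ids).
#' @export
simulate_layout <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_layout_impl(cfg))
}

simulate_layout_impl <- function(cfg) {
  w <- cfg$window_bp
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrna))
  mrna_ids <- sprintf("MRNA%04d", seq_len(cfg$n_mrna))
  decoy_ids <- if (cfg$n_short_decoys > 0) sprintf("CAND%03d", seq_len(cfg$n_short_decoys)) else character(0)
  bg_ids <- if (cfg$n_background > 0) sprintf("BG%04d", seq_len(cfg$n_background)) else character(0)
  lnc_len <- sample(300:3000, cfg$n_lncrna, replace = TRUE)
  mrna_len <- sample(1000:10000, cfg$n_mrna, replace = TRUE)
  decoy_len <- if (cfg$n_short_decoys > 0) sample(80:200, cfg$n_short_decoys, replace = TRUE) else integer(0)
  bg_len <- if (cfg$n_background > 0) sample(500:5000, cfg$n_background, replace = TRUE) else integer(0)

  n_pairs <- cfg$n_coupled_pairs + cfg$n_null_pairs + cfg$n_distal_pairs
  pair_lnc <- lnc_ids[seq_len(n_pairs)]
  pair_mrna <- mrna_ids[seq_len(n_pairs)]
  kind <- rep(c("coupled", "null", "distal"),
              c(cfg$n_coupled_pairs, cfg$n_null_pairs, cfg$n_distal_pairs))
  gap <- integer(n_pairs)
  in_window <- kind != "distal"
  gap[in_window] <- as.integer(floor(stats::runif(sum(in_window), 0, w + 1)))
  gap[in_window] <- pmin(gap[in_window], w)
  gap[!in_window] <- as.integer(2 * w + 1 + floor(stats::runif(sum(!in_window), 0, w)))

  len_of <- c(stats::setNames(lnc_len, lnc_ids), stats::setNames(mrna_len, mrna_ids),
              stats::setNames(decoy_len, decoy_ids), stats::setNames(bg_len, bg_ids))
  # A unit is a run of features placed contiguously; planted pairs are
  # two-feature units, everything else a singleton. Every lncRNA/mRNA/decoy
  # unit is followed by a pad strictly wider than the window, so the planted
  # geometry is the only in-window lncRNA-mRNA structure; background genes
  # (never paired) pack densely between them.
  units <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    ids <- c(pair_lnc[i], pair_mrna[i])
    if (stats::runif(1) < 0.5) ids <- rev(ids)  # which member sits upstream
    units[[i]] <- list(ids = ids, gap = gap[i], wide_pad = TRUE)
  }
  singles <- c(setdiff(lnc_ids, pair_lnc), setdiff(mrna_ids, pair_mrna), decoy_ids)
  units <- c(units,
             lapply(singles, function(id) list(ids = id, gap = 0L, wide_pad = TRUE)),
             lapply(bg_ids, function(id) list(ids = id, gap = 0L, wide_pad = FALSE)))
  units <- units[sample.int(length(units))]

  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom <- 1L
  pos <- 1
  rows <- vector("list", length(len_of))
  k <- 0L
  for (u in units) {
    span <- if (length(u$ids) == 2) len_of[u$ids[1]] + u$gap + len_of[u$ids[2]] else len_of[u$ids]
    # overlap case: a drawn gap of 0 nests the second feature against the first
    if (length(u$ids) == 2 && u$gap == 0) span <- len_of[u$ids[1]] + len_of[u$ids[2]]
    while (pos + span - 1 > cfg$chrom_length_bp) {
      chrom <- chrom + 1L
      pos <- 1
      if (chrom > cfg$n_chromosomes) {
        stop("infeasible packing: increase chrom_length_bp or n_chromosomes")
      }
    }
    start1 <- pos
    end1 <- start1 + len_of[u$ids[1]] - 1
    k <- k + 1L
    rows[[k]] <- data.frame(feature_id = u$ids[1], chrom = chrom_names[chrom],
                            start = start1, end = end1, stringsAsFactors = FALSE)
    if (length(u$ids) == 2) {
      if (u$gap == 0) {
        start2 <- max(start1, end1 - min(10, len_of[u$ids[2]] - 1))  # overlap -> gap 0
      } else {
        start2 <- end1 + u$gap
      }
      end2 <- start2 + len_of[u$ids[2]] - 1
      k <- k + 1L
      rows[[k]] <- data.frame(feature_id = u$ids[2], chrom = chrom_names[chrom],
                              start = start2, end = end2, stringsAsFactors = FALSE)
      pos <- max(end1, end2) + 1
    } else {
      pos <- end1 + 1
    }
    pos <- pos + if (u$wide_pad) {
      # spacing strictly beyond the window so no accidental pairs
      w + 1 + floor(stats::runif(1, 0, 0.05 * w))
    } else {
      200 + floor(stats::runif(1, 0, 1800))
    }
  }
  df <- do.call(rbind, rows[seq_len(k)])
  df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
  df$length_nt <- unname(len_of[df$feature_id])
  df$biotype <- ifelse(df$feature_id %in% mrna_ids, "mRNA",
                       ifelse(df$feature_id %in% bg_ids, "other", "candidate"))
  features <- feature_set(df, genome_name = "synthetic")

  coupled <- kind == "coupled"
  distal <- kind == "distal"
  both_up <- stats::runif(cfg$n_coupled_pairs) < cfg$both_up_fraction
  planted_pairs <- data.frame(lncrna_id = pair_lnc[coupled], mrna_id = pair_mrna[coupled],
                              rho_target = rep(cfg$rho, sum(coupled)), both_up = both_up,
                              stringsAsFactors = FALSE)
  null_pairs <- data.frame(lncrna_id = pair_lnc[kind == "null"],
                           mrna_id = pair_mrna[kind == "null"], stringsAsFactors = FALSE)
  distal_pairs <- data.frame(lncrna_id = pair_lnc[distal], mrna_id = pair_mrna[distal],
                             rho_target = rep(cfg$rho, sum(distal)), stringsAsFactors = FALSE)

  sign_coupled <- ifelse(both_up, 1, -1)
  de_ids <- c(pair_lnc[coupled], pair_mrna[coupled], pair_lnc[distal], pair_mrna[distal])
  de_lfc <- c(sign_coupled, sign_coupled, rep(1, 2 * cfg$n_distal_pairs)) * cfg$de_log2fc
  if (cfg$n_de_singleton_mrna > 0) {
    single_mrna <- setdiff(mrna_ids, pair_mrna)
    de_single <- single_mrna[seq_len(cfg$n_de_singleton_mrna)]
    half <- ceiling(length(de_single) / 2)
    de_ids <- c(de_ids, de_single)
    de_lfc <- c(de_lfc, cfg$de_log2fc * rep(c(1, -1), c(half, length(de_single) - half)))
  }
  truth <- structure(list(planted_pairs = planted_pairs, null_pairs = null_pairs,
                          distal_pairs = distal_pairs,
                          planted_de = stats::setNames(de_lfc, de_ids),
                          true_lncrna = lnc_ids),
                     class = "synthetic_truth")
  list(features = features, truth = truth)
}

#' Simulate negative-binomial counts with copula-coupled planted pairs
#'
#' Each feature's baseline mean is drawn log-uniformly from
#' `baseline_mean_log_range`; planted DE features have their case-group mean
#' multiplied by `2^log2fc`. Counts are negative binomial with dispersion
#' `nb_dispersion`. Coupled pairs (both planted and distal) share a
#' per-sample latent Gaussian: the mRNA member's latent is
#' `rho * z_lnc + sqrt(1 - rho^2) * eps`, and counts are the NB quantile of
#' the latent's normal CDF (a Gaussian copula over NB marginals), inducing
#' a Pearson correlation close to, but attenuated from, `rho`.
#'
#' @param features [feature_set()] from [simulate_layout()].
#' @param truth the matching `synthetic_truth`.
#' @param cfg the [sim_config()] (its seed stream is offset from the layout's,
#'   so layout and expression draws are independent but jointly reproducible).
#' @return An `expr_matrix` of counts (control columns first).
#' @export
simulate_expression <- function(features, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(cfg$rho) >= 1) stop("rho must lie in (-1, 1)")
  withr::with_seed(cfg$seed + 1L, simulate_expression_impl(features, truth, cfg))
}

simulate_expression_impl <- function(features, truth, cfg) {
  ids <- features$feature_id
  n_feat <- length(ids)
  n_samp <- cfg$n_control + cfg$n_case
  sample_ids <- c(sprintf("control_%02d", seq_len(cfg$n_control)),
                  sprintf("case_%02d", seq_len(cfg$n_case)))
  condition <- stats::setNames(rep(c("control", "case"), c(cfg$n_control, cfg$n_case)),
                               sample_ids)
  r <- cfg$baseline_mean_log_range
  rb <- cfg$background_mean_log_range
  bg <- features$biotype == "other"
  mu0 <- exp(stats::runif(n_feat, r[1], r[2]))
  mu0[bg] <- exp(stats::runif(sum(bg), rb[1], rb[2]))
  MU <- matrix(mu0, n_feat, n_samp)
  case_cols <- condition == "case"
  de_idx <- match(names(truth$planted_de), ids)
  ok <- !is.na(de_idx)
  MU[de_idx[ok], case_cols] <- MU[de_idx[ok], case_cols] * 2^truth$planted_de[ok]

  Z <- matrix(stats::rnorm(n_feat * n_samp), n_feat, n_samp)
  couple <- rbind(truth$planted_pairs[, c("lncrna_id", "mrna_id")],
                  truth$distal_pairs[, c("lncrna_id", "mrna_id")])
  for (i in seq_len(nrow(couple))) {
    a <- match(couple$lncrna_id[i], ids)
    b <- match(couple$mrna_id[i], ids)
    if (is.na(a) || is.na(b)) next
    Z[b, ] <- cfg$rho * Z[a, ] + sqrt(1 - cfg$rho^2) * Z[b, ]
  }
  counts <- matrix(stats::qnbinom(stats::pnorm(Z), size = 1 / cfg$nb_dispersion, mu = MU),
                   n_feat, n_samp, dimnames = list(ids, sample_ids))
  expression_matrix(counts, condition, unit = "counts")
}

#' Simulate a four-predictor coding-potential verdict table
#'
#' True lncRNAs receive a `noncoding` verdict from each predictor
#' independently with probability `1 - flip_prob`; every other feature
#' (mRNAs, short decoys) receives `coding` with the same probability.
#'
#' @param features a [feature_set()].
#' @param truth a `synthetic_truth` (or any list with a `true_lncrna`
#'   character vector).
#' @param flip_prob per-predictor error probability, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return Verdict data.frame consumable by [consensus_noncoding()].
#' @export
simulate_coding_calls <- function(features, truth, flip_prob = 0.05, seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob < 0.5)
  withr::with_seed(as.integer(seed), {
    ids <- features$feature_id
    is_lnc <- ids %in% truth$true_lncrna
    calls <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
    for (p in predictor_names) {
      wrong <- stats::runif(length(ids)) < flip_prob
      calls[[p]] <- ifelse(xor(is_lnc, wrong), "noncoding", "coding")
    }
    calls
  })
}

#' Simulate a complete benchmark dataset
#'
#' @param cfg a [sim_config()].
#' @return list with `features`, `truth`, `counts` (an `expr_matrix`),
#'   `coding_calls` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  lay <- simulate_layout(cfg)
  counts <- simulate_expression(lay$features, lay$truth, cfg)
  calls <- simulate_coding_calls(lay$features, lay$truth,
                                 flip_prob = cfg$flip_prob, seed = cfg$seed + 2L)
  structure(list(features = lay$features, truth = lay$truth, counts = counts,
                 coding_calls = calls, config = cfg),
            class = "cis_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits `annotation.gtf` (gene records with `gene_biotype`), `counts.tsv`,
#' `coding_calls.tsv`, `conditions.yaml` (sample -> condition map) and
#' `truth.json`.
#'
#' @param sim a `cis_simulation` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- sim$features
  gr <- as_granges(fs)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "cislink_sim", type = "gene",
    gene_id = fs$feature_id, gene_biotype = fs$biotype)
  rtracklayer::export(gr, file.path(dir, "annotation.gtf"), format = "gtf")
  write_expression_matrix(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$coding_calls, file.path(dir, "coding_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(list(conditions = as.list(sim$counts$condition))),
             file.path(dir, "conditions.yaml"))
  truth <- sim$truth
  jsonlite::write_json(list(planted_pairs = truth$planted_pairs,
                            null_pairs = truth$null_pairs,
                            distal_pairs = truth$distal_pairs,
                            planted_de = as.list(truth$planted_de),
                            true_lncrna = truth$true_lncrna),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
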