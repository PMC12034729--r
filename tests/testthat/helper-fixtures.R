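# Shared fixtures and independent oracles. Everything here is deliberately
# naive: oracles must not share code paths with the implementation.

make_features <- function(ids, chrom, start, end, biotype = "other",
                          strand = ".", length_nt = NULL) {
  df <- data.frame(feature_id = ids, chrom = chrom, start = start, end = end,
                   strand = strand, biotype = biotype, stringsAsFactors = FALSE)
  if (!is.null(length_nt)) df$length_nt <- length_nt
  feature_set(df)
}

# All-pairs scan applying the closest-edge gap predicate directly.
brute_force_pairs <- function(lnc, mrna, window) {
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(mrna))) {
      if (lnc$chrom[i] != mrna$chrom[j]) next
      gap <- max(0L, mrna$start[j] - lnc$end[i], lnc$start[i] - mrna$end[j])
      if (gap <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = lnc$feature_id[i], mrna_id = mrna$feature_id[j],
          distance_bp = as.integer(gap), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      distance_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
}

pair_key <- function(p) sort(paste(p$lncrna_id, p$mrna_id, p$distance_bp))

local_tempdir_checked <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

subset_fs <- function(fs, ids) {
  rows <- fs[fs$feature_id %in% ids, , drop = FALSE]
  make_features(rows$feature_id, rows$chrom, rows$start, rows$end,
                biotype = rows$biotype, strand = rows$strand,
                length_nt = rows$length_nt)
}

random_feature_set <- function(n, chroms = c("chr1", "chr2"), max_pos = 5e6,
                               prefix = "f") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(100:20000, n, replace = TRUE)
  make_features(sprintf("%s%04d", prefix, seq_len(n)),
                sample(chroms, n, replace = TRUE),
                start, start + len - 1L)
}

# Independent estimate of the Pearson correlation of two NB marginals joined
# by a Gaussian copula with latent correlation rho (the NB quantile transform
# attenuates rho). Large-sample Monte Carlo using a different construction
# (Cholesky on a 2x2 covariance) from the simulator's.
copula_attenuated_r <- function(rho, mu1, mu2, dispersion, n_mc = 2e5) {
  z1 <- rnorm(n_mc)
  e <- rnorm(n_mc)
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  z <- cbind(z1, e) %*% L
  x <- qnbinom(pnorm(z[, 1]), size = 1 / dispersion, mu = mu1)
  y <- qnbinom(pnorm(z[, 2]), size = 1 / dispersion, mu = mu2)
  cor(x, y)
}

# Small two-condition expression fixture with exact values.
toy_expr <- function(unit = "TPM") {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 1, 4, 3, 6, 5),
             c = c(10, 10, 10, 40, 40, 40))
  colnames(m) <- c("ctl1", "ctl2", "ctl3", "cs1", "cs2", "cs3")
  expression_matrix(m, setNames(rep(c("control", "case"), each = 3),
                                colnames(m)), unit = unit)
}
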