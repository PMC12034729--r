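test_that("pearson_r matches the hand-evaluated covariance formula", {
  expect_equal(pearson_r(1:4, 1:4), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # sum((x-3.5)(y-3.5)) = 14.5; both sums of squares = 17.5
  expect_equal(pearson_r(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)),
               14.5 / 17.5)
  expect_warning(r0 <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r0))
})

test_that("pearson_r is symmetric, affine-invariant, and agrees with stats::cor", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(2.5 * x + 3, y), pearson_r(x, y), tolerance = 1e-12)
  }
})

test_that("pearson_p matches numeric t-density integration and cor.test", {
  r <- 14.5 / 17.5
  n <- 6
  # oracle: integrate the t density with df = n - 2 beyond |t(r)|
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  dens <- function(t, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  tail_mass <- integrate(dens, tstat, Inf, df = n - 2, rel.tol = 1e-10)$value
  expect_equal(tstat, 2.961, tolerance = 1e-3)
  expect_equal(pearson_p(r, n), 2 * tail_mass, tolerance = 1e-6)
  expect_equal(pearson_p(r, n), 0.0415, tolerance = 5e-3)

  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    ct <- cor.test(x, y)
    expect_equal(pearson_p(pearson_r(x, y), 7), ct$p.value, tolerance = 1e-12)
  }

  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(1, 5), 0)
  expect_equal(pearson_p(-1, 5), 0)
  expect_error(pearson_p(0.5, 2), "n >= 3")
})

test_that("pearson_p decreases in |r| at fixed n and in n at fixed |r|", {
  rs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  expect_true(all(diff(vapply(rs, pearson_p, 1, n = 8)) < 0))
  ns <- c(4, 6, 10, 20, 50)
  expect_true(all(diff(vapply(ns, function(n) pearson_p(0.6, n), 1)) < 0))
})

test_that("t-based p tracks the permutation p at n = 10", {
  # the permutation p conditions on the observed sample, so per-pair
  # deviations of a few hundredths are expected even for exact-normal data;
  # the t approximation is adequate when the typical disagreement is < 0.01
  set.seed(2024)
  diffs <- vapply(1:12, function(i) {
    x <- rnorm(10)
    y <- 0.3 * x + rnorm(10)
    p_t <- pearson_p(pearson_r(x, y), 10)
    abs(p_t - permutation_p(x, y, n_perm = 100000L))
  }, numeric(1))
  expect_lt(mean(diffs), 0.01)
  expect_lt(max(diffs), 0.05)
})

make_screen_fixture <- function() {
  set.seed(31)
  n <- 10
  ids <- c("l1", "l2", "l3", "m1", "m2", "m3")
  base <- rnorm(n)
  vals <- rbind(
    l1 = base + rnorm(n, sd = 0.1),        # strongly correlated with m1
    l2 = rnorm(n),                          # independent of m2
    l3 = -base + rnorm(n, sd = 0.1),        # anti-correlated with m3
    m1 = base + rnorm(n, sd = 0.1),
    m2 = rnorm(n),
    m3 = base + rnorm(n, sd = 0.1))
  vals <- vals - min(vals) + 1
  colnames(vals) <- sprintf("s%02d", 1:n)
  cond <- setNames(rep(c("case", "control"), each = 5), colnames(vals))
  expr <- expression_matrix(vals, cond, unit = "TPM")
  pairs <- data.frame(lncrna_id = c("l1", "l2", "l3"),
                      mrna_id = c("m1", "m2", "m3"), chrom = "chr1",
                      distance_bp = 100L, r = NA_real_, p_value = NA_real_,
                      significant = NA, sign = NA_character_,
                      concordance = "both_up", stringsAsFactors = FALSE)
  list(expr = expr, pairs = pairs)
}

test_that("screen_pairs applies the joint |r| and p rule with signs", {
  fx <- make_screen_fixture()
  out <- screen_pairs(fx$pairs, fx$expr)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
  expect_equal(out$sign, c("positive", "negative", "negative"))
  expect_true(abs(out$r[1]) >= 0.8 && out$p_value[1] < 0.05)
  # r recomputed independently
  expect_equal(out$r[1], cor(fx$expr$values["l1", ], fx$expr$values["m1", ]))

  # a zero-variance profile is flagged undefined, never significant
  expr2 <- fx$expr
  expr2$values["l2", ] <- 3
  out2 <- screen_pairs(fx$pairs, expr2)
  expect_equal(out2$sign[2], "undefined")
  expect_false(out2$significant[2])

  # misaligned sample columns are an error
  expr3 <- fx$expr
  colnames(expr3$values)[1] <- "zz"
  names(expr3$condition)[1] <- "zz"
  expect_error(screen_pairs(fx$pairs, fx$expr, expr3), "not aligned")
})

test_that("significant set shrinks as min_abs_r rises and alpha falls", {
  set.seed(77)
  n <- 10
  n_pairs <- 120
  base <- matrix(rnorm(n_pairs * n), n_pairs, n)
  rho_mix <- runif(n_pairs)
  X <- base + matrix(rnorm(n_pairs * n, sd = 0.5), n_pairs, n)
  Y <- rho_mix * base + (1 - rho_mix) * matrix(rnorm(n_pairs * n), n_pairs, n)
  vals <- rbind(X, Y) - min(c(X, Y)) + 1
  rownames(vals) <- c(sprintf("l%03d", 1:n_pairs), sprintf("m%03d", 1:n_pairs))
  colnames(vals) <- sprintf("s%02d", 1:n)
  cond <- setNames(rep(c("case", "control"), each = 5), colnames(vals))
  expr <- expression_matrix(vals, cond, unit = "TPM")
  pairs <- data.frame(lncrna_id = sprintf("l%03d", 1:n_pairs),
                      mrna_id = sprintf("m%03d", 1:n_pairs), chrom = "chr1",
                      distance_bp = 0L, r = NA_real_, p_value = NA_real_,
                      significant = NA, sign = NA_character_,
                      concordance = "both_up", stringsAsFactors = FALSE)
  n_sig_r <- vapply(c(0.5, 0.8, 0.9, 0.99), function(mr) {
    sum(screen_pairs(pairs, expr, config = correlation_config(min_abs_r = mr))$significant)
  }, integer(1))
  expect_true(all(diff(n_sig_r) <= 0))
  n_sig_a <- vapply(c(0.1, 0.05, 0.01), function(a) {
    sum(screen_pairs(pairs, expr, config = correlation_config(alpha = a))$significant)
  }, integer(1))
  expect_true(all(diff(n_sig_a) <= 0))
})

test_that("per-condition centring removes group-shift-only correlation", {
  set.seed(55)
  n <- 12
  cond <- setNames(rep(c("control", "case"), each = 6), sprintf("s%02d", 1:n))
  shift <- ifelse(cond == "case", 40, 0)
  vals <- rbind(l1 = shift + rnorm(n, 10), m1 = shift + rnorm(n, 10))
  colnames(vals) <- names(cond)
  expr <- expression_matrix(vals, cond, unit = "TPM")
  pairs <- data.frame(lncrna_id = "l1", mrna_id = "m1", chrom = "chr1",
                      distance_bp = 0L, r = NA_real_, p_value = NA_real_,
                      significant = NA, sign = NA_character_,
                      concordance = "both_up", stringsAsFactors = FALSE)
  pooled <- screen_pairs(pairs, expr)
  centred <- screen_pairs(pairs, expr,
                          config = correlation_config(sample_scope = "per_condition"))
  expect_gt(abs(pooled$r), 0.9)       # DE shift alone fakes a high pooled r
  expect_lt(abs(centred$r), 0.8)      # centring exposes the absent coupling
})
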