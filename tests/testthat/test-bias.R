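# Fixtures: a tiny two-population allotriploid dataset built in code.
make_tiny_allo <- function(n_genes = 40, n_samples = 4, seed = 1,
                           p_alloc = 1 / 3, lambda = 300) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  acq <- paste0(genes, ".h")
  sids <- sprintf("a%02d", seq_len(n_samples))
  tot <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
                dimnames = list(genes, sids))
  c1 <- matrix(rbinom(length(tot), tot, p_alloc), n_genes, n_samples,
               dimnames = list(acq, sids))
  c2 <- tot - c1
  rownames(c2) <- genes
  list(c2 = c2, c1 = c1,
       map = data.frame(primary_id = genes, acquired_id = acq),
       samples = data.frame(sample_id = sids, population = "Beer",
                            ploidy_class = "allotriploid",
                            subgenome_ref = "1n-Beer"))
}

test_that("haploid fraction is the paired-read share of the 1n compartment", {
  d <- make_tiny_allo()
  # trivial construction: 1n 100, 2n 200 per gene
  c2 <- matrix(200, 3, 1, dimnames = list(c("g1", "g2", "g3"), "s"))
  c1 <- matrix(100, 3, 1, dimnames = list(c("h1", "h2", "h3"), "s"))
  map <- data.frame(primary_id = c("g1", "g2", "g3"),
                    acquired_id = c("h1", "h2", "h3"))
  expect_equal(haploid_fraction(c2, c1, map, "s"), 1 / 3)

  # brute-force sums on a random instance
  got <- haploid_fraction(d$c2, d$c1, d$map, "a01")
  want <- sum(d$c1[, "a01"]) / (sum(d$c1[, "a01"]) + sum(d$c2[, "a01"]))
  expect_equal(got, want)

  zero2 <- d$c2; zero2[, "a01"] <- 0
  zero1 <- d$c1; zero1[, "a01"] <- 0
  expect_error(haploid_fraction(zero2, zero1, d$map, "a01"), "no reads")
})

test_that("fraction excess z-test matches the closed-form statistic", {
  f <- c(0.40, 0.42, 0.38, 0.41)
  got <- test_fraction_excess(f)
  z_hand <- (mean(f) - 1 / 3) / (sd(f) / sqrt(4))
  expect_equal(got$z, z_hand)
  expect_equal(got$p, pnorm(z_hand, lower.tail = FALSE))

  expect_error(test_fraction_excess(rep(1 / 3, 5)), "zero spread")
  expect_error(test_fraction_excess(0.4), "at least 2")

  # strong rejection when the true share is 0.40
  set.seed(14)
  sim <- rnorm(30, 0.40, 0.02)
  expect_lt(test_fraction_excess(sim)$p, 1e-10)
})

test_that("per-sample regression recovers exact and random relationships", {
  # exact line y = x: equal counts in both compartments
  genes <- sprintf("g%02d", 1:10)
  vals <- c(3, 7, 15, 31, 63, 127, 255, 511, 1023, 2047)
  c2 <- matrix(vals, 10, 1, dimnames = list(genes, "s"))
  c1 <- matrix(vals, 10, 1, dimnames = list(paste0(genes, ".h"), "s"))
  map <- data.frame(primary_id = genes, acquired_id = paste0(genes, ".h"))
  fit <- fit_sample_regression(c2, c1, map, "s")
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$residual_sd, 0)

  # normal-equation oracle on a random 50-pair instance
  d <- make_tiny_allo(n_genes = 50, seed = 7)
  rf <- fit_sample_regression(d$c2, d$c1, d$map, "a01")
  x <- log2(d$c2[, "a01"] + 1)
  y <- log2(d$c1[, "a01"] + 1)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_hand <- mean(y) - slope_hand * mean(x)
  expect_equal(rf$slope, slope_hand)
  expect_equal(rf$intercept, int_hand)
  res <- y - int_hand - slope_hand * x
  expect_equal(rf$residual_sd, sqrt(sum(res^2) / (length(x) - 2)))

  expect_error(fit_sample_regression(c2[1:2, , drop = FALSE],
                                     c1[1:2, , drop = FALSE],
                                     map[1:2, ], "s"), "at least 3")
  flat2 <- c2; flat2[] <- 10
  expect_error(fit_sample_regression(flat2, c1, map, "s"), "zero variance")
})

test_that("regression under equal per-copy expression has slope 1, intercept log2(1/2)", {
  set.seed(122)
  lam <- exp(runif(400, log(100), log(10000)))  # spread across expression
  d <- make_tiny_allo(n_genes = 400, n_samples = 1, seed = 22,
                      lambda = lam)
  rf <- fit_sample_regression(d$c2, d$c1, d$map, "a01")
  # 1n ~ half the 2n count: y = x + log2(1/2) on the log2 scale
  expect_equal(rf$slope, 1, tolerance = 0.1)
  expect_equal(rf$intercept, -1, tolerance = 0.35)
})

test_that("prediction-interval calls equal the predict.lm oracle", {
  # a point exactly on the fitted line is always within
  genes <- sprintf("g%02d", 1:10)
  vals <- c(3, 7, 15, 31, 63, 127, 255, 511, 1023, 2047)
  c2 <- matrix(vals, 10, 1, dimnames = list(genes, "s"))
  c1 <- matrix(vals, 10, 1, dimnames = list(paste0(genes, ".h"), "s"))
  map <- data.frame(primary_id = genes, acquired_id = paste0(genes, ".h"))
  fit <- fit_sample_regression(c2, c1, map, "s")
  calls <- prediction_outliers(fit)
  expect_true(all(calls$direction == "within"))

  # toy and random instances against the independent interval computation
  set.seed(33)
  for (rep in 1:25) {
    d <- make_tiny_allo(n_genes = 30, seed = rep + 100)
    rf <- fit_sample_regression(d$c2, d$c1, d$map, "a01")
    for (level in c(0.9, 0.95, 0.99)) {
      got <- prediction_outliers(rf, level = level)
      want <- oracle_prediction_bounds(rf$pairs$x, rf$pairs$y, rf$pairs$x,
                                       level)
      expect_equal(got$predicted_1n, want$fit)
      expect_equal(got$lower, want$lwr)
      expect_equal(got$upper, want$upr)
      dir_want <- ifelse(rf$pairs$y > want$upr, "above",
                         ifelse(rf$pairs$y < want$lwr, "below", "within"))
      expect_equal(got$direction, dir_want)
    }
  }
})

test_that("consistency thresholds reproduce the per-population rules", {
  expect_equal(consistency_threshold(30), 25L)
  expect_equal(consistency_threshold(9), 7L)
  expect_equal(consistency_threshold(6), 5L)
  expect_equal(consistency_threshold(12), ceiling(25 / 30 * 12))

  samples <- data.frame(sample_id = sprintf("b%02d", 1:30),
                        population = "Beer",
                        ploidy_class = "allotriploid",
                        subgenome_ref = "1n-Beer")
  mk_calls <- function(n_above, n_below, n_within) {
    dirs <- c(rep("above", n_above), rep("below", n_below),
              rep("within", n_within))
    data.frame(primary_id = "gX", acquired_id = "gX.h",
               sample_id = samples$sample_id[seq_along(dirs)],
               direction = dirs)
  }
  over <- consistent_bias(mk_calls(26, 0, 4), samples)
  expect_equal(over$call, "1n_over")
  none <- consistent_bias(mk_calls(24, 0, 6), samples)
  expect_equal(none$call, "none")
  # direction-specific counting: 13 above + 13 below is not consistent
  split_dir <- consistent_bias(mk_calls(13, 13, 4), samples)
  expect_equal(split_dir$call, "none")
  expect_equal(split_dir$n_above, 13L)
  expect_equal(split_dir$n_below, 13L)
})

test_that("paired subgenome test matches the textbook formula and Holm example", {
  x2 <- c(100, 110, 95, 105, 98, 102)
  x1 <- c(130, 125, 118, 140, 121, 133)
  got <- paired_subgenome_test(x2, x1)
  d <- x1 - x2
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = length(d) - 1))

  # sign-balanced differences: t = 0, p = 1
  a <- c(10, 10, 10, 10)
  b <- c(11, 9, 11, 9)
  sym <- paired_subgenome_test(a, b)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(paired_subgenome_test(x2, x2 + 5), "zero variance")
  expect_error(paired_subgenome_test(1, 2), "at least 2")

  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
})

test_that("the subgenome_bias fit exposes coherent S3 methods", {
  cfg <- simulation_config(n_genes = 120, library_size = 6e4,
                           n_bias_genes = 10)
  sim <- simulate_counts(cfg, seed = 17)
  fit <- subgenome_bias(sim$counts_2n, sim$counts_1n, sim$ortholog_maps,
                        sim$samples)

  cf <- coef(fit)
  expect_equal(dim(cf), c(45L, 2L))
  expect_equal(colnames(cf), c("intercept", "slope"))

  # predict() on new 2n counts agrees with the stored regression line
  sid <- fit$fits$sample_id[1]
  nd <- data.frame(sample_id = sid, count_2n = c(0, 100, 1000))
  pr <- predict(fit, nd)
  x <- log2(nd$count_2n + 1)
  expect_equal(pr$predicted_1n,
               cf[sid, "intercept"] + cf[sid, "slope"] * x)
  expect_true(all(pr$lower <= pr$predicted_1n & pr$predicted_1n <= pr$upper))

  r <- residuals(fit)
  expect_equal(r$residual,
               fit$calls$observed_1n - fit$calls$predicted_1n)
  expect_output(print(fit), "Subgenome expression-bias fit")
  expect_output(print(summary(fit)), "Haploid read fraction")

  # interval bounds bracket the prediction in every call
  expect_true(all(fit$calls$lower <= fit$calls$predicted_1n &
                    fit$calls$predicted_1n <= fit$calls$upper))
  # consistency table bookkeeping
  expect_true(all(fit$consistent$n_above + fit$consistent$n_below <=
                    fit$consistent$n_evaluable))
  # paired-test adjustment is Holm within population
  for (pop in unique(fit$consistent$population)) {
    cp <- fit$consistent[fit$consistent$population == pop, ]
    ok <- !is.na(cp$p)
    expect_equal(cp$p_holm[ok], holm_adjust(cp$p[ok]))
  }
})

test_that("plot method draws a sample panel without error", {
  cfg <- simulation_config(n_genes = 60, library_size = 3e4)
  sim <- simulate_counts(cfg, seed = 2)
  fit <- subgenome_bias(sim$counts_2n, sim$counts_1n, sim$ortholog_maps,
                        sim$samples)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
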