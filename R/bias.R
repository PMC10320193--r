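# Core inference: per-sample 2n-vs-1n regression over ortholog pairs,
# prediction-interval outlier calls, per-population consolidation into
# consistently biased gene sets, and the haploid-fraction statistics.
#
# Rationale: with a diploid primary genome and one acquired haploid copy,
# equal per-copy expression puts one third of a gene pair's reads on the 1n
# copy. Rather than a hard ratio threshold, each sample gets its own OLS fit
# of (transformed) 1n counts on 2n counts, and genes falling outside the
# fit's prediction interval are the ones that do not follow that sample's
# overall 2n-vs-1n relationship.

#' Pair 2n and 1n counts for one sample via an ortholog map
#' @noRd
paired_counts <- function(counts_2n, counts_1n, map, sample) {
  check_count_matrix(counts_2n, "counts_2n")
  check_count_matrix(counts_1n, "counts_1n")
  check_ortholog_map(map)
  if (!sample %in% colnames(counts_2n) || !sample %in% colnames(counts_1n)) {
    stop("sample '", sample, "' absent from a count matrix", call. = FALSE)
  }
  missing2 <- setdiff(map$primary_id, rownames(counts_2n))
  missing1 <- setdiff(map$acquired_id, rownames(counts_1n))
  if (length(missing2) || length(missing1)) {
    stop("ortholog map names genes absent from the count matrices (e.g. '",
         c(missing2, missing1)[1L], "')", call. = FALSE)
  }
  data.frame(
    primary_id = map$primary_id,
    acquired_id = map$acquired_id,
    count_2n = counts_2n[map$primary_id, sample],
    count_1n = counts_1n[map$acquired_id, sample],
    row.names = NULL
  )
}

#' Haploid read fraction over ortholog pairs
#'
#' The share of reads assigned to the acquired (1n) subgenome among all
#' reads over genes present in both subgenomes of a sample. Under equal
#' per-copy expression of the three haplotypes the expectation is 1/3.
#'
#' @param counts_2n,counts_1n Compartment count matrices.
#' @param map Ortholog map for the sample's population.
#' @param sample Sample ID (column present in both matrices).
#' @return Fraction in `[0, 1]`.
#' @export
haploid_fraction <- function(counts_2n, counts_1n, map, sample) {
  pairs <- paired_counts(counts_2n, counts_1n, map, sample)
  tot <- sum(pairs$count_1n) + sum(pairs$count_2n)
  if (tot == 0) {
    stop("no reads over ortholog pairs for sample '", sample, "'",
         call. = FALSE)
  }
  sum(pairs$count_1n) / tot
}

#' One-sample z-test for excess haploid fraction
#'
#' Tests whether per-sample haploid fractions exceed the equal-per-copy
#' expectation: `z = (mean(f) - expected) / (sd(f) / sqrt(n))`, with an
#' upper-tail standard-normal p-value.
#'
#' @param fractions Numeric vector of per-sample haploid fractions.
#' @param expected Null expectation (default 1/3).
#' @return List with `z`, `p` (one-sided), `mean`, `sd`, `n`.
#' @export
test_fraction_excess <- function(fractions, expected = 1 / 3) {
  n <- length(fractions)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- sd(fractions)
  if (s == 0) stop("zero spread in fractions: z-test degenerate",
                   call. = FALSE)
  z <- (mean(fractions) - expected) / (s / sqrt(n))
  list(z = z, p = pnorm(z, lower.tail = FALSE), mean = mean(fractions),
       sd = s, n = n)
}

#' Per-sample OLS regression of 1n on 2n counts over ortholog pairs
#'
#' Fits ordinary least squares of transformed acquired-subgenome counts on
#' transformed primary-subgenome counts across the sample's ortholog pairs.
#' Pairs with zero counts in both compartments (gene effectively absent in
#' that sample) are excluded and recorded as non-evaluable. By default both
#' axes are `log2(count + 1)`; raw-count OLS is variance-dominated by the
#' most highly expressed genes, but is available with `log2_scale = FALSE`.
#'
#' @param counts_2n,counts_1n Compartment count matrices.
#' @param map Ortholog map for the sample's population.
#' @param sample Sample ID.
#' @param log2_scale Regress on `log2(count + pseudocount)` (default) or on
#'   raw counts.
#' @param pseudocount Pseudocount for the log2 scale.
#' @return Object of class `"sg_regression"`: slope, intercept,
#'   `residual_sd` (from `n - 2` degrees of freedom), `n_pairs`, predictor
#'   mean/sum-of-squares, and the evaluable pairs with their transformed
#'   coordinates.
#' @export
fit_sample_regression <- function(counts_2n, counts_1n, map, sample,
                                  log2_scale = TRUE, pseudocount = 1) {
  pairs <- paired_counts(counts_2n, counts_1n, map, sample)
  pairs <- pairs[pairs$count_2n + pairs$count_1n > 0, , drop = FALSE]
  if (nrow(pairs) < 3L) {
    stop("need at least 3 evaluable ortholog pairs for sample '", sample,
         "'", call. = FALSE)
  }
  if (log2_scale) {
    pairs$x <- log2(pairs$count_2n + pseudocount)
    pairs$y <- log2(pairs$count_1n + pseudocount)
  } else {
    pairs$x <- pairs$count_2n
    pairs$y <- pairs$count_1n
  }
  if (var(pairs$x) == 0) {
    stop("zero variance in 2n counts for sample '", sample, "'",
         call. = FALSE)
  }
  fit <- lm(y ~ x, data = pairs)
  res <- unname(fit$residuals)
  n <- nrow(pairs)
  structure(list(
    sample_id = sample,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    residual_sd = sqrt(sum(res^2) / (n - 2L)),
    n_pairs = n,
    x_mean = mean(pairs$x),
    x_ss = sum((pairs$x - mean(pairs$x))^2),
    scale = if (log2_scale) "log2" else "raw",
    pseudocount = pseudocount,
    pairs = pairs
  ), class = "sg_regression")
}

#' @export
print.sg_regression <- function(x, ...) {
  cat("2n-vs-1n regression for sample", x$sample_id, "\n")
  cat(sprintf("  1n = %.4f + %.4f * 2n  (%s scale, %d pairs, residual sd %.4f)\n",
              x$intercept, x$slope, x$scale, x$n_pairs, x$residual_sd))
  invisible(x)
}

#' Prediction interval half-width and center for a simple regression
#' @noRd
sg_interval <- function(fit, x, level) {
  pred <- fit$intercept + fit$slope * x
  tq <- qt(1 - (1 - level) / 2, df = fit$n_pairs - 2L)
  half <- tq * fit$residual_sd *
    sqrt(1 + 1 / fit$n_pairs + (x - fit$x_mean)^2 / fit$x_ss)
  list(pred = pred, lower = pred - half, upper = pred + half)
}

#' Flag ortholog pairs outside a sample's prediction interval
#'
#' For each pair, the two-sided prediction interval for a new observation at
#' the pair's 2n value is computed from the standard simple-regression
#' prediction variance, `s^2 * (1 + 1/n + (x - x_mean)^2 / Sxx)`, with a t
#' quantile on `n - 2` degrees of freedom. Pairs above the interval are 1n
#' over-expressed relative to the sample-wide trend, pairs below are 1n
#' under-expressed.
#'
#' @param fit An `"sg_regression"` object from [fit_sample_regression()].
#' @param pairs Data frame with columns `x`, `y` (and gene IDs); defaults to
#'   the fit's own pairs.
#' @param level Prediction-interval level (default 0.95).
#' @return Data frame of calls: gene IDs, `sample_id`, `observed_1n` and
#'   `predicted_1n` (on the regression scale), interval bounds, and
#'   `direction` in `above` / `below` / `within`.
#' @export
prediction_outliers <- function(fit, pairs = NULL, level = 0.95) {
  stopifnot(inherits(fit, "sg_regression"))
  if (fit$n_pairs < 3L) stop("fit has fewer than 3 pairs", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (is.null(pairs)) pairs <- fit$pairs
  iv <- sg_interval(fit, pairs$x, level)
  direction <- ifelse(pairs$y > iv$upper, "above",
                      ifelse(pairs$y < iv$lower, "below", "within"))
  data.frame(
    primary_id = pairs$primary_id,
    acquired_id = pairs$acquired_id,
    sample_id = fit$sample_id,
    observed_1n = pairs$y,
    predicted_1n = iv$pred,
    lower = iv$lower,
    upper = iv$upper,
    direction = direction,
    row.names = NULL
  )
}

#' Per-population deviation-count threshold
#'
#' The study's sample counts come with stated thresholds: a gene must
#' deviate in at least 25 of 30 Beer samples, 7 of 9 Teq/EtOH samples or
#' 5 of 6 Wine 1 samples. For other population sizes the threshold is
#' `ceiling(min_fraction * n)`.
#'
#' @param n_samples Number of samples in the population.
#' @param min_fraction Fraction of samples required (default 25/30).
#' @return Integer threshold.
#' @export
consistency_threshold <- function(n_samples, min_fraction = 25 / 30) {
  stopifnot(n_samples >= 1L)
  if (n_samples == 30L) return(25L)
  if (n_samples == 9L) return(7L)
  if (n_samples == 6L) return(5L)
  as.integer(ceiling(min_fraction * n_samples))
}

#' Consolidate per-sample deviation calls into per-population bias sets
#'
#' Counts, per gene and population, the samples in which the gene deviated
#' above or below the prediction interval. Counting is direction-specific: a
#' gene is called `1n_over` only if it deviates *above* in at least the
#' threshold number of the population's samples, and `1n_under` for
#' *below*, so consistent over- or under-expression in one subgenome is
#' required.
#'
#' @param calls Data frame of calls from [prediction_outliers()], covering
#'   every sample of each population; must contain `sample_id`.
#' @param samples Sample table mapping `sample_id` to `population`.
#' @param min_fraction Passed to [consistency_threshold()].
#' @return Data frame with one row per (population, gene): `n_above`,
#'   `n_below`, `n_evaluable`, `threshold` and `call` in
#'   `1n_over` / `1n_under` / `none`.
#' @export
consistent_bias <- function(calls, samples, min_fraction = 25 / 30) {
  stopifnot(is.data.frame(calls), all(c("primary_id", "sample_id",
                                        "direction") %in% names(calls)))
  check_sample_table(samples)
  idx <- match(calls$sample_id, samples$sample_id)
  if (anyNA(idx)) {
    stop("calls contain sample '",
         calls$sample_id[is.na(idx)][1L],
         "' unknown to the sample table", call. = FALSE)
  }
  calls$population <- samples$population[idx]
  out <- lapply(split(calls, calls$population), function(cp) {
    n_pop <- length(unique(cp$sample_id))
    thr <- consistency_threshold(n_pop, min_fraction)
    above <- tapply(cp$direction == "above", cp$primary_id, sum)
    below <- tapply(cp$direction == "below", cp$primary_id, sum)
    evaluable <- tapply(cp$direction, cp$primary_id, length)
    genes <- names(evaluable)
    call <- rep("none", length(genes))
    call[above[genes] >= thr] <- "1n_over"
    call[below[genes] >= thr] <- "1n_under"
    data.frame(
      population = cp$population[1L],
      gene_id = genes,
      n_above = as.integer(above[genes]),
      n_below = as.integer(below[genes]),
      n_evaluable = as.integer(evaluable[genes]),
      n_samples = n_pop,
      threshold = thr,
      call = call,
      row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t-test between corrected subgenome expression values
#'
#' Compares a gene's library-size-corrected 1n expression against its 2n
#' expression across the samples of a population with a standard paired
#' t-test on the per-sample differences (1n minus 2n).
#'
#' @param corrected_2n,corrected_1n Numeric vectors of per-sample corrected
#'   expression, aligned by sample.
#' @return List with `t`, `p` (two-sided), `mean_diff`, `df`.
#' @export
paired_subgenome_test <- function(corrected_2n, corrected_1n) {
  stopifnot(length(corrected_2n) == length(corrected_1n))
  if (length(corrected_2n) < 2L) {
    stop("need at least 2 paired samples", call. = FALSE)
  }
  d <- corrected_1n - corrected_2n
  if (var(d) == 0) {
    stop("zero variance of paired differences: p undefined", call. = FALSE)
  }
  tt <- t.test(corrected_1n, corrected_2n, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter))
}

#' Holm step-down adjustment
#' @param p Numeric vector of p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) p.adjust(p, method = "holm")

#' Benjamini-Hochberg step-up adjustment
#' @param p Numeric vector of p-values.
#' @return BH-adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

# The fitting front end --------------------------------------------------------

#' Fit the subgenome expression-bias model to allotriploid samples
#'
#' The central fitting function. For every allotriploid sample it (i)
#' computes the haploid read fraction over the population's ortholog pairs,
#' (ii) fits the per-sample OLS regression of transformed 1n counts on 2n
#' counts ([fit_sample_regression()]), and (iii) flags genes outside the
#' regression's prediction interval ([prediction_outliers()]). Calls are
#' consolidated per population into consistently biased gene sets
#' ([consistent_bias()]); per-population one-sided z-tests assess excess of
#' the haploid fraction over 1/3, and per-gene paired t-tests (with Holm
#' adjustment within population) compare subgenome expression after
#' correcting each compartment by its library size over the population's
#' ortholog pairs.
#'
#' @param counts_2n Primary-compartment counts for allotriploid samples.
#' @param counts_1n Acquired-compartment counts (rows: acquired gene IDs).
#' @param ortholog_maps Named list of per-population ortholog maps.
#' @param samples Sample table; every allotriploid sample must appear as a
#'   column of both count matrices.
#' @param level Prediction-interval level (default 0.95).
#' @param min_fraction Consistency fraction for populations without a stated
#'   threshold (default 25/30).
#' @param log2_scale,pseudocount Regression scale, see
#'   [fit_sample_regression()].
#' @param expected_fraction Null haploid fraction (default 1/3).
#' @return Object of class `"subgenome_bias"` with components `fits`
#'   (per-sample regression table), `calls` (per gene-sample deviation
#'   calls), `fractions`, `fraction_tests`, `consistent` (per-population
#'   consolidated calls with paired-test columns `t`, `p`, `p_holm`),
#'   `thresholds`, and the fitted per-sample regression objects. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`, `fitted`.
#' @examples
#' cfg <- simulation_config(n_genes = 120, library_size = 5e4,
#'                          n_bias_genes = 10)
#' sim <- simulate_counts(cfg, seed = 7)
#' fit <- subgenome_bias(sim$counts_2n, sim$counts_1n, sim$ortholog_maps,
#'                       sim$samples)
#' summary(fit)
#' @export
subgenome_bias <- function(counts_2n, counts_1n, ortholog_maps, samples,
                           level = 0.95, min_fraction = 25 / 30,
                           log2_scale = TRUE, pseudocount = 1,
                           expected_fraction = 1 / 3) {
  check_sample_table(samples)
  allo <- samples[samples$ploidy_class == "allotriploid", , drop = FALSE]
  if (nrow(allo) == 0L) stop("no allotriploid samples", call. = FALSE)
  missing <- setdiff(allo$sample_id,
                     intersect(colnames(counts_2n), colnames(counts_1n)))
  if (length(missing)) {
    stop("allotriploid sample '", missing[1L],
         "' missing from the count matrices", call. = FALSE)
  }
  bad_pop <- setdiff(unique(allo$population), names(ortholog_maps))
  if (length(bad_pop)) {
    stop("no ortholog map for population '", bad_pop[1L], "'", call. = FALSE)
  }

  reg_fits <- list()
  calls <- vector("list", nrow(allo))
  fractions <- numeric(nrow(allo))
  for (i in seq_len(nrow(allo))) {
    sid <- allo$sample_id[i]
    map <- ortholog_maps[[allo$population[i]]]
    rf <- fit_sample_regression(counts_2n, counts_1n, map, sid,
                                log2_scale = log2_scale,
                                pseudocount = pseudocount)
    reg_fits[[sid]] <- rf
    calls[[i]] <- prediction_outliers(rf, level = level)
    fractions[i] <- haploid_fraction(counts_2n, counts_1n, map, sid)
  }
  calls <- do.call(rbind, calls)
  calls$population <- allo$population[match(calls$sample_id, allo$sample_id)]

  fits <- data.frame(
    sample_id = allo$sample_id,
    population = allo$population,
    slope = vapply(reg_fits[allo$sample_id], `[[`, numeric(1), "slope"),
    intercept = vapply(reg_fits[allo$sample_id], `[[`, numeric(1),
                       "intercept"),
    residual_sd = vapply(reg_fits[allo$sample_id], `[[`, numeric(1),
                         "residual_sd"),
    n_pairs = vapply(reg_fits[allo$sample_id], `[[`, numeric(1), "n_pairs"),
    row.names = NULL
  )

  fraction_tab <- data.frame(sample_id = allo$sample_id,
                             population = allo$population,
                             fraction = fractions, row.names = NULL)
  fraction_tests <- do.call(rbind, lapply(
    split(fraction_tab, fraction_tab$population), function(fp) {
      res <- tryCatch(test_fraction_excess(fp$fraction, expected_fraction),
                      error = function(e) NULL)
      data.frame(population = fp$population[1L], n = nrow(fp),
                 mean_fraction = mean(fp$fraction),
                 median_fraction = median(fp$fraction),
                 z = if (is.null(res)) NA_real_ else res$z,
                 p = if (is.null(res)) NA_real_ else res$p)
    }))
  rownames(fraction_tests) <- NULL

  consistent <- consistent_bias(calls, samples, min_fraction)
  consistent <- add_paired_tests(consistent, counts_2n, counts_1n,
                                 ortholog_maps, allo)

  structure(list(
    fits = fits,
    calls = calls,
    fractions = fraction_tab,
    fraction_tests = fraction_tests,
    consistent = consistent,
    regressions = reg_fits,
    samples = allo,
    level = level,
    min_fraction = min_fraction,
    expected_fraction = expected_fraction,
    scale = if (log2_scale) "log2" else "raw",
    pseudocount = pseudocount
  ), class = "subgenome_bias")
}

#' Attach per-gene paired-test columns to a consistency table
#'
#' Each compartment is corrected by its library size over the population's
#' ortholog pairs (reads assigned to orthologs present in both subgenomes),
#' then per gene a paired t-test compares corrected 1n vs 2n expression
#' across the population's samples; Holm adjustment is applied within each
#' population over the genes actually tested.
#' @noRd
add_paired_tests <- function(consistent, counts_2n, counts_1n,
                             ortholog_maps, allo) {
  consistent$t <- NA_real_
  consistent$p <- NA_real_
  consistent$p_holm <- NA_real_
  for (pop in unique(consistent$population)) {
    map <- ortholog_maps[[pop]]
    sids <- allo$sample_id[allo$population == pop]
    c2 <- counts_2n[map$primary_id, sids, drop = FALSE]
    c1 <- counts_1n[map$acquired_id, sids, drop = FALSE]
    tot2 <- colSums(c2)
    tot1 <- colSums(c1)
    if (any(tot2 == 0) || any(tot1 == 0)) next
    corr2 <- sweep(c2, 2L, tot2, "/") * 1e6
    corr1 <- sweep(c1, 2L, tot1, "/") * 1e6
    rows <- which(consistent$population == pop)
    gidx <- match(consistent$gene_id[rows], map$primary_id)
    for (k in seq_along(rows)) {
      gi <- gidx[k]
      if (is.na(gi)) next
      res <- tryCatch(paired_subgenome_test(corr2[gi, ], corr1[gi, ]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        consistent$t[rows[k]] <- res$t
        consistent$p[rows[k]] <- res$p
      }
    }
    tested <- rows[!is.na(consistent$p[rows])]
    consistent$p_holm[tested] <- holm_adjust(consistent$p[tested])
  }
  consistent
}

# Methods ----------------------------------------------------------------------

#' @export
print.subgenome_bias <- function(x, ...) {
  cat("Subgenome expression-bias fit\n")
  cat("  samples:", nrow(x$fits), "allotriploid across",
      length(unique(x$fits$population)), "population(s)\n")
  cat("  regression scale:", x$scale,
      "| prediction level:", x$level, "\n")
  for (pop in unique(x$consistent$population)) {
    cp <- x$consistent[x$consistent$population == pop, ]
    cat(sprintf("  %-10s over: %4d  under: %4d  (threshold %d/%d)\n", pop,
                sum(cp$call == "1n_over"), sum(cp$call == "1n_under"),
                cp$threshold[1L], cp$n_samples[1L]))
  }
  invisible(x)
}

#' @export
summary.subgenome_bias <- function(object, ...) {
  cons <- object$consistent
  pop_summary <- do.call(rbind, lapply(split(cons, cons$population),
    function(cp) {
      data.frame(population = cp$population[1L],
                 n_genes_evaluated = nrow(cp),
                 n_1n_over = sum(cp$call == "1n_over"),
                 n_1n_under = sum(cp$call == "1n_under"),
                 threshold = cp$threshold[1L],
                 n_samples = cp$n_samples[1L])
    }))
  rownames(pop_summary) <- NULL
  out <- list(populations = pop_summary,
              fraction_tests = object$fraction_tests,
              fits = object$fits,
              level = object$level)
  class(out) <- "summary.subgenome_bias"
  out
}

#' @export
print.summary.subgenome_bias <- function(x, ...) {
  cat("Subgenome expression-bias fit (prediction level ", x$level, ")\n\n",
      sep = "")
  cat("Haploid read fraction (null expectation 1/3):\n")
  ft <- x$fraction_tests
  for (i in seq_len(nrow(ft))) {
    cat(sprintf("  %-10s n=%2d  median %.3f  mean %.3f  z=%6.2f  p=%.3g\n",
                ft$population[i], ft$n[i], ft$median_fraction[i],
                ft$mean_fraction[i], ft$z[i], ft$p[i]))
  }
  cat("\nConsistently biased genes per population:\n")
  ps <- x$populations
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %-10s %d over / %d under of %d evaluated (>= %d of %d samples)\n",
                ps$population[i], ps$n_1n_over[i], ps$n_1n_under[i],
                ps$n_genes_evaluated[i], ps$threshold[i], ps$n_samples[i]))
  }
  invisible(x)
}

#' @export
coef.subgenome_bias <- function(object, ...) {
  m <- cbind(intercept = object$fits$intercept, slope = object$fits$slope)
  rownames(m) <- object$fits$sample_id
  m
}

#' Predict acquired-subgenome expression from primary-subgenome counts
#'
#' @param object A `"subgenome_bias"` fit.
#' @param newdata Data frame with columns `sample_id` and `count_2n`. When
#'   omitted, the per-pair predictions made during fitting are returned.
#' @param level Prediction-interval level; defaults to the fit's level.
#' @param ... Unused.
#' @return Data frame with predicted value and prediction bounds on the
#'   fit's regression scale.
#' @export
predict.subgenome_bias <- function(object, newdata = NULL,
                                   level = object$level, ...) {
  if (is.null(newdata)) {
    return(object$calls[c("primary_id", "sample_id", "predicted_1n",
                          "lower", "upper")])
  }
  stopifnot(all(c("sample_id", "count_2n") %in% names(newdata)))
  out <- newdata
  out$predicted_1n <- out$lower <- out$upper <- NA_real_
  for (sid in unique(newdata$sample_id)) {
    rf <- object$regressions[[sid]]
    if (is.null(rf)) stop("no fit for sample '", sid, "'", call. = FALSE)
    rows <- which(newdata$sample_id == sid)
    x <- if (rf$scale == "log2") {
      log2(newdata$count_2n[rows] + rf$pseudocount)
    } else newdata$count_2n[rows]
    iv <- sg_interval(rf, x, level)
    out$predicted_1n[rows] <- iv$pred
    out$lower[rows] <- iv$lower
    out$upper[rows] <- iv$upper
  }
  out
}

#' @export
residuals.subgenome_bias <- function(object, ...) {
  data.frame(sample_id = object$calls$sample_id,
             primary_id = object$calls$primary_id,
             residual = object$calls$observed_1n - object$calls$predicted_1n)
}

#' @export
fitted.subgenome_bias <- function(object, ...) {
  data.frame(sample_id = object$calls$sample_id,
             primary_id = object$calls$primary_id,
             fitted = object$calls$predicted_1n)
}

#' Plot one sample's 2n-vs-1n regression with its prediction band
#'
#' @param x A `"subgenome_bias"` fit.
#' @param sample Sample ID to plot; defaults to the first fitted sample.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.subgenome_bias <- function(x, sample = x$fits$sample_id[1L], ...) {
  rf <- x$regressions[[sample]]
  if (is.null(rf)) stop("no fit for sample '", sample, "'", call. = FALSE)
  calls <- x$calls[x$calls$sample_id == sample, ]
  lab <- if (rf$scale == "log2") "log2(count + 1)" else "count"
  cols <- c(above = "firebrick", below = "steelblue",
            within = adjustcolor("grey40", 0.5))
  ord <- order(rf$pairs$x)
  plot(rf$pairs$x, rf$pairs$y, pch = 16, cex = 0.6,
       col = cols[calls$direction],
       xlab = paste("2n", lab), ylab = paste("1n", lab),
       main = paste("2n vs 1n,", sample), ...)
  abline(rf$intercept, rf$slope)
  lines(rf$pairs$x[ord], calls$lower[ord], lty = 2)
  lines(rf$pairs$x[ord], calls$upper[ord], lty = 2)
  legend("topleft", bty = "n", pch = 16,
         col = cols, legend = names(cols), cex = 0.8)
  invisible(x)
}
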