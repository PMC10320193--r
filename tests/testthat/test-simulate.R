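test_that("default configuration matches the study's population design", {
  cfg <- simulation_config()
  expect_equal(cfg$populations$n_samples, c(9L, 30L, 6L, 9L, 26L, 7L))
  expect_equal(cfg$populations$name,
               c("Teq/EtOH", "Beer", "Wine 1", "Wine 2", "Wine 3",
                 "Kombucha"))
  expect_equal(sum(cfg$populations$n_samples), 87L)
  expect_equal(unname(cfg$ortholog_retention), c(0.88, 0.70, 0.75))
  full <- simulation_config(full_scale = TRUE)
  expect_equal(full$n_genes, 5206L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(ortholog_retention =
    c("Teq/EtOH" = 1.2, Beer = 0.7, "Wine 1" = 0.75)), "\\(0, 1\\]")
  expect_error(simulation_config(ortholog_retention =
    c("Teq/EtOH" = 0, Beer = 0.7, "Wine 1" = 0.75)), "\\(0, 1\\]")
  pops <- data.frame(name = "A", ploidy_class = "diploid", n_samples = 1L)
  expect_error(simulation_config(populations = pops,
                                 ortholog_retention = numeric(0)),
               "n_samples")
  expect_error(simulation_config(haploid_allocation = 1), "allocation")
  expect_error(simulation_config(library_size = 0), "library_size")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
})

test_that("ortholog loss matches binomial retention expectations", {
  cfg <- simulation_config(n_genes = 5206)
  # average retained counts over seeds close to n * retention
  retained <- sapply(1:20, function(s) {
    lengths(lapply(simulate_ortholog_loss(cfg, seed = s), `[[`,
                   "primary_id"))
  })
  avg <- rowMeans(retained)
  expected <- 5206 * c(0.88, 0.70, 0.75)
  # binomial sd per population is < 33; averaging 20 seeds shrinks it ~4.5x
  expect_true(all(abs(avg - expected) < 30))

  # full retention: total map, shared core covers the genome
  cfg1 <- simulation_config(n_genes = 100, ortholog_retention =
    c("Teq/EtOH" = 1, Beer = 1, "Wine 1" = 1))
  maps <- simulate_ortholog_loss(cfg1, seed = 1)
  expect_equal(lengths(lapply(maps, `[[`, "primary_id")),
               c("Teq/EtOH" = 100L, Beer = 100L, "Wine 1" = 100L))
  expect_equal(length(attr(maps, "shared_core")), 100L)
})

test_that("mean shared-core size matches the product of retentions", {
  cfg <- simulation_config(n_genes = 1000)
  cores <- vapply(1:200, function(s) {
    length(attr(simulate_ortholog_loss(cfg, seed = s), "shared_core"))
  }, numeric(1))
  # independent retention: E[core] = 1000 * 0.88 * 0.70 * 0.75 = 462
  expect_equal(mean(cores), 462, tolerance = 5 / 462)
})

test_that("fixed seed gives identical datasets and compartments conserve totals", {
  cfg <- simulation_config(n_genes = 150, library_size = 5e4,
                           n_bias_genes = 8, n_de_genes = 6)
  a <- simulate_counts(cfg, seed = 5)
  b <- simulate_counts(cfg, seed = 5)
  expect_identical(a$counts_total, b$counts_total)
  expect_identical(a$counts_1n, b$counts_1n)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_counts(cfg, seed = 6)
  expect_false(identical(a$counts_total, c2$counts_total))

  # 2n + 1n == total for every allotriploid sample
  for (pop in names(a$ortholog_maps)) {
    map <- a$ortholog_maps[[pop]]
    sids <- a$samples$sample_id[a$samples$population == pop]
    onen <- matrix(0, nrow(a$counts_2n), length(sids),
                   dimnames = list(rownames(a$counts_2n), sids))
    onen[map$primary_id, ] <- a$counts_1n[map$acquired_id, sids]
    expect_equal(a$counts_2n[, sids] + onen,
                 a$counts_total[, sids, drop = FALSE][, ],
                 ignore_attr = TRUE)
  }

  # every gene has a truth row; biased genes are present in all subgenomes
  expect_setequal(a$truth$gene_id, rownames(a$counts_total))
  pres <- a$truth[grep("^present_1n", names(a$truth))]
  expect_true(all(rowSums(pres[a$truth$is_1n_biased, ]) == ncol(pres)))
})

test_that("expected-count mode splits compartments exactly at the allocation", {
  cfg <- simulation_config(
    n_genes = 10, library_size = 3000, baseline_log_sd = 0,
    dispersion = 0, noise_model = "expected",
    ortholog_retention = c("Teq/EtOH" = 1, Beer = 1, "Wine 1" = 1))
  sim <- simulate_counts(cfg, seed = 1)
  # every gene has lambda = 300 and allocation 1/3: exactly 100 / 200
  expect_true(all(sim$counts_2n == 200))
  expect_true(all(sim$counts_total == 300))
  for (pop in names(sim$ortholog_maps)) {
    map <- sim$ortholog_maps[[pop]]
    sids <- sim$samples$sample_id[sim$samples$population == pop]
    expect_true(all(sim$counts_1n[map$acquired_id, sids] == 100))
  }
})

test_that("biased genes show their configured haploid share empirically", {
  cfg <- simulation_config(
    n_genes = 60, library_size = 60 * 400, n_bias_genes = 50,
    bias_allocation = 0.6, baseline_log_sd = 0, dispersion = 0.02,
    ortholog_retention = c("Teq/EtOH" = 1, Beer = 1, "Wine 1" = 1))
  sim <- simulate_counts(cfg, seed = 3)
  map <- sim$ortholog_maps$Beer
  sids <- sim$samples$sample_id[sim$samples$population == "Beer"]
  bias <- sim$truth$gene_id[sim$truth$is_1n_biased]
  idx <- match(bias, map$primary_id)
  share <- colSums(sim$counts_1n[map$acquired_id[idx], sids]) /
    colSums(sim$counts_total[bias, sids])
  # binomial thinning at p = 0.6 over >= 200-count genes
  expect_true(all(abs(share - 0.6) < 0.03))
  expect_equal(median(share), 0.6, tolerance = 0.02)
})

test_that("empirical dispersion converges to the configured alpha", {
  pops <- data.frame(name = "X", ploidy_class = "diploid",
                     n_samples = 300L)
  cfg <- simulation_config(populations = pops, n_genes = 50,
                           ortholog_retention = numeric(0),
                           baseline_log_sd = 0, dispersion = 0.3,
                           library_size = 50 * 500)
  sim <- simulate_counts(cfg, seed = 9)
  m <- rowMeans(sim$counts_total)
  v <- apply(sim$counts_total, 1, var)
  alpha_hat <- (v - m) / m^2
  expect_equal(mean(alpha_hat), 0.3, tolerance = 0.1)
})
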