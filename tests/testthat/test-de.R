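two_pop_samples <- function(nA = 6, nB = 6) {
  data.frame(
    sample_id = c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB))),
    population = rep(c("PopA", "PopB"), c(nA, nB)),
    ploidy_class = "diploid"
  )
}

test_that("a gene with identical normalized counts in both groups is null", {
  samples <- two_pop_samples()
  # columns exactly proportional: after size-factor normalization every
  # gene is flat, so the group coefficient is identically zero
  base <- 10L * (1:30)
  f <- rep(c(1L, 2L), 6)
  counts <- outer(base, f)
  dimnames(counts) <- list(sprintf("g%03d", 1:30), samples$sample_id)
  de <- nb_wald_de(counts, samples, "PopA")
  flat <- de[de$gene_id == "g001", ]
  expect_equal(flat$log2fc, 0, tolerance = 1e-6)
  expect_equal(flat$p, 1, tolerance = 1e-6)
})

test_that("swapping focal and rest negates the fold-change and keeps p", {
  samples <- two_pop_samples()
  set.seed(6)
  counts <- random_counts(40, 12, lambda = 60)
  counts[1:5, 1:6] <- counts[1:5, 1:6] * 4L
  colnames(counts) <- samples$sample_id
  a <- nb_wald_de(counts, samples, "PopA")
  b <- nb_wald_de(counts, samples, "PopB")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("all-zero genes are excluded from the BH denominator", {
  samples <- two_pop_samples(3, 3)
  set.seed(7)
  counts <- random_counts(20, 6, lambda = 50)
  counts[3, ] <- 0L
  colnames(counts) <- samples$sample_id
  de <- nb_wald_de(counts, samples, "PopA")
  expect_true(is.na(de$p[3]) && is.na(de$padj[3]))
  ok <- !is.na(de$p)
  expect_equal(de$padj[ok], p.adjust(de$p[ok], "BH"))
})

test_that("DE calling applies the adjusted-p and fold-change cutoffs", {
  de <- data.frame(
    gene_id = paste0("g", 1:5),
    log2fc = c(1.01, 2, -1.5, 0.99, 1.2),
    padj = c(0.049, 0.051, 0.01, 0.001, NA)
  )
  got <- call_de(de)
  expect_setequal(got$gene_id, c("g1", "g3"))
  expect_equal(got$direction[got$gene_id == "g3"], "down")

  set.seed(9)
  rt <- data.frame(gene_id = paste0("r", 1:200),
                   log2fc = rnorm(200, 0, 1.5),
                   padj = runif(200))
  got <- call_de(rt, fdr = 0.2, min_abs_lfc = 0.8)
  want <- rt[!is.na(rt$padj) & rt$padj < 0.2 & abs(rt$log2fc) > 0.8, ]
  expect_setequal(got$gene_id, want$gene_id)
})

test_that("signature calling keeps strong top-half DE genes", {
  de_set <- data.frame(
    gene_id = paste0("g", 1:4),
    log2fc = c(2.0, 1.7, 1.5, 3.0),
    padj = c(1e-10, 1e-6, 1e-4, 1e-2),
    direction = "up"
  )
  sig <- call_signatures(de = NULL, de_set = de_set)
  expect_setequal(sig$gene_id, c("g1", "g2"))
  expect_equal(unname(attr(sig, "padj_cutoffs")["up"]),
               median(de_set$padj))

  # a single DE gene in a direction can never beat the strict median
  single <- de_set[1, ]
  expect_equal(nrow(call_signatures(NULL, de_set = single)), 0L)

  # signatures are DE genes with |lfc| > 1.6 by construction
  set.seed(11)
  rnd <- data.frame(gene_id = paste0("r", 1:100),
                    log2fc = rnorm(100, 0, 2),
                    padj = 10^-runif(100, 0, 8))
  rnd$direction <- ifelse(rnd$log2fc > 0, "up", "down")
  sig <- call_signatures(NULL, de_set = rnd)
  expect_true(all(abs(sig$log2fc) > 1.6))
  expect_true(all(sig$gene_id %in% rnd$gene_id))
  # brute-force check of the strict top-half rule per direction
  for (d in c("up", "down")) {
    dd <- rnd[rnd$direction == d, ]
    want <- dd$gene_id[abs(dd$log2fc) > 1.6 & dd$padj < median(dd$padj)]
    expect_setequal(sig$gene_id[sig$direction == d], want)
  }
})

test_that("Welch test matches the hand formula and BH the step-up oracle", {
  a <- c(5.1, 6.2, 5.8, 6.0, 5.5)
  b <- c(7.9, 8.3, 7.2, 8.8)
  got <- welch_t_test(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand))

  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(25)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("planted fold-changes are recovered by the one-vs-rest contrast", {
  cfg <- simulation_config(n_genes = 300, library_size = 2e5,
                           n_de_genes = 18, de_log2fc = 2)
  sim <- simulate_counts(cfg, seed = 23)
  truth <- sim$truth
  pop <- "Beer"
  de <- nb_wald_de(sim$counts_total, sim$samples, pop)
  called <- call_de(de)
  planted <- truth$gene_id[truth$is_de & truth$de_population == pop]
  expect_true(length(planted) >= 2)
  expect_true(all(planted %in% called$gene_id))
  # estimated magnitude near the planted effect
  est <- called$log2fc[match(planted, called$gene_id)]
  tru <- truth$de_log2fc[match(planted, truth$gene_id)]
  expect_equal(est, tru, tolerance = 0.2)
})
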