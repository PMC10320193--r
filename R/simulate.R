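# Synthetic allopolyploid RNA-seq data with known truth. The generator
# emulates the population structure of the study system: six populations,
# three of them allotriploid (2n + 1n) each with its own acquired haploid
# reference and partial ortholog retention from loss-of-heterozygosity, one
# autotriploid and two diploid populations. Counts are negative binomial;
# for allotriploid samples a gene's total count is thinned binomially into
# the two subgenome compartments, mirroring read assignment under
# competitive mapping and keeping totals exactly conserved.

DEFAULT_POPULATIONS <- data.frame(
  name = c("Teq/EtOH", "Beer", "Wine 1", "Wine 2", "Wine 3", "Kombucha"),
  ploidy_class = c("allotriploid", "allotriploid", "allotriploid",
                   "autotriploid", "diploid", "diploid"),
  n_samples = c(9L, 30L, 6L, 9L, 26L, 7L),
  stringsAsFactors = FALSE
)

DEFAULT_RETENTION <- c("Teq/EtOH" = 0.88, "Beer" = 0.70, "Wine 1" = 0.75)

#' Configuration for the allopolyploid count simulator
#'
#' Defaults reproduce the study design: populations Teq/EtOH, Beer and
#' Wine 1 are allotriploid with 9, 30 and 6 samples and per-gene 1n-ortholog
#' retention 0.88, 0.70 and 0.75; Wine 2 is autotriploid (9 samples) and
#' Wine 3 and Kombucha diploid (26 and 7 samples). The default scale is
#' reduced for fast simulation (500 genes, 2e5 expected reads per library);
#' `full_scale = TRUE` switches to the full 5,206-gene genome at 2e6 reads.
#'
#' @param populations Data frame with columns `name`, `ploidy_class`,
#'   `n_samples`; default the six study populations.
#' @param n_genes Number of primary-genome genes.
#' @param ortholog_retention Named vector, per allotriploid population, of
#'   the probability that a primary gene retains a 1n ortholog (in (0, 1]).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   per-gene relative expression distribution (log-normal).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`), scalar or per-gene vector, >= 0.
#' @param haploid_allocation Null per-gene fraction of a gene's transcripts
#'   coming from the 1n copy, in (0, 1); 1/3 under equal per-copy expression
#'   of three haplotypes.
#' @param n_bias_genes,bias_allocation Number of 1n-biased genes and their
#'   true allocation; biased genes are drawn from the shared ortholog core
#'   so they are present in every acquired subgenome.
#' @param n_de_genes,de_log2fc Number of population-DE genes and the
#'   magnitude of their log2 fold-change (direction alternates; focal
#'   populations are assigned round-robin).
#' @param library_size Expected reads per sample.
#' @param ploidy_scale Optional global expression scale for autotriploid
#'   samples (default 1: simulated like diploids).
#' @param noise_model `"nb"` for stochastic negative-binomial counts
#'   (Poisson when `dispersion == 0`), or `"expected"` for deterministic
#'   expected counts (useful for exactness checks).
#' @param full_scale If `TRUE`, use 5,206 genes and a 2e6-read library.
#' @return Validated configuration object of class `"sim_config"`.
#' @export
simulation_config <- function(populations = DEFAULT_POPULATIONS,
                              n_genes = 500L,
                              ortholog_retention = DEFAULT_RETENTION,
                              baseline_log_mean = 0,
                              baseline_log_sd = 1.5,
                              dispersion = 0.05,
                              haploid_allocation = 1 / 3,
                              n_bias_genes = 0L,
                              bias_allocation = 0.6,
                              n_de_genes = 0L,
                              de_log2fc = 2,
                              library_size = 2e5,
                              ploidy_scale = 1,
                              noise_model = c("nb", "expected"),
                              full_scale = FALSE) {
  noise_model <- match.arg(noise_model)
  if (isTRUE(full_scale)) {
    n_genes <- 5206L
    library_size <- 2e6
  }
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "ploidy_class", "n_samples") %in%
                  names(populations)))
  if (any(!populations$ploidy_class %in% PLOIDY_CLASSES)) {
    stop("invalid ploidy_class in populations", call. = FALSE)
  }
  if (any(populations$n_samples < 2L)) {
    stop("each population needs n_samples >= 2", call. = FALSE)
  }
  allo <- populations$name[populations$ploidy_class == "allotriploid"]
  if (!all(allo %in% names(ortholog_retention))) {
    stop("ortholog_retention must name every allotriploid population",
         call. = FALSE)
  }
  ret <- ortholog_retention[allo]
  if (any(ret <= 0 | ret > 1)) {
    stop("ortholog retention probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (any(dispersion < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (!(length(dispersion) %in% c(1L, n_genes))) {
    stop("dispersion must be scalar or length n_genes", call. = FALSE)
  }
  if (haploid_allocation <= 0 || haploid_allocation >= 1) {
    stop("haploid_allocation must lie in (0, 1)", call. = FALSE)
  }
  if (bias_allocation <= 0 || bias_allocation >= 1) {
    stop("bias_allocation must lie in (0, 1)", call. = FALSE)
  }
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  if (n_bias_genes < 0L || n_de_genes < 0L) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  if (baseline_log_sd < 0) stop("baseline_log_sd must be >= 0", call. = FALSE)
  if (ploidy_scale <= 0) stop("ploidy_scale must be positive", call. = FALSE)
  structure(list(
    populations = populations,
    n_genes = as.integer(n_genes),
    ortholog_retention = ret,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    haploid_allocation = haploid_allocation,
    n_bias_genes = as.integer(n_bias_genes),
    bias_allocation = bias_allocation,
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    library_size = library_size,
    ploidy_scale = ploidy_scale,
    noise_model = noise_model
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  genes:", x$n_genes, "  library size:", format(x$library_size), "\n")
  cat("  populations:",
      paste0(x$populations$name, " (", x$populations$n_samples, ")",
             collapse = ", "), "\n")
  cat("  1n retention:",
      paste0(names(x$ortholog_retention), "=", x$ortholog_retention,
             collapse = ", "), "\n")
  cat("  bias genes:", x$n_bias_genes, "at allocation", x$bias_allocation,
      " | DE genes:", x$n_de_genes, "at |log2FC|", x$de_log2fc, "\n")
  invisible(x)
}

#' @noRd
sim_gene_ids <- function(n) {
  sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
}

#' @noRd
sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "", x)

#' Simulate per-gene ortholog loss for each acquired subgenome
#'
#' Each primary gene is independently retained in a population's acquired
#' haploid subgenome with that population's retention probability, emulating
#' loss of heterozygosity. The intersection of the maps is reported as the
#' shared ortholog core.
#'
#' @param config A [simulation_config()] object.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return Named list of per-population ortholog maps (data frames with
#'   columns `primary_id`, `acquired_id`), with attribute `"shared_core"`
#'   holding the primary gene IDs retained in every acquired subgenome.
#' @export
simulate_ortholog_loss <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config$n_genes)
  with_seed(seed, {
    maps <- lapply(names(config$ortholog_retention), function(p) {
      keep <- runif(config$n_genes) < config$ortholog_retention[[p]]
      data.frame(primary_id = genes[keep],
                 acquired_id = paste0(genes[keep], ".", sanitize_id(p)))
    })
    names(maps) <- names(config$ortholog_retention)
    core <- Reduce(intersect, lapply(maps, `[[`, "primary_id"))
    structure(maps, shared_core = core)
  })
}

#' Shared ortholog core of a set of per-population maps
#' @param maps Named list of ortholog maps.
#' @return Character vector of primary gene IDs present in every map.
#' @export
shared_core <- function(maps) {
  Reduce(intersect, lapply(maps, `[[`, "primary_id"))
}

#' Simulate subgenome-resolved count matrices with known truth
#'
#' Per-gene relative expression is log-normal; per-sample expected counts
#' are `library_size` times the relative expression, rescaled by
#' `2^log2fc` for DE genes in their focal population. Totals are drawn
#' negative-binomially (Poisson at dispersion 0); for allotriploid samples
#' the total is then binomially thinned into the 1n compartment with the
#' gene's true allocation (0 where the gene has no 1n ortholog), and the 2n
#' compartment receives the remainder, so `2n + 1n == total` holds exactly.
#' Under `noise_model = "expected"` counts equal rounded expectations.
#'
#' @param config A [simulation_config()] object.
#' @param ortholog_maps Optional named list of per-population ortholog maps;
#'   generated via [simulate_ortholog_loss()] (same seed stream) when `NULL`.
#' @param seed Integer seed; output is deterministic given config + seed.
#' @return List of class `"subgenome_sim"` with elements `counts_2n`
#'   (primary-compartment counts, allotriploid samples), `counts_1n`
#'   (acquired-compartment counts indexed by acquired gene ID), `counts_total`
#'   (all samples; equals `2n + 1n` for allotriploid samples), `samples`,
#'   `truth` (per-gene truth table), `ortholog_maps`, and `config`.
#' @export
simulate_counts <- function(config, ortholog_maps = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config$n_genes)
  pops <- config$populations
  with_seed(seed, {
    if (is.null(ortholog_maps)) {
      ortholog_maps <- simulate_ortholog_loss(config, seed = NULL)
    }
    for (p in names(ortholog_maps)) {
      check_ortholog_map(ortholog_maps[[p]], p)
    }
    core <- shared_core(ortholog_maps)

    # per-gene baseline relative expression
    rel <- rlnorm(config$n_genes, config$baseline_log_mean,
                  config$baseline_log_sd)
    rel <- rel / sum(rel)
    lambda_base <- setNames(rel * config$library_size, genes)
    alpha <- rep_len(config$dispersion, config$n_genes)

    # truth: haplotype allocation
    p_alloc <- rep(config$haploid_allocation, config$n_genes)
    names(p_alloc) <- genes
    bias_genes <- character(0)
    if (config$n_bias_genes > 0L) {
      if (length(core) < config$n_bias_genes) {
        stop("cannot place ", config$n_bias_genes, " biased genes: only ",
             length(core), " genes are present in every acquired subgenome",
             call. = FALSE)
      }
      bias_genes <- sort(sample(core, config$n_bias_genes))
      p_alloc[bias_genes] <- config$bias_allocation
    }
    bias_dir <- if (config$bias_allocation > config$haploid_allocation) {
      "over"
    } else "under"

    # truth: population-DE genes, focal populations round-robin,
    # directions alternating
    de_tab <- data.frame(gene_id = character(0), population = character(0),
                         log2fc = numeric(0))
    if (config$n_de_genes > 0L) {
      cand <- setdiff(genes, bias_genes)
      if (length(cand) < config$n_de_genes) {
        stop("not enough genes for the requested DE truth set", call. = FALSE)
      }
      de_genes <- sort(sample(cand, config$n_de_genes))
      de_tab <- data.frame(
        gene_id = de_genes,
        population = rep_len(pops$name, config$n_de_genes),
        log2fc = rep_len(c(1, -1), config$n_de_genes) * abs(config$de_log2fc)
      )
    }

    # sample table
    samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
      n <- pops$n_samples[i]
      data.frame(
        sample_id = sprintf("%s_%02d", sanitize_id(pops$name[i]), seq_len(n)),
        population = pops$name[i],
        ploidy_class = pops$ploidy_class[i],
        subgenome_ref = if (pops$ploidy_class[i] == "allotriploid") {
          paste0("1n-", sanitize_id(pops$name[i]))
        } else NA_character_
      )
    }))
    rownames(samples) <- NULL
    allo_samples <- samples$sample_id[samples$ploidy_class == "allotriploid"]

    acquired_ids <- unlist(lapply(ortholog_maps, `[[`, "acquired_id"),
                           use.names = FALSE)
    counts_total <- matrix(0L, config$n_genes, nrow(samples),
                           dimnames = list(genes, samples$sample_id))
    counts_2n <- matrix(0L, config$n_genes, length(allo_samples),
                        dimnames = list(genes, allo_samples))
    counts_1n <- matrix(0L, length(acquired_ids), length(allo_samples),
                        dimnames = list(acquired_ids, allo_samples))

    expected <- config$noise_model == "expected"
    for (j in seq_len(nrow(samples))) {
      sid <- samples$sample_id[j]
      pop <- samples$population[j]
      lam <- lambda_base
      de_here <- de_tab[de_tab$population == pop, , drop = FALSE]
      if (nrow(de_here)) {
        lam[de_here$gene_id] <- lam[de_here$gene_id] * 2^de_here$log2fc
      }
      if (samples$ploidy_class[j] == "autotriploid") {
        lam <- lam * config$ploidy_scale
      }
      tot <- if (expected) {
        round(lam)
      } else {
        pois <- alpha == 0
        out <- numeric(config$n_genes)
        out[pois] <- rpois(sum(pois), lam[pois])
        if (any(!pois)) {
          out[!pois] <- rnbinom(sum(!pois), mu = lam[!pois],
                                size = 1 / alpha[!pois])
        }
        setNames(out, genes)
      }
      counts_total[, j] <- tot
      if (samples$ploidy_class[j] == "allotriploid") {
        map <- ortholog_maps[[pop]]
        if (is.null(map)) {
          stop("no ortholog map for allotriploid population '", pop, "'",
               call. = FALSE)
        }
        pg <- setNames(numeric(config$n_genes), genes)
        pg[map$primary_id] <- p_alloc[map$primary_id]
        one_n <- if (expected) {
          round(tot * pg)
        } else {
          setNames(rbinom(length(tot), tot, pg), genes)
        }
        counts_2n[, sid] <- tot - one_n
        counts_1n[map$acquired_id, sid] <- one_n[map$primary_id]
      }
    }

    present <- matrix(FALSE, config$n_genes, length(ortholog_maps))
    for (k in seq_along(ortholog_maps)) {
      present[, k] <- genes %in% ortholog_maps[[k]]$primary_id
    }
    if (length(ortholog_maps)) {
      colnames(present) <- paste0("present_1n.", names(ortholog_maps))
    }
    truth <- data.frame(
      gene_id = genes,
      baseline_lambda = lambda_base,
      dispersion = alpha,
      true_allocation = unname(p_alloc),
      is_1n_biased = genes %in% bias_genes,
      bias_direction = ifelse(genes %in% bias_genes, bias_dir, NA_character_),
      is_de = genes %in% de_tab$gene_id,
      de_population = de_tab$population[match(genes, de_tab$gene_id)],
      de_log2fc = de_tab$log2fc[match(genes, de_tab$gene_id)],
      present
    )
    if (any(truth$is_1n_biased & !apply(present, 1L, all))) {
      stop("internal error: biased gene absent from an acquired subgenome",
           call. = FALSE)
    }

    structure(list(
      counts_2n = structure(counts_2n, compartment = "2n"),
      counts_1n = structure(counts_1n, compartment = "1n"),
      counts_total = structure(counts_total, compartment = "total"),
      samples = samples,
      truth = truth,
      ortholog_maps = ortholog_maps,
      config = config
    ), class = "subgenome_sim")
  })
}

#' @export
print.subgenome_sim <- function(x, ...) {
  cat("Simulated allopolyploid RNA-seq dataset\n")
  cat("  ", nrow(x$counts_total), "genes x", ncol(x$counts_total),
      "samples (", ncol(x$counts_2n), "allotriploid )\n")
  cat("  biased genes:", sum(x$truth$is_1n_biased),
      " DE genes:", sum(x$truth$is_de), "\n")
  cat("  shared ortholog core:", length(shared_core(x$ortholog_maps)),
      "genes\n")
  invisible(x)
}

#' Write a per-gene truth table as long-format TSV
#'
#' One row per (gene, attribute) pair, so downstream tools need no knowledge
#' of the column layout.
#' @param truth Truth table from [simulate_counts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  attrs <- setdiff(names(truth), "gene_id")
  long <- do.call(rbind, lapply(attrs, function(a) {
    data.frame(gene_id = truth$gene_id, attribute = a,
               value = as.character(truth[[a]]))
  }))
  long <- long[order(long$gene_id, long$attribute), ]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Simulate a gene annotation (lengths and GO terms)
#'
#' Assigns log-normal gene lengths and random GO term memberships; a term of
#' choice can be planted so that it is enriched in a given gene set, for
#' testing enrichment recovery.
#'
#' @param gene_ids Character vector of gene IDs (the annotation universe).
#' @param n_terms Number of GO terms per category.
#' @param mean_genes_per_term Expected number of genes annotated per term.
#' @param planted_term Optional term ID to enrich.
#' @param planted_genes Genes carrying `planted_term`.
#' @param planted_category Category of the planted term.
#' @param seed Integer seed.
#' @return Annotation list (`lengths`, `go`) as from [read_annotation()].
#' @export
simulate_annotation <- function(gene_ids, n_terms = 20L,
                                mean_genes_per_term = 15,
                                planted_term = NULL, planted_genes = NULL,
                                planted_category = "BP", seed = NULL) {
  with_seed(seed, {
    lens <- setNames(round(rlnorm(length(gene_ids), log(1500), 0.4)),
                     gene_ids)
    cats <- c("BP", "MF", "CC")
    go <- do.call(rbind, lapply(cats, function(cat) {
      do.call(rbind, lapply(seq_len(n_terms), function(i) {
        k <- min(length(gene_ids),
                 max(2L, rpois(1L, mean_genes_per_term)))
        data.frame(gene_id = sample(gene_ids, k),
                   term = sprintf("GO:%s%04d", cat, i),
                   category = cat)
      }))
    }))
    if (!is.null(planted_term)) {
      go <- rbind(go, data.frame(gene_id = planted_genes,
                                 term = planted_term,
                                 category = planted_category))
      go <- go[!duplicated(go[c("gene_id", "term")]), ]
    }
    rownames(go) <- NULL
    list(lengths = lens, go = go)
  })
}
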