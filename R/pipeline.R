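# Config-driven end-to-end run: simulate (or load) subgenome-resolved
# counts, normalize, fit the bias model, run one-vs-rest DE with signature
# calling, enrichment and ordination, and write a manifest. Deterministic
# given config + seed; partial outputs are removed when a stage fails.

DEFAULT_THRESHOLDS <- list(
  de_fdr = 0.05,
  de_min_lfc = 1,
  signature_min_lfc = 1.6,
  prediction_level = 0.95,
  consistency_fraction = 25 / 30,
  enrich_alpha = 0.1,
  hit_min_identity = 85,
  hit_min_qcov = 0.95
)

#' Validate and complete a pipeline configuration
#'
#' @param config Named list, or path to a YAML file. Must contain either a
#'   `simulate` block (arguments for [simulation_config()]; `seed`
#'   mandatory at the top level) or an `inputs` block with paths
#'   `counts_2n`, `counts_1n`, `counts_total`, `samples`, `ortholog_map`
#'   (and optionally `annotation`). Thresholds default to the study values
#'   (DE: adjusted p < 0.05 and |log2FC| > 1; signatures |log2FC| > 1.6;
#'   prediction level 0.95; consistency fraction 25/30; enrichment adjusted
#'   p < 0.1; hit filter 85% identity / 95% query coverage).
#' @return Completed configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  thr <- DEFAULT_THRESHOLDS
  thr[names(config$thresholds)] <- config$thresholds
  config$thresholds <- thr
  if (!is.null(config$simulate)) {
    if (is.null(config$seed)) {
      stop("pipeline config: 'seed' is mandatory in simulate mode",
           call. = FALSE)
    }
    bad <- setdiff(names(config$simulate),
                   names(formals(simulation_config)))
    if (length(bad)) {
      stop("pipeline config: unknown simulate field '", bad[1L], "'",
           call. = FALSE)
    }
  } else if (!is.null(config$inputs)) {
    need <- c("counts_2n", "counts_1n", "counts_total", "samples",
              "ortholog_map")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing)) {
      stop("pipeline config: missing input field '", missing[1L], "'",
           call. = FALSE)
    }
    absent <- unlist(config$inputs[need])[!file.exists(
      unlist(config$inputs[need]))]
    if (length(absent)) {
      stop("pipeline config: input file not found: ", absent[1L],
           call. = FALSE)
    }
  } else {
    stop("pipeline config needs a 'simulate' or an 'inputs' block",
         call. = FALSE)
  }
  config
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load subgenome-resolved counts; (2) optional
#' ortholog-transfer filtering of a BLAST hit file; (3) normalization
#' (2n CPM, shared-core 1n CPM, collapsed counts); (4) the subgenome-bias
#' fit; (5) one-vs-rest DE, signature calling, and enrichment per focal
#' population; (6) ordination (PCA and Spearman matrix of log collapsed
#' counts); (7) a JSON manifest recording the package version, seed,
#' thresholds and the MD5 of every output. All randomness derives from the
#' config seed, so a rerun with the same config writes byte-identical
#' outputs.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  thr <- config$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage, fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] %5.1fs %s", stage,
                      proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))
    }
  }
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    created <<- c(created, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok && length(created)) unlink(created))

  # -- data ------------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- do.call(simulation_config, config$simulate)
    sim <- simulate_counts(cfg, seed = config$seed)
    counts_2n <- sim$counts_2n
    counts_1n <- sim$counts_1n
    counts_total <- sim$counts_total
    samples <- sim$samples
    maps <- sim$ortholog_maps
    annotation <- if (isTRUE(config$enrichment %||% TRUE)) {
      simulate_annotation(rownames(counts_total),
                          seed = config$seed + 1000L)
    }
    emit("counts_2n.tsv", function(p) write_counts(counts_2n, p))
    emit("counts_1n.tsv", function(p) write_counts(counts_1n, p))
    emit("counts_total.tsv", function(p) write_counts(counts_total, p))
    emit("samples.tsv", function(p) write_samples(samples, p))
    emit("ortholog_map.tsv", function(p) write_ortholog_map(maps, p))
    emit("truth.tsv", function(p) write_truth(sim$truth, p))
    if (!is.null(annotation)) {
      emit("annotation.tsv", function(p) write_annotation(annotation, p))
    }
    say("simulate", "%d genes x %d samples (seed %s)",
        nrow(counts_total), ncol(counts_total), config$seed)
  } else {
    inp <- config$inputs
    counts_2n <- read_counts(inp$counts_2n, compartment = "2n")
    counts_1n <- read_counts(inp$counts_1n, compartment = "1n")
    counts_total <- read_counts(inp$counts_total, compartment = "total")
    samples <- read_samples(inp$samples)
    maps <- read_ortholog_map(inp$ortholog_map)
    annotation <- if (!is.null(inp$annotation)) {
      read_annotation(inp$annotation)
    }
    say("load", "%d genes x %d samples", nrow(counts_total),
        ncol(counts_total))
  }

  # -- optional ortholog-transfer filter -------------------------------------
  if (!is.null(config$hits)) {
    hits <- read_hits(config$hits)
    flt <- filter_ortholog_hits(hits, thr$hit_min_identity,
                                thr$hit_min_qcov)
    emit("transfer_filtered.tsv", function(p) {
      write.table(flt, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    say("transfer-filter", "%d of %d hits kept", nrow(flt), nrow(hits))
  }

  # -- normalization ---------------------------------------------------------
  allo <- samples[samples$ploidy_class == "allotriploid", , drop = FALSE]
  core <- shared_core(maps)
  emit("cpm_2n.tsv", function(p) write_counts(cpm_by_subgenome(counts_2n), p))
  core_acquired <- lapply(names(maps), function(pop) {
    m <- maps[[pop]]
    setNames(m$acquired_id, m$primary_id)[core]
  })
  names(core_acquired) <- names(maps)
  shared_1n <- do.call(cbind, lapply(names(maps), function(pop) {
    sids <- allo$sample_id[allo$population == pop]
    sub <- counts_1n[core_acquired[[pop]], sids, drop = FALSE]
    rownames(sub) <- core
    sub
  }))
  shared_1n <- shared_1n[, intersect(allo$sample_id, colnames(shared_1n)),
                         drop = FALSE]
  emit("shared_cpm_1n.tsv", function(p) {
    write_counts(shared_core_normalize(shared_1n, core), p)
  })
  collapsed_allo <- do.call(cbind, lapply(names(maps), function(pop) {
    sids <- allo$sample_id[allo$population == pop]
    collapse_counts(counts_2n[, sids, drop = FALSE],
                    counts_1n[, sids, drop = FALSE], maps[[pop]])
  }))
  non_allo <- samples$sample_id[samples$ploidy_class != "allotriploid"]
  collapsed <- cbind(collapsed_allo,
                     counts_total[rownames(collapsed_allo), non_allo,
                                  drop = FALSE])
  collapsed <- collapsed[, samples$sample_id, drop = FALSE]
  attr(collapsed, "compartment") <- "total"
  emit("collapsed.tsv", function(p) write_counts(collapsed, p))
  say("normalize", "shared core %d genes; collapsed %d x %d",
      length(core), nrow(collapsed), ncol(collapsed))

  # -- subgenome bias --------------------------------------------------------
  fit <- subgenome_bias(counts_2n, counts_1n, maps, samples,
                        level = thr$prediction_level,
                        min_fraction = thr$consistency_fraction)
  tsv <- function(df) function(p) {
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  emit("bias_fits.tsv", tsv(fit$fits))
  emit("bias_calls.tsv", tsv(fit$calls))
  emit("bias_consistent.tsv", tsv(fit$consistent))
  emit("haploid_fractions.tsv", tsv(fit$fractions))
  emit("fraction_tests.tsv", tsv(fit$fraction_tests))
  say("bias", "%d deviation calls; %d consistently biased genes",
      sum(fit$calls$direction != "within"),
      sum(fit$consistent$call != "none"))

  # -- differential expression, signatures, enrichment -----------------------
  focal_pops <- config$de_populations %||% unique(samples$population)
  for (pop in focal_pops) {
    de <- nb_wald_de(collapsed, samples, pop)
    de_set <- call_de(de, fdr = thr$de_fdr, min_abs_lfc = thr$de_min_lfc)
    sigs <- call_signatures(de, de_set,
                            min_abs_lfc = thr$signature_min_lfc)
    tag <- sanitize_id(pop)
    emit(paste0("de_", tag, ".tsv"), tsv(de))
    emit(paste0("signatures_", tag, ".tsv"), tsv(sigs))
    if (!is.null(annotation) && nrow(de_set)) {
      enr <- enrich(de_set$gene_id, annotation,
                    universe = rownames(collapsed),
                    alpha = thr$enrich_alpha)
      emit(paste0("enrich_", tag, ".tsv"), tsv(enr))
    }
    say("de", "%s: %d DE, %d signatures", pop, nrow(de_set), nrow(sigs))
  }

  # -- ordination ------------------------------------------------------------
  logc <- log_transform(cpm_by_subgenome(collapsed))
  pca <- pca_samples(logc)
  emit("pca_scores.tsv", function(p) {
    df <- data.frame(sample_id = rownames(pca$scores),
                     pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                                drop = FALSE])
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  emit("pca_variance.tsv", function(p) {
    df <- data.frame(component = seq_along(pca$variance_explained),
                     variance_explained = pca$variance_explained)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  emit("spearman.tsv", function(p) write_counts(spearman_matrix(logc), p))
  say("ordinate", "PC1 explains %.1f%% of variance",
      100 * pca$variance_explained[1L])

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "subbias",
    version = as.character(packageVersion("subbias")),
    seed = config$seed,
    thresholds = thr,
    outputs = as.list(tools::md5sum(sort(created)))
  )
  names(manifest$outputs) <- basename(sort(created))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  created <- c(created, manifest_path)
  say("manifest", "%d outputs", length(manifest$outputs))
  ok <- TRUE
  invisible(manifest)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
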