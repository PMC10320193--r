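# Functional enrichment and ordination summaries.

#' Gene-ontology enrichment of a DE gene set
#'
#' For each GO term (run separately per category), tests the overlap
#' between the DE set and the term's genes with an upper-tail
#' hypergeometric test over the annotation universe, and reports the
#' enrichment score: the proportion of DE genes carrying the term divided
#' by the proportion of universe genes carrying it. P-values are
#' Benjamini-Hochberg-adjusted within category; a term is flagged
#' significant when its adjusted p-value is below `alpha`.
#'
#' Gene-length bias weighting (as used by read-count-aware enrichment
#' tools) is intentionally not applied: the score and test here operate on
#' gene sets only.
#'
#' @param de_genes Character vector of DE gene IDs.
#' @param annotation Annotation list (`lengths`, `go`) as from
#'   [read_annotation()] or [simulate_annotation()].
#' @param universe Gene universe; defaults to all annotated genes. Must
#'   contain `de_genes`.
#' @param alpha Adjusted-p significance cutoff (default 0.1).
#' @return Data frame with one row per term: `term`, `category`,
#'   `n_de_with_term`, `n_de`, `n_genome_with_term`, `n_genome`,
#'   `enrichment_score`, `p`, `padj`, `significant`; ordered by category
#'   then adjusted p.
#' @export
enrich <- function(de_genes, annotation, universe = NULL, alpha = 0.1) {
  if (is.null(universe)) universe <- names(annotation$lengths)
  universe <- unique(universe)
  if (length(de_genes) == 0L) {
    return(data.frame(term = character(0), category = character(0),
                      n_de_with_term = integer(0), n_de = integer(0),
                      n_genome_with_term = integer(0), n_genome = integer(0),
                      enrichment_score = numeric(0), p = numeric(0),
                      padj = numeric(0), significant = logical(0)))
  }
  if (!all(de_genes %in% universe)) {
    stop("DE genes outside the annotation universe", call. = FALSE)
  }
  go <- annotation$go
  go <- go[go$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n_de <- length(unique(de_genes))
  out <- do.call(rbind, lapply(split(go, go$category), function(gc) {
    terms <- split(gc$gene_id, gc$term)
    res <- do.call(rbind, lapply(names(terms), function(tm) {
      term_genes <- unique(terms[[tm]])
      K <- length(term_genes)
      k <- length(intersect(term_genes, de_genes))
      data.frame(
        term = tm,
        category = gc$category[1L],
        n_de_with_term = k,
        n_de = n_de,
        n_genome_with_term = K,
        n_genome = N,
        enrichment_score = (k / n_de) / (K / N),
        p = phyper(k - 1, K, N - K, n_de, lower.tail = FALSE)
      )
    }))
    res$padj <- p.adjust(res$p, method = "BH")
    res[order(res$padj, res$p, res$term), , drop = FALSE]
  }))
  out$significant <- out$padj < alpha
  rownames(out) <- NULL
  out
}

#' Principal component analysis over samples
#'
#' Samples are the observations; genes (rows of the input matrix) are
#' centered. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms.
#'
#' @param m Numeric matrix, genes x samples (typically log-transformed
#'   normalized counts).
#' @param scale. Scale gene rows to unit variance (default `FALSE`).
#' @return List with `scores` (samples x PCs), `loadings` (genes x PCs),
#'   `variance` (per-PC variance), and `variance_explained` (proportions).
#' @export
pca_samples <- function(m, scale. = FALSE) {
  pr <- prcomp(t(m), center = TRUE, scale. = scale.)
  for (k in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[i, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  v <- pr$sdev^2
  list(scores = pr$x, loadings = pr$rotation, variance = v,
       variance_explained = v / sum(v), center = pr$center)
}

#' Pairwise Spearman correlation between samples
#'
#' @param m Numeric matrix, genes x samples.
#' @return Symmetric sample-by-sample correlation matrix with unit diagonal;
#'   ties receive average ranks.
#' @export
spearman_matrix <- function(m) {
  cor(m, method = "spearman")
}
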