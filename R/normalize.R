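# Count transformations applied before any comparison. In allopolyploid
# samples only a fraction of each library maps to a given subgenome, so
# compartment-restricted library normalization is needed before comparing
# haploid (or diploid) expression across samples.

#' Counts-per-million within a subgenome compartment
#'
#' Divides each column by its compartment-restricted total and scales to
#' counts per million, so samples become comparable with respect to the
#' reads assigned to that subgenome.
#'
#' @param counts Count matrix restricted to one compartment.
#' @return Matrix of CPM values; every column sums to 1e6.
#' @export
cpm_by_subgenome <- function(counts) {
  check_count_matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero compartment total for sample '",
         colnames(counts)[totals == 0][1L], "'", call. = FALSE)
  }
  out <- sweep(counts, 2L, totals, "/") * 1e6
  attr(out, "compartment") <- attr(counts, "compartment")
  out
}

#' Normalize by the library size over a shared gene core
#'
#' Restricts the matrix to `shared_genes` and divides each column by the
#' total reads assigned to those genes, scaled to one million. Used when
#' comparing acquired-subgenome expression across populations whose
#' subgenomes retain different gene sets: only the ortholog core common to
#' all of them is a fair basis for the library size.
#'
#' @param counts Count matrix (rows may be a superset of `shared_genes`).
#' @param shared_genes Character vector of row IDs defining the core.
#' @return Normalized matrix restricted to `shared_genes`; columns sum to 1e6.
#' @export
shared_core_normalize <- function(counts, shared_genes) {
  check_count_matrix(counts)
  if (length(shared_genes) == 0L) {
    stop("shared gene set is empty", call. = FALSE)
  }
  missing <- setdiff(shared_genes, rownames(counts))
  if (length(missing)) {
    stop("shared genes absent from matrix: ", missing[1L], " ...",
         call. = FALSE)
  }
  cpm_by_subgenome(counts[shared_genes, , drop = FALSE])
}

#' Collapse primary and acquired counts into whole-genome totals
#'
#' For each primary gene with a 1n ortholog in `map`, collapsed counts are
#' `2n + 1n`; genes without an ortholog keep their 2n counts. The gene
#' universe is the primary genome, which makes allotriploid samples
#' comparable with samples mapped only to the primary reference.
#'
#' @param counts_2n Primary-compartment counts (rows: primary gene IDs).
#' @param counts_1n Acquired-compartment counts (rows: acquired gene IDs).
#'   Columns must match `counts_2n`. Any 1n gene with nonzero counts must
#'   have a primary partner in `map`.
#' @param map Ortholog map data frame (`primary_id`, `acquired_id`).
#' @return Collapsed count matrix over primary genes, tagged `"total"`.
#' @export
collapse_counts <- function(counts_2n, counts_1n, map) {
  check_count_matrix(counts_2n, "counts_2n")
  check_count_matrix(counts_1n, "counts_1n")
  check_ortholog_map(map)
  if (!identical(colnames(counts_2n), colnames(counts_1n))) {
    stop("counts_2n and counts_1n must have identical sample columns",
         call. = FALSE)
  }
  unmapped <- setdiff(rownames(counts_1n), map$acquired_id)
  active <- unmapped[rowSums(counts_1n[unmapped, , drop = FALSE]) > 0]
  if (length(active)) {
    stop("1n gene '", active[1L], "' has counts but no primary partner ",
         "in the ortholog map", call. = FALSE)
  }
  keep <- map$primary_id %in% rownames(counts_2n) &
    map$acquired_id %in% rownames(counts_1n)
  map <- map[keep, , drop = FALSE]
  out <- counts_2n
  out[map$primary_id, ] <- out[map$primary_id, , drop = FALSE] +
    counts_1n[map$acquired_id, , drop = FALSE]
  attr(out, "compartment") <- "total"
  out
}

#' Median-of-ratios size factors
#'
#' The standard library-size estimator for count-based differential
#' expression: per sample, the median across genes of the ratio of the
#' gene's count to its geometric mean over samples, computed over genes with
#' positive counts in every sample.
#'
#' @param counts Count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  lg <- log(counts)
  ok <- rowSums(is.finite(lg)) == ncol(counts)
  if (!any(ok)) {
    stop("no gene has positive counts in every sample; consider a ",
         "pseudo-reference fallback", call. = FALSE)
  }
  geo <- exp(rowMeans(lg[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2L, function(col) median(col / geo))
}

#' Transcripts per million
#'
#' @param counts Count matrix.
#' @param gene_lengths Named vector of gene lengths in bp covering every row.
#' @return TPM matrix; columns sum to 1e6.
#' @export
tpm <- function(counts, gene_lengths) {
  check_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    stop("missing gene length for '", missing[1L], "'", call. = FALSE)
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / len
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("zero total expression for sample '",
         colnames(counts)[denom == 0][1L], "'", call. = FALSE)
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Elementwise log2 with pseudocount
#'
#' @param m Numeric matrix.
#' @param pseudocount Added before taking log2 (default 1, so zeros map to 0).
#' @return `log2(m + pseudocount)`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  log2(m + pseudocount)
}
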