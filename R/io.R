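# Readers/writers for the tabular formats used throughout, plus the
# ortholog-transfer hit filter. All files are plain TSV with a header row,
# except BLAST tabular hit files where `#` comment lines are ignored.

#' Read a gene-by-sample count matrix from TSV
#'
#' The first column holds gene IDs; remaining columns are samples. Counts
#' must be non-negative integers with no missing cells.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param compartment Subgenome compartment the counts belong to:
#'   `"total"`, `"2n"` (primary diploid) or `"1n"` (acquired haploid).
#' @return Integer-valued numeric matrix with gene rownames, sample colnames
#'   and a `"compartment"` attribute.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, compartment = c("total", "2n", "1n")) {
  compartment <- match.arg(compartment)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fill = FALSE,
                    comment.char = "")
  if (ncol(tab) < 2L) stop("count file '", path, "' has no sample columns")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID '", genes[duplicated(genes)][1L], "' in ", path)
  }
  if (anyDuplicated(names(tab)[-1L])) {
    stop("duplicate sample ID in header of ", path)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    loc <- if (length(bad)) {
      paste0("gene '", genes[bad[1L, 1L]], "', sample '",
             names(tab)[-1L][bad[1L, 2L]], "'")
    } else "unknown cell"
    stop("non-numeric or missing count at ", loc, " in ", path)
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative count at gene '", genes[neg[1L, 1L]], "', sample '",
         colnames(m)[neg[1L, 2L]], "' in ", path)
  }
  if (any(m != round(m))) {
    nint <- which(m != round(m), arr.ind = TRUE)
    stop("non-integer count at gene '", genes[nint[1L, 1L]], "', sample '",
         colnames(m)[nint[1L, 2L]], "' in ", path)
  }
  rownames(m) <- genes
  structure(m, compartment = compartment)
}

#' Write a count (or numeric) matrix as TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table from TSV
#'
#' Columns: `sample_id`, `population`, `ploidy_class` (one of `diploid`,
#' `autotriploid`, `allotriploid`) and, for allotriploid samples only,
#' `subgenome_ref` naming the acquired-subgenome reference.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame, validated.
#' @export
read_samples <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fill = FALSE,
                    na.strings = c("NA", ""))
  tab$sample_id <- as.character(tab$sample_id)
  check_sample_table(tab)
  tab
}

#' Write a sample table as TSV
#' @param samples Sample table data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read gene annotation (lengths and GO terms) from TSV
#'
#' One row per (gene, GO term); the `length` column repeats per gene and must
#' be consistent. Genes without GO annotation may appear with empty `term`
#' and `category`.
#'
#' @param path Path to a TSV with columns `gene_id`, `length`, `term`,
#'   `category` (`BP`, `MF` or `CC`).
#' @return List with `lengths` (named numeric, bp) and `go` (data frame of
#'   gene_id/term/category rows).
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fill = FALSE, na.strings = "")
  need <- c("gene_id", "length")
  if (!all(need %in% names(tab))) {
    stop("annotation file needs columns gene_id and length")
  }
  n_lens <- tapply(tab$length, tab$gene_id, function(v) length(unique(v)))
  if (any(n_lens > 1L)) {
    stop("inconsistent length for gene '", names(n_lens)[n_lens > 1L][1L],
         "'")
  }
  first <- !duplicated(tab$gene_id)
  lengths_vec <- setNames(as.numeric(tab$length[first]),
                          tab$gene_id[first])
  if (any(lengths_vec <= 0)) {
    stop("non-positive gene length for '",
         names(lengths_vec)[lengths_vec <= 0][1L], "'")
  }
  go <- tab[!is.na(tab$term) & nzchar(tab$term),
            c("gene_id", "term", "category")]
  bad <- setdiff(unique(go$category), c("BP", "MF", "CC"))
  if (length(bad)) stop("unknown GO category: ", paste(bad, collapse = ", "))
  rownames(go) <- NULL
  list(lengths = lengths_vec, go = go)
}

#' Write gene annotation as TSV
#' @param annotation List as returned by [read_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  go <- annotation$go
  lens <- annotation$lengths
  noGo <- setdiff(names(lens), go$gene_id)
  tab <- rbind(
    data.frame(gene_id = go$gene_id, length = unname(lens[go$gene_id]),
               term = go$term, category = go$category),
    if (length(noGo)) {
      data.frame(gene_id = noGo, length = unname(lens[noGo]),
                 term = NA_character_, category = NA_character_)
    }
  )
  tab <- tab[order(tab$gene_id, tab$term, na.last = TRUE), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read per-population 2n-to-1n ortholog maps from TSV
#'
#' @param path TSV with columns `population`, `primary_id`, `acquired_id`.
#' @return Named list (one element per population) of data frames with
#'   columns `primary_id`, `acquired_id`; each map is injective in both
#'   directions.
#' @export
read_ortholog_map <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fill = FALSE)
  need <- c("population", "primary_id", "acquired_id")
  if (!all(need %in% names(tab))) {
    stop("ortholog map file needs columns ", paste(need, collapse = ", "))
  }
  maps <- split(tab[c("primary_id", "acquired_id")], tab$population)
  maps <- lapply(maps, function(m) { rownames(m) <- NULL; m })
  for (p in names(maps)) check_ortholog_map(maps[[p]], p)
  maps
}

#' Write per-population ortholog maps as TSV
#' @param maps Named list of per-population maps.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ortholog_map <- function(maps, path) {
  tab <- do.call(rbind, lapply(names(maps), function(p) {
    data.frame(population = p, maps[[p]][c("primary_id", "acquired_id")])
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST tabular hit file
#'
#' Accepts BLAST `-outfmt 7`-style files: lines starting with `#` are
#' ignored. Data columns, either named in a header row or positional, are:
#' `query_id`, `target_id`, `percent_identity`, `alignment_length`,
#' `query_length`, `e_value`, `bit_score`. The query length column is
#' required because the transfer filter evaluates query coverage.
#'
#' @param path Path to the hit file.
#' @return Data frame of hits.
#' @seealso [filter_ortholog_hits()]
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "target_id", "percent_identity", "alignment_length",
            "query_length", "e_value", "bit_score")
  tab <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, fill = FALSE)
  if (nrow(tab) == 0L) {
    tab <- as.data.frame(setNames(rep(list(character(0)), 7L), cols))
    tab$percent_identity <- numeric(0)
    return(tab)
  }
  # header row present if the identity column is not numeric
  if (is.na(suppressWarnings(as.numeric(tab[1L, 3L])))) {
    names(tab) <- as.character(unlist(tab[1L, ]))
    tab <- tab[-1L, , drop = FALSE]
    if (!all(cols %in% names(tab))) {
      stop("hit file header must name columns ", paste(cols, collapse = ", "))
    }
    tab <- tab[cols]
  } else {
    if (ncol(tab) < 7L) {
      stop("hit file needs 7 columns (including query_length; ",
           "cannot evaluate coverage without it)")
    }
    tab <- tab[, 1:7]
    names(tab) <- cols
  }
  for (nm in cols[3:7]) tab[[nm]] <- as.numeric(tab[[nm]])
  if (anyNA(tab$query_length)) {
    stop("missing query_length values: cannot evaluate coverage")
  }
  if (any(tab$percent_identity < 0 | tab$percent_identity > 100)) {
    stop("percent_identity outside [0, 100]")
  }
  if (any(tab$alignment_length <= 0) || any(tab$query_length <= 0)) {
    stop("alignment_length and query_length must be positive")
  }
  rownames(tab) <- NULL
  tab
}

#' Filter BLAST hits into an injective ortholog map
#'
#' Implements the ortholog-transfer rule used to carry the primary-genome
#' annotation onto an acquired haploid assembly: a hit survives when its
#' percent identity is at least `min_identity` and its alignment length
#' exceeds `min_query_coverage` of the query length. Among surviving hits
#' each query keeps its single best hit (highest bit score; ties broken by
#' lexicographic target ID), and when two queries claim the same target the
#' higher-scoring query wins (ties broken by lexicographic query ID), so the
#' returned map is injective in both directions.
#'
#' Hit files are expected to come from BLAST runs of the kind
#' `-outfmt 7 -max_target_seqs 3 -evalue 1e-10 -perc_identity 70`; those
#' upstream parameters are provenance, not enforced here.
#'
#' @param hits Data frame as returned by [read_hits()].
#' @param min_identity Minimum percent identity (inclusive). Default 85.
#' @param min_query_coverage Fraction of the query length the alignment must
#'   exceed (strict). Default 0.95.
#' @return Data frame with columns `primary_id` (query) and `acquired_id`
#'   (target), sorted by `primary_id`.
#' @export
filter_ortholog_hits <- function(hits, min_identity = 85,
                                 min_query_coverage = 0.95) {
  stopifnot(is.data.frame(hits))
  empty <- data.frame(primary_id = character(0), acquired_id = character(0))
  if (nrow(hits) == 0L) return(empty)
  keep <- hits$percent_identity >= min_identity &
    hits$alignment_length > min_query_coverage * hits$query_length
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  # best hit per query
  h <- h[order(h$query_id, -h$bit_score, h$target_id), , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  # one query per target
  h <- h[order(h$target_id, -h$bit_score, h$query_id), , drop = FALSE]
  h <- h[!duplicated(h$target_id), , drop = FALSE]
  out <- data.frame(primary_id = h$query_id, acquired_id = h$target_id)
  out <- out[order(out$primary_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
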