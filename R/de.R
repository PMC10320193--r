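# One-vs-rest differential expression on collapsed counts, with the
# downstream DE and transcriptomic-signature thresholds. The engine is a
# deliberately minimal negative-binomial Wald test: median-of-ratios size
# factors, gene-wise method-of-moments dispersion, a two-group NB GLM with
# log link, and a normal Wald p-value -- no dispersion shrinkage toward a
# trend, no fold-change shrinkage, no independent filtering. The package's
# focus is the contrast design and the thresholds applied downstream, and
# the engine's calibration is covered by the simulation tests.

#' Method-of-moments NB dispersion from normalized counts
#'
#' Per group, `alpha = (var - mean) / mean^2`; group estimates are pooled
#' with weights `n_group - 1` and floored.
#' @noRd
mom_dispersion <- function(y_norm, grp, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in levels(grp)) {
    v <- y_norm[grp == g]
    m <- mean(v)
    if (length(v) >= 2L && m > 0) {
      w <- length(v) - 1L
      num <- num + w * (var(v) - m) / m^2
      den <- den + w
    }
  }
  if (den == 0) return(NA_real_)
  max(num / den, floor)
}

#' One-vs-rest negative-binomial Wald differential expression
#'
#' Contrasts expression in `focal` population samples against all other
#' samples pooled. Counts are normalized with median-of-ratios size factors;
#' per gene, a negative-binomial GLM with log link and the gene's
#' method-of-moments dispersion is fit on the two-group design with the log
#' size factors as offset. The Wald statistic is the group coefficient over
#' its standard error, with a two-sided normal p-value and
#' Benjamini-Hochberg adjustment across genes. Genes with all-zero counts
#' (or where the fit fails) are reported with missing statistics and are
#' excluded from the adjustment denominator.
#'
#' @param counts Count matrix (typically collapsed totals so allotriploid
#'   and non-allotriploid samples are comparable).
#' @param samples Sample table covering every column of `counts`.
#' @param focal Name of the focal population.
#' @param min_dispersion Dispersion floor (default 1e-8).
#' @return Data frame of class `"de_result"`: `gene_id`, `base_mean`,
#'   `log2fc` (focal vs rest), `se`, `wald_z`, `p`, `padj`, `dispersion`,
#'   with the contrast label as attribute `"contrast"`.
#' @export
nb_wald_de <- function(counts, samples, focal, min_dispersion = 1e-8) {
  check_count_matrix(counts)
  pop <- samples$population[match(colnames(counts), samples$sample_id)]
  if (anyNA(pop)) {
    stop("sample '", colnames(counts)[is.na(pop)][1L],
         "' missing from the sample table", call. = FALSE)
  }
  if (!focal %in% pop) {
    stop("focal population '", focal, "' has no samples", call. = FALSE)
  }
  grp <- factor(ifelse(pop == focal, "focal", "rest"),
                levels = c("rest", "focal"))
  if (min(table(grp)) < 2L) {
    stop("focal group and rest each need at least 2 samples", call. = FALSE)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  X <- cbind(`(Intercept)` = 1, grpfocal = as.numeric(grp == "focal"))
  off <- log(sf)

  n_genes <- nrow(counts)
  log2fc <- se <- z <- p <- disp <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    a <- mom_dispersion(norm[g, ], grp, min_dispersion)
    if (is.na(a)) next
    disp[g] <- a
    fam <- MASS::negative.binomial(theta = 1 / a)
    f <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(f) || f$rank < 2L || !f$converged) next
    p1 <- seq_len(f$rank)
    covmat <- chol2inv(f$qr$qr[p1, p1, drop = FALSE])
    se_nat <- sqrt(diag(covmat))[match(2L, f$qr$pivot[p1])]
    b <- f$coefficients[["grpfocal"]]
    if (!is.finite(b) || !is.finite(se_nat) || se_nat <= 0) next
    log2fc[g] <- b / log(2)
    se[g] <- se_nat / log(2)
    z[g] <- b / se_nat
    p[g] <- 2 * pnorm(-abs(z[g]))
  }
  padj <- rep(NA_real_, n_genes)
  ok <- !is.na(p)
  padj[ok] <- p.adjust(p[ok], method = "BH")
  out <- data.frame(
    gene_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se = se,
    wald_z = z,
    p = p,
    padj = padj,
    dispersion = disp,
    row.names = NULL
  )
  attr(out, "contrast") <- paste(focal, "vs rest")
  class(out) <- c("de_result", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' A gene is DE when its adjusted p-value is below `fdr` and its absolute
#' log2 fold-change exceeds `min_abs_lfc` (defaults 0.05 and 1, i.e. at
#' least 2-fold up- or downregulation).
#'
#' @param de A `"de_result"` table from [nb_wald_de()].
#' @param fdr Adjusted-p cutoff (strictly below).
#' @param min_abs_lfc Absolute log2 fold-change cutoff (strictly above).
#' @return Subset of `de` with an added `direction` (`up`/`down`) column.
#' @export
call_de <- function(de, fdr = 0.05, min_abs_lfc = 1) {
  stopifnot(is.data.frame(de),
            all(c("gene_id", "log2fc", "padj") %in% names(de)))
  keep <- !is.na(de$padj) & de$padj < fdr & abs(de$log2fc) > min_abs_lfc
  out <- as.data.frame(de)[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(de, "contrast")
  out
}

#' Call population-specific transcriptomic signatures
#'
#' A signature is a gene strongly and specifically over- or under-expressed
#' in one population: among the DE genes of a direction, it must have an
#' absolute log2 fold-change above `min_abs_lfc` (default 1.6, at least
#' 3-fold) and an adjusted p-value strictly below the median adjusted
#' p-value of same-direction DE genes (the "top half"; ties at the median
#' are excluded).
#'
#' @param de A `"de_result"` table.
#' @param de_set DE calls from [call_de()] on the same contrast; computed
#'   with default thresholds when omitted.
#' @param min_abs_lfc Signature fold-change cutoff (default 1.6).
#' @return Data frame of signature genes with `direction`, carrying the
#'   per-direction adjusted-p cutoffs as attribute `"padj_cutoffs"`.
#' @export
call_signatures <- function(de, de_set = NULL, min_abs_lfc = 1.6) {
  if (is.null(de_set)) de_set <- call_de(de)
  stopifnot(all(c("gene_id", "log2fc", "padj", "direction") %in%
                  names(de_set)))
  cutoffs <- c(up = NA_real_, down = NA_real_)
  parts <- lapply(c("up", "down"), function(d) {
    dd <- de_set[de_set$direction == d, , drop = FALSE]
    if (nrow(dd) == 0L) return(dd)
    med <- median(dd$padj)
    cutoffs[[d]] <<- med
    dd[abs(dd$log2fc) > min_abs_lfc & dd$padj < med, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "padj_cutoffs") <- cutoffs
  attr(out, "contrast") <- attr(de_set, "contrast")
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value; the standard group comparison for expression levels
#' between sets of populations.
#'
#' @param a,b Numeric vectors of per-sample expression values.
#' @return List with `t`, `p`, `df`.
#' @export
welch_t_test <- function(a, b) {
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
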