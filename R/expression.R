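#' Reads-per-million normalization
#'
#' @param counts numeric matrix, miRNAs x samples.
#' @return matrix of RPM values (`count / sample total * 1e6`).
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Average replicate columns by group
#'
#' Replicate samples of the same tissue (or stage) are averaged after RPM
#' normalization, giving one column per group.
#'
#' @param mat numeric matrix, miRNAs x samples.
#' @param groups character vector of group labels, one per column.
#' @return matrix with one column per group (columns in first-appearance
#'   order).
#' @export
average_replicates <- function(mat, groups) {
  stopifnot(ncol(mat) == length(groups))
  ug <- unique(groups)
  out <- vapply(ug, function(g) {
    rowMeans(mat[, groups == g, drop = FALSE])
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), ug))
  out
}

#' Top-k most abundant miRNAs per tissue
#'
#' @param mat RPM matrix, miRNAs x tissues.
#' @param k list length per tissue.
#' @return list with `per_tissue` (named list of id vectors, descending RPM,
#'   ties broken by id) and `union` (sorted union of all lists).
#' @export
top_k <- function(mat, k = 15L) {
  stopifnot(nrow(mat) >= k)
  per <- lapply(seq_len(ncol(mat)), function(j) {
    ord <- order(-mat[, j], rownames(mat))
    rownames(mat)[ord][seq_len(k)]
  })
  names(per) <- colnames(mat)
  list(per_tissue = per, union = sort(unique(unlist(per))))
}

#' Classify miRNAs as ubiquitous, tissue-enriched, or neither
#'
#' A miRNA is ubiquitous when its maximum/minimum tissue RPM ratio is at most
#' `ubiquitous_fold` (requiring expression in every tissue). It is enriched
#' in a tissue set S when every RPM inside S exceeds `enriched_fold` times
#' the mean RPM outside S (which must be positive: a fold over a zero
#' baseline is undefined); S is grown greedily from the highest-expressing
#' tissue and the smallest qualifying S is reported, allowing enrichment in
#' one or a few tissues (e.g. muscle plus heart).
#'
#' @param mat RPM matrix, miRNAs x tissues (>= 2 tissues).
#' @param ubiquitous_fold maximum max/min ratio for ubiquitous expression.
#' @param enriched_fold minimum fold over the mean of the other tissues.
#' @return data.frame with `id`, `label` (`"ubiquitous"`, `"enriched"`,
#'   `"neither"`) and `tissues` (comma-joined enriched set, `""` otherwise).
#' @export
classify_expression <- function(mat, ubiquitous_fold = 3,
                                enriched_fold = 10) {
  stopifnot(ncol(mat) >= 2L)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    if (min(x) > 0 && max(x) / min(x) <= ubiquitous_fold) {
      return(list(label = "ubiquitous", tissues = ""))
    }
    ord <- order(-x, colnames(mat))
    for (kk in seq_len(ncol(mat) - 1L)) {
      inside <- ord[seq_len(kk)]
      outside <- ord[-seq_len(kk)]
      if (mean(x[outside]) > 0 &&
          all(x[inside] > enriched_fold * mean(x[outside]))) {
        return(list(label = "enriched",
                    tissues = paste(sort(colnames(mat)[inside]),
                                    collapse = ",")))
      }
    }
    list(label = "neither", tissues = "")
  })
  data.frame(id = rownames(mat),
             label = vapply(res, `[[`, character(1), "label"),
             tissues = vapply(res, `[[`, character(1), "tissues"),
             stringsAsFactors = FALSE)
}

#' Per-stage miRNA diversity and abundance proportions
#'
#' Diversity is the number of distinct miRNAs detected (raw count at least
#' `detect_min`) in each stage; proportions are each miRNA's share of the
#' stage total, with optional family-level sums.
#'
#' @param counts raw count matrix, miRNAs x stages.
#' @param detect_min minimum raw count to call a miRNA detected.
#' @param families optional named list mapping family name to member ids.
#' @return list with `diversity` (named integer vector per stage),
#'   `proportions` (matrix summing to 1 per stage), and `family_proportions`
#'   (matrix, families x stages; `NULL` when no families given).
#' @export
diversity_and_proportions <- function(counts, detect_min = 1L,
                                      families = NULL) {
  counts <- as.matrix(counts)
  diversity <- colSums(counts >= detect_min)
  totals <- colSums(counts)
  props <- sweep(counts, 2L, ifelse(totals > 0, totals, 1), "/")
  fam <- NULL
  if (!is.null(families)) {
    fam <- t(vapply(families, function(members) {
      colSums(props[intersect(members, rownames(props)), , drop = FALSE])
    }, numeric(ncol(props))))
    rownames(fam) <- names(families)
  }
  list(diversity = diversity, proportions = props,
       family_proportions = fam)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Cq_target - mean(Cq of the two reference miRNAs)`;
#' `ddCt` is the mean dCt in the focal tissue minus the mean dCt over all
#' other samples pooled; the fold enrichment is `2^(-ddCt)`. Statistical
#' support is a two-sample t-test on the dCt values with Bonferroni
#' adjustment by `n_tests` (the number of miRNA/tissue contrasts in the
#' batch).
#'
#' @param qpcr a [simulate_qpcr()]-shaped list (`cq` matrix, `tissue`
#'   labels, `reference_ids`), or any list with those elements.
#' @param target row name of the miRNA tested.
#' @param focal_tissue tissue whose enrichment is quantified.
#' @param n_tests number of tests in the batch (Bonferroni denominator).
#' @param var_equal use the pooled-variance t-test.
#' @return list of class `enrichment_result`: `target`, `tissue`, `ddct`,
#'   `fold` (`2^(-ddct)`), `fold_rounded`, `p_value`, `p_adjusted`,
#'   `significant` (adjusted p <= 0.05; `NA` when either group has fewer
#'   than two samples).
#' @export
ddct <- function(qpcr, target, focal_tissue, n_tests = 1L,
                 var_equal = TRUE) {
  cq <- qpcr$cq
  stopifnot(target %in% rownames(cq),
            all(qpcr$reference_ids %in% rownames(cq)),
            focal_tissue %in% qpcr$tissue)
  refmean <- colMeans(cq[qpcr$reference_ids, , drop = FALSE])
  dct <- cq[target, ] - refmean
  focal <- qpcr$tissue[colnames(cq)] == focal_tissue
  stopifnot(any(focal), any(!focal))
  dd <- mean(dct[focal]) - mean(dct[!focal])
  if (sum(focal) >= 2L && sum(!focal) >= 2L) {
    p <- tryCatch(
      t.test(dct[focal], dct[!focal], var.equal = var_equal)$p.value,
      error = function(e) if (dd == 0) 1 else 0)  # degenerate: zero variance
    p_adj <- min(1, p * n_tests)
    signif <- p_adj <= 0.05
  } else {
    p <- NA_real_; p_adj <- NA_real_; signif <- NA
  }
  structure(list(target = target, tissue = focal_tissue, ddct = dd,
                 fold = 2^(-dd), fold_rounded = round(2^(-dd)),
                 p_value = p, p_adjusted = p_adj, significant = signif),
            class = "enrichment_result")
}

#' Fold enrichment implied by a delta-delta-Ct value
#'
#' @param ddct numeric delta-delta-Ct value(s).
#' @return `2^(-ddct)`.
#' @export
ddct_fold <- function(ddct) 2^(-ddct)
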