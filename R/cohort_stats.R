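# Fingerprint matrices, hierarchical clustering, cohort comparisons and
# zero-codon cohort tables.
#
# A cohort_matrix is the genes (or pooled cohorts) x 59-sense-codon table of
# CU values that feeds the heat-map style clustering. Cells of absent
# families carry value 0 and mask TRUE: the lowest-value color on a heat
# map, but recoverable for re-analysis with other imputations.

#' Build a gene-by-codon CU matrix
#'
#' Assembles CU profiles into a matrix with rows in decreasing exon-count
#' order (the convention used for every fingerprint display; ties broken by
#' gene id) or in input order, and columns in the canonical codon order.
#' Absent-family cells are stored as 0 with a parallel mask.
#'
#' @param profiles list of `cu_profile` objects with unique `gene_id`s.
#' @param exon_counts named integer vector (`gene_id` -> exon count);
#'   required for `ordering = "exon_count"`.
#' @param ordering `"exon_count"` (default) or `"as_is"`.
#' @param code a `genetic_code`.
#' @return an object of class `cohort_matrix`: list with `values` (numeric
#'   matrix), `mask` (logical matrix, TRUE where the family is absent),
#'   `row_ids`, `col_ids`.
#' @export
build_matrix <- function(profiles, exon_counts = NULL,
                         ordering = c("exon_count", "as_is"),
                         code = build_genetic_code()) {
  ordering <- match.arg(ordering)
  ids <- unname(vapply(profiles, `[[`, character(1), "gene_id"))
  if (anyDuplicated(ids)) {
    stop("duplicate row labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (ordering == "exon_count") {
    if (is.null(exon_counts)) {
      stop("exon_counts required for exon_count ordering", call. = FALSE)
    }
    missing_ids <- setdiff(ids, names(exon_counts))
    if (length(missing_ids) > 0) {
      stop("no exon count for: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    ord <- order(-as.integer(exon_counts[ids]), ids)
    profiles <- profiles[ord]
    ids <- ids[ord]
  }
  values <- do.call(rbind, lapply(profiles, function(p)
    p$cu[code$sense_codons]))
  mask <- is.na(values)
  values[mask] <- 0
  dimnames(values) <- dimnames(mask) <- list(ids, code$sense_codons)
  structure(list(values = values, mask = mask,
                 row_ids = ids, col_ids = code$sense_codons),
            class = "cohort_matrix")
}

#' Pairwise Euclidean distances over a matrix axis
#'
#' @param mat a `cohort_matrix`.
#' @param axis `"rows"` (genes) or `"cols"` (codons).
#' @return a `dist` object. Masked cells contribute their stored value 0.
#' @export
euclidean_distance <- function(mat, axis = c("rows", "cols")) {
  stopifnot(inherits(mat, "cohort_matrix"))
  axis <- match.arg(axis)
  v <- if (axis == "rows") mat$values else t(mat$values)
  if (nrow(v) < 2L) stop("need at least 2 items to compute distances",
                         call. = FALSE)
  stats::dist(v, method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerative hierarchical clustering where the distance between two
#' clusters is the maximum pairwise member distance (`hclust` "complete"
#' method, which guarantees monotone merge heights).
#'
#' @param d a `dist` object, e.g. from [euclidean_distance()].
#' @param axis label recorded in the result (`"rows"` or `"cols"`).
#' @return an object of class `cluster_result`: list with `hclust` (the fit),
#'   `merges` (data.frame `a`, `b`, `height` in `hclust` merge encoding),
#'   `leaf_order` (left-to-right dendrogram labels) and `axis`.
#' @examples
#' d <- stats::dist(c(a = 0, b = 1, c = 10))
#' complete_linkage(d)$merges$height  # 1, 10
#' @export
complete_linkage <- function(d, axis = "rows") {
  stopifnot(inherits(d, "dist"))
  hc <- stats::hclust(d, method = "complete")
  structure(
    list(hclust = hc,
         merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                             height = hc$height),
         leaf_order = hc$labels[hc$order],
         axis = axis),
    class = "cluster_result")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param cr a `cluster_result`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(cr, path = NULL) {
  stopifnot(inherits(cr, "cluster_result"))
  phy <- ape::as.phylo(cr$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Cut a row clustering into k groups
#'
#' @param cr a `cluster_result`.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(cr, k) {
  stopifnot(inherits(cr, "cluster_result"))
  stats::cutree(cr$hclust, k = k)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param a,b non-empty numeric vectors of CU values (or any frequencies).
#' @return the two-tailed p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1 (exact)
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- (length(a) + length(b) <= 12L) && !anyDuplicated(c(a, b))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' Spearman rank correlation of two CU vectors
#'
#' Rho is computed on midranks; the two-sided p-value uses the
#' t-approximation. Zero-variance input yields `NA` with a warning (rho is
#' undefined there).
#'
#' @param x,y paired numeric vectors (same codon order), length >= 3.
#' @return list with `rho` and `p_value`.
#' @examples
#' spearman_cu(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_cu <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rho undefined: fewer than 3 complete pairs or zero variance",
            call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value))
}

#' Per-codon differential usage between two groups of genes
#'
#' For every sense codon, compares the CU values of the rows in group `a`
#' against group `b` with the two-sided rank-sum test. Masked (absent
#' family) cells are dropped from the samples; codons with fewer than one
#' observation on either side get `NA`.
#'
#' @param mat a `cohort_matrix`.
#' @param groups named character/factor vector assigning each `row_id` to a
#'   group.
#' @param a,b the two group labels to compare.
#' @param comparison label stored in the output.
#' @param code a `genetic_code`.
#' @return data.frame with `codon`, `amino_acid`, `comparison`, `p_value`,
#'   `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
differential_codon_usage <- function(mat, groups, a, b,
                                     comparison = paste(a, "vs", b),
                                     code = build_genetic_code()) {
  stopifnot(inherits(mat, "cohort_matrix"))
  groups <- stats::setNames(as.character(groups), names(groups))
  missing_rows <- setdiff(mat$row_ids, names(groups))
  if (length(missing_rows) > 0) {
    stop("no group for row(s): ", paste(missing_rows, collapse = ", "),
         call. = FALSE)
  }
  g <- groups[mat$row_ids]
  rows_a <- which(g == a)
  rows_b <- which(g == b)
  if (length(rows_a) == 0 || length(rows_b) == 0) {
    stop("group '", if (length(rows_a) == 0) a else b, "' has no rows",
         call. = FALSE)
  }
  res <- lapply(mat$col_ids, function(cod) {
    va <- mat$values[rows_a, cod][!mat$mask[rows_a, cod]]
    vb <- mat$values[rows_b, cod][!mat$mask[rows_b, cod]]
    p <- if (length(va) > 0 && length(vb) > 0) wilcoxon_rank_sum(va, vb) else NA_real_
    data.frame(codon = cod,
               amino_acid = unname(code$mapping[cod]),
               comparison = comparison,
               p_value = p,
               median_a = if (length(va)) stats::median(va) else NA_real_,
               median_b = if (length(vb)) stats::median(vb) else NA_real_,
               n_a = length(va), n_b = length(vb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Prioritize differentially used codons
#'
#' Returns the codons with p below `alpha`, ordered by ascending p. The
#' default uses raw p-values (significance threshold p < 0.05, no
#' multiple-testing correction); Benjamini-Hochberg adjustment over the
#' tested codons is available since 59 simultaneous tests invite it.
#'
#' @param results data.frame from [differential_codon_usage()] (columns
#'   `codon` and `p_value`).
#' @param alpha significance level in (0, 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return character vector of codons, most significant first.
#' @export
prioritize_codons <- function(results, alpha = 0.05,
                              adjust = c("none", "BH")) {
  stopifnot(alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < alpha
  results$codon[keep][order(p[keep])]
}

#' Zero-codon counts per cohort cell
#'
#' Tabulates zero-codons for every (species, tissue, cohort) cell of a gene
#' set. Two aggregations are reported: the sum over the cell's genes of each
#' gene's zero-codon count (`per_gene_sum`, the default headline number) and
#' the number of codons unused by the entire pooled cell (`pooled`).
#'
#' @param records a `cds_set`.
#' @param code a `genetic_code`.
#' @param policy zero-codon policy, see [zero_codons()].
#' @return data.frame with `species`, `tissue`, `cohort`, `n_genes`,
#'   `per_gene_sum`, `pooled`.
#' @export
zero_codon_table <- function(records, code = build_genetic_code(),
                             policy = "family_present") {
  stopifnot(inherits(records, "cds_set"))
  if (nrow(records) == 0L) {
    warning("empty gene set", call. = FALSE)
    return(data.frame(species = character(0), tissue = character(0),
                      cohort = character(0), n_genes = integer(0),
                      per_gene_sum = integer(0), pooled = integer(0)))
  }
  key <- interaction(records$species, records$tissue, records$cohort,
                     drop = TRUE, sep = "\r")
  cells <- lapply(levels(key), function(lv) {
    idx <- which(key == lv)
    counts <- count_cohort(new_cds_set(records[idx, , drop = FALSE]), code)
    per_gene <- sum(vapply(counts, function(cc)
      length(zero_codons(cc, code, policy)$zero_codons), integer(1)))
    pooled <- length(zero_codons(pool_cohort_counts(counts), code,
                                 policy)$zero_codons)
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    data.frame(species = parts[1], tissue = parts[2], cohort = parts[3],
               n_genes = length(idx),
               per_gene_sum = per_gene, pooled = pooled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
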