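profiles_from <- function(seqs, ids) {
  lapply(seq_along(seqs), function(i)
    cu_values(count_codons(seqs[i], ids[i]), CODE))
}

test_that("matrix rows follow decreasing exon count with masked families", {
  seqs <- rep("AUGCUGCUGUAA", 3)
  profs <- profiles_from(seqs, c("A", "B", "C"))
  mat <- build_matrix(profs, c(A = 79, B = 10, C = 50), code = CODE)
  expect_identical(mat$row_ids, c("A", "C", "B"))
  # ties broken by gene id
  mat2 <- build_matrix(profs, c(A = 10, B = 10, C = 50), code = CODE)
  expect_identical(mat2$row_ids, c("C", "A", "B"))
  single <- build_matrix(profs[1], c(A = 1), code = CODE)
  expect_equal(dim(single$values), c(1, 59))
  # masked cells: absent-family slots, stored as 0
  prof1 <- cu_values(count_codons("AUGCUGCUGUAA"), CODE)
  absent_slots <- sum(!prof1$family_present[sense_aa_vec])
  expect_equal(sum(single$mask), absent_slots)
  expect_true(all(single$values[single$mask] == 0))
  expect_error(build_matrix(profiles_from(seqs[1:2], c("A", "A")),
                            c(A = 1), code = CODE), "duplicate")
  expect_error(build_matrix(profs, NULL), "exon_counts")
})

test_that("euclidean distances match hand values and a naive oracle", {
  m <- structure(list(values = rbind(a = c(0, 0), b = c(3, 4)),
                      mask = matrix(FALSE, 2, 2),
                      row_ids = c("a", "b"), col_ids = c("x", "y")),
                 class = "cohort_matrix")
  expect_equal(as.numeric(euclidean_distance(m, "rows")), 5)
  m$values[2, ] <- m$values[1, ]
  expect_equal(as.numeric(euclidean_distance(m, "rows")), 0)
  set.seed(3)
  for (rep in 1:10) {
    v <- matrix(runif(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), paste0("c", 1:12)))
    cm <- structure(list(values = v, mask = matrix(FALSE, 8, 12),
                         row_ids = rownames(v), col_ids = colnames(v)),
                    class = "cohort_matrix")
    d <- as.matrix(euclidean_distance(cm, "rows"))
    for (i in 1:8) for (j in 1:8) {
      expect_equal(d[i, j], sqrt(sum((v[i, ] - v[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("complete linkage reproduces worked merges and is order invariant", {
  d <- stats::dist(matrix(c(0, 1, 10), ncol = 1,
                          dimnames = list(c("a", "b", "c"), NULL)))
  cr <- complete_linkage(d)
  expect_equal(cr$merges$height, c(1, 10))
  expect_equal(nrow(cr$merges), 2)  # n - 1 merges
  expect_true(all(diff(cr$merges$height) >= 0))
  # identical items merge at height 0
  same <- stats::dist(matrix(rep(1, 4), ncol = 1))
  expect_equal(complete_linkage(same)$merges$height, c(0, 0, 0))
  # height multiset invariant under row permutation
  set.seed(8)
  x <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(paste0("g", 1:7), NULL))
  h1 <- sort(complete_linkage(stats::dist(x))$merges$height)
  perm <- sample(7)
  h2 <- sort(complete_linkage(stats::dist(x[perm, ]))$merges$height)
  expect_equal(h1, h2, tolerance = 1e-12)
  # newick export round-trips through ape with the right leaves
  phy <- ape::read.tree(text = as_newick(cr))
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})

test_that("rank-sum p-values match exact enumeration and are symmetric", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  set.seed(12)
  for (rep in 1:20) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- sample(seq_len(100), na)  # distinct values, no ties
    b <- setdiff(sample(seq_len(100), na + nb), a)[seq_len(nb)]
    expect_equal(wilcoxon_rank_sum(a, b), oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a),
                 tolerance = 1e-12)
  }
  # large-sample route is also symmetric
  set.seed(13)
  a <- rnorm(30)
  b <- rnorm(25, 0.5)
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a))
})

test_that("spearman correlation handles monotone maps and degenerate input", {
  x <- c(0.2, 0.5, 0.1, 0.9, 0.7)
  expect_equal(spearman_cu(x, x)$rho, 1)
  expect_equal(spearman_cu(x, -x)$rho, -1)
  res <- spearman_cu(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$rho, 0.8)
  # invariance under strictly monotone transforms
  expect_equal(spearman_cu(exp(x), x^3)$rho, spearman_cu(x, x)$rho)
  expect_warning(res0 <- spearman_cu(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(res0$rho))
})

test_that("codon prioritization thresholds and orders by p", {
  res <- data.frame(codon = c("CGU", "CCA"), p_value = c(0.01, 0.2))
  expect_identical(prioritize_codons(res), "CGU")
  res_hi <- data.frame(codon = c("CGU", "CCA"), p_value = c(0.6, 0.2))
  expect_length(prioritize_codons(res_hi), 0)
  # BH step-up: thresholds 0.0167, 0.0333, 0.05 retain the first two
  res_bh <- data.frame(codon = c("a", "b", "c"),
                       p_value = c(0.01, 0.02, 0.9))
  expect_identical(prioritize_codons(res_bh, adjust = "BH"), c("a", "b"))
  expect_identical(prioritize_codons(res_bh, adjust = "none"), c("a", "b"))
  # ordering is by ascending p
  res_ord <- data.frame(codon = c("x", "y"), p_value = c(0.03, 0.001))
  expect_identical(prioritize_codons(res_ord), c("y", "x"))
})

test_that("differential usage drops masked cells and labels comparisons", {
  trial <- fingerprint_trial(501, n_genes = 8, len = 200)
  grp <- stats::setNames(trial$recs$cohort, trial$recs$gene_id)
  res <- differential_codon_usage(trial$mat, grp, "DC", "NDC", code = CODE)
  expect_equal(nrow(res), 59)
  expect_true(all(res$n_a <= 8 & res$n_b <= 8))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_error(differential_codon_usage(trial$mat, grp, "DC", "nope"),
               "has no rows")
})

test_that("zero-codon cohort table sums per-gene counts and pools", {
  # two genes: 5 and 5 zero-codons by construction (Leu/Val families with
  # one used codon each)
  cds <- make_cds_set(c("g1", "g2"),
                      c("ATGCTGCTGTAA", "ATGGTGGTCTAA"),
                      tissue = "muscle", cohort = "DC")
  tab <- zero_codon_table(cds, CODE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_genes, 2)
  # g1: 5 unused Leu codons; g2: Val family 2 used + 2 unused -> 2
  expect_equal(tab$per_gene_sum, 5 + 2)
  # pooled: Leu pools to CUG+GUx? no - Val is its own family; pooled zeros:
  # Leu 5 (only CUG used) + Val 2 (GUG, GUC used)
  expect_equal(tab$pooled, 5 + 2)
  # generator ground truth: injected zero-codons are recovered exactly
  spec <- cohort_spec(n_genes = 4, length_range = c(300, 300),
                      injected_zero_codons = c("CUA", "GCG"),
                      tissue = "skin", cohort = "NDC", seed = 77)
  gen <- generate_cohort(spec)
  tab2 <- zero_codon_table(gen$records, CODE)
  counts <- count_cohort(gen$records, CODE)
  manual <- sum(vapply(counts, function(cc)
    length(zero_codons(cc, CODE)$zero_codons), integer(1)))
  expect_equal(tab2$per_gene_sum, manual)
  expect_gte(tab2$per_gene_sum, 4 * 2)  # at least the injected ones
  expect_warning(empty <- zero_codon_table(cds[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})
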