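test_that("codon counting matches hand counts and keeps the stop separate", {
  cc <- count_codons("AUGCUGCUGUAA")
  expect_equal(unname(cc$counts[c("AUG", "CUG", "UAA")]), c(1, 2, 1))
  expect_equal(sum(cc$counts), 4)
  cc2 <- count_codons("AUGUAA")
  expect_equal(unname(cc2$counts[c("AUG", "UAA")]), c(1, 1))
  expect_equal(sum(cc2$counts), 2)
  expect_error(count_codons("AUGC"), "multiple of 3")
})

test_that("CU values normalize within each present family", {
  p <- cu_values(count_codons("AUGCUGCUGUAA"), CODE)
  expect_equal(unname(p$cu["CUG"]), 1)
  expect_equal(unname(p$cu[c("CUU", "CUC", "CUA", "UUA", "UUG")]),
               rep(0, 5))
  expect_true(p$family_present[["L"]])
  expect_false(any(p$family_present[setdiff(CODE$considered, "L")]))
  expect_true(all(is.na(p$cu[setdiff(names(p$cu),
                                     CODE$families$L$codons)])))
  expect_identical(p$terminal_stop, "UAA")

  # a gene using every sense codon once: cu = 1/degeneracy everywhere
  seq_all <- paste(c("AUG", CODE$sense_codons, "UAA"), collapse = "")
  p_all <- cu_values(count_codons(seq_all), CODE)
  expect_equal(p_all$cu, 1 / sense_degeneracy_vec, tolerance = 1e-15)
  # per-family normalization identity on random counts
  set.seed(5)
  for (rep in 1:20) {
    p_r <- cu_values(count_codons(rand_cds(200, names(CODE$mapping))), CODE)
    sums <- tapply(p_r$cu, sense_aa_vec, sum)
    expect_true(all(abs(sums[names(which(p_r$family_present))] - 1) < 1e-12))
  }
})

test_that("stop codon usage is a frequency over genes with a terminal stop", {
  cds <- make_cds_set(c("a", "b", "c"),
                      c("ATGCTGTAA", "ATGCTGTAA", "ATGCTGTGA"))
  expect_equal(stop_codon_usage(cds),
               c(UAA = 2 / 3, UAG = 0, UGA = 1 / 3))
  one <- make_cds_set("a", "ATGCTGTAG")
  expect_equal(stop_codon_usage(one), c(UAA = 0, UAG = 1, UGA = 0))
  # genes without terminal stop leave the denominator
  mix <- make_cds_set(c("a", "b"), c("ATGCTGTAA", "ATGCTGCTG"))
  expect_equal(stop_codon_usage(mix), c(UAA = 1, UAG = 0, UGA = 0))
  nostop <- make_cds_set("a", "ATGCTG")
  expect_warning(res <- stop_codon_usage(nostop), "no gene")
  expect_length(res, 0)
})

test_that("zero-codon detection honors both policies", {
  cc <- count_codons("AUGCUGCUGUAA")
  zc <- zero_codons(cc, CODE)
  expect_setequal(zc$zero_codons, c("CUU", "CUC", "CUA", "UUA", "UUG"))
  zc_raw <- zero_codons(cc, CODE, policy = "raw")
  expect_length(zc_raw$zero_codons, 58)  # 59 sense codons, only CUG used
  seq_all <- paste(c("AUG", CODE$sense_codons, "UAA"), collapse = "")
  expect_length(zero_codons(count_codons(seq_all), CODE)$zero_codons, 0)
  expect_length(zero_codons(count_codons(seq_all), CODE,
                            policy = "raw")$zero_codons, 0)
})

test_that("zero-codon counts are monotone under sequence extension", {
  set.seed(42)
  codons64 <- names(CODE$mapping)
  for (rep in 1:25) {
    base <- rand_cds(sample(5:50, 1), codons64)
    ext_codons <- sample(codons64, sample(1:20, 1), replace = TRUE)
    ext <- paste0(base, paste(ext_codons, collapse = ""))
    n_raw <- function(s) length(zero_codons(count_codons(s), CODE,
                                            policy = "raw")$zero_codons)
    expect_lte(n_raw(ext), n_raw(base))
    # family_present counts are monotone when the extension only uses
    # families already present (a new family makes its unused codons count)
    present <- names(which(cu_values(count_codons(base),
                                     CODE)$family_present))
    from_present <- unlist(lapply(CODE$families[present], `[[`, "codons"))
    if (length(from_present) > 0) {
      ext2 <- paste0(base, paste(sample(from_present, 10, replace = TRUE),
                                 collapse = ""))
      n_fp <- function(s) length(zero_codons(count_codons(s),
                                             CODE)$zero_codons)
      expect_lte(n_fp(ext2), n_fp(base))
    }
  }
})

test_that("extreme-bias cutoff is half the uniform expectation by default", {
  # Ser family split 9:1 over AGC/AGU; the four unused Ser codons sit below
  # t(6) = 1/12, the 0.1 value does not
  seq <- paste(c("AUG", rep("AGC", 9), "AGU", "UAA"), collapse = "")
  prof <- cu_values(count_codons(seq), CODE)
  expect_setequal(extremely_biased_codons(prof, CODE),
                  c("UCA", "UCC", "UCG", "UCU"))
  # uniform profile: 1/d >= 0.5/d, nothing flagged
  seq_all <- paste(c("AUG", CODE$sense_codons, "UAA"), collapse = "")
  expect_length(
    extremely_biased_codons(cu_values(count_codons(seq_all), CODE), CODE), 0)
  # absent families are never flagged
  expect_false(any(extremely_biased_codons(prof, CODE) %in%
                     CODE$families$P$codons))
  # per-degeneracy override: raising t(6) above 0.1 flags AGU too
  eb <- extremely_biased_codons(prof, CODE, cutoff = c("6" = 0.15))
  expect_true("AGU" %in% eb)
})

test_that("pooled counts conserve totals and mix CU values by weight", {
  a <- count_codons(strrep("CUG", 2), "a")
  b <- count_codons(strrep("CUG", 3), "b")
  pooled <- pool_cohort_counts(list(a, b), "ab")
  expect_equal(unname(pooled$counts["CUG"]), 5)
  expect_identical(pool_cohort_counts(list(a), "a")$counts, a$counts)
  expect_error(pool_cohort_counts(list()), "length")

  set.seed(9)
  codons64 <- names(CODE$mapping)
  seqs <- replicate(6, rand_cds(sample(30:120, 1), codons64))
  counts <- lapply(seq_along(seqs), function(i)
    count_codons(seqs[i], paste0("g", i)))
  pooled <- pool_cohort_counts(counts, "pool")
  # conservation: pooling equals counting the concatenation
  concat <- count_codons(paste(seqs, collapse = ""), "concat")
  expect_identical(pooled$counts, concat$counts)
  # pooled CU equals the family-count-weighted mixture of per-gene CU
  pooled_cu <- cu_values(pooled, CODE)$cu
  for (cod in sample(CODE$sense_codons, 15)) {
    fam <- CODE$families[[unname(CODE$mapping[cod])]]$codons
    fam_tot <- vapply(counts, function(cc) sum(cc$counts[fam]), numeric(1))
    if (sum(fam_tot) == 0) next
    per_gene <- vapply(counts, function(cc)
      unname(cu_values(cc, CODE)$cu[cod]), numeric(1))
    mix <- sum(fam_tot * per_gene, na.rm = TRUE) / sum(fam_tot)
    expect_equal(unname(pooled_cu[cod]), mix, tolerance = 1e-12)
  }
})

test_that("the long-format CU table carries counts, CU and flags per gene", {
  counts <- list(count_codons("AUGCUGCUGUAA", "g1"))
  tab <- cu_long_table(counts, CODE)
  expect_equal(nrow(tab), 59)
  row <- tab[tab$codon == "CUG", ]
  expect_equal(row$count, 2)
  expect_equal(row$cu, 1)
  expect_false(row$zero_codon)
  expect_true(all(tab$zero_codon[tab$codon %in%
                                   c("CUU", "CUC", "CUA", "UUA", "UUG")]))
})
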