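# Independent oracles used to validate the implementation routes.

# brute-force triplet scan: walk the sequence index by index, incrementing a
# 64-bin table (independent of count_codons' vectorized substring route)
oracle_count <- function(seq, codons) {
  counts <- stats::setNames(integer(length(codons)), codons)
  excluded <- 0L
  i <- 1L
  while (i < nchar(seq)) {
    tri <- substr(seq, i, i + 2L)
    if (tri %in% codons) {
      counts[tri] <- counts[tri] + 1L
    } else {
      excluded <- excluded + 1L
    }
    i <- i + 3L
  }
  list(counts = counts, excluded = excluded)
}

# naive O(n^3)-style agglomeration: keep explicit member lists, merge the
# pair of clusters with the smallest maximum pairwise member distance
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best) {
            best <- h
            bi <- i
            bj <- j
          }
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# exact two-sided rank-sum p by enumerating all C(n+m, n) rank assignments
# (valid for tie-free data)
oracle_ranksum_p <- function(a, b) {
  N <- length(a) + length(b)
  w <- sum(rank(c(a, b))[seq_along(a)])
  combs <- utils::combn(N, length(a))
  sums <- colSums(matrix(combs, nrow = length(a)))
  p <- 2 * min(mean(sums <= w), mean(sums >= w))
  min(p, 1)
}

# random in-frame CDS: n_codons triplets drawn uniformly from all 64
rand_cds <- function(n_codons, codons) {
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}
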