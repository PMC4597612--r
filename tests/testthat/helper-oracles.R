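# Independent oracles used across the suite. Each is deliberately coded
# as a different algorithm from the implementation it checks.

# number of nested structures over allowed pairs via interval DP
# (independent of enumerate_structures' generative recursion)
count_structures_dp <- function(seq, min_loop = 3L) {
  x <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(x)
  ok <- function(a, b) paste0(x[a], x[b]) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  C <- matrix(NA_real_, n + 1L, n + 1L)  # C[i, j+1] = count over x[i..j]
  cnt <- function(i, j) {
    if (i > j) return(1)
    if (!is.na(C[i, j + 1L])) return(C[i, j + 1L])
    tot <- cnt(i + 1L, j)
    if (i + min_loop + 1L <= j) {
      for (k in (i + min_loop + 1L):j) {
        if (ok(i, k)) tot <- tot + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
      }
    }
    C[i, j + 1L] <<- tot
    tot
  }
  cnt(1L, n)
}

# hypergeometric upper-tail P(X >= k) by direct combinatorial summation
hyper_tail_sum <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# single-pass gap scan counting CAGE clusters (with min total tags)
gap_scan_clusters <- function(pos, count, max_gap = 20L, min_tags = 2L) {
  o <- order(pos)
  pos <- pos[o]; count <- count[o]
  n_clusters <- 0L
  i <- 1L
  while (i <= length(pos)) {
    tot <- count[i]
    while (i < length(pos) && pos[i + 1L] - pos[i] <= max_gap) {
      i <- i + 1L
      tot <- tot + count[i]
    }
    if (tot >= min_tags) n_clusters <- n_clusters + 1L
    i <- i + 1L
  }
  n_clusters
}

revcomp_rna_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# brute-force window scan for seed-match cores (6mer of miRNA pos 2-7)
brute_seed_sites <- function(mirna, utr) {
  core <- revcomp_rna_str(substr(mirna, 2, 7))
  utr <- chartr("T", "U", toupper(utr))
  hits <- integer(0)
  if (nchar(utr) >= 6) {
    for (p in 0:(nchar(utr) - 6)) {
      if (substr(utr, p + 1, p + 6) == core) hits <- c(hits, p)
    }
  }
  hits
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
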