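# Independent brute-force oracles used across test files. These deliberately
# re-derive results from first principles with naive loops so they share no
# code path with the package implementation.

# Exhaustive 6-frame ORF enumeration: every ATG, every in-frame stop, plain
# loops over codons.
oracle_longest_orf <- function(seq) {
  rc <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  best_len <- 0L
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    n <- nchar(s)
    for (start in seq_len(max(0L, n - 2L))) {
      if (substr(s, start, start + 2L) != "ATG") next
      pos <- start + 3L
      while (pos + 2L <= n) {
        codon <- substr(s, pos, pos + 2L)
        if (grepl("N", codon)) break
        if (codon %in% c("TAA", "TAG", "TGA")) {
          best_len <- max(best_len, pos + 2L - start + 1L)
          break
        }
        pos <- pos + 3L
      }
    }
  }
  best_len
}

# Conditional NB exact test tabulated directly from explicit pmf formulas
# (lgamma algebra, not dnbinom).
oracle_exact_p <- function(a, b, n1, n2, phi) {
  t <- a + b
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  lpmf <- function(x, size, m) {
    if (phi < 1e-10) {
      x * log(m) - m - lgamma(x + 1)
    } else {
      lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
        size * log(size / (size + m)) + x * log(m / (size + m))
    }
  }
  x <- 0:t
  lf <- lpmf(x, n1 / phi, n1 * mu) + lpmf(t - x, n2 / phi, n2 * mu)
  f <- exp(lf - max(lf))
  sum(f[f <= f[a + 1] * (1 + 1e-12)]) / sum(f)
}

# Hand-written BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct choose() summation.
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# O(n*m) neighbour scan on 0-based half-open intervals.
oracle_neighbors <- function(placements, genes, window) {
  out <- list()
  for (i in seq_len(nrow(placements))) {
    for (j in seq_len(nrow(genes))) {
      if (placements$chrom[i] != genes$chrom[j]) next
      gap <- max(genes$start[j] - placements$end[i],
                 placements$start[i] - genes$end[j], 0L)
      if (gap <= window) {
        out[[length(out) + 1L]] <- data.frame(
          lncrna_id = placements$id[i], gene_id = genes$gene_id[j],
          distance_bp = as.integer(gap), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}

# Reflexive-transitive closure of a parent list by matrix powers.
oracle_closure <- function(parents) {
  ids <- names(parents)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(A) <- TRUE
  for (id in ids) A[id, parents[[id]]] <- TRUE
  repeat {
    B <- (A %*% A) > 0
    if (identical(B, A > 0) || all(B == (A > 0))) break
    A <- B
  }
  A > 0
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
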