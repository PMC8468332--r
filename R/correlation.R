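#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson correlation with the usual two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. A
#' zero-variance vector yields an explicitly flagged undefined result rather
#' than propagating NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n` and `undefined`.
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), undefined = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = max(-1, min(1, unname(ct$estimate))), p = ct$p.value,
       n = length(x), undefined = FALSE)
}

#' Spearman rank correlation (Pearson on midranks, t approximation)
#'
#' Computes rho as the Pearson correlation of midranks, with the p-value from
#' the same t transform. An exact permutation p-value is available for small
#' samples (n <= 10).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation distribution when `n <= 10`.
#' @return List with `rho`, `p`, `n` and `undefined`.
#' @export
cor_spearman <- function(x, y, exact = FALSE) {
  check_cor_input(x, y)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x), undefined = TRUE))
  }
  rho <- max(-1, min(1, cor(rx, ry)))
  n <- length(x)
  if (exact && n <= 10L) {
    perms <- perm_all(n)
    obs <- abs(rho)
    stats <- apply(perms, 1, function(pm) abs(cor(rx, ry[pm])))
    p <- mean(stats >= obs - 1e-12)
  } else {
    ct <- cor.test(rx, ry, method = "pearson", alternative = "two.sided")
    p <- ct$p.value
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  invisible(TRUE)
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(sub + (sub >= i), rep(i, nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

#' Correlate DE lncRNAs with their DE neighbour genes
#'
#' For every (lncRNA, gene) neighbour link in which both partners are
#' differentially expressed, computes Pearson and Spearman correlations of
#' their expression vectors across all samples, and a row-normalised TPM
#' matrix of the involved features for heat-map display.
#'
#' @param tpm TPM matrix (features x samples) containing both lncRNA and gene
#'   rows.
#' @param links neighbour links from [extract_neighbors()].
#' @param de_lncrnas character vector of DE lncRNA ids.
#' @param de_genes character vector of DE gene ids.
#' @return A list with `results` (`data.frame`: `lncrna_id`, `gene_id`,
#'   `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`, `n_samples`)
#'   and `scaled` (row-normalised TPM of the involved features). Empty with
#'   a warning when no link qualifies.
#' @export
correlate_links <- function(tpm, links, de_lncrnas, de_genes) {
  tpm <- as.matrix(tpm)
  keep <- links$lncrna_id %in% de_lncrnas & links$gene_id %in% de_genes &
    links$lncrna_id %in% rownames(tpm) & links$gene_id %in% rownames(tpm)
  pairs <- unique(links[keep, c("lncrna_id", "gene_id")])
  if (!nrow(pairs)) {
    warning("no qualifying (DE lncRNA, DE neighbour gene) pairs")
    return(list(results = data.frame(
      lncrna_id = character(), gene_id = character(),
      pearson_r = numeric(), pearson_p = numeric(),
      spearman_rho = numeric(), spearman_p = numeric(),
      n_samples = integer(), stringsAsFactors = FALSE),
      scaled = matrix(numeric(), 0, ncol(tpm))))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- tpm[pairs$lncrna_id[i], ]
    y <- tpm[pairs$gene_id[i], ]
    pe <- cor_pearson(x, y)
    sp <- cor_spearman(x, y)
    data.frame(lncrna_id = pairs$lncrna_id[i], gene_id = pairs$gene_id[i],
               pearson_r = pe$r, pearson_p = pe$p,
               spearman_rho = sp$rho, spearman_p = sp$p,
               n_samples = pe$n, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  feats <- unique(c(pairs$lncrna_id, pairs$gene_id))
  sub <- tpm[feats, , drop = FALSE]
  rs <- apply(sub, 1, sd)
  rs[rs == 0] <- 1
  scaled <- (sub - rowMeans(sub)) / rs
  list(results = results, scaled = scaled)
}
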