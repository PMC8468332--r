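#' Transcripts-per-million normalisation
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)` per sample. An all-zero
#' sample yields an all-zero TPM column with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @param lengths feature lengths in nt (positive), aligned with rows.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("lengths must match feature rows")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Scale samples to a common library size
#'
#' Multiplies each column to the geometric mean library size and rounds
#' half-to-even, producing pseudo-counts with (near-)equal column sums as
#' required by the conditional exact test. Zero counts are preserved exactly.
#'
#' @param counts integer matrix, features x samples.
#' @return List with `counts` (scaled matrix), `factors` (per-sample scale
#'   factors) and `target` (the common library size).
#' @export
equalize_libraries <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  }
  target <- exp(mean(log(libs)))
  factors <- target / libs
  scaled <- round(sweep(counts, 2, factors, "*"))  # round() is half-to-even
  storage.mode(scaled) <- "integer"
  list(counts = scaled, factors = factors, target = target)
}

#' Estimate the common negative-binomial dispersion by conditional maximum
#' likelihood
#'
#' Maximises, over the dispersion phi, the log-likelihood of the within-group
#' counts of every feature conditional on their group total (which removes
#' the per-feature mean from the likelihood). Requires equalised library
#' sizes. The search is a 1-D maximisation on \[1e-6, 10\] with tolerance
#' 1e-6.
#'
#' @param counts equalised integer matrix, features x samples.
#' @param groups factor of group labels per sample; every group used must
#'   have >= 2 replicates.
#' @return A `dispersion_estimate`: list with `phi`, `loglik` and `bracket`.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (ncol(counts) != length(groups)) stop("groups must match sample columns")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 replicates each")
  }
  if (all(counts == 0)) stop("all counts are zero")
  bracket <- c(1e-6, 10)
  nll <- function(phi) -conditional_loglik(counts, groups, phi)
  opt <- optimize(nll, interval = bracket, tol = 1e-6)
  structure(list(phi = opt$minimum, loglik = -opt$objective,
                 bracket = bracket),
            class = "dispersion_estimate")
}

# Summed conditional log-likelihood over features and groups at dispersion phi.
conditional_loglik <- function(counts, groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(groups)) {
    Y <- counts[, groups == g, drop = FALSE]
    n <- ncol(Y)
    z <- rowSums(Y)
    ll <- ll + sum(rowSums(lgamma(Y + r)) - n * lgamma(r) +
                     lgamma(n * r) - lgamma(z + n * r) +
                     lgamma(z + 1) - rowSums(lgamma(Y + 1)))
  }
  ll
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf(
    "<dispersion_estimate> phi = %.6f (BCV %.3f), cond. logLik = %.2f\n",
    x$phi, sqrt(x$phi), x$loglik))
  invisible(x)
}

#' Negative-binomial exact test for a two-group comparison
#'
#' The conditional exact test for overdispersed counts: with equal per-sample
#' library sizes, the group sums `a = sum(A)`, `b = sum(B)` are modelled as
#' negative binomial and the test conditions on `t = a + b`. The two-sided
#' p-value is the total conditional probability of all splits `(x, t - x)`
#' whose probability does not exceed that of the observed split. The common
#' mean is estimated as `t / (nA + nB)`; `phi = 0` gives the conditional
#' binomial (Poisson-limit) test; `t = 0` gives p = 1.
#'
#' @param counts_a,counts_b matrices (features x replicates) or vectors (one
#'   feature) of equalised counts.
#' @param phi common NB dispersion (>= 0).
#' @return Numeric vector of p-values in (0, 1\].
#' @export
exact_test <- function(counts_a, counts_b, phi) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  if (nrow(counts_a) != nrow(counts_b)) stop("feature rows must match")
  if (phi < 0) stop("dispersion must be non-negative")
  n1 <- ncol(counts_a)
  n2 <- ncol(counts_b)
  a <- rowSums(counts_a)
  b <- rowSums(counts_b)
  vapply(seq_along(a), function(i) {
    exact_test_sums(a[i], b[i], n1, n2, phi)
  }, numeric(1))
}

exact_test_sums <- function(a, b, n1, n2, phi, tol = 1e-12) {
  t <- a + b
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  x <- 0:t
  if (phi < 1e-10) {
    lf <- dpois(x, n1 * mu, log = TRUE) + dpois(t - x, n2 * mu, log = TRUE)
  } else {
    lf <- dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(t - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  lf <- lf - max(lf)
  f <- exp(lf)
  fobs <- f[a + 1]
  min(1, sum(f[f <= fobs * (1 + tol)]) / sum(f))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) m p_(j) / j`, capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential expression of every stimulus against the control
#'
#' For each stimulus-vs-control contrast: equalise the library sizes of the
#' six samples, estimate the common dispersion by conditional maximum
#' likelihood, run the NB exact test per feature, adjust p-values by
#' Benjamini-Hochberg within the contrast, and compute the signed fold change
#' from group mean TPM with a pseudo-TPM of 1 added to both means
#' (`FC = ratio` when the stimulus mean is higher, `-1/ratio` otherwise).
#' A feature is flagged DE when `|FC| > fc_threshold` and
#' `FDR < fdr_threshold`.
#'
#' @param counts integer matrix, features x samples.
#' @param lengths feature lengths (nt) aligned with rows.
#' @param condition factor of condition labels per sample.
#' @param control the control condition label.
#' @param fc_threshold absolute fold-change gate (default 2).
#' @param fdr_threshold FDR gate (default 0.05).
#' @return A `de_results` object: list with `tables` (per-stimulus
#'   `data.frame`s of id, mean TPM per group, `fc`, `p`, `fdr`, `de_flag`,
#'   `direction`), `summary` (up/down/total per stimulus), `venn`
#'   (partition of DE feature ids across stimuli), `dispersions`, `tpm`.
#' @export
run_de <- function(counts, lengths, condition, control = "control",
                   fc_threshold = 2, fdr_threshold = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (!control %in% levels(condition)) {
    stop("control condition '", control, "' not present")
  }
  stimuli <- setdiff(levels(condition), control)
  tpm <- compute_tpm(counts, lengths)
  tables <- list()
  dispersions <- list()
  for (stim in stimuli) {
    keep <- condition %in% c(control, stim)
    sub <- counts[, keep, drop = FALSE]
    grp <- droplevels(condition[keep])
    eq <- equalize_libraries(sub)
    disp <- estimate_common_dispersion(eq$counts, grp)
    p <- exact_test(eq$counts[, grp == stim, drop = FALSE],
                    eq$counts[, grp == control, drop = FALSE],
                    disp$phi)
    fdr <- bh_fdr(p)
    m_stim <- rowMeans(tpm[, condition == stim, drop = FALSE])
    m_ctrl <- rowMeans(tpm[, condition == control, drop = FALSE])
    ratio <- (m_stim + 1) / (m_ctrl + 1)
    fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
    de_flag <- abs(fc) > fc_threshold & fdr < fdr_threshold
    direction <- ifelse(!de_flag, "ns", ifelse(fc > 0, "up", "down"))
    tables[[stim]] <- data.frame(
      id = rownames(counts), mean_tpm_stimulus = m_stim,
      mean_tpm_control = m_ctrl, fc = fc, p = p, fdr = fdr,
      de_flag = de_flag, direction = direction,
      stringsAsFactors = FALSE, row.names = NULL)
    dispersions[[stim]] <- disp
  }
  de_ids <- lapply(tables, function(tb) tb$id[tb$de_flag])
  summary <- data.frame(
    stimulus = stimuli,
    up = vapply(tables, function(tb) sum(tb$direction == "up"), integer(1)),
    down = vapply(tables, function(tb) sum(tb$direction == "down"), integer(1)),
    total = vapply(tables, function(tb) sum(tb$de_flag), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(tables = tables, summary = summary,
                 venn = venn_partition(de_ids),
                 dispersions = dispersions, tpm = tpm,
                 thresholds = list(fc = fc_threshold, fdr = fdr_threshold),
                 control = control),
            class = "de_results")
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf("<de_results> |FC| > %g and FDR < %g, vs '%s'\n",
              x$thresholds$fc, x$thresholds$fdr, x$control))
  print(x$summary)
  invisible(x)
}
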