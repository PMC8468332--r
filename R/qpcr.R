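#' Amplification efficiency by the CT slope method
#'
#' Averages technical replicates per dilution point, fits ordinary least
#' squares of mean Ct on log10(dilution), and reports
#' `E = 10^(-1 / slope)`. A perfect doubling assay has slope -3.3219 and
#' E = 2. Estimates with a non-negative slope, or E outside (1, 2.2], are
#' flagged rather than rejected.
#'
#' @param series `data.frame` with columns `dilution` (relative template
#'   input) and `ct`; an optional `replicate` column marks technical
#'   replicates.
#' @param primer optional assay label stored in the result.
#' @return An `efficiency_estimate`: list with `primer`, `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `flagged`.
#' @export
efficiency_from_dilution <- function(series, primer = NA_character_) {
  if (!all(c("dilution", "ct") %in% names(series))) {
    stop("series needs 'dilution' and 'ct' columns")
  }
  mean_ct <- tapply(series$ct, series$dilution, mean)
  dil <- as.numeric(names(mean_ct))
  if (length(dil) < 3L) stop("need >= 3 dilution points")
  fit <- lm(ct ~ log_dil,
            data = data.frame(ct = as.numeric(mean_ct), log_dil = log10(dil)))
  slope <- unname(coef(fit)[2])
  eff <- 10^(-1 / slope)
  flagged <- slope >= 0 || !(eff > 1 && eff <= 2.2)
  structure(list(primer = primer, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = eff,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 flagged = flagged),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "<efficiency_estimate> %s: slope %.4f, E = %.4f, R^2 = %.4f%s\n",
    if (is.na(x$primer)) "assay" else x$primer, x$slope, x$efficiency,
    x$r_squared, if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = Ct(control) - Ct(treated)` for both the target and the reference
#' gene. With both efficiencies equal to 2 this reduces to `2^-ddCt`. The
#' ratio is multiplicative in dCt: adding 1 to `dCt_target` multiplies the
#' ratio by `E_target` exactly.
#'
#' @param ct_target_ctrl,ct_target_trt target-gene Ct in control and treated
#'   samples.
#' @param ct_ref_ctrl,ct_ref_trt reference-gene Ct in control and treated
#'   samples.
#' @param e_target,e_ref amplification efficiencies (> 0; 2 = perfect
#'   doubling).
#' @return Numeric vector of expression ratios (> 0).
#' @examples
#' pfaffl_ratio(20, 17, 15, 14, 2, 2)  # 2^3 / 2^1 = 4
#' @export
pfaffl_ratio <- function(ct_target_ctrl, ct_target_trt,
                         ct_ref_ctrl, ct_ref_trt,
                         e_target = 2, e_ref = 2) {
  if (any(e_target <= 0) || any(e_ref <= 0)) {
    stop("amplification efficiencies must be positive")
  }
  if (anyNA(c(ct_target_ctrl, ct_target_trt, ct_ref_ctrl, ct_ref_trt))) {
    stop("all Ct values must be finite")
  }
  e_target^(ct_target_ctrl - ct_target_trt) /
    e_ref^(ct_ref_ctrl - ct_ref_trt)
}

#' Relative qPCR quantification of every target against a reference gene
#'
#' Averages technical replicates, then computes, per target, stimulus and
#' individual, the Pfaffl ratio against the matched control well of the same
#' individual, using per-assay efficiencies. Per (target, stimulus) the
#' ratios are combined as a geometric mean and reported as a signed fold
#' change (ratios below 1 become `-1/ratio`).
#'
#' @param ct_table `data.frame` with columns `individual`, `condition`,
#'   `target`, `replicate`, `ct`.
#' @param efficiencies named numeric vector of per-assay efficiencies (must
#'   cover all targets and the reference).
#' @param ref_gene reference assay name.
#' @param control control condition label.
#' @return `data.frame` with `target`, `stimulus`, `ratio` (geometric mean)
#'   and signed `fc`.
#' @export
quantify_qpcr <- function(ct_table, efficiencies, ref_gene = "ref_18S",
                          control = "control") {
  needed <- c("individual", "condition", "target", "replicate", "ct")
  if (!all(needed %in% names(ct_table))) {
    stop("ct_table needs columns: ", paste(needed, collapse = ", "))
  }
  missing_e <- setdiff(unique(ct_table$target), names(efficiencies))
  if (length(missing_e)) {
    stop("no efficiency for assay(s): ", paste(missing_e, collapse = ", "))
  }
  agg <- stats::aggregate(ct ~ individual + condition + target,
                          data = ct_table, FUN = mean)
  conds <- setdiff(unique(agg$condition), control)
  targets <- setdiff(unique(agg$target), ref_gene)
  rows <- list()
  for (tg in targets) {
    for (cc in conds) {
      ratios <- vapply(unique(agg$individual), function(ind) {
        g <- function(target, condition) {
          v <- agg$ct[agg$individual == ind & agg$condition == condition &
                        agg$target == target]
          if (length(v) != 1L) NA_real_ else v
        }
        pfaffl_ratio(g(tg, control), g(tg, cc),
                     g(ref_gene, control), g(ref_gene, cc),
                     e_target = efficiencies[[tg]],
                     e_ref = efficiencies[[ref_gene]])
      }, numeric(1))
      ratios <- ratios[!is.na(ratios)]
      if (!length(ratios)) next
      gm <- exp(mean(log(ratios)))
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, stimulus = cc, ratio = gm,
        fc = if (gm >= 1) gm else -1 / gm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-platform correlation of RNA-Seq and qPCR fold changes
#'
#' Pearson correlation of log10 fold changes over matched (target, stimulus)
#' pairs. Signed fold changes are first converted to the ratio scale
#' (`-k` becomes `1/k`) so logs are defined.
#'
#' @param rnaseq_fc `data.frame` with `target`, `stimulus`, `fc` from the
#'   RNA-Seq side.
#' @param qpcr_fc `data.frame` with `target`, `stimulus`, `fc` from
#'   [quantify_qpcr()].
#' @return List with `r`, `p`, `n` and the merged pair table.
#' @export
cross_platform_correlation <- function(rnaseq_fc, qpcr_fc) {
  merged <- merge(rnaseq_fc[, c("target", "stimulus", "fc")],
                  qpcr_fc[, c("target", "stimulus", "fc")],
                  by = c("target", "stimulus"),
                  suffixes = c("_rnaseq", "_qpcr"))
  if (nrow(merged) < 3L) stop("need >= 3 matched (target, stimulus) pairs")
  merged$log10_rnaseq <- log10(signed_fc_to_ratio(merged$fc_rnaseq))
  merged$log10_qpcr <- log10(signed_fc_to_ratio(merged$fc_qpcr))
  ct <- cor_pearson(merged$log10_rnaseq, merged$log10_qpcr)
  list(r = ct$r, p = ct$p, n = nrow(merged), pairs = merged)
}

#' Convert a signed fold change to the ratio scale
#'
#' The signed convention reports down-regulation `-k` for a ratio of `1/k`;
#' this inverts it so logarithms are defined.
#'
#' @param fc numeric vector of signed fold changes (|fc| >= 1 by convention).
#' @return Positive ratios.
#' @export
signed_fc_to_ratio <- function(fc) {
  if (any(fc == 0)) stop("fold change of 0 has no ratio-scale equivalent")
  ifelse(fc >= 0, fc, -1 / fc)
}
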