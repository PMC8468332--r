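#' Coding-potential feature table
#'
#' Computes, per transcript, the four features of the coding-potential
#' classifier: longest-ORF length (bp), ORF coverage (ORF length / transcript
#' length), Fickett TESTCODE score, and hexamer usage bias.
#'
#' @param records a [transcript_records] table.
#' @param coding_freqs,noncoding_freqs hexamer frequency tables
#'   (see [hexamer_frequencies()]).
#' @return `data.frame` with columns `id`, `orf_length_bp`, `orf_coverage`,
#'   `fickett`, `hexamer_bias`.
#' @export
coding_features <- function(records, coding_freqs, noncoding_freqs) {
  orf_len <- longest_orf_lengths(records$sequence)
  data.frame(
    id = records$id,
    orf_length_bp = orf_len,
    orf_coverage = orf_len / records$length,
    fickett = vapply(records$sequence, fickett_score, numeric(1),
                     USE.NAMES = FALSE),
    hexamer_bias = vapply(records$sequence, hexamer_bias, numeric(1),
                          coding_freqs = coding_freqs,
                          noncoding_freqs = noncoding_freqs,
                          USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Train the logistic coding-potential model
#'
#' Fits a logistic regression of coding status on the four features of
#' [coding_features()] by iteratively reweighted least squares. Features are
#' standardised internally. Under perfect separation the fit falls back to an
#' L2-ridge IRLS (lambda = 1e-3) with a warning. The decision cutoff defaults
#' to 0.5, or can be chosen to maximise Youden's J on a held-out split.
#'
#' @param features feature `data.frame` from [coding_features()].
#' @param labels logical or 0/1 vector, `TRUE`/1 = coding.
#' @param cutoff decision threshold on the predicted probability, or
#'   `"youden"` to pick the threshold maximising sensitivity + specificity - 1
#'   on a 30% held-out split.
#' @param coding_freqs,noncoding_freqs optional hexamer tables stored in the
#'   model so it can score new transcripts.
#' @return An object of class `coding_model` with elements `coef`, `center`,
#'   `scale`, `cutoff`, `ridge` and the hexamer tables.
#' @export
train_coding_model <- function(features, labels, cutoff = 0.5,
                               coding_freqs = NULL, noncoding_freqs = NULL) {
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(features)) stop("labels must match feature rows")
  if (sum(y == 1L) < 20L || sum(y == 0L) < 20L) {
    stop("need >= 20 examples per class (have ",
         sum(y == 1L), " coding, ", sum(y == 0L), " non-coding)")
  }
  vars <- c("orf_length_bp", "orf_coverage", "fickett", "hexamer_bias")
  X <- as.matrix(features[, vars])
  ctr <- colMeans(X)
  # population SD so standardisation (hence the fit) is invariant to
  # duplicating the training rows
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  heldout <- NULL
  if (identical(cutoff, "youden")) {
    idx <- seq_len(nrow(Z))
    n_test <- max(1L, floor(0.3 * length(idx)))
    test <- idx[seq_len(n_test) * floor(length(idx) / n_test)]  # deterministic stride
    test <- unique(pmin(test, length(idx)))
    heldout <- list(Z = Z[test, , drop = FALSE], y = y[test])
    Z <- Z[-test, , drop = FALSE]
    y <- y[-test]
  }

  dat <- data.frame(y = y, Z)
  ridge <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        ridge <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- if (ridge) {
    warning("perfect separation detected; refitting with L2 ridge (lambda = 1e-3)")
    ridge_logistic_irls(cbind(1, Z), y, lambda = 1e-3)
  } else {
    unname(coef(fit))
  }
  names(beta) <- c("(Intercept)", vars)

  model <- structure(
    list(coef = beta, center = ctr, scale = scl, cutoff = 0.5, ridge = ridge,
         coding_freqs = coding_freqs, noncoding_freqs = noncoding_freqs),
    class = "coding_model"
  )
  if (identical(cutoff, "youden")) {
    hf <- as.data.frame(heldout$Z)
    attr(hf, "standardised") <- TRUE
    p <- predict(model, features = hf)
    grid <- sort(unique(c(p, 0.5)))
    j <- vapply(grid, function(th) {
      pred <- p >= th
      sens <- if (any(heldout$y == 1)) mean(pred[heldout$y == 1]) else 0
      spec <- if (any(heldout$y == 0)) mean(!pred[heldout$y == 0]) else 0
      sens + spec - 1
    }, numeric(1))
    model$cutoff <- grid[which.max(j)]
  } else {
    model$cutoff <- cutoff
  }
  model
}

# Plain IRLS for ridge-penalised logistic regression (intercept unpenalised).
ridge_logistic_irls <- function(X, y, lambda = 1e-3, tol = 1e-8, maxit = 100) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  beta
}

#' Predict coding probability
#'
#' @param object a `coding_model`.
#' @param records optional [transcript_records] to featurise and score (the
#'   model must then carry hexamer tables).
#' @param features optional precomputed standardisable feature table
#'   (columns as in [coding_features()], already standardised columns allowed
#'   when named `orf_length_bp` etc. on the standardised scale -- internal use).
#' @param ... unused.
#' @return Numeric vector of coding probabilities in \[0, 1\].
#' @export
predict.coding_model <- function(object, records = NULL, features = NULL, ...) {
  if (is.null(features)) {
    if (is.null(records)) stop("supply 'records' or 'features'")
    if (is.null(object$coding_freqs)) {
      stop("model carries no hexamer tables; supply 'features' instead")
    }
    features <- coding_features(records, object$coding_freqs,
                                object$noncoding_freqs)
    vars <- names(object$center)
    Z <- sweep(sweep(as.matrix(features[, vars]), 2, object$center),
               2, object$scale, "/")
  } else {
    vars <- names(object$center)
    Z <- as.matrix(features[, vars])
    if (!isTRUE(attr(features, "standardised"))) {
      Z <- sweep(sweep(Z, 2, object$center), 2, object$scale, "/")
    }
  }
  eta <- drop(cbind(1, Z) %*% object$coef)
  1 / (1 + exp(-eta))
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> logistic coding-potential classifier\n")
  cat("  coefficients (standardised features):\n")
  print(round(x$coef, 4))
  cat(sprintf("  cutoff: %.3f%s\n", x$cutoff,
              if (x$ridge) "  [ridge fallback]" else ""))
  invisible(x)
}

#' Build a coding-potential model from labelled transcripts
#'
#' Convenience wrapper: derives coding and non-coding hexamer tables from the
#' labelled training transcripts themselves, computes features and trains the
#' logistic model, which then carries everything needed to score new
#' transcripts.
#'
#' @param records labelled training [transcript_records].
#' @param labels logical vector, `TRUE` = coding.
#' @param cutoff see [train_coding_model()].
#' @return A `coding_model`.
#' @export
build_coding_model <- function(records, labels, cutoff = 0.5) {
  labels <- as.logical(labels)
  cf <- hexamer_frequencies(records$sequence[labels])
  nf <- hexamer_frequencies(records$sequence[!labels])
  feats <- coding_features(records, cf, nf)
  train_coding_model(feats, labels, cutoff = cutoff,
                     coding_freqs = cf, noncoding_freqs = nf)
}
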