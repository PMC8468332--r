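#' Read a GO DAG from an OBO subset
#'
#' Parses only `[Term]` stanzas and the `id`, `name`, `namespace` and `is_a`
#' lines (trailing `! comments` stripped). Obsolete terms are skipped. The
#' parent graph is checked for acyclicity.
#'
#' @param path path to an OBO-format file.
#' @return A `go_dag`: list with `terms` (`data.frame`: `id`, `name`,
#'   `namespace`) and `parents` (named list of is_a parent ids).
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character())
    } else if (startsWith(ln, "[")) {      # [Typedef] etc. ends a term
      terms <- flush(cur, terms)
      cur <- NULL
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) {
        cur$namespace <- sub("^namespace: ", "", ln)
      } else if (startsWith(ln, "is_a: ")) {
        p <- sub("\\s*!.*$", "", sub("^is_a: ", "", ln))
        cur$parents <- c(cur$parents, trimws(p))
      } else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  dag <- structure(list(
    terms = data.frame(
      id = vapply(terms, `[[`, character(1), "id"),
      name = vapply(terms, function(t) t$name %||% "", character(1)),
      namespace = vapply(terms, function(t) t$namespace %||% "",
                         character(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    parents = lapply(terms, `[[`, "parents")
  ), class = "go_dag")
  check_acyclic(dag)
  dag
}

check_acyclic <- function(dag) {
  state <- new.env()
  visit <- function(id, stack) {
    if (id %in% stack) stop("cycle in GO DAG involving ", id)
    if (isTRUE(state[[id]])) return(invisible())
    for (p in dag$parents[[id]] %||% character()) visit(p, c(stack, id))
    state[[id]] <- TRUE
  }
  for (id in names(dag$parents)) visit(id, character())
  invisible(TRUE)
}

#' All ancestors of a term (excluding itself)
#' @param dag a `go_dag`.
#' @param id term id.
#' @return Character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag, id) {
  out <- character()
  frontier <- dag$parents[[id]] %||% character()
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  out
}

#' Propagate direct annotations up the DAG (true-path rule)
#'
#' Annotates every gene to all ancestors of its direct terms. Idempotent.
#'
#' @param direct_map named list: gene id -> character vector of term ids.
#' @param dag a `go_dag`.
#' @return Named list with the propagated term sets.
#' @export
propagate_annotations <- function(direct_map, dag) {
  known <- names(dag$parents)
  offenders <- setdiff(unique(unlist(direct_map, use.names = FALSE)), known)
  if (length(offenders)) {
    stop("unknown term id(s): ", paste(offenders, collapse = ", "))
  }
  anc_cache <- new.env()
  get_anc <- function(id) {
    if (is.null(anc_cache[[id]])) anc_cache[[id]] <- go_ancestors(dag, id)
    anc_cache[[id]]
  }
  lapply(direct_map, function(terms) {
    terms <- unique(terms)
    sort(union(terms, unique(unlist(lapply(terms, get_anc),
                                    use.names = FALSE))))
  })
}

#' One-sided Fisher (hypergeometric) over-representation test per GO term
#'
#' For every term annotated to at least one study gene, tests
#' over-representation of the term in the study set against the background:
#' `p = P(X >= k)` for hypergeometric X with `K` background genes carrying
#' the term, study size `n`, background size `N`.
#'
#' @param study_genes character vector of study gene ids (must be a subset of
#'   the background).
#' @param background_genes character vector of background gene ids.
#' @param full_map propagated gene -> terms map
#'   (see [propagate_annotations()]).
#' @return `data.frame` sorted by ascending `p` then term id, with columns
#'   `term`, `k`, `n`, `K`, `N`, `p`, `most_specific` (NA until
#'   [reduce_most_specific()]).
#' @export
fisher_enrichment <- function(study_genes, background_genes, full_map) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!length(study_genes) || !length(background_genes)) {
    stop("study and background sets must be non-empty")
  }
  if (!all(study_genes %in% background_genes)) {
    stop("study set must be a subset of the background")
  }
  N <- length(background_genes)
  n <- length(study_genes)
  bg_map <- full_map[intersect(names(full_map), background_genes)]
  term_bg <- table(unlist(bg_map, use.names = FALSE))
  st_map <- full_map[intersect(names(full_map), study_genes)]
  term_st <- table(unlist(st_map, use.names = FALSE))
  terms <- names(term_st)
  k <- as.integer(term_st[terms])
  K <- as.integer(term_bg[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    most_specific = NA, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag most-specific enriched terms and select the top biological processes
#'
#' Among terms with `p < alpha`, a term is most specific when none of its
#' descendants in the DAG is also significant. Returns the input results with
#' the `most_specific` flag filled in, and attaches the up-to-20 most
#' enriched most-specific biological-process terms as the `top_bp` attribute.
#'
#' @param results output of [fisher_enrichment()].
#' @param dag a `go_dag`.
#' @param alpha significance cutoff (default 0.05).
#' @param n_top number of top BP terms to select (default 20).
#' @return The annotated results `data.frame`.
#' @export
reduce_most_specific <- function(results, dag, alpha = 0.05, n_top = 20L) {
  sig <- results$term[results$p < alpha]
  # descendants(t) = terms having t among their ancestors
  anc <- lapply(results$term, function(tt) go_ancestors(dag, tt))
  names(anc) <- results$term
  ms <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    tt <- results$term[i]
    if (!(tt %in% sig)) { ms[i] <- FALSE; next }
    has_sig_desc <- any(vapply(sig, function(s) {
      s != tt && tt %in% anc[[s]]
    }, logical(1)))
    ms[i] <- !has_sig_desc
  }
  results$most_specific <- ms
  ns <- dag$terms$namespace[match(results$term, dag$terms$id)]
  bp <- results[ms & ns == "biological_process", , drop = FALSE]
  bp <- bp[order(bp$p, bp$term), , drop = FALSE]
  attr(results, "top_bp") <- utils::head(bp, n_top)
  results
}
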