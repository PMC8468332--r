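mini_dag <- function() {
  read_obo_subset(system.file("extdata", "go_mini.obo", package = "lncmine"))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

test_that("OBO subset reader recovers terms, namespaces and parents", {
  dag <- mini_dag()
  expect_true(all(c("GO:0008150", "GO:0042742", "GO:0004364") %in%
                    dag$terms$id))
  expect_identical(dag$parents[["GO:0042742"]], "GO:0006952")
  expect_identical(
    dag$terms$namespace[dag$terms$id == "GO:0004364"], "molecular_function")
  # every non-root term has at least one parent
  roots <- c("GO:0008150", "GO:0003674", "GO:0005575")
  nonroot <- setdiff(dag$terms$id, roots)
  expect_true(all(lengths(dag$parents[nonroot]) >= 1L))
})

test_that("annotation propagation is the transitive closure and idempotent", {
  dag <- mini_dag()
  m <- propagate_annotations(list(g1 = "GO:0042742", g2 = "GO:0008150"), dag)
  expect_setequal(m$g1, c("GO:0042742", "GO:0006952", "GO:0002376",
                          "GO:0008150"))
  expect_identical(m$g2, "GO:0008150")  # root only: unchanged
  expect_identical(propagate_annotations(m, dag), m)
  expect_error(propagate_annotations(list(g1 = "GO:9999999"), dag),
               "unknown term")
})

test_that("propagation equals a reflexive-transitive-closure oracle on random DAGs", {
  set.seed(53)
  for (rep_ in 1:5) {
    n <- sample(10:50, 1)
    ids <- sprintf("T%02d", seq_len(n))
    parents <- setNames(vector("list", n), ids)
    for (i in 2:n) {  # edges only to earlier ids: guaranteed acyclic
      k <- sample(0:min(2, i - 1), 1)
      parents[[i]] <- if (k) sample(ids[seq_len(i - 1)], k) else character()
    }
    dag <- structure(list(
      terms = data.frame(id = ids, name = ids,
                         namespace = "biological_process",
                         stringsAsFactors = FALSE),
      parents = parents), class = "go_dag")
    closure <- oracle_closure(parents)
    genes <- setNames(lapply(1:8, function(j) sample(ids, sample(1:3, 1))),
                      paste0("g", 1:8))
    prop <- propagate_annotations(genes, dag)
    for (g in names(genes)) {
      expected <- sort(unique(unlist(
        lapply(genes[[g]], function(tt) ids[closure[tt, ]]))))
      expect_identical(prop[[g]], expected)
    }
    # ancestor term frequency is anti-monotone after propagation
    cnt <- table(unlist(prop, use.names = FALSE))
    for (id in ids) {
      for (p in parents[[id]]) {
        expect_gte(cnt[p] %||% 0L, cnt[id] %||% 0L)
      }
    }
  }
})

test_that("Fisher enrichment matches the hypergeometric closed forms", {
  dag <- mini_dag()
  # worked value: N=10, K=5, n=4, k=4 -> choose(5,4)/choose(10,4) = 5/210
  bg <- paste0("g", 1:10)
  map <- setNames(rep(list("GO:0006952"), 5), bg[1:5])
  map <- c(map, setNames(rep(list("GO:0008150"), 5), bg[6:10]))
  res <- fisher_enrichment(bg[1:4], bg, map)
  expect_equal(res$p[res$term == "GO:0006952"], 5 / 210, tolerance = 1e-12)

  # universal term -> p = 1; study = background -> all p = 1
  map_all <- setNames(rep(list("GO:0008150"), 10), bg)
  res_u <- fisher_enrichment(bg[1:4], bg, map_all)
  expect_equal(res_u$p, 1)
  res_sb <- fisher_enrichment(bg, bg, map)
  expect_true(all(res_sb$p == 1))

  expect_error(fisher_enrichment(c("zz"), bg, map), "subset")

  # random tuples against the choose() summation oracle
  set.seed(59)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("most-specific reduction keeps exactly the leaf-most significant terms", {
  dag <- mini_dag()
  res <- data.frame(
    term = c("GO:0006952", "GO:0042742", "GO:0002376", "GO:0006909"),
    k = 3, n = 5, K = 4, N = 20,
    p = c(0.01, 0.02, 0.2, 0.03),
    most_specific = NA, stringsAsFactors = FALSE)
  out <- reduce_most_specific(res, dag, alpha = 0.05)
  # significant parent (defense response) has a significant child -> not m.s.
  expect_false(out$most_specific[out$term == "GO:0006952"])
  expect_true(out$most_specific[out$term == "GO:0042742"])
  expect_false(out$most_specific[out$term == "GO:0002376"])  # not significant
  expect_true(out$most_specific[out$term == "GO:0006909"])
  top <- attr(out, "top_bp")
  expect_true(all(top$p < 0.05))
  expect_lte(nrow(top), 20L)

  # no significant terms -> empty selection
  res2 <- transform(res, p = 0.5)
  out2 <- reduce_most_specific(res2, dag, alpha = 0.05)
  expect_identical(nrow(attr(out2, "top_bp")), 0L)

  # random DAG: flags equal a brute-force descendant scan
  set.seed(61)
  n <- 30
  ids <- sprintf("T%02d", 1:n)
  parents <- setNames(vector("list", n), ids)
  for (i in 2:n) {
    parents[[i]] <- sample(ids[seq_len(i - 1)], sample(0:min(2, i - 1), 1))
  }
  rdag <- structure(list(
    terms = data.frame(id = ids, name = ids,
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = parents), class = "go_dag")
  rres <- data.frame(term = ids, k = 1, n = 5, K = 2, N = 50,
                     p = runif(n), most_specific = NA,
                     stringsAsFactors = FALSE)
  rout <- reduce_most_specific(rres, rdag, alpha = 0.4)
  closure <- oracle_closure(parents)
  sig <- rres$term[rres$p < 0.4]
  for (i in seq_len(n)) {
    tt <- rres$term[i]
    expected <- tt %in% sig &&
      !any(vapply(setdiff(sig, tt),
                  function(s) closure[s, tt], logical(1)))
    expect_identical(rout$most_specific[rout$term == tt], expected)
  }
})
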