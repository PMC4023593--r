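test_that("annotations propagate to all ancestors through the ontology", {
  # chain: t1 -> t2 -> t3 -> t4
  onto <- data.frame(child = c("t1", "t2", "t3"),
                     parent = c("t2", "t3", "t4"), stringsAsFactors = FALSE)
  g2t <- data.frame(gene = "g1", term = "t1", stringsAsFactors = FALSE)
  ann <- propagate_annotations(g2t, onto, universe = c("g1", "g2"))
  expect_setequal(names(ann$term_genes), c("t1", "t2", "t3", "t4"))
  for (tm in names(ann$term_genes))
    expect_equal(ann$term_genes[[tm]], "g1")

  # no ontology: direct annotations pass through unchanged
  flat <- propagate_annotations(g2t, NULL, universe = "g1")
  expect_equal(names(flat$term_genes), "t1")

  # genes outside the universe are dropped and counted
  g2t2 <- rbind(g2t, data.frame(gene = "alien", term = "t1"))
  ann2 <- propagate_annotations(g2t2, onto, universe = c("g1", "g2"))
  expect_equal(ann2$n_dropped, 1)
  expect_equal(ann2$term_genes[["t1"]], "g1")
})

test_that("a cyclic ontology is rejected with the cycle named", {
  onto <- data.frame(child = c("a", "b", "c"), parent = c("b", "c", "a"),
                     stringsAsFactors = FALSE)
  g2t <- data.frame(gene = "g1", term = "a", stringsAsFactors = FALSE)
  expect_error(propagate_annotations(g2t, onto, universe = "g1"),
               "cycle.*a, b, c")
})

test_that("propagation equals a depth-first transitive-closure oracle on random DAGs", {
  set.seed(151)
  for (i in 1:10) {
    n_terms <- sample(6:12, 1)
    terms <- sprintf("T%02d", seq_len(n_terms))
    # random DAG: edges only from lower to higher index
    edges <- expand.grid(child = terms, parent = terms,
                         stringsAsFactors = FALSE)
    edges <- edges[match(edges$child, terms) < match(edges$parent, terms), ]
    edges <- edges[runif(nrow(edges)) < 0.3, ]
    if (!nrow(edges)) next
    genes <- sprintf("g%02d", 1:8)
    g2t <- data.frame(gene = sample(genes, 12, replace = TRUE),
                      term = sample(terms, 12, replace = TRUE),
                      stringsAsFactors = FALSE)
    ann <- propagate_annotations(g2t, edges, universe = genes)
    anc <- oracle_ancestors(edges)
    for (r in seq_len(nrow(g2t))) {
      expected_terms <- unique(c(g2t$term[r], anc[[g2t$term[r]]]))
      for (tm in expected_terms)
        expect_true(g2t$gene[r] %in% ann$term_genes[[tm]])
    }
    # and no term set contains a gene it should not
    direct <- split(g2t$term, g2t$gene)
    for (tm in names(ann$term_genes)) {
      for (g in ann$term_genes[[tm]]) {
        reachable <- unique(unlist(lapply(direct[[g]], function(t0)
          c(t0, anc[[t0]]))))
        expect_true(tm %in% reachable)
      }
    }
  }
})

test_that("hypergeometric p-values match exact enumeration", {
  ann <- structure(list(term_genes = list(T1 = sprintf("g%02d", 1:4)),
                        universe = sprintf("g%02d", 1:10), n_dropped = 0L),
                   class = "annotation_set")
  out <- hypergeometric_enrichment(sprintf("g%02d", c(1, 2, 3, 7, 8)), ann)
  expect_equal(out$p, 66 / 252, tolerance = 1e-12)
  expect_equal(out$k, 3)

  # certain event: query = term = universe
  ann_all <- structure(list(term_genes = list(T1 = c("a", "b")),
                            universe = c("a", "b"), n_dropped = 0L),
                       class = "annotation_set")
  full <- hypergeometric_enrichment(c("a", "b"), ann_all)
  expect_equal(full$p, 1)

  # systematic agreement with enumeration for all N <= 12
  set.seed(161)
  for (i in 1:60) {
    N <- sample(3:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("x%02d", seq_len(N))
    ann_i <- structure(list(term_genes = list(T = universe[seq_len(K)]),
                            universe = universe, n_dropped = 0L),
                       class = "annotation_set")
    query <- sample(universe, n)
    k <- length(intersect(query, universe[seq_len(K)]))
    res <- hypergeometric_enrichment(query, ann_i)
    if (k == 0) {
      expect_equal(nrow(res), 0)
      expect_equal(attr(res, "n_untested"), 1)
    } else {
      expect_equal(res$p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("adding an unannotated gene changes n but not k", {
  universe <- sprintf("g%02d", 1:20)
  ann <- structure(list(term_genes = list(T1 = universe[1:6]),
                        universe = universe, n_dropped = 0L),
                   class = "annotation_set")
  base <- hypergeometric_enrichment(universe[c(1, 2, 3)], ann)
  grown <- hypergeometric_enrichment(universe[c(1, 2, 3, 15)], ann)
  expect_equal(grown$k, base$k)
  expect_equal(grown$n, base$n + 1)
  expect_false(grown$p == base$p)
})

test_that("q-values dominate p-values and significance shrinks with alpha", {
  set.seed(171)
  universe <- sprintf("g%03d", 1:60)
  term_genes <- lapply(1:15, function(i) sample(universe, sample(3:20, 1)))
  names(term_genes) <- sprintf("T%02d", 1:15)
  ann <- structure(list(term_genes = term_genes, universe = universe,
                        n_dropped = 0L), class = "annotation_set")
  query <- sample(universe, 12)
  res05 <- hypergeometric_enrichment(query, ann, alpha = 0.05)
  expect_true(all(res05$q >= res05$p - 1e-15))
  res01 <- hypergeometric_enrichment(query, ann, alpha = 0.01)
  expect_true(all(res01$term[res01$significant] %in%
                    res05$term[res05$significant]))
})

test_that("null queries are rarely called significant at q < 0.05", {
  set.seed(181)
  universe <- sprintf("g%03d", 1:200)
  term_genes <- lapply(1:30, function(i) sample(universe, sample(5:40, 1)))
  names(term_genes) <- sprintf("T%02d", 1:30)
  ann <- structure(list(term_genes = term_genes, universe = universe,
                        n_dropped = 0L), class = "annotation_set")
  n_sig <- 0
  n_tested <- 0
  for (i in 1:40) {
    query <- sample(universe, 15)
    res <- hypergeometric_enrichment(query, ann)
    n_sig <- n_sig + sum(res$significant)
    n_tested <- n_tested + nrow(res)
  }
  rate <- n_sig / n_tested
  se <- sqrt(0.05 * 0.95 / n_tested)
  expect_lte(rate, 0.05 + 3 * se)

  # queries outside the universe are dropped with a warning; empty errors
  expect_warning(hypergeometric_enrichment(c(universe[1], "alien"), ann),
                 "dropped")
  expect_error(suppressWarnings(hypergeometric_enrichment("alien", ann)),
               "empty query")
})
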