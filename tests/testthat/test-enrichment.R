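test_that("hypergeom_tail reproduces hand-enumerated values and edge cases", {
  expect_equal(hypergeom_tail(10, 5, 5, 0), 1)
  # N=4, n=2, K=2, i=2: one of the C(4,2)=6 draws contains both annotated genes
  expect_equal(hypergeom_tail(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 3, 2, 3), 0)   # i > min(n, K)
  expect_error(hypergeom_tail(10, 11, 2, 0), "n <= N", class = "lncora_config_error")
  expect_error(hypergeom_tail(10, 2, 11, 0), "K <= N", class = "lncora_config_error")
  expect_error(hypergeom_tail(10, 2, 2, -1), class = "lncora_config_error")
})

test_that("hypergeom_tail is 1 at i = 0 and non-increasing in i", {
  withr::local_seed(61)
  for (rep in 1:30) {
    N <- sample(2:60, 1); n <- sample(0:N, 1); K <- sample(0:N, 1)
    p <- vapply(0:(min(n, K) + 1L), function(i) hypergeom_tail(N, n, K, i),
                numeric(1))
    expect_equal(p[1], 1)
    expect_true(all(diff(p) <= 1e-14))
  }
})

test_that("hypergeom_tail is stable at realistic genome scale", {
  # no overflow / underflow at N = 1e5; compare against the log-space series
  p <- hypergeom_tail(100000, 600, 120, 10)
  k <- 10:120
  lt <- lchoose(120, k) + lchoose(100000 - 120, 600 - k) - lchoose(100000, 600)
  expect_equal(p, sum(exp(lt)), tolerance = 1e-10)
  expect_true(p > 0 && p < 1)
})

test_that("eq2_tail matches brute-force enumeration on the worked example", {
  # N=6, n=2, K=3, i=1, r=1: all C(6,3)=20 draws of n+r=3, at least i+r=2
  # annotated -> (C(3,2)*C(3,1) + C(3,3))/20 = 10/20, frozen from enumeration
  expect_equal(eq2_tail(6, 2, 3, 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(eq2_tail(6, 2, 3, 1, 1, form = "series"), 0.5, tolerance = 1e-12)
  expect_equal(eq2_tail(6, 2, 3, 1, 1), enum_hyper_tail(6, 3, 3, 2),
               tolerance = 1e-12)
})

test_that("eq2_tail reduces to the classical tail at r = 0", {
  expect_equal(eq2_tail(10, 5, 5, 0, 0), 1)
  for (N in c(4, 8, 12)) for (n in 0:N) for (K in c(0, N %/% 2, N))
    for (i in 0:(min(n, K) + 1L)) {
      expect_equal(eq2_tail(N, n, K, i, 0), hypergeom_tail(N, n, K, i),
                   tolerance = 1e-12)
      expect_equal(eq2_tail(N, n, K, i, 0, form = "series"),
                   hypergeom_tail(N, n, K, i), tolerance = 1e-12)
    }
})

test_that("printed series equals the substituted form on an N <= 30 grid", {
  for (N in c(6, 11, 17, 24, 30)) for (r in 0:5)
    for (n in unique(c(0, 1, N %/% 3, N %/% 2))) for (K in unique(c(0, 2, N %/% 2, N)))
      for (i in 0:(min(n + r, K) + 1L)) {
        if (n + r > N) next
        expect_equal(eq2_tail(N, n, K, i, r, form = "series"),
                     hypergeom_tail(N, n + r, K, i + r), tolerance = 1e-12)
      }
})

test_that("enrich_term computes counts by set intersection per mode", {
  universe <- paste0("g", 1:20)
  tm <- term_map(list(T1 = paste0("g", 1:4)), namespace = "custom")
  de <- c("g1", "g2", "x1")          # x1 outside the universe
  lnc <- c("g3", "y1")
  for (mode in c("eq1", "eq2_printed", "eq2_combined")) {
    inp <- enrichment_input(universe, de, lnc, tm, mode = mode)
    res <- enrich_term("T1", inp)
    expect_equal(res[, c("N", "n", "r", "K", "k_de", "k_lnc")],
                 data.frame(N = 20L, n = 2L, r = 1L, K = 4L, k_de = 2L, k_lnc = 1L),
                 ignore_attr = TRUE)
  }
  inp <- enrichment_input(universe, de, lnc, tm, mode = "eq2_combined")
  expect_equal(enrich_term("T1", inp)$p_value, hypergeom_tail(20, 3, 4, 3),
               tolerance = 1e-12)
  inp1 <- enrichment_input(universe, de, lnc, tm, mode = "eq1")
  expect_equal(enrich_term("T1", inp1)$p_value, hypergeom_tail(20, 2, 4, 2),
               tolerance = 1e-12)
})

test_that("eq1 and eq2_combined agree for every term when r = 0", {
  withr::local_seed(71)
  universe <- paste0("g", 1:50)
  tm <- term_map(lapply(stats::setNames(1:8, paste0("T", 1:8)),
                        function(i) sample(universe, 10)), namespace = "GO")
  de <- sample(universe, 12)
  r1 <- enrich_all(enrichment_input(universe, de, character(), tm, mode = "eq1"))
  r2 <- enrich_all(enrichment_input(universe, de, character(), tm,
                                    mode = "eq2_combined"))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("enrich_all sorts deterministically and applies alpha", {
  universe <- paste0("g", 1:30)
  tm <- term_map(list(T_hit = paste0("g", 1:5), T_bg = paste0("g", 20:24)),
                 namespace = "custom")
  de <- paste0("g", 1:5)
  res <- enrich_all(enrichment_input(universe, de, character(), tm, mode = "eq1"))
  expect_equal(res$term_id[1], "T_hit")
  expect_true(res$significant[1])
  expect_false(res$significant[res$term_id == "T_bg"])

  all_sig <- enrich_all(enrichment_input(universe, de, character(), tm,
                                         alpha = 1, mode = "eq1"))
  expect_true(all(all_sig$significant))

  none <- enrich_all(enrichment_input(universe, character(), character(), tm,
                                      mode = "eq1"))
  expect_equal(none$p_value, c(1, 1))
  expect_false(any(none$significant))
})

test_that("enrich_all is invariant to gene-set order and supports BH", {
  withr::local_seed(73)
  universe <- paste0("g", 1:40)
  tm <- term_map(list(A = sample(universe, 8), B = sample(universe, 12)),
                 namespace = "GO")
  de <- sample(universe, 10)
  r1 <- enrich_all(enrichment_input(universe, de, character(), tm))
  tm2 <- term_map(lapply(tm$map, rev), namespace = "GO")
  r2 <- enrich_all(enrichment_input(rev(universe), sample(de), character(), tm2))
  expect_equal(r1$p_value, r2$p_value)

  bh <- enrich_all(enrichment_input(universe, de, character(), tm), adjust = "BH")
  expect_equal(bh$p_adjusted, stats::p.adjust(bh$p_value, "BH"))
})

test_that("terms empty after universe intersection get p = 1", {
  tm <- term_map(list(T1 = c("zz1", "zz2")), namespace = "custom")
  inp <- enrichment_input(paste0("g", 1:10), "g1", character(), tm)
  res <- enrich_term("T1", inp)
  expect_equal(res$K, 0L)
  expect_equal(res$p_value, 1)
})

test_that("prune_go_parents removes significant ancestors of significant terms", {
  dag <- ontology_dag(c("A", "B", "C", "D"),
                      data.frame(child = c("B", "C"), parent = c("A", "B"),
                                 relation = "is_a"))
  res <- data.frame(term_id = c("A", "B", "C", "D"),
                    significant = c(TRUE, FALSE, TRUE, TRUE), pruned = FALSE)
  # chain C is_a B is_a A: A is a transitive ancestor of significant C
  out <- prune_go_parents(res, dag)
  expect_equal(out$pruned, c(TRUE, FALSE, FALSE, FALSE))
  # direct-only mode leaves the grandparent alone (B is not significant)
  out <- prune_go_parents(res, dag, transitive = FALSE)
  expect_equal(out$pruned, c(FALSE, FALSE, FALSE, FALSE))

  res2 <- data.frame(term_id = c("A", "B"), significant = TRUE, pruned = FALSE)
  out2 <- prune_go_parents(res2, dag)
  expect_equal(out2$pruned, c(TRUE, FALSE))

  # disjoint significant terms survive untouched
  res3 <- data.frame(term_id = c("A", "D"), significant = TRUE, pruned = FALSE)
  expect_equal(prune_go_parents(res3, dag)$pruned, c(FALSE, FALSE))
})

test_that("pruning keeps exactly the most specific significant terms", {
  withr::local_seed(83)
  for (rep in 1:20) {
    dag <- random_dag(sample(5:50, 1))
    res <- data.frame(term_id = dag$terms,
                      significant = stats::runif(length(dag$terms)) < 0.4,
                      pruned = FALSE)
    out <- prune_go_parents(res, dag)
    kept <- out$term_id[out$significant & !out$pruned]
    gone <- out$term_id[out$pruned]
    for (t in kept)
      expect_length(intersect(naive_ancestors(dag$edges, t), kept), 0)
    for (t in gone) {
      desc <- dag$terms[vapply(dag$terms, function(u)
        t %in% naive_ancestors(dag$edges, u), logical(1))]
      expect_true(length(intersect(desc, out$term_id[out$significant])) > 0)
    }
  }
})
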