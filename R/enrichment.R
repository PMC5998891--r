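#' Upper tail of the hypergeometric distribution
#'
#' The classical over-representation p-value: the probability of drawing at
#' least `i` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation,
#' \deqn{P(X \ge i) = \sum_{k=i}^{\min(n,K)} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.}
#' Returns 1 at `i = 0` and 0 when `i > min(n, K)`.  Evaluated through
#' [stats::phyper()], which works in log space and is safe for `N` up to
#' 1e5 and beyond.
#'
#' @param N universe size.
#' @param n number of drawn (DE) genes, `0 <= n <= N`.
#' @param K number of annotated genes in the universe, `0 <= K <= N`.
#' @param i minimum number of annotated genes among the drawn.
#' @return `P(X >= i)`.
#' @export
hypergeom_tail <- function(N, n, K, i) {
  N <- assert_count(N, "N"); n <- assert_count(n, "n")
  K <- assert_count(K, "K"); i <- assert_count(i, "i")
  if (K > N) config_error("need K <= N")
  if (n > N) config_error("need n <= N")
  if (i == 0L) return(1)
  stats::phyper(i - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' lncGene-augmented hypergeometric tail
#'
#' Extends the classical tail with `r` additional associated genes
#' (lncGenes) joining the draw.  The series form is
#' \deqn{P_j = \sum_{k=i}^{\min(n+r,K)} \frac{\binom{K}{k+r}\binom{N-K}{(n+r)-(k+r)}}{\binom{N}{n+r}},}
#' where out-of-support terms (`k + r > K`) contribute 0.  Algebraically
#' this equals the substituted form `hypergeom_tail(N, n + r, K, i + r)`,
#' which is the default evaluation route; `form = "series"` evaluates the
#' printed series literally in log space (both agree to 1e-12 and the
#' equality is asserted in the test suite).  With `r = 0` the statistic
#' reduces exactly to [hypergeom_tail()].
#'
#' @inheritParams hypergeom_tail
#' @param r number of lncGenes joining the draw; `n + r <= N`.
#' @param form evaluation route: `"substituted"` (default) or `"series"`.
#' @return the tail probability.
#' @export
eq2_tail <- function(N, n, K, i, r, form = c("substituted", "series")) {
  form <- match.arg(form)
  N <- assert_count(N, "N"); n <- assert_count(n, "n")
  K <- assert_count(K, "K"); i <- assert_count(i, "i")
  r <- assert_count(r, "r")
  if (K > N) config_error("need K <= N")
  if (n + r > N) config_error("need n + r <= N")
  if (form == "substituted") return(hypergeom_tail(N, n + r, K, i + r))
  hi <- min(n + r, K)
  if (i > hi) return(0)
  k <- seq.int(i, hi)
  # lchoose returns -Inf outside the support, so invalid terms vanish
  lt <- lchoose(K, k + r) + lchoose(N - K, (n + r) - (k + r)) - lchoose(N, n + r)
  sum(exp(lt))
}

#' Assemble the inputs of an enrichment run
#'
#' @param universe character vector of background gene ids (size `N`).
#' @param de_genes DE gene ids; clipped to the universe (size `n`).
#' @param lncgenes lncGene ids entering the augmented draw, after
#'   deduplication against `de_genes` (size `r`); also clipped to the
#'   universe.  May be a [derive_lncgenes()] result.
#' @param term_map a [term_map()].
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param mode `"eq1"` (DE genes only), `"eq2_combined"` (combined draw
#'   `n + r`, combined observed count; the default augmented mode) or
#'   `"eq2_printed"` (the literal augmented series: the global `r` shifts
#'   every term's tail start regardless of per-term lncGene hits).
#' @return object of class `enrichment_input`.
#' @export
enrichment_input <- function(universe, de_genes, lncgenes = character(),
                             term_map, alpha = 0.05,
                             mode = c("eq1", "eq2_combined", "eq2_printed")) {
  mode <- match.arg(mode)
  if (inherits(lncgenes, "lncgene_set")) lncgenes <- lncgenes$genes
  if (!inherits(term_map, "term_map")) config_error("term_map must be a term_map")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    config_error("alpha must be in [0, 1]")
  universe <- unique(as.character(universe))
  de_genes <- intersect(unique(as.character(de_genes)), universe)
  lncgenes <- intersect(unique(as.character(lncgenes)), universe)
  overlap <- intersect(de_genes, lncgenes)
  if (length(overlap)) {
    lnc_log("removing %d gene(s) present in both DE and lncGene sets from lncgenes",
            length(overlap), level = "WARN")
    lncgenes <- setdiff(lncgenes, de_genes)
  }
  structure(list(universe = universe, de_genes = de_genes,
                 lncgenes = lncgenes, term_map = term_map,
                 alpha = alpha, mode = mode),
            class = "enrichment_input")
}

#' Enrichment statistics for one term
#'
#' Counts `K` (term genes in the universe), `k_de` (DE genes in the term)
#' and `k_lnc` (lncGenes in the term) by exact set intersection, then
#' computes the tail p-value for the input's mode: `eq1` uses
#' `hypergeom_tail(N, n, K, k_de)`; `eq2_printed` uses
#' `eq2_tail(N, n, K, k_de, r)`; `eq2_combined` uses
#' `hypergeom_tail(N, n + r, K, k_de + k_lnc)`.  A term with `K = 0` after
#' universe intersection gets `p = 1` with a logged warning.
#'
#' @param term_id a term of the input's term map.
#' @param input an [enrichment_input()].
#' @return one-row `data.frame`: `term_id`, `label`, `namespace`, `N`, `n`,
#'   `r`, `K`, `k_de`, `k_lnc`, `p_value`, `significant`, `pruned`, `mode`.
#' @export
enrich_term <- function(term_id, input) {
  stopifnot(inherits(input, "enrichment_input"))
  tm <- input$term_map
  if (!term_id %in% names(tm$map))
    config_error(sprintf("term not in map: %s", term_id))
  genes <- intersect(tm$map[[term_id]], input$universe)
  N <- length(input$universe); n <- length(input$de_genes)
  r <- length(input$lncgenes)
  K <- length(genes)
  k_de <- length(intersect(genes, input$de_genes))
  k_lnc <- length(intersect(genes, input$lncgenes))
  p <- if (K == 0L) {
    lnc_log("term %s has no genes in the universe; p = 1", term_id, level = "WARN")
    1
  } else switch(input$mode,
    eq1          = hypergeom_tail(N, n, K, k_de),
    eq2_printed  = eq2_tail(N, n, K, k_de, r),
    eq2_combined = hypergeom_tail(N, n + r, K, k_de + k_lnc))
  label <- if (!is.null(tm$labels) && term_id %in% names(tm$labels))
    unname(tm$labels[term_id]) else NA_character_
  data.frame(term_id = term_id, label = label, namespace = tm$namespace,
             N = N, n = n, r = r, K = K, k_de = k_de, k_lnc = k_lnc,
             p_value = p, significant = p <= input$alpha, pruned = FALSE,
             mode = input$mode, stringsAsFactors = FALSE)
}

#' Enrichment statistics for every term of a map
#'
#' One row per term, sorted by ascending p-value with deterministic
#' tie-breaking (p, then K descending, then term_id).  Significance uses the
#' raw p-value (`p <= alpha`) by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg adjusted column and flags significance on it instead.
#'
#' @param input an [enrichment_input()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` of per-term results (see [enrich_term()]); with
#'   `adjust = "BH"` an extra `p_adjusted` column.
#' @export
enrich_all <- function(input, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(input, "enrichment_input"))
  terms <- names(input$term_map$map)
  if (!length(terms)) config_error("term map is empty")
  res <- do.call(rbind, lapply(terms, enrich_term, input = input))
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted <= input$alpha
  }
  res <- res[order(res$p_value, -res$K, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  lnc_log("enrich_all[%s/%s]: %d term(s), %d significant at alpha = %g",
          input$term_map$namespace, input$mode, nrow(res),
          sum(res$significant), input$alpha)
  res
}

#' Prune redundant significant GO parents
#'
#' Among significant terms, any term that is a proper ancestor (transitive
#' closure over the DAG, or direct parents only with
#' `transitive = FALSE`) of another significant term is flagged
#' `pruned = TRUE`, keeping the most specific annotations.  Non-significant
#' terms are untouched; results whose term is absent from the DAG pass
#' through unpruned with a logged warning.  The returned table is complete
#' -- callers filter on the flags.
#'
#' @param results `data.frame` from [enrich_all()].
#' @param dag an [ontology_dag()].
#' @param transitive prune any significant ancestor (default) rather than
#'   direct parents only.
#' @param relations edge relations to traverse (default: all in the DAG).
#' @return `results` with the `pruned` column filled in.
#' @export
prune_go_parents <- function(results, dag, transitive = TRUE, relations = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  results$pruned <- FALSE
  sig <- results$term_id[results$significant]
  known <- sig[sig %in% dag$terms]
  if (length(known) < length(sig))
    lnc_log("%d significant term(s) absent from the ontology pass through unpruned",
            length(sig) - length(known), level = "WARN")
  up <- character(0)
  for (t in known) {
    anc <- if (transitive) dag_ancestors(dag, t, relations) else {
      ed <- dag$edges
      if (!is.null(relations)) ed <- ed[ed$relation %in% relations, , drop = FALSE]
      unique(ed$parent[ed$child == t])
    }
    up <- union(up, intersect(anc, known))
  }
  results$pruned <- results$term_id %in% up
  lnc_log("pruned %d redundant significant parent term(s)", length(up))
  results
}
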