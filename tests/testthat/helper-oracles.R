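# Shared helpers: independent brute-force oracles and tiny fixture builders.
# Oracles deliberately avoid the code paths they check.

options(lncora.quiet = TRUE)

# P(X >= i) for X ~ hypergeometric(N, K, n) by exhaustive enumeration of all
# C(N, n) equally likely draws from the universe 1..N with genes 1..K
# annotated.  Valid for small N only.
enum_hyper_tail <- function(N, n, K, i) {
  if (n == 0L) return(as.numeric(i <= 0L))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # annotated genes are 1..K
  mean(hits >= i)
}

# Ancestors by naive repeated edge-following over the raw edge list.
naive_ancestors <- function(edges, term) {
  acc <- character(0)
  frontier <- term
  repeat {
    up <- unique(edges$parent[edges$child %in% frontier])
    up <- setdiff(up, c(acc, term))
    if (!length(up)) break
    acc <- c(acc, up)
    frontier <- up
  }
  acc
}

# All-pairs association scan with its own distance arithmetic: explicit
# overlap test, then nearest-end gap.
brute_associations <- function(lncrnas, genes, window) {
  out <- list()
  for (i in seq_len(nrow(lncrnas))) for (j in seq_len(nrow(genes))) {
    if (lncrnas$chrom[i] != genes$chrom[j]) next
    overlap <- lncrnas$start[i] <= genes$end[j] && genes$start[j] <= lncrnas$end[i]
    d <- if (overlap) 0L else min(abs(genes$start[j] - lncrnas$end[i]),
                                  abs(lncrnas$start[i] - genes$end[j]))
    if (d <= window)
      out[[length(out) + 1L]] <- data.frame(lncrna_id = lncrnas$feature_id[i],
                                            gene_id = genes$feature_id[j],
                                            distance = d)
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = integer()))
  res <- do.call(rbind, out)
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}

random_features <- function(n, prefix, chroms = 3L, span_max = 2e5) {
  start <- sample.int(span_max, n, replace = TRUE)
  features(paste0(prefix, seq_len(n)),
           chrom = paste0("chr", sample.int(chroms, n, replace = TRUE)),
           start = start, end = start + sample.int(3000, n, replace = TRUE),
           strand = sample(c("+", "-", "."), n, replace = TRUE),
           biotype = if (prefix == "G") "protein_coding" else "lncRNA")
}

# Random DAG: each node may take parents among lower-numbered nodes, which
# guarantees acyclicity.
random_dag <- function(n_nodes, p_edge = 0.15) {
  terms <- sprintf("T%02d", seq_len(n_nodes))
  edges <- list()
  for (i in seq_len(n_nodes)[-1]) {
    parents <- which(stats::runif(i - 1L) < p_edge)
    if (length(parents))
      edges[[length(edges) + 1L]] <- data.frame(child = terms[i],
                                                parent = terms[parents],
                                                relation = "is_a")
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(), relation = character())
  ontology_dag(terms, ed)
}

# Two-condition expression table from a named list of
# list(case = c(...), control = c(...)) replicate vectors.
toy_expression <- function(rows) {
  fpkm <- t(vapply(rows, function(r) c(r$case, r$control),
                   numeric(length(rows[[1]]$case) + length(rows[[1]]$control))))
  nc <- length(rows[[1]]$case); nw <- length(rows[[1]]$control)
  colnames(fpkm) <- c(paste0("case_", seq_len(nc)), paste0("control_", seq_len(nw)))
  rownames(fpkm) <- names(rows)
  expression_table(fpkm, stats::setNames(rep(c("case", "control"), c(nc, nw)),
                                         colnames(fpkm)))
}
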