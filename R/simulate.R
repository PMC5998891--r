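#' Configuration for the synthetic-data generator
#'
#' The generator emulates the study design the method assumes: a
#' two-condition (knock-down vs. wild-type) experiment with two replicates
#' per condition, FPKM-scale expression, a genome where lncRNAs sit at
#' controlled distances from protein-coding genes, and GO/KEGG-style term
#' maps with planted enriched terms -- including terms annotated only to
#' lncGenes, the scenario the augmented statistic exists for.
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @param n_genes,n_lncrnas feature counts (defaults desk-scale stand-ins
#'   for a vertebrate annotation).
#' @param n_chroms number of chromosomes features are spread over.
#' @param placement_mix named fractions (`overlapping`, `within_window`,
#'   `beyond_window`) describing where lncRNAs land relative to their target
#'   gene; must sum to 1.
#' @param window_bp association window (default 5000, the method default).
#' @param n_de_genes,n_de_lncrnas planted DE feature counts.
#' @param de_fold planted fold change (> the 1.5 calling threshold).
#' @param replicate_cv multiplicative replicate noise, as a coefficient of
#'   variation; interacts with the 15% variability filter.
#' @param n_replicates replicates per condition (default 2, as in the
#'   emulated design).
#' @param n_terms number of background terms per namespace.
#' @param term_size_range inclusive (min, max) genes per term.
#' @param planted_terms list of `list(term_id=, fraction_from_de=,
#'   fraction_from_lncgenes=, size=)` describing enriched terms to plant.
#'   The default plants one DE-driven term and one lncGene-only term.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L, n_lncrnas = 300L, n_chroms = 5L,
                              placement_mix = c(overlapping = 0.2,
                                                within_window = 0.5,
                                                beyond_window = 0.3),
                              window_bp = 5000L,
                              n_de_genes = 120L, n_de_lncrnas = 80L,
                              de_fold = 3, replicate_cv = 0.10,
                              n_replicates = 2L,
                              n_terms = 40L, term_size_range = c(10L, 40L),
                              planted_terms = NULL) {
  if (abs(sum(placement_mix) - 1) > 1e-9)
    config_error("placement_mix fractions must sum to 1")
  if (!all(c("overlapping", "within_window", "beyond_window") %in% names(placement_mix)))
    config_error("placement_mix needs overlapping/within_window/beyond_window")
  if (de_fold <= 1) config_error("de_fold must be > 1")
  if (replicate_cv < 0) config_error("replicate_cv must be >= 0")
  if (n_de_genes > n_genes || n_de_lncrnas > n_lncrnas)
    config_error("cannot plant more DE features than features")
  if (is.null(planted_terms))
    planted_terms <- list(
      list(term_id = "T:PLANT_DE", fraction_from_de = 0.8,
           fraction_from_lncgenes = 0, size = 10L),
      list(term_id = "T:PLANT_LNC", fraction_from_de = 0,
           fraction_from_lncgenes = 0.8, size = 10L))
  for (pt in planted_terms) {
    if (pt$fraction_from_de < 0 || pt$fraction_from_de > 1 ||
        pt$fraction_from_lncgenes < 0 || pt$fraction_from_lncgenes > 1)
      config_error("planted fractions must be in [0, 1]")
    if ((pt$size %||% 0) < 1) config_error("planted term size must be >= 1")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_lncrnas = as.integer(n_lncrnas), n_chroms = as.integer(n_chroms),
                 placement_mix = placement_mix, window_bp = as.integer(window_bp),
                 n_de_genes = as.integer(n_de_genes),
                 n_de_lncrnas = as.integer(n_de_lncrnas),
                 de_fold = de_fold, replicate_cv = replicate_cv,
                 n_replicates = as.integer(n_replicates),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 planted_terms = planted_terms),
            class = "simulation_config")
}

# Sub-seeds per stage keep stages independently reproducible while remaining
# a pure function of config$seed.  Offsets stay far below 2^31.
stage_seed <- function(config, stage) {
  config$seed + c(annotations = 1000L, expression = 2000L, terms = 3000L)[[stage]]
}

#' Simulate gene and lncRNA annotations with controlled geometry
#'
#' Genes are placed non-overlapping along each chromosome with inter-gene
#' gaps of at least 8x the window, so every lncRNA's distance to its one
#' target gene is exact and unambiguous.  Each lncRNA picks a target gene
#' and a placement class from `placement_mix`: `overlapping` (distance 0),
#' `within_window` (distance uniform in [1, window]), or `beyond_window`
#' (distance uniform in (window, 3*window], invisible to the association
#' scan).  Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genes` and `lncrnas` feature tables and `truth`, a
#'   `data.frame` (lncrna_id, gene_id, placement, distance, side).
#' @export
simulate_annotations <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "annotations"), {
    w <- config$window_bp
    gene_len <- sample(500:5000, config$n_genes, replace = TRUE)
    gap <- sample((8L * w):(10L * w), config$n_genes, replace = TRUE)
    chrom <- sort(rep_len(seq_len(config$n_chroms), config$n_genes))
    start <- integer(config$n_genes)
    pos <- stats::setNames(rep(1L, config$n_chroms), seq_len(config$n_chroms))
    for (i in seq_len(config$n_genes)) {
      start[i] <- pos[[chrom[i]]] + gap[i]
      pos[[chrom[i]]] <- start[i] + gene_len[i]
    }
    genes <- features(sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = paste0("chr", chrom), start = start,
                      end = start + gene_len - 1L,
                      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                      biotype = "protein_coding")

    placement <- sample(names(config$placement_mix), config$n_lncrnas,
                        replace = TRUE, prob = config$placement_mix)
    target <- sample.int(config$n_genes, config$n_lncrnas, replace = TRUE)
    lnc_len <- sample(200:2000, config$n_lncrnas, replace = TRUE)
    side <- sample(c("left", "right"), config$n_lncrnas, replace = TRUE)
    dist <- integer(config$n_lncrnas)
    ls <- integer(config$n_lncrnas)
    for (i in seq_len(config$n_lncrnas)) {
      g <- target[i]
      d <- switch(placement[i],
                  overlapping = 0L,
                  within_window = sample.int(w, 1L),
                  beyond_window = w + sample.int(2L * w, 1L))
      dist[i] <- d
      ls[i] <- if (placement[i] == "overlapping") {
        # start inside the gene span so the intervals always intersect
        genes$start[g] + sample.int(gene_len[g], 1L) - 1L
      } else if (side[i] == "left") {
        # lnc end = gene start - d, so the nearest-end gap is exactly d
        genes$start[g] - d - lnc_len[i] + 1L
      } else {
        genes$end[g] + d
      }
      ls[i] <- max(ls[i], 1L)   # clamp at chromosome origin (distance shrinks only off-target)
    }
    lncrnas <- features(sprintf("L%04d", seq_len(config$n_lncrnas)),
                        chrom = genes$chrom[target], start = ls,
                        end = ls + lnc_len - 1L, strand = ".",
                        biotype = "lncRNA")
    truth <- data.frame(lncrna_id = lncrnas$feature_id,
                        gene_id = genes$feature_id[target],
                        placement = placement, distance = dist,
                        side = side, stringsAsFactors = FALSE)
    list(genes = genes, lncrnas = lncrnas, truth = truth)
  })
}

#' Simulate a two-condition replicate FPKM table with planted DE
#'
#' Baseline expression is log-normal (median ~10 FPKM).  Features planted
#' as DE have their case-condition mean multiplied (up) or divided (down)
#' by `de_fold`, split half and half; planted features draw baselines of at
#' least twice the default 1-FPKM floor so that under noiseless settings
#' (`replicate_cv = 0`) the filter recovers the planted sets exactly.
#' Replicate noise is multiplicative log-normal with the configured CV,
#' mean-preserving.  Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param ann result of [simulate_annotations()] (provides feature ids).
#' @return list with `expression` (an `expression_table` holding genes and
#'   lncRNAs together), `de_genes`, `de_lncrnas` (planted id vectors), and
#'   `directions` (named up/down per planted feature).
#' @export
simulate_expression <- function(config, ann) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "expression"), {
    ids <- c(ann$genes$feature_id, ann$lncrnas$feature_id)
    nf <- length(ids)
    base <- stats::rlnorm(nf, meanlog = log(10), sdlog = 1)
    de_genes <- sort(sample(ann$genes$feature_id, config$n_de_genes))
    de_lncrnas <- sort(sample(ann$lncrnas$feature_id, config$n_de_lncrnas))
    planted <- c(de_genes, de_lncrnas)
    base[match(planted, ids)] <- pmax(base[match(planted, ids)], 2)
    dir <- rep_len(c("up", "down"), length(planted))
    names(dir) <- planted

    mean_ctrl <- base
    mean_case <- base
    pi <- match(planted, ids)
    mean_case[pi] <- ifelse(dir == "up", base[pi] * config$de_fold,
                            base[pi] / config$de_fold)

    nrep <- config$n_replicates
    noisy <- function(mu) {
      if (config$replicate_cv == 0) return(mu)
      sdlog <- sqrt(log(1 + config$replicate_cv^2))
      mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    cols <- c(paste0("case_", seq_len(nrep)), paste0("control_", seq_len(nrep)))
    fpkm <- cbind(
      vapply(seq_len(nrep), function(j) noisy(mean_case), numeric(nf)),
      vapply(seq_len(nrep), function(j) noisy(mean_ctrl), numeric(nf)))
    dimnames(fpkm) <- list(ids, cols)
    conditions <- stats::setNames(rep(c("case", "control"), each = nrep), cols)
    list(expression = expression_table(fpkm, conditions),
         de_genes = de_genes, de_lncrnas = de_lncrnas, directions = dir)
  })
}

#' Simulate GO/KEGG-style term maps with planted enriched terms
#'
#' Background terms draw members uniformly from the gene universe.  Each
#' planted term draws `round(fraction_from_de * size)` members from the
#' true DE genes and `round(fraction_from_lncgenes * size)` from the true
#' lncGenes (targets of DE lncRNAs placed overlapping/within window, minus
#' DE genes), padded to size with background genes annotated to neither
#' pool.  A toy ontology is built over the GO-namespace terms: every term
#' is_a a common root, and each planted term additionally gets a dedicated
#' parent term annotated to a superset of its genes, so parent pruning has
#' something to do.  Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param ann result of [simulate_annotations()].
#' @param expr result of [simulate_expression()].
#' @return list with `go_map`, `kegg_map` (term_maps), `dag`
#'   (`ontology_dag` over the GO terms), `lncgenes` (true lncGene ids after
#'   DE subtraction), and `expected`, a `data.frame` of per-planted-term
#'   analytic detectability (counts plus eq1/eq2_combined p-values).
#' @export
simulate_term_maps <- function(config, ann, expr) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "terms"), {
    universe <- ann$genes$feature_id
    assoc_truth <- ann$truth[ann$truth$placement %in% c("overlapping", "within_window") &
                               ann$truth$lncrna_id %in% expr$de_lncrnas, ]
    lncgenes <- sort(setdiff(unique(assoc_truth$gene_id), expr$de_genes))
    de <- intersect(expr$de_genes, universe)

    rand_term <- function(size) sort(sample(universe, size))
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    go <- lapply(sizes, rand_term)
    names(go) <- sprintf("T:%04d", seq_len(config$n_terms))

    neutral <- setdiff(universe, c(de, lncgenes))
    expected <- list()
    for (pt in config$planted_terms) {
      size <- as.integer(pt$size)
      n_de <- round(pt$fraction_from_de * size)
      n_ln <- round(pt$fraction_from_lncgenes * size)
      if (n_de > length(de) || n_ln > length(lncgenes))
        config_error(sprintf("planted term %s wants more members than available",
                             pt$term_id))
      members <- c(sample(de, n_de), sample(lncgenes, n_ln),
                   sample(neutral, size - n_de - n_ln))
      go[[pt$term_id]] <- sort(members)
      N <- length(universe); n <- length(de); r <- length(lncgenes)
      expected[[pt$term_id]] <- data.frame(
        term_id = pt$term_id, K = size, k_de = n_de, k_lnc = n_ln,
        N = N, n = n, r = r,
        p_eq1 = hypergeom_tail(N, n, size, n_de),
        p_eq2_combined = hypergeom_tail(N, n + r, size, n_de + n_ln),
        stringsAsFactors = FALSE)
    }
    expected <- do.call(rbind, c(expected, list(make.row.names = FALSE)))
    expected$expect_sig_eq1 <- expected$p_eq1 <= 0.05
    expected$expect_sig_eq2_combined <- expected$p_eq2_combined <= 0.05

    # ontology: shared root; planted terms get a significant-able parent
    edges <- data.frame(child = names(go), parent = "T:ROOT", relation = "is_a")
    labels <- stats::setNames(names(go), names(go))
    for (pt in config$planted_terms) {
      par_id <- paste0(pt$term_id, "_PARENT")
      pad <- sample(neutral, min(5L, length(neutral)))
      go[[par_id]] <- sort(unique(c(go[[pt$term_id]], pad)))
      edges <- rbind(edges,
                     data.frame(child = par_id, parent = "T:ROOT", relation = "is_a"))
      edges$parent[edges$child == pt$term_id] <- par_id
    }
    # the root annotates everything so it is never spuriously enriched
    go[["T:ROOT"]] <- universe
    dag <- ontology_dag(c("T:ROOT", names(go)), edges)
    attr(dag, "labels") <- labels

    kegg_sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                         max(5L, config$n_terms %/% 4L), replace = TRUE)
    kegg <- lapply(kegg_sizes, rand_term)
    names(kegg) <- sprintf("path:%04d", seq_along(kegg))

    list(go_map = term_map(go, namespace = "GO"),
         kegg_map = term_map(kegg, namespace = "KEGG"),
         dag = dag, lncgenes = lncgenes, expected = expected)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the three generator stages and writes `genes.gtf`, `lncrnas.gtf`,
#' `expression.tsv`, `conditions.tsv`, `go_map.tsv`, `kegg_map.tsv`,
#' `ontology.obo`, `truth/*.tsv` and `manifest.json` under `dir`.  All
#' outputs are plain text and byte-identical across reruns with the same
#' config.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; the in-memory dataset as attribute `"dataset"`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ann <- simulate_annotations(config)
  expr <- simulate_expression(config, ann)
  terms <- simulate_term_maps(config, ann, expr)

  write_gtf(ann$genes, file.path(dir, "genes.gtf"))
  write_gtf(ann$lncrnas, file.path(dir, "lncrnas.gtf"))
  write_expression(expr$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "conditions.tsv"))
  write_term_map(terms$go_map, file.path(dir, "go_map.tsv"))
  write_term_map(terms$kegg_map, file.path(dir, "kegg_map.tsv"))
  write_obo(terms$dag, file.path(dir, "ontology.obo"))

  write_tsv(data.frame(gene_id = expr$de_genes,
                       direction = unname(expr$directions[expr$de_genes])),
            file.path(dir, "truth", "de_genes.tsv"))
  write_tsv(data.frame(lncrna_id = expr$de_lncrnas,
                       direction = unname(expr$directions[expr$de_lncrnas])),
            file.path(dir, "truth", "de_lncrnas.tsv"))
  write_tsv(ann$truth, file.path(dir, "truth", "lncrna_placements.tsv"))
  write_tsv(data.frame(gene_id = terms$lncgenes),
            file.path(dir, "truth", "lncgenes.tsv"))
  write_tsv(terms$expected, file.path(dir, "truth", "planted_terms.tsv"))

  manifest <- unclass(config)
  manifest$placement_mix <- as.list(manifest$placement_mix)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- dir
  attr(out, "dataset") <- list(ann = ann, expr = expr, terms = terms)
  invisible(out)
}
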