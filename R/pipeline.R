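#' Parse a pipeline run configuration file
#'
#' The config is a flat `key = value` text file (`#` comments and blank
#' lines ignored; `[section]` headers allowed and ignored).  Recognised
#' keys: `genes_gtf`, `lncrnas_gtf`, `expression`, `conditions`, `go_map`,
#' `go_map_format` (tsv/gaf), `kegg_map`, `obo`, `out_dir`, `window_bp`,
#' `alpha`, `modes` (comma-separated subset of eq1, eq2_printed,
#' eq2_combined), `universe` (annotated/expressed), `fold_change_threshold`,
#' `min_fpkm`, `max_replicate_cv`, `dedup` (subtract_de/keep_all).
#' Overrides given as a named list take precedence over the file.
#'
#' @param path config file (may be `NULL` when everything comes from
#'   `overrides`).
#' @param overrides named list of key-value overrides.
#' @return object of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|\\[|$)", lines)]
    for (ln in lines) {
      parts <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
      if (length(parts) < 3L)
        config_error(sprintf("cannot parse config line: %s", ln))
      kv[[parts[2]]] <- parts[3]
    }
  }
  kv[names(overrides)] <- overrides
  num <- function(key, default) as.numeric(kv[[key]] %||% default)
  chr <- function(key, default = NULL) {
    v <- kv[[key]] %||% default
    if (is.null(v)) NULL else as.character(v)
  }
  modes <- strsplit(chr("modes", "eq1,eq2_combined"), ",")[[1]]
  modes <- trimws(modes)
  bad <- setdiff(modes, c("eq1", "eq2_printed", "eq2_combined"))
  if (length(bad)) config_error(sprintf("unknown mode(s): %s", paste(bad, collapse = ", ")))
  cfg <- structure(list(
    genes_gtf = chr("genes_gtf"), lncrnas_gtf = chr("lncrnas_gtf"),
    expression = chr("expression"), conditions = chr("conditions"),
    go_map = chr("go_map"), go_map_format = chr("go_map_format", "tsv"),
    kegg_map = chr("kegg_map"), obo = chr("obo"),
    out_dir = chr("out_dir", "lncora_run"),
    window_bp = num("window_bp", 5000), alpha = num("alpha", 0.05),
    modes = modes, universe = chr("universe", "annotated"),
    dedup = chr("dedup", "subtract_de"),
    de = de_config(fold_change_threshold = num("fold_change_threshold", 1.5),
                   min_fpkm = num("min_fpkm", 1),
                   max_replicate_cv = num("max_replicate_cv", 0.15))
  ), class = "run_config")
  if (!cfg$universe %in% c("annotated", "expressed"))
    config_error("universe must be 'annotated' or 'expressed'")
  need <- c("genes_gtf", "lncrnas_gtf", "expression", "conditions", "go_map")
  for (key in need)
    if (is.null(cfg[[key]])) config_error(sprintf("config key '%s' is required", key))
  for (key in c(need, "kegg_map", "obo"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      config_error(sprintf("config file for '%s' not found: %s", key, cfg[[key]]))
  cfg
}

# Stable content hash of the effective configuration, carried by every
# output so runs are attributable; pure function of the analytic config
# values (the output directory is deliberately excluded so reruns into a
# different directory stay byte-identical).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- unlist(cfg[setdiff(names(cfg), c("de", "out_dir"))], use.names = TRUE)
  flat <- c(flat, unlist(cfg$de[c("fold_change_threshold", "min_fpkm",
                                  "max_replicate_cv", "cv_scope")]))
  writeLines(paste(names(flat), flat, sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: parse annotations and expression; DE-filter genes and
#' lncRNAs (shared code path, one config); associate DE lncRNAs with genes
#' within the window and derive lncGenes; per-namespace, per-mode
#' enrichment; GO parent pruning (when an ontology is supplied); and a
#' cross-mode comparison.  All outputs are TSV/JSON under `out_dir`, each
#' TSV headed by a `# lncora_config_hash=` comment; a rerun on identical
#' inputs is byte-identical.  Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`de_genes`, `de_lncrnas`, `associations`, `lncgenes`, `enrichment`,
#'   `comparison`, `hash`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  emit <- function(df, name) {
    path <- out(name)
    con <- file(path, "w")
    writeLines(sprintf("# lncora_config_hash=%s", hash), con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = TRUE,
                                        append = TRUE))
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, lncora_config_error = function(e) stop(e),
             error = function(e) {
               if (inherits(e, "lncora_stage_error")) stop(e)
               stage_error(conditionMessage(e), stage = stage)
             })
  }

  ann <- run_stage("annotations", {
    list(genes = parse_gtf(config$genes_gtf, "protein_coding"),
         lncrnas = parse_gtf(config$lncrnas_gtf, "lncRNA"))
  })

  de <- run_stage("diffexp", {
    expr <- read_expression(config$expression, config$conditions)
    ids <- rownames(expr$fpkm)
    gene_rows <- ids %in% ann$genes$feature_id
    lnc_rows <- ids %in% ann$lncrnas$feature_id
    orphan <- sum(!gene_rows & !lnc_rows)
    if (orphan)
      lnc_log("%d expression row(s) match neither annotation", orphan, level = "WARN")
    subtab <- function(rows) expression_table(expr$fpkm[rows, , drop = FALSE],
                                              expr$conditions)
    de_genes <- filter_de(subtab(gene_rows), config$de)
    de_lncrnas <- filter_de(subtab(lnc_rows), config$de)
    emit(de_genes, "de_genes.tsv")
    emit(de_lncrnas, "de_lncrnas.tsv")
    lnc_log("DE summary: genes %d/%d (up %d, down %d); lncRNAs %d/%d (up %d, down %d)",
            length(de_ids(de_genes)), nrow(de_genes),
            sum(de_genes$status == "de_up"), sum(de_genes$status == "de_down"),
            length(de_ids(de_lncrnas)), nrow(de_lncrnas),
            sum(de_lncrnas$status == "de_up"), sum(de_lncrnas$status == "de_down"))
    list(genes = de_genes, lncrnas = de_lncrnas)
  })

  assoc <- run_stage("associate", {
    de_lnc_features <- ann$lncrnas[ann$lncrnas$feature_id %in% de_ids(de$lncrnas), ,
                                   drop = FALSE]
    a <- find_associations(de_lnc_features, ann$genes, config$window_bp)
    lg <- derive_lncgenes(a, de_genes = de_ids(de$genes), dedup = config$dedup)
    emit(a, "associations.tsv")
    emit(data.frame(gene_id = lg$genes), "lncgenes.tsv")
    lnc_log("lncGenes: %d associated gene(s), r = %d after %s",
            length(lg$all_genes), lg$r, lg$dedup)
    list(associations = a, lncgenes = lg)
  })

  enr <- run_stage("enrich", {
    maps <- list(GO = parse_term_map(config$go_map, config$go_map_format, "GO"))
    if (!is.null(config$kegg_map))
      maps$KEGG <- parse_term_map(config$kegg_map, "tsv", "KEGG")
    results <- list()
    for (ns in names(maps)) {
      universe <- switch(config$universe,
        annotated = intersect(term_universe(maps[[ns]]), ann$genes$feature_id),
        expressed = intersect(term_universe(maps[[ns]]),
                              de$genes$feature_id))
      for (mode in config$modes) {
        inp <- enrichment_input(universe, de_ids(de$genes),
                                assoc$lncgenes, maps[[ns]],
                                alpha = config$alpha, mode = mode)
        results[[ns]][[mode]] <- enrich_all(inp)
      }
    }
    results
  })

  if (!is.null(config$obo)) {
    enr <- run_stage("prune", {
      dag <- parse_obo(config$obo)
      for (mode in names(enr$GO))
        enr$GO[[mode]] <- prune_go_parents(enr$GO[[mode]], dag)
      enr
    })
  }
  run_stage("enrich", for (ns in names(enr)) for (mode in names(enr[[ns]]))
    emit(enr[[ns]][[mode]], sprintf("enrichment_%s_%s.tsv", ns, mode)))

  comparison <- run_stage("compare", {
    cmp <- lapply(enr, function(by_mode)
      if (length(by_mode) >= 2L) compare_modes(by_mode) else NULL)
    rows <- do.call(rbind, lapply(names(cmp), function(ns)
      if (!is.null(cmp[[ns]])) cbind(namespace = ns, cmp[[ns]]$counts)))
    if (!is.null(rows)) emit(rows, "comparison.tsv")
    gained <- do.call(rbind, lapply(names(cmp), function(ns) {
      if (is.null(cmp[[ns]])) return(NULL)
      g <- cmp[[ns]]$gained
      do.call(rbind, lapply(names(g), function(m)
        if (length(g[[m]])) data.frame(namespace = ns, mode = m, term_id = g[[m]])))
    }))
    if (!is.null(gained)) emit(gained, "additionally_detected.tsv")
    cmp
  })

  jsonlite::write_json(list(config_hash = hash, modes = config$modes,
                            universe = config$universe),
                       out("run_info.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotations = ann, de_genes = de$genes, de_lncrnas = de$lncrnas,
                 associations = assoc$associations, lncgenes = assoc$lncgenes,
                 enrichment = enr, comparison = comparison, hash = hash,
                 out_dir = config$out_dir))
}

#' Compare enrichment results across modes
#'
#' Takes per-mode [enrich_all()] results computed on identical inputs and
#' reports, per mode: significant term counts, post-pruning counts, and
#' terms gained/lost relative to the first (reference) mode -- the
#' "additionally detected" sets.
#'
#' @param results_by_mode named list of enrichment result `data.frame`s; the
#'   first entry is the reference (conventionally `eq1`).
#' @return list with `counts` (`data.frame`: mode, n_significant,
#'   n_significant_unpruned, n_gained, n_lost), `gained` and `lost` (named
#'   lists of term id vectors, keyed by mode).
#' @export
compare_modes <- function(results_by_mode) {
  if (length(results_by_mode) < 2L)
    config_error("compare_modes needs results from >= 2 modes")
  Ns <- vapply(results_by_mode, function(df) df$N[1] %||% NA_integer_, numeric(1))
  if (length(unique(Ns)) > 1L)
    config_error("mode results computed over different universes")
  sig_sets <- lapply(results_by_mode, function(df) df$term_id[df$significant])
  ref <- sig_sets[[1]]
  gained <- lapply(sig_sets, function(s) sort(setdiff(s, ref)))
  lost <- lapply(sig_sets, function(s) sort(setdiff(ref, s)))
  counts <- data.frame(
    mode = names(results_by_mode),
    n_significant = lengths(sig_sets),
    n_significant_unpruned = vapply(results_by_mode, function(df)
      sum(df$significant & !df$pruned), integer(1)),
    n_gained = lengths(gained), n_lost = lengths(lost),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, gained = gained, lost = lost)
}
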