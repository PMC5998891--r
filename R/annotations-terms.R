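#' Term-to-gene maps
#'
#' A term map bundles, for each GO term or KEGG pathway, the set of gene
#' identifiers annotated to it.  Identifier matching against expression
#' tables and annotation GTFs is exact, case-sensitive string match; use
#' [apply_id_map()] when the sources disagree on symbols vs. IDs.
#'
#' @param map named list: term_id -> character vector of gene ids.
#' @param labels optional named character vector of human-readable labels.
#' @param namespace `"GO"`, `"KEGG"` or `"custom"`.
#' @return an object of class `term_map`.
#' @export
term_map <- function(map, labels = NULL, namespace = c("GO", "KEGG", "custom")) {
  namespace <- match.arg(namespace)
  if (!length(map)) parse_error("term map is empty")
  if (is.null(names(map)) || any(names(map) == ""))
    parse_error("term map must be a named list (term_id -> gene ids)")
  map <- lapply(map, function(g) sort(unique(as.character(g))))
  if (any(lengths(map) == 0L))
    parse_error("every term's gene set must be non-empty")
  structure(list(map = map, labels = labels, namespace = namespace),
            class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("<term_map> %s: %d terms, %d distinct genes\n",
              x$namespace, length(x$map), length(unique(unlist(x$map)))))
  invisible(x)
}

#' Gene universe of a term map
#'
#' @param tm a `term_map`.
#' @return sorted character vector of all annotated genes.
#' @export
term_universe <- function(tm) {
  stopifnot(inherits(tm, "term_map"))
  sort(unique(unlist(tm$map, use.names = FALSE)))
}

#' Read a term-to-gene map
#'
#' Supports two plain-text formats: a two-column TSV (`term_id <TAB>
#' gene_id`, optional third column with the term label) and GAF 2.x gene
#' association files.  GAF rows carrying a `NOT` qualifier are excluded, as
#' are incomplete rows (both with logged counts).  Duplicate (term, gene)
#' pairs collapse to one.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @param namespace namespace tag for the resulting map.
#' @return a `term_map`.
#' @export
parse_term_map <- function(path, format = c("tsv", "gaf"),
                           namespace = c("GO", "KEGG", "custom")) {
  format <- match.arg(format)
  namespace <- match.arg(namespace)
  if (!file.exists(path)) parse_error(sprintf("term map not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|#|$)", lines)]
  if (!length(lines)) parse_error(sprintf("term map is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    ok <- lengths(fields) >= 2L
    pairs <- data.frame(
      term = vapply(fields[ok], `[[`, "", 1L),
      gene = vapply(fields[ok], `[[`, "", 2L),
      label = vapply(fields[ok], function(f) if (length(f) >= 3L) f[[3]] else NA_character_, ""),
      stringsAsFactors = FALSE
    )
  } else {
    # GAF 2.x: col 2 = DB object ID, col 3 = symbol, col 4 = qualifier,
    # col 5 = GO ID.  We key genes by symbol (col 3), the unit the rest of
    # the toolchain speaks; NOT-qualified rows are negative annotations.
    ok <- lengths(fields) >= 5L
    qual <- vapply(fields[ok], `[[`, "", 4L)
    not <- grepl("(^|\\|)NOT($|\\|)", qual)
    if (any(not)) lnc_log("excluded %d NOT-qualified GAF row(s)", sum(not))
    pairs <- data.frame(
      term = vapply(fields[ok], `[[`, "", 5L)[!not],
      gene = vapply(fields[ok], `[[`, "", 3L)[!not],
      label = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  skipped <- sum(!ok) + sum(pairs$term == "" | pairs$gene == "")
  pairs <- pairs[pairs$term != "" & pairs$gene != "", , drop = FALSE]
  if (skipped) lnc_log("skipped %d malformed term-map row(s)", skipped)
  if (!nrow(pairs)) parse_error(sprintf("no usable rows in term map: %s", path))
  map <- split(pairs$gene, pairs$term)
  lab <- pairs$label[!is.na(pairs$label)]
  labels <- NULL
  if (length(lab)) {
    lt <- pairs[!is.na(pairs$label), c("term", "label")]
    lt <- lt[!duplicated(lt$term), ]
    labels <- stats::setNames(lt$label, lt$term)
  }
  tm <- term_map(map, labels = labels, namespace = namespace)
  lnc_log("parsed %d term(s), %d gene(s) from %s", length(tm$map),
          length(term_universe(tm)), path)
  tm
}

#' Write a term map as two/three-column TSV
#'
#' @param tm a `term_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(tm, path) {
  stopifnot(inherits(tm, "term_map"))
  terms <- rep(names(tm$map), lengths(tm$map))
  genes <- unlist(tm$map, use.names = FALSE)
  if (!is.null(tm$labels)) {
    lab <- unname(tm$labels[terms])
    lab[is.na(lab)] <- ""
    writeLines(paste(terms, genes, lab, sep = "\t"), path)
  } else {
    writeLines(paste(terms, genes, sep = "\t"), path)
  }
  invisible(path)
}

#' Re-key gene identifiers through a two-column mapping file
#'
#' Applies an `old_id <TAB> new_id` translation to every gene set of a term
#' map; genes without a mapping are kept unchanged.  This is the explicit
#' escape hatch for symbol/ID mismatches -- matching is never fuzzy.
#'
#' @param tm a `term_map`.
#' @param path two-column TSV mapping file.
#' @return a re-keyed `term_map`.
#' @export
apply_id_map <- function(tm, path) {
  stopifnot(inherits(tm, "term_map"))
  m <- read_tsv(path, header = FALSE)
  if (ncol(m) < 2L) parse_error("id map needs two columns: old_id <TAB> new_id")
  trans <- stats::setNames(as.character(m[[2]]), as.character(m[[1]]))
  map <- lapply(tm$map, function(g) {
    hit <- g %in% names(trans)
    g[hit] <- unname(trans[g[hit]])
    unique(g)
  })
  term_map(map, labels = tm$labels, namespace = tm$namespace)
}
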