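#' Ontology DAGs
#'
#' An `ontology_dag` stores directed child -> parent edges between term
#' identifiers (GO-style `is_a`, optionally `part_of`).  The graph must be
#' acyclic; roots are terms with no parents.
#'
#' @param terms character vector of term ids (nodes).
#' @param edges `data.frame` with columns `child`, `parent`, `relation`.
#' @return an object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, edges = data.frame(child = character(),
                                                   parent = character(),
                                                   relation = character())) {
  terms <- unique(as.character(terms))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = if ("relation" %in% names(edges))
                        as.character(edges$relation) else
                          rep("is_a", nrow(edges)),
                      stringsAsFactors = FALSE)
  terms <- unique(c(terms, edges$child, edges$parent))
  if (any(edges$child == edges$parent))
    parse_error("ontology has a self-loop (term is_a itself)")
  dag <- structure(list(terms = terms, edges = edges), class = "ontology_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    parse_error(sprintf("ontology graph is cyclic: %s", paste(cyc, collapse = " -> ")))
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), length(dag_roots(x))))
  invisible(x)
}

# Kahn topological sort; returns NULL if acyclic, else one cycle path.
find_cycle <- function(dag) {
  terms <- dag$terms
  parents <- split(dag$edges$parent, factor(dag$edges$child, levels = terms))
  # Kahn on child -> parent edges: peel terms with no unresolved parents
  out <- lengths(parents)
  queue <- terms[out == 0L]
  children_of <- split(dag$edges$child, factor(dag$edges$parent, levels = terms))
  remaining <- out
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children_of[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # extract one cycle among unresolved nodes by following parents
  left <- names(remaining)[remaining > 0L]
  path <- left[[1]]
  repeat {
    nxt <- intersect(parents[[path[length(path)]]], left)[1]
    if (nxt %in% path)
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    path <- c(path, nxt)
  }
}

#' Root terms of a DAG
#' @param dag an `ontology_dag`.
#' @return character vector of terms with no parent.
#' @export
dag_roots <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  setdiff(dag$terms, unique(dag$edges$child))
}

#' Proper ancestors of a term
#'
#' Transitive closure over the configured relations, excluding the term
#' itself (a term is never its own ancestor).
#'
#' @param dag an `ontology_dag`.
#' @param term a term id present in the DAG.
#' @param relations edge relations to traverse (default: all present).
#' @return character vector of ancestor term ids (unsorted set).
#' @export
dag_ancestors <- function(dag, term, relations = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms)
    parse_error(sprintf("term not in ontology: %s", term))
  ed <- dag$edges
  if (!is.null(relations)) ed <- ed[ed$relation %in% relations, , drop = FALSE]
  parents <- split(ed$parent, ed$child)
  acc <- character(0)
  frontier <- term
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    up <- setdiff(up, acc)
    acc <- c(acc, up)
    frontier <- up
  }
  setdiff(acc, term)
}

#' Read an ontology from an OBO 1.2 flat file
#'
#' One node per non-obsolete `[Term]` stanza; edges from `is_a` lines and,
#' when `part_of = TRUE`, from `relationship: part_of` lines.  Obsolete
#' terms are dropped with a logged count; edges touching dropped terms are
#' removed.  A cyclic graph is a parse error naming one cycle.
#'
#' @param path OBO file.
#' @param part_of also traverse `part_of` relationships (default `FALSE`:
#'   `is_a` only).
#' @return an `ontology_dag`; term names, when present, are kept in
#'   `attr(, "labels")`.
#' @export
parse_obo <- function(path, part_of = FALSE) {
  if (!file.exists(path)) parse_error(sprintf("OBO not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  stanza_at <- grepl("^\\[", lines)
  stanza_id <- cumsum(stanza_at)
  is_term_stanza <- lines[stanza_at] == "[Term]"
  ids <- character(0); labels <- character(0)
  edges <- list(); obsolete <- character(0)
  for (s in which(is_term_stanza)) {
    body <- lines[stanza_id == s & !stanza_at]
    get1 <- function(key) sub(paste0("^", key, ":\\s*"), "",
                              grep(paste0("^", key, ":"), body, value = TRUE))
    id <- get1("id")[1]
    if (is.na(id) || !length(id)) next
    if (any(grepl("^is_obsolete:\\s*true", body))) { obsolete <- c(obsolete, id); next }
    ids <- c(ids, id)
    nm <- get1("name")
    if (length(nm)) labels[id] <- nm[1]
    isa <- sub("\\s*(!.*)?$", "", get1("is_a"))
    if (length(isa))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = isa,
                                                relation = "is_a")
    if (part_of) {
      rel <- get1("relationship")
      po <- grep("^part_of\\s", rel, value = TRUE)
      if (length(po)) {
        tgt <- sub("\\s*(!.*)?$", "", sub("^part_of\\s+", "", po))
        edges[[length(edges) + 1L]] <- data.frame(child = id, parent = tgt,
                                                  relation = "part_of")
      }
    }
  }
  if (length(obsolete)) lnc_log("dropped %d obsolete term(s)", length(obsolete))
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(), relation = character())
  # edges pointing at obsolete terms go with them; unknown parents are kept
  # as implicit nodes (OBO files may be truncated)
  ed <- ed[!(ed$parent %in% obsolete), , drop = FALSE]
  dag <- ontology_dag(ids, ed)
  attr(dag, "labels") <- labels
  lnc_log("parsed ontology: %d term(s), %d edge(s) from %s",
          length(dag$terms), nrow(dag$edges), path)
  dag
}

#' Write an `ontology_dag` as a minimal OBO 1.2 file
#'
#' @param dag an `ontology_dag`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  labels <- attr(dag, "labels") %||% character(0)
  parents <- split(dag$edges$parent, dag$edges$child)
  out <- c("format-version: 1.2", "")
  for (t in sort(dag$terms)) {
    out <- c(out, "[Term]", paste0("id: ", t))
    if (t %in% names(labels)) out <- c(out, paste0("name: ", labels[[t]]))
    for (p in sort(parents[[t]])) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
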