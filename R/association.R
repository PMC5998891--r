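#' Distance between two genomic features
#'
#' Coordinates are 1-based inclusive.  Returns `NA` for features on
#' different chromosomes, `0` when the spans intersect, and otherwise the
#' gap in base pairs between the nearest ends: adjacent intervals such as
#' `...-100` and `101-...` are 1 bp apart.
#'
#' @param a,b single-row feature records (anything with `chrom`, `start`,
#'   `end`).
#' @return integer distance, or `NA` if on different chromosomes.
#' @export
interval_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  as.integer(span_distance(a$start, a$end, b$start, b$end))
}

# Vectorised core: distance from one interval to many (same chromosome
# assumed filtered by caller).  gap = b.start - a.end when b is right of a;
# positive iff disjoint, and adjacent intervals score 1 by construction.
span_distance <- function(qs, qe, ss, se) {
  pmax(pmax(ss - qe, qs - se), 0L)
}

#' Associate lncRNAs with nearby or overlapping protein-coding genes
#'
#' Emits one record per (lncRNA, gene) pair on the same chromosome whose
#' spans overlap or lie within `window_bp` base pairs of each other
#' (boundary inclusive: distance == window is kept).  Association is
#' strand-agnostic; the `relation` label is classified from the gene's
#' perspective using the gene's strand only (a lncRNA on the 5' side of the
#' gene is `upstream`).  Genes with strand `"."` are labelled as if on `+`.
#'
#' @param lncrnas feature `data.frame` of (DE) lncRNAs.
#' @param genes feature `data.frame` of protein-coding genes.
#' @param window_bp non-negative window size in bp (default 5000).
#' @return `data.frame` with columns `lncrna_id`, `gene_id`, `relation`
#'   (`overlap`/`upstream`/`downstream`), `distance`, `window_bp`, sorted by
#'   (lncrna_id, gene_id).
#' @export
find_associations <- function(lncrnas, genes, window_bp = 5000) {
  validate_features(lncrnas); validate_features(genes)
  window_bp <- assert_count(window_bp, "window_bp")
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      relation = character(), distance = integer(),
                      window_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) {
    lnc_log("find_associations: empty gene list", level = "WARN")
    return(empty)
  }
  if (nrow(lncrnas) == 0L) return(empty)
  out <- list()
  for (chrom in intersect(unique(lncrnas$chrom), unique(genes$chrom))) {
    L <- lncrnas[lncrnas$chrom == chrom, , drop = FALSE]
    G <- genes[genes$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(L))) {
      d <- span_distance(L$start[i], L$end[i], G$start, G$end)
      hit <- which(d <= window_bp)
      if (!length(hit)) next
      # upstream = lncRNA lies 5' of the gene span w.r.t. gene strand
      before <- L$end[i] < G$start[hit]       # lncRNA left of gene
      minus <- G$strand[hit] == "-"
      rel <- ifelse(d[hit] == 0L, "overlap",
                    ifelse(xor(before, minus), "upstream", "downstream"))
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = L$feature_id[i], gene_id = G$feature_id[hit],
        relation = rel, distance = as.integer(d[hit]),
        window_bp = window_bp, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  lnc_log("find_associations: %d record(s) for %d lncRNA(s) x %d gene(s), window %d bp",
          nrow(res), nrow(lncrnas), nrow(genes), window_bp)
  res
}

#' Derive the lncGene set from association records
#'
#' Collapses association records to the unique set of associated
#' protein-coding genes ("lncGenes"); a gene supported by several lncRNAs
#' counts once.  `r`, the count entering the augmented enrichment draw, is
#' computed per deduplication policy: `subtract_de` (default) removes genes
#' already on the DE gene list so no gene is counted twice in the combined
#' draw; `keep_all` counts every associated gene.
#'
#' @param associations `data.frame` from [find_associations()] run on DE
#'   lncRNAs.
#' @param de_genes character vector of DE gene ids.
#' @param dedup `"subtract_de"` or `"keep_all"`.
#' @return object of class `lncgene_set`: list with `genes` (the r-counted
#'   identifiers), `all_genes` (before DE subtraction), `r`, `dedup`, and
#'   the supporting `associations`.
#' @export
derive_lncgenes <- function(associations, de_genes = character(),
                            dedup = c("subtract_de", "keep_all")) {
  dedup <- match.arg(dedup)
  all_genes <- sort(unique(associations$gene_id))
  genes <- if (dedup == "subtract_de") setdiff(all_genes, de_genes) else all_genes
  structure(list(genes = genes, all_genes = all_genes,
                 r = length(genes), dedup = dedup,
                 associations = associations),
            class = "lncgene_set")
}

#' @export
print.lncgene_set <- function(x, ...) {
  cat(sprintf("<lncgene_set> %d associated gene(s), r = %d (%s)\n",
              length(x$all_genes), x$r, x$dedup))
  invisible(x)
}

#' Write association records as TSV (or BED)
#'
#' Default output is the native 1-based TSV.  With `bed = TRUE` a BED6-style
#' file of the associated gene spans is written instead; conversion to
#' 0-based half-open coordinates happens at write time only.
#'
#' @param associations `data.frame` from [find_associations()].
#' @param path output file.
#' @param bed write BED instead of TSV.
#' @param genes feature table (required for BED export).
#' @return `path`, invisibly.
#' @export
write_associations <- function(associations, path, bed = FALSE, genes = NULL) {
  if (!bed) return(write_tsv(associations, path))
  if (is.null(genes)) config_error("BED export needs the gene feature table")
  g <- genes[match(associations$gene_id, genes$feature_id), ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", g$chrom, g$start - 1L, g$end,
                     paste0(associations$lncrna_id, "|", associations$gene_id),
                     associations$distance, g$strand), path)
  invisible(path)
}
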