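#' Genomic feature tables
#'
#' A feature table is a plain `data.frame` with one row per gene-level
#' feature and columns `feature_id`, `chrom`, `start`, `end`, `strand`,
#' `biotype` and `name`.  Coordinates are GTF-style 1-based inclusive and are
#' kept in that convention throughout the package; all distance arithmetic is
#' defined on it.
#'
#' @param feature_id character vector of unique identifiers.
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive span; `end >= start >= 1`.
#' @param strand one of `"+"`, `"-"`, `"."` per feature.
#' @param biotype `"protein_coding"` or `"lncRNA"` per feature (recycled).
#' @param name optional display name (defaults to `feature_id`).
#' @return a validated feature `data.frame`.
#' @export
features <- function(feature_id, chrom, start, end, strand = ".",
                     biotype = "protein_coding", name = feature_id) {
  df <- data.frame(
    feature_id = as.character(feature_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(feature_id)),
    biotype = rep_len(as.character(biotype), length(feature_id)),
    name = as.character(name),
    stringsAsFactors = FALSE
  )
  validate_features(df)
}

#' Validate a feature table
#'
#' Checks span sanity (`start >= 1`, `end >= start`), identifier uniqueness,
#' and allowed strand/biotype values.
#'
#' @param df a feature `data.frame`.
#' @return `df`, invisibly valid.
#' @export
validate_features <- function(df) {
  need <- c("feature_id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    parse_error(sprintf("feature table missing columns: %s", paste(miss, collapse = ", ")))
  if (!"name" %in% names(df)) df$name <- df$feature_id
  if (nrow(df) == 0L) return(df)
  if (any(df$start < 1L) || any(df$end < df$start))
    parse_error("invalid span: need start >= 1 and end >= start")
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup))
    parse_error(sprintf("duplicate feature_id: %s", paste(unique(dup), collapse = ", ")))
  if (!all(df$strand %in% c("+", "-", ".")))
    parse_error("strand must be one of '+', '-', '.'")
  if (!all(df$biotype %in% c("protein_coding", "lncRNA")))
    parse_error("biotype must be 'protein_coding' or 'lncRNA'")
  df
}

# Pull one attribute out of a GTF column-9 string.  GTF attributes look like
#   gene_id "g1"; gene_name "abc";
# Unquoted values are tolerated.
gtf_attribute <- function(attr, key) {
  pat <- paste0("(^|;)\\s*", key, "\\s+\"?([^\";]+)\"?")
  m <- regmatches(attr, regexec(pat, attr))
  vapply(m, function(g) if (length(g) >= 3L) g[[3]] else NA_character_, character(1))
}

#' Read gene-level features from a GTF file
#'
#' Parses a 9-column GTF, groups records by their `gene_id` attribute, and
#' collapses each gene's transcripts/exons to a single span
#' (`min(start)`..`max(end)` across its records).  Coordinates stay 1-based
#' inclusive as in the file.
#'
#' @param path path to a GTF file.
#' @param biotype biotype label assigned to all parsed features
#'   (`"protein_coding"` or `"lncRNA"`).
#' @return a feature `data.frame` (see [features()]), one row per gene.
#' @details Malformed lines (not 9 tab-separated columns, non-integer or
#'   inverted coordinates, missing `gene_id`) raise a parse error naming the
#'   offending line number.  Comment lines (`#`) and blank lines are skipped.
#' @export
parse_gtf <- function(path, biotype = c("protein_coding", "lncRNA")) {
  biotype <- match.arg(biotype)
  if (!file.exists(path)) parse_error(sprintf("GTF not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) parse_error(sprintf("GTF has no records: %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol9 <- lengths(fields) == 9L
  if (any(!ncol9))
    parse_error(sprintf("GTF line %d: expected 9 tab-separated columns, got %d",
                        idx[!ncol9][1], lengths(fields)[!ncol9][1]))
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    parse_error(sprintf("GTF line %d: non-integer coordinates", idx[bad][1]))
  bad <- end < start | start < 1L
  if (any(bad))
    parse_error(sprintf("GTF line %d: invalid span %d-%d",
                        idx[bad][1], start[bad][1], end[bad][1]))
  gene_id <- gtf_attribute(mat[, 9], "gene_id")
  if (anyNA(gene_id))
    parse_error(sprintf("GTF line %d: missing gene_id attribute", idx[is.na(gene_id)][1]))
  gene_name <- gtf_attribute(mat[, 9], "gene_name")

  # collapse over transcripts: gene span = union of record spans
  ord <- order(match(gene_id, unique(gene_id)))
  sp <- split(seq_along(gene_id)[ord], factor(gene_id[ord], levels = unique(gene_id)))
  rows <- lapply(sp, function(i) {
    chrom <- unique(mat[i, 1])
    if (length(chrom) > 1L)
      parse_error(sprintf("gene %s has records on multiple chromosomes: %s",
                          gene_id[i[1]], paste(chrom, collapse = ",")))
    strand <- unique(mat[i, 7])
    strand <- if (length(strand) == 1L && strand %in% c("+", "-")) strand else "."
    nm <- gene_name[i]
    nm <- nm[!is.na(nm)]
    data.frame(feature_id = gene_id[i[1]], chrom = chrom,
               start = min(start[i]), end = max(end[i]),
               strand = strand, biotype = biotype,
               name = if (length(nm)) nm[1] else gene_id[i[1]],
               stringsAsFactors = FALSE)
  })
  out <- validate_features(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  lnc_log("parsed %d %s gene(s) from %d GTF record(s) in %s",
          nrow(out), biotype, length(idx), path)
  out
}

#' Write a feature table as gene-level GTF
#'
#' One `gene` record per feature; round-trips through [parse_gtf()].
#'
#' @param df a feature `data.frame`.
#' @param path output file.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(df, path, source = "lncora") {
  validate_features(df)
  lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                   df$chrom, source, df$start, df$end, df$strand,
                   df$feature_id, df$name)
  writeLines(lines, path)
  invisible(path)
}
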