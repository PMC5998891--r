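#' Expression tables
#'
#' FPKM values per feature per sample, with each sample assigned to the
#' `case` (treatment, e.g. morpholino knock-down) or `control` (wild-type)
#' condition.
#'
#' @param fpkm numeric matrix, features x samples, non-negative; rownames are
#'   feature ids, colnames sample names.
#' @param conditions named character vector mapping every sample (column) to
#'   `"case"` or `"control"`.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(fpkm, conditions) {
  fpkm <- as.matrix(fpkm)
  if ((nrow(fpkm) > 0L && is.null(rownames(fpkm))) || is.null(colnames(fpkm)))
    config_error("fpkm matrix needs feature rownames and sample colnames")
  if (anyNA(fpkm) || any(fpkm < 0))
    parse_error("FPKM values must be non-negative and complete")
  miss <- setdiff(colnames(fpkm), names(conditions))
  if (length(miss))
    config_error(sprintf("samples without condition label: %s",
                         paste(miss, collapse = ", ")))
  conditions <- conditions[colnames(fpkm)]
  if (!all(conditions %in% c("case", "control")))
    config_error("conditions must be 'case' or 'control'")
  if (!all(c("case", "control") %in% conditions))
    config_error("need at least one sample per condition")
  structure(list(fpkm = fpkm, conditions = conditions),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d features; %d case + %d control sample(s)\n",
              nrow(x$fpkm), sum(x$conditions == "case"),
              sum(x$conditions == "control")))
  invisible(x)
}

#' Read an expression table from TSV
#'
#' The expression file has a header `feature_id <TAB> sample1 <TAB> ...`;
#' the condition map is a two-column TSV `sample <TAB> condition` with
#' condition `case` or `control`.
#'
#' @param expression_path expression TSV.
#' @param conditions_path condition map TSV.
#' @return an `expression_table`.
#' @export
read_expression <- function(expression_path, conditions_path) {
  ex <- read_tsv(expression_path)
  if (ncol(ex) < 2L) parse_error("expression table needs feature_id + sample columns")
  if (anyDuplicated(ex[[1]]))
    parse_error("duplicate feature ids in expression table")
  m <- as.matrix(ex[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(ex[[1]])
  cm <- read_tsv(conditions_path)
  if (ncol(cm) < 2L) parse_error("condition map needs columns: sample, condition")
  conditions <- stats::setNames(as.character(cm[[2]]), as.character(cm[[1]]))
  expression_table(m, conditions)
}

#' Write an expression table as TSV pair
#' @param table an `expression_table`.
#' @param expression_path,conditions_path output files.
#' @return invisibly, the expression path.
#' @export
write_expression <- function(table, expression_path, conditions_path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(feature_id = rownames(table$fpkm), table$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expression_path)
  write_tsv(data.frame(sample = names(table$conditions),
                       condition = unname(table$conditions)), conditions_path)
  invisible(expression_path)
}

#' DE filter configuration
#'
#' Default values reproduce the filtering rules of the source protocol: keep
#' features whose replicate coefficient of variation is at most 15% in both
#' conditions, whose signed fold change exceeds 1.5 in magnitude, and whose
#' mean FPKM in the up-regulated condition is at least 1.
#'
#' @param fold_change_threshold magnitude a signed fold change must exceed
#'   (strictly) to be called DE; > 1.
#' @param min_fpkm expression floor applied to the numerator condition of
#'   up-regulated features and the denominator condition of down-regulated
#'   ones.
#' @param max_replicate_cv maximum allowed replicate coefficient of
#'   variation (sd/mean) per condition; in (0, 1].
#' @param active_filters subset of `c("variability", "fold_change",
#'   "low_fpkm")`; disabled filters pass every feature through.
#' @param cv_scope `"per_condition"` (either condition failing fails the
#'   feature) or `"pooled"` (CV over all replicates of both conditions).
#' @return an object of class `de_config`.
#' @export
de_config <- function(fold_change_threshold = 1.5, min_fpkm = 1,
                      max_replicate_cv = 0.15,
                      active_filters = c("variability", "fold_change", "low_fpkm"),
                      cv_scope = c("per_condition", "pooled")) {
  cv_scope <- match.arg(cv_scope)
  if (!is.numeric(fold_change_threshold) || fold_change_threshold <= 1)
    config_error("fold_change_threshold must be > 1")
  if (!is.numeric(min_fpkm) || min_fpkm < 0)
    config_error("min_fpkm must be >= 0")
  if (!is.numeric(max_replicate_cv) || max_replicate_cv <= 0 || max_replicate_cv > 1)
    config_error("max_replicate_cv must be in (0, 1]")
  bad <- setdiff(active_filters, c("variability", "fold_change", "low_fpkm"))
  if (length(bad)) config_error(sprintf("unknown filter(s): %s", paste(bad, collapse = ", ")))
  structure(list(fold_change_threshold = fold_change_threshold,
                 min_fpkm = min_fpkm, max_replicate_cv = max_replicate_cv,
                 active_filters = active_filters, cv_scope = cv_scope),
            class = "de_config")
}

#' Per-condition mean FPKM of one feature
#'
#' Arithmetic mean over the replicate samples of each condition.
#'
#' @param table an `expression_table`.
#' @param feature_id a feature present in the table.
#' @return named numeric `c(mean_case =, mean_control =)`.
#' @export
condition_means <- function(table, feature_id) {
  stopifnot(inherits(table, "expression_table"))
  if (!feature_id %in% rownames(table$fpkm))
    config_error(sprintf("unknown feature: %s", feature_id))
  v <- table$fpkm[feature_id, ]
  c(mean_case = mean(v[table$conditions == "case"]),
    mean_control = mean(v[table$conditions == "control"]))
}

#' Signed fold change of condition means
#'
#' The ratio `r = mean_case / mean_control` reported in the signed
#' convention: `r` when `r >= 1`, else `-1/r`, so that symmetric thresholds
#' (e.g. |fc| > 1.5) apply and `|result| >= 1` always.  A zero denominator
#' with a non-zero numerator yields `Inf` (case-only expression), the
#' converse `-Inf`; both means zero yields `NA` ("undefined"; such features
#' are filtered as `low_fpkm` before fold change matters under default
#' config).
#'
#' @param mean_case,mean_control non-negative condition means.
#' @return signed fold change (numeric scalar, possibly infinite or `NA`).
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  stopifnot(length(mean_case) == length(mean_control))
  r <- mean_case / mean_control
  out <- ifelse(r >= 1, r, -1 / r)
  out[mean_case == 0 & mean_control == 0] <- NA_real_
  out[mean_case > 0 & mean_control == 0] <- Inf
  out[mean_case == 0 & mean_control > 0] <- -Inf
  out
}

#' Replicate coefficient of variation
#'
#' Sample standard deviation divided by the mean.  Needs at least two
#' values; a zero mean returns `NA` ("undefined" -- the feature fails the
#' variability filter).
#'
#' @param values numeric vector of replicate FPKMs (length >= 2).
#' @return CV (numeric scalar) or `NA`.
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2L)
    config_error("replicate_cv needs >= 2 values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

#' Classify every feature of an expression table as DE or filtered
#'
#' Filters apply in a fixed order, so the recorded `filter_reason` is the
#' first rule a feature fails: (1) variability -- replicate CV above
#' `max_replicate_cv` in either condition (or pooled, per `cv_scope`);
#' (2) fold change -- `|signed_fc|` not exceeding the threshold;
#' (3) expression floor -- up-regulated features need `mean_case >=
#' min_fpkm`, down-regulated need `mean_control >= min_fpkm`.  Survivors are
#' `de_up` or `de_down` by the sign of the fold change.  The surviving set
#' does not depend on the order, only the reason labels do.
#'
#' @param table an `expression_table`.
#' @param config a [de_config()].
#' @return `data.frame` with columns `feature_id`, `mean_case`,
#'   `mean_control`, `signed_fc`, `status` (`de_up`/`de_down`/`filtered`)
#'   and `filter_reason` (`variability`/`fold_change`/`low_fpkm`/`none`),
#'   one row per feature in input order.
#' @export
filter_de <- function(table, config = de_config()) {
  stopifnot(inherits(table, "expression_table"))
  if (!inherits(config, "de_config")) config_error("config must be a de_config")
  fpkm <- table$fpkm
  case <- fpkm[, table$conditions == "case", drop = FALSE]
  ctrl <- fpkm[, table$conditions == "control", drop = FALSE]
  filters <- config$active_filters
  if ("variability" %in% filters && (ncol(case) < 2L || ncol(ctrl) < 2L))
    config_error("variability filter needs >= 2 replicates per condition")

  n <- nrow(fpkm)
  if (n == 0L)
    return(data.frame(feature_id = character(), mean_case = numeric(),
                      mean_control = numeric(), signed_fc = numeric(),
                      status = character(), filter_reason = character(),
                      stringsAsFactors = FALSE))
  mean_case <- rowMeans(case)
  mean_control <- rowMeans(ctrl)
  fc <- signed_fold_change(mean_case, mean_control)

  status <- rep("filtered", n)
  reason <- rep("none", n)

  fail_var <- rep(FALSE, n)
  if ("variability" %in% filters) {
    cv_of <- function(m) apply(m, 1L, function(v) {
      mu <- mean(v); if (mu == 0) NA_real_ else stats::sd(v) / mu
    })
    if (config$cv_scope == "pooled") {
      cv <- cv_of(cbind(case, ctrl))
      fail_var <- is.na(cv) | cv > config$max_replicate_cv
    } else {
      cvc <- cv_of(case); cvw <- cv_of(ctrl)
      # an all-zero condition has undefined CV; treat as failing only if the
      # other condition is also degenerate -- a clean on/off feature is not
      # "variable".  Zero-mean with zero sd never happens (sd of zeros = 0).
      fail_var <- (!is.na(cvc) & cvc > config$max_replicate_cv) |
                  (!is.na(cvw) & cvw > config$max_replicate_cv)
    }
  }

  fail_fc <- rep(FALSE, n)
  if ("fold_change" %in% filters)
    fail_fc <- !is.na(fc) & abs(fc) <= config$fold_change_threshold

  up <- !is.na(fc) & fc > 0
  fail_floor <- rep(FALSE, n)
  if ("low_fpkm" %in% filters)
    fail_floor <- (up & mean_case < config$min_fpkm) |
      (!up & !is.na(fc) & mean_control < config$min_fpkm)

  # 0/0 features have an undefined fold change and can never be DE; they are
  # reported under the low_fpkm reason regardless of active filters
  undef <- is.na(fc)
  reason[fail_floor | undef] <- "low_fpkm"
  reason[fail_fc] <- "fold_change"
  reason[fail_var] <- "variability"   # applied last: first rule in order wins
  pass <- !(fail_var | fail_fc | fail_floor | undef)
  status[pass & up] <- "de_up"
  status[pass & !up & !undef] <- "de_down"
  reason[status != "filtered"] <- "none"

  out <- data.frame(feature_id = rownames(fpkm), mean_case = mean_case,
                    mean_control = mean_control, signed_fc = fc,
                    status = status, filter_reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  lnc_log("filter_de: %d features -> %d de_up, %d de_down, %d filtered (order: %s)",
          n, sum(out$status == "de_up"), sum(out$status == "de_down"),
          sum(out$status == "filtered"),
          paste(filters, collapse = " -> "))
  out
}

#' DE feature identifiers from a filter_de result
#' @param de `data.frame` from [filter_de()].
#' @return character vector of `de_up`/`de_down` feature ids.
#' @export
de_ids <- function(de) de$feature_id[de$status %in% c("de_up", "de_down")]
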