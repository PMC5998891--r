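#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Condition helpers: every user-facing failure is classed so the CLI can map
# it to an exit code (config -> 2, parse -> 3, stage -> 4).
lnc_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lncora_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error <- function(msg, ...) lnc_abort(msg, "lncora_config_error", ...)
parse_error  <- function(msg, ...) lnc_abort(msg, "lncora_parse_error", ...)
stage_error  <- function(msg, stage, ...) {
  lnc_abort(sprintf("[stage %s] %s", stage, msg), "lncora_stage_error",
            stage = stage, ...)
}

# Log to stderr; quiet by default inside tests via option.
lnc_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("lncora.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[lncora %s] %s", level, sprintf(...)))
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) config_error(sprintf("'%s' must be a single non-negative integer", name))
  invisible(as.integer(x))
}

# Deterministic table writer shared by all output stages: no quotes, no row
# names, tab separated -- byte-identical across reruns.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", ...)
}
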