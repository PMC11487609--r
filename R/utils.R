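#' @keywords internal
"_PACKAGE"

# Run code with a temporarily fixed RNG state, restoring the caller's state.
# All randomized constructors in the package funnel through this so that a
# seed argument fully determines the output without clobbering user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

mn_log <- function(..., level = "INFO") {
  message(sprintf("[mintnet %s] %s", level, paste0(...)))
}

mn_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

mn_stop <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# write.table with the conventions used for every tabular output:
# TSV, header row, no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
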