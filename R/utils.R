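## Shared internal helpers: argument checks, scoped RNG, self-describing TSV.

abort <- function(msg, class = NULL, ...) {
  stop(structure(
    class = c(class, "coevkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
## Every generator draws from its own stream; no global RNG state leaks.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12347L) %% 2147483647)
}

#' Write a table as TSV with a self-describing '#' parameter header
#'
#' All tabular pipeline outputs carry their generating parameters as
#' `# key: value` comment lines ahead of the column header, so a result file
#' documents how it was produced.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param params named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# coevkit %s",
                     as.character(utils::packageVersion("coevkit"))), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(params[[nm]], trim = TRUE), collapse = ",")),
               con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Read a TSV written by write_tsv_report (or any TSV with '#' comments).
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
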