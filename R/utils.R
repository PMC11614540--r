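# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded package functions never clobber user state.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from the run seed and a label, so
# stages are independently rerunnable. Always in [1, 2^31 - 2].
stage_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) + as.numeric(h) * 10007) %% 2147483646) + 1L
}

# set-valued cells are serialized as ";"-separated canonical strings
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_set <- function(x, order = NULL) {
  x <- unique(x[nzchar(x)])
  if (!is.null(order)) x <- order[order %in% x]
  paste(x, collapse = ";")
}

# lower snake_case canonicalization for enumeration cells
canon_enum <- function(x) {
  x <- trimws(tolower(x))
  gsub("[ /-]+", "_", x)
}

# sniff the delimiter from the header line: tab preferred, comma accepted
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  df <- utils::read.delim(path, sep = delim, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "\"", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# assemble row-indexed diagnostics and abort listing every offending row
fail_rows <- function(problems, context) {
  if (!length(problems)) return(invisible(NULL))
  stop(context, ":\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
}
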