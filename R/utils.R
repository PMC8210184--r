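# Internal helpers shared across modules.

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent TSV readers/writers: empty cell <-> NA, never factors.
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_strict <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = row_names, col.names = TRUE)
}
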