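# internal helpers shared across modules

# Run `code` under a temporarily seeded RNG, restoring the caller's RNG state.
# `seed = NULL` means: use (and advance) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage child seeds from one pipeline seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(network = 11L, omics = 23L, module = 37L, screen = 53L,
               drugs = 71L, synth = 89L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_plain <- function(path, header = TRUE, col_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = header, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  if (!is.null(col_names)) {
    if (ncol(df) < length(col_names)) {
      stop("expected at least ", length(col_names), " columns in ", path,
           call. = FALSE)
    }
    names(df)[seq_along(col_names)] <- col_names
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
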