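## Internal helpers: typed conditions and deterministic seed substreams.

ep_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "equipain_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ep_config_error <- function(msg, ...) ep_stop("equipain_config_error", msg, ...)
ep_validation_error <- function(msg, ...) ep_stop("equipain_validation_error", msg, ...)
ep_insufficient_data <- function(msg, ...) ep_stop("equipain_insufficient_data", msg, ...)
ep_segmentation_failure <- function(msg, ...) ep_stop("equipain_segmentation_failure", msg, ...)
ep_degenerate_error <- function(msg, ...) ep_stop("equipain_degenerate_error", msg, ...)

#' Derive a deterministic sub-stream seed
#'
#' Hashes a root seed together with string/integer labels into a new seed in
#' [1, 2^31 - 2], so that per-horse / per-observer randomness is reproducible
#' and independent of evaluation order.
#'
#' @param seed Integer root seed.
#' @param ... Labels (character or integer scalars) identifying the substream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- vapply(list(...), function(x) as.character(x)[1], character(1))
  h <- as.double(seed %% 2147483647L)
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% 2147483647
    }
    h <- (h * 131 + 17) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable CSV writer so repeated runs are byte-identical.
ep_write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
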