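# internal helpers: argument checks, hashing, seed derivation

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a stage seed from a global seed
#'
#' All stochastic stages of the pipeline draw their RNG seed from one global
#' seed through this scheme, so that re-runs and partial re-runs of a stage
#' agree. The stage label is hashed with a 31-multiplier rolling hash modulo
#' 2^31 - 1 and combined with the global seed and an index.
#'
#' @param seed Integer global seed.
#' @param stage Character label of the stage (e.g. `"simulate/Rab7/both/3"`).
#' @param index Optional nonnegative integer distinguishing repeated draws
#'   within a stage.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "simulate")
#' derive_seed(1L, "simulate", index = 2)
derive_seed <- function(seed, stage, index = 0L) {
  abort_if(!is_scalar_number(seed), "'seed' must be a single finite number")
  abort_if(!is.character(stage) || length(stage) != 1L,
           "'stage' must be a single string")
  m <- 2147483647            # 2^31 - 1, keeps everything in integer range
  h <- as.double(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  h <- (h + as.double(index) * 1000003) %% m
  as.integer(h)
}

# rolling 31-hash of a string, for config fingerprints in run manifests
hash_string <- function(s) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# fixed-width numeric formatting for result tables (9 significant digits)
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

write_result_csv <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
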