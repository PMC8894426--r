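# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so package functions never
#' leak global random state.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific substream seed from a run seed. Keeps every
# stage reproducible independently of execution order, and stays inside
# the 32-bit integer range.
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Center and scale columns of a matrix
#'
#' Columns are shifted to mean 0 and scaled to sample standard deviation
#' (n - 1 denominator) 1. Zero-variance columns are dropped with a warning.
#' @noRd
center_scale_columns <- function(x, context = "feature") {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant %s column(s): %s",
                    sum(!keep), context,
                    paste(utils::head(colnames(x)[!keep], 5L), collapse = ", ")),
            call. = FALSE)
  }
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
                  2L, sdv[keep], "/")
  attr(scaled, "dropped") <- colnames(x)[!keep]
  scaled
}

# 17 significant digits: doubles survive a write -> read round trip
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out[is.na(x)] <- "NA"
  out
}
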