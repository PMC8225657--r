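# internal helpers shared across modules

#' @importFrom stats runif rnorm rlnorm setNames cor aggregate approx prcomp var
#' @importFrom utils head tail read.delim write.table modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive reproducible sub-seeds from a master seed
#'
#' Every stochastic stage of the pipeline (GRN sampling, kinetics, each SSA
#' run, cell sampling, molecule sampling) draws its own sub-seed so that
#' stages can be re-run independently while the whole pipeline stays
#' reproducible under a single master seed.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character); each distinct name yields a distinct
#'   stream.
#' @param index Optional index within the stage (e.g. simulation number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # small string hash (djb2) folded with the master seed; kept below 2^31
  h <- 5381
  for (ch in utf8ToInt(paste0(stage, "#", index))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# largest-remainder rounding of proportional allocations so they sum to n
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  quota <- n * weights / sum(weights)
  alloc <- floor(quota)
  left <- n - sum(alloc)
  if (left > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(left)]
    alloc[extra] <- alloc[extra] + 1
  }
  as.integer(alloc)
}

# trapezoidal area under (x, y); x must be non-decreasing
trapz <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

assert_that <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE)
  invisible(TRUE)
}
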