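# Internal helpers shared across modules.

#' Derive a deterministic child seed
#'
#' Stage-specific seeds are derived from the single run seed so that every
#' source of randomness is reproducible from one integer, and stages do not
#' consume each other's RNG streams.
#'
#' @param seed Integer run seed.
#' @param label Character stage label (e.g. `"null"`, `"perm:17"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Row medians without the per-row overhead of apply() for the common
# 3-column case (odd n: the median is an order statistic, so it commutes
# with monotone transforms; even n does not, hence the general fallback).
row_medians <- function(m, na.rm = FALSE) {
  m <- as.matrix(m)
  if (ncol(m) == 1L) return(as.vector(m))
  if (ncol(m) == 3L && (!na.rm || !anyNA(m))) {
    return(m[, 1L] + m[, 2L] + m[, 3L] -
             pmax(m[, 1L], m[, 2L], m[, 3L]) -
             pmin(m[, 1L], m[, 2L], m[, 3L]))
  }
  if (ncol(m) == 2L && (!na.rm || !anyNA(m))) {
    return((m[, 1L] + m[, 2L]) / 2)
  }
  apply(m, 1L, stats::median, na.rm = na.rm)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted cluster structure. Hubert-Arabie
#' adjustment; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Consistent error classes for contract violations.
stop_schema <- function(...) stop(errorCondition(paste0(...), class = c("sennet_schema_error", "error")))
stop_value  <- function(...) stop(errorCondition(paste0(...), class = c("sennet_value_error", "error")))
stop_config <- function(...) stop(errorCondition(paste0(...), class = c("sennet_config_error", "error")))
stop_usage  <- function(...) stop(errorCondition(paste0(...), class = c("sennet_usage_error", "error")))

# message() wrapper so pipeline chatter is easy to silence/capture.
log_msg <- function(...) message("[sennet] ", ...)
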