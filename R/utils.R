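# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seeds, kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 599479) * 3571 + as.numeric(k)) %% 2147483647
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted guild memberships. 1 means identical
#' partitions (up to label names), 0 is the expectation under independent
#' random labelings.
#'
#' @param x,y vectors of labels of equal length.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)
  (sum_comb - expected) / (maximum - expected)
}

# Stop with a consistent message prefix.
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8

fmt_ids <- function(ids, max = 5L) {
  if (length(ids) > max) {
    paste0(paste(head(ids, max), collapse = ", "), ", ... (", length(ids), " total)")
  } else paste(ids, collapse = ", ")
}
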