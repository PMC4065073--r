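`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a protein symbol
#'
#' Trims surrounding whitespace, removes internal whitespace and upper-cases,
#' so that murine-style (`Myh9`) and human-style (`MYH9`) spellings collapse
#' onto one namespace. Normalization is idempotent.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalized symbols (empty strings possible for
#'   blank input; callers drop those).
#' @examples
#' normalize_symbol(c(" Myh9 ", "MYH 10"))
#' @export
normalize_symbol <- function(x) {
  toupper(gsub("[[:space:]]+", "", trimws(as.character(x))))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used by the pipeline
#' to score recovery of planted community structure.
#'
#' @param x,y vectors of cluster labels over the same items (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

## Map linear indices in 1..n(n-1)/2 to (i, j) pairs with i < j, enumerated
## row-major: (1,2),(1,3),...,(1,n),(2,3),...  Used to sample random edges
## without materializing all pairs.
pair_from_index <- function(idx, n) {
  offsets <- c(0, cumsum((n - 1):1))
  i <- findInterval(idx - 1, offsets, rightmost.closed = FALSE)
  j <- idx - offsets[i] + i
  cbind(i, j)
}

stop_stage <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
}
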