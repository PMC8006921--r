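`%||%` <- function(a, b) if (is.null(a)) b else a

## Symbol matching between expression tables and gene-set libraries is
## case-insensitive by default (microarray annotation tables are inconsistent
## about SYMBOL case); originals are preserved everywhere.
match_symbols <- function(x, table, ignore_case = TRUE) {
  if (ignore_case) match(toupper(x), toupper(table)) else match(x, table)
}

symbols_in <- function(x, table, ignore_case = TRUE) {
  !is.na(match_symbols(x, table, ignore_case))
}

## Column-wise cumulative sum without an apply() loop.
col_cumsum <- function(m) {
  k <- nrow(m)
  if (k == 1L) return(m)
  cs <- matrix(cumsum(m), nrow = k)
  offs <- c(0, cs[k, -ncol(m)])
  sweep(cs, 2L, offs, "-")
}

## Sample standard deviation per row (n - 1 denominator).
row_sd <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

## Independent sub-seeds for the generator's artifact streams, so adding one
## generator never perturbs another. Kept below 2^31 - 1 (R integers).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
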