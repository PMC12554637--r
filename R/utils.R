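# numerically stable row-wise log(sum(exp(x))) for a matrix of log values
rowLogSumExp <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) == 1L) return(drop(x))
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- -Inf
  out
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
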