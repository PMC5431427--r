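`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    config_error(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

assert_interval <- function(x, field, lower_ok = -Inf) {
  if (length(x) != 2L || !is.numeric(x) || any(is.na(x)) || x[1] > x[2] || x[1] < lower_ok)
    config_error(field, "must be a numeric interval c(lo, hi) with lo <= hi")
  as.numeric(x)
}

assert_numeric_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (any(!is.finite(x)) && anyNA(x))
    stop(sprintf("%s contains NA/NaN values", what), call. = FALSE)
  invisible(x)
}

assert_symmetric <- function(x, what, tol = 1e-8) {
  assert_numeric_matrix(x, what)
  if (nrow(x) != ncol(x) || max(abs(x - t(x))) > tol)
    stop(sprintf("%s must be a symmetric square matrix", what), call. = FALSE)
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Relabel an integer partition so label 1 is the largest class, 0 stays 0.
# Ties broken by first appearance order of the old label.
relabel_by_size <- function(labels) {
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  old <- labels[pos]
  tab <- table(old)
  first_seen <- vapply(names(tab), function(l) match(l, as.character(old)), 1L)
  ord <- order(-as.integer(tab), first_seen)
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  out <- labels
  out[pos] <- as.integer(map[as.character(old)])
  out
}
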