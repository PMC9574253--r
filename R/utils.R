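# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ovitherm_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("ovitherm_format_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(name, " must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_validation(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

# Column means ignoring NA, with all-NA columns mapped to `fill`.
col_means_filled <- function(m, fill = 0) {
  cm <- colMeans(m, na.rm = TRUE)
  cm[!is.finite(cm)] <- fill
  cm
}

# Replace missing dosages by the per-marker mean dosage (markers as columns).
impute_column_mean <- function(m) {
  if (!anyNA(m)) return(m)
  cm <- col_means_filled(m)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- cm[idx[, 2L]]
  m
}
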