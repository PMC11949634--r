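# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score a numeric vector; constant vectors map to 0
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# scale and mean-centre the named continuous columns of a model frame,
# adding "<col>_z" companions (models are always fitted on the _z columns)
scale_continuous <- function(df, cols) {
  for (cl in cols) {
    if (!cl %in% names(df)) stop(sprintf("column '%s' not in frame", cl), call. = FALSE)
    df[[paste0(cl, "_z")]] <- zscore(df[[cl]])
  }
  df
}
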