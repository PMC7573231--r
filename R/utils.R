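#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# classed errors so callers/tests can distinguish failure modes
smt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sealmito_error", "error", "condition")))
}

# slope and its standard error from a simple linear regression y ~ t.
# Closed form; returns c(slope, se). n < 3 gives se = Inf (cannot assess).
slope_se <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(c(NA_real_, Inf))
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  if (sxx == 0) return(c(NA_real_, Inf))
  sxy <- sum((t - tm) * (y - ym))
  b <- sxy / sxx
  if (n < 3L) return(c(b, Inf))
  rss <- sum((y - ym - b * (t - tm))^2)
  se <- sqrt(max(rss, 0) / (n - 2L) / sxx)
  c(b, se)
}

# contiguous TRUE runs of a logical vector -> data.frame(start_idx, end_idx)
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

# evaluate `code` under a fixed RNG seed when one is given, leaving the
# caller's RNG state untouched; NULL means "use the ambient RNG stream"
maybe_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         format(signif(x, digits), digits = digits, trim = TRUE,
                scientific = FALSE))
}

#' Write a data frame as a fixed-format TSV
#'
#' Numeric columns are rounded to 6 significant digits and written without
#' quoting so that repeated runs with the same inputs are byte-identical.
#'
#' @param df data frame
#' @param path output path
#' @export
write_tsv_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
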