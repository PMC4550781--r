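# Internal helpers shared across modules.

# Largest-remainder apportionment: integer counts summing exactly to n,
# proportional to non-negative weights. Ties go to the earlier element.
largest_remainder <- function(weights, n) {
  stopifnot(length(weights) >= 1L, all(weights >= 0), sum(weights) > 0, n >= 0)
  raw <- weights / sum(weights) * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    take <- ord[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_binary <- function(x, what) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("%s must be strictly 0 or 1", what), call. = FALSE)
  }
  invisible(x)
}

# Has the fragment table been collapsed over replicates yet?
is_collapsed <- function(table) !("replicate" %in% names(table))
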