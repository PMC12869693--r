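# Immutable run-length tag array with two-rank distinct-tag queries --------
#
# The frozen structure keeps a sparse monotone sequence of run starts over
# [0, N] (the Elias-Fano contract: space proportional to the number of runs,
# logarithmic rank) and one packed tag per run. Distinct-tag queries do two
# rank queries and touch only the runs overlapping the interval, never the
# interval width; an access counter records every structure element touched
# so the cost contract is testable.

tag_array_new <- function(run_start, tags, N) {
  acc <- new.env(parent = emptyenv()); acc$n <- 0
  structure(list(run_start = run_start, tags = tags, N = N,
                 run_count = length(tags), acc = acc),
            class = "tag_array")
}

# run-length encode a per-row packed tag vector
tag_array_from_rows <- function(rows) {
  rl <- rle(rows)
  r <- length(rl$values)
  tag_array_new(cumsum(c(0, rl$lengths[-r])), rl$values, length(rows))
}

#' Freeze a run-length B+ tree into an immutable tag array
#'
#' Copies the runs in order (the tree must be fully covered: a remaining GAP
#' run is an integrity error), dropping the sentinel and coalescing any
#' adjacent equal tags.
#'
#' @param tree An `rlb_tree`.
#' @return An object of class `tag_array`.
#' @export
freeze_tags <- function(tree) {
  runs <- iterate_runs(tree)
  runs <- runs[-nrow(runs), , drop = FALSE]      # sentinel
  if (any(runs$tag == TAG_GAP))
    err_integrity("tree still contains GAP runs; construction incomplete")
  keep <- c(TRUE, runs$tag[-1L] != runs$tag[-nrow(runs)])
  tag_array_new(runs$start[keep], runs$tag[keep], tree$N)
}

#' @export
print.tag_array <- function(x, ...) {
  cat(sprintf("tag array: N = %g rows in %d runs (mean run length %.2f)\n",
              x$N, x$run_count, x$N / x$run_count))
  invisible(x)
}

# counted binary search: last j with run_start[j] <= x
tag_rank <- function(arr, x) {
  lo <- 1L; hi <- arr$run_count
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    arr$acc$n <- arr$acc$n + 1
    if (arr$run_start[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Tag at a BWT row
#'
#' @param arr A `tag_array`.
#' @param i A 0-based row, `0 <= i < N`.
#' @return The packed tag of the run containing `i`.
#' @export
tag_at_row <- function(arr, i) {
  if (i < 0 || i >= arr$N) err_domain("row out of range")
  arr$tags[findInterval(i, arr$run_start)]
}

#' Distinct graph positions in a row interval
#'
#' Two rank queries give the first and last overlapping run; the tags of
#' those runs are collected, sorted by `(v, o, b)` and deduplicated, and
#' reserved bookkeeping tags (end-marker rows) are filtered out.
#'
#' @param arr A `tag_array`.
#' @param iv Inclusive row interval `c(A, B)`; empty if `B < A`.
#' @return A data frame with columns `v`, `o`, `b`, sorted.
#' @export
distinct_tags <- function(arr, iv) {
  if (iv[2] < iv[1]) return(tag_unpack(numeric(0)))
  if (iv[1] < 0 || iv[2] >= arr$N) err_domain("interval out of range")
  j1 <- tag_rank(arr, iv[1])
  j2 <- tag_rank(arr, iv[2])
  t <- arr$tags[j1:j2]
  arr$acc$n <- arr$acc$n + (j2 - j1 + 1)
  u <- sort(unique(t))
  u <- u[!tag_is_reserved(u)]
  tag_unpack(u)
}

#' Access counter of a tag array
#'
#' Structure elements touched by [distinct_tags()] since creation or the
#' last reset; used to assert the output-sensitive cost contract.
#'
#' @param arr A `tag_array`.
#' @return A count.
#' @export
tag_access_count <- function(arr) arr$acc$n

#' @rdname tag_access_count
#' @export
tag_access_reset <- function(arr) { arr$acc$n <- 0; invisible(arr) }

#' Unpack packed tags to (v, o, b) columns
#'
#' @param tag Numeric vector of packed tags.
#' @return A data frame with columns `v`, `o`, `b`.
#' @export
tag_unpack_public <- function(tag) tag_unpack(tag)

# expand a tag array to one packed tag per row
tag_array_rows <- function(arr) {
  rep(arr$tags, diff(c(arr$run_start, arr$N)))
}
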