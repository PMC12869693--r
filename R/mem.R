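# Maximal exact match enumeration over the bidirectional index -------------
#
# A match [i, j) of the query is a MEM when it occurs in the indexed text,
# extending right by query[j] loses all occurrences (or the query ends or
# hits an N), and likewise extending left by query[i-1]. For a fixed start
# the maximal right extension is unique, so each query start yields at most
# one MEM; a start is kept when its full-length interval cannot be extended
# left. 'N' in the query never matches.

#' Find maximal exact matches of a query
#'
#' @param index An `msbwt_index`.
#' @param query Query string over `{A,C,G,T,N}`.
#' @param Lmin Minimum MEM length (default 31).
#' @return A data frame with columns `q_start`, `q_end` (half-open, 0-based
#'   on the query), `A`, `B` (the match's row interval) and `width`, sorted
#'   by `q_start`.
#' @export
find_mems <- function(index, query, Lmin = 31) {
  if (Lmin < 1) err_domain("Lmin must be >= 1")
  qc <- chars_of(toupper(query))
  if (!all(qc %in% c(DNA_BASES)))
    err_domain("query must be over {A,C,G,T,N}")
  L <- length(qc)
  out <- list()
  for (i in seq_len(L)) {          # 1-based start
    if (qc[i] == "N") next
    bi <- bi_init(index)
    j <- i
    while (j <= L && qc[j] != "N") {
      nb <- bi_extend_forward(index, bi, qc[j])
      if (lex_width(nb$fwd) == 0) break
      bi <- nb
      j <- j + 1L
    }
    len <- j - i
    if (len < Lmin) next
    left_blocked <- i == 1L || qc[i - 1L] == "N" ||
      lex_width(bi_extend_backward(index, bi, qc[i - 1L])$fwd) == 0
    if (!left_blocked) next
    out[[length(out) + 1L]] <-
      c(q_start = i - 1L, q_end = j - 1L, A = bi$fwd[1], B = bi$fwd[2])
  }
  if (length(out) == 0L)
    return(data.frame(q_start = numeric(0), q_end = numeric(0),
                      A = numeric(0), B = numeric(0), width = numeric(0)))
  d <- as.data.frame(do.call(rbind, out))
  d$width <- d$B + 1 - d$A
  d[order(d$q_start), , drop = FALSE]
}

#' Find MEMs and their distinct graph positions
#'
#' Each MEM is annotated with [distinct_tags()] over its row interval.
#'
#' @inheritParams find_mems
#' @param arr The `tag_array` of the index.
#' @return As [find_mems()], plus `n_tags` and a list column `tags` of
#'   `(v, o, b)` data frames.
#' @export
mems_with_tags <- function(index, arr, query, Lmin = 31) {
  d <- find_mems(index, query, Lmin)
  tags <- lapply(seq_len(nrow(d)),
                 function(i) distinct_tags(arr, c(d$A[i], d$B[i])))
  d$n_tags <- vapply(tags, nrow, 0L)
  d$tags <- tags
  d
}
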