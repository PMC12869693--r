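# Sampled tag array and one-to-all coordinate translation -------------------
#
# Only tag runs whose graph offset is o = 0 (node starts, either
# orientation) are kept, each with its BWT interval; all other rows are gap
# regions. A value index maps each sampled tag to the runs carrying it, so
# all haplotype positions traversing a given node start can be enumerated
# with the r-index. Space is proportional to the number of sampled runs.

#' Build the sampled tag array (node-start runs only)
#'
#' @param arr A frozen `tag_array`.
#' @return An object of class `sampled_tag_array`.
#' @export
build_sampled <- function(arr) {
  ends <- c(arr$run_start[-1L], arr$N)
  u <- tag_unpack(arr$tags)
  keep <- u$o == 0 & u$v > 0
  starts <- arr$run_start[keep]
  tags <- arr$tags[keep]
  by_tag <- split(seq_along(tags), as.character(tags))
  structure(list(starts = starts, ends = ends[keep], tags = tags,
                 by_tag = by_tag, n = sum(keep), N = arr$N),
            class = "sampled_tag_array")
}

#' @export
print.sampled_tag_array <- function(x, ...) {
  cat(sprintf("sampled tag array: %d node-start runs over %g rows (%d distinct tags)\n",
              x$n, x$N, length(x$by_tag)))
  invisible(x)
}

# sampled run containing a row, or 0
sampled_run_of <- function(sampled, row) {
  if (sampled$n == 0L) return(0L)
  j <- findInterval(row, sampled$starts)
  if (j >= 1L && row < sampled$ends[j]) j else 0L
}

#' Phase 1: node-start tags traversed by a haplotype interval
#'
#' Starts at the row of `(sid, q - 1)` and LF-steps backward to offset `p`;
#' whenever the current row lies in a sampled run, the run's tag is
#' recorded with its offset relative to `p`.
#'
#' @param index An `msbwt_index`.
#' @param sampled A `sampled_tag_array` built over the matching tag array.
#' @param sid 0-based sequence id.
#' @param p,q Half-open interval `[p, q)` on the sequence, `0 <= p < q <=
#'   |H|`.
#' @return A data frame with columns `offset` (relative to `p`), `v`, `o`,
#'   `b`, `packed`, in ascending offset order.
#' @export
find_tags <- function(index, sampled, sid, p, q) {
  if (sid < 0 || sid >= index$m) err_domain("no such sequence")
  l <- index$lens[sid + 1]
  if (p < 0 || q > l || p >= q) err_domain("bad interval [p, q)")
  row <- row_of_seq_pos(index, sid, q - 1)
  offs <- numeric(0); tags <- numeric(0)
  for (j in seq(q - 1, p)) {
    k <- sampled_run_of(sampled, row)
    if (k > 0L) { offs <- c(offs, j - p); tags <- c(tags, sampled$tags[k]) }
    if (j > p) row <- lf_code(index, bwt_code_at(index, row), row)
  }
  o <- order(offs)
  cbind(data.frame(offset = offs[o]), tag_unpack(tags[o]),
        data.frame(packed = tags[o]))
}

#' Phase 2: all haplotype positions at a node-start tag
#'
#' Enumerates the sampled runs carrying the tag and locates every row of
#' their BWT intervals: each resulting `(sid, offset)` is a haplotype
#' position whose suffix starts at exactly this graph position.
#'
#' @param index An `msbwt_index`.
#' @param sampled A `sampled_tag_array`.
#' @param tag A `graph_position` (or `c(v, o, b)`), with `o = 0`.
#' @return A data frame with columns `sid`, `offset`, sorted; empty if the
#'   tag is absent from the value index.
#' @export
find_sequences <- function(index, sampled, tag) {
  packed <- as_packed_tag(tag)
  if (tag_unpack(packed)$o != 0) err_domain("tag must be a node start (o = 0)")
  runs <- sampled$by_tag[[as.character(packed)]]
  if (is.null(runs))
    return(data.frame(sid = numeric(0), offset = numeric(0)))
  out <- lapply(runs, function(k)
    locate_all(index, c(sampled$starts[k], sampled$ends[k] - 1))[, c("sid", "offset")])
  out <- do.call(rbind, out)
  out <- unique(out[order(out$sid, out$offset), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' One-to-all coordinate translation
#'
#' Maps the interval `[p, q)` on sequence `sid` to every haplotype position
#' passing through the same node starts: phase 1 collects the node-start
#' tags the interval traverses, phase 2 enumerates, for each tag, all
#' `(sid', offset')` pairs whose suffix starts at that graph position. The
#' query sequence's own hits are included (`other = FALSE`) as a
#' consistency handle. With `collapse_rc = TRUE`, hits on reverse-complement
#' partner sequences are re-expressed on the forward sequence (`sid'`
#' becomes the partner id and `offset'` is mirrored to `len - 1 - offset'`).
#'
#' An interval crossing no node start yields an empty report: sub-node
#' resolution is left to offset arithmetic by the caller.
#'
#' @inheritParams find_tags
#' @param collapse_rc Collapse reverse-complement hits onto forward
#'   coordinates (default `FALSE`: raw pairs).
#' @return A data frame with columns `offset` (within `[p, q)`), `v`, `o`,
#'   `b`, `sid2`, `offset2`, `other`, `strand`.
#' @export
translate_coords <- function(index, sampled, sid, p, q, collapse_rc = FALSE) {
  ft <- find_tags(index, sampled, sid, p, q)
  empty <- data.frame(offset = numeric(0), v = numeric(0), o = numeric(0),
                      b = numeric(0), sid2 = numeric(0), offset2 = numeric(0),
                      other = logical(0), strand = character(0))
  if (nrow(ft) == 0L) return(empty)
  res <- lapply(seq_len(nrow(ft)), function(i) {
    hits <- find_sequences(index, sampled, ft$packed[i])
    if (nrow(hits) == 0L) return(NULL)
    data.frame(offset = ft$offset[i], v = ft$v[i], o = ft$o[i], b = ft$b[i],
               sid2 = hits$sid, offset2 = hits$offset)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res$strand <- "+"
  if (collapse_rc) {
    is_rc <- res$sid2 %% 2 == 1
    lens <- index$lens[res$sid2 + 1]
    res$offset2[is_rc] <- lens[is_rc] - 1 - res$offset2[is_rc]
    res$sid2[is_rc] <- res$sid2[is_rc] - 1
    res$strand[is_rc] <- "-"
  }
  res$other <- res$sid2 != sid
  rownames(res) <- NULL
  res[order(res$offset, res$sid2, res$offset2),
      c("offset", "v", "o", "b", "sid2", "offset2", "other", "strand")]
}
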