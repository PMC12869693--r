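# Graph positions and their packed representation --------------------------
#
# A graph position is the triplet (v, o, b): node id (>= 1), 0-based offset
# within the node, and orientation (0 = forward strand of the node, 1 =
# reverse). v = 0 is reserved for bookkeeping tags. Positions are packed into
# a single double
#
#     packed = (v * 2^20 + o) * 2 + b
#
# so run containers can hold them in plain numeric vectors, and the natural
# numeric order of packed values equals the lexicographic (v, o, b) order.
# Offsets are limited to o < 2^20 (node length < ~1 Mbp) and node ids to
# v < 2^30, which keeps packed values exactly representable in a double.

TAG_MAXO <- 2^20
TAG_GAP  <- 0  # unassigned rows during construction      (v = 0, o = 0, b = 0)
TAG_END  <- 2  # end-marker rows of the BWT               (v = 0, o = 1, b = 0)
TAG_SENT <- 6  # sentinel entry of the run-length B+ tree (v = 0, o = 3, b = 0)

tag_pack <- function(v, o, b) ((v * TAG_MAXO) + o) * 2 + b

tag_unpack <- function(tag) {
  b  <- tag %% 2
  vo <- (tag - b) / 2
  o  <- vo %% TAG_MAXO
  data.frame(v = (vo - o) / TAG_MAXO, o = o, b = b)
}

# reserved tags have v == 0, i.e. packed < 2 * TAG_MAXO
tag_is_reserved <- function(tag) tag < 2 * TAG_MAXO

#' Create a graph position
#'
#' A graph position identifies where a suffix of an indexed haplotype starts
#' in the pangenome graph: node `v`, 0-based offset `o` within the node, and
#' orientation `b` (0 = forward strand of the node, 1 = reverse strand, with
#' the offset counted along the traversal direction).
#'
#' @param v Node identifier (positive integer; internal id).
#' @param o 0-based offset within the node.
#' @param b Orientation flag, 0 or 1.
#' @return An object of class `graph_position` (a named list).
#' @export
graph_position <- function(v, o, b = 0) {
  v <- as.numeric(v); o <- as.numeric(o); b <- as.numeric(b)
  if (length(v) != 1L || length(o) != 1L || length(b) != 1L ||
      is.na(v) || is.na(o) || is.na(b) || v < 1 || o < 0 || o >= TAG_MAXO ||
      !b %in% c(0, 1))
    err_domain("invalid graph position (v, o, b)")
  structure(list(v = v, o = o, b = b), class = "graph_position")
}

#' @export
print.graph_position <- function(x, ...) {
  cat(sprintf("graph position (v = %d, o = %d, b = %d)\n", x$v, x$o, x$b))
  invisible(x)
}

# accept a graph_position, a length-3 vector, or a 1-row data frame
as_packed_tag <- function(pos) {
  if (inherits(pos, "graph_position")) return(tag_pack(pos$v, pos$o, pos$b))
  if (is.data.frame(pos)) {
    if (nrow(pos) != 1L) err_domain("expected a single graph position")
    return(tag_pack(pos$v, pos$o, pos$b))
  }
  if (is.numeric(pos) && length(pos) == 3L) return(tag_pack(pos[1], pos[2], pos[3]))
  if (is.numeric(pos) && length(pos) == 1L) return(as.numeric(pos))
  err_domain("cannot interpret graph position")
}
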