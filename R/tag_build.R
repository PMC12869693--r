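# Three-stage tag-array construction and whole-index merge ------------------
#
# Stage 1 anchors the BWT interval of every unique k-mer with the k-mer's
# graph position; stage 2 extends anchors backward through the graph,
# following the grouped-predecessor rule at variation; stage 3 walks every
# haplotype (and reverse-complement) backwards with LF and fills the rows no
# unique context reaches. Stage 3 alone would already build the array; the
# first two stages exist so the expensive traversal touches few rows.

#' Stage 1: anchor unique k-mers
#'
#' For each unique k-mer with backward-search interval `[A, B]`, inserts the
#' run `(A, B + 1 - A)` tagged with the k-mer's graph position.
#'
#' @param index An `msbwt_index` built over the same text the k-mers were
#'   enumerated from.
#' @param tree An `rlb_tree` over `[0, N)`.
#' @param kmers A data frame from [unique_kmers()].
#' @return A stage report: k-mers anchored, runs inserted, rows covered.
#' @export
anchor_unique_kmers <- function(index, tree, kmers) {
  before <- covered_count(tree)
  inserted <- 0L
  if (nrow(kmers)) {
    packed <- if ("packed" %in% names(kmers)) kmers$packed
              else tag_pack(kmers$v, kmers$o, kmers$b)
    for (i in seq_len(nrow(kmers))) {
      iv <- backward_search(index, kmers$kmer[i])
      w <- lex_width(iv)
      if (w == 0) next
      insert_run(tree, iv[1], w, packed[i])
      inserted <- inserted + 1L
    }
  }
  list(stage = "anchor", kmers = nrow(kmers), runs_inserted = inserted,
       covered = covered_count(tree),
       rows_covered = covered_count(tree) - before,
       coverage = covered_count(tree) / tree$N)
}

#' Stage 2: extend anchors backward through the graph
#'
#' Breadth-first worklist seeded from the anchor intervals. Each item
#' `(interval, position)` is extended by its unique predecessor branches
#' (single predecessor, or, at variation, each last-base character
#' contributed by exactly one predecessor node); the extended interval is
#' `[LF(c, A), LF(c, B + 1) - 1]`. Branches stop at ambiguity, empty
#' intervals, sequence starts, already-seen intervals, or `max_rounds`.
#'
#' @param graph The `pangenome_graph`.
#' @param index An `msbwt_index`.
#' @param tree The `rlb_tree` after stage 1.
#' @param kmers The unique k-mer table used for stage 1.
#' @param max_rounds Maximum extension depth per branch (default 256).
#' @return A stage report including rows covered per round.
#' @export
extend_anchors <- function(graph, index, tree, kmers, max_rounds = 256) {
  before <- covered_count(tree)
  queue <- vector("list", 256L); head <- 1L; tail <- 0L
  push <- function(item) {
    tail <<- tail + 1L
    if (tail > length(queue)) length(queue) <<- 2L * length(queue)
    queue[[tail]] <<- item
  }
  seen <- new.env(parent = emptyenv())
  by_round <- numeric(0)
  if (nrow(kmers)) {
    packed <- if ("packed" %in% names(kmers)) kmers$packed
              else tag_pack(kmers$v, kmers$o, kmers$b)
    for (i in seq_len(nrow(kmers))) {
      iv <- backward_search(index, kmers$kmer[i])
      if (lex_width(iv) == 0) next
      key <- as.character(iv[1])
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        push(c(iv[1], iv[2], packed[i], 0))
      }
    }
  }
  while (head <= tail) {
    item <- queue[[head]]; queue[head] <- list(NULL); head <- head + 1L
    depth <- item[4]
    if (depth >= max_rounds) next
    up <- unique_predecessors_packed(graph, item[3])
    if (length(up$chars) == 0L) next
    for (i in seq_along(up$chars)) {
      code <- match(up$chars[i], ALPHABET)
      A2 <- lf_code(index, code, item[1])
      B2 <- lf_code(index, code, item[2] + 1) - 1
      if (B2 < A2) next
      key <- as.character(A2)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cb <- covered_count(tree)
      insert_run(tree, A2, B2 + 1 - A2, up$tags[i])
      d <- depth + 1
      if (d > length(by_round)) by_round <- c(by_round, numeric(d - length(by_round)))
      by_round[d] <- by_round[d] + (covered_count(tree) - cb)
      push(c(A2, B2, up$tags[i], d))
    }
  }
  list(stage = "extend", rounds = length(by_round),
       rows_covered_per_round = by_round,
       covered = covered_count(tree),
       rows_covered = covered_count(tree) - before,
       coverage = covered_count(tree) / tree$N)
}

#' Stage 3: fill remaining gaps by haplotype traversal
#'
#' For each indexed sequence (forward and reverse complement alike), walks
#' backward with LF from its end-marker row over all `|H|` positions; any
#' row still GAP receives the graph position of the corresponding base.
#' A row already tagged differently from the traversal tag is an integrity
#' error (it would mean stages 1-2 assigned a wrong tag). Finally the
#' end-marker rows receive the reserved END tag, so coverage reaches `N`.
#'
#' Run on a fresh tree this stage builds the complete tag array on its own.
#'
#' @param graph The `pangenome_graph`.
#' @param index An `msbwt_index`.
#' @param tree The `rlb_tree` (stages 1-2 applied, or fresh).
#' @return A stage report.
#' @export
fill_gaps <- function(graph, index, tree) {
  before <- covered_count(tree)
  ix <- indexed_sequences(graph)
  m <- index$m
  if (length(ix$seqs) != m) err_domain("graph does not match index")
  for (sid0 in seq_len(m) - 1L) {
    tv <- ix$tags[[sid0 + 1L]]
    l <- index$lens[sid0 + 1L]
    row <- sid0
    if (l > 0) for (j in seq(l - 1, 0)) {
      row <- lf_code(index, bwt_code_at(index, row), row)
      cur <- tag_at(tree, row)
      t <- tv[j + 1]
      if (cur == TAG_GAP) insert_run(tree, row, 1, t)
      else if (cur != t)
        err_integrity(sprintf(
          "row %g tagged %g but haplotype traversal expects %g", row, cur, t))
    }
  }
  insert_run(tree, 0, m, TAG_END)
  if (covered_count(tree) != tree$N)
    err_integrity("traversal finished with uncovered rows")
  list(stage = "fill", covered = covered_count(tree),
       rows_covered = covered_count(tree) - before, coverage = 1)
}

#' Build index and tag array for a whole graph
#'
#' Runs text construction, BWT indexing and the three construction stages,
#' and freezes the result.
#'
#' @param graph A `pangenome_graph`.
#' @param k Anchor k-mer length (default 31).
#' @param degree RLB+ tree degree (default 64).
#' @param max_rounds Extension depth cap (default 256).
#' @return A list with `index` (`msbwt_index`), `tags` (`tag_array`) and a
#'   per-stage `report`.
#' @export
build_tags <- function(graph, k = 31, degree = 64, max_rounds = 256) {
  text <- build_text(graph)
  index <- build_msbwt(text)
  tree <- new_tree(index$N, degree)
  kmers <- unique_kmers(graph, k)
  r1 <- anchor_unique_kmers(index, tree, kmers)
  r2 <- extend_anchors(graph, index, tree, kmers, max_rounds)
  r3 <- fill_gaps(graph, index, tree)
  list(index = index, tags = freeze_tags(tree),
       report = list(anchor = r1, extend = r2, fill = r3,
                     coverage = c(anchor = r1$coverage, extend = r2$coverage,
                                  fill = r3$coverage)))
}

# restrict a graph to the walks of one component (nodes and edges are kept,
# so node ids and therefore tags are unchanged)
component_graph <- function(graph, component) {
  walks <- Filter(function(w) graph$comp[w$steps[1L, 1L]] == component,
                  graph$walks)
  if (length(walks) == 0L)
    err_domain(sprintf("component %d has no haplotype walks", component))
  for (i in seq_along(walks)) walks[[i]]$sid <- i - 1L
  g <- graph
  g$walks <- walks
  g
}

#' Build index and tag array for one graph component
#'
#' Runs the full pipeline on the component-restricted text (the walks of
#' that weakly connected component, in their original relative order; node
#' ids, and hence tags, are unchanged).
#'
#' @param graph A `pangenome_graph`.
#' @param component Component id (from the graph's component labelling).
#' @param k,degree,max_rounds As in [build_tags()].
#' @return As [build_tags()], plus `component` and the restricted `graph`.
#' @export
build_component <- function(graph, component, k = 31, degree = 64,
                            max_rounds = 256) {
  g <- component_graph(graph, component)
  res <- build_tags(g, k = k, degree = degree, max_rounds = max_rounds)
  res$component <- component
  res$graph <- g
  res
}

#' Merge per-component tag arrays into the whole-index array
#'
#' For each global BWT row in order, the owning sequence's component is
#' determined through the whole index, and the next unread tag of that
#' component's array is emitted (per-component cursors advance by one row
#' per hit). The output equals, row for row, the array built on the whole
#' text directly.
#'
#' @param whole_index An `msbwt_index` over all sequences in global sid
#'   order.
#' @param parts A list of [build_component()] results (or lists with
#'   `component` and `tags`).
#' @param graph The full `pangenome_graph`.
#' @return A `tag_array` over the whole index.
#' @export
merge_components <- function(whole_index, parts, graph) {
  N <- whole_index$N
  loc <- locate_all(whole_index, c(0, N - 1))
  wcomp <- vapply(graph$walks, function(w) graph$comp[w$steps[1L, 1L]], 0L)
  comp_row <- wcomp[loc$sid %/% 2 + 1]
  out <- rep(NA_real_, N)
  for (p in parts) {
    rows <- which(comp_row == p$component)
    expanded <- tag_array_rows(p$tags)
    if (length(rows) != length(expanded))
      err_integrity(sprintf(
        "component %d: %d global rows but %d component rows",
        p$component, length(rows), length(expanded)))
    out[rows] <- expanded
  }
  if (anyNA(out))
    err_integrity("rows belonging to a component without a part")
  tag_array_from_rows(out)
}
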