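# Run-Length B+ tree -------------------------------------------------------
#
# Mutable ordered map from BWT start positions to packed tags with implicit
# run lengths: a run stored as (start, tag) extends to the start of the next
# entry. A sentinel entry at position N with a reserved tag closes the last
# run, and unassigned rows are materialised as runs with the reserved GAP
# tag, so the entries always partition [0, N). Inserting applies the four
# merge conditions (no merge / forward / backward / bidirectional), and the
# entry removals caused by merges are repaired with borrow-then-merge
# rebalancing, propagating upward as in a standard B+ tree.
#
# Nodes are environments: leaves carry parallel vectors `starts`/`tags` plus
# chain links `prv`/`nxt`; internal nodes carry `keys` (minimum start of
# each child subtree) and `kids`. Every descent from the root increments the
# tree's visit counter by the number of nodes touched.

new_leaf <- function(starts, tags, prv = NULL, nxt = NULL, par = NULL) {
  e <- new.env(parent = emptyenv())
  e$leaf <- TRUE; e$starts <- starts; e$tags <- tags
  e$prv <- prv; e$nxt <- nxt; e$par <- par
  e
}

new_internal <- function(keys, kids, par = NULL) {
  e <- new.env(parent = emptyenv())
  e$leaf <- FALSE; e$keys <- keys; e$kids <- kids; e$par <- par
  for (k in kids) k$par <- e
  e
}

#' Create a run-length B+ tree over domain [0, N)
#'
#' The fresh tree holds a single GAP run covering the whole domain plus the
#' sentinel entry at `N`.
#'
#' @param N Domain size (number of BWT rows), at least 1.
#' @param degree Maximum entries per node (at least 4; default 64).
#' @return An object of class `rlb_tree`.
#' @export
new_tree <- function(N, degree = 64) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    err_domain("N must be a single integer >= 1")
  if (!is.numeric(degree) || length(degree) != 1L || degree < 4)
    err_domain("degree must be at least 4")
  tr <- new.env(parent = emptyenv())
  tr$N <- as.numeric(N)
  tr$degree <- as.integer(degree)
  tr$minkeys <- as.integer(ceiling(degree / 2))
  tr$root <- new_leaf(c(0, as.numeric(N)), c(TAG_GAP, TAG_SENT))
  tr$run_count <- 1L    # runs excluding the sentinel
  tr$covered <- 0       # rows with a non-GAP tag
  tr$visits <- 0        # node visits, for the O(log) cost property
  class(tr) <- "rlb_tree"
  tr
}

#' @export
print.rlb_tree <- function(x, ...) {
  cat(sprintf("run-length B+ tree: N = %g, %d runs, %g/%g rows covered, degree %d\n",
              x$N, x$run_count, x$covered, x$N, x$degree))
  invisible(x)
}

node_size <- function(node) if (node$leaf) length(node$starts) else length(node$kids)
node_min <- function(node) if (node$leaf) node$starts[1L] else node$keys[1L]

descend <- function(tree, pos) {
  node <- tree$root
  repeat {
    tree$visits <- tree$visits + 1
    if (node$leaf) return(node)
    i <- findInterval(pos, node$keys)
    if (i < 1L) i <- 1L
    node <- node$kids[[i]]
  }
}

kid_index <- function(par, node) {
  for (i in seq_along(par$kids)) if (identical(par$kids[[i]], node)) return(i)
  err_integrity("child not found in parent")
}

update_min_upward <- function(node) {
  repeat {
    par <- node$par
    if (is.null(par)) return(invisible())
    i <- kid_index(par, node)
    nm <- node_min(node)
    if (par$keys[i] == nm) return(invisible())
    par$keys[i] <- nm
    if (i > 1L) return(invisible())
    node <- par
  }
}

# entry containing position pos: list(leaf, j, start, tag, end)
entry_at <- function(tree, pos) {
  leaf <- descend(tree, pos)
  j <- findInterval(pos, leaf$starts)
  if (j < 1L) err_integrity("position below leaf minimum")
  end <- if (j < length(leaf$starts)) leaf$starts[j + 1L]
         else if (!is.null(leaf$nxt)) leaf$nxt$starts[1L]
         else Inf   # sentinel entry itself
  list(leaf = leaf, j = j, start = leaf$starts[j], tag = leaf$tags[j], end = end)
}

split_leaf <- function(tree, leaf) {
  len <- length(leaf$starts)
  h <- ceiling(len / 2)
  right <- new_leaf(leaf$starts[(h + 1L):len], leaf$tags[(h + 1L):len],
                    prv = leaf, nxt = leaf$nxt, par = leaf$par)
  if (!is.null(leaf$nxt)) leaf$nxt$prv <- right
  leaf$nxt <- right
  leaf$starts <- leaf$starts[1:h]; leaf$tags <- leaf$tags[1:h]
  insert_child_after(tree, leaf, right)
}

split_internal <- function(tree, node) {
  len <- length(node$kids)
  h <- ceiling(len / 2)
  right <- new_internal(node$keys[(h + 1L):len], node$kids[(h + 1L):len],
                        par = node$par)
  node$keys <- node$keys[1:h]; node$kids <- node$kids[1:h]
  insert_child_after(tree, node, right)
}

insert_child_after <- function(tree, node, right) {
  par <- node$par
  if (is.null(par)) {
    tree$root <- new_internal(c(node_min(node), node_min(right)),
                              list(node, right))
    return(invisible())
  }
  i <- kid_index(par, node)
  par$kids <- append(par$kids, list(right), after = i)
  par$keys <- append(par$keys, node_min(right), after = i)
  right$par <- par
  if (length(par$kids) > tree$degree) split_internal(tree, par)
  invisible()
}

ins_entry <- function(tree, start, tag) {
  leaf <- descend(tree, start)
  j <- findInterval(start, leaf$starts)
  if (j >= 1L && leaf$starts[j] == start)
    err_integrity("entry already present at this start")
  leaf$starts <- append(leaf$starts, start, after = j)
  leaf$tags <- append(leaf$tags, tag, after = j)
  tree$run_count <- tree$run_count + 1L
  if (j == 0L) update_min_upward(leaf)
  if (length(leaf$starts) > tree$degree) split_leaf(tree, leaf)
  invisible()
}

set_tag_entry <- function(tree, start, tag) {
  leaf <- descend(tree, start)
  j <- findInterval(start, leaf$starts)
  if (j < 1L || leaf$starts[j] != start) err_integrity("no entry at this start")
  leaf$tags[j] <- tag
  invisible()
}

del_entry <- function(tree, start) {
  leaf <- descend(tree, start)
  j <- findInterval(start, leaf$starts)
  if (j < 1L || leaf$starts[j] != start) err_integrity("no entry at this start")
  leaf$starts <- leaf$starts[-j]; leaf$tags <- leaf$tags[-j]
  tree$run_count <- tree$run_count - 1L
  if (!identical(leaf, tree$root) && length(leaf$starts) < tree$minkeys) {
    rebalance_leaf(tree, leaf)
  } else if (j == 1L && length(leaf$starts) > 0L) {
    update_min_upward(leaf)
  }
  invisible()
}

rebalance_leaf <- function(tree, leaf) {
  par <- leaf$par
  i <- kid_index(par, leaf)
  left <- if (i > 1L) par$kids[[i - 1L]] else NULL
  right <- if (i < length(par$kids)) par$kids[[i + 1L]] else NULL
  if (!is.null(left) && length(left$starts) > tree$minkeys) {
    l <- length(left$starts)
    leaf$starts <- c(left$starts[l], leaf$starts)
    leaf$tags <- c(left$tags[l], leaf$tags)
    left$starts <- left$starts[-l]; left$tags <- left$tags[-l]
    update_min_upward(leaf)
  } else if (!is.null(right) && length(right$starts) > tree$minkeys) {
    leaf$starts <- c(leaf$starts, right$starts[1L])
    leaf$tags <- c(leaf$tags, right$tags[1L])
    right$starts <- right$starts[-1L]; right$tags <- right$tags[-1L]
    update_min_upward(leaf)
    update_min_upward(right)
  } else if (!is.null(left)) {
    left$starts <- c(left$starts, leaf$starts)
    left$tags <- c(left$tags, leaf$tags)
    left$nxt <- leaf$nxt
    if (!is.null(leaf$nxt)) leaf$nxt$prv <- left
    remove_child(tree, par, i)
  } else {
    leaf$starts <- c(leaf$starts, right$starts)
    leaf$tags <- c(leaf$tags, right$tags)
    leaf$nxt <- right$nxt
    if (!is.null(right$nxt)) right$nxt$prv <- leaf
    update_min_upward(leaf)
    remove_child(tree, par, i + 1L)
  }
  invisible()
}

rebalance_internal <- function(tree, node) {
  par <- node$par
  i <- kid_index(par, node)
  left <- if (i > 1L) par$kids[[i - 1L]] else NULL
  right <- if (i < length(par$kids)) par$kids[[i + 1L]] else NULL
  if (!is.null(left) && length(left$kids) > tree$minkeys) {
    l <- length(left$kids)
    moved <- left$kids[[l]]
    node$kids <- c(list(moved), node$kids)
    node$keys <- c(left$keys[l], node$keys)
    moved$par <- node
    left$kids <- left$kids[-l]; left$keys <- left$keys[-l]
    update_min_upward(node)
  } else if (!is.null(right) && length(right$kids) > tree$minkeys) {
    moved <- right$kids[[1L]]
    node$kids <- c(node$kids, list(moved))
    node$keys <- c(node$keys, right$keys[1L])
    moved$par <- node
    right$kids <- right$kids[-1L]; right$keys <- right$keys[-1L]
    update_min_upward(node)
    update_min_upward(right)
  } else if (!is.null(left)) {
    for (k in node$kids) k$par <- left
    left$kids <- c(left$kids, node$kids)
    left$keys <- c(left$keys, node$keys)
    remove_child(tree, par, i)
  } else {
    for (k in right$kids) k$par <- node
    node$kids <- c(node$kids, right$kids)
    node$keys <- c(node$keys, right$keys)
    update_min_upward(node)
    remove_child(tree, par, i + 1L)
  }
  invisible()
}

remove_child <- function(tree, par, i) {
  par$kids[[i]] <- NULL
  par$keys <- par$keys[-i]
  if (is.null(par$par)) {
    if (length(par$kids) == 1L) {
      tree$root <- par$kids[[1L]]
      tree$root$par <- NULL
    }
  } else if (length(par$kids) < tree$minkeys) {
    rebalance_internal(tree, par)
  } else if (i == 1L) {
    update_min_upward(par)
  }
  invisible()
}

#' Tag of the run containing a row
#'
#' @param tree An `rlb_tree`.
#' @param i A 0-based row, `0 <= i < N`.
#' @return The packed tag of the run containing `i` (possibly the GAP tag).
#'   Use [tag_unpack_public()] or compare against reserved values.
#' @export
tag_at <- function(tree, i) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 0 || i >= tree$N)
    err_domain("row out of range")
  entry_at(tree, i)$tag
}

#' Insert a tag run into the tree
#'
#' Rows of `[start, start + length)` that were GAP now carry `tag`; overlap
#' with runs already carrying the same tag is absorbed, and the four merge
#' conditions (none / forward / backward / bidirectional) are applied, with
#' leaf splits on overflow and borrow-then-merge rebalancing on the
#' underflows that bidirectional merges can cause. Overlap with a
#' differently-tagged assigned region raises a conflict error unless
#' `overwrite` is set (testing only).
#'
#' @param tree An `rlb_tree`.
#' @param start 0-based start row.
#' @param length Run length, at least 1.
#' @param tag The packed tag (or a `graph_position` / `c(v,o,b)` triple);
#'   must not be the GAP tag.
#' @param overwrite Allow replacing differently-tagged assigned rows.
#' @return The tree, invisibly.
#' @export
insert_run <- function(tree, start, length, tag, overwrite = FALSE) {
  tag <- as_packed_tag(tag)
  if (is.na(start) || is.na(length) || length < 1 || start < 0 ||
      start + length > tree$N)
    err_domain("run out of bounds")
  if (tag == TAG_GAP || tag == TAG_SENT)
    err_domain("cannot insert a GAP or sentinel run")
  s <- start; e <- start + length
  if (!overwrite) {
    # pre-scan so a conflict raises before any mutation (atomic insert)
    while (s < e) {
      ent <- entry_at(tree, s)
      if (ent$tag != tag && ent$tag != TAG_GAP)
        err_conflict(sprintf(
          "rows [%g, %g) already tagged differently (existing %g, new %g)",
          s, min(e, ent$end), ent$tag, tag))
      s <- ent$end
    }
    s <- start
  }
  while (s < e) {
    ent <- entry_at(tree, s)
    st <- ent$start; en <- ent$end; old <- ent$tag
    pe <- min(e, en)
    if (old == tag) { s <- pe; next }
    prev_tag <- if (s > st) old else if (st > 0) entry_at(tree, st - 1)$tag else NA_real_
    next_tag <- if (pe < en) old else entry_at(tree, pe)$tag
    if (s == st && pe == en) {
      pm <- !is.na(prev_tag) && prev_tag == tag
      nm <- next_tag == tag
      if (pm && nm) { del_entry(tree, st); del_entry(tree, en) }
      else if (pm) del_entry(tree, st)
      else if (nm) { set_tag_entry(tree, st, tag); del_entry(tree, en) }
      else set_tag_entry(tree, st, tag)
    } else if (s > st && pe == en) {
      if (next_tag == tag) { del_entry(tree, en); ins_entry(tree, s, tag) }
      else ins_entry(tree, s, tag)
    } else if (s == st && pe < en) {
      ins_entry(tree, pe, old)
      if (!is.na(prev_tag) && prev_tag == tag) del_entry(tree, st)
      else set_tag_entry(tree, st, tag)
    } else {
      ins_entry(tree, pe, old)
      ins_entry(tree, s, tag)
    }
    if (old == TAG_GAP) tree$covered <- tree$covered + (pe - s)
    s <- pe
  }
  invisible(tree)
}

#' Canonical run sequence of the tree
#'
#' Flattens the leaves left to right, including GAP runs and the sentinel;
#' run lengths are derived from successive start differences.
#'
#' @param tree An `rlb_tree`.
#' @return A data frame with columns `start`, `tag`, `length` (sentinel
#'   length 0).
#' @export
iterate_runs <- function(tree) {
  leaf <- descend(tree, 0)
  starts <- numeric(0); tags <- numeric(0)
  while (!is.null(leaf)) {
    starts <- c(starts, leaf$starts)
    tags <- c(tags, leaf$tags)
    leaf <- leaf$nxt
  }
  data.frame(start = starts, tag = tags,
             length = c(diff(starts), 0))
}

#' Number of rows carrying a non-GAP tag
#' @param tree An `rlb_tree`.
#' @return A count in `[0, N]`.
#' @export
covered_count <- function(tree) tree$covered

#' Number of runs (excluding the sentinel)
#' @param tree An `rlb_tree`.
#' @return A count.
#' @export
run_count <- function(tree) tree$run_count

#' Structural audit of the tree
#'
#' Checks B+ occupancy and depth invariants, separator-key consistency,
#' the leaf chain, strictly increasing starts starting at 0, the sentinel,
#' that adjacent runs differ in tag, and the covered/run-count bookkeeping.
#' Errors (integrity condition) on any violation.
#'
#' @param tree An `rlb_tree`.
#' @return `TRUE`, invisibly.
#' @export
rlb_audit <- function(tree) {
  depths <- integer(0)
  walk <- function(node, depth) {
    if (node$leaf) {
      depths <<- c(depths, depth)
      if (!identical(node, tree$root) &&
          (length(node$starts) < tree$minkeys || length(node$starts) > tree$degree))
        err_integrity("leaf occupancy out of bounds")
      if (is.unsorted(node$starts, strictly = TRUE))
        err_integrity("leaf starts not strictly increasing")
    } else {
      if (!identical(node, tree$root) &&
          (length(node$kids) < tree$minkeys || length(node$kids) > tree$degree))
        err_integrity("internal occupancy out of bounds")
      if (identical(node, tree$root) && length(node$kids) < 2L)
        err_integrity("internal root with fewer than 2 children")
      if (length(node$keys) != length(node$kids))
        err_integrity("key/child count mismatch")
      for (i in seq_along(node$kids)) {
        k <- node$kids[[i]]
        if (!identical(k$par, node)) err_integrity("broken parent pointer")
        if (node$keys[i] != node_min(k)) err_integrity("separator key != child min")
        walk(k, depth + 1L)
      }
    }
  }
  walk(tree$root, 0L)
  if (length(unique(depths)) != 1L) err_integrity("leaves at unequal depth")
  runs <- iterate_runs(tree)
  n <- nrow(runs)
  if (runs$start[1L] != 0) err_integrity("first run does not start at 0")
  if (runs$start[n] != tree$N || runs$tag[n] != TAG_SENT)
    err_integrity("missing or misplaced sentinel")
  if (is.unsorted(runs$start, strictly = TRUE))
    err_integrity("run starts not strictly increasing")
  if (n > 1L && any(runs$tag[-n] == runs$tag[-1L]))
    err_integrity("adjacent runs share a tag")
  if (tree$run_count != n - 1L) err_integrity("run_count out of sync")
  cov <- sum(runs$length[runs$tag != TAG_GAP & runs$tag != TAG_SENT])
  if (cov != tree$covered) err_integrity("covered_count out of sync")
  invisible(TRUE)
}

#' Visit counter of the tree
#'
#' Number of nodes touched by descents since creation (or since
#' [reset_visits()]); used to check the logarithmic cost bound.
#'
#' @param tree An `rlb_tree`.
#' @return A count.
#' @export
tree_visits <- function(tree) tree$visits

#' @rdname tree_visits
#' @export
reset_visits <- function(tree) { tree$visits <- 0; invisible(tree) }
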