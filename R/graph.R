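# Pangenome graph model: oriented nodes, edges, haplotype walks -------------

edge_key <- function(v1, b1, v2, b2) paste(v1, b1, v2, b2, sep = ".")

# Assemble and validate a pangenome_graph from parsed parts. Edges are stored
# closed under reversal; incoming-edge lists are precomputed per oriented
# node start for predecessor queries.
make_graph <- function(nodes, node_names, edges, walks) {
  n <- length(nodes)
  if (n < 1L) err_format("graph has no segments")
  if (any(nchar(nodes) == 0L)) err_format("empty segment sequence")
  bad <- grepl("[^ACGTN]", nodes)
  if (any(bad))
    err_format(sprintf("non-ACGTN base in segment '%s'", node_names[which(bad)[1L]]))

  # symmetrize edge set
  if (nrow(edges)) {
    edges <- rbind(edges,
                   data.frame(v1 = edges$v2, b1 = 1L - edges$b2,
                              v2 = edges$v1, b2 = 1L - edges$b1))
    edges <- unique(edges)
    edges <- edges[order(edges$v1, edges$b1, edges$v2, edges$b2), , drop = FALSE]
    rownames(edges) <- NULL
    if (any(edges$v1 < 1L | edges$v1 > n | edges$v2 < 1L | edges$v2 > n))
      err_format("edge references unknown segment")
  }
  ekeys <- if (nrow(edges)) edge_key(edges$v1, edges$b1, edges$v2, edges$b2) else character(0)

  # incoming oriented edges per (v, b) node start
  in_edges <- list()
  if (nrow(edges)) {
    tgt <- paste(edges$v2, edges$b2, sep = ".")
    in_edges <- split(data.frame(v = edges$v1, b = edges$b1), tgt)
  }

  # walks: validate steps and edge support
  if (length(walks) == 0L) err_format("graph has no haplotype walks (P/W lines)")
  eset <- ekeys
  for (w in walks) {
    st <- w$steps
    if (nrow(st) == 0L) err_format(sprintf("empty walk '%s'", w$name))
    if (any(st[, 1L] < 1L | st[, 1L] > n))
      err_format(sprintf("walk '%s' references unknown segment", w$name))
    if (nrow(st) > 1L) {
      k <- edge_key(st[-nrow(st), 1L], st[-nrow(st), 2L], st[-1L, 1L], st[-1L, 2L])
      if (!all(k %in% eset))
        err_format(sprintf("walk '%s' uses a step pair not supported by an edge", w$name))
    }
  }

  # weakly connected components over the node set
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) data.frame(from = as.character(edges$v1),
                                    to = as.character(edges$v2)) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  memb <- igraph::components(g)$membership
  comp <- as.integer(memb[as.character(seq_len(n))])

  for (w in walks) {
    if (length(unique(comp[w$steps[, 1L]])) != 1L)
      err_format(sprintf("walk '%s' crosses components", w$name))
  }

  structure(list(nodes = nodes, node_names = node_names,
                 name2id = stats::setNames(seq_len(n), node_names),
                 edges = edges, edge_keys = ekeys, in_edges = in_edges,
                 walks = walks, comp = comp),
            class = "pangenome_graph")
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat(sprintf("pangenome graph: %d nodes (%d bp), %d oriented edges, %d haplotypes, %d component(s)\n",
              length(x$nodes), sum(nchar(x$nodes)), nrow(x$edges),
              length(x$walks), max(x$comp)))
  invisible(x)
}

#' Read a pangenome graph from GFA1
#'
#' Parses S (segments), L (links) and P/W (haplotype path/walk) lines.
#' Segments are assigned dense internal ids in S-line order starting at 1;
#' walks receive dense 0-based sequence identifiers in file order. P-line
#' overlaps must be `*` or `0M`. The edge set is closed under reversal.
#'
#' @param path Path to a GFA1 file.
#' @return A `pangenome_graph`.
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) err_usage(sprintf("GFA file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  types <- substr(lines, 1L, 1L)

  slines <- strsplit(lines[types == "S"], "\t", fixed = TRUE)
  if (length(slines) == 0L) err_format("GFA has no S lines")
  node_names <- vapply(slines, `[`, "", 2L)
  nodes <- toupper(vapply(slines, `[`, "", 3L))
  if (anyDuplicated(node_names))
    err_format("duplicate segment name in GFA")
  name2id <- stats::setNames(seq_along(node_names), node_names)

  seg_id <- function(nm, line) {
    id <- name2id[nm]
    if (anyNA(id))
      err_format(sprintf("unknown segment '%s' in line: %s",
                         nm[which(is.na(id))[1L]], line))
    unname(id)
  }
  ori_bit <- function(o, line) {
    b <- match(o, c("+", "-")) - 1L
    if (anyNA(b)) err_format(sprintf("bad orientation in line: %s", line))
    b
  }

  e_from <- integer(0); e_fb <- integer(0); e_to <- integer(0); e_tb <- integer(0)
  walks <- list()
  sid <- 0L
  for (ln in lines) {
    t <- substr(ln, 1L, 1L)
    if (t == "L") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 6L) err_format(sprintf("malformed L line: %s", ln))
      e_from <- c(e_from, seg_id(f[2L], ln)); e_fb <- c(e_fb, ori_bit(f[3L], ln))
      e_to   <- c(e_to,   seg_id(f[4L], ln)); e_tb <- c(e_tb, ori_bit(f[5L], ln))
    } else if (t == "P") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) err_format(sprintf("malformed P line: %s", ln))
      segs <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
      if (length(segs) == 0L || !nzchar(f[3L]))
        err_format(sprintf("empty walk in P line '%s'", f[2L]))
      nm <- sub("[+-]$", "", segs)
      ob <- ori_bit(sub("^.*([+-])$", "\\1", segs), ln)
      if (length(f) >= 4L && nzchar(f[4L]) && f[4L] != "*") {
        ov <- strsplit(f[4L], ",", fixed = TRUE)[[1L]]
        if (!all(ov %in% c("0M", "*")))
          err_format(sprintf("P line '%s' has non-trivial overlaps", f[2L]))
      }
      walks[[length(walks) + 1L]] <-
        list(sid = sid, name = f[2L],
             steps = cbind(v = seg_id(nm, ln), b = ob))
      sid <- sid + 1L
    } else if (t == "W") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 7L) err_format(sprintf("malformed W line: %s", ln))
      wstr <- f[7L]
      if (!nzchar(wstr)) err_format(sprintf("empty walk in W line for sample '%s'", f[2L]))
      toks <- regmatches(wstr, gregexpr("[<>][^<>]+", wstr))[[1L]]
      if (length(toks) == 0L) err_format(sprintf("malformed W walk: %s", wstr))
      nm <- substring(toks, 2L)
      ob <- ifelse(substr(toks, 1L, 1L) == ">", 0L, 1L)
      walks[[length(walks) + 1L]] <-
        list(sid = sid, name = paste(f[2L], f[3L], f[4L], sep = "#"),
             steps = cbind(v = seg_id(nm, ln), b = as.integer(ob)))
      sid <- sid + 1L
    }
  }
  edges <- data.frame(v1 = e_from, b1 = e_fb, v2 = e_to, b2 = e_tb)
  make_graph(nodes, node_names, edges, walks)
}

#' Write a pangenome graph as GFA1
#'
#' Emits S lines in internal id order, one L line per undirected edge, and a
#' P line per haplotype walk (overlaps `*`). `read_gfa(write_gfa(g))` parses
#' to an equal graph.
#'
#' @param graph A `pangenome_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  out <- c("H\tVN:Z:1.0",
           sprintf("S\t%s\t%s", graph$node_names, graph$nodes))
  e <- graph$edges
  if (nrow(e)) {
    k1 <- edge_key(e$v1, e$b1, e$v2, e$b2)
    k2 <- edge_key(e$v2, 1L - e$b2, e$v1, 1L - e$b1)
    keep <- k1 <= k2
    ee <- e[keep, , drop = FALSE]
    out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t0M",
                          graph$node_names[ee$v1], c("+", "-")[ee$b1 + 1L],
                          graph$node_names[ee$v2], c("+", "-")[ee$b2 + 1L]))
  }
  for (w in graph$walks) {
    segs <- paste0(graph$node_names[w$steps[, 1L]],
                   c("+", "-")[w$steps[, 2L] + 1L], collapse = ",")
    out <- c(out, sprintf("P\t%s\t%s\t*", w$name, segs))
  }
  writeLines(out, path)
  invisible(path)
}

get_walk <- function(graph, walk) {
  if (is.numeric(walk) && length(walk) == 1L) {
    i <- walk + 1L
    if (i < 1L || i > length(graph$walks)) err_domain("no such haplotype walk")
    return(graph$walks[[i]])
  }
  if (is.list(walk) && !is.null(walk$steps)) return(walk)
  err_domain("walk must be a 0-based haplotype index or a walk object")
}

# traversal-oriented sequence of one step
step_seq <- function(graph, v, b) {
  s <- graph$nodes[v]
  if (b == 1L) rc_string(s) else s
}

#' Spell the DNA sequence of a haplotype walk
#'
#' Concatenates, over the walk steps, the node sequence (orientation 0) or
#' its reverse complement (orientation 1).
#'
#' @param walk A walk object from the graph, or a 0-based haplotype index.
#' @param graph A `pangenome_graph`.
#' @return A DNA string.
#' @export
spell <- function(walk, graph) {
  w <- get_walk(graph, walk)
  paste(vapply(seq_len(nrow(w$steps)),
               function(i) step_seq(graph, w$steps[i, 1L], w$steps[i, 2L]),
               character(1L)),
        collapse = "")
}

# packed graph position per spelled base of a step sequence (matrix v,b)
steps_tags_packed <- function(graph, steps) {
  lens <- nchar(graph$nodes)[steps[, 1L]]
  v <- rep(steps[, 1L], lens)
  b <- rep(steps[, 2L], lens)
  o <- sequence(lens) - 1  # offset counted along the traversal direction
  tag_pack(v, o, b)
}

#' Graph positions of every base of a haplotype walk
#'
#' One position per spelled base, in walk order. For a step `(v, 0)` the
#' positions are `(v,0,0), (v,1,0), ...`; for `(v, 1)` they are
#' `(v,0,1), (v,1,1), ...`, with the offset counted along the traversal
#' direction (offset 0 is the first base emitted by the step).
#'
#' @inheritParams spell
#' @return A data frame with columns `v`, `o`, `b`.
#' @export
graph_positions_of <- function(walk, graph) {
  w <- get_walk(graph, walk)
  tag_unpack(steps_tags_packed(graph, w$steps))
}

# internal: packed predecessors of a packed position
predecessors_packed <- function(graph, tag) {
  u <- tag_unpack(tag)
  v <- u$v; o <- u$o; b <- u$b
  if (o > 0) {
    s <- step_seq(graph, v, b)
    return(list(chars = substr(s, o, o), tags = tag_pack(v, o - 1, b)))
  }
  ie <- graph$in_edges[[paste(v, b, sep = ".")]]
  if (is.null(ie) || nrow(ie) == 0L)
    return(list(chars = character(0), tags = numeric(0)))
  chars <- character(nrow(ie)); tags <- numeric(nrow(ie))
  for (i in seq_len(nrow(ie))) {
    pv <- ie$v[i]; pb <- ie$b[i]
    s <- step_seq(graph, pv, pb)
    l <- nchar(s)
    chars[i] <- substr(s, l, l)
    tags[i] <- tag_pack(pv, l - 1, pb)
  }
  list(chars = chars, tags = tags)
}

#' Immediate predecessors of a graph position
#'
#' All (character, position) pairs that can precede `pos` along an
#' edge-consistent path: within a node this is the single previous base;
#' at a node start, one pair per incoming oriented edge, giving the last
#' traversal-oriented base of the predecessor node.
#'
#' @param pos A `graph_position` (or length-3 numeric `c(v, o, b)`).
#' @param graph A `pangenome_graph`.
#' @return A data frame with columns `char`, `v`, `o`, `b`.
#' @export
predecessors <- function(pos, graph) {
  tag <- as_packed_tag(pos)
  u <- tag_unpack(tag)
  if (u$v < 1 || u$v > length(graph$nodes) || u$o >= nchar(graph$nodes[u$v]))
    err_domain("invalid graph position for this graph")
  p <- predecessors_packed(graph, tag)
  cbind(data.frame(char = p$chars, stringsAsFactors = FALSE), tag_unpack(p$tags))
}

#' Unique predecessor branches of a graph position
#'
#' Applies the grouped-predecessor rule used during anchor extension: when a
#' position has several predecessors, they are grouped by the character of
#' their last base, and only characters contributed by exactly one
#' predecessor give a unique continuation. With a single predecessor (or
#' within a node) that predecessor is returned unconditionally.
#'
#' @inheritParams predecessors
#' @return A data frame with columns `char`, `v`, `o`, `b` (possibly empty).
#' @export
unique_predecessors <- function(pos, graph) {
  p <- predecessors(pos, graph)
  if (nrow(p) <= 1L) return(p)
  tab <- table(p$char)
  p[p$char %in% names(tab)[tab == 1L], , drop = FALSE]
}

# internal grouped rule on packed positions
unique_predecessors_packed <- function(graph, tag) {
  p <- predecessors_packed(graph, tag)
  if (length(p$chars) <= 1L) return(p)
  tab <- table(p$chars)
  keep <- p$chars %in% names(tab)[tab == 1L]
  list(chars = p$chars[keep], tags = p$tags[keep])
}

# sequences of the indexed text in sid order: forward spelling of each walk
# followed by its reverse complement, with per-base packed tags
indexed_sequences <- function(graph) {
  m <- length(graph$walks)
  seqs <- character(2L * m); tags <- vector("list", 2L * m)
  for (i in seq_len(m)) {
    w <- graph$walks[[i]]
    fwd <- spell(w, graph)
    rsteps <- cbind(v = rev(w$steps[, 1L]), b = 1L - rev(w$steps[, 2L]))
    seqs[2L * i - 1L] <- fwd
    seqs[2L * i] <- rc_string(fwd)
    tags[[2L * i - 1L]] <- steps_tags_packed(graph, w$steps)
    tags[[2L * i]] <- steps_tags_packed(graph, rsteps)
  }
  list(seqs = seqs, tags = tags)
}

#' Unique k-mers of the indexed text
#'
#' Enumerates every length-`k` window of every haplotype walk and of every
#' reverse-complement walk (the indexed text), keyed by the k-mer string,
#' and returns exactly those k-mers whose set of distinct starting graph
#' positions has size 1. K-mers containing `N` are never unique anchors.
#'
#' @param graph A `pangenome_graph`.
#' @param k K-mer length, at least 2.
#' @return A data frame with columns `kmer`, `v`, `o`, `b`, `packed`,
#'   sorted by `kmer`.
#' @export
unique_kmers <- function(graph, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    err_domain("k must be a single integer >= 2")
  k <- as.integer(k)
  ix <- indexed_sequences(graph)
  km_all <- character(0); pos_all <- numeric(0)
  for (i in seq_along(ix$seqs)) {
    s <- ix$seqs[i]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    cc <- chars_of(s)
    cn <- cumsum(cc == "N")
    ok <- (cn[starts + k - 1L] - c(0L, cn)[starts]) == 0L
    if (!any(ok)) next
    starts <- starts[ok]
    km_all <- c(km_all, substring(s, starts, starts + k - 1L))
    pos_all <- c(pos_all, ix$tags[[i]][starts])
  }
  if (length(km_all) == 0L)
    return(data.frame(kmer = character(0), v = numeric(0), o = numeric(0),
                      b = numeric(0), packed = numeric(0)))
  o <- order(km_all, pos_all, method = "radix")
  g <- km_all[o]; p <- pos_all[o]
  n <- length(g)
  newg <- c(TRUE, g[-1L] != g[-n])
  newv <- newg | c(TRUE, p[-1L] != p[-n])
  gid <- cumsum(newg)
  ndist <- tabulate(gid[newv])
  firsts <- which(newg)
  keep <- ndist[gid[firsts]] == 1L
  res_km <- g[firsts][keep]
  res_pos <- p[firsts][keep]
  cbind(data.frame(kmer = res_km, stringsAsFactors = FALSE),
        tag_unpack(res_pos), data.frame(packed = res_pos))
}
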