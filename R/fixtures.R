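# Bundled fixtures: hand-built toy graph and a synthetic pangenome ---------
# generator. The generator's defaults are the study conditions used by the
# test suite and the reproduction script; variation acts at node granularity
# (explicit bubbles), so the extension-rule edge cases (multi-predecessor
# junctions, equal last bases) are realisable graph structure.

#' The bundled toy pangenome
#'
#' A small fixed graph (8 nodes, 3 haplotypes, two bubbles and a shared
#' tail) stored as GFA text under `inst/extdata/toy.gfa`; its complete tag
#' array, computed with the naive permute-by-suffix-array construction, is
#' checked in alongside it for regression tests.
#'
#' @return A `pangenome_graph`.
#' @export
toy_graph <- function() {
  read_gfa(system.file("extdata", "toy.gfa", package = "pantag",
                       mustWork = TRUE))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(v) v[sample.int(length(v), 1L)]

# a random sequence of length n differing from s
mutated_dna <- function(s) {
  n <- nchar(s)
  repeat {
    x <- random_dna(n)
    if (x != s) return(x)
  }
}

#' Generate a random synthetic pangenome
#'
#' Deterministic for a seed. Each component is an independent backbone of
#' nodes with random sequences; with probability `mut_rate` per interior
#' backbone node a variant event is created: a SNP-style substitution
#' bubble (alternative node of equal length), a deletion (edge skipping the
#' node) or a small insertion node. Haplotype walks choose variants
#' independently; the first haplotype always follows the backbone, and
#' events no haplotype uses are dropped, so every node is traversed and
#' every walk is edge-supported.
#'
#' @param n_nodes Backbone nodes in total across components (default 30).
#' @param n_haps Haplotypes per component (default 4).
#' @param mut_rate Variant event probability per interior node (default
#'   0.05).
#' @param seed Optional integer seed (sets the RNG).
#' @param n_components Number of weakly connected components (default 1).
#' @param node_len Range of node lengths in bp (default 4-12).
#' @return A `pangenome_graph`.
#' @export
random_pangenome <- function(n_nodes = 30, n_haps = 4, mut_rate = 0.05,
                             seed = NULL, n_components = 1,
                             node_len = c(4, 12)) {
  if (n_nodes < 2 * n_components || n_haps < 1 || mut_rate < 0 || mut_rate > 1 ||
      n_components < 1 || node_len[1] < 1 || node_len[2] < node_len[1])
    err_domain("degenerate generator parameters")
  if (!is.null(seed)) set.seed(seed)

  nodes <- character(0); node_names <- character(0)
  walks <- list(); sid <- 0L
  per_comp <- diff(floor(seq(0, n_nodes, length.out = n_components + 1)))

  for (ci in seq_len(n_components)) {
    nb <- per_comp[ci]
    ref_seq <- vapply(seq_len(nb),
                      function(i) random_dna(pick1(node_len[1]:node_len[2])),
                      "")
    ref_id <- length(nodes) + seq_len(nb)
    nodes <- c(nodes, ref_seq)
    node_names <- c(node_names, sprintf("c%dn%d", ci, seq_len(nb)))

    # variant events on interior backbone positions
    ev_type <- rep("none", nb)
    interior <- if (nb > 2L) 2:(nb - 1L) else integer(0)
    hit <- interior[stats::runif(length(interior)) < mut_rate]
    ev_type[hit] <- sample(c("snp", "del", "ins"), length(hit), replace = TRUE)
    alt_id <- integer(nb)
    for (i in which(ev_type == "snp")) {
      alt_id[i] <- length(nodes) + 1L
      nodes <- c(nodes, mutated_dna(ref_seq[i]))
      node_names <- c(node_names, sprintf("c%dn%da", ci, i))
    }
    for (i in which(ev_type == "ins")) {
      alt_id[i] <- length(nodes) + 1L
      nodes <- c(nodes, random_dna(pick1(node_len[1]:node_len[2])))
      node_names <- c(node_names, sprintf("c%dn%di", ci, i))
    }

    # haplotype choices: hap 1 is the backbone
    choice <- matrix(FALSE, n_haps, nb)
    for (i in which(ev_type != "none"))
      choice[, i] <- c(FALSE, stats::runif(n_haps - 1) < 0.5)[seq_len(n_haps)]
    used <- apply(choice, 2L, any)

    hwalks <- vector("list", n_haps)
    for (h in seq_len(n_haps)) {
      vs <- integer(0)
      for (i in seq_len(nb)) {
        if (choice[h, i] && used[i]) {
          if (ev_type[i] == "snp") { vs <- c(vs, alt_id[i]); next }
          if (ev_type[i] == "del") next
          if (ev_type[i] == "ins") { vs <- c(vs, alt_id[i], ref_id[i]); next }
        }
        vs <- c(vs, ref_id[i])
      }
      hwalks[[h]] <- vs
    }
    # drop nodes created but unused by every haplotype
    for (h in seq_len(n_haps)) {
      walks[[length(walks) + 1L]] <-
        list(sid = sid, name = sprintf("c%dh%d", ci, h),
             steps = cbind(v = hwalks[[h]], b = 0L))
      sid <- sid + 1L
    }
  }

  used_nodes <- sort(unique(unlist(lapply(walks, function(w) w$steps[, 1L]))))
  remap <- integer(length(nodes)); remap[used_nodes] <- seq_along(used_nodes)
  nodes <- nodes[used_nodes]; node_names <- node_names[used_nodes]
  pairs <- unique(do.call(rbind, lapply(walks, function(w) {
    st <- w$steps
    if (nrow(st) < 2L) return(NULL)
    cbind(st[-nrow(st), 1L], st[-1L, 1L])
  })))
  for (i in seq_along(walks))
    walks[[i]]$steps[, 1L] <- remap[walks[[i]]$steps[, 1L]]
  edges <- if (is.null(pairs) || nrow(pairs) == 0L)
    data.frame(v1 = integer(0), b1 = integer(0), v2 = integer(0), b2 = integer(0))
  else data.frame(v1 = remap[pairs[, 1L]], b1 = 0L,
                  v2 = remap[pairs[, 2L]], b2 = 0L)
  make_graph(nodes, node_names, edges, walks)
}

#' Grouped-predecessor fixture
#'
#' A hand-built graph in which one junction node has five predecessors
#' whose last bases are A, A, A, T and C: under the grouped-predecessor
#' rule, backward extension through the junction start proceeds through
#' exactly the T and C branches.
#'
#' @return A `pangenome_graph`. The junction node is named `"X"`.
#' @export
grouped_predecessor_graph <- function() {
  nodes <- c(P1 = "GGCA", P2 = "TCGA", P3 = "ACTA", P4 = "CGGT", P5 = "GATC",
             X = "TTGCA", Z = "CAGGT")
  node_names <- names(nodes)
  walks <- list()
  for (i in 1:5)
    walks[[i]] <- list(sid = i - 1L, name = sprintf("h%d", i),
                       steps = cbind(v = c(i, 6L, 7L), b = 0L))
  edges <- data.frame(v1 = c(1:5, 6L), b1 = 0L, v2 = c(rep(6L, 5), 7L), b2 = 0L)
  make_graph(unname(nodes), node_names, edges, walks)
}
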