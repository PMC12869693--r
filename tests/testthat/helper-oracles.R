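# Independent oracles: naive suffix sorting by string comparison (radix
# order in the C locale on remapped letters), brute-force tag arrays built
# by listing graph positions in text order and permuting by the naive
# suffix array, and a flat-array reference for the run-length B+ tree.
# None of these touch the package's index structures.

# Letters that sort like the index alphabet: sentinels of sequences
# 1..m get letters below every base letter, bases map to letters above.
# Supports up to 80 sequences (enough for all fixtures).
oracle_letters <- function(m) {
  stopifnot(m <= 80)
  list(sent = vapply(33:(32 + m), function(x) rawToChar(as.raw(x)), ""),
       base = c(A = "q", C = "r", G = "s", N = "t", T = "u"))
}

# naive suffix array (0-based) of the concatenated text of a
# text_collection-like list with fields seqs (character vector)
naive_sa <- function(seqs) {
  m <- length(seqs)
  lt <- oracle_letters(m)
  mapped <- vapply(seq_len(m), function(i) {
    body <- chartr("ACGNT", paste(lt$base, collapse = ""), seqs[i])
    paste0(body, lt$sent[i])
  }, "")
  txt <- paste(mapped, collapse = "")
  n <- nchar(txt)
  suf <- substring(txt, seq_len(n), n)
  order(suf, method = "radix") - 1L
}

# naive BWT (merged '$') as a character vector, from the naive SA
naive_bwt <- function(seqs) {
  m <- length(seqs)
  txt <- paste(paste0(seqs, "$"), collapse = "")
  n <- nchar(txt)
  sa0 <- naive_sa(seqs)
  prev <- ifelse(sa0 == 0L, n, sa0)
  ch <- substring(txt, prev, prev)
  ch                      # '$' already merged in this rendering
}

# (sid, offset) per row from the naive SA
naive_doc <- function(seqs) {
  lens <- nchar(seqs)
  starts0 <- cumsum(c(0, head(lens + 1L, -1L)))
  sa0 <- naive_sa(seqs)
  s <- findInterval(sa0, starts0)
  data.frame(row = seq_along(sa0) - 1L, sid = s - 1L,
             offset = sa0 - starts0[s])
}

# random multi-sequence text collection for index tests
random_seqs <- function(n_seqs, total_len) {
  lens <- as.vector(stats::rmultinom(1, total_len - n_seqs, rep(1, n_seqs))) + 1L
  vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T", "T", "A", "C", "G", "N"), l,
                 replace = TRUE), collapse = ""), "")
}

# gold-standard tag array: graph positions listed in text order (END tag on
# end-marker positions) permuted by the naive SA. Packed tags per row.
oracle_tag_rows <- function(graph) {
  ix <- pantag:::indexed_sequences(graph)
  textorder <- unlist(lapply(seq_along(ix$seqs), function(i)
    c(ix$tags[[i]], pantag:::TAG_END)))
  sa0 <- naive_sa(ix$seqs)
  textorder[sa0 + 1L]
}

# brute-force one-to-all node-start map, purely from haplotype walks:
# for every sequence and offset with a node-start position, all (sid',
# offset') sharing that exact packed tag.
oracle_node_start_map <- function(graph) {
  ix <- pantag:::indexed_sequences(graph)
  rows <- do.call(rbind, lapply(seq_along(ix$seqs), function(i) {
    tv <- ix$tags[[i]]
    u <- pantag:::tag_unpack(tv)
    keep <- u$o == 0
    data.frame(sid = i - 1L, offset = which(keep) - 1L, packed = tv[keep])
  }))
  rows
}

# flat-array reference semantics for insert_run
flat_insert <- function(arr, start, len, tag) {
  idx <- (start + 1L):(start + len)
  old <- arr[idx]
  if (any(old != 0 & old != tag)) stop("flat conflict")
  arr[idx] <- tag
  arr
}

# quadratic brute-force MEM enumeration against explicit text sequences
brute_mems <- function(seqs, query, Lmin) {
  qc <- strsplit(query, "")[[1]]
  L <- length(qc)
  hay <- paste(seqs, collapse = "#")
  occurs <- function(i, j) {           # query[i..j] 1-based inclusive
    s <- substr(query, i, j)
    if (grepl("N", s, fixed = TRUE)) return(FALSE)
    grepl(s, hay, fixed = TRUE)
  }
  out <- list()
  ml <- integer(L)
  l <- 0L
  for (i in seq_len(L)) {
    if (l > 0L) l <- l - 1L
    while (i + l <= L && occurs(i, i + l)) l <- l + 1L
    ml[i] <- l
  }
  for (i in seq_len(L)) {
    if (ml[i] < Lmin) next
    if (i > 1L && ml[i - 1L] >= ml[i] + 1L) next   # left-extendable
    out[[length(out) + 1L]] <- c(q_start = i - 1L, q_end = i - 1L + ml[i])
  }
  if (length(out) == 0L)
    return(data.frame(q_start = numeric(0), q_end = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

# a query stitched from substrings of the indexed text (mosaic read)
mosaic_query <- function(seqs, len, seg = c(20, 60)) {
  out <- character(0); tot <- 0L
  while (tot < len) {
    s <- seqs[sample.int(length(seqs), 1L)]
    L <- nchar(s)
    w <- min(sample(seg[1]:seg[2], 1L), L, len - tot)
    if (w < 1L) break
    i <- sample.int(L - w + 1L, 1L)
    out <- c(out, substr(s, i, i + w - 1L))
    tot <- tot + w
  }
  paste(out, collapse = "")
}
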