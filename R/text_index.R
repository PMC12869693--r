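# Multi-string BWT / FM-index over haplotypes plus reverse complements -----
#
# The indexed text is T = H0$0 H1$1 ... H(2m-1)$(2m-1): for every haplotype
# walk, its forward spelling immediately followed by its reverse complement
# (FMD pairing, so the reverse-complement partner of sequence sid is
# sid XOR 1). End-markers are distinct and ordered by sequence index during
# suffix sorting, but collapse to the single BWT symbol '$'. All rows,
# offsets and text positions in this module are 0-based.

#' Build the text collection indexed for a graph
#'
#' For each haplotype walk, in sid order, emits the forward spelling and
#' then its reverse complement as the next sequence.
#'
#' @param graph A `pangenome_graph`.
#' @return An object of class `text_collection`: sequences, per-sequence
#'   lengths, 0-based text start offsets, total length `N` (including one
#'   end-marker per sequence), the reverse-complement pairing, and the
#'   per-base packed graph positions of every sequence.
#' @export
build_text <- function(graph) {
  if (length(graph$walks) < 1L) err_domain("graph has no haplotypes")
  ix <- indexed_sequences(graph)
  m <- length(ix$seqs)
  lens <- nchar(ix$seqs)
  starts0 <- cumsum(c(0, lens[-m] + 1))
  structure(list(seqs = ix$seqs, n_seqs = m, lens = as.numeric(lens),
                 starts0 = as.numeric(starts0), N = as.numeric(sum(lens) + m),
                 rc_pair = as.numeric(bitwXor(seq_len(m) - 1L, 1L)),
                 walk_of_seq = (seq_len(m) - 1L) %/% 2L + 1L,
                 tagvecs = ix$tags),
            class = "text_collection")
}

# suffix array by prefix doubling; s = integer codes, all comparisons on
# (rank, rank shifted by k) pairs via radix order. Returns 1-based positions.
sa_prefix_doubling <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  rk <- s
  k <- 1L
  repeat {
    key2 <- c(rk[-seq_len(min(k, n))], rep(0L, min(k, n)))
    o <- order(rk, key2, method = "radix")
    d <- c(TRUE, rk[o[-1L]] != rk[o[-n]] | key2[o[-1L]] != key2[o[-n]])
    new <- integer(n)
    new[o] <- cumsum(d)
    rk <- new
    if (rk[o[n]] == n) return(o)
    k <- 2L * k
  }
}

#' Build the run-length multi-string BWT index
#'
#' Sorts all suffixes of the concatenated text (end-markers distinct and
#' ordered by sequence index), sets `BWT[i] = T[SA[i]-1]` with wrap-around,
#' run-length encodes the BWT over the merged alphabet `{$,A,C,G,N,T}`, and
#' stores suffix-array samples at run boundaries (plus at every '$' row,
#' where the text-predecessor map is not defined by LF over the merged
#' alphabet) to support r-index-style locate.
#'
#' @param text A `text_collection`.
#' @return An object of class `msbwt_index`.
#' @export
build_msbwt <- function(text) {
  if (!inherits(text, "text_collection")) err_domain("expected a text_collection")
  text$N <- as.numeric(text$N)
  m <- text$n_seqs
  codes <- integer(text$N)
  pos <- 1L
  for (i in seq_len(m)) {
    l <- text$lens[i]
    if (l > 0) codes[pos:(pos + l - 1L)] <- m + base_codes(text$seqs[i]) - 1L
    codes[pos + l] <- i                      # distinct sentinel, ordered by sid
    pos <- pos + l + 1L
  }
  sa <- sa_prefix_doubling(codes)
  n <- as.numeric(text$N)
  prev <- ifelse(sa == 1L, n, sa - 1L)
  pc <- codes[prev]
  merged <- ifelse(pc <= m, 1L, pc - m + 1L)   # 1='$', 2..6 = A,C,G,N,T

  rl <- rle(merged)
  r <- length(rl$values)
  run_len <- as.numeric(rl$lengths)
  run_start <- cumsum(c(0, run_len[-r]))
  occ <- matrix(0, nrow = r, ncol = 6L)
  for (code in 1:6)
    occ[, code] <- cumsum(ifelse(rl$values == code, run_len, 0))
  tot <- occ[r, ]
  C <- c(0, cumsum(tot))[1:6]

  SA0 <- sa - 1
  dollars <- which(merged == 1L) - 1
  srows <- sort(unique(c(run_start, run_start + run_len - 1, dollars)))
  ssa <- SA0[srows + 1]

  br <- sort(unique(c(run_start, dollars)))
  br <- br[br > 0]
  phiQ <- SA0[br + 1]
  phiR <- SA0[br]
  o <- order(phiQ)

  structure(list(N = n, m = m, lens = text$lens, starts0 = text$starts0,
                 rc_pair = text$rc_pair,
                 run_char = rl$values, run_start = run_start,
                 run_len = run_len, r = r, C = C, occ = occ,
                 srows = srows, ssa = ssa,
                 phiQ = phiQ[o], phiR = phiR[o]),
            class = "msbwt_index")
}

#' @export
print.msbwt_index <- function(x, ...) {
  cat(sprintf("multi-string BWT index: N = %d rows, %d sequences, %d runs (n/r = %.1f)\n",
              x$N, x$m, x$r, x$N / x$r))
  invisible(x)
}

# rank of a single merged-alphabet code in BWT[0..i-1], i in [0, N]
bwt_rank <- function(index, code, i) {
  if (i <= 0) return(0)
  j <- findInterval(i - 1, index$run_start)
  base <- if (j > 1L) index$occ[j - 1L, code] else 0
  if (index$run_char[j] == code) base + (i - index$run_start[j]) else base
}

# ranks of all six codes at once
bwt_rank_all <- function(index, i) {
  if (i <= 0) return(numeric(6L))
  j <- findInterval(i - 1, index$run_start)
  base <- if (j > 1L) index$occ[j - 1L, ] else numeric(6L)
  base[index$run_char[j]] <- base[index$run_char[j]] + (i - index$run_start[j])
  base
}

bwt_code_at <- function(index, row) {
  index$run_char[findInterval(row, index$run_start)]
}

lf_code <- function(index, code, i) index$C[code] + bwt_rank(index, code, i)

#' LF-mapping for an arbitrary character
#'
#' `lf_char(index, c, i)` returns `C[c] + rank(c, i)`, the number of
#' suffixes starting with a character below `c` plus the occurrences of `c`
#' in `BWT[0..i-1]`.
#'
#' @param index An `msbwt_index`.
#' @param c A single character in `{A,C,G,T,N,$}`.
#' @param i A row bound, `0 <= i <= N`.
#' @return A 0-based row.
#' @export
lf_char <- function(index, c, i) {
  code <- match(c, ALPHABET)
  if (is.na(code)) err_domain(sprintf("unknown character '%s'", c))
  if (i < 0 || i > index$N) err_domain("row out of range")
  lf_code(index, code, i)
}

lex_width <- function(iv) max(0, iv[2] + 1 - iv[1])

empty_interval <- function() c(0, -1)

#' Backward search for a pattern
#'
#' Narrows the inclusive lexicographic row interval of suffixes starting
#' with `P`, one character at a time from right to left. The empty pattern
#' maps to the full interval `[0, N-1]`; an absent pattern yields an empty
#' interval (second bound below the first).
#'
#' @param index An `msbwt_index`.
#' @param P Pattern over `{A,C,G,T,N}`.
#' @return Numeric `c(A, B)`, inclusive bounds.
#' @export
backward_search <- function(index, P) {
  iv <- c(0, index$N - 1)
  if (nchar(P) == 0L) return(iv)
  codes <- match(chars_of(P), ALPHABET)
  if (anyNA(codes) || any(codes == 1L))
    err_domain("pattern must be over {A,C,G,T,N}")
  for (code in rev(codes)) {
    iv <- c(lf_code(index, code, iv[1]), lf_code(index, code, iv[2] + 1) - 1)
    if (iv[2] < iv[1]) return(empty_interval())
  }
  iv
}

# SA value at an arbitrary row: LF-walk until a sampled row is reached.
# Every '$'-row is sampled, so the walk never needs LF across an end-marker.
sa_at_row <- function(index, row) {
  t <- 0
  repeat {
    p <- findInterval(row, index$srows)
    if (p >= 1L && index$srows[p] == row) return(index$ssa[p] + t)
    row <- lf_code(index, bwt_code_at(index, row), row)
    t <- t + 1
  }
}

# phi: SA[i-1] from SA[i], via run-boundary samples (predecessor on the
# sampled SA values of run-start and '$' rows).
phi_prev <- function(index, p) {
  j <- findInterval(p, index$phiQ)
  if (j < 1L) err_integrity("phi called below the smallest sampled value")
  index$phiR[j] + (p - index$phiQ[j])
}

pos_to_seq <- function(index, p) {
  s <- findInterval(p, index$starts0)
  c(sid = as.numeric(s - 1), offset = as.numeric(p - index$starts0[s]))
}

#' Sequence and offset of a BWT row
#'
#' Returns the sequence id owning suffix `SA[i]` and the 0-based offset of
#' the suffix start within that sequence (`offset == |H|` for the
#' end-marker row).
#'
#' @param index An `msbwt_index`.
#' @param i A 0-based row.
#' @return Named numeric `c(sid, offset)`.
#' @export
sequence_of_row <- function(index, i) {
  if (i < 0 || i >= index$N) err_domain("row out of range")
  pos_to_seq(index, sa_at_row(index, i))
}

#' Locate every occurrence in a row interval
#'
#' One `(sid, offset)` pair per row of `iv`, in row order, derived r-index
#' style: a toehold SA value for the last row (LF-walk to the nearest
#' sampled row) followed by repeated neighbour derivation with `phi`.
#'
#' @param index An `msbwt_index`.
#' @param iv Inclusive interval `c(A, B)`.
#' @return A data frame with columns `row`, `sid`, `offset`.
#' @export
locate_all <- function(index, iv) {
  if (iv[2] < iv[1])
    return(data.frame(row = numeric(0), sid = numeric(0), offset = numeric(0)))
  if (iv[1] < 0 || iv[2] >= index$N) err_domain("interval out of range")
  A <- iv[1]; B <- iv[2]
  p <- numeric(B - A + 1)
  cur <- sa_at_row(index, B)
  p[B - A + 1] <- cur
  if (B > A) {
    for (i in seq(B - A, 1)) {
      cur <- phi_prev(index, cur)
      p[i] <- cur
    }
  }
  s <- findInterval(p, index$starts0)
  data.frame(row = as.numeric(A:B), sid = as.numeric(s - 1),
             offset = as.numeric(p - index$starts0[s]))
}

#' Row of a sequence position
#'
#' The BWT row whose suffix starts at `offset` of sequence `sid`; computed
#' by LF-stepping backwards from the end-marker row of `sid` (row `sid`
#' itself) `|H| - offset` times.
#'
#' @param index An `msbwt_index`.
#' @param sid 0-based sequence id.
#' @param offset 0-based offset, `0 <= offset <= |H|`.
#' @return A 0-based row.
#' @export
row_of_seq_pos <- function(index, sid, offset) {
  if (sid < 0 || sid >= index$m) err_domain("no such sequence")
  l <- index$lens[sid + 1]
  if (offset < 0 || offset > l) err_domain("offset out of range")
  row <- as.numeric(sid)
  steps <- l - offset
  while (steps > 0) {
    row <- lf_code(index, bwt_code_at(index, row), row)
    steps <- steps - 1
  }
  row
}

# Bidirectional (FMD) intervals -------------------------------------------

#' Initial bidirectional interval (empty pattern)
#'
#' @param index An `msbwt_index`.
#' @return A `bi_interval`: forward interval for the pattern and interval
#'   of its reverse complement, both `[0, N-1]`.
#' @export
bi_init <- function(index) {
  structure(list(fwd = c(0, index$N - 1), rev = c(0, index$N - 1)),
            class = "bi_interval")
}

bi_empty <- function() {
  structure(list(fwd = c(0, -1), rev = c(0, -1)), class = "bi_interval")
}

#' @export
print.bi_interval <- function(x, ...) {
  cat(sprintf("bi-interval: fwd [%g, %g], rev [%g, %g], width %g\n",
              x$fwd[1], x$fwd[2], x$rev[1], x$rev[2], lex_width(x$fwd)))
  invisible(x)
}

#' Extend a bidirectional interval backward (prepend a character)
#'
#' Updates the forward interval by LF with `c` and keeps the
#' reverse-complement interval synchronised with the cumulative-width rule
#' over the small alphabet, so both intervals track pattern `cP`.
#'
#' @param index An `msbwt_index`.
#' @param bi A `bi_interval`.
#' @param c A single character in `{A,C,G,T,N}`.
#' @return A `bi_interval` (possibly empty).
#' @export
bi_extend_backward <- function(index, bi, c) {
  if (lex_width(bi$fwd) == 0) return(bi_empty())
  code <- match(c, ALPHABET)
  if (is.na(code) || code == 1L) err_domain("extension character must be a base")
  rA <- bwt_rank_all(index, bi$fwd[1])
  rB <- bwt_rank_all(index, bi$fwd[2] + 1)
  cnt <- rB - rA
  w <- cnt[code]
  if (w == 0) return(bi_empty())
  newA <- index$C[code] + rA[code]
  dc <- COMP_CODE[code]
  below <- if (dc > 1L) sum(cnt[COMP_CODE[seq_len(dc - 1L)]]) else 0
  revA <- bi$rev[1] + below
  structure(list(fwd = c(newA, newA + w - 1), rev = c(revA, revA + w - 1)),
            class = "bi_interval")
}

#' Extend a bidirectional interval forward (append a character)
#'
#' Implemented as backward extension of the complement character on the
#' reverse-complement side, with the two component intervals swapped.
#'
#' @inheritParams bi_extend_backward
#' @return A `bi_interval` (possibly empty).
#' @export
bi_extend_forward <- function(index, bi, c) {
  cc <- COMP_CHAR[[c]]
  if (is.null(cc)) err_domain("extension character must be a base")
  swapped <- structure(list(fwd = bi$rev, rev = bi$fwd), class = "bi_interval")
  r <- bi_extend_backward(index, swapped, cc)
  structure(list(fwd = r$rev, rev = r$fwd), class = "bi_interval")
}
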