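# Multi-string BWT / FMD index against the naive suffix-sort oracle

single_seq_collection <- function(s) {
  structure(list(seqs = s, n_seqs = length(s), lens = as.numeric(nchar(s)),
                 starts0 = as.numeric(cumsum(c(0, head(nchar(s) + 1, -1)))),
                 N = sum(nchar(s)) + length(s),
                 rc_pair = as.numeric(bitwXor(seq_along(s) - 1L, 1L)),
                 walk_of_seq = (seq_along(s) - 1L) %/% 2L + 1L,
                 tagvecs = vector("list", length(s))),
            class = "text_collection")
}

expand_bwt <- function(idx) rep(pantag:::ALPHABET[idx$run_char], idx$run_len)

test_that("build_text pairs each haplotype with its reverse complement", {
  g <- pantag:::make_graph(
    "AC", "n",
    data.frame(v1 = integer(0), b1 = integer(0), v2 = integer(0), b2 = integer(0)),
    list(list(sid = 0L, name = "h", steps = cbind(v = 1L, b = 0L))))
  tc <- build_text(g)
  expect_identical(tc$seqs, c("AC", "GT"))
  expect_identical(tc$N, 6)
  expect_true(is.numeric(tc$N))
  expect_identical(tc$rc_pair, c(1, 0))

  g3 <- toy_graph()
  tc3 <- build_text(g3)
  expect_identical(tc3$n_seqs, 2L * length(g3$walks))
  # rc pairing is a fixed-point-free involution
  expect_identical(tc3$rc_pair[tc3$rc_pair + 1], as.numeric(0:(tc3$n_seqs - 1)))
  expect_true(all(tc3$rc_pair != 0:(tc3$n_seqs - 1)))
  for (i in seq(1, tc3$n_seqs, by = 2))
    expect_identical(tc3$seqs[i + 1], pantag:::rc_string(tc3$seqs[i]))
})

test_that("BWT of known texts matches hand and oracle values", {
  idx <- build_msbwt(single_seq_collection("ACG"))
  expect_identical(paste(expand_bwt(idx), collapse = ""), "G$AC")

  idx2 <- build_msbwt(single_seq_collection(c("A", "C")))
  expect_identical(paste(expand_bwt(idx2), collapse = ""), "AC$$")
  # the '$' symbols at rows 2 and 3 are the end-markers of sids 1 and 0:
  # their rows' suffixes start the sequences of sids 0 and 1 respectively
  expect_identical(unname(sequence_of_row(idx2, 2)), c(0, 0))
  expect_identical(unname(sequence_of_row(idx2, 3)), c(1, 0))
  # end-marker rows 0..m-1 sort by sid, offset |H|
  expect_identical(unname(sequence_of_row(idx2, 0)), c(0, 1))
  expect_identical(unname(sequence_of_row(idx2, 1)), c(1, 1))
  # T = "A$0C$1": the row of suffix "C$1" is (sid 1, offset 0)
  expect_identical(row_of_seq_pos(idx2, 1, 0), 3)
})

test_that("lf_char follows C[c] + rank(c, i)", {
  idx <- build_msbwt(single_seq_collection("ACG"))  # BWT "G$AC"
  expect_identical(lf_char(idx, "C", 3), 2)
  for (c in c("$", "A", "C", "G", "T", "N"))
    expect_identical(lf_char(idx, c, 0), idx$C[match(c, pantag:::ALPHABET)])
  expect_identical(lf_char(idx, "$", idx$N), 1)     # one sequence
  expect_error(lf_char(idx, "X", 0), class = "pantag_domain_error")
})

test_that("backward_search narrows to the right interval", {
  idx <- build_msbwt(single_seq_collection("ACG"))
  expect_identical(backward_search(idx, "CG"), c(2, 2))
  expect_identical(backward_search(idx, ""), c(0, idx$N - 1))
  iv <- backward_search(idx, "T")
  expect_lt(iv[2], iv[1])
})

test_that("row_of_seq_pos inverts sequence_of_row", {
  idx <- build_msbwt(single_seq_collection("ACG"))   # T = "ACG$"
  expect_identical(row_of_seq_pos(idx, 0, 3), 0)     # end-marker row
  expect_identical(row_of_seq_pos(idx, 0, 1), 2)     # suffix "CG$"
  expect_error(row_of_seq_pos(idx, 0, 9), class = "pantag_domain_error")
})

test_that("index operations agree with the naive oracle on random texts", {
  set.seed(101)
  for (rep in 1:40) {
    seqs <- random_seqs(sample(1:8, 1), sample(20:300, 1))
    tc <- single_seq_collection(seqs)
    idx <- build_msbwt(tc)
    expect_identical(paste(expand_bwt(idx), collapse = ""),
                     paste(naive_bwt(seqs), collapse = ""))
    nd <- naive_doc(seqs)
    # locate over the full interval is a permutation equal to the naive SA doc
    la <- locate_all(idx, c(0, idx$N - 1))
    expect_identical(la$sid, as.numeric(nd$sid))
    expect_identical(la$offset, as.numeric(nd$offset))
    # sequence_of_row spot checks (all rows of one random text is O(N^2))
    for (row in sample(0:(idx$N - 1), min(25, idx$N))) {
      so <- sequence_of_row(idx, row)
      expect_identical(unname(so),
                       as.numeric(c(nd$sid[row + 1], nd$offset[row + 1])))
    }
    # row_of_seq_pos inverts on random rows
    for (row in sample(0:(idx$N - 1), min(10, idx$N)))
      expect_identical(row_of_seq_pos(idx, nd$sid[row + 1], nd$offset[row + 1]),
                       as.numeric(row))
    # backward_search equals a scan of the naive suffix order
    txt <- paste(paste0(seqs, "$"), collapse = "")
    for (q in 1:5) {
      P <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), replace = TRUE),
                 collapse = "")
      iv <- backward_search(idx, P)
      sa0 <- naive_sa(seqs)
      hit <- which(substring(txt, sa0 + 1, sa0 + nchar(P)) == P)
      if (length(hit) == 0L) expect_lt(iv[2], iv[1])
      else expect_identical(iv, c(min(hit) - 1, max(hit) - 1))
    }
    # LF at non-'$' rows equals the naive-SA-derived LF
    sa0 <- naive_sa(seqs)
    bwt <- expand_bwt(idx)
    rows <- which(bwt != "$")
    rows <- sample(rows, min(30, length(rows)))
    for (row1 in rows) {
      want <- which(sa0 == (sa0[row1] - 1 + idx$N) %% idx$N) - 1
      expect_identical(lf_char(idx, bwt[row1], row1 - 1), as.numeric(want))
    }
  }
})

test_that("LF restricted to non-'$' rows is injective and traverses sequences", {
  set.seed(5)
  seqs <- random_seqs(3, 60)
  idx <- build_msbwt(single_seq_collection(seqs))
  # iterating LF from the end-marker row of sid visits exactly that sequence
  for (sid in 0:2) {
    row <- sid
    seen <- numeric(0)
    for (step in seq_len(idx$lens[sid + 1])) {
      row <- pantag:::lf_code(idx, pantag:::bwt_code_at(idx, row), row)
      seen <- c(seen, sa_off <- sequence_of_row(idx, row))
      expect_identical(sequence_of_row(idx, row)[["sid"]], as.numeric(sid))
    }
    offs <- unname(seen[names(seen) == "offset"])
    expect_identical(sort(offs), as.numeric(0:(idx$lens[sid + 1] - 1)))
  }
})

test_that("bidirectional extension matches backward search in both directions", {
  set.seed(77)
  g <- random_pangenome(n_nodes = 10, n_haps = 3, mut_rate = 0.2, seed = 8,
                        node_len = c(3, 8))
  idx <- build_msbwt(build_text(g))
  for (q in 1:200) {
    P <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), replace = TRUE),
               collapse = "")
    iv <- backward_search(idx, P)
    bb <- bi_init(idx)
    for (ch in rev(strsplit(P, "")[[1]])) {
      bb <- bi_extend_backward(idx, bb, ch)
      expect_identical(pantag:::lex_width(bb$fwd), pantag:::lex_width(bb$rev))
    }
    bf <- bi_init(idx)
    for (ch in strsplit(P, "")[[1]]) bf <- bi_extend_forward(idx, bf, ch)
    if (iv[2] < iv[1]) {
      expect_identical(pantag:::lex_width(bb$fwd), 0)
      expect_identical(pantag:::lex_width(bf$fwd), 0)
    } else {
      expect_identical(bb$fwd, iv)
      expect_identical(bf$fwd, iv)
      expect_identical(bb$rev, backward_search(idx, pantag:::rc_string(P)))
    }
  }
  # extending the empty bi-interval stays empty
  e <- pantag:::bi_empty()
  expect_identical(pantag:::lex_width(bi_extend_backward(idx, e, "A")$fwd), 0)
  expect_identical(pantag:::lex_width(bi_extend_forward(idx, e, "A")$fwd), 0)
})

test_that("run count equals maximal equal-character segments of the oracle BWT", {
  set.seed(9)
  for (rep in 1:10) {
    seqs <- random_seqs(sample(1:4, 1), sample(30:120, 1))
    idx <- build_msbwt(single_seq_collection(seqs))
    expect_identical(idx$r, length(rle(naive_bwt(seqs))$values))
    expect_identical(sum(idx$run_len), as.numeric(idx$N))
  }
})
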