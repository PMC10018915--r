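# R reimplementation of winnowing over per-k-mer hashes (taken from w = 1
# extraction, where every k-mer is reported): leftmost minimum per window,
# consecutive duplicates collapsed. Independent of the C++ window logic.
winnow_reference <- function(seq, k, w) {
  per <- extract_minimizers(seq, k, 1L)
  m <- nchar(seq) - k + 1L
  stopifnot(nrow(per) == m)  # odd k over ACGT: no palindromes, none skipped
  sel <- integer(0)
  for (s in seq_len(m - w + 1L)) {
    win <- per$hash[s:(s + w - 1L)]       # fixed-width hex: lexicographic
    sel <- c(sel, s - 1L + which(win == min(win))[1L])
  }
  out <- per[sel[c(TRUE, diff(sel) != 0L)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("minimizer extraction handles trivial and degenerate inputs", {
  expect_identical(nrow(extract_minimizers("ACGTACGTAC", k = 15, w = 5)), 0L)

  # homopolymer: one canonical k-mer; each window selects its leftmost slot
  mm <- extract_minimizers("AAAAAA", k = 3, w = 2)
  expect_identical(length(unique(mm$hash)), 1L)
  expect_identical(mm$pos, c(2L, 3L, 4L))
  expect_identical(unique(mm$strand), "+")

  # w = 1: one minimizer at every k-mer end position
  seq <- random_reference(200, seed = 2)
  mm1 <- extract_minimizers(seq, k = 15, w = 1)
  expect_identical(mm1$pos, 14:199)

  # non-ACGT bases knock out the k-mers covering them
  seqN <- paste0(substr(seq, 1, 50), "N", substr(seq, 52, 200))
  mmN <- extract_minimizers(seqN, k = 15, w = 1)
  expect_identical(mmN$pos, setdiff(14:199, 50:64))
})

test_that("window winnowing matches a brute-force reference scan", {
  for (seed in 1:5) {
    seq <- random_reference(400 + 37 * seed, seed = seed)
    got <- extract_minimizers(seq, k = 15, w = 10)
    ref <- winnow_reference(seq, 15L, 10L)
    rownames(ref) <- NULL
    expect_identical(got, ref, label = paste("seed", seed))
  }
})

test_that("index construction matches direct extraction and is deterministic", {
  p <- map_params()
  idx1 <- build_index(c(one = strrep("A", 100)), p)
  expect_identical(length(unique(idx1$table$hash)), 1L)

  seq <- random_reference(10000, seed = 9)
  idx <- build_index(c(chrA = seq), p)
  direct <- extract_minimizers(seq, p$k, p$w)
  expect_identical(idx$table$hash, direct$hash)
  expect_identical(idx$table$pos, direct$pos)
  expect_true(all(idx$table$pos >= p$k - 1L))

  dup <- build_index(c(a = seq, b = seq), p)
  expect_identical(nrow(dup$table), 2L * nrow(idx$table))

  idx2 <- build_index(c(chrA = seq), p)
  expect_identical(idx$table, idx2$table)

  expect_error(build_index(character(0)), "no non-empty records")
  expect_error(build_index(c(x = "")), "no non-empty records")
})

test_that("anchor collection produces strand-correct diagonal groups", {
  p <- map_params()
  ref <- random_reference(30000, seed = 21)
  idx <- build_index(c(chr = ref), p)

  # the dominant group carries the true placement; stray 1-anchor groups can
  # arise from chance k-mer collisions in a random reference
  dominant <- function(groups) groups[[which.max(vapply(groups, function(s)
    nrow(s$anchors), integer(1)))]]

  fwd <- substr(ref, 5001, 9000)
  g <- dominant(collect_anchors(idx, fwd, "fwd", p))
  expect_identical(g$strand, "+")
  expect_identical(unique(g$anchors$y - g$anchors$x), -5000L)

  rev <- revcomp(substr(ref, 12001, 16000))
  g2 <- dominant(collect_anchors(idx, rev, "rev", p))
  expect_identical(g2$strand, "-")
  # on the reverse-complemented read the match is again a perfect diagonal
  expect_identical(length(unique(g2$anchors$y - g2$anchors$x)), 1L)

  expect_identical(collect_anchors(idx, strrep("C", 400), "none", p), list())
  expect_identical(collect_anchors(idx, "ACGT", "short", p), list())
})

test_that("FASTA input (plain and gzip) matches in-memory sequences", {
  seqs <- c(s1 = random_reference(3000, seed = 4),
            s2 = random_reference(2000, seed = 5))
  fa <- withr::local_tempfile(fileext = ".fa")
  fagz <- withr::local_tempfile(fileext = ".fa.gz")
  write_fasta(seqs, fa)
  write_fasta(seqs, fagz)
  p <- map_params()
  mem <- build_index(seqs, p)
  expect_identical(build_index(fa, p)$table, mem$table)
  expect_identical(build_index(fagz, p)$table, mem$table)
  expect_identical(build_index(fa, p)$names, c("s1", "s2"))
})
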