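test_that("anchor construction enforces span/coordinate invariants", {
  a <- anchors(c(50, 30), c(20, 40), 15)
  expect_identical(a$w, c(15L, 15L))
  expect_error(anchors(10, 10, 0), "span")
  expect_error(anchors(10, 20, 15), "fit the span")
  expect_error(anchors(20, 10, 15), "fit the span")
  expect_identical(nrow(anchors(integer(0), integer(0), 15)), 0L)
})

test_that("sort_anchors orders by (x, y), stably, and is idempotent", {
  a <- anchors(c(50, 30), c(20, 40), 15)
  s <- sort_anchors(a)
  expect_identical(s$x, c(30L, 50L))
  expect_identical(s$y, c(40L, 20L))

  set.seed(11)
  r <- anchors(14L + sample.int(50, 100, TRUE), 14L + sample.int(50, 100, TRUE), 15)
  s1 <- sort_anchors(r)
  ref <- r[order(r$x, r$y), ]
  rownames(ref) <- NULL
  expect_identical(s1, ref)
  expect_identical(sort_anchors(s1), s1)

  # stability on full (x, y) ties: distinguish duplicates by span
  t0 <- data.frame(x = c(99L, 99L, 99L), y = c(99L, 99L, 99L),
                   w = c(11L, 12L, 13L))
  expect_identical(sort_anchors(t0)$w, c(11L, 12L, 13L))
})

test_that("anchor sets reject mixed groups and record read metadata", {
  mixed <- data.frame(x = c(30L, 50L), y = c(40L, 20L), w = 15L,
                      rid = c(0L, 1L), strand = "+")
  expect_error(sort_anchors(mixed), "group")
  mixed2 <- data.frame(x = c(30L, 50L), y = c(40L, 20L), w = 15L,
                       rid = 0L, strand = c("+", "-"))
  expect_error(sort_anchors(mixed2), "group")

  s <- anchor_set(anchors(integer(0), integer(0), 15))
  expect_s3_class(s, "anchor_set")
  expect_identical(nrow(s$anchors), 0L)

  s2 <- anchor_set(anchors(50, 120, 15), read_id = "r9", strand = "-")
  expect_identical(s2$read_length, 121L)
  expect_identical(s2$strand, "-")
})

test_that("anchor TSV round-trips and rejects malformed rows", {
  sets <- list(
    anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15), "r1"),
    anchor_set(anchors(c(99, 199), c(50, 150), 15), "r2", rid = 3L,
               strand = "-"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_anchor_tsv(sets, path)
  back <- read_anchor_tsv(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$anchors, sets[[1]]$anchors)
  expect_identical(back[[2]]$rid, 3L)
  expect_identical(back[[2]]$strand, "-")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#read_id\trid\tstrand\tx\ty\tw", empty)
  expect_identical(read_anchor_tsv(empty), list())

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\t0\t+\t100\t100\t15", "r1\t0\t+\tnope\t200\t15"), bad)
  expect_error(read_anchor_tsv(bad), "malformed")
})

test_that("map_params validates the probe ladder and thresholds", {
  p <- map_params()
  expect_identical(p$probe_deltas[1], 0L)
  expect_identical(p$probe_deltas[length(p$probe_deltas)], p$max_range)
  expect_error(map_params(probe_deltas = c(0L, 16L, 8L, 5000L)), "increasing")
  expect_error(map_params(probe_deltas = c(16L, 512L, 5000L)), "start at 0")
  expect_error(map_params(probe_deltas = c(0L, 16L, 4096L)), "max_range")
  expect_error(map_params(mask_level = 0), "mask_level")
  expect_error(map_params(max_skip = 2.5), "max_skip")
  expect_identical(map_params(max_skip = 25)$max_skip, 25)
})
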