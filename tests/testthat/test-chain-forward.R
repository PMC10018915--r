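test_that("probe-based successor ranges equal the linear scan", {
  p <- map_params()
  s1 <- anchor_set(anchors(115, 115, 15))
  expect_identical(successor_ranges(s1, p), 2L)  # empty range

  s10 <- anchor_set(anchors(seq(100, 1000, 100), seq(100, 1000, 100), 15))
  expect_identical(successor_ranges(s10, p)[1], 11L)  # all 9 in range

  # spacing 400: probe at delta 16 overshoots (gap 6400), decrement to the
  # last anchor within 5000 (gap 4800), 12 successors for the first anchor
  s400 <- anchor_set(anchors(399 + seq(0, 8000, 400), 399 + seq(0, 8000, 400), 15))
  expect_identical(successor_ranges(s400, p)[1], 14L)
  expect_identical(successor_ranges(s400, p), oracle_successor_ranges(s400, p))

  # cap at max_range successors: 6000 anchors one base apart
  xy <- seq_len(6000L) + 14L
  big <- anchor_set(anchors(xy, xy, 15))
  rb <- successor_ranges(big, p)
  expect_identical(rb[1], 5002L)  # 5000 successors for anchor 1
  expect_identical(rb, oracle_successor_ranges(big, p))

  for (seed in 1:6) {
    s <- gen_suite(1L, size_pool = 50:400, seed = 300L + seed)[[1L]]
    expect_identical(successor_ranges(s, p), oracle_successor_ranges(s, p),
                     label = paste("seed", seed))
    # the two independent oracles agree with each other too
    expect_identical(oracle_successor_ranges(s, p),
                     oracle_successor_ranges_slow(s, p),
                     label = paste("oracle xcheck seed", seed))
  }
})

test_that("condense matches its defining predicate", {
  expect_identical(condense(integer(0)), integer(0))
  # 0-based spec example end_idx = [2,2,5,4,5] translates to 1-based [3,3,6,5,6]
  expect_identical(condense(c(3L, 3L, 6L, 5L, 6L)), c(1L, 3L))
  # all ranges empty
  expect_identical(condense(c(2L, 3L, 4L)), integer(0))
  p <- map_params()
  for (seed in 1:4) {
    s <- gen_suite(1L, size_pool = 50:300, seed = 400L + seed)[[1L]]
    e <- successor_ranges(s, p)
    expect_identical(condense(e), which(e > seq_along(e) + 1L))
  }
})

test_that("forward DP equals the backward oracle on small worked examples", {
  p <- map_params()
  s1 <- anchor_set(anchors(115, 115, 15))
  expect_same_state(chain_forward(s1, p), chain_backward(s1, p))

  s3 <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
  f3 <- chain_forward(s3, p)
  expect_identical(f3$S, c(15L, 30L, 45L))
  expect_identical(f3$P, c(0L, 1L, 2L))
  expect_identical(f3$V, c(15L, 30L, 45L))
})

test_that("forward tie-breaks match backward nearest-predecessor semantics", {
  p <- map_params()
  # duplicate predecessors offering equal candidates: the nearer (later) one
  # must win, as in the backward scan
  dup <- anchor_set(anchors(c(300, 300, 400), c(300, 300, 400), 15))
  bw <- chain_backward(dup, p)
  expect_identical(bw$P, c(0L, 0L, 2L))
  expect_same_state(chain_forward(dup, p), bw)

  # a tie equal to an anchor's own span never displaces its chain-start state
  # (two far predecessors whose candidates equal w_j would otherwise claim it)
  for (seed in 1:6) {
    s <- gen_tie_set(120L, seed = 500L + seed)
    expect_same_state(chain_forward(s, p), chain_backward(s, p),
                      label = paste("tie seed", seed))
  }
})

test_that("restricting sources to the condensed workload changes nothing", {
  p <- map_params()
  for (seed in 1:6) {
    s <- gen_suite(1L, size_pool = 50:400, seed = 600L + seed)[[1L]]
    e <- successor_ranges(s, p)
    full <- chain_forward(s, p, ranges = e)
    cond <- chain_forward(s, p, ranges = e, workload = condense(e))
    expect_same_state(full, cond, label = paste("seed", seed))
  }
})

test_that("V equals the maximum score along each backtrack path", {
  p <- map_params()
  for (seed in 1:6) {
    s <- gen_suite(1L, size_pool = 50:300, seed = 700L + seed)[[1L]]
    st <- chain_forward(s, p)
    expect_identical(st$V, oracle_v_by_path(st$S, st$P),
                     label = paste("seed", seed))
  }
})

test_that("inconsistent successor ranges are a contract violation", {
  p <- map_params()
  s <- anchor_set(anchors(c(115, 215), c(115, 215), 15))
  expect_error(chain_forward(s, p, ranges = c(4L, 3L)), "out of bounds")
  expect_error(chain_forward(s, p, ranges = c(3L)), "inconsistent")
})
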