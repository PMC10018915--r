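#' Chaining score of one anchor pair
#'
#' Score contributed by chaining anchor `i` (earlier) to anchor `j` (later),
#' on end coordinates: with reference gap `dr = xj - xi`, query gap
#' `dq = yj - yi` and gap difference `dd = |dr - dq|`, the pair is unchainable
#' (`NA`, the NO_CHAIN signal) when `dr <= 0`, `dq <= 0`, `dq > max_dist_y`,
#' `dr > max_dist_x` or `dd > bandwidth`; otherwise the score is
#' `min(dq, dr, wj) - trunc(dd * 0.01 * avg_span) - (ilog2(dd) %/% 2)` where
#' `ilog2` is the integer floor of log2 (and 0 at `dd = 0`). All arithmetic is
#' integer; legitimate negative scores are representable, which is why
#' NO_CHAIN is signalled out of band as `NA` rather than by a sentinel value.
#'
#' @param xi,yi coordinates of the earlier anchor (vectorized).
#' @param xj,yj,wj coordinates and span of the later anchor (vectorized).
#' @param avg_span mean anchor span of the whole anchor set (one number,
#'   computed once before the DP).
#' @param params a [map_params()] object.
#' @return Integer vector of scores, `NA` where the pair is unchainable.
#' @examples
#' p <- map_params()
#' pair_score(115, 115, 215, 218, 15, avg_span = 15, params = p)  # 15
#' pair_score(100, 200, 200, 150, 15, avg_span = 15, params = p)  # NA: dq < 0
#' @export
pair_score <- function(xi, yi, xj, yj, wj, avg_span, params = map_params()) {
  n <- max(length(xi), length(yi), length(xj), length(yj), length(wj))
  pair_score_cpp(as.integer(rep_len(xi, n)), as.integer(rep_len(yi, n)),
                 as.integer(rep_len(xj, n)), as.integer(rep_len(yj, n)),
                 as.integer(rep_len(wj, n)), as.numeric(avg_span),
                 params$max_dist_x, params$max_dist_y, params$bandwidth)
}

#' Predecessor range start of one anchor
#'
#' The sequential (backward) DP scans predecessors `st .. j-1` where `st` is
#' the smallest index whose reference gap to `j` is within `max_dist_x`,
#' additionally bounded so that at most `max_range` predecessors are examined.
#'
#' @param set an [anchor_set()].
#' @param j anchor index (1-based).
#' @param params a [map_params()] object.
#' @return The 1-based start index `st` (`st == j` means no predecessors).
#' @export
predecessor_range <- function(set, j, params = map_params()) {
  x <- set$anchors$x
  n <- length(x)
  if (j < 1L || j > n) stop("anchor index out of range")
  st <- j
  while (st > 1L && x[j] - x[st - 1L] <= params$max_dist_x) st <- st - 1L
  max(st, j - params$max_range)
}

as_chain_state <- function(res, n) {
  structure(list(S = as.integer(res$S),
                 P = as.integer(res$P) + 1L,  # 0 = chain start
                 V = as.integer(res$V),
                 n = as.integer(n)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat("chain_state over", x$n, "anchors; best score",
      if (x$n > 0L) max(x$S) else 0L, "\n")
  invisible(x)
}

#' Sequential predecessor-order chaining DP (the backward engine)
#'
#' The classic chaining dynamic program: anchors are processed in sorted
#' order; each anchor `j` scans its predecessors from nearest (`j - 1`) down
#' to [predecessor_range()] and keeps the best `S[i] + pair_score(i, j)`,
#' updating only on strict improvement, so the NEAREST predecessor wins score
#' ties. With finite `params$max_skip` the scan terminates early after
#' `max_skip` consecutive scored-but-non-improving candidates (the speed
#' heuristic, which can only miss improvements); with `max_skip = Inf` the DP
#' is exact and serves as the normative oracle for [chain_forward()].
#'
#' @param set an [anchor_set()].
#' @param params a [map_params()] object.
#' @return A `chain_state`: integer vectors `S` (best chain score per anchor,
#'   at least the anchor's own span), `P` (best predecessor index, 1-based,
#'   0 = chain start) and `V` (maximum of `S` along the chain from its start:
#'   `V[i] = max(S[i], V[P[i]])`).
#' @examples
#' s <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
#' chain_backward(s)$S  # 15 30 45
#' @export
chain_backward <- function(set, params = map_params()) {
  stopifnot(inherits(set, "anchor_set"))
  a <- set$anchors
  res <- chain_backward_cpp(a$x, a$y, a$w,
                            params$max_dist_x, params$max_dist_y,
                            params$bandwidth, params$max_range,
                            skip_code(params))
  as_chain_state(res, nrow(a))
}

#' Dynamic successor ranges via the probe-delta speed heuristic
#'
#' For each anchor `i`, the successor range is the run of following anchors
#' whose reference gap stays within `max_dist_x`, capped at `max_range`
#' successors. Because anchors are sorted by reference position the range is a
#' prefix of the following anchors, and it is found with few iterations by
#' probing offsets `params$probe_deltas` in ascending order, stopping at the
#' first out-of-threshold probe and then decrementing to the exact boundary.
#' Probes beyond the last anchor count as out of threshold, so the heuristic
#' is total on short tails. The result equals a full linear scan for every
#' anchor; the probes only save iterations.
#'
#' @param set an [anchor_set()].
#' @param params a [map_params()] object.
#' @return Integer vector `end_idx`: for each anchor `i` the 1-based EXCLUSIVE
#'   upper index of its successor range (candidate successors are
#'   `(i+1) .. (end_idx[i]-1)`; `end_idx[i] == i + 1` means an empty range).
#' @examples
#' s <- anchor_set(anchors(seq(100, 1000, 100), seq(100, 1000, 100), 15))
#' successor_ranges(s)  # every anchor reaches the end: 11 11 ... 11
#' @export
successor_ranges <- function(set, params = map_params()) {
  stopifnot(inherits(set, "anchor_set"))
  successor_ranges_cpp(set$anchors$x, params$max_dist_x, params$max_range,
                       params$probe_deltas) + 1L
}

#' Condensed workload vector
#'
#' Indices of the anchors with a non-empty successor range, in ascending
#' order. Only these anchors can push scores in the forward DP; the sparse
#' majority with zero successors (typically anchors that do not continue into
#' any chain) are skipped as score sources.
#'
#' @param end_idx successor ranges from [successor_ranges()].
#' @return Integer vector of 1-based anchor indices.
#' @examples
#' condense(c(3L, 3L, 6L, 5L, 6L))  # anchors 1 and 3
#' @export
condense <- function(end_idx) {
  n <- length(end_idx)
  which(end_idx > seq_len(n) + 1L)
}

#' Forward-transformed chaining DP (the successor-order engine)
#'
#' Reorders the chaining loops so that each anchor `i`, taken in ascending
#' order, PUSHES candidate scores `S[i] + pair_score(i, j)` to every successor
#' `j` in its range, instead of each `j` pulling from its predecessors. This
#' removes the sequential max-reduction over predecessors: all updates from
#' one source are independent. A successor is updated when the candidate
#' strictly exceeds its stored score, or equals it and the stored score is not
#' the anchor's own span (a tie never displaces a not-yet-chained anchor).
#' Since sources arrive in ascending order, the last writer on a tie is the
#' nearest predecessor — exactly the backward engine's tie-break — and the
#' returned `S`, `P`, `V` are bit-identical to [chain_backward()] with
#' `max_skip = Inf`. `V[i]` is finalized when the loop reaches `i`, at which
#' point every update into `i` has happened.
#'
#' @param set an [anchor_set()].
#' @param params a [map_params()] object.
#' @param ranges optional precomputed [successor_ranges()]; validated against
#'   the set (an out-of-bounds range is a contract violation).
#' @param workload optional [condense()]d index vector restricting which
#'   anchors act as score sources. Anchors with empty ranges push nothing, so
#'   restricting to the condensed workload leaves the result unchanged.
#' @return A `chain_state` (see [chain_backward()]).
#' @examples
#' s <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
#' identical(chain_forward(s)$S, chain_backward(s)$S)
#' @export
chain_forward <- function(set, params = map_params(), ranges = NULL,
                          workload = NULL) {
  stopifnot(inherits(set, "anchor_set"))
  a <- set$anchors
  if (is.null(ranges)) ranges <- successor_ranges(set, params)
  if (length(ranges) != nrow(a))
    stop("successor ranges inconsistent with anchors")
  src <- if (is.null(workload)) NULL else as.integer(workload) - 1L
  res <- chain_forward_cpp(a$x, a$y, a$w, as.integer(ranges) - 1L,
                           params$max_dist_x, params$max_dist_y,
                           params$bandwidth, src)
  as_chain_state(res, nrow(a))
}
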