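#' Backtrack chains from a chain state
#'
#' Extracts chains so that no anchor is used in more than one chain. Candidate
#' end anchors are visited in descending `(S, index)` order; from each unused
#' anchor with `S >= min_score` the predecessor pointers are followed until a
#' used anchor or a chain start is reached. The score of a chain truncated at
#' a used anchor is the end anchor's `S` minus `S` at the truncation point
#' (floored at 0). Chains with fewer than `min_cnt` anchors or score below
#' `min_score` are dropped, but their anchors still count as used.
#'
#' @param state a `chain_state` from [chain_backward()] or [chain_forward()].
#' @param set the [anchor_set()] the state was computed from.
#' @param params a [map_params()] object.
#' @return A data.frame with one row per chain: `score`, `n_anchors`,
#'   `q_start`/`q_end` and `r_start`/`r_end` (0-based half-open intervals),
#'   `rid`, `strand`, and a list column `anchor_indices` (ascending 1-based
#'   indices into the set). Ordered by descending score.
#' @examples
#' s <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
#' backtrack(chain_backward(s), s)
#' @export
backtrack <- function(state, set, params = map_params()) {
  stopifnot(inherits(state, "chain_state"), inherits(set, "anchor_set"))
  a <- set$anchors
  n <- nrow(a)
  if (state$n != n) stop("chain state inconsistent with anchor set")
  if (n == 0L) return(empty_chains())
  S <- state$S
  P <- state$P
  used <- logical(n)
  out <- list()
  for (k in order(-S, -seq_len(n))) {
    if (used[k] || S[k] < params$min_score) next
    path <- integer(0)
    cur <- k
    trunc_score <- 0L
    repeat {
      path <- c(path, cur)
      used[cur] <- TRUE
      p <- P[cur]
      if (p == 0L) break
      if (used[p]) {
        trunc_score <- S[p]
        break
      }
      cur <- p
    }
    score <- max(0L, S[k] - trunc_score)
    if (length(path) < params$min_cnt || score < params$min_score) next
    idx <- rev(path)
    first <- idx[1L]
    last <- idx[length(idx)]
    out[[length(out) + 1L]] <- data.frame(
      score = score, n_anchors = length(idx),
      q_start = a$y[first] - a$w[first] + 1L, q_end = a$y[last] + 1L,
      r_start = a$x[first] - a$w[first] + 1L, r_end = a$x[last] + 1L,
      rid = set$rid, strand = set$strand, sum_span = sum(a$w[idx]),
      anchor_indices = I(list(idx)))
  }
  if (length(out) == 0L) return(empty_chains())
  ch <- do.call(rbind, out)
  ch <- ch[order(-ch$score), , drop = FALSE]
  rownames(ch) <- NULL
  ch
}

empty_chains <- function() {
  data.frame(score = integer(), n_anchors = integer(),
             q_start = integer(), q_end = integer(),
             r_start = integer(), r_end = integer(),
             rid = integer(), strand = character(), sum_span = integer(),
             anchor_indices = I(list()))
}

#' Classify primary and secondary chains of one read
#'
#' Chains (possibly pooled across reference sequences and strands of one read)
#' are sorted by descending score; a chain is primary iff its query-interval
#' overlap with every higher-scoring primary is below `mask_level` times its
#' own query-interval length. Each secondary records the score of its
#' best-overlapping primary; each primary records the best secondary score
#' shadowed by it (`f2`, 0 when none), the input to [mapping_quality()].
#'
#' @param chains a chains data.frame as returned by [backtrack()] (rows from
#'   several anchor sets of one read may be concatenated).
#' @param params a [map_params()] object.
#' @return The chains with logical `is_primary`, integer `f2` and `mapq`
#'   columns added, sorted by descending score (ties by query start, rid,
#'   strand for determinism).
#' @export
identify_primary <- function(chains, params = map_params()) {
  n <- nrow(chains)
  if (n == 0L) {
    chains$is_primary <- logical(0)
    chains$f2 <- integer(0)
    chains$mapq <- integer(0)
    return(chains)
  }
  ord <- order(-chains$score, chains$q_start, chains$rid, chains$strand,
               method = "radix")
  chains <- chains[ord, , drop = FALSE]
  rownames(chains) <- NULL
  is_primary <- logical(n)
  best_sec <- integer(n)   # per primary: best shadowed secondary score
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    prim <- which(is_primary[seq_len(i - 1L)])
    ov <- if (length(prim) == 0L) integer(0) else
      pmax(0L, pmin(chains$q_end[prim], chains$q_end[i]) -
                 pmax(chains$q_start[prim], chains$q_start[i]))
    own <- chains$q_end[i] - chains$q_start[i]
    hit <- prim[ov >= params$mask_level * own & ov > 0L]
    if (length(hit) == 0L) {
      is_primary[i] <- TRUE
    } else {
      parent[i] <- hit[1L]  # highest-scoring overlapping primary
      best_sec[hit[1L]] <- max(best_sec[hit[1L]], chains$score[i])
    }
  }
  chains$is_primary <- is_primary
  chains$f2 <- best_sec
  sec <- which(!is_primary)
  chains$f2[sec] <- chains$score[parent[sec]]
  chains$mapq <- 0L
  for (i in which(is_primary)) {
    chains$mapq[i] <- mapping_quality(chains$score[i], best_sec[i],
                                      chains$n_anchors[i])
  }
  chains
}

#' Empirical mapping quality of a primary chain
#'
#' `mapq = round(40 * (1 - f2/f1) * min(1, m/10) * ln(f1))`, clamped to
#' `[0, 60]`: confidence grows with the primary chain score `f1` and its
#' anchor count `m`, and shrinks to 0 as the best overlapping secondary score
#' `f2` approaches `f1` (an equally good alternative placement).
#'
#' @param f1 primary chain score (> 0).
#' @param f2 best overlapping secondary chain score (0 when none); `f2 <= f1`.
#' @param m number of anchors in the primary chain (>= 1).
#' @return Integer mapping quality in `[0, 60]`.
#' @examples
#' mapping_quality(100, 100, 20)  # 0: ambiguous placement
#' mapping_quality(45, 0, 12)     # 60 after clamping
#' @export
mapping_quality <- function(f1, f2, m) {
  if (any(f1 <= 0)) stop("f1 must be > 0")
  if (any(f2 < 0) || any(f2 > f1)) stop("f2 must satisfy 0 <= f2 <= f1")
  if (any(m < 1)) stop("m must be >= 1")
  q <- round(40 * (1 - f2 / f1) * pmin(1, m / 10) * log(f1))
  as.integer(pmax(0, pmin(60, q)))
}
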