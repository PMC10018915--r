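#' Mapping and chaining parameters
#'
#' Bundles every threshold used by seeding, chaining and chain postprocessing.
#' Defaults follow the ONT mapping convention of the upstream long-read
#' mapper: seeds are 15-mers winnowed in windows of 10, chaining allows gaps
#' up to 5000 bases on either sequence within a 500-base band, and at most
#' 5000 predecessors/successors are examined per anchor.
#'
#' @param k k-mer size for minimizer seeding (anchors get span `w = k`).
#' @param w minimizer window: one k-mer is selected from every window of `w`
#'   consecutive k-mers.
#' @param max_dist_x maximum reference gap (bases) between chainable anchors.
#' @param max_dist_y maximum query gap (bases) between chainable anchors.
#' @param bandwidth maximum absolute difference between the query gap and the
#'   reference gap of a chainable pair.
#' @param max_range cap on the number of predecessors/successors examined per
#'   anchor.
#' @param probe_deltas strictly increasing integer offsets probed by the
#'   successor-range speed heuristic; must start at 0 and end at `max_range`.
#' @param max_skip `Inf` (default) disables the skip heuristic, making the
#'   sequential DP exact; a finite value terminates each predecessor scan
#'   after that many consecutive non-improving scored candidates.
#' @param min_score minimum chain score kept by [backtrack()].
#' @param min_cnt minimum number of anchors in a kept chain.
#' @param mask_level a chain is secondary when its query-interval overlap with
#'   a better primary reaches this fraction of its own query length.
#'
#' @return An object of class `map_params` (a validated list).
#' @examples
#' p <- map_params()
#' p$max_dist_x
#' map_params(max_skip = 25)
#' @export
map_params <- function(k = 15L, w = 10L,
                       max_dist_x = 5000L, max_dist_y = 5000L,
                       bandwidth = 500L, max_range = 5000L,
                       probe_deltas = c(0L, 16L, 512L, 1024L, 2048L,
                                        3072L, 4096L, 5000L),
                       max_skip = Inf,
                       min_score = 40L, min_cnt = 3L, mask_level = 0.5) {
  p <- list(k = as.integer(k), w = as.integer(w),
            max_dist_x = as.integer(max_dist_x),
            max_dist_y = as.integer(max_dist_y),
            bandwidth = as.integer(bandwidth),
            max_range = as.integer(max_range),
            probe_deltas = as.integer(probe_deltas),
            max_skip = max_skip,
            min_score = as.integer(min_score),
            min_cnt = as.integer(min_cnt),
            mask_level = as.numeric(mask_level))
  if (p$k < 1L || p$k > 31L) stop("k must be in [1, 31]")
  if (p$w < 1L) stop("w must be >= 1")
  if (p$max_dist_x < 1L || p$max_dist_y < 1L) stop("gap limits must be >= 1")
  if (p$bandwidth < 0L) stop("bandwidth must be >= 0")
  if (p$max_range < 1L) stop("max_range must be >= 1")
  d <- p$probe_deltas
  if (length(d) < 1L || d[1L] != 0L || any(diff(d) <= 0L) ||
      d[length(d)] != p$max_range)
    stop("probe_deltas must be strictly increasing, start at 0 and end at max_range")
  if (!(is.infinite(p$max_skip) || (p$max_skip >= 1 && p$max_skip == trunc(p$max_skip))))
    stop("max_skip must be Inf or a positive integer")
  if (p$min_cnt < 1L) stop("min_cnt must be >= 1")
  if (p$mask_level <= 0 || p$mask_level > 1) stop("mask_level must be in (0, 1]")
  structure(p, class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat("map_params: k=", x$k, " w=", x$w,
      " max_dist_x/y=", x$max_dist_x, "/", x$max_dist_y,
      " bandwidth=", x$bandwidth, " max_range=", x$max_range,
      " max_skip=", if (is.infinite(x$max_skip)) "Inf" else x$max_skip,
      " min_score=", x$min_score, " min_cnt=", x$min_cnt,
      " mask_level=", x$mask_level, "\n", sep = "")
  invisible(x)
}

# internal: max_skip encoded for the C++ engine (<= 0 means unbounded)
skip_code <- function(params) {
  if (is.infinite(params$max_skip)) 0L else as.integer(params$max_skip)
}
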