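#' Default read-length bin edges
#'
#' Reads of similar length are batched together so that downstream chaining
#' workloads are balanced: 1 kb steps up to 10 kb, 5 kb steps to 50 kb, then
#' wide 50-100 kb and 100-150 kb bins (long reads vary too much in length for
#' narrow bins to fill), and an open-ended final bin.
#'
#' @return Numeric vector of bin edges (left-open intervals, last edge `Inf`).
#' @export
default_bin_edges <- function() {
  c(seq(0, 10000, by = 1000), seq(15000, 50000, by = 5000), 1e5, 1.5e5, Inf)
}

#' Bin reads by length into batches
#'
#' Each read is assigned to exactly one bin; one batch per non-empty bin is
#' emitted (bins in ascending length order, reads within a batch in input
#' order).
#'
#' @param read_lengths a data.frame with columns `read_id` and `length`
#'   (lengths > 0).
#' @param edges bin edges; see [default_bin_edges()].
#' @return A list of batches, each a list with `bin` (label like `"1-2kb"`),
#'   `read_id` and `length`.
#' @examples
#' bin_reads(data.frame(read_id = c("r1", "r2", "r3"),
#'                      length = c(1500, 2500, 2600)))
#' @export
bin_reads <- function(read_lengths, edges = default_bin_edges()) {
  stopifnot(is.data.frame(read_lengths),
            all(c("read_id", "length") %in% names(read_lengths)))
  if (nrow(read_lengths) == 0L) return(list())
  if (any(read_lengths$length <= 0)) stop("read lengths must be > 0")
  edges <- sort(unique(c(0, edges)))
  bin <- findInterval(read_lengths$length, edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  lab <- function(i) {
    lo <- edges[i]; hi <- edges[i + 1L]
    fmt <- function(v) if (is.infinite(v)) "Inf" else
      if (v >= 1000) paste0(v / 1000, "kb") else paste0(v, "b")
    paste0(fmt(lo), "-", fmt(hi))
  }
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- which(bin == b)
    list(bin = lab(b), read_id = read_lengths$read_id[sel],
         length = read_lengths$length[sel])
  })
  out
}
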