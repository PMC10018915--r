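#' Construct a table of anchors
#'
#' An anchor is one exact minimizer match between a read and a reference,
#' stored as the 0-based coordinates of the LAST matched base on the reference
#' (`x`) and on the query (`y`), plus the match span `w`. For reverse-strand
#' matches `y` is the coordinate on the reverse-complemented read, so chaining
#' is strand-agnostic.
#'
#' @param x,y integer end coordinates (0-based) on reference and query.
#' @param w integer span(s), recycled; each must satisfy `w >= 1`,
#'   `x >= w - 1`, `y >= w - 1`.
#' @return A `data.frame` with integer columns `x`, `y`, `w`.
#' @examples
#' anchors(c(50, 30), c(20, 40), 15)
#' @export
anchors <- function(x, y, w) {
  x <- as.integer(x); y <- as.integer(y)
  w <- as.integer(rep_len(w, length(x)))
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (length(x) > 0L) {
    if (any(w < 1L)) stop("anchor span w must be >= 1")
    if (any(x < w - 1L) || any(y < w - 1L))
      stop("anchor coordinates must fit the span: x >= w - 1 and y >= w - 1")
  }
  data.frame(x = x, y = y, w = w)
}

#' Sort anchors into canonical chaining order
#'
#' Anchors are ordered lexicographically by `(x, y)`; the sort is stable, so
#' full ties keep their input order (this makes the DP's nearest-predecessor
#' tie-break well defined). Duplicates are preserved.
#'
#' @param a a data.frame of anchors (columns `x`, `y`, `w`; optionally `rid`
#'   and `strand`, which must then be constant).
#' @return The same data.frame, reordered; row names dropped.
#' @examples
#' sort_anchors(anchors(c(50, 30), c(20, 40), 15))
#' @export
sort_anchors <- function(a) {
  if (!is.null(a$rid) && length(unique(a$rid)) > 1L)
    stop("anchors mix reference sequences; group by (rid, strand) first")
  if (!is.null(a$strand) && length(unique(a$strand)) > 1L)
    stop("anchors mix strands; group by (rid, strand) first")
  if (nrow(a) > 1L) a <- a[order(a$x, a$y, method = "radix"), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Bundle sorted anchors of one (read, reference, strand) group
#'
#' The chaining DP's input container: anchors of one read against one target
#' sequence and strand, sorted by [sort_anchors()].
#'
#' @param a data.frame of anchors (see [anchors()]).
#' @param read_id read name.
#' @param read_length read length in bases; defaults to `max(y) + 1`.
#' @param rid reference sequence index (0-based).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `anchor_set`.
#' @examples
#' anchor_set(anchors(c(115, 215), c(115, 218), 15), read_id = "r1")
#' @export
anchor_set <- function(a, read_id = "read", read_length = NULL,
                       rid = 0L, strand = "+") {
  stopifnot(is.data.frame(a), all(c("x", "y", "w") %in% names(a)))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  a <- sort_anchors(a[, c("x", "y", "w"), drop = FALSE])
  if (is.null(read_length))
    read_length <- if (nrow(a) > 0L) max(a$y) + 1L else 0L
  structure(list(anchors = a, read_id = as.character(read_id),
                 read_length = as.integer(read_length),
                 rid = as.integer(rid), strand = strand),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set: read '", x$read_id, "' (", x$read_length, " bp), rid ",
      x$rid, ", strand ", x$strand, ", ", nrow(x$anchors), " anchors\n",
      sep = "")
  invisible(x)
}

#' Read anchor sets from the plain-text TSV dialect
#'
#' One row per anchor with columns `read_id`, `rid`, `strand`, `x`, `y`, `w`;
#' lines starting with `#` are headers/comments. Rows are grouped by
#' `(read_id, rid, strand)` into one [anchor_set()] each.
#'
#' @param path file path.
#' @return A list of `anchor_set` objects (possibly empty).
#' @seealso [write_anchor_tsv()]
#' @export
read_anchor_tsv <- function(path) {
  cols <- c("read_id", "rid", "strand", "x", "y", "w")
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      col.names = cols,
                      colClasses = c("character", "integer", "character",
                                     "integer", "integer", "integer")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        as.data.frame(stats::setNames(
          list(character(), integer(), character(),
               integer(), integer(), integer()), cols))
      } else {
        stop("malformed anchor TSV '", path, "': ", conditionMessage(e),
             call. = FALSE)
      }
    })
  if (anyNA(raw$x) || anyNA(raw$y) || anyNA(raw$w)) {
    bad <- which(is.na(raw$x) | is.na(raw$y) | is.na(raw$w))[1L]
    stop("malformed anchor TSV '", path, "' at data row ", bad)
  }
  if (nrow(raw) == 0L) return(list())
  key <- paste(raw$read_id, raw$rid, raw$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(raw)), factor(key, levels = unique(key))),
                function(idx) {
                  g <- raw[idx, , drop = FALSE]
                  anchor_set(anchors(g$x, g$y, g$w), read_id = g$read_id[1L],
                             rid = g$rid[1L], strand = g$strand[1L])
                })
  names(out) <- NULL
  out
}

#' Write anchor sets to the plain-text TSV dialect
#'
#' @param sets a single `anchor_set` or a list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @seealso [read_anchor_tsv()]
#' @export
write_anchor_tsv <- function(sets, path) {
  if (inherits(sets, "anchor_set")) sets <- list(sets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#read_id\trid\tstrand\tx\ty\tw", con)
  for (s in sets) {
    a <- s$anchors
    if (nrow(a) == 0L) next
    utils::write.table(
      data.frame(s$read_id, s$rid, s$strand, a$x, a$y, a$w),
      con, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
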