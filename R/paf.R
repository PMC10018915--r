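#' Write mapping records as PAF
#'
#' Tab-separated, newline-terminated lines with the 12 mandatory PAF columns
#' (query name, length, start, end; strand; target name, length, start, end;
#' residue matches; alignment block length; mapq) followed by a `tp:A:P`/`S`
#' tag marking primary vs secondary records. Coordinates are 0-based
#' half-open; query coordinates of `-` strand hits are on the original read
#' orientation.
#'
#' @param paf a data.frame as returned by [map_reads()].
#' @param path output path, or `""` to print to stdout.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path = "") {
  lines <- character(nrow(paf))
  if (nrow(paf) > 0L) {
    lines <- paste(paf$qname, paf$qlen, paf$qstart, paf$qend, paf$strand,
                   paf$tname, paf$tlen, paf$tstart, paf$tend,
                   paf$nmatch, paf$blocklen, paf$mapq,
                   paste0("tp:A:", ifelse(paf$tp, "P", "S")),
                   sep = "\t")
  }
  if (identical(path, "")) {
    if (length(lines) > 0L) cat(lines, sep = "\n")
    if (length(lines) > 0L) cat("\n")
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a PAF file
#'
#' Parses the 12 mandatory columns and the `tp:A:` tag (when present) back
#' into the [map_reads()] data.frame layout, validating interval and mapq
#' invariants.
#'
#' @param path PAF file path.
#' @return A data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `blocklen`,
#'   `mapq`, `tp` (logical: primary).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad) > 0L)
    stop("malformed PAF '", path, "' at line ", bad[1L],
         ": fewer than 12 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  tp <- vapply(parts, function(p) {
    t <- grep("^tp:A:", p, value = TRUE)
    if (length(t) == 0L) TRUE else substring(t[1L], 6L, 6L) == "P"
  }, logical(1))
  paf <- data.frame(
    qname = m[, 1L], qlen = as.integer(m[, 2L]),
    qstart = as.integer(m[, 3L]), qend = as.integer(m[, 4L]),
    strand = m[, 5L],
    tname = m[, 6L], tlen = as.integer(m[, 7L]),
    tstart = as.integer(m[, 8L]), tend = as.integer(m[, 9L]),
    nmatch = as.integer(m[, 10L]), blocklen = as.integer(m[, 11L]),
    mapq = as.integer(m[, 12L]), tp = tp)
  validate_paf(paf, path)
  paf
}

empty_paf <- function() {
  data.frame(qname = character(), qlen = integer(), qstart = integer(),
             qend = integer(), strand = character(), tname = character(),
             tlen = integer(), tstart = integer(), tend = integer(),
             nmatch = integer(), blocklen = integer(), mapq = integer(),
             tp = logical())
}

validate_paf <- function(paf, what = "PAF") {
  ok <- paf$qstart >= 0L & paf$qstart < paf$qend & paf$qend <= paf$qlen &
    paf$tstart >= 0L & paf$tstart < paf$tend & paf$tend <= paf$tlen &
    paf$strand %in% c("+", "-") & paf$mapq >= 0L & paf$mapq <= 60L
  if (any(!ok))
    stop("invalid PAF record in ", what, " (record ", which(!ok)[1L], ")")
  invisible(paf)
}
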