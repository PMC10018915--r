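#' Extract minimizers from one DNA sequence
#'
#' Classic (w,k)-minimizer winnowing: for every window of `w` consecutive
#' k-mers, the k-mer with the minimal 64-bit hash is selected (leftmost on
#' hash ties); a position selected by consecutive windows is reported once.
#' K-mers are strand-canonical (the lexicographically smaller of the k-mer and
#' its reverse complement is hashed; palindromic k-mers are skipped) and the
#' hash is a fixed, unseeded invertible integer mix, so output is fully
#' deterministic. K-mers covering non-ACGT characters are skipped.
#'
#' @param seq a single DNA string (character scalar).
#' @param k k-mer size (1-31).
#' @param w window size in k-mers (>= 1); `w = 1` selects every k-mer.
#' @return A data.frame with columns `hash` (16-hex-digit string), `pos`
#'   (0-based end coordinate of the k-mer) and `strand` (`"+"` when the
#'   forward k-mer is the canonical one), sorted by position.
#' @examples
#' extract_minimizers(strrep("A", 30), k = 15, w = 10)
#' @export
extract_minimizers <- function(seq, k = 15L, w = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  extract_minimizers_cpp(seq, as.integer(k), as.integer(w))
}

#' Build a minimizer hash index of a reference
#'
#' Indexes every record of the reference into a multimap from minimizer hash
#' to the list of (reference sequence, end position, strand) occurrences.
#' Multi-occurring minimizers keep all their positions. Optionally, the most
#' repetitive minimizers can be dropped with `max_occ` (off by default).
#'
#' @param reference a FASTA file path (optionally gzip-compressed), a named
#'   character vector of sequences, or a `Biostrings::DNAStringSet`.
#' @param params a [map_params()] object (uses `k` and `w`).
#' @param max_occ drop minimizers occurring more than this many times in the
#'   reference (`Inf` = keep all).
#' @return An object of class `minimizer_index`: the `k`/`w` used, the
#'   occurrence `table` (data.frame `hash`, `rid`, `pos`, `strand`; `rid` is
#'   the 0-based record index), record `names` and `lengths`, and an internal
#'   lookup environment.
#' @examples
#' idx <- build_index(c(chr = strrep("ACGTTGCA", 40)), map_params())
#' idx$lengths
#' @export
build_index <- function(reference, params = map_params(), max_occ = Inf) {
  seqs <- as_dna_characters(reference)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L))
    stop("cannot build index: reference has no non-empty records")
  per <- lapply(seq_along(seqs), function(i) {
    mm <- extract_minimizers(seqs[[i]], params$k, params$w)
    if (nrow(mm) > 0L) mm$rid <- i - 1L else mm$rid <- integer(0)
    mm
  })
  table <- do.call(rbind, per)[, c("hash", "rid", "pos", "strand")]
  rownames(table) <- NULL
  if (is.finite(max_occ)) {
    occ <- table(table$hash)
    keep <- table$hash %in% names(occ)[occ <= max_occ]
    table <- table[keep, , drop = FALSE]
    rownames(table) <- NULL
  }
  lookup <- new.env(parent = emptyenv(), size = max(16L, nrow(table)))
  if (nrow(table) > 0L)
    list2env(split(seq_len(nrow(table)), table$hash), envir = lookup)
  structure(list(k = params$k, w = params$w, table = table,
                 names = names(seqs),
                 lengths = vapply(seqs, nchar, integer(1), USE.NAMES = FALSE),
                 lookup = lookup),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat("minimizer_index: k=", x$k, " w=", x$w, "; ", length(x$names),
      " record(s), ", nrow(x$table), " minimizer occurrence(s), ",
      length(ls(x$lookup)), " distinct hash key(s)\n", sep = "")
  invisible(x)
}

#' Collect sorted anchors of one read against an index
#'
#' Queries every read minimizer against the reference index. Each hash match
#' yields one anchor of span `k`: when read and reference minimizers are on
#' the same strand the anchor joins the `+` group with query coordinate on the
#' read as sequenced; when they differ it joins the `-` group with the query
#' coordinate mapped onto the reverse-complemented read, so that chaining is
#' strand-agnostic. Anchors are grouped by (reference sequence, strand) and
#' each group is sorted by [sort_anchors()].
#'
#' @param index a [build_index()] result.
#' @param read a single DNA string.
#' @param read_id read name used in the returned sets.
#' @param params a [map_params()] object; `k` and `w` must match the index.
#' @return A list of [anchor_set()] objects, one per (rid, strand) group with
#'   at least one anchor; empty list when nothing matches (e.g. read shorter
#'   than `k`).
#' @export
collect_anchors <- function(index, read, read_id = "read",
                            params = map_params()) {
  stopifnot(inherits(index, "minimizer_index"))
  if (params$k != index$k || params$w != index$w)
    stop("params (k, w) do not match the index")
  L <- nchar(read)
  mm <- extract_minimizers(read, index$k, index$w)
  if (nrow(mm) == 0L) return(list())
  hit_rows <- lapply(mm$hash, function(h)
    if (exists(h, envir = index$lookup, inherits = FALSE))
      get(h, envir = index$lookup) else integer(0))
  nh <- lengths(hit_rows)
  if (sum(nh) == 0L) return(list())
  qi <- rep.int(seq_len(nrow(mm)), nh)
  ri <- unlist(hit_rows, use.names = FALSE)
  same <- mm$strand[qi] == index$table$strand[ri]
  x <- index$table$pos[ri]
  y <- ifelse(same, mm$pos[qi], L + index$k - 2L - mm$pos[qi])
  rid <- index$table$rid[ri]
  strand <- ifelse(same, "+", "-")
  key <- paste(rid, strand, sep = "/")
  groups <- split(seq_along(x), key)
  out <- lapply(groups, function(g)
    anchor_set(anchors(x[g], y[g], index$k), read_id = read_id,
               read_length = L, rid = rid[g[1L]], strand = strand[g[1L]]))
  names(out) <- NULL
  out[order(vapply(out, function(s) s$rid * 2L + (s$strand == "-"), numeric(1)))]
}

# Normalize FASTA path / DNAStringSet / character vector to named character.
as_dna_characters <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    ss <- tryCatch(Biostrings::readDNAStringSet(reference),
                   error = function(e)
                     stop("malformed or unreadable FASTA '", reference, "': ",
                          conditionMessage(e), call. = FALSE))
    seqs <- as.character(ss)   # zero records => empty vector (caller decides)
  } else if (is.character(reference)) {
    if (length(reference) == 1L && grepl("[^A-Za-z]", reference))
      stop("input file not found: '", reference, "'")  # path-like, not DNA
    seqs <- reference
  } else {
    stop("reference must be a FASTA path, character vector or DNAStringSet")
  }
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  # record ids up to first whitespace
  if (!is.null(names(seqs))) names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs
}
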