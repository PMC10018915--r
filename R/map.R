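#' Map reads against a reference: seed, chain, backtrack, classify, PAF
#'
#' The end-to-end pipeline: build (or reuse) a minimizer index of the
#' reference, bin reads by length, collect anchors per read, chain every
#' (reference, strand) anchor group with the selected engine, backtrack
#' chains, classify primary/secondary with mapping quality, and emit PAF
#' records. With `engine = "both"` every read is chained by BOTH engines and
#' the resulting PAF records are compared field by field; the first mismatch
#' aborts with a diff report naming the read — the differential mode used to
#' validate that the forward transform changes nothing.
#'
#' @param reference FASTA path (optionally gzipped), named character vector,
#'   `DNAStringSet`, or a prebuilt [build_index()] object.
#' @param reads FASTA path or named character vector of read sequences.
#' @param params a [map_params()] object.
#' @param engine `"forward"` (default), `"backward"`, or `"both"`.
#' @param compare with `engine = "both"`, compare `"primary"` records only
#'   (default) or `"all"` records including secondaries.
#' @param verbose print per-bin batch sizes and stage timings.
#' @return A PAF data.frame (see [read_paf()] for columns); zero rows when no
#'   read produces a chain. Residue matches are approximated as the summed
#'   anchor spans capped by the interval length; the block length is the
#'   larger of the two interval lengths.
#' @examples
#' ref <- c(chr1 = random_reference(20000, seed = 5))
#' reads <- c(r1 = substr(ref[[1]], 2001, 6000))
#' map_reads(ref, reads, engine = "both")[, c("qname", "tstart", "tend", "mapq")]
#' @export
map_reads <- function(reference, reads, params = map_params(),
                      engine = c("forward", "backward", "both"),
                      compare = c("primary", "all"), verbose = FALSE) {
  engine <- match.arg(engine)
  compare <- match.arg(compare)
  t0 <- proc.time()[["elapsed"]]
  index <- if (inherits(reference, "minimizer_index")) reference
           else build_index(reference, params)
  if (verbose)
    message(sprintf("index: %d keys [%.2fs]", length(ls(index$lookup)),
                    proc.time()[["elapsed"]] - t0))
  read_seqs <- as_dna_characters(reads)
  if (length(read_seqs) == 0L) return(empty_paf())
  batches <- bin_reads(data.frame(read_id = names(read_seqs),
                                  length = nchar(read_seqs)))
  out <- vector("list", length(read_seqs))
  oi <- 0L
  for (b in batches) {
    tb <- proc.time()[["elapsed"]]
    for (rn in b$read_id) {
      oi <- oi + 1L
      out[[oi]] <- map_one_read(index, read_seqs[[rn]], rn, params,
                                engine, compare)
    }
    if (verbose)
      message(sprintf("bin %s: %d read(s) [%.2fs]", b$bin,
                      length(b$read_id), proc.time()[["elapsed"]] - tb))
  }
  paf <- do.call(rbind, c(out[seq_len(oi)], list(empty_paf())))
  rownames(paf) <- NULL
  paf
}

map_one_read <- function(index, seq, read_id, params, engine, compare) {
  groups <- collect_anchors(index, seq, read_id, params)
  if (length(groups) == 0L) return(empty_paf())
  run <- function(eng) {
    chains <- do.call(rbind, lapply(groups, function(g) {
      state <- tryCatch(
        if (eng == "forward") chain_forward(g, params)
        else chain_backward(g, params),
        error = function(e)
          stop("chaining contract violation on read '", read_id, "': ",
               conditionMessage(e), call. = FALSE))
      backtrack(state, g, params)
    }))
    # query intervals of '-' groups are on the reverse-complemented read;
    # express them on the original orientation before overlap comparison
    L <- nchar(seq)
    neg <- chains$strand == "-"
    if (any(neg)) {
      qs <- L - chains$q_end[neg]
      qe <- L - chains$q_start[neg]
      chains$q_start[neg] <- qs
      chains$q_end[neg] <- qe
    }
    chains <- identify_primary(chains, params)
    paf_from_chains(chains, index, read_id, L)
  }
  if (engine != "both") return(run(engine))
  fwd <- run("forward")
  bwd <- run("backward")
  cf <- if (compare == "primary") fwd[fwd$tp, , drop = FALSE] else fwd
  cb <- if (compare == "primary") bwd[bwd$tp, , drop = FALSE] else bwd
  rownames(cf) <- rownames(cb) <- NULL
  if (!identical(cf, cb)) {
    stop("engine mismatch on read '", read_id, "':\nforward:\n",
         paste(utils::capture.output(print(cf)), collapse = "\n"),
         "\nbackward:\n",
         paste(utils::capture.output(print(cb)), collapse = "\n"),
         call. = FALSE)
  }
  fwd
}

paf_from_chains <- function(chains, index, read_id, read_len) {
  if (nrow(chains) == 0L) return(empty_paf())
  tlen <- index$lengths[chains$rid + 1L]
  qlen_i <- chains$q_end - chains$q_start
  rlen_i <- chains$r_end - chains$r_start
  data.frame(
    qname = read_id, qlen = read_len,
    qstart = chains$q_start, qend = chains$q_end,
    strand = chains$strand,
    tname = index$names[chains$rid + 1L], tlen = tlen,
    tstart = chains$r_start, tend = chains$r_end,
    nmatch = pmin(chains$sum_span, qlen_i, rlen_i),
    blocklen = pmax(qlen_i, rlen_i),
    mapq = chains$mapq, tp = chains$is_primary)
}

#' Chain anchors from a TSV file and report the result
#'
#' Direct access to the chaining stage for tests and debugging: reads anchor
#' sets from the [read_anchor_tsv()] dialect, chains each with the selected
#' engine, and prints `S`, `P`, `V` and the backtracked chains in a
#' deterministic text format (identical bytes for equivalent engines).
#'
#' @param path anchor TSV path.
#' @param params a [map_params()] object.
#' @param engine `"forward"` or `"backward"`.
#' @param quiet suppress printing.
#' @return Invisibly, a list per anchor set with `set`, `state` and `chains`.
#' @export
chain_file <- function(path, params = map_params(),
                       engine = c("forward", "backward"), quiet = FALSE) {
  engine <- match.arg(engine)
  sets <- read_anchor_tsv(path)
  res <- lapply(sets, function(s) {
    state <- if (engine == "forward") chain_forward(s, params)
             else chain_backward(s, params)
    chains <- backtrack(state, s, params)
    list(set = s, state = state, chains = chains)
  })
  if (!quiet) {
    for (r in res) {
      cat(">", r$set$read_id, " rid=", r$set$rid, " strand=", r$set$strand,
          " n=", r$state$n, "\n", sep = "")
      cat("S: ", paste(r$state$S, collapse = " "), "\n", sep = "")
      cat("P: ", paste(r$state$P, collapse = " "), "\n", sep = "")
      cat("V: ", paste(r$state$V, collapse = " "), "\n", sep = "")
      if (nrow(r$chains) > 0L) {
        for (ci in seq_len(nrow(r$chains))) {
          cat("chain ", ci, ": score=", r$chains$score[ci],
              " anchors=", paste(r$chains$anchor_indices[[ci]],
                                 collapse = ","), "\n", sep = "")
        }
      }
    }
  }
  invisible(res)
}
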