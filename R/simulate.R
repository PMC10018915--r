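#' Random DNA reference sequence
#'
#' Uniform i.i.d. bases; deterministic under `seed`.
#'
#' @param length sequence length in bases.
#' @param seed integer seed.
#' @return A single DNA string.
#' @export
random_reference <- function(length, seed = 1L) {
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Plant collinear anchor chains in uniform noise
#'
#' Generates `n_chains` collinear anchor runs — reference and query gaps close
#' to `gap_mean`, with the per-link gap difference drawn uniformly from
#' `[-gap_jitter, gap_jitter]` (kept below the chaining bandwidth so planted
#' links stay chainable) — plus `noise_anchors` anchors uniform over the
#' coordinate rectangle. Chains occupy disjoint query blocks so each should
#' come back as its own primary chain. The defaults emulate a read with two
#' true placements' worth of seed runs and 5x background noise, the regime the
#' chaining DP is designed for; they are not a calibrated fit to any real
#' dataset.
#'
#' @param n_chains number of planted chains.
#' @param chain_len anchors per planted chain.
#' @param gap_mean mean query gap between consecutive planted anchors (bases).
#' @param gap_jitter maximum absolute difference between the reference and
#'   query gaps of a planted link; must stay below `params$bandwidth`.
#' @param noise_anchors number of uniform background anchors.
#' @param read_length query length (bases); the planted chains must fit, else
#'   generation fails.
#' @param ref_length reference span (bases) over which reference coordinates
#'   are drawn. Spurious seed hits scatter over the whole indexed reference,
#'   which is orders of magnitude longer than a read; the genome-scale
#'   default keeps uniform noise as sparse in the reference dimension as real
#'   spurious anchors are.
#' @param seed integer seed (generation is a pure function of the arguments).
#' @param span anchor span `w` (defaults to the seeding k-mer size).
#' @param params a [map_params()] object (bandwidth feasibility check).
#' @return A list: `set` (an [anchor_set()]) and `truth`, a list of integer
#'   vectors giving each planted chain's anchor indices INTO THE SORTED set.
#' @examples
#' sim <- plant_chains(n_chains = 1, noise_anchors = 0, seed = 7)
#' length(sim$truth[[1]])
#' @export
plant_chains <- function(n_chains = 2L, chain_len = 25L, gap_mean = 100L,
                         gap_jitter = 20L, noise_anchors = 5L * n_chains * chain_len,
                         read_length = 12000L, ref_length = 1000000L,
                         seed = 1L, span = 15L, params = map_params()) {
  if (gap_jitter >= params$bandwidth)
    stop("gap_jitter must be smaller than the chaining bandwidth")
  if (gap_mean < 1L || chain_len < 1L || n_chains < 1L)
    stop("n_chains, chain_len and gap_mean must be >= 1")
  block <- read_length %/% n_chains
  need <- span + (chain_len - 1L) * (gap_mean + gap_jitter) + gap_jitter + 1L
  if (need > block)
    stop("planted chains do not fit the read: need ", need,
         " bases per chain but each query block has ", block)
  if (ref_length <= need + span)
    stop("ref_length too small for the planted chains")
  ref_span <- as.integer(ref_length)
  with_seed(seed, {
    px <- integer(0); py <- integer(0); pid <- integer(0)
    for (cc in seq_len(n_chains)) {
      dq <- gap_mean + sample(seq(-gap_jitter, gap_jitter), chain_len - 1L,
                              replace = TRUE)
      dd <- sample(seq(-gap_jitter, gap_jitter), chain_len - 1L, replace = TRUE)
      y0 <- (cc - 1L) * block + span - 1L +
        sample.int(block - need + 1L, 1L) - 1L
      x0 <- span - 1L + sample.int(ref_span - need, 1L)
      y <- as.integer(y0 + cumsum(c(0L, dq)))
      x <- as.integer(x0 + cumsum(c(0L, dq + dd)))
      px <- c(px, x); py <- c(py, y); pid <- c(pid, rep.int(cc, chain_len))
    }
    nx <- as.integer(span - 1L + floor(runif(noise_anchors) * (ref_span - span)))
    ny <- as.integer(span - 1L + floor(runif(noise_anchors) * (read_length - span)))
    x <- c(px, nx); y <- c(py, ny)
    id <- c(pid, rep.int(0L, noise_anchors))
    ord <- order(x, y, method = "radix")
    set <- anchor_set(anchors(x[ord], y[ord], span), read_id = "planted",
                      read_length = read_length)
    pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
    truth <- lapply(seq_len(n_chains), function(cc) sort(pos[which(id == cc)]))
    list(set = set, truth = truth)
  })
}

#' Simulate a read from a reference window
#'
#' Extracts `reference[start .. start+length-1]` (0-based start), applies
#' per-base substitutions and single-base insertions/deletions at the stated
#' rates, and reverse-complements the result for `strand = "-"` (so the read
#' is sequenced from the opposite strand). Deterministic under `seed`.
#'
#' @param reference a single DNA string.
#' @param start 0-based window start.
#' @param length window length; the window must lie within the reference.
#' @param sub_rate per-base substitution probability, in `[0, 0.3)`.
#' @param indel_rate per-base probability of a 1-base indel (insertion or
#'   deletion with equal probability), in `[0, 0.3)`.
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed.
#' @return A single DNA string.
#' @examples
#' ref <- random_reference(200, seed = 3)
#' simulate_read(ref, 50, 100, 0, 0, "+", seed = 1) == substr(ref, 51, 150)
#' @export
simulate_read <- function(reference, start, length, sub_rate = 0,
                          indel_rate = 0, strand = "+", seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 0.3 || indel_rate < 0 || indel_rate >= 0.3)
    stop("error rates must lie in [0, 0.3)")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  L <- nchar(reference)
  if (start < 0L || length < 1L || start + length > L)
    stop("window [", start, ", ", start + length, ") out of reference bounds")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    v <- strsplit(substr(reference, start + 1L, start + length), "")[[1L]]
    if (sub_rate > 0) {
      hit <- which(runif(length) < sub_rate)
      if (length(hit) > 0L) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- bases[(match(v[hit], bases) - 1L + shift) %% 4L + 1L]
      }
    }
    if (indel_rate > 0) {
      hit <- which(runif(length) < indel_rate)
      if (length(hit) > 0L) {
        ins <- runif(length(hit)) < 0.5
        pieces <- v
        pieces[hit[!ins]] <- ""                       # deletions
        pieces[hit[ins]] <- paste0(v[hit[ins]],       # insert after the base
                                   sample(bases, sum(ins), replace = TRUE))
        v <- strsplit(paste(pieces, collapse = ""), "")[[1L]]
      }
    }
    out <- paste(v, collapse = "")
    if (strand == "-") out <- revcomp(out)
    out
  })
}

#' Reverse complement of a DNA string
#' @param seq a single DNA string.
#' @return Its reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Sample read lengths from an ONT-like mixture
#'
#' A log-normal mixture clipped to `[500, 1e6]` bases. The default components
#' (weights 0.72/0.28, medians 3 kb and 18 kb) give a long-tailed distribution
#' with mean around 8.25 kb, emulating a typical nanopore WGS length profile;
#' all parameters are configurable.
#'
#' @param n number of reads.
#' @param weights mixture weights (sum to 1).
#' @param meanlog,sdlog log-normal parameters per component.
#' @param seed integer seed.
#' @return Integer vector of `n` lengths in `[500, 1e6]`.
#' @export
sample_read_lengths <- function(n, weights = c(0.72, 0.28),
                                meanlog = log(c(3000, 18000)),
                                sdlog = c(0.6, 0.5), seed = 1L) {
  stopifnot(n >= 0, length(weights) == length(meanlog),
            length(weights) == length(sdlog))
  if (n == 0L) return(integer(0))
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    len <- rlnorm(n, meanlog[comp], sdlog[comp])
    as.integer(pmin(1e6, pmax(500, round(len))))
  })
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
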