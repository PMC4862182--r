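# Mate realignment: best placement by highest
# alignment score, plus the total-matches (TM) count of near-best placements
# used as a mappability proxy (high TM = repetitive, low TM = unique).

#' Build a k-mer realignment index for a genome
#'
#' @param ref a `GenomeReference`.
#' @param k seed length (8-16; default 16).
#' @return a `RealignIndex` (keeps a handle to the genome).
#' @export
realign_index <- function(ref, k = 16L) {
  stopifnot(inherits(ref, "GenomeReference"))
  if (sum(as.numeric(ref$chrom_lengths)) == 0) stop("reference has zero length")
  ptr <- cpp_build_index(as.character(ref$seqs), ref$chrom_names, as.integer(k))
  obj <- list(ptr = ptr, ref = ref, k = as.integer(k))
  class(obj) <- "RealignIndex"
  obj
}

#' @export
print.RealignIndex <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("RealignIndex: k =", info$k, ",", format(info$n_kmers, big.mark = ","),
      "indexed positions\n")
  invisible(x)
}

as_realign_index <- function(x) {
  if (inherits(x, "RealignIndex")) return(x)
  if (inherits(x, "GenomeReference")) return(realign_index(x))
  stop("need a GenomeReference or RealignIndex")
}

#' Realign one mate sequence to the reference
#'
#' Seed-and-extend local alignment (match +1, mismatch -2, gap open -2,
#' gap extend -1) over both strands. A placement qualifies when at least
#' `min_aligned` query bases fall in aligned (match/mismatch) columns. The
#' best hit is the highest-scoring placement (ties broken by lexicographic
#' (chrom, start, strand), "+" preferred); TM counts placements scoring at
#' least `near_best_fraction` of the best.
#'
#' @param seq DNA string (length >= `min_aligned`).
#' @param index a `RealignIndex` (or `GenomeReference`, indexed on the fly).
#' @param min_aligned minimum aligned query bases (default 50).
#' @param near_best_fraction hits scoring >= this fraction of the best count
#'   toward TM (default 0.9).
#' @param tm_unique_threshold TM above this marks the mate repetitive
#'   (default 3).
#' @return `NULL` if no qualifying placement; otherwise a list with elements
#'   `best` (chrom, start, end, strand, score, aligned, identity), `tm`,
#'   `repetitive`, and `hits` (data.frame of all qualifying placements).
#' @export
realign_mate <- function(seq, index, min_aligned = 50L,
                         near_best_fraction = 0.9, tm_unique_threshold = 3L) {
  if (is.na(seq) || !nzchar(seq)) stop("empty query sequence")
  index <- as_realign_index(index)
  if (nchar(seq) < min_aligned) return(NULL)
  hits <- cpp_realign(index$ptr, seq, as.integer(min_aligned))
  if (!nrow(hits)) return(NULL)
  hits$identity <- hits$matches / pmax(hits$cols, 1L)
  best_score <- max(hits$score)
  tm <- sum(hits$score >= near_best_fraction * best_score)
  cand <- hits[hits$score == best_score, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start, cand$strand), , drop = FALSE]
  best <- cand[1, , drop = FALSE]
  list(best = list(chrom = best$chrom, start = best$start, end = best$end,
                   strand = best$strand, score = best$score,
                   aligned = best$aligned, identity = best$identity),
       tm = tm, repetitive = tm > tm_unique_threshold, hits = hits)
}

#' Realign all mate sequences of a set of discordant pairs
#'
#' Both ends of every pair are realigned (which end acts as the mate depends
#' on the candidate region a pair is later assigned to). Identical sequences
#' are aligned once.
#'
#' @param pairs data.frame from [extract_discordant()].
#' @param index a `RealignIndex` or `GenomeReference`.
#' @inheritParams realign_mate
#' @return data.frame keyed by (`qname`, `end_idx`) with the best placement
#'   and TM per realignable sequence; sequences without a qualifying
#'   placement are absent.
#' @export
batch_realign <- function(pairs, index, min_aligned = 50L,
                          near_best_fraction = 0.9, tm_unique_threshold = 3L) {
  index <- as_realign_index(index)
  if (!nrow(pairs)) return(empty_realignments())
  long <- data.frame(
    qname = rep(pairs$qname, 2L),
    end_idx = rep(c(1L, 2L), each = nrow(pairs)),
    seq = c(pairs$r1_seq, pairs$r2_seq),
    stringsAsFactors = FALSE)
  useq <- unique(long$seq)
  res <- lapply(useq, function(s) {
    r <- realign_mate(s, index, min_aligned, near_best_fraction, tm_unique_threshold)
    if (is.null(r)) return(NULL)
    data.frame(chrom = r$best$chrom, start = r$best$start, end = r$best$end,
               strand = r$best$strand, score = r$best$score,
               aligned = r$best$aligned, identity = r$best$identity,
               tm = r$tm, repetitive = r$repetitive, stringsAsFactors = FALSE)
  })
  names(res) <- useq
  keep <- !vapply(res, is.null, TRUE)
  if (!any(keep)) return(empty_realignments())
  tab <- do.call(rbind, res[keep])
  tab$seq <- useq[keep]
  out <- merge(long, tab, by = "seq")
  out <- out[order(out$qname, out$end_idx),
             c("qname", "end_idx", "chrom", "start", "end", "strand",
               "score", "aligned", "identity", "tm", "repetitive")]
  rownames(out) <- NULL
  out
}

empty_realignments <- function() {
  data.frame(qname = character(), end_idx = integer(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             score = integer(), aligned = integer(), identity = numeric(),
             tm = integer(), repetitive = logical(), stringsAsFactors = FALSE)
}

#' Exhaustive local-alignment scan of a query against one subject
#'
#' Full Smith-Waterman dynamic programming over the whole subject with
#' iterative best-hit masking -- a brute-force reference scanner, independent
#' of the seeded realignment path, kept for verification and debugging.
#'
#' @param query,subject DNA strings.
#' @param min_aligned minimum aligned query bases per reported hit.
#' @param keep_fraction stop once hit scores fall below this fraction of the
#'   first (best) hit.
#' @param max_hits cap on reported hits.
#' @return data.frame of hits with 0-based half-open subject coordinates.
#' @export
sw_scan <- function(query, subject, min_aligned = 1L, keep_fraction = 0.5,
                    max_hits = 64L) {
  cpp_sw_scan(toupper(query), toupper(subject), as.integer(min_aligned),
              keep_fraction, as.integer(max_hits))
}
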