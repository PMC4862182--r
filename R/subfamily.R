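# L1 subfamily analysis: contig assembly from event-supporting reads,
# best-mapping subfamily assignment against a consensus library, and
# Fisher-exact enrichment of subfamilies among transducing vs solo L1s.

# longest exact suffix(a)/prefix(b) overlap, length >= min_overlap
best_overlap <- function(a, b, min_overlap) {
  kmax <- min(nchar(a), nchar(b))
  for (k in seq(kmax, min_overlap)) {
    if (k < min_overlap) break
    if (substring(a, nchar(a) - k + 1L, nchar(a)) == substring(b, 1L, k))
      return(k)
  }
  0L
}

#' Assemble a contig from event-supporting reads
#'
#' Greedy maximum-overlap layout with exact-match overlaps of at least
#' `min_overlap` bases; reverse-complement orientations are considered. The
#' longest resulting sequence is returned. When no merge is possible, the
#' longest single read is returned as the contig, provided it spans at least
#' `2 * min_overlap` bases; otherwise `NULL`.
#'
#' @param reads character vector of >= 2 DNA strings.
#' @param min_overlap minimum exact overlap (default 20).
#' @return a `Contig` list (`seq`, `n_reads`) or `NULL`.
#' @export
assemble_contig <- function(reads, min_overlap = 20L) {
  stopifnot(length(reads) >= 2L)
  seqs <- toupper(reads)
  nmerged <- rep(1L, length(seqs))
  repeat {
    n <- length(seqs)
    best <- list(ov = 0L)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (orient in c("fwd", "rc")) {
        sj <- if (orient == "fwd") seqs[j] else revcomp(seqs[j])
        ov <- best_overlap(seqs[i], sj, min_overlap)
        if (ov > best$ov) best <- list(ov = ov, i = i, j = j, sj = sj)
      }
    }
    if (best$ov == 0L) break
    merged <- paste0(seqs[best$i], substring(best$sj, best$ov + 1L))
    cnt <- nmerged[best$i] + nmerged[best$j]
    seqs <- seqs[-c(best$i, best$j)]
    nmerged <- nmerged[-c(best$i, best$j)]
    seqs <- c(seqs, merged)
    nmerged <- c(nmerged, cnt)
    if (length(seqs) == 1L) break
  }
  k <- which.max(nchar(seqs))
  if (nmerged[k] == 1L && nchar(seqs[k]) < 2L * min_overlap) return(NULL)
  structure(list(seq = seqs[k], n_reads = nmerged[k]), class = "Contig")
}

local_score <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE, type = "DNA")
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1, scoreOnly = TRUE))
}

#' Assign the most probable L1 subfamily to a contig
#'
#' The contig is locally aligned to every consensus in the library (both
#' orientations); the subfamily with the highest alignment score -- i.e. the
#' fewest mismatches over the aligned span -- wins. Co-best subfamilies give
#' "ambiguous"; contigs shorter than 50 bp give "NA".
#'
#' @param contig a `Contig` (or plain DNA string).
#' @param library named character vector of consensus sequences.
#' @return list with `subfamily`, `score`, `margin` (best minus second-best).
#' @export
assign_subfamily <- function(contig, library) {
  if (!length(library)) stop("empty consensus library")
  seq <- if (inherits(contig, "Contig")) contig$seq else contig
  if (is.null(seq) || nchar(seq) < 50L)
    return(list(subfamily = "NA", score = NA_real_, margin = NA_real_))
  rc <- revcomp(seq)
  scores <- vapply(library, function(cons)
    max(local_score(seq, cons), local_score(rc, cons)), 0)
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]
  second <- if (length(scores) >= 2) scores[ord[2]] else -Inf
  margin <- best - max(second, 0)
  if (length(scores) >= 2 && best == second)
    return(list(subfamily = "ambiguous", score = best, margin = 0))
  list(subfamily = names(scores)[ord[1]], score = unname(best),
       margin = unname(best - second))
}

#' Subfamily enrichment among transducing vs solo L1s
#'
#' For each subfamily observed in either group, builds the 2x2 contingency
#' table (is-subfamily vs not, transducing vs solo) and computes the sample
#' odds ratio and the two-sided Fisher exact p-value (minimum-likelihood
#' convention). Ambiguous/NA assignments are excluded.
#'
#' @param transducing,solo character vectors of subfamily assignments (or
#'   lists/data.frames with a `subfamily` element).
#' @return data.frame with columns `subfamily`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value` (a = transducing with subfamily, b =
#'   transducing without, c = solo with, d = solo without).
#' @export
subfamily_enrichment <- function(transducing, solo) {
  getsub <- function(x) {
    if (is.data.frame(x)) x <- x$subfamily
    if (is.list(x)) x <- vapply(x, function(e)
      if (is.list(e)) e$subfamily else as.character(e), "")
    x <- as.character(x)
    x[!is.na(x) & !x %in% c("ambiguous", "NA")]
  }
  td <- getsub(transducing); so <- getsub(solo)
  if (!length(td) || !length(so))
    stop("both groups must contain assigned subfamilies")
  out <- lapply(sort(unique(c(td, so))), function(sf) {
    a <- sum(td == sf); b <- sum(td != sf)
    c_ <- sum(so == sf); d <- sum(so != sf)
    if (a + c_ == 0) return(NULL) # absent from both groups
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c_)
    data.frame(subfamily = sf, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the L1-side reads of a candidate region
#'
#' Reads supporting the inserted L1 body (rather than the unique transduced
#' sequence) are the region's mates that either found no unique placement in
#' the reference or realigned repetitively (TM above the uniqueness
#' threshold). These feed contig assembly for subfamily assignment.
#'
#' @param region a `CandidateRegion`.
#' @param realignments data.frame from [batch_realign()].
#' @param tm_unique_threshold mates with TM above this are treated as
#'   repetitive (default 3).
#' @return character vector of read sequences.
#' @export
l1_side_reads <- function(region, realignments, tm_unique_threshold = 3L) {
  if (!nrow(region$pairs)) return(character(0))
  seqs <- ifelse(region$pairs$mate_end == 1L, region$pairs$r1_seq,
                 region$pairs$r2_seq)
  key <- paste(region$pairs$qname, region$pairs$mate_end)
  idx <- match(key, paste(realignments$qname, realignments$end_idx))
  unplaced <- is.na(idx)
  repet <- !unplaced & realignments$tm[idx] > tm_unique_threshold
  unique(seqs[unplaced | repet])
}

#' Annotate calls with their most probable L1 subfamily
#'
#' For each call, assembles a contig from the region's L1-side reads (see
#' [l1_side_reads()]) and assigns the best-mapping subfamily from the
#' consensus library; calls without enough L1-side evidence keep "NA".
#'
#' @param calls data.frame from [call_transductions()].
#' @param regions list from [build_candidate_regions()] (the same ones the
#'   calls were made from).
#' @param realignments data.frame from [batch_realign()].
#' @param library named consensus library.
#' @param min_overlap contig assembly overlap (default 20).
#' @return `calls` with the `subfamily` column filled in.
#' @export
annotate_subfamilies <- function(calls, regions, realignments, library,
                                 min_overlap = 20L) {
  if (!nrow(calls)) return(calls)
  mei_ids <- vapply(regions, function(r) r$mei$mei_id %||% NA_character_, "")
  for (i in seq_len(nrow(calls))) {
    region <- regions[[match(calls$mei_id[i], mei_ids)]]
    reads <- l1_side_reads(region, realignments)
    if (length(reads) < 2L) next
    contig <- assemble_contig(reads, min_overlap = min_overlap)
    if (is.null(contig)) next
    calls$subfamily[i] <- assign_subfamily(contig, library)$subfamily
  }
  calls
}
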