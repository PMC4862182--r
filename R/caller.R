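# The caller core: candidate regions around MEI calls, clustering of
# realigned mates into transduction source loci, hallmark detection,
# filtering, donor classification and cross-sample merging.

#' Default caller configuration
#'
#' Numeric defaults mirror the method's published operating point: +/-500 bp
#' candidate windows, >=50 aligned bases per realigned mate, source clusters
#' of 4-30 reads with mean TM <= 3, >=50 bp of transduced sequence, polyA
#' runs of >=6 non-reference A/T, 5 kb donor-classification flanks and a
#' 100 bp cross-sample merge distance.
#'
#' @param ... overrides for individual fields.
#' @return named list of configuration values.
#' @export
caller_config <- function(...) {
  cfg <- list(window = 500L, min_realign_len = 50L, min_reads = 4L,
              max_reads = 30L, max_mean_tm = 3.0, min_overlap = 1L,
              min_ts_length = 50L, polya_k = 6L, donor_flank = 5000L,
              merge_distance = 100L, reciprocal_overlap = 0.5,
              min_anchor_mapq = 20L, near_best_fraction = 0.9,
              tm_unique_threshold = 3L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$min_reads < 1L) stop("min_reads must be >= 1")
  if (cfg$max_reads < cfg$min_reads) stop("max_reads must be >= min_reads")
  if (cfg$window < 0L || cfg$min_ts_length < 1L || cfg$polya_k < 1L)
    stop("invalid configuration value")
  invisible(cfg)
}

#' Build candidate regions around MEI calls
#'
#' Each MEI insertion interval is widened by `window` bp on both sides
#' (clamped to the chromosome) to form the search interval; a discordant pair
#' is collected by a region when one of its confidently mapped ends (the
#' anchor for that region) overlaps the search interval. The other end of the
#' pair is the region's mate. Regions without any support are retained and
#' marked empty.
#'
#' @param meis data.frame from [read_mei_calls()].
#' @param pairs data.frame from [extract_discordant()].
#' @param window extension in bp (default 500).
#' @param chrom_lengths named integer vector used for clamping (optional).
#' @param min_anchor_mapq anchor mapping-quality floor (default 20).
#' @return list of `CandidateRegion` lists with fields `mei`, `chrom`,
#'   `search_start`, `search_end`, and `pairs` (collected pairs with a
#'   `mate_end` column naming the non-anchor end).
#' @export
build_candidate_regions <- function(meis, pairs, window = 500L,
                                    chrom_lengths = NULL,
                                    min_anchor_mapq = 20L) {
  regions <- vector("list", nrow(meis))
  for (i in seq_len(nrow(meis))) {
    mei <- meis[i, ]
    s <- max(0L, mei$start - window)
    e <- mei$end + window
    if (!is.null(chrom_lengths) && mei$chrom %in% names(chrom_lengths))
      e <- min(e, chrom_lengths[[mei$chrom]])
    sel <- integer(0); mate_end <- integer(0)
    if (nrow(pairs)) {
      ok1 <- !is.na(pairs$r1_chrom) & pairs$r1_mapped &
        pairs$r1_mapq >= min_anchor_mapq & pairs$r1_chrom == mei$chrom &
        pairs$r1_start < e & pairs$r1_end > s
      ok2 <- !is.na(pairs$r2_chrom) & pairs$r2_mapped &
        pairs$r2_mapq >= min_anchor_mapq & pairs$r2_chrom == mei$chrom &
        pairs$r2_start < e & pairs$r2_end > s
      sel <- which(ok1 | ok2)
      # anchor preference: an end overlapping the region; if both do, the
      # higher-mapq end anchors and the other is the mate
      mate_end <- ifelse(ok1[sel] & ok2[sel],
                         ifelse(pairs$r1_mapq[sel] >= pairs$r2_mapq[sel], 2L, 1L),
                         ifelse(ok1[sel], 2L, 1L))
    }
    rp <- pairs[sel, , drop = FALSE]
    rp$mate_end <- mate_end
    regions[[i]] <- structure(
      list(mei = mei, chrom = mei$chrom, search_start = s, search_end = as.integer(e),
           pairs = rp, empty = nrow(rp) == 0L),
      class = "CandidateRegion")
  }
  regions
}

#' @export
print.CandidateRegion <- function(x, ...) {
  cat(sprintf("CandidateRegion %s:%d-%d (%d pair(s): %d TL, %d SA)\n",
              x$chrom, x$search_start, x$search_end, nrow(x$pairs),
              sum(x$pairs$category == "TL"), sum(x$pairs$category == "SA")))
  invisible(x)
}

# realignment rows for the mate ends of a region's pairs
region_mate_realignments <- function(region, realignments) {
  if (!nrow(region$pairs) || !nrow(realignments)) return(empty_realignments())
  key <- paste(region$pairs$qname, region$pairs$mate_end)
  idx <- match(key, paste(realignments$qname, realignments$end_idx))
  out <- realignments[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster realigned mates into transduction source loci
#'
#' Mates are partitioned by source chromosome and chained by interval overlap
#' (single linkage, overlap >= `min_overlap` bp, no gaps). A chain survives if
#' it has `min_reads`-`max_reads` members and mean TM <= `max_mean_tm`; chains
#' exceeding `max_reads` flag the region as a repetitive source (solo mobile
#' element or collapsed duplication signature). Realignment hits overlapping
#' the region's own search interval are excluded from source inference. The
#' reconstructed transduced sequence is the reference substring of the
#' chained interval.
#'
#' @param region a `CandidateRegion`.
#' @param realignments data.frame from [batch_realign()].
#' @param min_reads,max_reads cluster size bounds (default 4 and 30,
#'   inclusive).
#' @param max_mean_tm mean total-matches ceiling (default 3.0, inclusive).
#' @param min_overlap minimum chaining overlap in bp (default 1).
#' @param ref optional `GenomeReference` for sequence reconstruction.
#' @return list with `clusters` (list of SourceCluster lists) and
#'   `repetitive_source` (logical region flag).
#' @export
cluster_sources <- function(region, realignments, min_reads = 4L,
                            max_reads = 30L, max_mean_tm = 3.0,
                            min_overlap = 1L, ref = NULL) {
  mates <- region_mate_realignments(region, realignments)
  out <- list(clusters = list(), repetitive_source = FALSE)
  if (!nrow(mates)) return(out)
  self <- mates$chrom == region$chrom &
    mates$start < region$search_end & mates$end > region$search_start
  mates <- mates[!self, , drop = FALSE]
  if (!nrow(mates)) return(out)
  for (chr in unique(mates$chrom)) {
    m <- mates[mates$chrom == chr, , drop = FALSE]
    m <- m[order(m$start, m$end), , drop = FALSE]
    chain_id <- integer(nrow(m))
    cid <- 1L; chain_end <- m$end[1]; chain_id[1] <- 1L
    for (j in seq_len(nrow(m))[-1]) {
      if (m$start[j] <= chain_end - min_overlap) {
        chain_id[j] <- cid
        chain_end <- max(chain_end, m$end[j])
      } else {
        cid <- cid + 1L
        chain_id[j] <- cid
        chain_end <- m$end[j]
      }
    }
    for (cc in split(m, chain_id)) {
      n <- nrow(cc)
      if (n > max_reads) { out$repetitive_source <- TRUE; next }
      if (n < min_reads) next
      mtm <- mean(cc$tm)
      if (mtm > max_mean_tm) next
      s <- min(cc$start); e <- max(cc$end)
      seq <- if (!is.null(ref)) get_seq(ref, chr, s, e) else NA_character_
      strand <- names(sort(table(cc$strand), decreasing = TRUE))[1]
      out$clusters <- c(out$clusters, list(list(
        chrom = chr, start = s, end = e, n_members = n, mean_tm = mtm,
        members = cc, seq = seq, strand = strand)))
    }
  }
  # deterministic cluster order
  if (length(out$clusters) > 1L) {
    ord <- order(vapply(out$clusters, `[[`, "", "chrom"),
                 vapply(out$clusters, `[[`, 1L, "start"))
    out$clusters <- out$clusters[ord]
  }
  out
}

#' Count mates with a non-reference polyA/polyT run in a region
#'
#' A mate is counted when it contains a run of at least `k` consecutive A (or
#' T) bases that is non-reference: the mate is unmapped (or placed with mapq
#' 0), or the run does not match a homopolymer at the corresponding mapped
#' reference position.
#'
#' @param region a `CandidateRegion`.
#' @param ref a `GenomeReference`.
#' @param k minimum run length (default 6, i.e. AAAAAA/TTTTTT).
#' @return integer count of polyA-supporting mates.
#' @export
detect_polyA <- function(region, ref, k = 6L) {
  if (!nrow(region$pairs)) return(0L)
  n <- 0L
  for (i in seq_len(nrow(region$pairs))) {
    p <- region$pairs[i, ]
    me <- p$mate_end
    seqv <- if (me == 1L) p$r1_seq else p$r2_seq
    mapped <- if (me == 1L) p$r1_mapped else p$r2_mapped
    mapq <- if (me == 1L) p$r1_mapq else p$r2_mapq
    mchrom <- if (me == 1L) p$r1_chrom else p$r2_chrom
    mstart <- if (me == 1L) p$r1_start else p$r2_start
    ra <- homopolymer_runs(seqv, "A", k)
    rt <- homopolymer_runs(seqv, "T", k)
    ra$base <- rep("A", nrow(ra)); rt$base <- rep("T", nrow(rt))
    runs <- rbind(ra, rt)
    if (!nrow(runs)) next
    if (!mapped || mapq == 0L || is.na(mchrom)) { n <- n + 1L; next }
    nonref <- FALSE
    clen <- ref$chrom_lengths[[mchrom]]
    for (j in seq_len(nrow(runs))) {
      rs <- mstart + runs$start[j]; re <- mstart + runs$end[j]
      if (rs < 0 || re > clen) { nonref <- TRUE; break }
      refsub <- strsplit(get_seq(ref, mchrom, rs, re), "")[[1]]
      if (sum(refsub == runs$base[j]) < k) { nonref <- TRUE; break }
    }
    if (nonref) n <- n + 1L
  }
  n
}

#' Filter a transduction call
#'
#' Adds `SEGDUP` when the target search interval overlaps a segmental
#' duplication, `REF_L1_AT_TARGET` when it overlaps an annotated reference
#' repeat of the L1 family, and `SHORT_TS` when the reconstructed transduced
#' sequence is shorter than `min_ts_length` (short-read data cannot reliably
#' support transductions below ~50-60 bp). A call passes iff no flag is set.
#'
#' @param call a one-row call data.frame (see [call_transductions()]).
#' @param segdups a `SegDupTrack` (or NULL).
#' @param repeats a `RepeatAnnotation` (or NULL).
#' @param min_ts_length minimum transduced-sequence length (default 50).
#' @return the call with updated `filters` and `pass` fields.
#' @export
apply_filters <- function(call, segdups = NULL, repeats = NULL,
                          min_ts_length = 50L) {
  flags <- character(0)
  existing <- call$filters
  if (length(existing) == 1 && !is.na(existing) && nzchar(existing))
    flags <- strsplit(existing, ",", fixed = TRUE)[[1]]
  ss <- call$search_start; se <- call$search_end
  if (!is.null(segdups) &&
      nrow(overlap_query(segdups, call$target_chrom, ss, se)))
    flags <- union(flags, "SEGDUP")
  if (!is.null(repeats) &&
      nrow(overlap_query(repeats, call$target_chrom, ss, se, family_prefix = "L1")))
    flags <- union(flags, "REF_L1_AT_TARGET")
  if (call$ts_len < min_ts_length)
    flags <- union(flags, "SHORT_TS")
  call$filters <- paste(sort(flags), collapse = ",")
  call$pass <- !nzchar(call$filters)
  call
}

#' Classify the donor context of a transduction source
#'
#' Class 2 when an annotated L1-family repeat lies within `flank` bp of the
#' transduced source interval (truncated donor elements surround the source);
#' class 1 otherwise (no donor L1 annotated nearby -- the donor segregates
#' separately in the population).
#'
#' @param call a one-row call data.frame.
#' @param repeats a `RepeatAnnotation` (or NULL, giving class 1).
#' @param flank bp to either side (default 5000).
#' @return integer 1 or 2.
#' @export
classify_donor <- function(call, repeats = NULL, flank = 5000L) {
  if (is.null(repeats)) return(1L)
  hit <- overlap_query(repeats, call$source_chrom,
                       max(0L, call$source_start - flank),
                       call$source_end + flank, family_prefix = "L1")
  if (nrow(hit)) 2L else 1L
}

#' Call L1-mediated 3' transductions
#'
#' Joins candidate regions with surviving source clusters into transduction
#' calls: one call per (region, cluster), annotated with the TSD carried over
#' from the MEI annotation, the polyA-supporting read count, donor class and
#' filter flags, ordered deterministically by (target chrom, target start,
#' source chrom, source start).
#'
#' @param regions list from [build_candidate_regions()].
#' @param realignments data.frame from [batch_realign()].
#' @param ref a `GenomeReference`.
#' @param segdups a `SegDupTrack` or NULL.
#' @param repeats a `RepeatAnnotation` or NULL.
#' @param config list from [caller_config()].
#' @return data.frame with one row per call.
#' @export
call_transductions <- function(regions, realignments, ref, segdups = NULL,
                               repeats = NULL, config = caller_config()) {
  calls <- list()
  for (region in regions) {
    if (region$empty) next
    cl <- cluster_sources(region, realignments,
                          min_reads = config$min_reads,
                          max_reads = config$max_reads,
                          max_mean_tm = config$max_mean_tm,
                          min_overlap = config$min_overlap, ref = ref)
    if (!length(cl$clusters)) next
    polya <- detect_polyA(region, ref, k = config$polya_k)
    mei <- region$mei
    for (sc in cl$clusters) {
      call <- data.frame(
        id = NA_character_,
        sample = mei$sample,
        mei_id = mei$mei_id %||% NA_character_,
        target_chrom = region$chrom,
        target_start = mei$start, target_end = mei$end,
        search_start = region$search_start, search_end = region$search_end,
        tsd_seq = mei$tsd_seq %||% NA_character_,
        source_chrom = sc$chrom, source_start = sc$start,
        source_end = sc$end, source_strand = sc$strand,
        ts_len = sc$end - sc$start, ts_seq = sc$seq,
        polya_reads = polya, subfamily = NA_character_,
        n_reads = sc$n_members, mean_tm = sc$mean_tm,
        donor_class = NA_integer_,
        filters = if (cl$repetitive_source) "REPETITIVE_SOURCE" else "",
        pass = NA, stringsAsFactors = FALSE)
      call$donor_class <- classify_donor(call, repeats, flank = config$donor_flank)
      call <- apply_filters(call, segdups, repeats,
                            min_ts_length = config$min_ts_length)
      calls <- c(calls, list(call))
    }
  }
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  out <- out[order(out$target_chrom, out$target_start, out$source_chrom,
                   out$source_start), , drop = FALSE]
  out$id <- sprintf("td%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(id = character(), sample = character(), mei_id = character(),
             target_chrom = character(), target_start = integer(),
             target_end = integer(), search_start = integer(),
             search_end = integer(), tsd_seq = character(),
             source_chrom = character(), source_start = integer(),
             source_end = integer(), source_strand = character(),
             ts_len = integer(), ts_seq = character(), polya_reads = integer(),
             subfamily = character(), n_reads = integer(), mean_tm = numeric(),
             donor_class = integer(), filters = character(), pass = logical(),
             stringsAsFactors = FALSE)
}

# insertion point: midpoint of the target interval
insertion_point <- function(calls) {
  as.integer(floor((calls$target_start + calls$target_end) / 2))
}

#' Merge transduction calls across samples
#'
#' Calls merge when their target insertion points lie within
#' `merge_distance` bp on the same chromosome and their source intervals
#' reciprocally overlap by at least `reciprocal_overlap`. A merged call is
#' polymorphic when it is absent from at least one sample of the cohort.
#'
#' @param calls data.frame of calls (typically PASS calls pooled over the
#'   samples of one species).
#' @param merge_distance target-point distance in bp (default 100).
#' @param reciprocal_overlap minimum reciprocal source overlap (default 0.5).
#' @param cohort character vector of all sample ids in the species cohort
#'   (default: samples observed in `calls`).
#' @return data.frame with one row per merged event: representative
#'   coordinates, `samples` (comma list), `n_samples`, `polymorphic`.
#' @export
merge_across_samples <- function(calls, merge_distance = 100L,
                                 reciprocal_overlap = 0.5, cohort = NULL) {
  if (is.null(cohort)) cohort <- unique(calls$sample)
  if (!nrow(calls)) {
    out <- calls
    out$samples <- character(0); out$n_samples <- integer(0)
    out$polymorphic <- logical(0)
    return(out)
  }
  calls <- calls[order(calls$target_chrom, insertion_point(calls)), , drop = FALSE]
  pts <- insertion_point(calls)
  group <- integer(nrow(calls))
  reps <- list() # per group: point, source interval
  gid <- 0L
  for (i in seq_len(nrow(calls))) {
    assigned <- FALSE
    for (g in rev(seq_len(gid))) {
      r <- reps[[g]]
      if (r$chrom != calls$target_chrom[i]) next
      if (abs(pts[i] - r$point) > merge_distance) break
      ov <- min(r$src_end, calls$source_end[i]) -
        max(r$src_start, calls$source_start[i])
      len1 <- r$src_end - r$src_start
      len2 <- calls$source_end[i] - calls$source_start[i]
      if (r$src_chrom == calls$source_chrom[i] && ov > 0 &&
          ov >= reciprocal_overlap * len1 && ov >= reciprocal_overlap * len2) {
        group[i] <- g; assigned <- TRUE
        reps[[g]]$point <- pts[i] # single linkage: chain from the nearest member
        break
      }
    }
    if (!assigned) {
      gid <- gid + 1L
      group[i] <- gid
      reps[[gid]] <- list(chrom = calls$target_chrom[i], point = pts[i],
                          src_chrom = calls$source_chrom[i],
                          src_start = calls$source_start[i],
                          src_end = calls$source_end[i])
    }
  }
  merged <- lapply(split(seq_len(nrow(calls)), group), function(idx) {
    sub <- calls[idx, , drop = FALSE]
    rep <- sub[1, , drop = FALSE]
    rep$samples <- paste(sort(unique(sub$sample)), collapse = ",")
    rep$n_samples <- length(unique(sub$sample))
    rep$polymorphic <- rep$n_samples < length(cohort)
    rep
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$target_chrom, insertion_point(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
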