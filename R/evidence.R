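# Evidence extraction: MEI calls from an upstream caller, and TL/SA
# discordant read pairs from a coordinate-sorted BAM.

#' Read non-reference MEI calls (upstream MEI caller TSV dialect)
#'
#' The expected dialect is a tab-separated file with a header line and columns
#' `sample`, `chrom`, `start`, `end`, `family`, `tier` and optionally
#' `tsd_seq`, `polya`, `strand`. Coordinates are 0-based half-open and denote
#' the insertion breakpoint locus (for point insertions, the TSD interval),
#' not the whole element; intervals longer than 1000 bp are rejected. Both
#' confidence tiers ("high" and "low") are retained: lower-confidence
#' candidates increase sensitivity and are vetted downstream by the caller's
#' own clustering and filtering.
#'
#' @param path input TSV.
#' @param family_filter keep only calls with this family label (default "L1").
#' @return data.frame of MEI calls with a logical `canonical_tsd` column
#'   (TSD present with length 4-25 bp).
#' @export
read_mei_calls <- function(path, family_filter = "L1") {
  if (!file.exists(path)) stop("MEI file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse MEI file ", path, ": ", conditionMessage(e)))
  need <- c("sample", "chrom", "start", "end", "family", "tier")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MEI file lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$tsd_seq)) df$tsd_seq <- NA_character_
  if (is.null(df$polya)) df$polya <- NA
  if (is.null(df$strand)) df$strand <- NA_character_
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ok <- !is.na(row$start) && !is.na(row$end) && row$start >= 0 &&
      row$end >= row$start && (row$end - row$start) <= 1000 &&
      row$tier %in% c("high", "low") && nzchar(row$chrom)
    if (ok && !is.na(row$tsd_seq) && nzchar(row$tsd_seq))
      ok <- nchar(row$tsd_seq) >= 1 && nchar(row$tsd_seq) <= 50
    if (!ok) stop("malformed MEI row ", i, " in ", path)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df <- df[df$family == family_filter, , drop = FALSE]
  if (!nrow(df)) warning("no MEI calls with family '", family_filter, "' in ", path)
  tsd_len <- ifelse(is.na(df$tsd_seq) | !nzchar(df$tsd_seq), NA_integer_,
                    nchar(df$tsd_seq))
  df$canonical_tsd <- !is.na(tsd_len) & tsd_len >= 4 & tsd_len <= 25
  df$mei_id <- sprintf("mei%05d", seq_len(max(nrow(df), 0L)))
  rownames(df) <- NULL
  df
}

# reference-consumed width of a CIGAR string (M/D/N/=/X ops)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- gregexpr("([0-9]+)([MIDNSHP=X])", cg)[[1]]
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
    kinds <- sub("[0-9]+", "", ops)
    sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

#' Extract TL/SA discordant read pairs from a BAM file
#'
#' Scans primary alignments (duplicates, QC failures, secondary and
#' supplementary records skipped) and emits one row per qualifying pair:
#' \describe{
#'   \item{TL}{both reads mapped, on different chromosomes ("translocation"
#'     signature of a distal duplicative insertion);}
#'   \item{SA}{one read unmapped, or placed with mapping quality 0 (the
#'     standard encoding of an ambiguous, effectively random placement).}
#' }
#' Concordant pairs and same-chromosome distant pairs are not emitted (distant
#' same-chromosome sources are recovered through SA-mate realignment instead).
#' The anchor end -- the confidently placed read that defines the target
#' locus -- must have mapping quality >= `min_anchor_mapq`.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param min_mate_seq minimum mate sequence length (default 30).
#' @param min_anchor_mapq minimum anchor mapping quality (default 20).
#' @return data.frame with one row per pair: per-end placement columns
#'   (`r1_*`, `r2_*`, 0-based half-open), `category` ("TL"/"SA") and `anchor`
#'   (1 or 2, the end with the better anchor; for TL pairs either mapped end
#'   may serve as the region anchor downstream).
#' @export
extract_discordant <- function(bam, min_mate_seq = 30L, min_anchor_mapq = 20L) {
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam)
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isNotPassingQualityControls = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(flag = flag, what = what))[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_pairs())
  dt <- data.table::data.table(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    start = as.integer(res$pos) - 1L,
    mapq = as.integer(res$mapq),
    strand = as.character(res$strand),
    seq = as.character(res$seq),
    cigar = as.character(res$cigar))
  dt[, `:=`(mapped = bitwAnd(flag, 4L) == 0L,
            first = bitwAnd(flag, 64L) > 0L)]
  dt[mapped == FALSE, `:=`(chrom = NA_character_, start = NA_integer_, mapq = 0L)]
  w <- cigar_ref_width(dt$cigar)
  dt[, end := ifelse(mapped, start + ifelse(is.na(w), nchar(seq), w), NA_integer_)]
  # pair up primary records by read name
  dt <- dt[order(qname, -first)]
  cnt <- dt[, .N, by = qname]
  keep <- cnt[N == 2L, qname]
  dt <- dt[qname %in% keep]
  if (!nrow(dt)) return(empty_pairs())
  r1 <- dt[seq(1L, .N, by = 2L)]
  r2 <- dt[seq(2L, .N, by = 2L)]
  stopifnot(all(r1$qname == r2$qname))
  pairs <- data.table::data.table(
    qname = r1$qname,
    r1_chrom = r1$chrom, r1_start = r1$start, r1_end = r1$end,
    r1_strand = r1$strand, r1_mapq = r1$mapq, r1_mapped = r1$mapped,
    r1_seq = r1$seq,
    r2_chrom = r2$chrom, r2_start = r2$start, r2_end = r2$end,
    r2_strand = r2$strand, r2_mapq = r2$mapq, r2_mapped = r2$mapped,
    r2_seq = r2$seq)
  n_mapped <- pairs$r1_mapped + pairs$r2_mapped
  ambiguous <- (pairs$r1_mapped & pairs$r1_mapq == 0L) |
    (pairs$r2_mapped & pairs$r2_mapq == 0L)
  category <- rep(NA_character_, nrow(pairs))
  category[n_mapped == 1L] <- "SA"
  category[n_mapped == 2L & ambiguous] <- "SA"
  diff_chrom <- n_mapped == 2L & !ambiguous & pairs$r1_chrom != pairs$r2_chrom
  category[diff_chrom] <- "TL"
  pairs$category <- category
  pairs <- pairs[!is.na(category)]
  if (!nrow(pairs)) return(empty_pairs())
  # anchor = the better-placed end; it must clear the anchor mapq threshold
  a1 <- ifelse(pairs$r1_mapped, pairs$r1_mapq, -1L)
  a2 <- ifelse(pairs$r2_mapped, pairs$r2_mapq, -1L)
  pairs$anchor <- ifelse(a1 >= a2, 1L, 2L)
  best_mapq <- pmax(a1, a2)
  pairs <- pairs[best_mapq >= min_anchor_mapq]
  if (!nrow(pairs)) return(empty_pairs())
  mate_seq <- ifelse(pairs$anchor == 1L, pairs$r2_seq, pairs$r1_seq)
  pairs <- pairs[nchar(mate_seq) >= min_mate_seq]
  pairs <- pairs[order(qname)]
  out <- as.data.frame(pairs)
  attr(out, "min_anchor_mapq") <- min_anchor_mapq
  out
}

empty_pairs <- function() {
  out <- data.frame(
    qname = character(), r1_chrom = character(), r1_start = integer(),
    r1_end = integer(), r1_strand = character(), r1_mapq = integer(),
    r1_mapped = logical(), r1_seq = character(), r2_chrom = character(),
    r2_start = integer(), r2_end = integer(), r2_strand = character(),
    r2_mapq = integer(), r2_mapped = logical(), r2_seq = character(),
    category = character(), anchor = integer(), stringsAsFactors = FALSE)
  attr(out, "min_anchor_mapq") <- 20L
  out
}
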