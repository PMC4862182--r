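#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a `GenomeReference` object. Sequences are
#' uppercased; IUPAC ambiguity codes are preserved. All coordinates used by
#' this package are 0-based half-open.
#'
#' @param path path to a FASTA file.
#' @return A `GenomeReference` object with elements `seqs` (DNAStringSet),
#'   `chrom_names`, and `chrom_lengths` (named integer vector).
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence in FASTA")
  names(seqs) <- nm
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  obj <- list(seqs = seqs, chrom_names = nm,
              chrom_lengths = stats::setNames(Biostrings::width(seqs), nm))
  class(obj) <- "GenomeReference"
  obj
}

#' Build a GenomeReference from in-memory sequences
#'
#' @param seqs named character vector or DNAStringSet.
#' @return a `GenomeReference`.
#' @export
genome_reference <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm)) stop("sequences must have unique names")
  obj <- list(seqs = Biostrings::DNAStringSet(toupper(seqs)), chrom_names = nm,
              chrom_lengths = stats::setNames(Biostrings::width(seqs), nm))
  class(obj) <- "GenomeReference"
  obj
}

#' @export
print.GenomeReference <- function(x, ...) {
  cat("GenomeReference:", length(x$chrom_names), "sequence(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Extract reference sequence
#'
#' @param ref a `GenomeReference`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval; `start == end` returns `""`.
#' @return uppercase DNA string of length `end - start`.
#' @export
get_seq <- function(ref, chrom, start, end) {
  stopifnot(inherits(ref, "GenomeReference"))
  if (!chrom %in% ref$chrom_names) stop("unknown chromosome: ", chrom)
  len <- ref$chrom_lengths[[chrom]]
  if (start < 0 || end > len || start > end)
    stop(sprintf("interval [%d,%d) outside [0,%d) on %s", start, end, len, chrom))
  if (start == end) return("")
  as.character(Biostrings::subseq(ref$seqs[[chrom]], start + 1L, end))
}

#' Write a GenomeReference to FASTA (optionally with .fai index)
#'
#' @param ref a `GenomeReference`.
#' @param path output FASTA path.
#' @param index also write a samtools-style index if `Rsamtools` can.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, index = TRUE) {
  Biostrings::writeXStringSet(ref$seqs, path)
  if (index) try(Rsamtools::indexFa(path), silent = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Interval tracks (repeats, segmental duplications)
# ---------------------------------------------------------------------------

new_interval_track <- function(df, kind) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end))
    stop("interval with start >= end at row ",
         which(df$start >= df$end)[1])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  obj <- list(records = df, kind = kind)
  class(obj) <- c(if (kind == "repeat") "RepeatAnnotation" else "SegDupTrack",
                  "IntervalTrack")
  obj
}

#' Load an interval track (repeat annotation or segmental duplications)
#'
#' Accepts BED3/BED6 (0-based half-open, consumed natively) or a
#' RepeatMasker-style whitespace table (1-based inclusive; converted to the
#' internal 0-based half-open convention on load). For `kind = "repeat"`, the
#' BED name column (or RepeatMasker columns 10/11) provides the subfamily and
#' family labels; the family is the leading letters of the subfamily name
#' (e.g. "L1PA3" -> "L1") unless a repeat class column says otherwise.
#'
#' @param path input file.
#' @param kind `"repeat"` or `"segdup"`.
#' @param format `"auto"`, `"bed"` or `"rmout"`.
#' @param chrom_names optional character vector of known chromosomes; records
#'   on other chromosomes are kept with a warning (the reference may be a
#'   subset).
#' @return a `RepeatAnnotation` or `SegDupTrack`.
#' @export
load_intervals <- function(path, kind = c("repeat", "segdup"),
                           format = c("auto", "bed", "rmout"),
                           chrom_names = NULL) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) stop("interval file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (length(lines) &&
                  grepl("^\\s*(SW|score)\\b", lines[1], ignore.case = TRUE))
      "rmout" else "bed"
  }
  if (format == "rmout") {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines, ignore.case = TRUE)]
    body <- body[grepl("[0-9]", body)]
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(fields, length, 1L) < 11L)
    if (length(bad)) stop("malformed RepeatMasker row ", bad[1], " in ", path)
    df <- data.frame(
      chrom = vapply(fields, `[`, "", 5L),
      start = as.integer(vapply(fields, `[`, "", 6L)) - 1L, # 1-based incl -> 0-based
      end = as.integer(vapply(fields, `[`, "", 7L)),
      subfamily = vapply(fields, `[`, "", 10L),
      class = vapply(fields, `[`, "", 11L),
      strand = ifelse(vapply(fields, `[`, "", 9L) %in% c("C", "-"), "-", "+"),
      stringsAsFactors = FALSE)
  } else {
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    fields <- strsplit(lines, "\\s+")
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad)) stop("malformed BED row ", bad[1], " in ", path)
    df <- data.frame(
      chrom = vapply(fields, `[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
      subfamily = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, ""),
      class = NA_character_,
      strand = vapply(fields, function(f)
        if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "+", ""),
      stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end))
      stop("non-numeric coordinates in BED: ", path)
  }
  if (!is.null(chrom_names)) {
    unknown <- setdiff(unique(df$chrom), chrom_names)
    if (length(unknown))
      warning("intervals on chromosomes absent from the reference kept: ",
              paste(unknown, collapse = ", "))
  }
  if (kind == "repeat") {
    fam <- ifelse(!is.na(df$class) & grepl("^LINE/L1", df$class), "L1",
                  sub("^([A-Za-z]+[0-9]?).*$", "\\1", df$subfamily))
    # name-derived family: leading alpha block ("L1PA3" -> "L1", "AluY" -> "Alu")
    fam2 <- sub("^(L1|Alu|SVA|LTR|ERV)[A-Za-z0-9_.-]*$", "\\1", df$subfamily)
    df$family <- ifelse(!is.na(df$class) & grepl("^LINE/L1", df$class), "L1", fam2)
    df$family[is.na(df$family)] <- fam[is.na(df$family)]
    df <- df[, c("chrom", "start", "end", "family", "subfamily", "strand")]
  } else {
    df <- df[, c("chrom", "start", "end")]
  }
  new_interval_track(df, kind)
}

#' Build an interval track from a data.frame
#'
#' @param df data.frame with 0-based half-open `chrom`, `start`, `end` (plus
#'   `family`, `subfamily`, `strand` for repeats).
#' @param kind `"repeat"` or `"segdup"`.
#' @return a `RepeatAnnotation` or `SegDupTrack`.
#' @export
interval_track <- function(df, kind = c("repeat", "segdup")) {
  kind <- match.arg(kind)
  if (kind == "repeat") {
    if (is.null(df$strand)) df$strand <- "+"
    if (is.null(df$family))
      df$family <- sub("^(L1|Alu|SVA|LTR|ERV)[A-Za-z0-9_.-]*$", "\\1", df$subfamily)
    df <- df[, c("chrom", "start", "end", "family", "subfamily", "strand")]
  } else {
    df <- df[, c("chrom", "start", "end")]
  }
  new_interval_track(df, kind)
}

#' @export
print.IntervalTrack <- function(x, ...) {
  cat(class(x)[1], "with", nrow(x$records), "record(s)\n")
  invisible(x)
}

#' Records of an interval track
#' @param x an `IntervalTrack`.
#' @return data.frame of records (0-based half-open).
#' @export
interval_records <- function(x) {
  stopifnot(inherits(x, "IntervalTrack"))
  x$records
}

#' Interval overlap query (half-open semantics)
#'
#' @param x an `IntervalTrack`.
#' @param chrom chromosome.
#' @param start,end 0-based half-open query interval.
#' @param family_prefix for repeat tracks, keep only records whose family
#'   starts with this prefix (e.g. `"L1"`).
#' @return data.frame of overlapping records.
#' @export
overlap_query <- function(x, chrom, start, end, family_prefix = NULL) {
  stopifnot(inherits(x, "IntervalTrack"))
  df <- x$records
  if (!nrow(df) || end <= start)
    return(df[0, , drop = FALSE])
  hit <- df$chrom == chrom & df$start < end & df$end > start
  if (!is.null(family_prefix) && "family" %in% names(df))
    hit <- hit & startsWith(df$family, family_prefix)
  out <- df[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interval track as BED
#'
#' @param x an `IntervalTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  df <- x$records
  if (inherits(x, "RepeatAnnotation")) {
    out <- data.frame(df$chrom, df$start, df$end, df$subfamily, 0L, df$strand)
  } else {
    out <- data.frame(df$chrom, df$start, df$end)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# L1 consensus library
# ---------------------------------------------------------------------------

#' Load an L1 subfamily consensus library
#'
#' @param path FASTA of consensus sequences, one per subfamily.
#' @param require_full_length require at least one consensus > 6 kb (the
#'   expected size of a full-length element).
#' @return named character vector (subfamily -> uppercase consensus).
#' @export
load_consensus_library <- function(path, require_full_length = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate subfamily names in consensus library")
  lib <- stats::setNames(toupper(as.character(seqs)), nm)
  if (require_full_length && !any(nchar(lib) > 6000L))
    stop("no full-length (>6 kb) consensus in library")
  lib
}
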