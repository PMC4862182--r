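# Call-set writers: provenance-stamped TSV, VCF v4.2 with symbolic
# <INS:ME:L1> records, and BED of source intervals.

provenance_lines <- function(config, prefix = "##") {
  if (is.null(config)) return(character(0))
  keys <- names(config)
  vals <- vapply(config, function(v) paste(format(v), collapse = ","), "")
  c(sprintf("%stiger_version=%s", prefix, as.character(utils::packageVersion("tiger"))),
    sprintf("%sparam_%s=%s", prefix, keys, vals))
}

#' Write transduction calls as TSV
#'
#' @param calls data.frame from [call_transductions()].
#' @param path output path.
#' @param config optional configuration list embedded as `#param_*` header
#'   lines for provenance.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(config, prefix = "#"), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call TSV written by [write_calls_tsv()]
#' @param path input path.
#' @return data.frame of calls.
#' @export
read_calls_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write transduction calls as VCF v4.2
#'
#' One record per call with symbolic ALT `<INS:ME:L1>`; POS is the 1-based
#' insertion point (midpoint of the target interval). INFO carries SVTYPE,
#' MEINFO, TDSRC (1-based inclusive for display), TDLEN, POLYAREADS, SUBFAM,
#' DONORCLASS and SAMPLES. PASS calls get FILTER `PASS`; filtered calls are
#' emitted with their flag names unless `pass_only`.
#'
#' @param calls data.frame of calls.
#' @param path output path.
#' @param ref optional `GenomeReference` for contig header lines and REF base.
#' @param config optional configuration for provenance header lines.
#' @param pass_only drop non-PASS calls (default FALSE).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, ref = NULL, config = NULL,
                      pass_only = FALSE) {
  if (pass_only) calls <- calls[calls$pass, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           provenance_lines(config),
           if (!is.null(ref))
             sprintf("##contig=<ID=%s,length=%d>", ref$chrom_names,
                     ref$chrom_lengths),
           "##ALT=<ID=INS:ME:L1,Description=\"L1 mobile element insertion with 3' transduction\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info: NAME,START,END,POLARITY\">",
           "##INFO=<ID=TDSRC,Number=1,Type=String,Description=\"Transduction source locus (1-based inclusive)\">",
           "##INFO=<ID=TDLEN,Number=1,Type=Integer,Description=\"Transduced sequence length\">",
           "##INFO=<ID=TDSEQ,Number=1,Type=String,Description=\"Reconstructed transduced sequence\">",
           "##INFO=<ID=POLYAREADS,Number=1,Type=Integer,Description=\"Mates with a non-reference polyA/polyT run\">",
           "##INFO=<ID=SUBFAM,Number=1,Type=String,Description=\"L1 subfamily\">",
           "##INFO=<ID=DONORCLASS,Number=1,Type=Integer,Description=\"Donor context class (1/2)\">",
           "##INFO=<ID=SAMPLES,Number=1,Type=String,Description=\"Carrier samples\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  rows <- character(nrow(calls))
  pts <- insertion_point(calls)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    pos1 <- pts[i] + 1L
    refbase <- if (!is.null(ref)) get_seq(ref, cl$target_chrom, pts[i], pts[i] + 1L) else "N"
    samples <- if (!is.null(cl$samples)) cl$samples else cl$sample
    info <- sprintf(
      "SVTYPE=INS;MEINFO=L1,%d,%d,%s;TDSRC=%s:%d-%d;TDLEN=%d;TDSEQ=%s;POLYAREADS=%d;SUBFAM=%s;DONORCLASS=%d;SAMPLES=%s",
      cl$target_start + 1L, cl$target_end,
      ifelse(is.na(cl$source_strand), ".", cl$source_strand),
      cl$source_chrom, cl$source_start + 1L, cl$source_end,
      cl$ts_len, ifelse(is.na(cl$ts_seq), ".", cl$ts_seq),
      cl$polya_reads, ifelse(is.na(cl$subfamily), "NA", cl$subfamily),
      cl$donor_class, samples)
    filt <- if (isTRUE(cl$pass)) "PASS" else gsub(",", ";", cl$filters)
    rows[i] <- paste(cl$target_chrom, pos1, cl$id, refbase, "<INS:ME:L1>",
                     ".", filt, info, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write source intervals as BED
#'
#' @param calls data.frame of calls.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_source_bed <- function(calls, path) {
  df <- data.frame(calls$source_chrom, calls$source_start, calls$source_end,
                   calls$id, 0L,
                   ifelse(is.na(calls$source_strand), "+", calls$source_strand))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the configuration embedded in an output file's provenance header
#'
#' Inverse of the `#param_*` header written by [write_calls_tsv()] (and, with
#' `##` prefixes, [write_vcf()]): returns the configuration list, with
#' numeric values restored, so a run's parameters round-trip with its output.
#'
#' @param path a provenance-stamped output file.
#' @return named list of configuration values.
#' @export
read_provenance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- grep("^#{1,2}param_", lines, value = TRUE)
  keys <- sub("=.*$", "", sub("^#{1,2}param_", "", pl))
  vals <- lapply(sub("^[^=]*=", "", pl), function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, keys)
}
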