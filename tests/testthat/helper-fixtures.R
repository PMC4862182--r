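# Programmatic fixtures shared across the suite. Everything is generated in
# code at test time; nothing binary ships with the package.

random_genome <- function(n, seed = 1, chroms = "chrA") {
  set.seed(seed)
  per <- floor(n / length(chroms))
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), per, replace = TRUE), collapse = ""), "")
  genome_reference(setNames(seqs, chroms))
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a SAM file and convert to sorted, indexed BAM; records is a character
# vector of tab-joined SAM lines (without header)
fixture_bam <- function(records, chrom_lengths, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "fixture.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  writeLines(c(hdr, records), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "fixture_unsorted"),
                           indexDestination = FALSE, overwrite = TRUE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "fixture"))
  Rsamtools::indexBam(bam)
  bam
}

# one SAM line; pos is 0-based (converted to 1-based SAM)
sam_line <- function(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, seq) {
  paste(qname, flag, rname, pos + 1L, mapq, cigar, mrnm, mpos + 1L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# a paired-end fixture pair: returns two SAM lines.
# placement lists: list(rname, pos (0-based), strand ("+"/"-"), mapq,
# cigar or NULL, mapped (logical))
sam_pair <- function(qname, p1, p2) {
  f1 <- 1L + 64L; f2 <- 1L + 128L
  if (!p1$mapped) { f1 <- f1 + 4L; f2 <- f2 + 8L }
  if (!p2$mapped) { f2 <- f2 + 4L; f1 <- f1 + 8L }
  if (p1$mapped && identical(p1$strand, "-")) { f1 <- f1 + 16L; f2 <- f2 + 32L }
  if (p2$mapped && identical(p2$strand, "-")) { f2 <- f2 + 16L; f1 <- f1 + 32L }
  mk <- function(p, f, mate) {
    rname <- if (p$mapped) p$rname else (if (mate$mapped) mate$rname else "*")
    pos <- if (p$mapped) p$pos else (if (mate$mapped) mate$pos else -1L)
    cigar <- if (p$mapped) (p$cigar %||% paste0(nchar(p$seq), "M")) else "*"
    mrnm <- if (mate$mapped) mate$rname else rname
    mpos <- if (mate$mapped) mate$pos else pos
    mapq <- if (p$mapped) p$mapq else 0L
    sam_line(qname, f, rname, pos, mapq, cigar,
             if (identical(mrnm, rname)) "=" else mrnm, mpos, p$seq)
  }
  c(mk(p1, f1, p2), mk(p2, f2, p1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# implant an allele string at 0-based pos of a chromosome; returns new string
implant_at <- function(chromseq, pos, allele) {
  paste0(substring(chromseq, 1, pos), allele, substring(chromseq, pos + 1))
}

# small MEI TSV on disk
fixture_mei <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "mei.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

mei_row <- function(chrom, start, end, sample = "s1", family = "L1",
                    tier = "high", tsd_seq = NA, polya = NA, strand = NA) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             family = family, tier = tier, tsd_seq = tsd_seq, polya = polya,
             strand = strand, stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p by hypergeometric enumeration
# (minimum-likelihood convention), used as the oracle for fisher.test
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total (transducing)
  n <- c + d          # row 2 total (solo)
  k <- a + c          # column 1 total (with subfamily)
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# fabricated caller inputs: a discordant-pair row, a candidate region and a
# realignment table, used by test-caller.R and test-acceptance.R
fake_pair_row <- function(qname, mate_seq = rand_dna(101), mate_mapped = FALSE,
                          mate_chrom = NA, mate_start = NA, mate_mapq = 0L,
                          anchor_chrom = "chrT", anchor_start = 1000L,
                          category = "SA") {
  data.frame(qname = qname,
             r1_chrom = anchor_chrom, r1_start = anchor_start,
             r1_end = anchor_start + 101L, r1_strand = "+", r1_mapq = 60L,
             r1_mapped = TRUE, r1_seq = rand_dna(101),
             r2_chrom = mate_chrom, r2_start = mate_start,
             r2_end = if (is.na(mate_start)) NA_integer_ else mate_start + nchar(mate_seq),
             r2_strand = "-", r2_mapq = mate_mapq,
             r2_mapped = mate_mapped, r2_seq = mate_seq,
             category = category, anchor = 1L, mate_end = 2L,
             stringsAsFactors = FALSE)
}

fake_region <- function(pairs, chrom = "chrT", s = 500L, e = 1600L,
                        mei_start = 1000L, mei_end = 1010L) {
  mei <- mei_row(chrom, mei_start, mei_end)
  mei$mei_id <- "mei00001"
  structure(list(mei = mei, chrom = chrom, search_start = s, search_end = e,
                 pairs = pairs, empty = nrow(pairs) == 0L),
            class = "CandidateRegion")
}

fake_realn <- function(qnames, chrom, starts, ends, tms = 1L) {
  data.frame(qname = qnames, end_idx = 2L, chrom = chrom, start = starts,
             end = ends, strand = "+", score = ends - starts,
             aligned = ends - starts, identity = 1, tm = tms,
             repetitive = tms > 3L, stringsAsFactors = FALSE)
}
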