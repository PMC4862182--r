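# Synthetic-data simulator: unique background genomes, implanted 3'
# transduction and solo-L1 events (TSD + truncated L1 [+ TS] + polyA + TSD),
# paired-end reads with substitution errors, and truth-based evaluation.

#' Simulation configuration
#'
#' Defaults describe the data the caller targets: 101 bp Illumina-like pairs
#' at ~20x coverage with a 350 +/- 50 bp insert, heterozygous events composed
#' of a 4-25 bp TSD, a 5'-truncated L1 (100-6000 bp suffix of a consensus),
#' 60-500 bp of transduced sequence and a 10-30 bp polyA tail, on a unique
#' background genome split across several chromosomes (sources are drawn on a
#' different chromosome than their target, matching the inter-chromosomal
#' translocation signature the caller keys on).
#'
#' @param ... overrides for individual fields.
#' @return named list (class `SimConfig`).
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_length = 5e6, n_chrom = 5L,
    read_length = 101L, insert_mean = 350, insert_sd = 50,
    coverage = 20, error_rate = 0.001,
    n_transductions = 50L, n_solo = 20L,
    ts_range = c(60L, 500L), l1_trunc_range = c(100L, 6000L),
    tsd_range = c(4L, 25L), polya_range = c(10L, 30L),
    zygosity = "het",
    mei_jitter = 100L, mei_false = 10L,
    n_repeats = 0L, repeat_length = 1000L, repeat_copies = 5L,
    repeat_family = "SIMREP",
    min_event_gap = 3000L,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$genome_length > 0, cfg$read_length > 0, cfg$coverage > 0,
            cfg$insert_mean >= cfg$read_length,
            cfg$zygosity %in% c("het", "hom"))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic L1 consensus library
#'
#' One ancestral random sequence plus `n - 1` derived subfamilies at the
#' given substitution divergence; all full-length (> 6 kb by default). A
#' stand-in for a real consensus library in fully self-contained runs.
#'
#' @param n number of subfamilies.
#' @param length consensus length in bp.
#' @param divergence per-base substitution divergence from the ancestor.
#' @param seed RNG seed.
#' @return named character vector (`L1SIM1` ... `L1SIMn`).
#' @export
synthetic_l1_library <- function(n = 4L, length = 6500L, divergence = 0.08,
                                 seed = 1L) {
  set.seed(derive_seed(seed, "l1lib"))
  base <- strsplit(random_dna(length), "")[[1]]
  lib <- character(n)
  lib[1] <- paste(base, collapse = "")
  for (i in seq_len(n)[-1]) {
    mut <- base
    k <- round(divergence * length)
    pos <- sample(length, k)
    mut[pos] <- vapply(mut[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    lib[i] <- paste(mut, collapse = "")
  }
  stats::setNames(lib, paste0("L1SIM", seq_len(n)))
}

#' Build a synthetic background genome
#'
#' I.i.d.-uniform sequence split over `n_chrom` chromosomes, optionally with
#' planted identical repeat copies (to exercise TM accounting and the
#' repetitive-source guard), with matching annotation records.
#'
#' @param config a `SimConfig`.
#' @return list with `ref` (`GenomeReference`) and `repeats`
#'   (`RepeatAnnotation`, possibly empty).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  max_event <- max(config$l1_trunc_range) + max(config$ts_range) +
    max(config$polya_range) + 2 * max(config$tsd_range)
  if (config$genome_length < 10 * max_event)
    stop("genome shorter than 10x the maximum event size")
  set.seed(derive_seed(config$seed, "genome"))
  per <- floor(config$genome_length / config$n_chrom)
  seqs <- stats::setNames(
    vapply(seq_len(config$n_chrom), function(i) random_dna(per), ""),
    paste0("chr", seq_len(config$n_chrom)))
  ann <- data.frame(chrom = character(), start = integer(), end = integer(),
                    family = character(), subfamily = character(),
                    strand = character(), stringsAsFactors = FALSE)
  if (config$n_repeats > 0) {
    for (r in seq_len(config$n_repeats)) {
      unit <- random_dna(config$repeat_length)
      for (cp in seq_len(config$repeat_copies)) {
        chr <- sample(names(seqs), 1)
        pos <- sample(per - config$repeat_length - 1000, 1) + 500
        substr(seqs[[chr]], pos + 1, pos + config$repeat_length) <- unit
        ann <- rbind(ann, data.frame(
          chrom = chr, start = pos, end = pos + config$repeat_length,
          family = config$repeat_family,
          subfamily = paste0(config$repeat_family, r),
          strand = "+", stringsAsFactors = FALSE))
      }
    }
  }
  list(ref = genome_reference(seqs), repeats = interval_track(ann, "repeat"))
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Implant transduction and solo-L1 events into a genome
#'
#' Each 3' transduction inserts `TSD + 5'-truncated L1 + TS + polyA + TSD` at
#' the target, where the TS is copied verbatim from a distal source locus on
#' a different chromosome and the TSD duplicates the target site sequence;
#' solo L1 events omit the TS. Event positions are drawn with a minimum
#' mutual gap (bounded redraws on collision). The genome grows by exactly the
#' sum of inserted allele lengths.
#'
#' @param ref a `GenomeReference` (the original reference).
#' @param config a `SimConfig`.
#' @param library consensus library (named character); default: a synthetic
#'   library derived from the config seed.
#' @return list with `genome` (mutated `GenomeReference`) and `truth`
#'   (data.frame of `SimTruthEvent` records; target/source coordinates are on
#'   the original reference).
#' @export
implant_events <- function(ref, config, library = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(library)) library <- synthetic_l1_library(seed = config$seed)
  set.seed(derive_seed(config$seed, "events"))
  n_td <- config$n_transductions
  n_solo <- config$n_solo
  n <- n_td + n_solo
  margin <- 2000L
  gap <- config$min_event_gap
  # draw non-colliding target positions and (for TDs) source intervals
  taken <- data.frame(chrom = character(), start = integer(), end = integer())
  collide <- function(chrom, s, e) {
    any(taken$chrom == chrom & taken$start < e + gap & taken$end > s - gap)
  }
  claim <- function(chrom, s, e) {
    taken <<- rbind(taken, data.frame(chrom = chrom, start = s, end = e))
  }
  draw_locus <- function(span, exclude_chrom = NULL) {
    for (try in 1:200) {
      chroms <- setdiff(ref$chrom_names, exclude_chrom)
      chrom <- sample(chroms, 1)
      lim <- ref$chrom_lengths[[chrom]] - span - margin
      if (lim <= margin) next
      s <- sample(seq(margin, lim), 1)
      if (!collide(chrom, s, s + span)) { claim(chrom, s, s + span); return(list(chrom = chrom, pos = s)) }
    }
    stop("could not place event without collision; genome too small")
  }
  if (n == 0L) {
    return(list(genome = genome_reference(as.character(ref$seqs)),
                truth = data.frame(event_id = character(), type = character(),
                                   target_chrom = character(),
                                   target_pos = integer(),
                                   source_chrom = character(),
                                   source_start = integer(),
                                   source_end = integer(),
                                   subfamily = character(), l1_len = integer(),
                                   ts_len = integer(), tsd_len = integer(),
                                   polya_len = integer(), zygosity = character(),
                                   tsd_seq = character(), ts_seq = character(),
                                   allele_len = integer(),
                                   stringsAsFactors = FALSE)))
  }
  truth <- vector("list", n)
  types <- c(rep("TD", n_td), rep("SOLO_L1", n_solo))
  for (i in seq_len(n)) {
    type <- types[i]
    tsd_len <- runif_int(1, config$tsd_range)
    polya_len <- runif_int(1, config$polya_range)
    l1_len <- runif_int(1, config$l1_trunc_range)
    subfam <- sample(names(library), 1)
    cons <- library[[subfam]]
    l1_len <- min(l1_len, nchar(cons))
    ts_len <- if (type == "TD") runif_int(1, config$ts_range) else 0L
    tgt <- draw_locus(tsd_len)
    src <- if (type == "TD") draw_locus(ts_len, exclude_chrom = tgt$chrom) else NULL
    truth[[i]] <- data.frame(
      event_id = sprintf("ev%04d", i), type = type,
      target_chrom = tgt$chrom, target_pos = tgt$pos,
      source_chrom = if (is.null(src)) NA_character_ else src$chrom,
      source_start = if (is.null(src)) NA_integer_ else src$pos,
      source_end = if (is.null(src)) NA_integer_ else src$pos + ts_len,
      subfamily = subfam, l1_len = l1_len, ts_len = ts_len,
      tsd_len = tsd_len, polya_len = polya_len,
      zygosity = config$zygosity, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  # assemble alleles and stitch per chromosome
  truth$tsd_seq <- vapply(seq_len(nrow(truth)), function(i)
    get_seq(ref, truth$target_chrom[i], truth$target_pos[i],
            truth$target_pos[i] + truth$tsd_len[i]), "")
  truth$ts_seq <- ifelse(truth$type == "TD",
                         vapply(seq_len(nrow(truth)), function(i) {
                           if (truth$type[i] != "TD") return("")
                           get_seq(ref, truth$source_chrom[i],
                                   truth$source_start[i], truth$source_end[i])
                         }, ""), "")
  alleles <- vapply(seq_len(nrow(truth)), function(i) {
    cons <- library[[truth$subfamily[i]]]
    l1frag <- substring(cons, nchar(cons) - truth$l1_len[i] + 1L)
    paste0(truth$tsd_seq[i], l1frag, truth$ts_seq[i],
           strrep("A", truth$polya_len[i]), truth$tsd_seq[i])
  }, "")
  truth$allele_len <- nchar(alleles)
  mut <- as.list(as.character(ref$seqs))
  for (chr in unique(truth$target_chrom)) {
    ev <- truth[truth$target_chrom == chr, , drop = FALSE]
    ord <- order(ev$target_pos)
    ev <- ev[ord, ]
    al <- alleles[truth$target_chrom == chr][ord]
    s <- mut[[chr]]
    pieces <- character(2 * nrow(ev) + 1)
    prev <- 0L
    for (j in seq_len(nrow(ev))) {
      pieces[2 * j - 1] <- substring(s, prev + 1L, ev$target_pos[j])
      pieces[2 * j] <- al[j]
      prev <- ev$target_pos[j]
    }
    pieces[2 * nrow(ev) + 1] <- substring(s, prev + 1L)
    mut[[chr]] <- paste(pieces, collapse = "")
  }
  list(genome = genome_reference(unlist(mut)), truth = truth)
}

#' Simulate paired-end reads
#'
#' FR-oriented pairs drawn uniformly over the genome with normal insert sizes
#' and uniform per-base substitution errors. For heterozygous simulations,
#' half the fragments are drawn from the mutated haplotype and half from the
#' original reference.
#'
#' @param genome mutated `GenomeReference` (the carrier haplotype).
#' @param config a `SimConfig`.
#' @param original original `GenomeReference`; used as the second haplotype
#'   when `config$zygosity == "het"`.
#' @param out_prefix path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return list with `fq1`, `fq2`, `n_pairs`.
#' @export
simulate_reads <- function(genome, config, original = NULL,
                           out_prefix = tempfile("sim")) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, "reads"))
  rl <- config$read_length
  if (config$insert_mean < rl) stop("insert smaller than read length")
  haps <- list(genome)
  if (identical(config$zygosity, "het") && !is.null(original))
    haps <- list(genome, original)
  total <- sum(vapply(haps, function(h) sum(as.numeric(h$chrom_lengths)), 0)) /
    length(haps)
  n_pairs <- round(config$coverage * total / (2 * rl))
  per_hap <- diff(round(seq(0, n_pairs, length.out = length(haps) + 1)))
  fq1 <- paste0(out_prefix, "_1.fastq")
  fq2 <- paste0(out_prefix, "_2.fastq")
  con1 <- file(fq1, "w"); con2 <- file(fq2, "w")
  on.exit({ close(con1); close(con2) })
  serial <- 0L
  for (h in seq_along(haps)) {
    hap <- haps[[h]]
    nh <- per_hap[h]
    if (nh == 0) next
    lens <- hap$chrom_lengths
    chrom_idx <- sample.int(length(lens), nh, replace = TRUE,
                            prob = as.numeric(lens))
    frag <- pmax(rl, pmin(2000L, round(stats::rnorm(nh, config$insert_mean,
                                                    config$insert_sd))))
    for (ci in seq_along(lens)) {
      sel <- which(chrom_idx == ci)
      if (!length(sel)) next
      L <- lens[[ci]]
      f <- pmin(frag[sel], L)
      pos <- floor(stats::runif(length(sel), 0, L - f + 1)) # 0-based
      chromseq <- hap$seqs[[ci]]
      r1 <- as.character(Biostrings::extractAt(
        chromseq, IRanges::IRanges(pos + 1L, pos + rl)))
      r2 <- as.character(Biostrings::reverseComplement(Biostrings::extractAt(
        chromseq, IRanges::IRanges(pos + f - rl + 1L, pos + f))))
      if (config$error_rate > 0) {
        r1 <- add_errors(r1, config$error_rate)
        r2 <- add_errors(r2, config$error_rate)
      }
      ids <- sprintf("sim%08d", serial + seq_along(sel))
      serial <- serial + length(sel)
      qual <- strrep("I", rl)
      writeLines(paste0("@", ids, "\n", r1, "\n+\n", qual), con1)
      writeLines(paste0("@", ids, "\n", r2, "\n+\n", qual), con2)
    }
  }
  list(fq1 = fq1, fq2 = fq2, n_pairs = n_pairs)
}

# uniform substitution errors over a character vector of reads
add_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    for (p in sample.int(rl, nerr[i])) {
      b <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
  }
  reads
}

#' Map simulated reads to the original reference with bwa
#'
#' Thin wrapper over `bwa mem` and `samtools sort/index` (both must be on
#' PATH). Reads originating in inserted alleles go unmapped or map distally,
#' producing the TL/SA discordant-pair signatures the caller consumes.
#'
#' @param fq1,fq2 FASTQ paths.
#' @param ref_fasta reference FASTA path (indexed on first use).
#' @param out_bam output BAM path.
#' @param threads bwa threads (default 1).
#' @return `out_bam`, invisibly.
#' @export
map_reads <- function(fq1, fq2, ref_fasta, out_bam, threads = 1L) {
  bwa <- Sys.which("bwa"); st <- Sys.which("samtools")
  if (!nzchar(bwa) || !nzchar(st))
    stop("bwa and samtools must be on PATH to map simulated reads")
  if (!file.exists(paste0(ref_fasta, ".bwt"))) {
    rc <- system2(bwa, c("index", shQuote(ref_fasta)), stdout = FALSE, stderr = FALSE)
    if (rc != 0) stop("bwa index failed")
  }
  cmd <- sprintf("%s mem -t %d %s %s %s 2>/dev/null | %s sort -o %s - 2>/dev/null",
                 bwa, threads, shQuote(ref_fasta), shQuote(fq1), shQuote(fq2),
                 st, shQuote(out_bam))
  rc <- system(cmd)
  if (rc != 0) stop("bwa mem | samtools sort failed")
  rc <- system2(st, c("index", shQuote(out_bam)), stdout = FALSE, stderr = FALSE)
  if (rc != 0) stop("samtools index failed")
  invisible(out_bam)
}

#' Write a truth-derived MEI call file
#'
#' Emulates an imperfect upstream MEI caller: every implanted event (TD and
#' solo) yields one L1 call with positional jitter, plus optional false
#' candidate loci at random positions.
#'
#' @param truth truth data.frame from [implant_events()].
#' @param path output TSV.
#' @param ref `GenomeReference` (for false-candidate placement bounds).
#' @param sample sample id written to the file.
#' @param jitter maximum absolute positional jitter in bp (uniform).
#' @param n_false number of false MEI candidates.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
write_mei_file <- function(truth, path, ref, sample = "sim", jitter = 100L,
                           n_false = 0L, seed = 1L) {
  set.seed(derive_seed(seed, "mei"))
  off <- if (jitter > 0) sample(seq(-jitter, jitter), nrow(truth), replace = TRUE)
  else rep(0L, nrow(truth))
  start <- pmax(0L, truth$target_pos + off)
  df <- data.frame(
    sample = sample, chrom = truth$target_chrom, start = start,
    end = start + pmax(1L, truth$tsd_len),
    family = "L1",
    tier = sample(c("high", "low"), nrow(truth), replace = TRUE, prob = c(0.8, 0.2)),
    tsd_seq = truth$tsd_seq, polya = TRUE, strand = "+",
    stringsAsFactors = FALSE)
  if (n_false > 0) {
    chrom <- sample(ref$chrom_names, n_false, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample(ref$chrom_lengths[[ch]] - 1000L, 1) + 500L, 1L)
    df <- rbind(df, data.frame(
      sample = sample, chrom = chrom, start = pos, end = pos + 10L,
      family = "L1", tier = "low", tsd_seq = NA_character_, polya = FALSE,
      strand = "+", stringsAsFactors = FALSE))
  }
  df <- df[order(df$chrom, df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth table
#' @param truth truth data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate caller sensitivity against simulation truth
#'
#' A truth transduction counts as detected when some PASS call has its target
#' insertion point within `tolerance` bp of the true target position and a
#' source interval overlapping the true source interval.
#'
#' @param calls data.frame of calls.
#' @param truth truth data.frame from [implant_events()].
#' @param tolerance target-position tolerance in bp (default 500).
#' @return list with `sensitivity`, `n_detected`, `n_events`, `detected`
#'   (logical per truth TD event), and `false_pass` (PASS calls matching no
#'   truth event).
#' @export
evaluate_sensitivity <- function(calls, truth, tolerance = 500L) {
  td <- truth[truth$type == "TD", , drop = FALSE]
  if (!nrow(td)) stop("truth contains no transduction events")
  pass <- calls[which(calls$pass), , drop = FALSE]
  pts <- if (nrow(pass)) insertion_point(pass) else integer(0)
  hit_matrix <- matrix(FALSE, nrow = nrow(pass), ncol = nrow(td))
  detected <- logical(nrow(td))
  for (i in seq_len(nrow(td))) {
    if (!nrow(pass)) break
    ok <- pass$target_chrom == td$target_chrom[i] &
      abs(pts - td$target_pos[i]) <= tolerance &
      pass$source_chrom == td$source_chrom[i] &
      pass$source_start < td$source_end[i] &
      pass$source_end > td$source_start[i]
    detected[i] <- any(ok)
    hit_matrix[, i] <- ok
  }
  matched_call <- if (nrow(pass)) apply(hit_matrix, 1, any) else logical(0)
  list(sensitivity = mean(detected), n_detected = sum(detected),
       n_events = nrow(td), detected = detected,
       false_pass = pass[!matched_call, , drop = FALSE])
}
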