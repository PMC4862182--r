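test_that("genome building is deterministic and plants annotated repeats", {
  cfg <- sim_config(genome_length = 2e5, n_chrom = 2, seed = 1,
                    n_repeats = 1, repeat_length = 1000, repeat_copies = 5)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(as.character(g1$ref$seqs), as.character(g2$ref$seqs))
  expect_equal(nrow(interval_records(g1$repeats)), 5L)
  expect_error(build_genome(sim_config(genome_length = 5e4, n_chrom = 1)),
               "10x")
})

test_that("a repeat-free genome is overwhelmingly 50-mer unique", {
  cfg <- sim_config(genome_length = 5e5, n_chrom = 1, seed = 2)
  g <- build_genome(cfg)$ref
  s <- as.character(g$seqs[[1]])
  starts <- seq(1, nchar(s) - 49, by = 7)  # systematic sample of 50-mers
  kmers <- substring(s, starts, starts + 49)
  expect_gte(mean(!(duplicated(kmers) | duplicated(kmers, fromLast = TRUE))),
             0.999)
})

test_that("implantation conserves length exactly (worked 1078 bp event)", {
  lib <- synthetic_l1_library(n = 1, length = 6500, seed = 3)
  cfg <- sim_config(genome_length = 2e5, n_chrom = 2, seed = 3,
                    n_transductions = 1, n_solo = 0,
                    ts_range = c(126, 126), l1_trunc_range = c(908, 908),
                    tsd_range = c(12, 12), polya_range = c(20, 20))
  g <- build_genome(cfg)$ref
  imp <- implant_events(g, cfg, lib)
  # TSD 12 + L1 908 + TS 126 + polyA 20 + TSD 12
  expect_equal(imp$truth$allele_len, 908L + 126L + 20L + 2L * 12L)
  expect_equal(sum(imp$genome$chrom_lengths) - sum(g$chrom_lengths), 1078)
  # the transduced sequence equals the reference at the source coordinates
  expect_identical(imp$truth$ts_seq,
                   get_seq(g, imp$truth$source_chrom, imp$truth$source_start,
                           imp$truth$source_end))
  # inserted allele structure is present verbatim in the mutated genome
  cons <- lib[[1]]
  allele <- paste0(imp$truth$tsd_seq,
                   substring(cons, nchar(cons) - 907L),
                   imp$truth$ts_seq, strrep("A", 20), imp$truth$tsd_seq)
  mut <- as.character(imp$genome$seqs[[imp$truth$target_chrom]])
  expect_equal(length(gregexpr(allele, mut, fixed = TRUE)[[1]]), 1L)
})

test_that("zero events leave the genome unchanged; truth conservation holds", {
  cfg0 <- sim_config(genome_length = 2e5, n_chrom = 2, seed = 4,
                     n_transductions = 0, n_solo = 0)
  g <- build_genome(cfg0)$ref
  imp0 <- implant_events(g, cfg0)
  expect_identical(as.character(imp0$genome$seqs), as.character(g$seqs))
  cfg <- sim_config(genome_length = 4e5, n_chrom = 2, seed = 4,
                    n_transductions = 5, n_solo = 3,
                    l1_trunc_range = c(100, 2000))
  g2 <- build_genome(cfg)$ref
  imp <- implant_events(g2, cfg)
  expect_equal(sum(imp$genome$chrom_lengths) - sum(g2$chrom_lengths),
               sum(imp$truth$allele_len))
  expect_equal(sum(imp$truth$type == "TD"), 5L)
  expect_equal(sum(imp$truth$type == "SOLO_L1"), 3L)
  # solo alleles have no TS
  expect_true(all(imp$truth$ts_len[imp$truth$type == "SOLO_L1"] == 0L))
})

test_that("read simulation hits the coverage target and is seed-stable", {
  cfg <- sim_config(genome_length = 2e5, n_chrom = 1, seed = 5,
                    n_transductions = 0, n_solo = 0, coverage = 20,
                    zygosity = "hom", error_rate = 0)
  g <- build_genome(cfg)$ref
  dir <- withr::local_tempdir()
  r1 <- simulate_reads(g, cfg, out_prefix = file.path(dir, "a"))
  expect_equal(r1$n_pairs, round(20 * 2e5 / (2 * 101)))
  # error-free reads are exact substrings of the genome
  lines <- readLines(r1$fq1, n = 80)
  reads <- lines[seq(2, 80, by = 4)]
  s <- as.character(g$seqs[[1]])
  hits <- vapply(reads, function(rd)
    grepl(rd, s, fixed = TRUE) || grepl(revcomp(rd), s, fixed = TRUE), TRUE)
  expect_true(all(hits))
  # same seed -> byte-identical FASTQ
  r2 <- simulate_reads(g, cfg, out_prefix = file.path(dir, "b"))
  expect_identical(readLines(r1$fq1), readLines(r2$fq1))
  expect_identical(readLines(r1$fq2), readLines(r2$fq2))
  expect_error(simulate_reads(g, sim_config(insert_mean = 50), ),
               "insert")
})

test_that("error injection perturbs roughly the configured base fraction", {
  cfg0 <- sim_config(genome_length = 2e5, n_chrom = 1, seed = 6,
                     n_transductions = 0, n_solo = 0, coverage = 5,
                     zygosity = "hom", error_rate = 0)
  g <- build_genome(cfg0)$ref
  dir <- withr::local_tempdir()
  clean <- simulate_reads(g, cfg0, out_prefix = file.path(dir, "clean"))
  cfg1 <- cfg0; cfg1$error_rate <- 0.01
  noisy <- simulate_reads(g, cfg1, out_prefix = file.path(dir, "noisy"))
  a <- readLines(clean$fq1); b <- readLines(noisy$fq1)
  ra <- strsplit(paste(a[seq(2, length(a), 4)], collapse = ""), "")[[1]]
  rb <- strsplit(paste(b[seq(2, length(b), 4)], collapse = ""), "")[[1]]
  expect_equal(mean(ra != rb), 0.01, tolerance = 0.15)
})

test_that("sensitivity evaluation counts position+source matches", {
  truth <- data.frame(
    event_id = sprintf("ev%02d", 1:51), type = "TD",
    target_chrom = "chr1", target_pos = 10000L * (1:51),
    source_chrom = "chr2", source_start = 5000L * (1:51),
    source_end = 5000L * (1:51) + 200L, stringsAsFactors = FALSE)
  mkcall <- function(i, off = 0L) {
    data.frame(target_chrom = "chr1", target_start = 10000L * i + off,
               target_end = 10000L * i + off + 10L,
               source_chrom = "chr2", source_start = 5000L * i + 20L,
               source_end = 5000L * i + 180L, pass = TRUE,
               stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, lapply(1:43, mkcall))
  ev <- evaluate_sensitivity(calls, truth, tolerance = 500L)
  expect_equal(ev$n_detected, 43L)
  expect_equal(round(ev$sensitivity, 3), 0.843)
  expect_equal(nrow(ev$false_pass), 0L)
  # perfect and empty call sets
  all51 <- do.call(rbind, lapply(1:51, mkcall))
  expect_equal(evaluate_sensitivity(all51, truth)$sensitivity, 1.0)
  expect_equal(evaluate_sensitivity(all51[0, ], truth)$sensitivity, 0)
  # a call off by more than the tolerance does not count
  off <- evaluate_sensitivity(mkcall(1, off = 600L), truth)
  expect_equal(off$n_detected, 0L)
  expect_equal(nrow(off$false_pass), 1L)
  expect_error(evaluate_sensitivity(all51, truth[truth$type != "TD", ]),
               "no transduction")
})

test_that("the MEI file derived from truth parses and jitters within bounds", {
  cfg <- sim_config(genome_length = 4e5, n_chrom = 2, seed = 7,
                    n_transductions = 4, n_solo = 2,
                    l1_trunc_range = c(100, 1500))
  g <- build_genome(cfg)$ref
  imp <- implant_events(g, cfg)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mei.tsv")
  write_mei_file(imp$truth, path, g, jitter = 100L, n_false = 3L, seed = 7)
  meis <- read_mei_calls(path)
  expect_equal(nrow(meis), 6L + 3L)
  m <- merge(meis, imp$truth, by.x = c("chrom", "tsd_seq"),
             by.y = c("target_chrom", "tsd_seq"))
  expect_true(all(abs(m$start - m$target_pos) <= 100L))
})
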