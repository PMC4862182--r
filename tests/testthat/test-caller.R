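# Caller unit tests on fabricated regions and realignment tables (no BAM
# round trip; that path is covered in test-evidence and test-pipeline).
# fake_pair_row / fake_region / fake_realn come from helper-fixtures.R.

test_that("candidate regions use the +/-500 bp window with clamping", {
  meis <- rbind(mei_row("chr1", 10000L, 10010L), mei_row("chr1", 200L, 210L))
  meis$mei_id <- c("mei00001", "mei00002")
  pairs <- rbind(
    fake_pair_row("in1", anchor_chrom = "chr1", anchor_start = 10400L,
                  mate_mapped = TRUE, mate_chrom = "chr2", mate_start = 100L,
                  mate_mapq = 60L, category = "TL"),
    fake_pair_row("out1", anchor_chrom = "chr1", anchor_start = 10600L,
                  mate_mapped = TRUE, mate_chrom = "chr2", mate_start = 200L,
                  mate_mapq = 60L, category = "TL"))
  regions <- build_candidate_regions(meis, pairs, window = 500L,
                                     chrom_lengths = c(chr1 = 50000L))
  # anchor [10400,10501) overlaps [9500,10510); [10600,10701) does not
  expect_equal(regions[[1]]$pairs$qname, "in1")
  expect_equal(regions[[1]]$search_start, 9500L)
  expect_equal(regions[[1]]$search_end, 10510L)
  # clamped at the chromosome start
  expect_equal(regions[[2]]$search_start, 0L)
  expect_equal(regions[[2]]$search_end, 710L)
  expect_true(regions[[2]]$empty)
})

test_that("cluster size bounds are inclusive at 4 and 30", {
  mk <- function(n) {
    qn <- sprintf("q%02d", seq_len(n))
    pairs <- do.call(rbind, lapply(qn, fake_pair_row))
    region <- fake_region(pairs)
    # heavily overlapping placements on another chromosome
    realn <- fake_realn(qn, "chrS", starts = 5000L + seq_len(n),
                        ends = 5101L + seq_len(n))
    cluster_sources(region, realn)
  }
  expect_length(mk(3)$clusters, 0L)            # 3 reads: below minimum
  expect_length(mk(4)$clusters, 1L)            # 4 reads: kept
  expect_length(mk(30)$clusters, 1L)           # 30 reads: kept
  r31 <- mk(31)
  expect_length(r31$clusters, 0L)              # 31 reads: dropped ...
  expect_true(r31$repetitive_source)           # ... and region flagged
  expect_false(mk(4)$repetitive_source)
})

test_that("mean TM boundary is inclusive at 3.0", {
  qn <- sprintf("q%02d", 1:4)
  pairs <- do.call(rbind, lapply(qn, fake_pair_row))
  region <- fake_region(pairs)
  realn <- fake_realn(qn, "chrS", 5000L + 1:4, 5101L + 1:4,
                      tms = c(1L, 1L, 2L, 8L))   # mean exactly 3.0
  expect_length(cluster_sources(region, realn)$clusters, 1L)
  realn$tm <- c(1L, 1L, 2L, 9L)                  # mean 3.25
  expect_length(cluster_sources(region, realn)$clusters, 0L)
  # just-below threshold also drops the mean-3.0 chain
  realn$tm <- c(1L, 1L, 2L, 8L)
  expect_length(cluster_sources(region, realn, max_mean_tm = 2.99)$clusters, 0L)
})

test_that("chaining is overlap-connected without gaps", {
  ref <- random_genome(20000, seed = 21, chroms = "chrS")
  qn <- sprintf("q%02d", 1:6)
  pairs <- do.call(rbind, lapply(qn, fake_pair_row))
  region <- fake_region(pairs)
  # six reads tiling [5000,5607) with 20 bp overlaps
  starts <- 5000L + (0:5) * 81L  # 101 - 20 overlap
  realn <- fake_realn(qn, "chrS", starts, starts + 101L)
  cl <- cluster_sources(region, realn, ref = ref)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$clusters[[1]]$start, 5000L)
  expect_equal(cl$clusters[[1]]$end, 5506L)
  expect_equal(nchar(cl$clusters[[1]]$seq), 506L)
  expect_identical(cl$clusters[[1]]$seq, get_seq(ref, "chrS", 5000L, 5506L))
  # a 50 bp gap splits the mates into two chains, each evaluated on its own
  starts2 <- c(5000L, 5010L, 5020L, 5030L, 5252L, 5262L, 5272L, 5282L)
  qn2 <- sprintf("g%02d", 1:8)
  pairs2 <- do.call(rbind, lapply(qn2, fake_pair_row))
  realn2 <- fake_realn(qn2, "chrS", starts2, starts2 + 101L)
  cl2 <- cluster_sources(fake_region(pairs2), realn2, ref = ref)
  expect_length(cl2$clusters, 2L)
  # book-ended intervals (zero overlap) do not chain
  starts3 <- c(5000L, 5000L, 5000L, 5101L, 5101L, 5101L)
  realn3 <- fake_realn(qn, "chrS", starts3, starts3 + 101L)
  cl3 <- cluster_sources(fake_region(pairs), realn3, min_reads = 3L, ref = ref)
  expect_length(cl3$clusters, 2L)
})

test_that("hits overlapping the candidate region are excluded from sources", {
  qn <- sprintf("q%02d", 1:4)
  pairs <- do.call(rbind, lapply(qn, fake_pair_row))
  region <- fake_region(pairs, chrom = "chrT", s = 500L, e = 1600L)
  # best hits inside the region's own search interval -> self-matching
  realn <- fake_realn(qn, "chrT", 900L + 1:4, 1001L + 1:4)
  expect_length(cluster_sources(region, realn)$clusters, 0L)
  # same chromosome but outside the search interval is acceptable
  realn2 <- fake_realn(qn, "chrT", 8000L + 1:4, 8101L + 1:4)
  expect_length(cluster_sources(region, realn2)$clusters, 1L)
})

test_that("polyA detection requires six non-reference consecutive A/T", {
  ref <- random_genome(5000, seed = 22, chroms = "chrR")
  g <- as.character(ref$seqs[[1]])
  # unmapped mate with a 6 bp tail -> counted
  p1 <- fake_pair_row("a1", mate_seq = paste0(substring(g, 101, 195), "AAAAAA"))
  # unmapped mate with only a 5 bp run -> not counted
  stopifnot(!grepl("AAAAAA|TTTTTT", substring(g, 201, 296)))
  p2 <- fake_pair_row("a2", mate_seq = paste0(substring(g, 201, 296), "AAAAA"))
  expect_equal(detect_polyA(fake_region(p1), ref), 1L)
  expect_equal(detect_polyA(fake_region(p2), ref), 0L)
  # mapped mate whose A6 run matches the reference homopolymer -> not counted
  g2 <- g
  substr(g2, 1001, 1010) <- "AAAAAAAAAA"
  ref2 <- genome_reference(c(chrR = g2))
  mseq <- get_seq(ref2, "chrR", 950, 1051)
  p3 <- fake_pair_row("a3", mate_seq = mseq, mate_mapped = TRUE,
                      mate_chrom = "chrR", mate_start = 950L, mate_mapq = 60L,
                      category = "TL")
  expect_equal(detect_polyA(fake_region(p3), ref2), 0L)
  # same mapped run placed where the reference lacks it -> counted
  p4 <- fake_pair_row("a4", mate_seq = mseq, mate_mapped = TRUE,
                      mate_chrom = "chrR", mate_start = 2000L, mate_mapq = 60L,
                      category = "TL")
  expect_equal(detect_polyA(fake_region(p4), ref2), 1L)
  expect_equal(detect_polyA(fake_region(p1[0, ]), ref), 0L)
})

base_call <- function(ts_len = 120L) {
  data.frame(id = "td00001", sample = "s1", mei_id = "mei00001",
             target_chrom = "chrT", target_start = 1000L, target_end = 1010L,
             search_start = 500L, search_end = 1510L, tsd_seq = NA,
             source_chrom = "chrS", source_start = 5000L,
             source_end = 5000L + ts_len, source_strand = "+",
             ts_len = ts_len, ts_seq = NA, polya_reads = 2L,
             subfamily = NA, n_reads = 6L, mean_tm = 1, donor_class = NA,
             filters = "", pass = NA, stringsAsFactors = FALSE)
}

test_that("filters flag segdups, reference L1s and short TS", {
  segdup <- interval_track(data.frame(chrom = "chrT", start = 400L, end = 2000L),
                           "segdup")
  l1ann <- interval_track(data.frame(chrom = "chrT", start = 1200L, end = 1400L,
                                     subfamily = "L1PA4"), "repeat")
  aluann <- interval_track(data.frame(chrom = "chrT", start = 1200L, end = 1400L,
                                      subfamily = "AluY"), "repeat")
  c1 <- apply_filters(base_call(), segdups = segdup)
  expect_equal(c1$filters, "SEGDUP"); expect_false(c1$pass)
  c2 <- apply_filters(base_call(), repeats = l1ann)
  expect_equal(c2$filters, "REF_L1_AT_TARGET"); expect_false(c2$pass)
  # non-L1 repeat at the target does not trigger the filter
  c3 <- apply_filters(base_call(), repeats = aluann)
  expect_true(c3$pass)
  c4 <- apply_filters(base_call(ts_len = 49L))
  expect_equal(c4$filters, "SHORT_TS"); expect_false(c4$pass)
  c5 <- apply_filters(base_call(ts_len = 50L))
  expect_true(c5$pass)
  # pre-existing flags are preserved and combined
  cc <- base_call(ts_len = 30L); cc$filters <- "REPETITIVE_SOURCE"
  c6 <- apply_filters(cc, segdups = segdup)
  expect_equal(c6$filters, "REPETITIVE_SOURCE,SEGDUP,SHORT_TS")
})

test_that("donor classification uses a 5 kb flank", {
  call <- base_call()  # source chrS:[5000,5120)
  near <- interval_track(data.frame(chrom = "chrS", start = 1800L, end = 2100L,
                                    subfamily = "L1PA7"), "repeat")  # 2.9 kb away
  far <- interval_track(data.frame(chrom = "chrS", start = 10500L, end = 10900L,
                                   subfamily = "L1PA7"), "repeat")   # >5 kb away
  expect_equal(classify_donor(call, near), 2L)
  expect_equal(classify_donor(call, far), 1L)
  expect_equal(classify_donor(call, NULL), 1L)
  # exactly at the 5 kb boundary (half-open): start 10120 is within
  edge <- interval_track(data.frame(chrom = "chrS", start = 10119L, end = 10300L,
                                    subfamily = "L1X"), "repeat")
  expect_equal(classify_donor(call, edge), 2L)
})

test_that("call_transductions joins regions and clusters deterministically", {
  ref <- random_genome(20000, seed = 23, chroms = c("chrS", "chrT"))
  qn <- sprintf("q%02d", 1:6)
  pairs <- do.call(rbind, lapply(qn, fake_pair_row))
  region <- fake_region(pairs)
  starts <- 5000L + (0:5) * 40L
  realn <- fake_realn(qn, "chrS", starts, starts + 101L)
  calls <- call_transductions(list(region), realn, ref)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$pass)
  expect_equal(calls$source_chrom, "chrS")
  expect_equal(calls$ts_len, calls$source_end - calls$source_start)
  expect_identical(calls$ts_seq,
                   get_seq(ref, "chrS", calls$source_start, calls$source_end))
  # a cluster failing mean TM produces no call
  realn$tm <- c(1L, 1L, 9L, 9L, 9L, 9L)
  expect_equal(nrow(call_transductions(list(region), realn, ref)), 0L)
  # idempotence: identical inputs give identical output
  calls2 <- call_transductions(list(region), fake_realn(qn, "chrS", starts, starts + 101L), ref)
  expect_identical(calls, calls2)
})

test_that("merging collapses jittered duplicates and labels polymorphism", {
  # same event in 3 of 5 samples, targets within 20 bp
  one <- do.call(rbind, lapply(1:3, function(i) {
    cl <- base_call(); cl$sample <- paste0("s", i)
    cl$target_start <- cl$target_start + (i - 1L) * 10L
    cl$target_end <- cl$target_end + (i - 1L) * 10L
    cl
  }))
  m <- merge_across_samples(one, cohort = paste0("s", 1:5))
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_samples, 3L)
  expect_true(m$polymorphic)
  m2 <- merge_across_samples(one, cohort = paste0("s", 1:3))
  expect_false(m2$polymorphic)
  # two events 5 kb apart stay separate
  two <- rbind(base_call(), within(base_call(), {
    target_start <- target_start + 5000L; target_end <- target_end + 5000L
    id <- "td00002"
  }))
  expect_equal(nrow(merge_across_samples(two)), 2L)
  # 50 truth events, jittered +/-0-80 bp across 5 samples -> 50 merged calls
  set.seed(24)
  truth_pos <- sort(sample(seq(5000L, 5e6L, by = 15000L), 50))
  calls <- do.call(rbind, lapply(seq_along(truth_pos), function(i) {
    do.call(rbind, lapply(1:5, function(s) {
      cl <- base_call()
      jit <- sample(-80:80, 1)
      cl$sample <- paste0("s", s)
      cl$target_start <- truth_pos[i] + jit
      cl$target_end <- cl$target_start + 10L
      cl$source_start <- 10000L * i
      cl$source_end <- cl$source_start + 150L
      cl
    }))
  }))
  merged <- merge_across_samples(calls, cohort = paste0("s", 1:5))
  expect_equal(nrow(merged), 50L)
  expect_true(all(merged$n_samples == 5L))
})

test_that("tightening min_reads or max_mean_tm never increases PASS calls", {
  ref <- random_genome(80000, seed = 25, chroms = c("chrS", "chrT"))
  set.seed(26)
  regions <- list(); realn_all <- list()
  for (r in 1:6) {
    n <- sample(3:8, 1)
    qn <- sprintf("r%d_q%02d", r, seq_len(n))
    pairs <- do.call(rbind, lapply(qn, fake_pair_row))
    regions[[r]] <- fake_region(pairs, mei_start = 1000L + 300L * r,
                                mei_end = 1010L + 300L * r)
    starts <- sample(5000:30000, 1) + cumsum(c(0, sample(10:60, n - 1, TRUE)))
    realn_all[[r]] <- fake_realn(qn, "chrS", as.integer(starts),
                                 as.integer(starts + 101L),
                                 tms = sample(1:4, n, TRUE))
  }
  realn <- do.call(rbind, realn_all)
  n_pass <- function(cfg) sum(call_transductions(regions, realn, ref, config = cfg)$pass)
  base <- n_pass(caller_config())
  for (mr in 4:8)
    expect_lte(n_pass(caller_config(min_reads = mr)), base)
  prev <- base
  for (mt in c(3, 2.5, 2, 1.5, 1)) {
    cur <- n_pass(caller_config(max_mean_tm = mt))
    expect_lte(cur, prev)
    prev <- cur
  }
})
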