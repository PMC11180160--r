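test_that("depth profile counts aligned spans only", {
  ref <- reference_seq("r", strrep("A", 10))
  one <- aligned_reads("r1", 2, 7, 0, 0, "AAAAA")
  expect_equal(depth_profile(one, ref), c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0))
  none <- aligned_reads(character(0), integer(0), integer(0), integer(0),
                        integer(0), character(0))
  expect_equal(depth_profile(none, ref), integer(10))
  # clipped bases do not add depth
  clipped <- aligned_reads("r2", 2, 7, 2, 1, "GGAAAAAT")
  expect_equal(sum(depth_profile(clipped, ref)), 5)
  bad <- aligned_reads("r3", 8, 12, 0, 0, "AAAA")
  expect_error(depth_profile(bad, ref), "bounds")
})

test_that("depth profile matches a loop oracle and the simulated coverage", {
  set.seed(5)
  starts <- sample(0:180, 60, replace = TRUE)
  ends <- starts + sample(5:20, 60, replace = TRUE)
  aln <- aligned_reads(paste0("r", 1:60), starts, ends, 0, 0,
                       strrep("A", ends - starts))
  ref <- reference_seq("r", strrep("A", 200))
  expect_equal(depth_profile(aln, ref), hand_depth(starts, ends, 200))

  pair <- simulate_genome_pair(50000, c(20000, 21000), seed = 2)
  aln20 <- simulate_alignments(pair, "wildtype", depth = 20, seed = 3)
  d <- depth_profile(aln20, pair$reference)
  expect_lt(abs(mean(d) - 20) / 20, 0.1)
})

test_that("gap detection finds, merges and filters low-coverage runs", {
  g <- detect_gaps(c(5, 5, 0, 0, 0, 5), max_internal_depth = 0,
                   min_gap_len = 3, max_spike_len = 1)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(2, 5))
  expect_equal(g$internal_max_depth, 0L)

  # depth-3 spike inside a zero run: absorbed when counted as low depth
  spiky <- c(5, 0, 0, 3, 0, 0, 5)
  merged <- detect_gaps(spiky, max_internal_depth = 3, min_gap_len = 2,
                        max_spike_len = 1)
  expect_equal(c(merged$start, merged$end), c(1, 6))
  # a spike of width 1 is not strictly shorter than max_spike_len 1:
  # the run stays split and both halves fall below min_gap_len 3
  split <- detect_gaps(spiky, max_internal_depth = 0, min_gap_len = 3,
                       max_spike_len = 1)
  expect_equal(nrow(split), 0)
  # widening the tolerance merges through the spike
  wide <- detect_gaps(spiky, max_internal_depth = 0, min_gap_len = 3,
                      max_spike_len = 2)
  expect_equal(c(wide$start, wide$end), c(1, 6))

  all0 <- detect_gaps(rep(0L, 50), max_internal_depth = 0, min_gap_len = 10,
                      max_spike_len = 5)
  expect_equal(c(all0$start, all0$end), c(0, 50))

  short <- detect_gaps(c(5, 0, 0, 5), max_internal_depth = 0,
                       min_gap_len = 3, max_spike_len = 1)
  expect_equal(nrow(short), 0)
})

test_that("junction reads are selected by boundary proximity and clip length", {
  pair <- simulate_genome_pair(60000, c(25000, 30000), seed = 4)
  aln <- simulate_alignments(pair, depth = 20, seed = 5)
  depth <- depth_profile(aln, pair$reference)
  gaps <- detect_gaps(depth)
  expect_equal(nrow(gaps), 1)
  jr <- collect_junction_reads(aln, gaps[1, ], min_clip = 10)
  expect_gt(nrow(jr), 1)
  expect_true(all(jr$clip_suffix >= 10 | jr$clip_prefix >= 10))
  # every selected read's clipped tail crosses the simulated junction
  expect_true(all(jr$side %in% c("left", "right")))
  # reads far from the boundary, or unclipped at it, are excluded
  far <- aligned_reads("far", 1000, 1150, 0, 0, strrep("A", 150))
  expect_equal(nrow(collect_junction_reads(far, gaps[1, ], min_clip = 1)), 0)
  flush <- aligned_reads("flush", gaps$start[1] - 150, gaps$start[1], 0, 0,
                         strrep("A", 150))
  expect_equal(nrow(collect_junction_reads(flush, gaps[1, ], min_clip = 1)), 0)
})

test_that("greedy overlap assembly merges reads and reports failure", {
  a <- assemble_junction(c(a = "ACGTACGT", b = "ACGTTTTT"), min_overlap = 4)
  expect_true(a$success)
  expect_equal(a$contig, "ACGTACGTTTTT")

  # three staggered 30-mers tiling a 50-base truth with 20-base overlaps
  truth <- "ATGCGTACGTTAGCCATGGCATCGATCGATTGCCAGTACGGATCCGATAA"
  reads <- c(r1 = substr(truth, 1, 30), r2 = substr(truth, 11, 40),
             r3 = substr(truth, 21, 50))
  asm <- assemble_junction(reads, min_overlap = 15)
  expect_true(asm$success)
  expect_equal(asm$contig, truth)
  expect_equal(asm$support, 3)
  # read order must not matter
  asm2 <- assemble_junction(reads[c(3, 1, 2)], min_overlap = 15)
  expect_equal(asm2$contig, truth)

  fail <- assemble_junction(c(x = "AAAAAAAAAA", y = "CCCCCCCCCC"),
                            min_overlap = 4)
  expect_false(fail$success)
  expect_true(is.na(fail$contig))
  expect_error(assemble_junction("ACGT"), "two reads")
})

test_that("deletion calling anchors, left-aligns and classifies breakpoints", {
  ref <- reference_seq("r", "AAAACGTTTT")
  call <- call_deletion("AAAATTTT", ref, min_anchor = 3)
  expect_equal(call$deleted_interval, c(4, 6))
  expect_equal(call$length, 2)
  expect_equal(call$inserted_sequence, "")
  expect_equal(call$classification, "clean")

  # tandem AG at the breakpoint: deleting either AG copy gives the same
  # allele; enumerating placements by hand on CCTTG-AGAG-CAATT shows four
  # equivalent intervals [4,6), [5,7), [6,8), [7,9) (the GAGA run slides),
  # so the canonical call is the leftmost with 3 bases of microhomology
  ref2 <- reference_seq("r2", "CCTTGAGAGCAATT")
  call2 <- call_deletion("CCTTGAGCAATT", ref2, min_anchor = 4)
  expect_equal(call2$length, 2)
  expect_equal(call2$microhomology_len, 3)
  expect_equal(call2$deleted_interval,
               left_align_interval(ref2$sequence, c(7, 9)))
  expect_equal(call2$deleted_interval, c(4, 6))
  # idempotence of canonicalization: calling on the allele implied by the
  # left-aligned interval reproduces the same interval
  allele2 <- paste0(substr(ref2$sequence, 1, 5), substr(ref2$sequence, 8, 14))
  expect_equal(call_deletion(allele2, ref2, min_anchor = 4)$deleted_interval,
               call2$deleted_interval)

  # inserted bases between the anchors
  ref3 <- reference_seq(
    "r3", "TGACTGGTCAATGCGGCGTACCTGATCCGGATTACGCATGGATCGATTGC")
  contig3 <- paste0(substr(ref3$sequence, 1, 20), "TTTT",
                    substr(ref3$sequence, 41, 50))
  call3 <- call_deletion(contig3, ref3, min_anchor = 8)
  expect_equal(call3$classification, "with_insertion")
  expect_equal(call3$inserted_sequence, "TTTT")
  expect_equal(call3$deleted_interval, c(20, 40))

  # ambiguous anchoring is an error
  ref4 <- reference_seq("r4", strrep("ACGTACGTACGT", 4))
  expect_error(call_deletion(paste0("ACGTACGT", "ACGTACGT"), ref4,
                             min_anchor = 6), "ambiguous")
})

test_that("simulated deletions are recovered exactly through the pipeline", {
  pair <- simulate_genome_pair(100000, c(40000, 56020), seed = 7)
  aln <- simulate_alignments(pair, depth = 20, error_rate = 0, seed = 8)
  res <- detect_deletion(aln, pair$reference)
  expect_false(is.null(res$call))
  expect_equal(res$call$length, 16020)
  expect_equal(res$call$classification, "clean")
  truth <- left_align_interval(pair$reference$sequence,
                               pair$truth$deleted_interval)
  expect_equal(res$call$deleted_interval, truth)

  # wild-type reads: flat profile, no gap at default thresholds
  wt <- simulate_alignments(pair, "wildtype", depth = 20, seed = 9)
  expect_equal(nrow(detect_gaps(depth_profile(wt, pair$reference))), 0)
})

test_that("independent read sets from one allele give identical junctions", {
  pair <- simulate_genome_pair(60000, c(20000, 28000), seed = 21)
  calls <- lapply(c(22, 23), function(s) {
    aln <- simulate_alignments(pair, depth = 20, seed = s)
    detect_deletion(aln, pair$reference)$call
  })
  cmp <- junctions_identical(calls[[1]], calls[[2]], pair$reference)
  expect_true(cmp$identical)
  expect_length(cmp$mismatches, 0)
  # a self-comparison is trivially identical
  self <- junctions_identical(calls[[1]], calls[[1]], pair$reference)
  expect_true(self$identical)
  # perturbing the interval is detected and reported
  shifted <- calls[[2]]
  shifted$deleted_interval <- shifted$deleted_interval + 1L
  cmp2 <- junctions_identical(calls[[1]], shifted, pair$reference)
  expect_false(cmp2$identical)
  expect_match(cmp2$mismatches[1], "interval")
  other <- calls[[2]]
  other$reference_name <- "elsewhere"
  expect_error(junctions_identical(calls[[1]], other, pair$reference),
               "comparable")
})

test_that("in-silico PCR predicts amplicons with inclusive primer footprints", {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- "GATTACAGGATTACAG"
  rev <- "CCATGGTACCATGGTA" # applied as given; template carries its rc
  spacer <- strrep("A", 100)
  template <- paste0(fwd, spacer, rc(rev))
  amp <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, nchar(fwd) + 100 + nchar(rev))
  expect_equal(amp$start, 0)

  none <- insilico_pcr(strrep("ACGT", 100), fwd, rev)
  expect_equal(nrow(none), 0)
  expect_error(insilico_pcr(template, "ACGT", rev), "15 bases")
})

test_that("deletion brings distant primer sites into amplifiable range", {
  pair <- simulate_genome_pair(50000, c(20000, 36020), seed = 31)
  wt <- pair$reference$sequence
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # primers ~200 bp outside either flank of the deletion
  fwd <- substr(wt, 19801, 19820)
  rev <- rc(substr(wt, 36201, 36220))
  amp_wt <- insilico_pcr(wt, fwd, rev, max_amplicon = 3000)
  expect_equal(nrow(amp_wt), 0) # wild-type span 16,420 bp: too long
  amp_del <- insilico_pcr(pair$deletion_allele, fwd, rev, max_amplicon = 3000)
  expect_equal(nrow(amp_del), 1)
  # amplicon-length identity: deletion amplicon = wt span - deletion length
  wt_span <- 36220 - 19800
  expect_equal(amp_del$length, wt_span - pair$truth$length)
})

test_that("whole-allele differencing recovers the deletion call", {
  pair <- simulate_genome_pair(80000, c(30000, 46020), seed = 41)
  call <- diff_alleles(pair$reference, pair$deletion_allele)
  expect_equal(call$length, 16020)
  expect_equal(call$classification, "clean")
  expect_equal(call$deleted_interval,
               left_align_interval(pair$reference$sequence,
                                   pair$truth$deleted_interval))
})
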