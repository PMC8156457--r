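test_that("packaged reference has mitochondrial genome geometry", {
  ref <- mt_reference()
  expect_s3_class(ref, "MtReference")
  expect_identical(ref$length, 16569L)
  expect_identical(nchar(ref$sequence), 16569L)
  expect_true(ref$circular)
  expect_false(grepl("[^ACGTN]", ref$sequence))
})

test_that("load_reference validates its input", {
  one <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt"), one)
  ref <- load_reference(one, circular = FALSE)
  expect_identical(ref$length, 4L)
  expect_identical(ref$sequence, "ACGT")
  expect_false(ref$circular)

  two <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s2", "GGCC"), two)
  expect_error(load_reference(two), "ambiguous")

  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(load_reference(empty))
  expect_error(load_reference(tempfile()), "not found")
})

test_that("control-region annotation honours the origin wrap", {
  expect_setequal(annotate_position(16100), c("D-loop", "HV1"))
  expect_setequal(annotate_position(300), c("D-loop", "HV2"))
  expect_identical(annotate_position(1000), "other")
  expect_setequal(annotate_position(16500), "D-loop")  # wrap, past HV1
  expect_setequal(annotate_position(50), "D-loop")     # wrap, before HV2
  expect_error(annotate_position(0), "range")
  expect_error(annotate_position(16570), "range")
  regions <- mt_regions()
  expect_identical(regions$start[regions$label == "D-loop"], 16024L)
  expect_identical(regions$end[regions$label == "D-loop"], 576L)
  expect_true(regions$wraps_origin[regions$label == "D-loop"])
})

test_that("find_homopolymers reports maximal runs and merges at the origin", {
  ref <- mt_reference_from_string("ACGTTTTA", circular = FALSE)
  tr <- find_homopolymers(ref, 4L)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$start, 4L)
  expect_identical(tr$end, 7L)
  expect_identical(tr$base, "T")
  expect_identical(tr$run_length, 4L)

  expect_identical(nrow(find_homopolymers(
    mt_reference_from_string("AAAA", circular = FALSE), 5L)), 0L)
  expect_error(find_homopolymers(ref, 1L), "min_len")

  # circular: TT...TT across the origin merges into one run of 4
  circ <- mt_reference_from_string("TTACGTT", circular = TRUE)
  tr <- find_homopolymers(circ, 4L)
  expect_identical(nrow(tr), 1L)
  expect_true(tr$wraps)
  expect_identical(tr$start, 6L)
  expect_identical(tr$end, 2L)
  expect_identical(tr$run_length, 4L)
})

test_that("find_homopolymers matches a brute-force scan on random sequences", {
  set.seed(11)
  for (i in 1:300) {
    s <- random_seq(sample(20:600, 1))
    ml <- sample(2:5, 1)
    ref <- mt_reference_from_string(s, circular = FALSE)
    got <- find_homopolymers(ref, ml)
    want <- brute_homopolymers(s, ml, circular = FALSE)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$run_length, want$run_length)
    }
  }
})

test_that("packaged-reference homopolymer track matches the brute-force scan", {
  ref <- mt_reference()
  got <- find_homopolymers(ref, 4L)
  want <- brute_homopolymers(ref$sequence, 4L, circular = TRUE)
  expect_identical(nrow(got), nrow(want))
  expect_setequal(paste(got$start, got$end), paste(want$start, want$end))
})

test_that("homopolymer track is monotone in the length threshold", {
  set.seed(12)
  ref <- mt_reference_from_string(random_seq(2000), circular = TRUE)
  for (k in 2:5) {
    a <- find_homopolymers(ref, k)
    b <- find_homopolymers(ref, k + 1L)
    expect_true(all(paste(b$start, b$end) %in% paste(a$start, a$end)))
    expect_true(sum(a$run_length) <= ref$length)
    # non-overlap among non-wrapping runs
    nw <- a[!a$wraps, , drop = FALSE]
    if (nrow(nw) > 1L) {
      expect_true(all(nw$start[-1L] > nw$end[-nrow(nw)]))
    }
  }
})

test_that("run membership distinguishes SNVs from indels (adjacency)", {
  ref <- mt_reference_from_string("ACGTTTTA", circular = FALSE)
  tr <- find_homopolymers(ref, 4L)
  expect_true(position_in_run(tr, 5, "SNV"))
  expect_false(position_in_run(tr, 3, "SNV"))
  expect_true(position_in_run(tr, 3, "ins"))   # adjacent to run start
  expect_true(position_in_run(tr, 8, "del"))   # adjacent to run end
  expect_false(position_in_run(tr, 1, "SNV"))
  expect_false(position_in_run(tr, 2, "del"))
  expect_error(position_in_run(tr, 99, "SNV"), "range")
  expect_identical(homopolymer_run_length(tr, 5, "SNV"), 4L)
  expect_identical(homopolymer_run_length(tr, 1, "SNV"), 0L)

  # adjacency across the circular origin
  circ <- mt_reference_from_string("TTACGTT", circular = TRUE)
  trc <- find_homopolymers(circ, 4L)
  expect_true(position_in_run(trc, 1, "SNV"))   # inside wrapped run
  expect_true(position_in_run(trc, 5, "ins"))   # before wrapped run start
  expect_true(position_in_run(trc, 3, "del"))   # after wrapped run end
  expect_false(position_in_run(trc, 4, "SNV"))
})

test_that("homopolymer BED export is 0-based half-open and splits wrapped runs", {
  circ <- mt_reference_from_string("TTACGTT", circular = TRUE)
  p <- tempfile(fileext = ".bed")
  write_homopolymer_bed(find_homopolymers(circ, 4L), p)
  bed <- read.delim(p, header = FALSE)
  expect_identical(nrow(bed), 2L)
  expect_identical(bed$V2, c(5L, 0L))
  expect_identical(bed$V3, c(7L, 2L))
})
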