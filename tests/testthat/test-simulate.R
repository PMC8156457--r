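test_that("leakage weight is flat for EDTA and grows after the threshold for Streck", {
  p <- list(w0 = 0.05, threshold_days = 3, k = 0.5)
  expect_equal(leakage_weight("EDTA", 10, p), 0.05)
  expect_equal(leakage_weight("EDTA", 1, p), leakage_weight("EDTA", 14, p))
  expect_equal(leakage_weight("Streck", 3, p), 0.05)  # continuity
  expect_equal(leakage_weight("Streck", 5, p), 0.05 * exp(1))
  expect_equal(leakage_weight("Streck", 1, p), 0.05)
  w <- leakage_weight("Streck", 0:14, p)
  expect_true(all(diff(w) >= 0))
  expect_error(leakage_weight("Streck", -1, p), ">= 0")
})

test_that("foetal fraction dilution is the expected closed form", {
  expect_equal(dilute_foetal_fraction(0.10, 0), 0.10)
  expect_equal(dilute_foetal_fraction(0.10, 1), 0.05)
  grid <- seq(0, 5, by = 0.25)
  expect_true(all(diff(dilute_foetal_fraction(0.08, grid)) < 0))
  expect_error(dilute_foetal_fraction(1.2, 0))
})

test_that("homopolymer indel error rate is non-decreasing and capped", {
  r <- homopolymer_indel_rate(2:15)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r < 0.5))
  expect_identical(r[1], 0)  # no errors below length 3
})

test_that("draw_haplotype unions defining variants along the path", {
  tree <- load_haplotree()
  root_set <- tree$cumulative[[tree$root]]
  expect_length(root_set, 0)

  # independent path walk: follow parent pointers in the raw file
  raw <- read.delim(system.file("extdata", "haplotree_synthetic.tsv",
                                package = "cfmito"),
                    stringsAsFactors = FALSE)
  walk <- function(name) {
    keys <- character(0)
    while (name != "") {
      row <- raw[raw$name == name, ]
      toks <- strsplit(row$variants, ",")[[1]]
      keys <- c(keys, toks[nzchar(toks)])
      name <- ifelse(is.na(row$parent), "", row$parent)
    }
    unique(keys)
  }
  for (nm in sample(raw$name[raw$parent != "" & !is.na(raw$parent)], 8)) {
    hv <- draw_haplotype(tree, nm)
    expect_setequal(paste0(hv$pos, hv$alt), walk(nm))
  }
  expect_error(draw_haplotype(tree, "ZZZ9"), "unknown")
})

test_that("fragment origins follow the mixture weights", {
  set.seed(21)
  ref <- mt_reference()
  cfg <- sim_config(n_samples = 1, substitution_error_rate = 0,
                    homopolymer_indel_base_rate = 0)
  tv <- mk_truth_variants(100, substr(ref$sequence, 100, 100), "T")
  truth <- mk_truth(tv, weights = c(maternal_cf = 0.6, foetal_cf = 0.1,
                                    leukocyte = 0.3),
                    mean_depth = 10000 * 170 / ref$length)
  smp <- simulate_sample(truth, cfg, ref)
  n <- nrow(smp$fragments)
  p_hat <- mean(smp$fragments$origin == "leukocyte")
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(p_hat - 0.3), 3 * se)

  # zero foetal weight produces no foetal fragments
  truth0 <- mk_truth(tv, weights = c(maternal_cf = 0.7, foetal_cf = 0,
                                     leukocyte = 0.3), mean_depth = 5)
  smp0 <- simulate_sample(truth0, cfg, ref)
  expect_false(any(smp0$fragments$origin == "foetal_cf"))
  expect_error(simulate_sample(truth0, cfg, ref, mean_depth = 0), "> 0")
})

test_that("noiseless homoplasmic simulation is fully penetrant and recoverable", {
  set.seed(22)
  ref <- mt_reference()
  cfg <- sim_config(substitution_error_rate = 0,
                    homopolymer_indel_base_rate = 0)
  pos <- c(500L, 4000L, 9000L, 15000L)
  tv <- mk_truth_variants(pos, substring(ref$sequence, pos, pos), "T")
  tv$alt <- ifelse(tv$ref == "T", "A", "T")
  truth <- mk_truth(tv, mean_depth = 8)
  smp <- simulate_sample(truth, cfg, ref)

  # every overlapping fragment carries every truth variant
  L <- ref$length
  for (j in seq_along(pos)) {
    off <- (pos[j] - smp$fragments$start) %% L
    cover <- smp$fragments$frag_id[off < smp$fragments$length]
    carry <- smp$events$frag_id[smp$events$pos == pos[j]]
    expect_setequal(cover, carry)
  }

  # a permissive caller recovers exactly the truth set at covered sites
  pl <- build_pileup(smp, ref)
  calls <- call_variants(pl, ref, min_alt_call = 1L)
  covered <- pos[pl$depth[pos] >= 1L]
  expect_setequal(calls$pos, covered)
  expect_true(all(calls$ref_reads == 0L))
})

test_that("the cohort simulation is reproducible under a fixed seed", {
  cfg <- sim_config(n_samples = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$samples[[2]]$fragments, b$samples[[2]]$fragments)
  expect_identical(a$samples[[2]]$events, b$samples[[2]]$events)
})

test_that("cohort truth respects maternal inheritance and mixture closure", {
  set.seed(31)
  cfg <- sim_config(n_samples = 12, seed = 31)
  truths <- simulate_truth_samples(cfg)
  for (tr in truths) {
    expect_equal(sum(tr$mixture_weights), 1, tolerance = 1e-12)
    expect_true(all(tr$variants$het > 0 & tr$variants$het <= 1))
    # foetal de-novo disabled by default: foetal pool = maternal pool
    expect_false(any(tr$variants$origin == "foetal_denovo"))
    expect_equal(tr$foetal_fraction,
                 dilute_foetal_fraction(tr$ff0, tr$leaked))
  }
})

test_that("buffy-coat pairs share more variants when shipped as whole blood", {
  set.seed(41)
  ref <- mt_reference()
  hp3 <- find_homopolymers(ref, 3L)
  cfg <- sim_config(substitution_error_rate = 0,
                    homopolymer_indel_base_rate = 0)
  tree <- load_haplotree()

  shared_for <- function(tube, days) {
    haplo <- draw_haplotype(tree, "H1a")
    haplo$ref <- substring(ref$sequence, haplo$pos, haplo$pos)
    bad <- haplo$alt == haplo$ref
    haplo$alt[bad] <- ifelse(haplo$ref[bad] == "A", "G", "A")
    pr_pos <- seq(200L, 1600L, by = 100L)
    pr <- mk_truth_variants(pr_pos,
                            substring(ref$sequence, pr_pos, pr_pos), "T",
                            origin = rep(c("cf_private", "leuk_private"),
                                         length.out = length(pr_pos)))
    pr$alt <- ifelse(pr$ref == "T", "C", "T")
    tv <- rbind(mk_truth_variants(haplo$pos, haplo$ref, haplo$alt), pr)
    leaked <- leakage_weight(tube, days, cfg$leakage)
    w <- leaked / (1 + leaked)
    truth <- mk_truth(tv, weights = c(maternal_cf = 0.9 * (1 - w),
                                      foetal_cf = 0.1 * (1 - w),
                                      leukocyte = w),
                      mean_depth = 20, tube = tube, days = days)
    pair <- simulate_buffy_pair(truth, cfg, ref, hp3)
    kept <- lapply(pair, function(s) {
      calls <- call_variants(build_pileup(s, ref), ref)
      run_cascade(calls, ref)$kept
    })
    shared_variants(kept$cfdna, kept$buffy)
  }

  streck <- mean(replicate(4, shared_for("Streck", 12)))
  edta <- mean(replicate(4, shared_for("EDTA", 12)))
  expect_gt(streck / edta, 1)
})

test_that("sample output formats round-trip and parse", {
  set.seed(51)
  ref <- mt_reference()
  cfg <- sim_config()
  tv <- mk_truth_variants(c(100L, 9906L), c("G", "G"), c("A", ""),
                          type = c("SNV", "del"))
  tv$ref <- substring(ref$sequence, tv$pos, tv$pos)
  tv$alt[1] <- ifelse(tv$ref[1] == "A", "G", "A")
  truth <- mk_truth(tv, mean_depth = 2)
  smp <- simulate_sample(truth, cfg, ref)

  sam <- tempfile(fileext = ".sam")
  write_sam(smp, ref, sam)
  lines <- readLines(sam)
  expect_identical(lines[2], sprintf("@SQ\tSN:chrM\tLN:%d", ref$length))
  aln <- strsplit(lines[-(1:2)], "\t")
  # SEQ length always matches the CIGAR M length
  for (f in aln) {
    expect_identical(nchar(f[10]), as.integer(sub("M", "", f[6])))
  }

  vcfp <- tempfile(fileext = ".vcf")
  write_truth_vcf(truth, ref, vcfp)
  vl <- readLines(vcfp)
  expect_true(any(grepl("^##contig=<ID=chrM,length=16569>", vl)))
  body <- vl[!startsWith(vl, "#")]
  expect_identical(length(body), nrow(tv))
  expect_true(all(grepl("ORIGIN=shared;HET=", body)))

  pfx <- tempfile()
  write_fragments_tsv(smp, pfx)
  back <- read_fragments_tsv(pfx, smp$sample_id)
  expect_equal(back$fragments, smp$fragments)
  expect_equal(back$events[, c("pos", "ref", "alt", "type")],
               smp$events[, c("pos", "ref", "alt", "type")])
})
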