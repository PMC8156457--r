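mk_toy_cohort <- mk_toy_cohort_acc

test_that("frequency spectrum equals column means of the presence matrix", {
  set.seed(111)
  for (rep in 1:25) {
    co <- mk_toy_cohort(sample(3:12, 1), sample(5:40, 1))
    spec <- frequency_spectrum(co)
    want <- colMeans(co$presence)
    expect_equal(spec$frequency, unname(want[spec$key]))
    expect_true(all(spec$frequency > 0 & spec$frequency <= 1))
    expect_true(all(diff(spec$frequency) <= 0))
  }

  # 3 samples, variant carried by 1 -> 1/3; by all -> 1
  sets <- list(
    a = data.frame(hgvs = c("m.5A>G", "m.9A>G"), pos = c(5L, 9L), ref = "A",
                   alt = "G", type = "SNV", stringsAsFactors = FALSE),
    b = data.frame(hgvs = "m.9A>G", pos = 9L, ref = "A", alt = "G",
                   type = "SNV", stringsAsFactors = FALSE),
    c = data.frame(hgvs = "m.9A>G", pos = 9L, ref = "A", alt = "G",
                   type = "SNV", stringsAsFactors = FALSE))
  spec <- frequency_spectrum(build_cohort(sets))
  expect_equal(spec$frequency[spec$key == "m.5A>G"], 1 / 3)
  expect_equal(spec$frequency[spec$key == "m.9A>G"], 1)
})

test_that("genome bins use 1-kb sections with a long final bin", {
  v <- data.frame(pos = c(1L, 1000L, 1001L, 16100L, 16569L))
  b <- genome_bins(v)
  expect_identical(unname(b["bin1"]), 2L)
  expect_identical(unname(b["bin2"]), 1L)
  expect_identical(unname(b["bin16"]), 2L)
  expect_identical(sum(b), nrow(v))  # conservation
  expect_error(genome_bins(data.frame(pos = 0L)), ">= 1")

  set.seed(112)
  for (rep in 1:25) {
    pos <- sample(16569L, sample(10:200, 1), replace = TRUE)
    got <- genome_bins(data.frame(pos = pos))
    want <- vapply(1:16, function(k) {
      lo <- (k - 1L) * 1000L + 1L
      hi <- if (k == 16L) 16569L else k * 1000L
      sum(pos >= lo & pos <= hi)
    }, integer(1))
    expect_identical(unname(got), want)
  }
})

test_that("regional intersections equal brute-force membership tallies", {
  set.seed(113)
  regions <- c("Central", "Northwestern", "Volga-Ural", "Yakutia")
  for (rep in 1:25) {
    co <- mk_toy_cohort(sample(8:16, 1), sample(10:50, 1), regions)
    present <- intersect(regions, co$meta$region)
    if (length(present) < 2) next
    venn <- region_intersection(co, present)
    expect_identical(sum(venn$cells), venn$total)  # conservation
    # brute force: for each variant, find its exact region membership
    all_keys <- unique(unlist(venn$sets))
    want <- table(vapply(all_keys, function(k) {
      paste(present[vapply(present, function(r) k %in% venn$sets[[r]],
                           logical(1))], collapse = "&")
    }, character(1)))
    expect_identical(as.integer(venn$cells[names(want)]),
                     as.integer(want))
  }

  co <- mk_toy_cohort(6, 20, c("Central", "Northwestern"))
  expect_error(region_intersection(co, c("Central", "Yakutia")),
               "zero samples")
})

test_that("identical and disjoint region sets produce degenerate Venn cells", {
  sets <- list(
    a = data.frame(hgvs = "m.5A>G", pos = 5L, ref = "A", alt = "G",
                   type = "SNV", stringsAsFactors = FALSE),
    b = data.frame(hgvs = "m.5A>G", pos = 5L, ref = "A", alt = "G",
                   type = "SNV", stringsAsFactors = FALSE))
  manifest <- data.frame(sample_id = c("a", "b"),
                         region = c("Central", "Yakutia"))
  venn <- region_intersection(build_cohort(sets, manifest),
                              c("Central", "Yakutia"))
  expect_identical(unname(venn$cells["Central&Yakutia"]), 1L)
  expect_identical(venn$total, 1L)

  sets$b <- data.frame(hgvs = "m.7A>G", pos = 7L, ref = "A", alt = "G",
                       type = "SNV", stringsAsFactors = FALSE)
  venn2 <- region_intersection(build_cohort(sets, manifest),
                               c("Central", "Yakutia"))
  expect_true(is.na(venn2$cells["Central&Yakutia"]))
  expect_identical(venn2$total, 2L)
})

test_that("variant-count normalisation is division by mtDNA content", {
  expect_equal(normalize_variant_count(0, 1e-4), 0)
  expect_equal(normalize_variant_count(10, 2e-4), 50000)
  expect_equal(normalize_variant_count(10, 4e-4),
               normalize_variant_count(10, 2e-4) / 2)
  expect_error(normalize_variant_count(10, 0), "> 0")
})

test_that("shared-variant counts are exact set intersections", {
  a <- sprintf("m.%dA>G", 1:7)
  expect_identical(shared_variants(a, a), 7L)
  expect_identical(shared_variants(a, sprintf("m.%dC>T", 8:9)), 0L)
  set.seed(114)
  for (rep in 1:20) {
    x <- sample(sprintf("m.%dA>G", 1:50), 20)
    y <- sample(sprintf("m.%dA>G", 1:50), 20)
    expect_identical(shared_variants(x, y), length(intersect(x, y)))
  }
})

test_that("top variants rank by frequency and honour the ancestral list", {
  anc <- load_ancestral_variants()
  expect_setequal(anc, c("m.750A>G", "m.2706A>G", "m.263A>G", "m.15326A>G",
                         "m.9769delT", "m.12272delA"))

  sets <- list(
    a = data.frame(hgvs = c("m.750A>G", "m.100A>G"), pos = c(750L, 100L),
                   ref = "A", alt = "G", type = "SNV",
                   stringsAsFactors = FALSE),
    b = data.frame(hgvs = c("m.750A>G", "m.100A>G"), pos = c(750L, 100L),
                   ref = "A", alt = "G", type = "SNV",
                   stringsAsFactors = FALSE),
    c = data.frame(hgvs = "m.200A>G", pos = 200L, ref = "A", alt = "G",
                   type = "SNV", stringsAsFactors = FALSE))
  co <- build_cohort(sets)
  top <- top_variants(co, k = 5)
  expect_false("m.750A>G" %in% top$key)
  expect_identical(top$key[1], "m.100A>G")
  # ranking equals the sorted spectrum minus ancestral rows
  spec <- frequency_spectrum(co)
  expect_identical(top$key, spec$key[!spec$key %in% anc][1:2])

  # ancestral-only cohort with exclusion on -> empty
  only_anc <- list(a = sets$a[1, ], b = sets$b[1, ])
  expect_identical(nrow(top_variants(build_cohort(only_anc), k = 5)), 0L)
})
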