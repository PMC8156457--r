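# shared fixtures: built in code, no binary data

# independent brute-force homopolymer scan (explicit character walk, used
# as the oracle for find_homopolymers)
brute_homopolymers <- function(s, min_len, circular = FALSE) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(start = i, end = j, base = ch[i],
                                      len = j - i + 1L, wraps = FALSE)
    i <- j + 1L
  }
  if (circular && length(runs) >= 2L &&
      runs[[1L]]$base == runs[[length(runs)]]$base) {
    first <- runs[[1L]]; last <- runs[[length(runs)]]
    runs[[1L]] <- list(start = last$start, end = first$end,
                       base = first$base, len = first$len + last$len,
                       wraps = TRUE)
    runs[[length(runs)]] <- NULL
  }
  runs <- Filter(function(r) r$len >= min_len, runs)
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r$start, end = r$end, base = r$base,
               run_length = r$len, wraps = r$wraps,
               stringsAsFactors = FALSE)
  }))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# MtVariant rows with sensible defaults for filter tests
mk_var <- function(pos, ref = "A", alt = "G", type = "SNV", depth = 20L,
                   alt_reads = 10L, ref_reads = depth - alt_reads) {
  v <- data.frame(pos = as.integer(pos), ref = ref, alt = alt, type = type,
                  depth = as.integer(depth),
                  alt_reads = as.integer(alt_reads),
                  ref_reads = as.integer(ref_reads),
                  stringsAsFactors = FALSE)
  v$het_fraction <- v$alt_reads / (v$alt_reads + v$ref_reads)
  v$hgvs <- hgvs_name(v)
  v$hp_run_length <- 0L
  v$flag_low_depth <- FALSE
  v$flag_homopolymer <- FALSE
  v$flag_low_alt <- FALSE
  v$het_class <- "unclassified"
  v
}

# hand-built ground-truth sample for targeted simulations
mk_truth <- function(variants, weights = c(maternal_cf = 0.85,
                                           foetal_cf = 0.1,
                                           leukocyte = 0.05),
                     mean_depth = 10, sample_id = "T0001",
                     tube = "EDTA", days = 1L) {
  structure(list(sample_id = sample_id, region = "Central",
                 tube_type = tube, transport_days = days,
                 haplogroup = "H1a", variants = variants,
                 mixture_weights = weights, ff0 = 0.1, leaked = 0.05,
                 foetal_fraction = 0.095, mean_depth = mean_depth,
                 total_reads = 3e6), class = "TruthSample")
}

mk_truth_variants <- function(pos, ref, alt, origin = "shared", het = 1,
                              type = "SNV") {
  data.frame(pos = as.integer(pos), ref = ref, alt = alt, type = type,
             origin = origin, het = het, stringsAsFactors = FALSE)
}

# random toy cohort for set-algebra oracle checks
mk_toy_cohort_acc <- function(n_samples, n_variants, regions = NULL) {
  keys <- sprintf("m.%dA>G", sample(seq_len(16000), n_variants))
  sets <- lapply(seq_len(n_samples), function(i) {
    carried <- keys[runif(n_variants) < 0.4]
    pos <- as.integer(sub("^m\\.(\\d+).*$", "\\1", carried))
    data.frame(hgvs = carried, pos = pos,
               ref = rep("A", length(carried)),
               alt = rep("G", length(carried)),
               type = rep("SNV", length(carried)),
               stringsAsFactors = FALSE)
  })
  names(sets) <- sprintf("s%03d", seq_len(n_samples))
  manifest <- data.frame(sample_id = names(sets),
                         region = if (is.null(regions)) "Central"
                                  else sample(regions, n_samples,
                                              replace = TRUE),
                         stringsAsFactors = FALSE)
  build_cohort(sets, manifest)
}

# small tree file for error-path tests
write_tree_file <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
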