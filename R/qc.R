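# Per-sample mtDNA quantification and contamination screening.

#' Per-sample mtDNA quality control
#'
#' Computes the per-sample mtDNA quantification used for quality control
#' and contamination screening: mtDNA content (ratio of mitochondrial
#' reads to total reads), fraction of the mitochondrial genome covered at
#' depth >= 1, and mean per-position depth (circular wrap handled).
#'
#' @param sample A sample object with a `fragments` data.frame (e.g. from
#'   [simulate_sample()]).
#' @param total_reads Total (nuclear + mitochondrial) reads of the sample.
#' @param ref An `MtReference`.
#' @param meta Optional named list merged into the output row (tube type,
#'   transport days, foetal fraction, ...).
#' @return One-row data.frame with `sample_id`, `total_reads`, `mt_reads`,
#'   `mt_content`, `coverage_fraction`, `mean_depth` plus any metadata.
#' @export
compute_qc <- function(sample, total_reads, ref = mt_reference(),
                       meta = NULL) {
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a positive count")
  }
  mt_reads <- nrow(sample$fragments)
  if (total_reads < mt_reads) {
    stop("total_reads must be at least the mitochondrial fragment count")
  }
  depth <- fragment_depth(sample$fragments, ref$length)
  out <- data.frame(
    sample_id = if (!is.null(sample$sample_id)) sample$sample_id else NA,
    total_reads = total_reads, mt_reads = mt_reads,
    mt_content = mt_reads / total_reads,
    coverage_fraction = mean(depth >= 1L),
    mean_depth = mean(depth),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

#' Expected genome coverage at a given mean depth
#'
#' Poisson (Lander--Waterman) approximation of the fraction of reference
#' positions covered at least once when fragments are placed uniformly at
#' random: `1 - exp(-c)` for mean depth `c`. Used for QC expectations, not
#' inference.
#'
#' @param mean_depth Non-negative mean depth (vectorised).
#' @return Expected covered fraction in `[0, 1)`.
#' @export
expected_coverage <- function(mean_depth) {
  if (any(mean_depth < 0)) stop("mean depth must be >= 0")
  1 - exp(-mean_depth)
}

#' Simulate genome coverage under uniform fragment placement
#'
#' Places `round(mean_depth * ref_length / fragment_len)` fragments of
#' fixed length uniformly at random on the circular reference and returns
#' the covered fraction of each simulated sample. Companion to
#' [expected_coverage()] for checking the coverage--depth relationship.
#'
#' @param mean_depth Target mean depth (x).
#' @param n_samples Number of simulated samples.
#' @param fragment_len Fragment length in bp.
#' @param ref_length Reference length in bp.
#' @return Numeric vector (`n_samples`) of covered fractions.
#' @export
simulate_coverage <- function(mean_depth, n_samples = 200L,
                              fragment_len = 170L, ref_length = 16569L) {
  n_frag <- round(mean_depth * ref_length / fragment_len)
  vapply(seq_len(n_samples), function(i) {
    fr <- data.frame(start = sample.int(ref_length, n_frag, replace = TRUE),
                     length = rep(as.integer(fragment_len), n_frag))
    mean(fragment_depth(fr, ref_length) >= 1L)
  }, numeric(1))
}

#' Classify samples by mtDNA content
#'
#' Assigns each sample to a low/medium/high mtDNA-content class. Default
#' boundaries are the cohort tertiles of `mt_content`; explicit cutoffs
#' override them. Values tied with a boundary fall into the lower class;
#' an all-equal cohort is assigned "medium" throughout.
#'
#' @param mt_content Numeric vector of per-sample mtDNA content.
#' @param cutoffs Optional length-2 numeric vector `(c1, c2)`: low is
#'   `<= c1`, medium `(c1, c2]`, high `> c2`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_mt_content <- function(mt_content, cutoffs = NULL) {
  if (!length(mt_content)) stop("cohort is empty")
  lv <- c("low", "medium", "high")
  if (is.null(cutoffs)) {
    if (length(unique(mt_content)) == 1L) {
      return(factor(rep("medium", length(mt_content)), levels = lv))
    }
    cutoffs <- stats::quantile(mt_content, c(1 / 3, 2 / 3), type = 1,
                               names = FALSE)
  }
  stopifnot(length(cutoffs) == 2L, cutoffs[1] <= cutoffs[2])
  cls <- ifelse(mt_content <= cutoffs[1], "low",
                ifelse(mt_content <= cutoffs[2], "medium", "high"))
  factor(cls, levels = lv)
}

#' Rank-based comparison of groups
#'
#' Kruskal--Wallis rank-sum test (tie-corrected H, chi-square reference
#' with `g - 1` degrees of freedom) as used for all cohort group
#' comparisons; p-values are reported per comparison without
#' multiple-testing correction.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 non-empty
#'   groups).
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
compare_groups <- function(values, groups) {
  groups <- if (is.factor(groups)) groups else as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("all groups must be non-empty")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}
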