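# Pileup construction and the permissive frequency caller.
#
# A permissive pileup caller stands in for a full somatic caller: it emits
# every non-reference allele with minimal read support and leaves all
# quality control to the downstream filtration cascade, where the
# screening thresholds live.

#' Per-position sequencing depth from fragments
#'
#' Accumulates fragment intervals into a depth vector over the circular
#' reference; fragments spanning the origin contribute to both ends.
#'
#' @param fragments Data.frame with columns `start` and `length`.
#' @param ref_length Reference length in bp.
#' @return Integer vector of length `ref_length`.
#' @export
fragment_depth <- function(fragments, ref_length) {
  L <- as.integer(ref_length)
  delta <- integer(L + 1L)
  if (nrow(fragments)) {
    if (any(fragments$start < 1L | fragments$start > L)) {
      stop("fragment start outside reference after wrap normalisation")
    }
    ends <- fragments$start + fragments$length - 1L
    wrap <- ends > L
    # non-wrapping part
    s1 <- fragments$start
    e1 <- ifelse(wrap, L, ends)
    add <- tabulate(s1, nbins = L + 1L)
    sub <- tabulate(pmin(e1 + 1L, L + 1L), nbins = L + 1L)
    delta <- delta + add - sub
    if (any(wrap)) {
      e2 <- ends[wrap] - L
      delta <- delta + tabulate(rep(1L, sum(wrap)), nbins = L + 1L) -
        tabulate(pmin(e2 + 1L, L + 1L), nbins = L + 1L)
    }
  }
  cumsum(delta)[seq_len(L)]
}

#' Build a pileup from simulated or parsed fragments
#'
#' Computes per-position depth and aggregated non-reference allele counts.
#' Insertions are keyed to their anchor position; deletions to the first
#' deleted base.
#'
#' @param sample A list with `fragments` and `events` (as produced by
#'   [simulate_sample()] or [read_fragments_tsv()]).
#' @param ref An `MtReference`.
#' @return An object of class `mt_pileup`: list with `depth` (integer
#'   vector) and `alleles` (data.frame: `pos`, `ref`, `alt`, `type`,
#'   `count`).
#' @export
build_pileup <- function(sample, ref) {
  depth <- fragment_depth(sample$fragments, ref$length)
  ev <- sample$events
  if (nrow(ev)) {
    key <- paste(ev$pos, ev$ref, ev$alt, ev$type, sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    alleles <- data.frame(
      pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
      ref = vapply(parts, `[[`, character(1), 2L),
      alt = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "",
                   character(1)),
      type = vapply(parts, function(p) p[[length(p)]], character(1)),
      count = as.integer(agg$Freq),
      stringsAsFactors = FALSE
    )
    alleles <- alleles[order(alleles$pos, alleles$alt), , drop = FALSE]
    rownames(alleles) <- NULL
  } else {
    alleles <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), type = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(depth = depth, alleles = alleles), class = "mt_pileup")
}

#' Call variants from a pileup
#'
#' Permissive frequency-based caller: one variant record per (position,
#' non-reference allele) with at least `min_alt_call` supporting reads.
#' No filters are applied here; see [run_cascade()].
#'
#' @param pileup An `mt_pileup`.
#' @param ref An `MtReference` (for HGVS-style naming).
#' @param min_alt_call Minimum alternative-allele reads to emit a call.
#' @return Data.frame of `MtVariant` records: `pos`, `ref`, `alt`, `type`,
#'   `depth`, `alt_reads`, `ref_reads`, `het_fraction`, `hgvs`,
#'   `hp_run_length` (0 until the homopolymer filter runs) and logical
#'   filter-flag columns (all `FALSE`).
#' @export
call_variants <- function(pileup, ref, min_alt_call = 2L) {
  al <- pileup$alleles
  if (nrow(al) == 0L) return(.empty_variants())
  depth <- pileup$depth[al$pos]
  alt_total <- stats::ave(al$count, al$pos, FUN = sum)
  keep <- al$count >= min_alt_call
  v <- data.frame(
    pos = al$pos[keep], ref = al$ref[keep], alt = al$alt[keep],
    type = al$type[keep], depth = depth[keep],
    alt_reads = al$count[keep],
    ref_reads = pmax(depth[keep] - alt_total[keep], 0L),
    stringsAsFactors = FALSE
  )
  v$het_fraction <- v$alt_reads / (v$alt_reads + v$ref_reads)
  v$hgvs <- hgvs_name(v)
  v$hp_run_length <- 0L
  v$flag_low_depth <- FALSE
  v$flag_homopolymer <- FALSE
  v$flag_low_alt <- FALSE
  v$het_class <- "unclassified"
  rownames(v) <- NULL
  v
}

.empty_variants <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             type = character(0), depth = integer(0), alt_reads = integer(0),
             ref_reads = integer(0), het_fraction = numeric(0),
             hgvs = character(0), hp_run_length = integer(0),
             flag_low_depth = logical(0), flag_homopolymer = logical(0),
             flag_low_alt = logical(0), het_class = character(0),
             stringsAsFactors = FALSE)
}
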