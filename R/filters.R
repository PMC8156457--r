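# The two-step filtration cascade and heteroplasmy classification.
#
# Thresholds follow the screening protocol the package implements:
# variants with sequencing depth < 5 are removed; variants within
# homopolymers of length >= 4 are removed (with a stricter >= 3 mode for
# indel reporting); an optional third step removes variants with fewer
# than 4 reads supporting the alternative allele. Flags are independent
# predicates, so the kept set does not depend on filter order.

#' HGVS-style variant name
#'
#' `m.{pos}{ref}>{alt}` for SNVs, `m.{pos}del{ref}` for single-base
#' deletions named at the first deleted base, `m.{pos}ins{alt}` for
#' insertions anchored at the preceding base.
#'
#' @param variants Data.frame with columns `pos`, `ref`, `alt`, `type`.
#' @return Character vector of names.
#' @export
hgvs_name <- function(variants) {
  ifelse(variants$type == "SNV",
         sprintf("m.%d%s>%s", variants$pos, variants$ref, variants$alt),
         ifelse(variants$type == "del",
                sprintf("m.%ddel%s", variants$pos, variants$ref),
                sprintf("m.%dins%s", variants$pos, variants$alt)))
}

#' Depth filter
#'
#' Flags variants whose total sequencing depth (reference plus
#' alternative reads) is below `min_depth`.
#'
#' @param variants `MtVariant` data.frame.
#' @param min_depth Minimum total depth to keep (default 5).
#' @return The data.frame with `flag_low_depth` set.
#' @export
filter_depth <- function(variants, min_depth = 5L) {
  variants$flag_low_depth <- variants$depth < min_depth
  variants
}

#' Homopolymer filter
#'
#' Flags variants associated with homopolymer runs: SNVs when the
#' position lies inside a run, indels when inside or immediately adjacent
#' to a run boundary (left-alignment places run indels at the edge).
#' Separate tracks can be supplied for SNVs and indels, supporting the
#' stricter >= 3 indel mode used for indel reporting next to the standard
#' >= 4 cascade.
#'
#' @param variants `MtVariant` data.frame.
#' @param snv_track `HomopolymerTrack` applied to SNVs.
#' @param indel_track `HomopolymerTrack` applied to indels (defaults to
#'   `snv_track`).
#' @return The data.frame with `flag_homopolymer` and `hp_run_length` set.
#' @export
filter_homopolymer <- function(variants, snv_track,
                               indel_track = snv_track) {
  n <- nrow(variants)
  rl <- integer(n)
  for (i in seq_len(n)) {
    if (variants$type[i] == "SNV") {
      rl[i] <- homopolymer_run_length(snv_track, variants$pos[i], "SNV")
    } else {
      rl[i] <- homopolymer_run_length(indel_track, variants$pos[i],
                                      variants$type[i])
    }
  }
  variants$hp_run_length <- rl
  variants$flag_homopolymer <- rl > 0L
  variants
}

#' Alternative-allele support filter
#'
#' Flags variants supported by fewer than `min_alt` alternative-allele
#' reads; low alternative support outside homopolymers can still stem
#' from sequencing errors.
#'
#' @param variants `MtVariant` data.frame.
#' @param min_alt Minimum alternative reads to keep (default 4).
#' @return The data.frame with `flag_low_alt` set.
#' @export
filter_alt_support <- function(variants, min_alt = 4L) {
  variants$flag_low_alt <- variants$alt_reads < min_alt
  variants
}

#' Heteroplasmy classification
#'
#' A variant represented by the alternative allele only is homoplasmic;
#' in approximate mode a variant whose reference allele is supported by
#' fewer than `min_ref_reads` reads is also counted as homoplasmic, by
#' symmetry with the alternative-support error argument. The fraction is
#' always `alt / (alt + ref)`.
#'
#' @param variants `MtVariant` data.frame (must have `alt_reads >= 1`).
#' @param min_ref_reads Reference-read bound of the approximate rule.
#' @param approximate Logical; use the approximate rule.
#' @return The data.frame with `het_class` and `het_fraction` set.
#' @export
classify_heteroplasmy <- function(variants, min_ref_reads = 4L,
                                  approximate = FALSE) {
  if (any(variants$alt_reads == 0L)) {
    stop("alt_reads must be >= 1 for every variant record")
  }
  homo <- if (approximate) variants$ref_reads < min_ref_reads
          else variants$ref_reads == 0L
  variants$het_class <- ifelse(homo, "homoplasmic", "heteroplasmic")
  variants$het_fraction <-
    variants$alt_reads / (variants$alt_reads + variants$ref_reads)
  variants
}

#' Kept variants after filtration
#'
#' @param variants `MtVariant` data.frame with flag columns.
#' @return The subset with no filter flag set.
#' @export
variants_kept <- function(variants) {
  variants[!(variants$flag_low_depth | variants$flag_homopolymer |
               variants$flag_low_alt), , drop = FALSE]
}

.stage_counts <- function(variants, keep, stage) {
  v <- variants[keep, , drop = FALSE]
  indel <- v$type %in% c("del", "ins")
  data.frame(stage = stage, total = nrow(v), indels = sum(indel),
             snps = sum(!indel), stringsAsFactors = FALSE)
}

#' Run the filtration cascade
#'
#' Applies the depth filter, then the homopolymer filter, then (if
#' enabled) the alternative-support filter, and reports survivor counts
#' at every stage split into SNVs and indels. Because the flags are
#' independent predicates, the final kept set is order-invariant; the
#' staged report mirrors the screening protocol's filtration table.
#'
#' @param variants `MtVariant` data.frame from [call_variants()].
#' @param ref An `MtReference` used to build the homopolymer tracks.
#' @param min_depth Depth threshold (stage 1).
#' @param hp_snv_min Homopolymer run length filtering SNVs (stage 2).
#' @param hp_indel_min Homopolymer run length filtering indels: 4 for the
#'   standard cascade, 3 for the stricter indel-reporting mode.
#' @param min_alt Alternative-support threshold (stage 3).
#' @param alt_filter Logical; apply stage 3.
#' @return List with `variants` (all records, flags set), `kept` (records
#'   passing every filter) and `report` (stage count data.frame with
#'   columns `stage`, `total`, `indels`, `snps`).
#' @export
run_cascade <- function(variants, ref, min_depth = 5L, hp_snv_min = 4L,
                        hp_indel_min = 4L, min_alt = 4L,
                        alt_filter = TRUE) {
  snv_track <- find_homopolymers(ref, min_len = hp_snv_min)
  indel_track <- if (hp_indel_min == hp_snv_min) snv_track
                 else find_homopolymers(ref, min_len = hp_indel_min)
  variants <- filter_depth(variants, min_depth)
  variants <- filter_homopolymer(variants, snv_track, indel_track)
  variants <- filter_alt_support(variants, min_alt)
  if (!alt_filter) variants$flag_low_alt <- FALSE

  keep1 <- !variants$flag_low_depth
  keep2 <- keep1 & !variants$flag_homopolymer
  keep3 <- keep2 & !variants$flag_low_alt
  report <- rbind(
    .stage_counts(variants, rep(TRUE, nrow(variants)), "total"),
    .stage_counts(variants, keep1, "depth_filter"),
    .stage_counts(variants, keep2, "homopolymer_filter"),
    if (alt_filter) .stage_counts(variants, keep3, "alt_support_filter")
  )
  list(variants = variants, kept = variants[keep3, , drop = FALSE],
       report = report)
}
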