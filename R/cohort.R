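# Cohort-level analyses: frequency spectrum, genome bins, regional
# intersections, variant-count normalisation, pairwise sharing.

#' Build a cohort presence table
#'
#' Assembles per-sample kept-variant sets into a samples-by-variants
#' presence matrix plus a distinct-variant information table. Variant
#' identity is the canonical (pos, ref, alt) key.
#'
#' @param variant_sets Named list (by sample id) of `MtVariant`
#'   data.frames (typically the `kept` element of [run_cascade()]).
#' @param manifest Optional per-sample metadata data.frame with a
#'   `sample_id` column (region, tube, days, mt_content, ...).
#' @return List of class `CohortTable`: `presence` (logical matrix,
#'   samples x distinct variants keyed by HGVS name), `variant_info`
#'   (data.frame `key`, `pos`, `ref`, `alt`, `type`) and `meta`.
#' @export
build_cohort <- function(variant_sets, manifest = NULL) {
  stopifnot(length(variant_sets) >= 1L, !is.null(names(variant_sets)))
  info <- do.call(rbind, lapply(variant_sets, function(v) {
    v[, c("hgvs", "pos", "ref", "alt", "type"), drop = FALSE]
  }))
  info <- info[!duplicated(info$hgvs), , drop = FALSE]
  info <- info[order(info$pos, info$alt), , drop = FALSE]
  names(info)[1L] <- "key"
  rownames(info) <- NULL

  presence <- matrix(FALSE, nrow = length(variant_sets),
                     ncol = nrow(info),
                     dimnames = list(names(variant_sets), info$key))
  for (s in names(variant_sets)) {
    presence[s, unique(variant_sets[[s]]$hgvs)] <- TRUE
  }
  if (!is.null(manifest)) {
    manifest <- manifest[match(names(variant_sets), manifest$sample_id), ,
                         drop = FALSE]
  }
  structure(list(presence = presence, variant_info = info,
                 meta = manifest), class = "CohortTable")
}

#' Population frequency spectrum
#'
#' Per-variant population frequency: the fraction of cohort samples
#' carrying the variant.
#'
#' @param cohort A `CohortTable`.
#' @return Data.frame `key`, `pos`, `ref`, `alt`, `type`, `carriers`,
#'   `frequency`, ordered by frequency descending.
#' @export
frequency_spectrum <- function(cohort) {
  stopifnot(nrow(cohort$presence) >= 1L)
  carriers <- colSums(cohort$presence)
  out <- cohort$variant_info
  out$carriers <- as.integer(carriers[out$key])
  out$frequency <- out$carriers / nrow(cohort$presence)
  out <- out[order(-out$frequency, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct-variant counts per genome bin
#'
#' Divides the mitochondrial genome into 1-kb sections (16 bins, the last
#' covering 15,001..16,569) and counts distinct variants per bin.
#'
#' @param variants Data.frame with a `pos` column (distinct variants).
#' @param bin_size Bin width in bp.
#' @param n_bins Number of bins; positions beyond `n_bins * bin_size`
#'   fall into the last bin.
#' @return Named integer vector of length `n_bins`.
#' @export
genome_bins <- function(variants, bin_size = 1000L, n_bins = 16L) {
  if (nrow(variants) && (any(variants$pos < 1L))) {
    stop("positions must be >= 1")
  }
  b <- pmin(ceiling(variants$pos / bin_size), n_bins)
  counts <- tabulate(b, nbins = n_bins)
  names(counts) <- paste0("bin", seq_len(n_bins))
  counts
}

#' Regional variant-set intersection
#'
#' Exact set algebra over per-region distinct-variant sets: every
#' non-empty membership cell of the Venn decomposition, plus per-region
#' sets and the distinct total.
#'
#' @param cohort A `CohortTable` whose `meta` has a `region` column.
#' @param regions Regions to intersect (>= 2, each with samples).
#' @return List of class `VennResult`: `sets` (named list of key
#'   vectors), `cells` (named integer vector; names like `"A&B"` denote
#'   the exclusive cell of samples in exactly those regions) and `total`.
#' @export
region_intersection <- function(cohort, regions) {
  stopifnot(length(regions) >= 2L, !is.null(cohort$meta),
            "region" %in% names(cohort$meta))
  sets <- lapply(regions, function(r) {
    idx <- which(cohort$meta$region == r)
    if (!length(idx)) stop("region with zero samples: '", r, "'")
    colnames(cohort$presence)[colSums(cohort$presence[idx, , drop = FALSE]) > 0L]
  })
  names(sets) <- regions
  all_keys <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_keys %in% s,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L)
  cell_of <- apply(membership, 1L, function(m) {
    paste(regions[m], collapse = "&")
  })
  cells <- table(cell_of)
  cells <- stats::setNames(as.integer(cells), names(cells))
  structure(list(sets = sets, cells = cells, total = length(all_keys)),
            class = "VennResult")
}

#' Normalise a variant count to mtDNA content
#'
#' Samples enriched with mtDNA yield more called variants for purely
#' technical reasons; dividing the count by the sample's mtDNA content
#' puts regions/samples with different mtDNA rates on a common scale.
#'
#' @param n_variants Variant count (vectorised).
#' @param mt_content Positive mtDNA content (mt reads / total reads).
#' @return `n_variants / mt_content`.
#' @export
normalize_variant_count <- function(n_variants, mt_content) {
  if (any(mt_content <= 0)) stop("mt_content must be > 0")
  n_variants / mt_content
}

#' Shared variants between two samples
#'
#' @param a,b `MtVariant` data.frames (or character key vectors) filtered
#'   identically.
#' @return Number of (pos, ref, alt) keys present in both.
#' @export
shared_variants <- function(a, b) {
  ka <- if (is.data.frame(a)) a$hgvs else as.character(a)
  kb <- if (is.data.frame(b)) b$hgvs else as.character(b)
  length(intersect(ka, kb))
}

#' Packaged ancestral variant list
#'
#' Editable list of broadly shared (ancestral) variants excluded when
#' ranking population-informative variants; the packaged default holds
#' the six variants exceeding 15% cohort frequency.
#'
#' @param path TSV with an `hgvs` column; defaults to the packaged list.
#' @return Character vector of HGVS-style names.
#' @export
load_ancestral_variants <- function(path = system.file(
  "extdata", "ancestral_variants.tsv", package = "cfmito",
  mustWork = TRUE)) {
  utils::read.delim(path, stringsAsFactors = FALSE)$hgvs
}

#' Top-ranked variants by population frequency
#'
#' Frequency-ranked variant tables, optionally excluding the ancestral
#' set and optionally restricted by variant class; with `per_region =
#' TRUE` adds per-region frequencies (fraction of each region's samples
#' carrying the variant).
#'
#' @param cohort A `CohortTable`.
#' @param k Number of rows to keep (`Inf` for all).
#' @param type `"all"`, `"SNV"` or `"indel"`.
#' @param exclude_ancestral Drop variants in `ancestral`.
#' @param ancestral Character vector of ancestral HGVS names.
#' @param per_region Add per-region frequency columns (requires region
#'   metadata).
#' @return Data.frame ordered by frequency descending.
#' @export
top_variants <- function(cohort, k = 5L, type = c("all", "SNV", "indel"),
                         exclude_ancestral = TRUE,
                         ancestral = load_ancestral_variants(),
                         per_region = FALSE) {
  type <- match.arg(type)
  spec <- frequency_spectrum(cohort)
  if (type == "SNV") spec <- spec[spec$type == "SNV", , drop = FALSE]
  if (type == "indel") {
    spec <- spec[spec$type %in% c("del", "ins"), , drop = FALSE]
  }
  if (exclude_ancestral) {
    spec <- spec[!spec$key %in% ancestral, , drop = FALSE]
  }
  spec <- utils::head(spec, k)
  if (per_region) {
    stopifnot(!is.null(cohort$meta), "region" %in% names(cohort$meta))
    for (r in unique(cohort$meta$region)) {
      idx <- which(cohort$meta$region == r)
      spec[[paste0("freq_", r)]] <- colMeans(
        cohort$presence[idx, spec$key, drop = FALSE])
    }
  }
  rownames(spec) <- NULL
  spec
}
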