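#' Load a mitochondrial reference sequence
#'
#' Reads a single-record FASTA file into an `MtReference` object. The
#' mitochondrial genome is circular, so downstream coordinate arithmetic
#' (fragment placement, homopolymer scanning, D-loop annotation) treats the
#' last and first positions as adjacent when `circular = TRUE`.
#'
#' @param path Path to a FASTA file containing exactly one sequence record.
#' @param circular Logical; whether the sequence is circular. The packaged
#'   mitochondrial reference is circular.
#' @return An object of class `MtReference`: a list with fields `name`,
#'   `sequence` (upper-case character string over \{A,C,G,T,N\}), `length`
#'   and `circular`.
#' @seealso [mt_reference()] for the packaged synthetic reference,
#'   [mt_reference_from_string()] to build one in code.
#' @export
load_reference <- function(path, circular = TRUE) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: '", path, "'")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA: no sequence records in '", path, "'")
  }
  if (length(seqs) > 1L) {
    stop("ambiguous reference: FASTA contains ", length(seqs),
         " records, expected exactly one")
  }
  mt_reference_from_string(
    sequence = as.character(seqs[[1L]]),
    name = sub("\\s.*$", "", names(seqs)[1L]),
    circular = circular
  )
}

#' Build an MtReference from a nucleotide string
#'
#' @param sequence Nucleotide string (case-insensitive, alphabet A/C/G/T/N).
#' @param name Sequence label.
#' @param circular Logical; circular topology flag.
#' @return An `MtReference` object.
#' @export
mt_reference_from_string <- function(sequence, name = "chrM", circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference alphabet must be {A,C,G,T,N}")
  }
  structure(
    list(name = name, sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "MtReference"
  )
}

#' The packaged synthetic mitochondrial reference
#'
#' Loads the 16,569-bp synthetic circular mitochondrial reference shipped
#' with the package. The sequence is synthetic (generated, not a copy of
#' rCRS) but has rCRS geometry: 16,569 bp, circular, with the control
#' region annotated at the canonical coordinates. Bases at positions used
#' by the packaged annotation tables are fixed so that variant names such
#' as m.15326A>G are expressible against it.
#'
#' @return An `MtReference` of length 16,569.
#' @export
mt_reference <- function() {
  load_reference(system.file("extdata", "chrM_synthetic.fa",
                             package = "cfmito", mustWork = TRUE),
                 circular = TRUE)
}

#' @export
print.MtReference <- function(x, ...) {
  cat(sprintf("MtReference '%s': %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Fixed control-region annotations
#'
#' Region coordinates of the mitochondrial control region: the D-loop
#' spans 16,024..576 (wrapping the origin of the circular genome) and
#' contains the two hypervariable segments HV1 (16,024..16,383) and
#' HV2 (57..372). Coordinates are 1-based inclusive.
#'
#' @param ref An `MtReference`; only used to validate that the canonical
#'   coordinates fit (must be >= 16,383 bp). Defaults to coordinates only.
#' @return A data.frame with columns `label`, `start`, `end`,
#'   `wraps_origin`.
#' @export
mt_regions <- function(ref = NULL) {
  regions <- data.frame(
    label = c("D-loop", "HV1", "HV2"),
    start = c(16024L, 16024L, 57L),
    end = c(576L, 16383L, 372L),
    wraps_origin = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "MtReference"))
    if (ref$length < max(regions$start, regions$end)) {
      stop("reference too short for canonical control-region coordinates")
    }
  }
  regions
}

#' Annotate a position with its region labels
#'
#' Returns every control-region label containing the position, honouring
#' the origin wrap of the D-loop; positions outside all regions get
#' `"other"`.
#'
#' @param pos 1-based position (scalar).
#' @param regions Region table as returned by [mt_regions()].
#' @param ref_length Reference length, used for the range check.
#' @return Character vector of region labels.
#' @export
annotate_position <- function(pos, regions = mt_regions(),
                              ref_length = 16569L) {
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > ref_length) {
    stop("position out of range [1, ", ref_length, "]")
  }
  hit <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    hit[i] <- if (regions$wraps_origin[i]) (pos >= s || pos <= e)
              else (pos >= s && pos <= e)
  }
  if (!any(hit)) "other" else regions$label[hit]
}

#' Find homopolymer runs in a reference
#'
#' Scans the sequence for maximal single-nucleotide runs of length at
#' least `min_len`. Variants inside such runs are the dominant error mode
#' of semiconductor sequencing and are removed by the filtration cascade.
#' On a circular reference a run touching both ends is merged into a
#' single origin-wrapping run.
#'
#' @param ref An `MtReference`.
#' @param min_len Minimum run length to report (>= 2).
#' @return A `HomopolymerTrack`: data.frame with columns `start`, `end`
#'   (1-based inclusive), `base`, `run_length`, `wraps`; attributes
#'   `ref_length`, `circular`, `min_len`. For a wrapping run `start` lies
#'   near the end of the sequence and `end` near the beginning.
#' @export
find_homopolymers <- function(ref, min_len = 4L) {
  stopifnot(inherits(ref, "MtReference"))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 2L) stop("min_len must be >= 2")
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, base = r$values,
                     run_length = r$lengths, wraps = FALSE,
                     stringsAsFactors = FALSE)
  # merge a run spanning the circular origin (first and last runs, same base)
  if (ref$circular && nrow(runs) >= 2L &&
      runs$base[1L] == runs$base[nrow(runs)]) {
    n <- nrow(runs)
    merged <- data.frame(
      start = runs$start[n], end = runs$end[1L], base = runs$base[1L],
      run_length = runs$run_length[1L] + runs$run_length[n], wraps = TRUE,
      stringsAsFactors = FALSE
    )
    runs <- rbind(merged, runs[-c(1L, n), , drop = FALSE])
  }
  runs <- runs[runs$run_length >= min_len, , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  structure(runs, ref_length = ref$length, circular = ref$circular,
            min_len = min_len, class = c("HomopolymerTrack", "data.frame"))
}

# run index covering pos (inside-run semantics only); 0L if none
.run_index_at <- function(track, pos) {
  inside <- ifelse(track$wraps,
                   pos >= track$start | pos <= track$end,
                   pos >= track$start & pos <= track$end)
  w <- which(inside)
  if (length(w)) w[1L] else 0L
}

#' Test whether a position falls in (or beside) a homopolymer run
#'
#' SNVs count as "within" a run only when the position itself lies inside
#' the run. Indels additionally count when the position is immediately
#' adjacent to a run boundary, because left-alignment places an indel
#' arising in a run at the run edge.
#'
#' @param track A `HomopolymerTrack` from [find_homopolymers()].
#' @param pos 1-based position (scalar).
#' @param variant_type One of `"SNV"`, `"del"`, `"ins"`.
#' @return Logical scalar.
#' @seealso [homopolymer_run_length()]
#' @export
position_in_run <- function(track, pos, variant_type = c("SNV", "del", "ins")) {
  variant_type <- match.arg(variant_type)
  homopolymer_run_length(track, pos, variant_type) > 0L
}

#' Length of the homopolymer run at/beside a position
#'
#' Same membership semantics as [position_in_run()] but returns the run
#' length (0 when the position is not associated with any run).
#'
#' @inheritParams position_in_run
#' @return Integer run length, 0 if none.
#' @export
homopolymer_run_length <- function(track, pos,
                                   variant_type = c("SNV", "del", "ins")) {
  variant_type <- match.arg(variant_type)
  L <- attr(track, "ref_length")
  circular <- isTRUE(attr(track, "circular"))
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > L) {
    stop("position out of range [1, ", L, "]")
  }
  if (nrow(track) == 0L) return(0L)
  i <- .run_index_at(track, pos)
  if (i == 0L && variant_type != "SNV") {
    # adjacency: position immediately before start or after end (circular)
    before <- track$start - 1L
    after <- track$end + 1L
    if (circular) {
      before <- ifelse(before < 1L, L, before)
      after <- ifelse(after > L, 1L, after)
    }
    w <- which(pos == before | pos == after)
    if (length(w)) i <- w[1L]
  }
  if (i == 0L) 0L else track$run_length[i]
}

#' Write a homopolymer track as BED
#'
#' Output is BED-like TSV (0-based half-open). An origin-wrapping run is
#' written as two lines covering its tail and head segments.
#'
#' @param track A `HomopolymerTrack`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_homopolymer_bed <- function(track, path) {
  L <- attr(track, "ref_length")
  rows <- list()
  for (i in seq_len(nrow(track))) {
    nm <- sprintf("%s%d", track$base[i], track$run_length[i])
    if (track$wraps[i]) {
      rows[[length(rows) + 1L]] <- c("chrM", track$start[i] - 1L, L, nm)
      rows[[length(rows) + 1L]] <- c("chrM", 0L, track$end[i], nm)
    } else {
      rows[[length(rows) + 1L]] <- c("chrM", track$start[i] - 1L,
                                     track$end[i], nm)
    }
  }
  m <- do.call(rbind, rows)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
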