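# ClinVar-style annotation of kept variants.

.CLNSIG_LEVELS <- c("Benign", "Likely benign", "Pathogenic",
                    "Conflicting interpretations of pathogenicity",
                    "Drug response", "Not provided")

#' Load a ClinVar-style annotation table
#'
#' Reads a tab-separated annotation table keyed by (pos, ref, alt) with
#' columns `pos`, `ref`, `alt`, `type`, `rsid`, `clinvar_id`,
#' `significance` (closed vocabulary: Benign, Likely benign, Pathogenic,
#' Conflicting interpretations of pathogenicity, Drug response, Not
#' provided) and `diagnoses` (`|`-separated; `Not provided` when absent).
#' The packaged default is a small frozen table of mitochondrial variants
#' with published clinical annotations.
#'
#' @param path Table path; defaults to the packaged table.
#' @return Data.frame of class `ClinVarTable` with a `key` column
#'   (HGVS-style name).
#' @export
load_clinvar_table <- function(path = system.file("extdata",
                                                  "clinvar_mini.tsv",
                                                  package = "cfmito",
                                                  mustWork = TRUE)) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  if (nrow(tb)) {
    bad <- setdiff(unique(tb$significance), .CLNSIG_LEVELS)
    if (length(bad)) {
      stop("significance outside the closed vocabulary: ",
           paste(bad, collapse = ", "))
    }
    tb$key <- hgvs_name(tb)
    if (anyDuplicated(tb$key)) {
      stop("duplicate (pos, ref, alt) key(s) in annotation table")
    }
  } else {
    tb$key <- character(0)
  }
  class(tb) <- c("ClinVarTable", "data.frame")
  tb
}

#' Annotate variants against a ClinVar-style table
#'
#' Exact-key join on the canonical (pos, ref, alt) name; unmatched
#' variants are marked unannotated. Annotating an already annotated table
#' is a no-op on the annotation columns (idempotent join).
#'
#' @param variants `MtVariant` data.frame (must carry `hgvs` names).
#' @param table A `ClinVarTable`.
#' @return The variants with columns `annotated`, `rsid`, `clinvar_id`,
#'   `significance`, `diagnoses` added/refreshed.
#' @export
annotate_variants <- function(variants, table = load_clinvar_table()) {
  m <- match(variants$hgvs, table$key)
  variants$annotated <- !is.na(m)
  variants$rsid <- table$rsid[m]
  variants$clinvar_id <- table$clinvar_id[m]
  variants$significance <- table$significance[m]
  variants$diagnoses <- table$diagnoses[m]
  variants
}

.split_diagnoses <- function(x) {
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(d) {
    d <- trimws(d)
    d[nzchar(d) & d != "Not provided"]
  })
}

#' Summarise diagnoses and significance over an annotated set
#'
#' Tallies ClinVar diagnoses over annotated variants: a variant with k
#' diagnoses contributes to k diagnosis rows, split into cases where the
#' diagnosis is the only one provided versus provided in combination with
#' others. Also reports the significance distribution and the fraction of
#' annotated variants carrying any diagnosis. When the input has a
#' `sample_id` column a patient-level tally (fraction of samples carrying
#' each diagnosis) is added.
#'
#' @param annotated Output of [annotate_variants()]; may contain one row
#'   per (sample, variant) for patient-level tallies, in which case the
#'   variant-level summary uses distinct variants.
#' @return List of class `DiagnosisSummary`: `diagnoses` (data.frame
#'   `diagnosis`, `n_only`, `n_combination`, `n_total`, ordered by count
#'   descending then name), `significance` (table of proportions),
#'   `prop_with_diagnosis`, and optionally `patients` (data.frame
#'   `diagnosis`, `n_samples`, `prop_samples`).
#' @export
summarize_diagnoses <- function(annotated) {
  ann <- annotated[annotated$annotated, , drop = FALSE]
  distinct <- ann[!duplicated(ann$hgvs), , drop = FALSE]
  dlist <- .split_diagnoses(distinct$diagnoses)

  rows <- list()
  for (i in seq_along(dlist)) {
    ds <- dlist[[i]]
    if (!length(ds)) next
    only <- length(ds) == 1L
    for (d in ds) {
      rows[[length(rows) + 1L]] <- data.frame(
        diagnosis = d, only = only, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    tall <- do.call(rbind, rows)
    agg <- stats::aggregate(cbind(n_only = tall$only,
                                  n_combination = !tall$only),
                            by = list(diagnosis = tall$diagnosis), FUN = sum)
    agg$n_total <- agg$n_only + agg$n_combination
    agg <- agg[order(-agg$n_total, agg$diagnosis), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(diagnosis = character(0), n_only = integer(0),
                      n_combination = integer(0), n_total = integer(0),
                      stringsAsFactors = FALSE)
  }

  sig <- table(factor(distinct$significance, levels = .CLNSIG_LEVELS))
  out <- list(
    diagnoses = agg,
    significance = if (nrow(distinct)) sig / nrow(distinct) else sig,
    prop_with_diagnosis = if (nrow(distinct)) {
      mean(vapply(dlist, length, integer(1)) > 0L)
    } else NA_real_,
    n_annotated = nrow(distinct)
  )

  if ("sample_id" %in% names(ann) && nrow(ann)) {
    n_samp <- length(unique(annotated$sample_id))
    per <- lapply(seq_len(nrow(ann)), function(i) {
      ds <- .split_diagnoses(ann$diagnoses[i])[[1L]]
      if (!length(ds)) return(NULL)
      data.frame(sample_id = ann$sample_id[i], diagnosis = ds,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    if (!is.null(per)) {
      per <- unique(per)
      pt <- as.data.frame(table(diagnosis = per$diagnosis),
                          stringsAsFactors = FALSE)
      names(pt)[2L] <- "n_samples"
      pt$prop_samples <- pt$n_samples / n_samp
      pt <- pt[order(-pt$n_samples, pt$diagnosis), , drop = FALSE]
      rownames(pt) <- NULL
      out$patients <- pt
    }
  }
  class(out) <- "DiagnosisSummary"
  out
}
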