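# End-to-end orchestration and standard-format I/O.

#' Pipeline configuration
#'
#' Collects the screening thresholds (depth < 5, homopolymer >= 4 with
#' the >= 3 indel-reporting mode, alternative support < 4, haplogroup
#' discard score 0.5) together with simulator parameters, the output
#' directory and the seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_samples Cohort size.
#' @param out_dir Output directory (created if missing).
#' @param min_depth,hp_snv_min,hp_indel_min,min_alt Filtration cascade
#'   thresholds, see [run_cascade()].
#' @param discard_score Haplogroup confidence discard threshold.
#' @param approximate_homoplasmy Logical; use the approximate homoplasmy
#'   rule of [classify_heteroplasmy()].
#' @param sim Additional arguments passed to [sim_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_samples = 50L,
                            out_dir = tempfile("cfmito_run_"),
                            min_depth = 5L, hp_snv_min = 4L,
                            hp_indel_min = 4L, min_alt = 4L,
                            discard_score = 0.5,
                            approximate_homoplasmy = FALSE,
                            sim = list()) {
  stopifnot(min_depth >= 1L, hp_snv_min >= 2L, hp_indel_min >= 2L,
            min_alt >= 1L, discard_score >= 0, discard_score <= 1)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              out_dir = out_dir, min_depth = min_depth,
              hp_snv_min = hp_snv_min, hp_indel_min = hp_indel_min,
              min_alt = min_alt, discard_score = discard_score,
              approximate_homoplasmy = approximate_homoplasmy, sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

# md5 of the configuration (excluding the output directory)
.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# TSV with a provenance comment line (seed + config hash)
.write_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called variants as VCF v4.2
#'
#' Contig `chrM`; FILTER carries `LOW_DEPTH`, `HOMOPOLYMER` and
#' `LOW_ALT_SUPPORT` flags (`PASS` when none); INFO carries depth, allele
#' reads, heteroplasmy class and fraction, and the homopolymer run
#' length. Deletions are left-anchored on output per VCF convention.
#'
#' @param variants `MtVariant` data.frame.
#' @param ref An `MtReference`.
#' @param path Output path.
#' @param meta Extra `##` meta lines (e.g. seed/config stamps).
#' @return Invisibly, the path.
#' @export
write_variants_vcf <- function(variants, ref, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", ref$length),
    "##FILTER=<ID=LOW_DEPTH,Description=\"Total depth below threshold\">",
    "##FILTER=<ID=HOMOPOLYMER,Description=\"Inside or adjacent to a homopolymer run\">",
    "##FILTER=<ID=LOW_ALT_SUPPORT,Description=\"Alternative-allele reads below threshold\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AR,Number=1,Type=Integer,Description=\"Alternative-allele reads\">",
    "##INFO=<ID=RR,Number=1,Type=Integer,Description=\"Reference-allele reads\">",
    "##INFO=<ID=HETCLASS,Number=1,Type=String,Description=\"Heteroplasmy class\">",
    "##INFO=<ID=HETFRAC,Number=1,Type=Float,Description=\"Heteroplasmy fraction alt/(alt+ref)\">",
    "##INFO=<ID=HPLEN,Number=1,Type=Integer,Description=\"Homopolymer run length (0 if none)\">",
    meta,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  v <- variants[order(variants$pos, variants$alt), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    flags <- c("LOW_DEPTH", "HOMOPOLYMER", "LOW_ALT_SUPPORT")[
      c(v$flag_low_depth[i], v$flag_homopolymer[i], v$flag_low_alt[i])]
    filt <- if (length(flags)) paste(flags, collapse = ";") else "PASS"
    vr <- .vcf_repr(v$pos[i], v$ref[i], v$alt[i], v$type[i], ref)
    writeLines(sprintf(
      "chrM\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AR=%d;RR=%d;HETCLASS=%s;HETFRAC=%.6g;HPLEN=%d",
      vr$pos, vr$ref, vr$alt, filt, v$depth[i], v$alt_reads[i],
      v$ref_reads[i], v$het_class[i], v$het_fraction[i],
      v$hp_run_length[i]), con)
  }
  invisible(path)
}

#' Read a VCF written by the package
#'
#' Reconstructs the internal `MtVariant` representation (first-deleted-
#' base deletions, anchored insertions, filter flags, heteroplasmy
#' annotations) from a VCF emitted by [write_variants_vcf()].
#'
#' @param path VCF path.
#' @return `MtVariant` data.frame.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(.empty_variants())
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  pos <- as.integer(fix$POS)
  ref <- fix$REF; alt <- fix$ALT
  type <- ifelse(nchar(ref) == nchar(alt), "SNV",
                 ifelse(nchar(ref) > nchar(alt), "del", "ins"))
  v <- data.frame(
    pos = ifelse(type == "del", pos + 1L, pos),
    ref = ifelse(type == "del", substring(ref, 2L),
                 ifelse(type == "ins", ref, ref)),
    alt = ifelse(type == "del", "",
                 ifelse(type == "ins", substring(alt, 2L), alt)),
    type = type, stringsAsFactors = FALSE
  )
  v$depth <- as.integer(info_get(fix$INFO, "DP"))
  v$alt_reads <- as.integer(info_get(fix$INFO, "AR"))
  v$ref_reads <- as.integer(info_get(fix$INFO, "RR"))
  v$het_fraction <- as.numeric(info_get(fix$INFO, "HETFRAC"))
  v$hgvs <- hgvs_name(v)
  v$hp_run_length <- as.integer(info_get(fix$INFO, "HPLEN"))
  v$flag_low_depth <- grepl("LOW_DEPTH", fix$FILTER)
  v$flag_homopolymer <- grepl("HOMOPOLYMER", fix$FILTER)
  v$flag_low_alt <- grepl("LOW_ALT_SUPPORT", fix$FILTER)
  v$het_class <- info_get(fix$INFO, "HETCLASS")
  v
}

#' Run the full screening pipeline on a simulated cohort
#'
#' Executes every stage in order -- cohort simulation, per-sample QC,
#' pileup and variant calling, filtration cascade, heteroplasmy
#' classification, haplogroup assignment, annotation, cohort statistics
#' -- and writes the run artefacts (QC, filter report, haplogroup,
#' annotation and cohort TSVs plus per-sample filtered VCFs) under the
#' configured output directory. Every output carries the seed and a
#' configuration hash; a rerun with the same configuration is
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort simulation, QC table,
#'   per-sample cascades, haplogroup calls, annotated variants, cohort
#'   table and summary tables, plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  ref <- mt_reference()
  tree <- load_haplotree()
  clinvar <- load_clinvar_table()
  stamp <- sprintf("# cfmito seed=%d config_md5=%s", config$seed,
                   .config_hash(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "vcf"), showWarnings = FALSE)

  sim_args <- config$sim
  sim_args$n_samples <- config$n_samples
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_cohort(scfg, ref, tree)

  qc_rows <- list(); cascades <- list(); kept_sets <- list()
  hg_rows <- list(); annotated <- list()
  for (i in seq_along(sim$samples)) {
    smp <- sim$samples[[i]]
    tr <- sim$truth[[i]]
    qc_rows[[i]] <- compute_qc(
      smp, tr$total_reads, ref,
      meta = list(region = tr$region, tube_type = tr$tube_type,
                  transport_days = tr$transport_days,
                  foetal_fraction = tr$foetal_fraction))
    pl <- build_pileup(smp, ref)
    calls <- call_variants(pl, ref)
    casc <- run_cascade(calls, ref, min_depth = config$min_depth,
                        hp_snv_min = config$hp_snv_min,
                        hp_indel_min = config$hp_indel_min,
                        min_alt = config$min_alt)
    kept <- classify_heteroplasmy(
      casc$kept, approximate = config$approximate_homoplasmy)
    cascades[[i]] <- casc
    kept_sets[[smp$sample_id]] <- kept
    hg_rows[[i]] <- assign_haplogroup(kept, tree,
                                      discard_threshold = config$discard_score,
                                      sample_id = smp$sample_id)
    ann <- annotate_variants(kept, clinvar)
    if (nrow(ann)) ann$sample_id <- smp$sample_id
    annotated[[i]] <- ann
    write_variants_vcf(kept, ref,
                       file.path(config$out_dir, "vcf",
                                 paste0(smp$sample_id, ".vcf")),
                       meta = sub("^# ", "##", stamp))
  }
  qc <- do.call(rbind, qc_rows)
  qc$mt_content_class <- as.character(classify_mt_content(qc$mt_content))
  haplogroups <- do.call(rbind, hg_rows)
  annotated <- do.call(rbind, annotated)

  report <- Reduce(function(a, b) {
    a[, c("total", "indels", "snps")] <-
      a[, c("total", "indels", "snps")] + b[, c("total", "indels", "snps")]
    a
  }, lapply(cascades, `[[`, "report"))

  cohort <- build_cohort(kept_sets, manifest = cbind(
    sim$manifest, mt_content = qc$mt_content))
  spectrum <- frequency_spectrum(cohort)
  bins <- genome_bins(cohort$variant_info)
  main_regions <- intersect(c("Central", "Northwestern", "Volga-Ural",
                              "Yakutia"), unique(sim$manifest$region))
  venn <- if (length(main_regions) >= 2L) {
    region_intersection(cohort, main_regions)
  } else NULL

  .write_tsv(sim$manifest, file.path(config$out_dir, "manifest.tsv"), stamp)
  .write_tsv(qc, file.path(config$out_dir, "qc.tsv"), stamp)
  .write_tsv(report, file.path(config$out_dir, "filter_report.tsv"), stamp)
  .write_tsv(haplogroups, file.path(config$out_dir, "haplogroups.tsv"),
             stamp)
  .write_tsv(annotated, file.path(config$out_dir, "annotated.tsv"), stamp)
  .write_tsv(spectrum, file.path(config$out_dir, "spectrum.tsv"), stamp)
  .write_tsv(data.frame(bin = names(bins), n_variants = as.integer(bins)),
             file.path(config$out_dir, "genome_bins.tsv"), stamp)
  if (!is.null(venn)) {
    .write_tsv(data.frame(cell = names(venn$cells),
                          n_variants = as.integer(venn$cells)),
               file.path(config$out_dir, "venn.tsv"), stamp)
  }
  .write_tsv(top_variants(cohort, k = 5L, type = "SNV"),
             file.path(config$out_dir, "top_snv.tsv"), stamp)
  .write_tsv(top_variants(cohort, k = 5L, type = "indel"),
             file.path(config$out_dir, "top_indel.tsv"), stamp)

  invisible(list(sim = sim, qc = qc, cascades = cascades,
                 haplogroups = haplogroups, annotated = annotated,
                 cohort = cohort, spectrum = spectrum, bins = bins,
                 venn = venn, report = report, out_dir = config$out_dir))
}

#' Write simulated fragments and allele events as TSV
#'
#' Plain-text alternative to SAM for exchanging simulated alignments.
#'
#' @param sample A [simulate_sample()] result.
#' @param path Output prefix; writes `<path>.fragments.tsv` and
#'   `<path>.events.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_fragments_tsv <- function(sample, path) {
  fp <- paste0(path, ".fragments.tsv")
  ep <- paste0(path, ".events.tsv")
  utils::write.table(sample$fragments, fp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sample$events, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fp, ep))
}

#' Read fragments and allele events written by [write_fragments_tsv()]
#'
#' @param path Prefix used when writing.
#' @param sample_id Optional sample label.
#' @return A sample list usable by [build_pileup()].
#' @export
read_fragments_tsv <- function(path, sample_id = NA_character_) {
  fragments <- utils::read.delim(paste0(path, ".fragments.tsv"),
                                 stringsAsFactors = FALSE)
  events <- utils::read.delim(paste0(path, ".events.tsv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(ref = "character",
                                             alt = "character"))
  events$alt[is.na(events$alt)] <- ""
  list(sample_id = sample_id, fragments = fragments, events = events)
}
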