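# Synthetic cf-mtDNA cohort generator.
#
# Emulates the mixture structure of the cell-free mitochondrial DNA pool in
# maternal plasma: maternal cf-mtDNA, foetal cf-mtDNA (maternally inherited,
# so the same haplotype by default) and leukocyte mtDNA leaking from
# degrading blood cells during transport. Leakage is tube- and time-
# dependent: EDTA tubes ship plasma (constant small leakage) while Streck
# tubes ship whole blood, where leakage grows after a 72-h threshold.
# Sequencing noise follows the semiconductor-platform error profile:
# uniform substitutions plus indels concentrated in homopolymer runs.

.REGION_LEVELS <- c("Central", "Northwestern", "Volga-Ural", "Yakutia", "Others")

# cohort composition by geographic region (study-reported shares)
.REGION_WEIGHTS <- c(Central = 0.469, Northwestern = 0.318,
                     `Volga-Ural` = 0.0849, Yakutia = 0.102, Others = 0.0255)

# superclade priors: Yakutia weighted to the east-Eurasian clades C/D,
# everywhere else H-dominant. Illustrative generator defaults.
.CLADE_PRIOR_EUR <- c(H = 0.50, U = 0.12, J = 0.11, T = 0.06, K = 0.03,
                      C = 0.03, D = 0.02, M = 0.03, N = 0.02, W = 0.02,
                      B = 0.02, I = 0.04)
.CLADE_PRIOR_YAKUTIA <- c(H = 0.08, U = 0.02, J = 0.02, T = 0.02, K = 0.01,
                          C = 0.45, D = 0.33, M = 0.03, N = 0.01, W = 0.005,
                          B = 0.02, I = 0.005)

# transport-day ranges and Streck probability by region: remote regions ship
# longer and predominantly as whole blood
.REGION_DAYS <- list(Central = 1:5, Northwestern = 1:3, `Volga-Ural` = 2:8,
                     Yakutia = 4:14, Others = 2:10)
.REGION_STRECK <- c(Central = 0.5, Northwestern = 0.3, `Volga-Ural` = 0.7,
                    Yakutia = 0.9, Others = 0.7)

#' Simulator configuration
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. Defaults emulate the screening cohort the package models:
#' mean mtDNA depth spanning 1--40x, transport times of 1--14 days with a
#' 72-h (3-day) leakage threshold for Streck tubes, ~95% of truth variants
#' homoplasmic, and indel sequencing errors concentrated in homopolymer
#' runs.
#'
#' @param n_samples Number of samples in the cohort.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @param fragment_mean_len Mean cfDNA fragment length in bp (cfDNA
#'   fragments are nucleosome-sized; 170 bp is the typical scale).
#' @param depth_range Range of mean mtDNA sequencing depth (x).
#' @param foetal_fraction_mean Mean baseline foetal fraction before
#'   dilution by leaked nuclear DNA.
#' @param leakage List with `w0` (baseline leaked leukocyte mass relative
#'   to the cf pool), `threshold_days` (72-h threshold = 3 days) and `k`
#'   (post-threshold exponential growth rate per day, Streck only).
#' @param substitution_error_rate Per-base substitution error probability.
#' @param homopolymer_indel_base_rate Per-fragment indel error probability
#'   in a length-3 homopolymer run; the rate grows with run length, see
#'   [homopolymer_indel_rate()].
#' @param leakage_noise_sdlog Standard deviation (log scale) of the
#'   mean-one lognormal sample-to-sample variability multiplying the
#'   leaked mass: cell lysis and handling vary between samples, so mtDNA
#'   content and foetal fraction are continuously (negatively) coupled at
#'   every leakage level, not only at the tube/time change-points. The
#'   multiplier is independent of transport time, so the expected leaked
#'   mass still follows [leakage_weight()] exactly.
#' @param homoplasmic_fraction Proportion of private truth variants
#'   simulated at heteroplasmy 1.0; the remainder draw from Beta(2,2).
#' @param cf_private_mean,leuk_private_mean Poisson means of the number of
#'   private variants of the cell-free pool and of the leukocyte pool.
#' @param denovo_foetal_mean Poisson mean of de-novo foetal variants
#'   (default 0: foetal mtDNA is maternally inherited).
#' @param total_reads_range Per-sample total (nuclear + mt) read count
#'   range.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100L,
                       seed = 1L,
                       fragment_mean_len = 170,
                       depth_range = c(1, 40),
                       foetal_fraction_mean = 0.10,
                       leakage = list(w0 = 0.05, threshold_days = 3, k = 0.35),
                       leakage_noise_sdlog = 0.6,
                       substitution_error_rate = 1e-4,
                       homopolymer_indel_base_rate = 0.002,
                       homoplasmic_fraction = 0.95,
                       cf_private_mean = 4,
                       leuk_private_mean = 6,
                       denovo_foetal_mean = 0,
                       total_reads_range = c(3e6, 4e6)) {
  cfg <- list(
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    fragment_mean_len = fragment_mean_len, depth_range = depth_range,
    foetal_fraction_mean = foetal_fraction_mean, leakage = leakage,
    leakage_noise_sdlog = leakage_noise_sdlog,
    substitution_error_rate = substitution_error_rate,
    homopolymer_indel_base_rate = homopolymer_indel_base_rate,
    homoplasmic_fraction = homoplasmic_fraction,
    cf_private_mean = cf_private_mean,
    leuk_private_mean = leuk_private_mean,
    denovo_foetal_mean = denovo_foetal_mean,
    total_reads_range = total_reads_range
  )
  stopifnot(cfg$n_samples >= 1L,
            cfg$fragment_mean_len > 0,
            length(cfg$depth_range) == 2L, all(cfg$depth_range > 0),
            cfg$foetal_fraction_mean >= 0, cfg$foetal_fraction_mean <= 1,
            cfg$leakage$w0 >= 0, cfg$leakage$threshold_days >= 0,
            cfg$leakage$k >= 0, cfg$leakage_noise_sdlog >= 0,
            cfg$substitution_error_rate >= 0,
            cfg$substitution_error_rate <= 1,
            cfg$homoplasmic_fraction >= 0, cfg$homoplasmic_fraction <= 1)
  # indel error rate must be non-decreasing in run length and capped < 0.5
  rates <- homopolymer_indel_rate(3:12, cfg$homopolymer_indel_base_rate)
  stopifnot(all(diff(rates) >= 0), all(rates < 0.5))
  class(cfg) <- "sim_config"
  cfg
}

#' Homopolymer indel error rate
#'
#' Per-fragment probability of an indel sequencing error in a homopolymer
#' run, doubling with each additional base of run length (capped below
#' 0.5). Runs shorter than 3 do not generate indel errors.
#'
#' @param run_length Integer vector of run lengths.
#' @param base_rate Rate at run length 3.
#' @return Numeric vector of probabilities.
#' @export
homopolymer_indel_rate <- function(run_length, base_rate = 0.002) {
  ifelse(run_length < 3, 0, pmin(0.45, base_rate * 2^(run_length - 3)))
}

#' Leukocyte leakage weight
#'
#' Relative mass of leukocyte DNA leaked into the cell-free pool as a
#' function of collection tube and transport time. EDTA tubes ship plasma,
#' so the leaked mass stays at the baseline `w0` regardless of transport
#' time; Streck tubes ship whole blood, where blood cells degrade in
#' transit: the weight stays at `w0` up to `threshold_days` (72 h) and
#' grows exponentially at rate `k` per day beyond it.
#'
#' @param tube_type `"EDTA"` or `"Streck"`.
#' @param transport_days Non-negative number of days in transit.
#' @param params List with `w0`, `threshold_days`, `k`.
#' @return Leaked mass relative to the baseline cell-free pool.
#' @export
leakage_weight <- function(tube_type,
                           transport_days,
                           params = list(w0 = 0.05, threshold_days = 3,
                                         k = 0.35)) {
  tube_type <- match.arg(tube_type, c("EDTA", "Streck"))
  if (any(transport_days < 0)) stop("transport_days must be >= 0")
  w0 <- params$w0
  if (tube_type == "EDTA") {
    rep(w0, length(transport_days))
  } else {
    excess <- pmax(0, transport_days - params$threshold_days)
    w0 * exp(params$k * excess)
  }
}

#' Foetal fraction after dilution by leaked nuclear DNA
#'
#' Leaked maternal leukocyte DNA adds maternal nuclear material to the
#' plasma pool, diluting the foetal fraction: `ff0 / (1 + leaked)`.
#'
#' @param ff0 Baseline foetal fraction in `[0, 1]`.
#' @param leaked Leaked nuclear mass relative to the baseline pool (>= 0).
#' @return Diluted foetal fraction; strictly decreasing in `leaked`.
#' @export
dilute_foetal_fraction <- function(ff0, leaked) {
  stopifnot(all(ff0 >= 0 & ff0 <= 1), all(leaked >= 0))
  ff0 / (1 + leaked)
}

# random alt base differing from ref
.random_alt <- function(ref_base, n = length(ref_base)) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    sample(setdiff(bases, ref_base[i]), 1L)
  }, character(1L))
}

.base_at <- function(ref, pos) substring(ref$sequence, pos, pos)

#' Draw ground-truth samples for a cohort
#'
#' Samples region, tube type, transport time, haplogroup, private variant
#' sets, heteroplasmy levels, mixture weights and sequencing depth for
#' each cohort member. Uses the current RNG state; [simulate_cohort()]
#' seeds it from the configuration.
#'
#' @param config A [sim_config()].
#' @param ref An `MtReference`.
#' @param tree A `HaploTree` (see [load_haplotree()]).
#' @return List of `TruthSample` objects.
#' @export
simulate_truth_samples <- function(config, ref = mt_reference(),
                                   tree = load_haplotree()) {
  leaves <- haplotree_leaves(tree)
  leaf_clade <- vapply(leaves, collapse_to_superclade, character(1L))
  lapply(seq_len(config$n_samples), function(i) {
    region <- sample(names(.REGION_WEIGHTS), 1L, prob = .REGION_WEIGHTS)
    days <- sample(.REGION_DAYS[[region]], 1L)
    tube <- if (stats::runif(1) < .REGION_STRECK[[region]]) "Streck" else "EDTA"
    prior <- if (region == "Yakutia") .CLADE_PRIOR_YAKUTIA else .CLADE_PRIOR_EUR
    clade <- sample(names(prior), 1L, prob = prior)
    cand <- leaves[leaf_clade == clade]
    hg <- if (length(cand)) sample(cand, 1L) else sample(leaves, 1L)

    haplo <- draw_haplotype(tree, hg)
    haplo$ref <- .base_at(ref, haplo$pos)
    used <- haplo$pos

    draw_private <- function(n_mean, origin) {
      n <- stats::rpois(1L, n_mean)
      if (n == 0L) {
        return(data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), type = character(0),
                          origin = character(0), het = numeric(0),
                          stringsAsFactors = FALSE))
      }
      pos <- sample(setdiff(seq_len(ref$length), used), n)
      used <<- c(used, pos)
      rb <- .base_at(ref, pos)
      het <- ifelse(stats::runif(n) < config$homoplasmic_fraction, 1,
                    stats::rbeta(n, 2, 2))
      data.frame(pos = pos, ref = rb, alt = .random_alt(rb), type = "SNV",
                 origin = origin, het = het, stringsAsFactors = FALSE)
    }

    variants <- rbind(
      data.frame(pos = haplo$pos, ref = haplo$ref, alt = haplo$alt,
                 type = "SNV", origin = "shared", het = 1,
                 stringsAsFactors = FALSE),
      draw_private(config$cf_private_mean, "cf_private"),
      draw_private(config$leuk_private_mean, "leuk_private"),
      draw_private(config$denovo_foetal_mean, "foetal_denovo")
    )

    sdl <- config$leakage_noise_sdlog
    leaked <- leakage_weight(tube, days, config$leakage) *
      exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    ff0 <- min(1, max(0.01, stats::rnorm(1, config$foetal_fraction_mean,
                                         0.03)))
    ff <- dilute_foetal_fraction(ff0, leaked)
    w_leu <- leaked / (1 + leaked)
    weights <- c(maternal_cf = (1 - ff0) * (1 - w_leu),
                 foetal_cf = ff0 * (1 - w_leu),
                 leukocyte = w_leu)

    d <- config$depth_range
    base_depth <- exp(stats::runif(1, log(d[1]), log(max(d[1], d[2] / 2))))
    mean_depth <- min(d[2], base_depth * (1 + leaked))
    total_reads <- round(stats::runif(1, config$total_reads_range[1],
                                      config$total_reads_range[2]))

    structure(list(
      sample_id = sprintf("S%04d", i), region = region, tube_type = tube,
      transport_days = days, haplogroup = hg, variants = variants,
      mixture_weights = weights, ff0 = ff0, leaked = leaked,
      foetal_fraction = ff, mean_depth = mean_depth,
      total_reads = total_reads
    ), class = "TruthSample")
  })
}

# tissues carrying each truth-variant class
.carrying_origins <- function(origin) {
  switch(origin,
         shared = c("maternal_cf", "foetal_cf", "leukocyte"),
         cf_private = c("maternal_cf", "foetal_cf"),
         foetal_denovo = "foetal_cf",
         leuk_private = "leukocyte",
         stop("unknown truth-variant origin: ", origin))
}

#' Simulate aligned fragments for one sample
#'
#' Places cfDNA fragments uniformly on the circular reference, tags each
#' with a tissue of origin drawn from the sample's mixture weights, loads
#' truth variants onto covering fragments with probability equal to their
#' heteroplasmy (when the fragment's tissue carries them), and injects
#' sequencing errors: substitutions uniformly over sequenced bases, indels
#' preferentially inside homopolymer runs.
#'
#' @param truth A `TruthSample`.
#' @param config A [sim_config()].
#' @param ref An `MtReference`.
#' @param hp_track Homopolymer track used for indel error placement
#'   (defaults to runs of length >= 3 on `ref`).
#' @param mean_depth Override of the truth sample's mean depth.
#' @return List with `fragments` (data.frame: `frag_id`, `start`,
#'   `length`, `origin`), `events` (data.frame of carried non-reference
#'   alleles: `frag_id`, `pos`, `ref`, `alt`, `type`, `source`) and
#'   `truth` (the truth variant table).
#' @export
simulate_sample <- function(truth, config, ref = mt_reference(),
                            hp_track = NULL, mean_depth = NULL) {
  L <- ref$length
  if (is.null(mean_depth)) mean_depth <- truth$mean_depth
  if (mean_depth <= 0) stop("mean depth must be > 0")
  if (is.null(hp_track)) hp_track <- find_homopolymers(ref, min_len = 3L)

  n_frag <- stats::rpois(1L, mean_depth * L / config$fragment_mean_len)
  fragments <- data.frame(
    frag_id = seq_len(n_frag),
    start = if (n_frag) sample.int(L, n_frag, replace = TRUE) else integer(0),
    length = if (n_frag) {
      pmin(pmax(round(stats::rnorm(n_frag, config$fragment_mean_len,
                                   0.15 * config$fragment_mean_len)), 50L),
           2L * round(config$fragment_mean_len))
    } else integer(0),
    origin = if (n_frag) {
      sample(names(truth$mixture_weights), n_frag, replace = TRUE,
             prob = truth$mixture_weights)
    } else character(0),
    stringsAsFactors = FALSE
  )

  covers <- function(pos) {
    off <- (pos - fragments$start) %% L
    off < fragments$length
  }

  ev <- list()
  tv <- truth$variants
  for (j in seq_len(nrow(tv))) {
    idx <- which(covers(tv$pos[j]) &
                   fragments$origin %in% .carrying_origins(tv$origin[j]))
    if (!length(idx)) next
    carry <- idx[stats::runif(length(idx)) < tv$het[j]]
    if (!length(carry)) next
    ev[[length(ev) + 1L]] <- data.frame(
      frag_id = carry, pos = tv$pos[j], ref = tv$ref[j], alt = tv$alt[j],
      type = tv$type[j], source = "truth", stringsAsFactors = FALSE)
  }

  # substitution errors, uniform over sequenced bases
  if (n_frag > 0 && config$substitution_error_rate > 0) {
    n_err <- stats::rpois(1L, sum(fragments$length) *
                            config$substitution_error_rate)
    if (n_err > 0) {
      fi <- sample.int(n_frag, n_err, replace = TRUE,
                       prob = fragments$length)
      off <- floor(stats::runif(n_err) * fragments$length[fi])
      pos <- ((fragments$start[fi] + off - 1L) %% L) + 1L
      rb <- .base_at(ref, pos)
      ev[[length(ev) + 1L]] <- data.frame(
        frag_id = fi, pos = pos, ref = rb, alt = .random_alt(rb),
        type = "SNV", source = "error", stringsAsFactors = FALSE)
    }
  }

  # indel errors concentrated in homopolymer runs
  if (n_frag > 0 && config$homopolymer_indel_base_rate > 0 &&
      nrow(hp_track) > 0) {
    for (r in seq_len(nrow(hp_track))) {
      rate <- homopolymer_indel_rate(hp_track$run_length[r],
                                     config$homopolymer_indel_base_rate)
      idx <- which(covers(hp_track$start[r]))
      hit <- idx[stats::runif(length(idx)) < rate]
      if (!length(hit)) next
      is_del <- stats::runif(length(hit)) < 0.7
      b <- hp_track$base[r]
      ev[[length(ev) + 1L]] <- data.frame(
        frag_id = hit,
        pos = ifelse(is_del, hp_track$start[r],
                     if (hp_track$wraps[r]) hp_track$start[r]
                     else hp_track$end[r]),
        ref = b, alt = ifelse(is_del, "", b),
        type = ifelse(is_del, "del", "ins"),
        source = "error", stringsAsFactors = FALSE)
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(frag_id = integer(0), pos = integer(0), ref = character(0),
               alt = character(0), type = character(0),
               source = character(0), stringsAsFactors = FALSE)
  # a fragment reports one allele per position: truth alleles win collisions
  events <- events[order(events$frag_id, events$pos,
                         events$source != "truth"), , drop = FALSE]
  events <- events[!duplicated(events[, c("frag_id", "pos")]), , drop = FALSE]
  rownames(events) <- NULL

  list(sample_id = truth$sample_id, fragments = fragments, events = events,
       truth = tv)
}

#' Simulate a full cohort
#'
#' Seeds the RNG from the configuration and generates truth samples plus
#' sequenced fragments for each; the whole cohort is reproducible bit for
#' bit under a fixed seed.
#'
#' @inheritParams simulate_truth_samples
#' @return List of class `cf_cohort_sim` with `truth` (list of
#'   `TruthSample`), `samples` (list of [simulate_sample()] results) and
#'   `manifest` (data.frame: sample_id, region, tube_type, transport_days,
#'   foetal_fraction, mean_depth, total_reads).
#' @export
simulate_cohort <- function(config, ref = mt_reference(),
                            tree = load_haplotree()) {
  set.seed(config$seed)
  hp3 <- find_homopolymers(ref, min_len = 3L)
  truth <- simulate_truth_samples(config, ref, tree)
  samples <- lapply(truth, simulate_sample, config = config, ref = ref,
                    hp_track = hp3)
  manifest <- data.frame(
    sample_id = vapply(truth, `[[`, character(1), "sample_id"),
    region = vapply(truth, `[[`, character(1), "region"),
    tube_type = vapply(truth, `[[`, character(1), "tube_type"),
    transport_days = vapply(truth, `[[`, integer(1), "transport_days"),
    haplogroup = vapply(truth, `[[`, character(1), "haplogroup"),
    foetal_fraction = vapply(truth, `[[`, numeric(1), "foetal_fraction"),
    mean_depth = vapply(truth, `[[`, numeric(1), "mean_depth"),
    total_reads = vapply(truth, `[[`, numeric(1), "total_reads"),
    stringsAsFactors = FALSE
  )
  structure(list(config = config, truth = truth, samples = samples,
                 manifest = manifest), class = "cf_cohort_sim")
}

#' Simulate a paired cfDNA / buffy-coat sample
#'
#' The buffy-coat member is drawn purely from the leukocyte haplotype
#' (shared inherited variants plus leukocyte-private ones); the cfDNA
#' member is drawn from the sample's full tissue mixture at the same
#' depth. Comparing the two recovers the pool-overlap analysis: pairs
#' shipped as whole blood (Streck) share more variants because leaked
#' leukocyte mtDNA enters the cell-free pool.
#'
#' @inheritParams simulate_sample
#' @return List with `cfdna` and `buffy` sample simulations.
#' @export
simulate_buffy_pair <- function(truth, config, ref = mt_reference(),
                                hp_track = NULL) {
  cfdna <- simulate_sample(truth, config, ref, hp_track)
  buffy_truth <- truth
  buffy_truth$sample_id <- paste0(truth$sample_id, "_BC")
  buffy_truth$mixture_weights <- c(maternal_cf = 0, foetal_cf = 0,
                                   leukocyte = 1)
  buffy <- simulate_sample(buffy_truth, config, ref, hp_track)
  list(cfdna = cfdna, buffy = buffy)
}

#' Write simulated fragments as minimal SAM
#'
#' Emits a positional sketch of the sample: header plus one alignment line
#' per fragment (QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ, M-only CIGAR with
#' substitution payloads applied to SEQ; indel payloads are carried by the
#' events table and truth VCF, not the CIGAR). Fragments wrapping the
#' circular origin are written as two records sharing a QNAME.
#'
#' @param sample A [simulate_sample()] result.
#' @param ref An `MtReference`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(sample, ref, path) {
  L <- ref$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chrM\tLN:%d", L)), con)
  fr <- sample$fragments
  ev <- sample$events[sample$events$type == "SNV", , drop = FALSE]
  seq_chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(fr))) {
    s <- fr$start[i]; len <- fr$length[i]
    pos_all <- ((s + seq_len(len) - 2L) %% L) + 1L
    bases <- seq_chars[pos_all]
    mine <- ev[ev$frag_id == fr$frag_id[i], , drop = FALSE]
    if (nrow(mine)) {
      m <- match(mine$pos, pos_all)
      ok <- !is.na(m)
      bases[m[ok]] <- mine$alt[ok]
    }
    qname <- sprintf("%s_f%06d", sample$sample_id, fr$frag_id[i])
    if (s + len - 1L <= L) {
      writeLines(sprintf("%s\t0\tchrM\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                         qname, s, len, paste(bases, collapse = "")), con)
    } else {
      head_len <- L - s + 1L
      writeLines(sprintf("%s\t0\tchrM\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                         qname, s, head_len,
                         paste(bases[seq_len(head_len)], collapse = "")), con)
      writeLines(sprintf("%s\t2048\tchrM\t1\t60\t%dM\t*\t0\t0\t%s\t*",
                         qname, len - head_len,
                         paste(bases[(head_len + 1L):len], collapse = "")),
                 con)
    }
  }
  invisible(path)
}

#' Write a truth VCF for a simulated sample
#'
#' VCF v4.2 on contig `chrM` with INFO keys `ORIGIN` (tissue class of the
#' truth variant) and `HET` (simulated heteroplasmy within the carrying
#' tissue).
#'
#' @param truth A `TruthSample`.
#' @param ref An `MtReference`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_vcf <- function(truth, ref, path) {
  tv <- truth$variants[order(truth$variants$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", ref$length),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Tissue class of the simulated truth variant\">",
    "##INFO=<ID=HET,Number=1,Type=Float,Description=\"Simulated heteroplasmy in the carrying tissue\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (j in seq_len(nrow(tv))) {
    vr <- .vcf_repr(tv$pos[j], tv$ref[j], tv$alt[j], tv$type[j], ref)
    writeLines(sprintf("chrM\t%d\t.\t%s\t%s\t.\tPASS\tORIGIN=%s;HET=%.4f",
                       vr$pos, vr$ref, vr$alt, tv$origin[j], tv$het[j]), con)
  }
  invisible(path)
}

# convert internal variant representation (first-deleted-base deletions,
# anchored insertions) to VCF POS/REF/ALT
.vcf_repr <- function(pos, ref_allele, alt_allele, type, ref) {
  if (type == "SNV") {
    list(pos = pos, ref = ref_allele, alt = alt_allele)
  } else if (type == "ins") {
    list(pos = pos, ref = .base_at(ref, pos),
         alt = paste0(.base_at(ref, pos), alt_allele))
  } else if (type == "del") {
    if (pos <= 1L) stop("cannot left-anchor a deletion at position 1")
    anchor <- .base_at(ref, pos - 1L)
    list(pos = pos - 1L, ref = paste0(anchor, ref_allele), alt = anchor)
  } else stop("unknown variant type: ", type)
}
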