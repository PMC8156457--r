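# Generates the packaged text fixtures under inst/extdata:
#   chrM_synthetic.fa        16,569-bp synthetic circular reference
#   haplotree_synthetic.tsv  reduced synthetic haplogroup tree
#   clinvar_mini.tsv         frozen mini annotation table
#   ancestral_variants.tsv   ancestral variant list
#
# The reference is synthetic but constrained so that every variant named in
# the packaged annotation tables is expressible against it (the reference
# base at each named position matches the variant name) and none of those
# positions sits inside or beside a homopolymer run (length >= 3), so they
# are not removed by the homopolymer filter. Run from the package root:
#   Rscript data-raw/make_extdata.R

source("R/reference.R")
set.seed(743L)

L <- 16569L
bases <- c("A", "C", "G", "T")
seq <- sample(bases, L, replace = TRUE)

# positions with a required reference base (from the packaged annotation
# tables); each gets an isolation window so no homopolymer run >= 3
# touches it
constraints <- c(
  `263` = "A", `489` = "T", `750` = "A", `951` = "G", `961` = "T",
  `980` = "T", `1008` = "A", `2193` = "T", `2706` = "A", `3010` = "G",
  `8410` = "C", `9769` = "T", `9808` = "T", `9906` = "G", `9916` = "C",
  `10151` = "A", `10400` = "C", `11560` = "A", `12272` = "A",
  `13708` = "G", `14470` = "T", `14783` = "T", `15262` = "T",
  `15301` = "G", `15326` = "A", `15452` = "C", `15833` = "C"
)

isolate <- function(seq, pos, b) {
  others <- setdiff(bases, b)
  x <- others[1]; y <- others[2]
  pat <- c(x, y, x, b, x, y, x)             # no adjacent repeats, centre = b
  idx <- (pos - 3L):(pos + 3L)
  ok <- idx >= 1L & idx <= L
  seq[idx[ok]] <- pat[ok]
  seq
}
for (p in names(constraints)) {
  seq <- isolate(seq, as.integer(p), constraints[[p]])
}
# 15511/15514 (both ref T) are 3 bp apart: one joint window
seq[15508:15517] <- c("G", "A", "C", "T", "A", "C", "T", "G", "C", "A")
constraints <- c(constraints, `15511` = "T", `15514` = "T")

ref <- mt_reference_from_string(paste(seq, collapse = ""),
                                name = "chrM_synthetic")
stopifnot(ref$length == L)

hp3 <- find_homopolymers(ref, min_len = 3L)
blocked <- unique(unlist(lapply(seq_len(nrow(hp3)), function(i) {
  if (hp3$wraps[i]) c(hp3$start[i]:L, 1L:hp3$end[i],
                      hp3$start[i] - 1L, hp3$end[i] + 1L)
  else (hp3$start[i] - 1L):(hp3$end[i] + 1L)
})))
cpos <- as.integer(names(constraints))
stopifnot(!any(cpos %in% blocked),
          all(seq[cpos] == unname(constraints)))

## ---- haplogroup tree ----------------------------------------------------

# candidate positions for tree-defining variants: away from homopolymer
# runs and from the constrained annotation positions
candidates <- setdiff(seq(25L, L - 25L), blocked)
candidates <- candidates[!(candidates %in%
                             unlist(lapply(cpos, function(p) (p - 3L):(p + 3L))))]

nodes <- rbind(
  data.frame(name = "MRCA", parent = "", n = 0),
  data.frame(name = c("M", "N"), parent = "MRCA", n = 14),
  data.frame(name = "R", parent = "N", n = 14),
  data.frame(name = c("H", "U", "J", "T", "K", "B"), parent = "R", n = 14),
  data.frame(name = c("C", "D", "M7"), parent = "M", n = c(14, 14, 12)),
  data.frame(name = c("W", "I", "N1a"), parent = "N", n = c(14, 14, 28)),
  data.frame(name = c("H1", "H2"), parent = "H", n = 12),
  data.frame(name = c("H1c4b", "H1a"), parent = "H1", n = 10),
  data.frame(name = "H2a1c", parent = "H2", n = 10),
  data.frame(name = c("U5", "U4"), parent = "U", n = 12),
  data.frame(name = "U5a", parent = "U5", n = 10),
  data.frame(name = c("J1", "J2"), parent = "J", n = 12),
  data.frame(name = "J1c2", parent = "J1", n = 10),
  data.frame(name = "T2", parent = "T", n = 12),
  data.frame(name = "T2b", parent = "T2", n = 10),
  data.frame(name = "K1", parent = "K", n = 12),
  data.frame(name = "K1a", parent = "K1", n = 10),
  data.frame(name = "B4", parent = "B", n = 12),
  data.frame(name = "B4a", parent = "B4", n = 10),
  data.frame(name = c("C4", "C5"), parent = "C", n = c(12, 14)),
  data.frame(name = c("C4a", "C4b"), parent = "C4", n = 10),
  data.frame(name = c("D4", "D2"), parent = "D", n = 12),
  data.frame(name = "D4i2a1", parent = "D4", n = 10),
  data.frame(name = "D2a", parent = "D2", n = 10),
  data.frame(name = "M7a", parent = "M7", n = 16),
  data.frame(name = "W1", parent = "W", n = 14),
  data.frame(name = "I1", parent = "I", n = 14)
)

# fixed tokens: ancestral trunk variants on M; population-informative
# variants of the annotation tables on their carrying clades
fixed_tokens <- list(
  M = c("263G", "750G", "2706G", "15326G", "10400T", "14783C"),
  C = "15301A", D = "489C", J = "15452A"
)

alt_for <- function(p) sample(setdiff(bases, seq[p]), 1L)
pool <- sample(candidates)
take <- function(n) {
  out <- pool[seq_len(n)]
  pool <<- pool[-seq_len(n)]
  out
}

tokens <- character(nrow(nodes))
for (i in seq_len(nrow(nodes))) {
  fx <- fixed_tokens[[nodes$name[i]]]
  n_rand <- nodes$n[i] - length(fx)
  rand <- if (n_rand > 0) {
    ps <- take(n_rand)
    paste0(ps, vapply(ps, alt_for, character(1)))
  } else character(0)
  tokens[i] <- paste(c(fx, rand), collapse = ",")
}
tree <- data.frame(name = nodes$name, parent = nodes$parent,
                   variants = tokens, stringsAsFactors = FALSE)

## ---- annotation tables --------------------------------------------------

cv <- function(pos, ref_b, alt, type, rsid, cvid, sig, dx) {
  data.frame(pos = pos, ref = ref_b, alt = alt, type = type, rsid = rsid,
             clinvar_id = cvid, significance = sig, diagnoses = dx,
             stringsAsFactors = FALSE)
}
conf <- "Conflicting interpretations of pathogenicity"
clinvar <- rbind(
  cv(15301, "G", "A", "SNV", "rs193302991", "140591", conf,
     "Familial cancer of breast"),
  cv(14783, "T", "C", "SNV", "rs193302982", "140588", conf,
     "Familial cancer of breast"),
  cv(15452, "C", "A", "SNV", "rs193302994", "143925", "Benign",
     "Neoplasm of ovary|Leigh syndrome"),
  cv(3010, "G", "A", "SNV", "rs3928306", "441149", "Drug response",
     "Not provided"),
  cv(13708, "G", "A", "SNV", "rs28359178", "9696", "Benign",
     "Leber's optic atrophy|Leigh syndrome"),
  cv(961, "T", "G", "SNV", ".", ".", "Pathogenic",
     "Nonsyndromic sensorineural mitochondrial deafness"),
  cv(15511, "T", "C", "SNV", ".", ".", "Pathogenic", "Neoplasm of ovary"),
  cv(951, "G", "A", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(980, "T", "C", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(1008, "A", "G", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(8410, "C", "T", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(11560, "A", "G", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(14470, "T", "A", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(15262, "T", "C", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(15514, "T", "C", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(15833, "C", "T", "SNV", ".", ".", "Pathogenic", "Not provided"),
  cv(489, "T", "C", "SNV", ".", ".", "Likely benign", "Not provided"),
  cv(10400, "C", "T", "SNV", ".", ".", "Benign", "Not provided"),
  cv(263, "A", "G", "SNV", ".", ".", "Benign", "Not provided"),
  cv(750, "A", "G", "SNV", ".", ".", "Benign", "Not provided"),
  cv(2706, "A", "G", "SNV", ".", ".", "Benign", "Not provided"),
  cv(15326, "A", "G", "SNV", ".", ".", "Benign", "Not provided")
)
stopifnot(all(seq[clinvar$pos] == clinvar$ref))

ancestral <- data.frame(
  hgvs = c("m.750A>G", "m.2706A>G", "m.263A>G", "m.15326A>G",
           "m.9769delT", "m.12272delA"),
  stringsAsFactors = FALSE
)
stopifnot(seq[9769] == "T", seq[12272] == "A")

## ---- write --------------------------------------------------------------

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
lines <- c(">chrM_synthetic synthetic circular mitochondrial reference, 16569 bp",
           vapply(split(seq, ceiling(seq_along(seq) / 60)),
                  paste, character(1), collapse = ""))
writeLines(lines, "inst/extdata/chrM_synthetic.fa")
write.table(tree, "inst/extdata/haplotree_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clinvar, "inst/extdata/clinvar_mini.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ancestral, "inst/extdata/ancestral_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("extdata written: reference", ref$length, "bp;",
    nrow(tree), "tree nodes;", nrow(clinvar), "annotation rows\n")
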