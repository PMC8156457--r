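# Haplogroup assignment by Kulczynski set scoring.
#
# Each tree node is scored against the sample's variant set with the
# Kulczynski measure, the mean of the overlap fraction relative to the
# node's cumulative defining set and relative to the sample set
# (restricted to tree-informative positions so private variants do not
# dilute confidence). Calls with confidence <= 0.5 are discarded, the
# low-confidence regime typical of samples carrying few variants.

#' Load a haplogroup tree
#'
#' Reads a tab-separated tree file with columns `name`, `parent` (empty
#' for the root) and `variants` (comma-separated `POS` + `ALT` tokens,
#' e.g. `750G`; empty for the root). Validates the topology (single root,
#' resolvable parents, no cycles) and caches the cumulative root-to-node
#' variant set of every node.
#'
#' The packaged default is a deliberately small synthetic tree covering
#' superclades H, U, J, T, K, C, D, M, N, W, B and I; a fuller tree in
#' the same schema can be supplied instead.
#'
#' @param path Tree TSV path; defaults to the packaged synthetic tree.
#' @return An object of class `HaploTree`: list with `nodes` (data.frame),
#'   `cumulative` (named list of variant-key character vectors), `depth`
#'   (named integer vector, root = 0) and `positions` (sorted integer
#'   vector of all tree-informative positions).
#' @export
load_haplotree <- function(path = system.file("extdata",
                                              "haplotree_synthetic.tsv",
                                              package = "cfmito",
                                              mustWork = TRUE)) {
  nodes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  stopifnot(all(c("name", "parent", "variants") %in% names(nodes)))
  nodes$parent[is.na(nodes$parent)] <- ""
  nodes$variants[is.na(nodes$variants)] <- ""
  if (anyDuplicated(nodes$name)) stop("duplicate node names in tree")
  root <- nodes$name[nodes$parent == ""]
  if (length(root) != 1L) stop("tree must have exactly one root")
  unresolved <- setdiff(nodes$parent, c("", nodes$name))
  if (length(unresolved)) {
    stop("orphan node(s): parent not found: ",
         paste(unresolved, collapse = ", "))
  }
  if (any(nodes$variants == "" & nodes$parent != "")) {
    stop("non-root nodes must have a non-empty defining variant set")
  }

  own <- lapply(strsplit(nodes$variants, ",", fixed = TRUE),
                function(x) x[nzchar(x)])
  names(own) <- nodes$name
  parent_of <- stats::setNames(nodes$parent, nodes$name)

  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$name)
  cumulative <- stats::setNames(vector("list", nrow(nodes)), nodes$name)
  for (nm in nodes$name) {
    chain <- character(0)
    cur <- nm
    while (cur != "") {
      if (cur %in% chain) stop("cycle detected at node '", cur, "'")
      chain <- c(chain, cur)
      cur <- parent_of[[cur]]
    }
    depth[nm] <- length(chain) - 1L
    cumulative[[nm]] <- unique(unlist(own[rev(chain)], use.names = FALSE))
  }

  positions <- sort(unique(as.integer(
    sub("[ACGT]$", "", unlist(cumulative, use.names = FALSE)))))
  structure(list(nodes = nodes, root = root, cumulative = cumulative,
                 depth = depth, positions = positions),
            class = "HaploTree")
}

#' Leaf nodes of a haplogroup tree
#'
#' @param tree A `HaploTree`.
#' @return Character vector of node names with no children.
#' @export
haplotree_leaves <- function(tree) {
  setdiff(tree$nodes$name, tree$nodes$parent)
}

#' Variant set of a haplogroup
#'
#' Union of the defining variants on the root-to-node path.
#'
#' @param tree A `HaploTree`.
#' @param haplogroup Node name.
#' @return Data.frame with columns `pos` and `alt`.
#' @export
draw_haplotype <- function(tree, haplogroup) {
  if (!haplogroup %in% tree$nodes$name) {
    stop("unknown haplogroup: '", haplogroup, "'")
  }
  keys <- tree$cumulative[[haplogroup]]
  data.frame(pos = as.integer(sub("[ACGT]$", "", keys)),
             alt = sub("^[0-9]+", "", keys),
             stringsAsFactors = FALSE)
}

#' Kulczynski node score
#'
#' `0.5 * (|S ∩ E| / |E| + |S ∩ E| / |S|)` for sample set `S` and node
#' cumulative set `E`; the caller is responsible for restricting `S` to
#' tree-informative positions.
#'
#' @param sample_keys Character vector of sample variant keys (`POS` +
#'   `ALT`).
#' @param node_keys Non-empty character vector of node cumulative keys.
#' @return Score in `[0, 1]`; 0 with a warning when `S` is empty.
#' @export
score_node <- function(sample_keys, node_keys) {
  if (!length(node_keys)) stop("node cumulative set must be non-empty")
  if (!length(sample_keys)) {
    warning("sample has no tree-informative variants; score is 0")
    return(0)
  }
  ov <- length(intersect(sample_keys, node_keys))
  0.5 * (ov / length(node_keys) + ov / length(sample_keys))
}

#' Collapse a haplogroup name to its superclade
#'
#' @param name Haplogroup name beginning with the clade letter (e.g.
#'   `"H1c4b"`).
#' @return Single-letter superclade (upper case).
#' @export
collapse_to_superclade <- function(name) {
  if (!length(name) || any(!nzchar(name))) stop("empty haplogroup name")
  first <- toupper(substr(name, 1L, 1L))
  if (any(!grepl("^[A-Z]$", first))) {
    stop("haplogroup name must begin with a clade letter")
  }
  first
}

#' Assign a haplogroup to a sample
#'
#' Restricts the sample's variant set to tree-informative positions,
#' scores every non-root node with the Kulczynski measure and returns the
#' best node (ties broken by greater tree depth, then lexicographic
#' name). Calls with confidence at or below the discard threshold are
#' flagged as discarded.
#'
#' @param variants Either an `MtVariant` data.frame (its SNV records are
#'   used) or a character vector of `POS` + `ALT` keys.
#' @param tree A `HaploTree`.
#' @param discard_threshold Confidence at or below which the call is
#'   discarded (default 0.5).
#' @param sample_id Optional sample label.
#' @return One-row data.frame (`HaplogroupCall`): `sample_id`,
#'   `haplogroup`, `superclade`, `confidence`, `n_sample_variants`,
#'   `n_informative`, `discarded`.
#' @export
assign_haplogroup <- function(variants, tree, discard_threshold = 0.5,
                              sample_id = NA_character_) {
  if (!inherits(tree, "HaploTree") || nrow(tree$nodes) < 2L) {
    stop("tree is empty or not a HaploTree")
  }
  if (is.data.frame(variants)) {
    snv <- variants[variants$type == "SNV", , drop = FALSE]
    keys <- paste0(snv$pos, snv$alt)
    n_total <- nrow(variants)
  } else {
    keys <- as.character(variants)
    n_total <- length(keys)
  }
  pos <- suppressWarnings(as.integer(sub("[ACGT]$", "", keys)))
  S <- unique(keys[!is.na(pos) & pos %in% tree$positions])

  cand <- setdiff(tree$nodes$name, tree$root)
  scores <- vapply(cand, function(nm) {
    suppressWarnings(score_node(S, tree$cumulative[[nm]]))
  }, numeric(1))
  ord <- order(-scores, -tree$depth[cand], cand)
  best <- cand[ord[1L]]
  conf <- scores[ord[1L]]
  data.frame(
    sample_id = sample_id, haplogroup = best,
    superclade = collapse_to_superclade(best),
    confidence = unname(conf), n_sample_variants = n_total,
    n_informative = length(S),
    discarded = unname(conf) <= discard_threshold,
    stringsAsFactors = FALSE
  )
}
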