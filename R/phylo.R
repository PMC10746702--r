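# Distance phylogenetics over consensus alignments: Jukes-Cantor distances
# with pairwise deletion, neighbor-joining with non-negative branch lengths,
# column-bootstrap supports, and Robinson-Foulds tree comparison.

encode_alignment <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences differ in length", call. = FALSE)
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")), BASES),
              nrow = length(seqs), ncol = L, byrow = TRUE,
              dimnames = list(names(seqs), NULL))
  m # NA marks gap/N/other: excluded pairwise
}

jc_from_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      L <- sum(ok)
      if (L < 1) stop(sprintf("no comparable sites for pair %s/%s",
                              rownames(m)[[i]], rownames(m)[[j]]), call. = FALSE)
      p <- sum(m[i, ok] != m[j, ok]) / L
      if (p >= 0.75) stop(sprintf("saturated pair %s/%s (p = %.3f)",
                                  rownames(m)[[i]], rownames(m)[[j]], p),
                          call. = FALSE)
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Jukes-Cantor distance matrix with pairwise deletion
#'
#' For every pair, sites where either sequence has a gap/`N` are excluded;
#' `p` is the mismatch fraction over the remaining sites and
#' `d = -(3/4) ln(1 - (4/3) p)`. A pair with `p >= 0.75` is beyond the JC
#' saturation bound and raises an error naming the pair.
#'
#' @param seqs named character vector of equal-length DNA sequences (an
#'   alignment in shared reference coordinates).
#' @return symmetric numeric matrix of substitutions/site with zero diagonal.
#' @export
jc_distance <- function(seqs) {
  if (length(seqs) < 3) stop("need at least 3 sequences", call. = FALSE)
  jc_from_matrix(encode_alignment(seqs))
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Saitou-Nei agglomeration on the Q-criterion (via the `ape` implementation)
#' followed by a clean-up pass: any negative branch length is clamped to 0
#' and the deficit transferred to its sibling branch, preserving path
#' lengths through the parent node. The result is unrooted.
#'
#' @param dm symmetric distance matrix with labelled rows/columns (or `dist`).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (any(dm < 0) || any(abs(dm - t(dm)) > 1e-9)) {
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(dm))
  clamp_negative_branches(ape::unroot(tree))
}

clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[[1]]
    deficit <- -tree$edge.length[[e]]
    tree$edge.length[[e]] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
    if (length(sibs) > 0) {
      tree$edge.length[[sibs[[1]]]] <- tree$edge.length[[sibs[[1]]]] + deficit
      if (tree$edge.length[[sibs[[1]]]] < 0) tree$edge.length[[sibs[[1]]]] <- 0
    }
  }
  tree
}

# Canonical string keys for the non-trivial bipartitions of an unrooted tree.
# Each internal edge splits the leaves in two; the side NOT containing the
# alphabetically first label is sorted and pasted, giving a rooting-invariant
# key. Only splits with >= 2 leaves on both sides are returned.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  ref <- sort(labs)[[1]]
  nnode <- tree$Nnode
  # leaves under each edge's child, by postorder accumulation
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + nnode)
  for (i in seq_len(n)) below[[i]] <- labs[[i]]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next # trivial split
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds comparison of two binary unrooted trees
#'
#' `rf` is the size of the symmetric difference of the two sets of
#' non-trivial bipartitions; `max_rf = 2(n - 3)` for fully resolved unrooted
#' trees on `n` leaves, and `nrf = rf / max_rf`. Rooted inputs are unrooted
#' first (the normalization assumes the unrooted convention).
#'
#' @param t1,t2 `ape::phylo` trees on identical leaf sets, fully resolved.
#' @return object of class `RFReport`: list with `rf`, `max_rf`, `nrf`,
#'   `n_leaves`.
#' @export
rf_metrics <- function(t1, t2) {
  t1 <- ape::unroot(t1); t2 <- ape::unroot(t2)
  sym <- c(setdiff(t1$tip.label, t2$tip.label),
           setdiff(t2$tip.label, t1$tip.label))
  if (length(sym) > 0) {
    stop("leaf sets differ: ", paste(sym, collapse = ","), call. = FALSE)
  }
  if (!ape::is.binary(t1) || !ape::is.binary(t2)) {
    stop("trees must be fully resolved (binary)", call. = FALSE)
  }
  n <- length(t1$tip.label)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  max_rf <- 2L * (n - 3L)
  structure(list(rf = rf, max_rf = max_rf,
                 nrf = if (max_rf > 0) rf / max_rf else 0,
                 n_leaves = n), class = "RFReport")
}

#' @export
print.RFReport <- function(x, ...) {
  cat(sprintf("RF = %d, maxRF = %d, nRF = %.4f (%d leaves)\n",
              x$rf, x$max_rf, x$nrf, x$n_leaves))
  invisible(x)
}

#' Neighbor-joining with column bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree per
#' replicate, and annotates every internal bipartition of the point tree
#' with the number of completed replicates containing it (stored in
#' `node.label`; attribute `n_completed` holds the replicate count).
#' Replicates in which some pair saturates (`p >= 0.75`) are skipped with a
#' log message.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param n_reps number of bootstrap replicates (0 = point tree only).
#' @param seed RNG seed for the column resampling.
#' @return unrooted `phylo` tree with bootstrap counts as `node.label`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1) {
  m <- encode_alignment(alignment)
  if (ncol(m) < 1) stop("empty alignment", call. = FALSE)
  point <- nj_tree(jc_from_matrix(m))
  if (n_reps == 0) return(point)
  keys <- tree_bipartitions(point)
  counts <- setNames(rep(0L, length(keys)), keys)
  completed <- 0L
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- try(nj_tree(jc_from_matrix(m[, cols, drop = FALSE])),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) {
      ad_log("warn", "bootstrap replicate ", r, " skipped: ",
             attr(rep_tree, "condition")$message)
      next
    }
    completed <- completed + 1L
    hit <- keys %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  point <- annotate_supports(point, counts)
  attr(point, "n_completed") <- completed
  point
}

# Write the per-bipartition bootstrap counts onto the internal nodes of the
# point tree. Node i's label is the count of the bipartition below its
# parent edge (NA for the root-adjacent basal node of the unrooted tree).
annotate_supports <- function(tree, counts) {
  n <- length(tree$tip.label)
  labs_all <- rep("", tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  labs <- tree$tip.label
  ref <- sort(labs)[[1]]
  for (i in seq_len(n)) below[[i]] <- labs[[i]]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(counts)) {
      labs_all[[ch - n]] <- as.character(counts[[key]])
    }
  }
  tree$node.label <- labs_all
  tree
}
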