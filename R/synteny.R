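# Anchor detection and collinear block chaining.
#
# Anchors are homologous gene pairs; blocks are maximum-score chains of
# anchors that are strictly monotone in gene rank on both contigs (the gap
# unit is gene rank, not bp, so chaining is robust to intergenic length
# variation). Defaults mirror the conventions of whole-genome synteny tools:
# minimum block size 5, maximum rank gap 25.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

blosum62 <- function() {
  if (is.null(.ad_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ad_cache$blosum62 <- e$BLOSUM62
  }
  .ad_cache$blosum62
}

#' Global protein alignment with BLOSUM62 and affine gaps
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap cost
#' `open + extend * L` for a gap of length `L` (open = 11, extend = 1, the
#' classic protein-search parameterisation). Identity is computed over all
#' aligned columns, gaps included in the denominator.
#'
#' @param p1,p2 amino-acid strings (standard 20-letter alphabet).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return list with `score`, `identity` (fraction in \[0,1\]), and the two
#'   gapped alignment strings `aligned1`, `aligned2`.
#' @export
align_proteins <- function(p1, p2, gap_open = 11, gap_extend = 1) {
  if (nchar(p1) == 0 || nchar(p2) == 0) stop("empty protein sequence", call. = FALSE)
  chars <- unique(strsplit(paste0(p1, p2), "")[[1]])
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-amino-acid symbol: ", paste(bad, collapse = ","), call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  a1 <- as.character(Biostrings::alignedPattern(pa))
  a2 <- as.character(Biostrings::alignedSubject(pa))
  cols1 <- strsplit(a1, "")[[1]]
  cols2 <- strsplit(a2, "")[[1]]
  list(score = Biostrings::score(pa),
       identity = sum(cols1 == cols2) / length(cols1),
       aligned1 = a1, aligned2 = a2)
}

protein_kmers <- function(p, k) {
  n <- nchar(p)
  if (n < k) return(character())
  unique(substring(p, 1:(n - k + 1), k:n))
}

#' Find homologous anchor gene pairs
#'
#' Candidate pairs come either from a precomputed homology hit table (BLAST
#' 12-column tabular, see [read_homology_hits()]) or from the internal
#' aligner: genes sharing at least `min_shared_kmers` protein `kmer_k`-mers
#' are aligned with [align_proteins()] (a seed-and-extend shortcut playing
#' the role of the usual BLAST step on synthetic data). Per query, the
#' `top_k` hits by score with identity `>= min_identity` are kept; in self
#' mode a gene is never its own anchor.
#'
#' @param genesA,genesB gene tables (see [read_gff_genes()]); pass the same
#'   table twice with `self = TRUE` for self-comparison.
#' @param hits optional homology hit table; when `NULL` the internal aligner
#'   is used.
#' @param min_identity minimum alignment identity to keep a pair.
#' @param top_k maximum number of hits kept per query gene.
#' @param self logical: self-comparison mode.
#' @param kmer_k,min_shared_kmers seeding parameters of the internal aligner.
#' @return `data.frame` of anchors: `gene_a`, `gene_b`, `contig_a`,
#'   `contig_b`, `rank_a`, `rank_b`, `score`.
#' @export
find_anchors <- function(genesA, genesB, hits = NULL, min_identity = 0.5,
                         top_k = 5, self = FALSE, kmer_k = 5,
                         min_shared_kmers = 2) {
  if (is.null(hits)) {
    hits <- internal_homology_search(genesA, genesB, kmer_k, min_shared_kmers,
                                     min_identity)
  } else {
    unknown <- c(setdiff(hits$query, genesA$gene_id),
                 setdiff(hits$subject, genesB$gene_id))
    if (length(unknown) > 0) {
      stop("hit references unknown gene: ", unknown[[1]], call. = FALSE)
    }
    hits <- hits[hits$pident / 100 >= min_identity,
                 c("query", "subject", "bitscore")]
    names(hits) <- c("gene_a", "gene_b", "score")
  }
  if (self) hits <- hits[hits$gene_a != hits$gene_b, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_anchor_table())
  # top_k per query by score
  hits <- hits[order(hits$gene_a, -hits$score), , drop = FALSE]
  keep <- stats::ave(hits$score, hits$gene_a, FUN = seq_along) <= top_k
  hits <- hits[keep, , drop = FALSE]
  ia <- match(hits$gene_a, genesA$gene_id)
  ib <- match(hits$gene_b, genesB$gene_id)
  out <- data.frame(gene_a = hits$gene_a, gene_b = hits$gene_b,
                    contig_a = genesA$contig_id[ia],
                    contig_b = genesB$contig_id[ib],
                    rank_a = genesA$gene_rank[ia],
                    rank_b = genesB$gene_rank[ib],
                    score = hits$score, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_anchor_table <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             contig_a = character(), contig_b = character(),
             rank_a = integer(), rank_b = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

internal_homology_search <- function(genesA, genesB, kmer_k, min_shared,
                                     min_identity) {
  protA <- vapply(genesA$cds, function(x) as.character(translate_cds(x)), "")
  protB <- vapply(genesB$cds, function(x) as.character(translate_cds(x)), "")
  names(protA) <- genesA$gene_id
  names(protB) <- genesB$gene_id
  # invert B's k-mer sets once, then count shared k-mers per (query, subject)
  kmB <- lapply(protB, protein_kmers, k = kmer_k)
  idx <- split(rep(seq_along(kmB), lengths(kmB)), unlist(kmB))
  rows <- vector("list", length(protA))
  for (i in seq_along(protA)) {
    km <- protein_kmers(protA[[i]], kmer_k)
    cand <- unlist(idx[km], use.names = FALSE)
    if (length(cand) == 0) next
    counts <- tabulate(cand, nbins = length(protB))
    cand <- which(counts >= min_shared)
    if (length(cand) == 0) next
    res <- lapply(cand, function(j) {
      aln <- align_proteins(protA[[i]], protB[[j]])
      if (aln$identity < min_identity) return(NULL)
      data.frame(gene_a = names(protA)[[i]], gene_b = names(protB)[[j]],
                 score = aln$score, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  out
}

# Optimal single chain over one contig pair and orientation by dynamic
# programming. Anchors must all share contig_a/contig_b. Transitions require
# strictly increasing rank_a, strictly increasing (plus) or strictly
# decreasing (minus) rank_b, and rank increments <= max_gap on both sides.
# Chain score = sum(anchor scores) - gap_penalty * sum((da-1) + (db-1)).
best_chain <- function(anchors, orientation = c("plus", "minus"),
                       max_gap = 25, gap_penalty = 1.0) {
  orientation <- match.arg(orientation)
  n <- nrow(anchors)
  if (n == 0) return(NULL)
  ord <- order(anchors$rank_a, anchors$rank_b)
  a <- anchors[ord, , drop = FALSE]
  best <- a$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- a$rank_a[[i]] - a$rank_a[[j]]
      db <- if (orientation == "plus") a$rank_b[[i]] - a$rank_b[[j]] else
        a$rank_b[[j]] - a$rank_b[[i]]
      if (da < 1 || db < 1 || da > max_gap || db > max_gap) next
      cand <- best[[j]] + a$score[[i]] - gap_penalty * ((da - 1) + (db - 1))
      if (cand > best[[i]]) {
        best[[i]] <- cand
        prev[[i]] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- integer()
  i <- end
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[[i]]
  }
  list(rows = ord[chain], score = best[[end]], orientation = orientation)
}

#' Chain anchors into collinear synteny blocks
#'
#' Per contig pair and orientation, maximum-score chains of anchors are found
#' by dynamic programming (see Details in the package vignette); disjoint
#' chains are extracted greedily by descending chain score, each anchor
#' belonging to at most one block, and chains shorter than `min_block_size`
#' are discarded.
#'
#' @param anchors anchor table from [find_anchors()].
#' @param max_gap maximum rank increment (gene ranks) between consecutive
#'   anchors, on both genomes.
#' @param min_block_size minimum number of anchors per reported block.
#' @param gap_penalty score penalty per skipped gene rank.
#' @return list of `SyntenyBlock` objects: each a list with `block_id`,
#'   `contig_a`, `contig_b`, `orientation`, `score`, `ks_summary` (NA until
#'   [block_ks()]), and an `anchors` data.frame ordered along the chain.
#' @export
chain_collinear <- function(anchors, max_gap = 25, min_block_size = 5,
                            gap_penalty = 1.0) {
  blocks <- list()
  if (nrow(anchors) == 0) return(blocks)
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$contig_a, anchors$contig_b, sep = "\r"))
  bid <- 0L
  for (grp in groups) {
    remaining <- anchors[grp, , drop = FALSE]
    repeat {
      cand <- list(best_chain(remaining, "plus", max_gap, gap_penalty),
                   best_chain(remaining, "minus", max_gap, gap_penalty))
      cand <- Filter(Negate(is.null), cand)
      if (length(cand) == 0) break
      scores <- vapply(cand, `[[`, numeric(1), "score")
      top <- cand[[which.max(scores)]]
      rows <- top$rows
      if (length(rows) >= min_block_size) {
        bid <- bid + 1L
        chain_anchors <- remaining[rows, , drop = FALSE]
        rownames(chain_anchors) <- NULL
        blocks[[bid]] <- structure(list(
          block_id = bid,
          contig_a = chain_anchors$contig_a[[1]],
          contig_b = chain_anchors$contig_b[[1]],
          orientation = top$orientation,
          score = top$score,
          n_anchors = nrow(chain_anchors),
          ks_summary = NA_real_,
          anchors = chain_anchors), class = "SyntenyBlock")
      }
      remaining <- remaining[-rows, , drop = FALSE]
      if (nrow(remaining) < min_block_size) break
    }
  }
  validate_blocks(blocks)
  blocks
}

validate_blocks <- function(blocks) {
  for (b in blocks) {
    stopifnot(all(diff(b$anchors$rank_a) > 0))
    db <- diff(b$anchors$rank_b)
    stopifnot(if (b$orientation == "plus") all(db > 0) else all(db < 0))
  }
  invisible(TRUE)
}

#' @export
print.SyntenyBlock <- function(x, ...) {
  cat(sprintf("SyntenyBlock %d: %s ~ %s (%s), %d anchors, score %.1f, Ks %s\n",
              x$block_id, x$contig_a, x$contig_b, x$orientation, x$n_anchors,
              x$score,
              if (is.na(x$ks_summary)) "NA" else sprintf("%.4f", x$ks_summary)))
  invisible(x)
}

#' Self-synteny with tandem filtering
#'
#' For a genome compared against itself: removes tandem anchors (both genes
#' on one contig within `tandem_rank_window` gene ranks), canonicalises each
#' anchor pair so every duplicated segment is reported once, and chains the
#' remainder with [chain_collinear()]. In an allotetraploid the resulting
#' block pairs are the homoeologous (between-subgenome) duplicate regions.
#'
#' @param genes gene table of the genome.
#' @param anchors self-mode anchor table (see [find_anchors()] with
#'   `self = TRUE`).
#' @param tandem_rank_window same-contig rank distance below which an anchor
#'   is treated as a tandem duplicate and dropped.
#' @inheritParams chain_collinear
#' @return list of `SyntenyBlock` objects.
#' @export
self_synteny <- function(genes, anchors, tandem_rank_window = 5,
                         max_gap = 25, min_block_size = 5, gap_penalty = 1.0) {
  if (nrow(anchors) == 0) return(list())
  tandem <- anchors$contig_a == anchors$contig_b &
    abs(anchors$rank_a - anchors$rank_b) < tandem_rank_window
  if (any(tandem)) {
    ad_log("debug", "self_synteny: filtered ", sum(tandem), " tandem anchors")
    anchors <- anchors[!tandem, , drop = FALSE]
  }
  if (nrow(anchors) == 0) return(list())
  # canonical order: (contig, rank) of side a lexicographically before side b
  flip <- anchors$contig_a > anchors$contig_b |
    (anchors$contig_a == anchors$contig_b & anchors$rank_a > anchors$rank_b)
  if (any(flip)) {
    tmp <- anchors[flip, ]
    anchors[flip, c("gene_a", "contig_a", "rank_a")] <-
      tmp[, c("gene_b", "contig_b", "rank_b")]
    anchors[flip, c("gene_b", "contig_b", "rank_b")] <-
      tmp[, c("gene_a", "contig_a", "rank_a")]
  }
  anchors <- anchors[!duplicated(anchors[c("gene_a", "gene_b")]), , drop = FALSE]
  chain_collinear(anchors, max_gap = max_gap, min_block_size = min_block_size,
                  gap_penalty = gap_penalty)
}

#' Read a blocks TSV back into `SyntenyBlock` objects
#'
#' Inverse of [write_blocks()].
#'
#' @param path blocks TSV path.
#' @return list of `SyntenyBlock`s.
#' @export
read_blocks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$block_id), function(d) {
    anchors <- d[setdiff(names(d), c("block_id", "orientation", "n_anchors",
                                     "score", "ks_summary"))]
    rownames(anchors) <- NULL
    structure(list(block_id = d$block_id[[1]],
                   contig_a = d$contig_a[[1]], contig_b = d$contig_b[[1]],
                   orientation = d$orientation[[1]], score = d$score[[1]],
                   n_anchors = nrow(d), ks_summary = d$ks_summary[[1]],
                   anchors = anchors), class = "SyntenyBlock")
  })
}

#' Write synteny blocks as TSV
#'
#' One row per anchor with its block metadata: `block_id`, `contig_a`,
#' `contig_b`, `orientation`, `n_anchors`, `score`, `ks_summary`, `gene_a`,
#' `gene_b`, `rank_a`, `rank_b` (and `ks` when [block_ks()] has run).
#'
#' @param blocks list of `SyntenyBlock`s.
#' @param path output TSV path.
#' @export
write_blocks <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    cbind(data.frame(block_id = b$block_id, orientation = b$orientation,
                     n_anchors = b$n_anchors, score = b$score,
                     ks_summary = b$ks_summary),
          b$anchors)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(block_id = integer(), orientation = character(),
                     n_anchors = integer(), score = numeric(),
                     ks_summary = numeric())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
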