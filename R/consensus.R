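# Chloroplast consensus building and per-gene nucleotide diversity.
#
# Consensus sequences are built per accession against one shared reference,
# so all accessions remain in reference coordinates and per-gene diversity
# needs no multiple alignment. Only substitution variants passing the phred
# quality threshold (default 30, strict >=) are applied; indels are skipped
# so the consensus keeps the reference length.

#' Apply quality-filtered variants to a reference sequence
#'
#' Substitutions with `qual >= min_qual` are applied; lower-quality records
#' are ignored. Indel records (REF or ALT longer than 1 bp) are skipped with
#' a warning so the consensus stays reference-length. When several accepted
#' substitutions hit one position, the highest-quality one wins (warned).
#' A REF allele that does not match the reference is an error naming
#' `contig:pos`.
#'
#' @param reference single named DNA string (one element of [read_fasta()]
#'   output) or an unnamed string plus `contig_id`.
#' @param variants variant table (see [read_variant_table()]).
#' @param min_qual phred threshold; records with `qual >= min_qual` are used.
#' @param contig_id reference contig name; defaults to `names(reference)`.
#' @return consensus DNA string, same length as the reference.
#' @export
apply_variants <- function(reference, variants, min_qual = 30,
                           contig_id = names(reference)) {
  ref <- unname(reference[[1]])
  contig_id <- contig_id %||% "ref"
  v <- variants[variants$contig_id == contig_id, , drop = FALSE]
  if (nrow(v) == 0) return(setNames(ref, contig_id))
  indel <- nchar(v$ref) != 1L | nchar(v$alt) != 1L
  if (any(indel)) {
    ad_log("warn", "skipping ", sum(indel), " indel variant record(s)")
    v <- v[!indel, , drop = FALSE]
  }
  if (nrow(v) == 0) return(setNames(ref, contig_id))
  if (any(v$pos < 1 | v$pos > nchar(ref))) {
    stop("variant position outside reference", call. = FALSE)
  }
  ref_at <- substring(ref, v$pos, v$pos)
  bad <- which(ref_at != v$ref)
  if (length(bad) > 0) {
    stop(sprintf("REF mismatch at %s:%d (expected %s, file says %s)",
                 contig_id, v$pos[[bad[[1]]]], ref_at[[bad[[1]]]],
                 v$ref[[bad[[1]]]]), call. = FALSE)
  }
  v <- v[v$qual >= min_qual, , drop = FALSE]
  if (nrow(v) == 0) return(setNames(ref, contig_id))
  v <- v[order(v$pos, -v$qual), , drop = FALSE]
  dup <- duplicated(v$pos)
  if (any(dup)) {
    ad_log("warn", "overlapping accepted variants at ", sum(dup),
           " position(s); keeping highest quality")
    v <- v[!dup, , drop = FALSE]
  }
  chars <- strsplit(ref, "")[[1]]
  chars[v$pos] <- v$alt
  setNames(paste(chars, collapse = ""), contig_id)
}

#' Coverage masks and the comprehensively-covered gene filter
#'
#' A coverage mask is a `data.frame` of 1-based inclusive intervals
#' (`contig_id`, `start`, `end`) giving the reference positions covered by
#' one accession's reads. `filter_covered_genes()` keeps the genes whose
#' interval is covered at fraction `>= min_fraction` in EVERY accession —
#' the regions on which per-gene diversity across accessions is meaningful.
#'
#' @param genes gene table (see [read_gff_genes()]).
#' @param masks named list of coverage mask data.frames, one per accession.
#' @param min_fraction minimum covered fraction per gene per accession
#'   (default 1.0: comprehensive coverage).
#' @return the subset of `genes` passing the filter.
#' @export
filter_covered_genes <- function(genes, masks, min_fraction = 1.0) {
  if (length(masks) == 0) stop("no coverage masks supplied", call. = FALSE)
  if (min_fraction <= 0) return(genes)
  keep <- rep(TRUE, nrow(genes))
  for (acc in names(masks) %||% seq_along(masks)) {
    mask <- masks[[acc]]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      mi <- mask[mask$contig_id == g$contig_id, , drop = FALSE]
      gene_ir <- IRanges::IRanges(g$start, g$end)
      cov_ir <- IRanges::reduce(IRanges::IRanges(mi$start, mi$end))
      covered <- sum(IRanges::width(IRanges::intersect(gene_ir, cov_ir)))
      frac <- covered / (g$end - g$start + 1)
      if (frac < min_fraction) {
        keep[[i]] <- FALSE
        ad_log("warn", "gene ", g$gene_id, " covered ",
               sprintf("%.0f%%", 100 * frac), " in accession ", acc,
               ": dropped")
      }
    }
  }
  genes[keep, , drop = FALSE]
}

#' Nucleotide diversity (Pi) of a set of aligned sequences
#'
#' Sites containing a gap or `N` in ANY sequence are excluded (complete
#' deletion, the DnaSP convention). Over the `L` remaining sites,
#' `pi = (2 / (n (n - 1))) * sum_{i<j} d_ij / L`, the average pairwise
#' difference per site. The reported `sd` is the sample standard deviation
#' of the `n (n - 1) / 2` per-pair per-site distances.
#'
#' @param seqs >= 2 equal-length DNA strings (shared reference coordinates).
#' @param gene_id optional identifier carried into the result.
#' @return object of class `PiResult`: list with `gene_id`, `pi`, `sd`,
#'   `n_sites` (sites used), `n_seqs`.
#' @export
nucleotide_diversity <- function(seqs, gene_id = NA_character_) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  m <- encode_alignment(seqs)
  ok <- colSums(is.na(m)) == 0
  L <- sum(ok)
  if (L == 0) stop("no comparable sites", call. = FALSE)
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  per_pair <- numeric(n * (n - 1) / 2)
  k <- 0L
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      d <- sum(m[i, ] != m[j, ])
      per_pair[[k]] <- d / L
      total <- total + d
    }
  }
  pi <- 2 / (n * (n - 1)) * total / L
  structure(list(gene_id = gene_id, pi = pi,
                 sd = if (k > 1) sd(per_pair) else 0,
                 n_sites = L, n_seqs = n), class = "PiResult")
}

#' Per-gene nucleotide diversity across accession consensuses
#'
#' Extracts each gene's interval from every accession consensus (all in
#' shared reference coordinates) and computes [nucleotide_diversity()] per
#' gene. Rows are sorted by `pi` descending.
#'
#' @param consensuses named list (or vector) of accession consensus
#'   sequences, all the same length as the reference.
#' @param genes gene table restricted to one reference contig (coordinates
#'   index into the consensuses).
#' @return `data.frame` with columns `gene_id`, `pi`, `sd`, `n_sites`,
#'   `n_seqs`, sorted by `pi` descending.
#' @export
pi_table <- function(consensuses, genes) {
  seqs <- unlist(consensuses)
  if (length(unique(nchar(seqs))) != 1) {
    stop("consensus sequences differ in length", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sub <- substring(seqs, g$start, g$end)
    res <- nucleotide_diversity(setNames(sub, names(seqs)), g$gene_id)
    data.frame(gene_id = res$gene_id, pi = res$pi, sd = res$sd,
               n_sites = res$n_sites, n_seqs = res$n_seqs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pi, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
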