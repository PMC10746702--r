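# Subgenome assignment: Ks-based partitioning of self-synteny block pairs
# and depth-of-coverage (DOC) classification of contigs from progenitor
# reads, plus reconciliation of the two routes.

#' Partition self-synteny block pairs into A and B subgenome copies
#'
#' Each self-synteny block is a pair of homoeologous copies (its `a` and `b`
#' sides). For each side the median NG86 dS to the progenitor-A ortholog is
#' computed over that side's genes with an entry in `ortholog_ks_to_refA`;
#' the side with the strictly lower median is labelled `A` (it is the copy
#' closer to progenitor A), the other `B`. Sides without usable orthologs,
#' or tied medians, leave both copies unassigned (logged).
#'
#' @param self_blocks list of `SyntenyBlock`s from [self_synteny()] of the
#'   tetraploid genome against itself.
#' @param ortholog_ks_to_refA named numeric vector: tetraploid gene id ->
#'   dS versus its progenitor-A ortholog.
#' @return `data.frame` of `SubgenomeLabel` rows: `unit_id` (block copy id
#'   `<block>_a` / `<block>_b`), `block_id`, `side`, `contig_id`, `label`
#'   (`A`, `B`, or `unassigned`), `evidence` = `"ks"`, `median_ks`.
#' @export
partition_ab <- function(self_blocks, ortholog_ks_to_refA) {
  rows <- lapply(self_blocks, function(b) {
    if (is.null(b$anchors) || nrow(b$anchors) == 0) {
      stop("malformed block pair: block ", b$block_id, " has no anchors",
           call. = FALSE)
    }
    med <- function(genes) {
      ks <- ortholog_ks_to_refA[genes[genes %in% names(ortholog_ks_to_refA)]]
      if (length(ks) == 0) NA_real_ else median(ks, na.rm = TRUE)
    }
    ma <- med(b$anchors$gene_a)
    mb <- med(b$anchors$gene_b)
    lab_a <- lab_b <- "unassigned"
    if (!is.na(ma) && !is.na(mb) && ma != mb) {
      lab_a <- if (ma < mb) "A" else "B"
      lab_b <- if (ma < mb) "B" else "A"
    } else {
      ad_log("warn", "block ", b$block_id,
             ": unassigned (missing orthologs or tied medians)")
    }
    data.frame(
      unit_id = paste0("block", b$block_id, c("_a", "_b")),
      block_id = b$block_id, side = c("a", "b"),
      contig_id = c(b$contig_a, b$contig_b),
      label = c(lab_a, lab_b), evidence = "ks",
      median_ks = c(ma, mb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame()
  rownames(out) <- NULL
  out
}

#' Assign reads to contigs by shared k-mers and compute depth of coverage
#'
#' Indexes all canonical contig k-mers, assigns each read to the contig with
#' which it shares the most k-mers (ties and reads sharing none are counted
#' unassigned), and reports per-contig mean depth = assigned bases / contig
#' length. This is a defined, deterministic stand-in for read mapping that
#' is exact on simulated data; it is NOT a general-purpose aligner.
#'
#' @param reads named character vector of read sequences (or FASTQ path).
#' @param contigs named character vector of contig sequences.
#' @param k k-mer size (odd, <= 31; default 31).
#' @param sample_name name of the depth column in the result.
#' @return `data.frame` with `contig_id`, `length`, and a depth column named
#'   `sample_name`; attribute `unassigned_fraction` gives the unassigned
#'   read fraction.
#' @export
assign_reads_by_kmer <- function(reads, contigs, k = 31, sample_name = "depth") {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (k > min(nchar(reads))) stop("k exceeds read length", call. = FALSE)
  idx <- .kmer_assign_cpp(as.character(reads), as.character(contigs),
                          as.integer(k))
  assigned_bases <- vapply(seq_along(contigs), function(ci) {
    sum(nchar(reads)[idx == ci])
  }, numeric(1))
  unassigned <- mean(idx == 0)
  if (unassigned > 0) {
    ad_log("info", sprintf("%.2f%% of reads unassigned (tie or no shared k-mer)",
                           100 * unassigned))
  }
  out <- data.frame(contig_id = names(contigs), length = nchar(contigs),
                    stringsAsFactors = FALSE)
  out[[sample_name]] <- assigned_bases / out$length
  attr(out, "unassigned_fraction") <- unassigned
  out
}

#' Classify contigs by depth of coverage from the two progenitors
#'
#' The classification rule: a contig covered below `threshold` by progenitor
#' A's reads but at or above it by progenitor B's reads is of B origin (A
#' reads fail to map to it), and symmetrically; below threshold in both is
#' `unassigned_both` (typically organellar/repeat contigs), at or above in
#' both `unassigned_ambiguous`. Optionally only contigs of length >= the
#' assembly N90 are classified. The summary table reports, per condition,
#' the contig count, total bp, and the mean (sd) of the OTHER progenitor's
#' depth — the shape of a depth-of-coverage classification table.
#'
#' @param depths depth table with columns `contig_id`, `length`, and one
#'   depth column per sample (see [assign_reads_by_kmer()] /
#'   [read_depth_table()]).
#' @param sampleA,sampleB names of the two progenitor depth columns.
#' @param threshold DOC threshold (x); comparison is strictly `<`.
#' @param n90_filter restrict to contigs with length >= assembly N90.
#' @param length_weighted if `TRUE`, summary means are weighted by contig
#'   length (default unweighted per-contig means).
#' @return list with `labels` (`data.frame`: `unit_id`, `contig_id`, `label`
#'   in `{A, B, unassigned}`, `condition`, `evidence` = `"doc"`, both
#'   depths) and `summary` (the per-condition `DocSummary` table).
#' @export
classify_contigs_doc <- function(depths, sampleA, sampleB, threshold = 16.0,
                                 n90_filter = TRUE, length_weighted = FALSE) {
  for (s in c(sampleA, sampleB)) {
    if (!s %in% names(depths)) stop("missing sample depth column: ", s, call. = FALSE)
    if (anyNA(depths[[s]])) stop("missing sample depth for some contig: ", s, call. = FALSE)
  }
  if (n90_filter && nrow(depths) > 0) {
    n90 <- assembly_stats(depths$length)$N90
    depths <- depths[depths$length >= n90, , drop = FALSE]
  }
  dA <- depths[[sampleA]]
  dB <- depths[[sampleB]]
  lowA <- dA < threshold
  lowB <- dB < threshold
  condition <- ifelse(lowA & !lowB, paste0("doc_under_", sampleA),
               ifelse(lowB & !lowA, paste0("doc_under_", sampleB),
               ifelse(lowA & lowB, "doc_under_both", "ambiguous")))
  # A reads absent => contig belongs to the B subgenome, and vice versa
  label <- ifelse(lowA & !lowB, "B", ifelse(lowB & !lowA, "A", "unassigned"))
  labels <- data.frame(unit_id = depths$contig_id,
                       contig_id = depths$contig_id,
                       label = label, condition = condition,
                       evidence = "doc", stringsAsFactors = FALSE)
  labels[[sampleA]] <- dA
  labels[[sampleB]] <- dB
  mstat <- function(x, w) {
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    if (length_weighted) {
      mu <- sum(x * w) / sum(w)
      c(mu, sqrt(sum(w * (x - mu)^2) / sum(w)))
    } else {
      c(mean(x), if (length(x) > 1) sd(x) else 0)
    }
  }
  conds <- c(paste0("doc_under_", sampleA), paste0("doc_under_", sampleB),
             "doc_under_both", "ambiguous")
  other <- c(sampleB, sampleA, NA, NA)
  srows <- lapply(seq_along(conds), function(i) {
    sel <- condition == conds[[i]]
    ms <- if (is.na(other[[i]])) c(NA_real_, NA_real_) else
      mstat(depths[[other[[i]]]][sel], depths$length[sel])
    data.frame(condition = conds[[i]], contig_number = sum(sel),
               total_size = sum(depths$length[sel]),
               other_sample = other[[i]],
               other_depth_mean = ms[[1]], other_depth_sd = ms[[2]],
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, srows)
  stopifnot(sum(summary$contig_number) == nrow(depths))
  list(labels = labels, summary = summary)
}

#' Reconcile Ks-based and DOC-based subgenome labels
#'
#' Maps each Ks-labelled block copy to its contig and compares with the DOC
#' label of that contig. Blocks detected within a single contig (both sides
#' on one contig) are flagged self-contained and excluded from the
#' agreement, as are units where either route is unassigned. The agreement
#' fraction is reported together with the per-unit comparison.
#'
#' @param ks_labels output of [partition_ab()].
#' @param doc_labels `labels` element of [classify_contigs_doc()].
#' @return list with `agreement` (fraction in \[0,1\], `NA` when no unit is
#'   comparable), `n_compared`, `disagreements` (data.frame), and `detail`
#'   (all compared units).
#' @export
reconcile <- function(ks_labels, doc_labels) {
  if (nrow(ks_labels) == 0) {
    return(list(agreement = NA_real_, n_compared = 0L,
                disagreements = data.frame(), detail = data.frame()))
  }
  self_contained <- stats::ave(ks_labels$contig_id, ks_labels$block_id,
                               FUN = function(x) length(unique(x))) == "1"
  if (any(self_contained)) {
    ad_log("info", "excluding ", length(unique(ks_labels$block_id[self_contained])),
           " self-contained block(s) from reconciliation")
  }
  doc <- setNames(doc_labels$label, doc_labels$contig_id)
  detail <- ks_labels[!self_contained, , drop = FALSE]
  detail$doc_label <- unname(doc[detail$contig_id])
  detail$self_contained <- FALSE
  comparable <- !is.na(detail$doc_label) & detail$doc_label != "unassigned" &
    detail$label != "unassigned"
  detail$comparable <- comparable
  agree <- detail$label[comparable] == detail$doc_label[comparable]
  list(agreement = if (any(comparable)) mean(agree) else NA_real_,
       n_compared = sum(comparable),
       disagreements = detail[comparable, , drop = FALSE][!agree, , drop = FALSE],
       detail = detail)
}
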