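# Readers and writers for every on-disk format the pipeline touches.
# Convention: coordinates are 1-based inclusive on disk (GFF/VCF style) and
# converted at this boundary; in memory gene intervals keep the on-disk
# representation in `start`/`end` plus a pre-extracted coding sequence.

VALID_DNA <- c("A", "C", "G", "T", "N")

check_dna <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), VALID_DNA)
  if (length(bad) > 0) {
    stop(sprintf("%s contains unsupported residue(s): %s (only A,C,G,T,N allowed)",
                 what, paste(bad, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write FASTA genome sequences
#'
#' Sequences are uppercased on read and validated against the alphabet
#' `{A,C,G,T,N}`; IUPAC ambiguity codes other than `N` are rejected so that
#' foreign data fails loudly rather than silently perturbing downstream
#' counts. `read_fasta()` returns a named character vector (names are the
#' sequence ids); `write_fasta()` wraps at `width` columns and round-trips
#' exactly up to line wrapping.
#'
#' @param path file path (FASTA; may be gzip-compressed on read).
#' @return `read_fasta()`: named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate id: ", dup[[1]], call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id: ", ids[nchar(seqs) == 0][[1]], call. = FALSE)
  }
  check_dna(seqs, basename(path))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA strings.
#' @param width line-wrap width for the sequence lines.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write FASTQ reads
#'
#' Reads are returned as a named character vector of uppercase sequences;
#' qualities are a constant-Q affair in this package (the simulator emits a
#' single phred value) and are not retained on read. `write_fastq()` writes
#' four-line records with a constant quality character; a `.gz` suffix
#' triggers gzip compression.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_fastq
#' @param reads named character vector of read sequences.
#' @param qual_char single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), 4)] <- reads
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep(qual_char, nchar(reads))
  writeLines(lines, con)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read CDS gene models from a GFF3 file
#'
#' Parses CDS features (other feature types are ignored), extracts the coding
#' sequence from `fasta`, reverse-complements minus-strand models so the
#' stored `cds` is always the 5'->3' coding strand, trims a terminal stop
#' codon, and assigns `gene_rank`: the 1..n ordinal of each gene along its
#' contig by start coordinate. Models whose CDS length is not divisible by 3
#' or that contain an internal stop codon are skipped with a warning log.
#'
#' @param path GFF3 file with CDS features carrying an `ID` attribute.
#' @param fasta named character vector of contig sequences (see [read_fasta()]).
#' @return a `data.frame` with columns `gene_id`, `contig_id`, `start`, `end`
#'   (1-based inclusive), `strand`, `cds`, `gene_rank`.
#' @export
read_gff_genes <- function(path, fasta) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) {
    ad_log("warn", "no CDS features in ", path)
    return(empty_gene_table())
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene", seq_along(gr))
  grdf <- as.data.frame(gr)
  df <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(grdf$seqnames),
    start = as.integer(grdf$start),
    end = as.integer(grdf$end),
    strand = as.character(grdf$strand),
    stringsAsFactors = FALSE
  )
  build_gene_table(df, fasta)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), contig_id = character(), start = integer(),
             end = integer(), strand = character(), cds = character(),
             gene_rank = integer(), stringsAsFactors = FALSE)
}

# Shared finishing step: CDS extraction, validation, rank assignment.
build_gene_table <- function(df, fasta) {
  unknown <- setdiff(df$contig_id, names(fasta))
  if (length(unknown) > 0) {
    stop("gene on unknown contig: ", unknown[[1]], call. = FALSE)
  }
  clen <- nchar(fasta)[df$contig_id]
  if (any(df$start < 1 | df$end > clen | df$start > df$end)) {
    bad <- which(df$start < 1 | df$end > clen | df$start > df$end)[[1]]
    stop(sprintf("coordinates outside contig for gene %s (%s:%d-%d)",
                 df$gene_id[[bad]], df$contig_id[[bad]], df$start[[bad]],
                 df$end[[bad]]), call. = FALSE)
  }
  cds <- substring(fasta[df$contig_id], df$start, df$end)
  minus <- df$strand == "-"
  if (any(minus)) cds[minus] <- reverse_complement(cds[minus])
  keep <- rep(TRUE, nrow(df))
  phase_bad <- nchar(cds) %% 3L != 0L
  if (any(phase_bad)) {
    for (g in df$gene_id[phase_bad]) {
      ad_log("warn", "skipping gene ", g, ": CDS length not divisible by 3")
    }
    keep <- keep & !phase_bad
  }
  ok <- keep
  for (i in which(keep)) {
    tr <- try(translate_cds(cds[[i]]), silent = TRUE)
    if (inherits(tr, "try-error")) {
      ad_log("warn", "skipping gene ", df$gene_id[[i]], ": ",
             attr(tr, "condition")$message)
      ok[[i]] <- FALSE
    } else {
      cds[[i]] <- attr(tr, "cds") # terminal stop trimmed
    }
  }
  df <- df[ok, , drop = FALSE]
  df$cds <- cds[ok]
  df <- df[order(df$contig_id, df$start), , drop = FALSE]
  df$gene_rank <- stats::ave(df$start, df$contig_id, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' @rdname read_gff_genes
#' @param genes gene table as returned by `read_gff_genes()`.
#' @param source source column value to write.
#' @export
write_gff_genes <- function(genes, path, source = "allodonor") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$contig_id, source, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Assembly contiguity statistics
#'
#' `Nx` is the smallest contig length `L` such that contigs of length `>= L`
#' together cover at least `x`% of the assembly; `Lx` is the number of
#' contigs needed to reach that fraction. The N90 value doubles as the length
#' cutoff used to select contigs for depth-of-coverage classification.
#'
#' @param lengths vector of positive contig lengths (bp).
#' @return list with `n_contigs`, `total_bp`, `N50`, `N90`, `L50`, `L90`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1)) # N50 = 4, N90 = 2
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("contig lengths must be positive", call. = FALSE)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(lengths)
  cum <- cumsum(lengths)
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[[1]]
    list(N = lengths[[i]], L = i)
  }
  s50 <- nx(50); s90 <- nx(90)
  list(n_contigs = length(lengths), total_bp = total,
       N50 = s50$N, N90 = s90$N, L50 = s50$L, L90 = s90$L)
}

read_typed_tsv <- function(path, required, what) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s %s: missing column(s) %s", what, path,
                 paste(missing, collapse = ",")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    ad_log("warn", what, ": ignoring extra column(s) ",
           paste(extra, collapse = ","))
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad) > 0) {
    stop(sprintf("line %d: expected %d columns", bad[[1]] + 1L,
                 length(required)), call. = FALSE)
  }
  df[required]
}

#' Typed TSV readers: depth tables, homology hits, two-column maps
#'
#' `read_depth_table()` expects a header line `contig_id  length  <sample1>
#' <sample2> ...` and returns one row per contig with one numeric depth
#' column per sample. `read_homology_hits()` reads the 12-column BLAST
#' tabular dialect (qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore), headerless. `read_tsv_map()`
#' reads a headered two-column key/value map into a named character vector.
#'
#' @param path TSV file path.
#' @return typed `data.frame` (or named vector for `read_tsv_map()`).
#' @export
read_depth_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("contig_id", "length") %in% names(df))) {
    stop("depth table must have contig_id and length columns", call. = FALSE)
  }
  samples <- setdiff(names(df), c("contig_id", "length"))
  if (length(samples) == 0) stop("depth table has no sample columns", call. = FALSE)
  for (s in c("length", samples)) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric value in column %s",
                               which(is.na(v))[[1]] + 1L, s), call. = FALSE)
    df[[s]] <- v
  }
  if (any(df$length <= 0)) stop("contig length must be > 0", call. = FALSE)
  if (any(df[samples] < 0)) stop("depths must be >= 0", call. = FALSE)
  df
}

#' @rdname read_depth_table
#' @param depths depth table (`data.frame`) to write.
#' @export
write_depth_table <- function(depths, path) {
  write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_depth_table
#' @export
read_homology_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) != 12L) {
    stop(sprintf("line 1: expected 12 columns, found %d", ncol(df)),
         call. = FALSE)
  }
  names(df) <- cols
  for (cc in cols[3:12]) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric %s",
                               which(is.na(v))[[1]], cc), call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' @rdname read_depth_table
#' @param key,value column names to use for the returned map.
#' @export
read_tsv_map <- function(path, key = NULL, value = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2) stop("map file needs at least two columns", call. = FALSE)
  key <- key %||% names(df)[[1]]
  value <- value %||% names(df)[[2]]
  setNames(as.character(df[[value]]), as.character(df[[key]]))
}

#' VCF-like variant tables
#'
#' The consensus stage consumes a minimal VCF-like TSV with columns
#' `CHROM POS REF ALT QUAL` (1-based positions, phred-scaled quality).
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `contig_id`, `pos`, `ref`, `alt`, `qual`.
#' @export
read_variant_table <- function(path) {
  df <- read_typed_tsv(path, c("CHROM", "POS", "REF", "ALT", "QUAL"), "variant table")
  out <- data.frame(contig_id = as.character(df$CHROM),
                    pos = as.integer(df$POS),
                    ref = toupper(as.character(df$REF)),
                    alt = toupper(as.character(df$ALT)),
                    qual = as.numeric(df$QUAL),
                    stringsAsFactors = FALSE)
  if (any(out$qual < 0)) stop("negative QUAL", call. = FALSE)
  out
}

#' @rdname read_variant_table
#' @param variants variant table to write.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.frame(CHROM = variants$contig_id, POS = variants$pos,
                    REF = variants$ref, ALT = variants$alt,
                    QUAL = variants$qual)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
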