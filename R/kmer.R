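# k-mer histogram and genome-size estimation from reads.

#' Canonical k-mer histogram of a read set
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and its
#' reverse complement) over all reads; windows containing `N` are skipped.
#' `k` must be odd (an even k can equal its own reverse complement, making
#' the canonical form ambiguous) and between 15 and 31 for genome-scale use,
#' though any odd `k <= 31` is accepted for small inputs.
#'
#' @param reads character vector of read sequences.
#' @param k odd k-mer size, at most 31.
#' @return object of class `KmerHistogram`: list with `k`, `counts` (a
#'   `data.frame` of `multiplicity`, `n_kmers` sorted by multiplicity) and
#'   `total_kmers` (= sum of multiplicity x n_kmers).
#' @export
kmer_histogram <- function(reads, k) {
  if (k %% 2 == 0) stop("k must be odd (canonical-form ambiguity)", call. = FALSE)
  if (k > 31) stop("k must be <= 31", call. = FALSE)
  m <- .kmer_hist_cpp(as.character(reads), as.integer(k))
  df <- as.data.frame(m)
  df <- df[order(df$multiplicity), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(k = as.integer(k), counts = df,
                 total_kmers = sum(as.numeric(df$multiplicity) * df$n_kmers)),
            class = "KmerHistogram")
}

#' @export
print.KmerHistogram <- function(x, ...) {
  cat(sprintf("KmerHistogram: k = %d, %d distinct multiplicities, %.0f total k-mers\n",
              x$k, nrow(x$counts), x$total_kmers))
  invisible(x)
}

#' Estimate genome size from a k-mer histogram
#'
#' Single-peak homozygous model: the error peak at low multiplicity is
#' separated from the main (coverage) peak at the first local minimum of
#' the histogram; `peak_depth` is the multiplicity of the main peak above
#' that cutoff and `genome_size = sum(m * count(m), m > cutoff) /
#' peak_depth`. With error-free reads the error peak is absent and a cutoff
#' of 0 is accepted.
#'
#' @param hist a [kmer_histogram()] result.
#' @return list with `error_cutoff`, `peak_depth`, `genome_size_bp`.
#' @export
estimate_genome_size <- function(hist) {
  df <- hist$counts
  full <- rep(0, max(df$multiplicity))
  full[df$multiplicity] <- df$n_kmers
  if (length(full) < 2) stop("degenerate histogram", call. = FALSE)
  if (full[[1]] <= full[[2]]) {
    cutoff <- 0L # no descending error limb at multiplicity 1: accept everything
  } else {
    drops <- which(diff(full) > 0) # first rise after the descending error limb
    if (length(drops) == 0) {
      stop("cannot separate error peak: histogram has no local minimum",
           call. = FALSE)
    }
    cutoff <- drops[[1]]
  }
  main <- full
  if (cutoff > 0) main[seq_len(cutoff)] <- 0
  peak_depth <- which.max(main)
  m <- seq_along(full)
  use <- m > cutoff
  genome_size <- sum(m[use] * full[use]) / peak_depth
  list(error_cutoff = cutoff, peak_depth = peak_depth,
       genome_size_bp = genome_size)
}
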