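# Nei-Gojobori (1986) synonymous/nonsynonymous rate estimation.
#
# Site counting: for each codon position the synonymous site fraction is the
# number of the three single-base neighbours that encode the same amino acid,
# divided by 3; mutations to stop codons count as nonsynonymous sites.
# Difference counting: for a codon pair differing at d positions, all d!
# substitution orders are enumerated; paths passing through a stop codon are
# excluded and the synonymous/nonsynonymous step counts are averaged with
# equal weight over the remaining paths (all paths, if every one is blocked).
# Proportions are Jukes-Cantor corrected; pS or pN >= 0.75 sets a saturation
# flag instead of a numeric rate. All per-codon quantities are precomputed
# into 64-entry / 64x64 lookup tables, so estimation over long CDS is a
# vectorised table lookup.

.ad_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  if (is.null(.ad_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- names(gc) # codons with T
    .ad_cache$gc <- gc
  }
  .ad_cache$gc
}

codon_index <- function(codons) {
  match(codons, names(genetic_code()))
}

# Per-codon synonymous site count (sum over the 3 positions of the fraction
# of synonymous single-base neighbours). Stop codons -> NA.
ng86_site_table <- function() {
  if (!is.null(.ad_cache$sites)) return(.ad_cache$sites)
  gc <- genetic_code()
  codons <- names(gc)
  sites <- vapply(codons, function(cd) {
    if (gc[[cd]] == "*") return(NA_real_)
    chars <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[[pos]])) {
        nb <- chars
        nb[[pos]] <- b
        nb <- paste(nb, collapse = "")
        if (gc[[nb]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .ad_cache$sites <- sites
  sites
}

# Path-averaged synonymous (Sd) and nonsynonymous (Nd) difference counts for
# every ordered codon pair; stop-containing pairs -> NA.
ng86_diff_tables <- function() {
  if (!is.null(.ad_cache$sd)) return(list(sd = .ad_cache$sd, nd = .ad_cache$nd))
  gc <- genetic_code()
  codons <- names(gc)
  n <- length(codons)
  sd_t <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_t <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    ci <- strsplit(codons[[i]], "")[[1]]
    if (gc[[i]] == "*") next
    for (j in seq_len(n)) {
      if (gc[[j]] == "*") next
      cj <- strsplit(codons[[j]], "")[[1]]
      diffpos <- which(ci != cj)
      d <- length(diffpos)
      if (d == 0L) { sd_t[i, j] <- 0; nd_t[i, j] <- 0; next }
      paths <- lapply(perms[[d]], function(ord) diffpos[ord])
      step_counts <- lapply(paths, function(order) {
        cur <- ci
        s_cnt <- 0; n_cnt <- 0; blocked <- FALSE
        for (pos in order) {
          nxt <- cur
          nxt[[pos]] <- cj[[pos]]
          aa_from <- gc[[paste(cur, collapse = "")]]
          aa_to <- gc[[paste(nxt, collapse = "")]]
          # endpoints are non-stop, so a stop here is always an intermediate
          if (aa_to == "*") blocked <- TRUE
          if (aa_from == aa_to) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
          cur <- nxt
        }
        c(s = s_cnt, n = n_cnt, blocked = as.numeric(blocked))
      })
      m <- do.call(rbind, step_counts)
      ok <- m[, "blocked"] == 0
      if (!any(ok)) ok <- rep(TRUE, nrow(m)) # all blocked: fall back to all
      sd_t[i, j] <- mean(m[ok, "s"])
      nd_t[i, j] <- mean(m[ok, "n"])
    }
  }
  .ad_cache$sd <- sd_t
  .ad_cache$nd <- nd_t
  list(sd = sd_t, nd = nd_t)
}

#' Translate a coding sequence
#'
#' Validates that the CDS length is a multiple of 3, contains only `A,C,G,T`,
#' and has no internal stop codon; a terminal stop is allowed and trimmed.
#'
#' @param cds DNA string (coding strand, 5'->3').
#' @return the protein string; the trimmed CDS is attached as attribute
#'   `"cds"`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (nchar(cds) == 0L) stop("empty CDS", call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  idx <- codon_index(codons)
  if (anyNA(idx)) stop("CDS contains untranslatable codon: ",
                       codons[is.na(idx)][[1]], call. = FALSE)
  aa <- unname(genetic_code()[idx])
  n <- length(aa)
  if (aa[[n]] == "*") {
    aa <- aa[-n]
    codons <- codons[-n]
  }
  if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
  structure(paste(aa, collapse = ""), cds = paste(codons, collapse = ""))
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Protein-guided codon alignment of two CDS
#'
#' Translates both CDS, aligns the proteins globally (BLOSUM62, affine gaps,
#' see [align_proteins()]), and back-threads the alignment onto codons.
#' Columns with a gap in either protein are dropped, so the result is a pair
#' of equal-length codon vectors ready for [ng86()].
#'
#' @param cds1,cds2 coding sequences (length divisible by 3, translatable).
#' @return list with codon character vectors `codons1`, `codons2` and the
#'   aligned protein strings.
#' @export
codon_align <- function(cds1, cds2) {
  p1 <- translate_cds(cds1); p2 <- translate_cds(cds2)
  c1 <- split_codons(attr(p1, "cds"))
  c2 <- split_codons(attr(p2, "cds"))
  aln <- align_proteins(as.character(p1), as.character(p2))
  a1 <- strsplit(aln$aligned1, "")[[1]]
  a2 <- strsplit(aln$aligned2, "")[[1]]
  i1 <- cumsum(a1 != "-")
  i2 <- cumsum(a2 != "-")
  keep <- a1 != "-" & a2 != "-"
  list(codons1 = c1[i1[keep]], codons2 = c2[i2[keep]],
       aligned1 = aln$aligned1, aligned2 = aln$aligned2)
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) dS/dN for an aligned codon pair set
#'
#' @param codons1,codons2 equal-length character vectors of codons (no stops,
#'   no gaps; produce them with [codon_align()]).
#' @return object of class `KsEstimate`: a list with expected site counts
#'   `S`, `N`, path-averaged difference counts `Sd`, `Nd`, proportions `pS`,
#'   `pN`, Jukes-Cantor rates `dS`, `dN` (`NA` when saturated), saturation
#'   flags, and `n_codons`.
#' @examples
#' ng86(rep("GGG", 10), c("GGA", rep("GGG", 9))) # dS = 0.107326, dN = 0
#' @export
ng86 <- function(codons1, codons2) {
  if (length(codons1) != length(codons2)) {
    stop("codon vectors differ in length", call. = FALSE)
  }
  if (length(codons1) == 0) stop("no codon columns", call. = FALSE)
  i1 <- codon_index(codons1); i2 <- codon_index(codons2)
  if (anyNA(i1) || anyNA(i2)) stop("invalid codon in input", call. = FALSE)
  sites <- ng86_site_table()
  if (anyNA(sites[i1]) || anyNA(sites[i2])) {
    stop("stop codon in aligned codons", call. = FALSE)
  }
  diffs <- ng86_diff_tables()
  n_codons <- length(codons1)
  S <- (sum(sites[i1]) + sum(sites[i2])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(diffs$sd[cbind(i1, i2)])
  Nd <- sum(diffs$nd[cbind(i1, i2)])
  if (S == 0 && Sd > 0) stop("internal inconsistency: Sd > 0 with S = 0", call. = FALSE)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = jc_correct(pS), dN = jc_correct(pN),
                 saturated_s = pS >= 0.75, saturated_n = pN >= 0.75,
                 n_codons = n_codons),
            class = "KsEstimate")
}

#' @export
print.KsEstimate <- function(x, ...) {
  cat(sprintf("NG86 estimate over %d codons\n", x$n_codons))
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.3f  Nd = %.3f\n", x$S, x$N, x$Sd, x$Nd))
  ds <- if (x$saturated_s) "saturated" else sprintf("%.6f", x$dS)
  dn <- if (x$saturated_n) "saturated" else sprintf("%.6f", x$dN)
  cat(sprintf("  dS = %s  dN = %s\n", ds, dn))
  invisible(x)
}

#' NG86 dS/dN between two coding sequences
#'
#' Convenience wrapper: [codon_align()] followed by [ng86()].
#'
#' @inheritParams codon_align
#' @return a `KsEstimate`.
#' @export
ks_pair <- function(cds1, cds2) {
  aln <- codon_align(cds1, cds2)
  ng86(aln$codons1, aln$codons2)
}

#' Per-block Ks summary
#'
#' Computes the NG86 dS for every anchor gene pair in a synteny block and
#' summarises the block as the median of the defined (non-saturated) values.
#'
#' @param block a `SyntenyBlock` (see [chain_collinear()]).
#' @param cds_map named character vector mapping gene id to CDS.
#' @return the block with `ks_summary` set (`NA` if no anchor has a defined
#'   dS) and a `ks_values` vector attached to its anchor table.
#' @export
block_ks <- function(block, cds_map) {
  anchors <- block$anchors
  ks <- vapply(seq_len(nrow(anchors)), function(i) {
    ga <- anchors$gene_a[[i]]; gb <- anchors$gene_b[[i]]
    if (!ga %in% names(cds_map) || !gb %in% names(cds_map)) {
      stop("missing CDS for anchor pair ", ga, "/", gb, call. = FALSE)
    }
    est <- ks_pair(cds_map[[ga]], cds_map[[gb]])
    if (est$saturated_s) NA_real_ else est$dS
  }, numeric(1))
  block$anchors$ks <- ks
  defined <- ks[!is.na(ks)]
  if (length(defined) == 0) {
    ad_log("warn", "block ", block$block_id, ": all anchor pairs saturated")
    block$ks_summary <- NA_real_
  } else {
    block$ks_summary <- median(defined)
  }
  block
}

#' Modal peak of a Ks distribution
#'
#' Gaussian kernel density on a 1000-point grid over `[0, max(values)]`;
#' bandwidth by Silverman's rule of thumb unless overridden. The mode is the
#' grid argmax — the quantity reported as the "modal Ks" of a divergence or
#' duplication event.
#'
#' @param values numeric vector of Ks values (at least 5 finite values).
#' @param bandwidth optional numeric kernel bandwidth.
#' @return object of class `KsDistribution`: list with `values`, `mode`,
#'   `bandwidth`, and the density `grid`/`density` vectors.
#' @export
ks_mode <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 finite Ks values", call. = FALSE)
  bw <- bandwidth %||% stats::bw.nrd0(values)
  den <- stats::density(values, bw = bw, n = 1000, from = 0, to = max(values))
  structure(list(values = values, mode = den$x[[which.max(den$y)]],
                 bandwidth = bw, grid = den$x, density = den$y),
            class = "KsDistribution")
}

#' @export
print.KsDistribution <- function(x, ...) {
  cat(sprintf("Ks distribution: n = %d, mode = %.4f (bw = %.4g)\n",
              length(x$values), x$mode, x$bandwidth))
  invisible(x)
}
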