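# Gene-family copy numbers, the twofold-amplification filter, pathway
# rollup, and the best-hit + shared-family "true ortholog" rule.

#' Per-family per-species gene counts
#'
#' @param maps named list (one element per species) of named character
#'   vectors mapping gene id -> family id. Genes mapping to `NA` or `""`
#'   are tallied in an `unassigned` bucket reported via attribute
#'   `unassigned`.
#' @return `data.frame` with `family_id` and one integer count column per
#'   species.
#' @export
count_by_family <- function(maps) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  unassigned <- setNames(integer(length(maps)), names(maps))
  tabs <- lapply(names(maps), function(sp) {
    fam <- maps[[sp]]
    bad <- is.na(fam) | fam == ""
    unassigned[[sp]] <<- sum(bad)
    if (sum(bad) > 0) {
      ad_log("warn", sum(bad), " gene(s) without family in ", sp)
    }
    table(fam[!bad])
  })
  all_fams <- sort(unique(unlist(lapply(tabs, names))))
  if (length(all_fams) == 0) {
    ad_log("warn", "empty family mapping")
    out <- data.frame(family_id = character(), stringsAsFactors = FALSE)
    for (sp in names(maps)) out[[sp]] <- integer()
    attr(out, "unassigned") <- unassigned
    return(out)
  }
  out <- data.frame(family_id = all_fams, stringsAsFactors = FALSE)
  for (i in seq_along(maps)) {
    cnt <- as.integer(tabs[[i]][all_fams])
    cnt[is.na(cnt)] <- 0L
    out[[names(maps)[[i]]]] <- cnt
  }
  attr(out, "unassigned") <- unassigned
  out
}

#' Detect amplified gene families
#'
#' A family is amplified when the tetraploid count is at least `fold` times
#' EACH diploid count and both diploid counts are at least 1 (unless
#' `allow_zero_diploid`). This is the residual-polyploidy signature: a
#' family retaining roughly both progenitor complements doubles its copy
#' number relative to each diploid.
#'
#' @param rows family count table (see [count_by_family()] or
#'   [simulate_family_counts()]).
#' @param tetra column name of the tetraploid counts.
#' @param diploids character vector (length 2) of diploid column names.
#' @param fold amplification factor (default 2).
#' @param allow_zero_diploid if `TRUE`, families with a zero diploid count
#'   can still qualify (default `FALSE`).
#' @return the input with columns `ratio_<diploid>` and logical `amplified`.
#' @export
amplified_families <- function(rows, tetra = "tetraploid",
                               diploids = c("diploid_A", "diploid_B"),
                               fold = 2.0, allow_zero_diploid = FALSE) {
  need <- c(tetra, diploids)
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0) {
    stop("missing species column: ", paste(missing, collapse = ","), call. = FALSE)
  }
  t_cnt <- rows[[tetra]]
  d1 <- rows[[diploids[[1]]]]
  d2 <- rows[[diploids[[2]]]]
  rows[[paste0("ratio_", diploids[[1]])]] <- ifelse(d1 > 0, t_cnt / d1, Inf)
  rows[[paste0("ratio_", diploids[[2]])]] <- ifelse(d2 > 0, t_cnt / d2, Inf)
  amp <- t_cnt >= fold * d1 & t_cnt >= fold * d2
  if (!allow_zero_diploid) amp <- amp & d1 >= 1 & d2 >= 1
  rows$amplified <- amp
  rows
}

#' Roll amplified families up to pathways
#'
#' Counts amplified families per pathway; a family mapped to several
#' pathways is counted in each of them. Families without a pathway are
#' reported via attribute `unmapped`.
#'
#' @param amplified character vector of amplified family ids.
#' @param family_to_pathway `data.frame` with columns `family_id`,
#'   `pathway` (one row per membership).
#' @return `data.frame` of `pathway`, `n_families`, sorted descending.
#' @export
pathway_rollup <- function(amplified, family_to_pathway) {
  if (length(amplified) == 0) {
    out <- data.frame(pathway = character(), n_families = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "unmapped") <- character()
    return(out)
  }
  hit <- family_to_pathway[family_to_pathway$family_id %in% amplified, ,
                           drop = FALSE]
  unmapped <- setdiff(amplified, hit$family_id)
  if (length(unmapped) > 0) {
    ad_log("info", length(unmapped), " amplified family(ies) without pathway")
  }
  tab <- table(hit$pathway)
  out <- data.frame(pathway = names(tab), n_families = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_families, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' True orthologs: best homology hit within the same gene family
#'
#' A candidate pair `(g, h)` is a true ortholog iff `h` is `g`'s best
#' homology hit AND both genes belong to the same gene family — requiring
#' agreement between the similarity-search route and the family-annotation
#' route.
#'
#' @param best_hits named character vector: gene -> its best-hit gene.
#' @param family_of named character vector: gene -> family id.
#' @return `data.frame` of kept pairs: `gene`, `ortholog`, `family_id`.
#' @export
true_orthologs <- function(best_hits, family_of) {
  g <- names(best_hits)
  h <- unname(best_hits)
  fg <- unname(family_of[g])
  fh <- unname(family_of[h])
  keep <- !is.na(fg) & !is.na(fh) & fg == fh
  data.frame(gene = g[keep], ortholog = h[keep], family_id = fg[keep],
             stringsAsFactors = FALSE)
}
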