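# Truth-labelled synthetic allotetraploid generator.
#
# The generator realises the system the pipeline is built to analyse: a
# random ancestor, two diploid progenitors separated by a configurable
# pairwise synonymous divergence (default Ks 0.05, the scale of a recent
# allopolyploidy event), an allotetraploid formed as the union of both
# progenitor genomes (each copy carrying a small amount of additional
# post-hybridization divergence), short single-end reads from each
# progenitor, and gene-family count tables with a known amplified subset.
# Divergence convention: diverge() applies the FULL pairwise target to one
# lineage while the other keeps the ancestral state, so the single knob
# equals the pairwise dS measured between the two emitted genomes.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults are the desk-scale preset: 20 contigs x 50 kb per progenitor,
#' 10 genes of 900 bp per contig (180 kb of CDS per genome), progenitor
#' divergence dS 0.05 / dN 0.01, 10% gene fractionation in the tetraploid,
#' 100 bp reads at 40x with 0.5% error, and 1000 gene families of which 100
#' are amplified.
#'
#' @param seed integer RNG seed.
#' @param n_contigs,contig_length,genes_per_contig,cds_length genome layout;
#'   `cds_length` (bp, multiple of 3) includes start and stop codons.
#' @param target_dS,target_dN pairwise NG86 divergence between progenitors.
#' @param extra_ds,extra_dn additional divergence applied independently to
#'   each subgenome copy after hybridization.
#' @param fractionation_rate per-gene loss probability in the tetraploid.
#' @param read_length,coverage,error_rate read simulation parameters.
#' @param n_families,n_amplified family count table parameters.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_contigs = 20, contig_length = 50000,
                       genes_per_contig = 10, cds_length = 900,
                       target_dS = 0.05, target_dN = 0.01,
                       extra_ds = 0.01, extra_dn = 0.002,
                       fractionation_rate = 0.1,
                       read_length = 100, coverage = 40, error_rate = 0.005,
                       n_families = 1000, n_amplified = 100) {
  stopifnot(cds_length %% 3 == 0, target_dS >= 0, target_dN >= 0,
            fractionation_rate >= 0, fractionation_rate < 1, coverage > 0,
            n_amplified <= n_families, target_dS < 0.75)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons_total) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  internal <- sample(sense, n_codons_total - 2L, replace = TRUE)
  paste(c("ATG", internal, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulate an ancestral genome with gene models
#'
#' Uniform-random DNA with non-overlapping genes placed at regular spacing;
#' each CDS begins with ATG, contains no internal stop codon, and ends with
#' a stop codon. Strands are drawn at random; the stored `cds` is always the
#' coding strand with the terminal stop trimmed (matching
#' [read_gff_genes()]).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default: `config$seed`).
#' @return list with `genome` (named character vector) and `genes`
#'   (gene table).
#' @export
simulate_ancestor <- function(config, seed = config$seed) {
  set.seed(seed)
  slot <- config$contig_length %/% config$genes_per_contig
  if (config$cds_length + 1 > slot) {
    stop("genes do not fit: genes_per_contig * (cds_length + spacing) exceeds contig_length",
         call. = FALSE)
  }
  genome <- character(config$n_contigs)
  names(genome) <- sprintf("ctg%02d", seq_len(config$n_contigs))
  rows <- list()
  for (ci in seq_len(config$n_contigs)) {
    chars <- strsplit(random_dna(config$contig_length), "")[[1]]
    for (gi in seq_len(config$genes_per_contig)) {
      start <- (gi - 1L) * slot + 101L
      end <- start + config$cds_length - 1L
      cds_full <- random_cds(config$cds_length %/% 3L)
      strand <- sample(c("+", "-"), 1L)
      span <- if (strand == "+") cds_full else reverse_complement(cds_full)
      chars[start:end] <- strsplit(span, "")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%02d", names(genome)[[ci]], gi),
        contig_id = names(genome)[[ci]], start = start, end = end,
        strand = strand,
        cds = substr(cds_full, 1L, config$cds_length - 3L),
        gene_rank = gi, stringsAsFactors = FALSE)
    }
    genome[[ci]] <- paste(chars, collapse = "")
  }
  list(genome = genome, genes = do.call(rbind, rows))
}

# Synonymous / nonsynonymous single-base neighbour lists per codon
# (nonsynonymous excludes stop codons: the simulator never writes a stop).
codon_neighbours <- function() {
  if (!is.null(.ad_cache$nb)) return(.ad_cache$nb)
  gc <- genetic_code()
  nb <- lapply(names(gc), function(cd) {
    if (gc[[cd]] == "*") return(list(syn = character(), nonsyn = character()))
    chars <- strsplit(cd, "")[[1]]
    syn <- character(); nonsyn <- character()
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[[pos]])) {
        x <- chars; x[[pos]] <- b
        x <- paste(x, collapse = "")
        if (gc[[x]] == gc[[cd]]) syn <- c(syn, x)
        else if (gc[[x]] != "*") nonsyn <- c(nonsyn, x)
      }
    }
    list(syn = syn, nonsyn = nonsyn)
  })
  names(nb) <- names(gc)
  .ad_cache$nb <- nb
  nb
}

# Fast NG86 over two codon vectors (no alignment, no validation) used by the
# calibration loop.
measure_ds_dn <- function(cod1, cod2) {
  i1 <- codon_index(cod1); i2 <- codon_index(cod2)
  sites <- ng86_site_table()
  diffs <- ng86_diff_tables()
  S <- (sum(sites[i1]) + sum(sites[i2])) / 2
  N <- 3 * length(cod1) - S
  Sd <- sum(diffs$sd[cbind(i1, i2)])
  Nd <- sum(diffs$nd[cbind(i1, i2)])
  c(dS = jc_correct(Sd / S), dN = jc_correct(Nd / N))
}

# Mutate an exact number of codons (sampled without replacement) rather than
# Bernoulli-thinning: the realised difference count is then nearly
# deterministic, which lets the calibration loop hit tight targets even on
# small genomes.
mutate_codons <- function(codons, n_syn, n_nonsyn) {
  nb <- codon_neighbours()
  out <- codons
  n <- length(codons)
  for (i in sample.int(n, min(n, round(n_syn)))) {
    opts <- nb[[out[[i]]]]$syn
    if (length(opts) > 0) out[[i]] <- opts[[sample.int(length(opts), 1L)]]
  }
  for (i in sample.int(n, min(n, round(n_nonsyn)))) {
    opts <- nb[[out[[i]]]]$nonsyn
    if (length(opts) > 0) out[[i]] <- opts[[sample.int(length(opts), 1L)]]
  }
  out
}

#' Diverge a genome to a target NG86 dS / dN
#'
#' CDS are mutated codon-wise: selected codons are replaced by a uniform
#' random synonymous (or nonsynonymous, never stop) single-base neighbour.
#' The per-codon rates are calibrated in a propose/measure/adjust loop: the
#' realised NG86 dS and dN against the input are measured with the package's
#' own estimator and the rates rescaled until both are within `tol` (10%) of
#' target (up to `max_rounds` proposals, then error). Intergenic DNA is
#' mutated at `target_dS` substitutions per site.
#'
#' @param genome named character vector of contig sequences.
#' @param genes gene table for `genome`.
#' @param target_dS,target_dN NG86 divergence targets vs the input.
#' @param seed RNG seed.
#' @param tol relative tolerance of the calibration loop; the effective
#'   tolerance is floored at two substitution counts (the granularity of a
#'   discrete mutation count), so tiny genomes remain attainable while
#'   genome-scale CDS (>= 100 kb) calibrates to within a couple of percent.
#' @param max_rounds maximum calibration proposals.
#' @return list with mutated `genome` and `genes` (ids unchanged).
#' @export
diverge <- function(genome, genes, target_dS, target_dN, seed,
                    tol = 0.02, max_rounds = 10) {
  stopifnot(target_dS < 0.75)
  if (target_dS == 0 && target_dN == 0) return(list(genome = genome, genes = genes))
  set.seed(seed)
  cods <- lapply(genes$cds, split_codons)
  lens <- lengths(cods)
  all_cod <- unlist(cods)
  sites <- ng86_site_table()
  S_tot <- sum(sites[codon_index(all_cod)])
  N_tot <- 3 * length(all_cod) - S_tot
  n_syn <- if (target_dS > 0) 0.75 * (1 - exp(-4 / 3 * target_dS)) * S_tot else 0
  n_nonsyn <- if (target_dN > 0) 0.75 * (1 - exp(-4 / 3 * target_dN)) * N_tot else 0
  tol_s <- max(tol, 2 / max(n_syn, 1))
  tol_n <- max(tol, 2 / max(n_nonsyn, 1))
  ok <- FALSE
  for (round in seq_len(max_rounds)) {
    prop <- mutate_codons(all_cod, n_syn, n_nonsyn)
    m <- measure_ds_dn(all_cod, prop)
    ok_s <- target_dS == 0 || (is.finite(m[["dS"]]) &&
                                 abs(m[["dS"]] - target_dS) <= tol_s * target_dS)
    ok_n <- target_dN == 0 || (is.finite(m[["dN"]]) &&
                                 abs(m[["dN"]] - target_dN) <= tol_n * target_dN)
    if (ok_s && ok_n) { ok <- TRUE; break }
    if (target_dS > 0 && !ok_s) {
      n_syn <- n_syn * target_dS / max(m[["dS"]], target_dS / 4, na.rm = TRUE)
    }
    if (target_dN > 0 && !ok_n) {
      n_nonsyn <- n_nonsyn * target_dN / max(m[["dN"]], target_dN / 4, na.rm = TRUE)
    }
  }
  if (!ok) stop("divergence target unattainable after ", max_rounds,
                " calibration rounds", call. = FALSE)
  new_cds <- vapply(split(prop, rep(seq_along(lens), lens)),
                    paste, "", collapse = "")
  genes$cds <- unname(new_cds)
  # splice mutated CDS back and mutate intergenic sites at target_dS per site
  chars_by_contig <- lapply(genome, function(s) strsplit(s, "")[[1]])
  gene_mask <- lapply(genome, function(s) rep(FALSE, nchar(s)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    chars <- chars_by_contig[[g$contig_id]]
    stop_codon <- if (g$strand == "+") {
      paste(chars[(g$end - 2):g$end], collapse = "")
    } else {
      reverse_complement(paste(chars[g$start:(g$start + 2)], collapse = ""))
    }
    coding <- paste0(g$cds, stop_codon)
    span <- if (g$strand == "+") coding else reverse_complement(coding)
    chars_by_contig[[g$contig_id]][g$start:g$end] <- strsplit(span, "")[[1]]
    gene_mask[[g$contig_id]][g$start:g$end] <- TRUE
  }
  if (target_dS > 0) {
    for (ct in names(genome)) {
      chars <- chars_by_contig[[ct]]
      inter <- which(!gene_mask[[ct]])
      hit <- inter[runif(length(inter)) < target_dS]
      if (length(hit) > 0) {
        chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(BASES, b), 1L), "")
        chars_by_contig[[ct]] <- chars
      }
    }
  }
  genome <- vapply(chars_by_contig, paste, "", collapse = "")
  list(genome = genome, genes = genes)
}

# Prefix contig and gene ids (e.g. "A." / "tetB.") keeping structure intact.
relabel_genome <- function(genome, genes, prefix) {
  names(genome) <- paste0(prefix, names(genome))
  genes$contig_id <- paste0(prefix, genes$contig_id)
  genes$gene_id <- paste0(prefix, genes$gene_id)
  list(genome = genome, genes = genes)
}

# Ancestral lineage id of any simulated gene: strip the lineage prefix.
# Used to define gene families (one family per ancestral gene).
ancestral_family <- function(gene_ids) {
  paste0("fam_", sub("^(tetA\\.|tetB\\.|A\\.|B\\.)", "", gene_ids))
}

#' Build an allotetraploid from two progenitor genomes
#'
#' The tetraploid is the union of relabelled copies of both progenitor
#' genomes; each copy is independently re-diverged by a small additional
#' amount (`extra_ds`/`extra_dn`), emulating post-hybridization divergence
#' from the sampled progenitor accessions. Genes are then deleted
#' independently with probability `fractionation_rate` and ranks
#' recomputed. The returned truth table records every contig origin,
#' gene family, and progenitor-to-tetraploid ortholog pair.
#'
#' @param progA,progB lists with `genome` and `genes` (progenitor A ids must
#'   be disjoint from progenitor B ids; use [relabel_genome()] prefixes).
#' @param fractionation_rate per-gene loss probability in the tetraploid.
#' @param seed RNG seed.
#' @param extra_ds,extra_dn post-hybridization divergence per copy.
#' @return list with `genome`, `genes`, and `truth` (list with
#'   `contig_origin`, `gene_family`, `ortholog_pairs`).
#' @export
build_allotetraploid <- function(progA, progB, fractionation_rate = 0.1,
                                 seed = 1, extra_ds = 0.01, extra_dn = 0.002) {
  if (length(intersect(names(progA$genome), names(progB$genome))) > 0) {
    stop("progenitor contig ids must be disjoint", call. = FALSE)
  }
  copyA <- diverge(progA$genome, progA$genes, extra_ds, extra_dn,
                   seed = derive_seed(seed, 101))
  copyB <- diverge(progB$genome, progB$genes, extra_ds, extra_dn,
                   seed = derive_seed(seed, 102))
  copyA <- relabel_genome(copyA$genome, copyA$genes, "tet")
  copyB <- relabel_genome(copyB$genome, copyB$genes, "tet")
  genome <- c(copyA$genome, copyB$genome)
  genes <- rbind(copyA$genes, copyB$genes)
  parent <- c(progA$genes$gene_id, progB$genes$gene_id)
  set.seed(derive_seed(seed, 103))
  keep <- runif(nrow(genes)) >= fractionation_rate
  genes <- genes[keep, , drop = FALSE]
  parent <- parent[keep]
  ord <- order(genes$contig_id, genes$start)
  genes <- genes[ord, , drop = FALSE]
  parent <- parent[ord]
  genes$gene_rank <- stats::ave(genes$start, genes$contig_id, FUN = seq_along)
  rownames(genes) <- NULL
  origin <- data.frame(
    contig_id = names(genome),
    origin = ifelse(names(genome) %in% names(copyA$genome), "A", "B"),
    stringsAsFactors = FALSE)
  all_gene_ids <- c(progA$genes$gene_id, progB$genes$gene_id, genes$gene_id)
  truth <- list(
    contig_origin = origin,
    gene_family = data.frame(gene_id = all_gene_ids,
                             family_id = ancestral_family(all_gene_ids),
                             stringsAsFactors = FALSE),
    ortholog_pairs = data.frame(
      progenitor_gene = parent,
      tetraploid_gene = genes$gene_id, stringsAsFactors = FALSE))
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate single-end reads
#'
#' Reads are drawn uniformly along the genome (contigs weighted by the
#' number of valid start positions), from either strand, with independent
#' per-base substitution errors at `error_rate`. The read count is
#' `round(coverage * genome_bp / read_length)`.
#'
#' @param genome named character vector of contigs.
#' @param coverage target mean depth (x).
#' @param read_length read length (bp); must not exceed the shortest contig.
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed.
#' @param prefix read-name prefix.
#' @return named character vector of read sequences.
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate, seed,
                           prefix = "read") {
  if (read_length > min(nchar(genome))) {
    stop("read_length exceeds shortest contig", call. = FALSE)
  }
  set.seed(seed)
  total <- sum(nchar(genome))
  n_reads <- round(coverage * total / read_length)
  npos <- nchar(genome) - read_length + 1L
  ctg <- sample.int(length(genome), n_reads, replace = TRUE, prob = npos)
  pos <- floor(runif(n_reads) * npos[ctg]) + 1L
  reads <- substring(genome[ctg], pos, pos + read_length - 1L)
  rev <- runif(n_reads) < 0.5
  if (any(rev)) reads[rev] <- reverse_complement(reads[rev])
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(read_length, n_err[[i]])
      for (p in at) {
        b <- substr(reads[[i]], p, p)
        substr(reads[[i]], p, p) <- sample(setdiff(BASES, b), 1L)
      }
    }
  }
  names(reads) <- paste0(prefix, seq_len(n_reads))
  reads
}

#' Simulate gene-family copy-number tables with a known amplified subset
#'
#' Background families: each diploid count drawn from `{1,2,3}`, tetraploid
#' count equal to the diploid sum, minus one with probability 0.5
#' (fractionation); a guard decrements once more in the corner case where
#' the sum would itself satisfy the amplification rule (equal diploid
#' counts, no loss), keeping truth strictly outside the rule. Amplified
#' families: tetraploid count at least twice EACH diploid count, both
#' diploids >= 1.
#'
#' @param n_families total number of families.
#' @param n_amplified number of amplified families.
#' @param seed RNG seed.
#' @param species column names: tetraploid, diploid A, diploid B.
#' @return list with `rows` (`data.frame`: `family_id` + one count column
#'   per species) and `amplified` (character vector of family ids).
#' @export
simulate_family_counts <- function(n_families, n_amplified, seed,
                                   species = c("tetraploid", "diploid_A",
                                               "diploid_B")) {
  stopifnot(n_amplified <= n_families, length(species) == 3)
  set.seed(seed)
  fam <- sprintf("fam%05d", seq_len(n_families))
  amp_set <- sort(sample(fam, n_amplified))
  d1 <- sample(1:3, n_families, replace = TRUE)
  d2 <- sample(1:3, n_families, replace = TRUE)
  tet <- d1 + d2 - (runif(n_families) < 0.5)
  over <- tet >= 2 * pmax(d1, d2)
  tet[over] <- tet[over] - 1L # keep background strictly outside the rule
  is_amp <- fam %in% amp_set
  tet[is_amp] <- 2L * pmax(d1, d2)[is_amp] +
    sample(0:2, sum(is_amp), replace = TRUE)
  rows <- data.frame(family_id = fam, stringsAsFactors = FALSE)
  rows[[species[[1]]]] <- as.integer(tet)
  rows[[species[[2]]]] <- d1
  rows[[species[[3]]]] <- d2
  list(rows = rows, amplified = amp_set)
}

# Evolve a sequence along a phylogeny under JC: per branch of length t, each
# site substitutes with probability 3/4 (1 - exp(-4/3 t)).
evolve_along_tree <- function(tree, root_seq) {
  n <- length(tree$tip.label)
  root <- n + 1L
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- strsplit(root_seq, "")[[1]]
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    t_len <- pre$edge.length[[e]]
    psub <- 0.75 * (1 - exp(-4 / 3 * t_len))
    chars <- seqs[[p]]
    hit <- which(runif(length(chars)) < psub)
    if (length(hit) > 0) {
      chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    }
    seqs[[ch]] <- chars
  }
  leaves <- vapply(seqs[seq_len(n)], paste, "", collapse = "")
  setNames(leaves, tree$tip.label)
}

#' Simulate a set of accessions descending from a shared reference
#'
#' Emulates the chloroplast stage's inputs: a reference sequence with gene
#' models, a random phylogeny over `n_accessions`, leaf sequences evolved
#' under Jukes-Cantor along that tree from the reference, per-accession
#' VCF-like variant records versus the reference (true variants carry phred
#' qualities in \[40, 60\]; additional decoy records at random positions
#' carry qualities below 30 and must be discarded by the consensus filter),
#' and per-accession coverage masks (full coverage except a configurable
#' number of half-covered genes used to exercise the coverage filter).
#'
#' @param n_accessions number of leaves (accessions).
#' @param n_genes,gene_length,contig_length reference layout (one contig).
#' @param tree_depth approximate root-to-tip substitutions/site.
#' @param n_uncovered_genes genes given partial coverage in one accession.
#' @param n_decoys low-quality decoy variant records per accession.
#' @param seed RNG seed.
#' @return list with `reference`, `genes`, `tree` (the generating phylogeny),
#'   `variants` (named list of variant tables), `masks` (named list of
#'   interval data.frames), and `leaf_seqs`.
#' @export
simulate_accession_set <- function(n_accessions = 23, n_genes = 30,
                                   gene_length = 300, contig_length = 15000,
                                   tree_depth = 0.02, n_uncovered_genes = 2,
                                   n_decoys = 5, seed = 1) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_contigs = 1, contig_length = contig_length,
                    genes_per_contig = n_genes, cds_length = gene_length,
                    coverage = 1)
  anc <- simulate_ancestor(cfg, seed = derive_seed(seed, 11))
  ref <- setNames(unname(anc$genome), "cpref")
  genes <- anc$genes
  genes$contig_id <- "cpref"
  genes$gene_id <- sub("^ctg01", "cp", genes$gene_id)
  tree <- ape::rtree(n_accessions, tip.label = sprintf("acc%02d", seq_len(n_accessions)))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) * tree_depth
  leaf_seqs <- evolve_along_tree(tree, ref[[1]])
  ref_chars <- strsplit(ref[[1]], "")[[1]]
  variants <- list(); masks <- list()
  for (acc in names(leaf_seqs)) {
    chars <- strsplit(leaf_seqs[[acc]], "")[[1]]
    pos <- which(chars != ref_chars)
    v <- data.frame(contig_id = "cpref", pos = pos, ref = ref_chars[pos],
                    alt = chars[pos],
                    qual = round(runif(length(pos), 40, 60), 1),
                    stringsAsFactors = FALSE)
    same <- sample(which(chars == ref_chars), n_decoys)
    decoy <- data.frame(contig_id = "cpref", pos = same,
                        ref = ref_chars[same],
                        alt = vapply(ref_chars[same],
                                     function(b) sample(setdiff(BASES, b), 1L), ""),
                        qual = round(runif(n_decoys, 2, 29.5), 1),
                        stringsAsFactors = FALSE)
    v <- rbind(v, decoy)
    variants[[acc]] <- v[order(v$pos), , drop = FALSE]
    masks[[acc]] <- data.frame(contig_id = "cpref", start = 1L,
                               end = contig_length, stringsAsFactors = FALSE)
  }
  if (n_uncovered_genes > 0) {
    # hide the first half of a few genes from accession 1's mask so the
    # comprehensive-coverage filter has something to drop
    drop_genes <- genes[sample.int(nrow(genes), n_uncovered_genes), ]
    acc <- names(leaf_seqs)[[1]]
    covered <- IRanges::IRanges(1L, contig_length)
    for (i in seq_len(nrow(drop_genes))) {
      g <- drop_genes[i, ]
      mid <- g$start + (g$end - g$start) %/% 2L
      covered <- IRanges::setdiff(covered, IRanges::IRanges(g$start, mid))
    }
    masks[[acc]] <- data.frame(contig_id = "cpref",
                               start = IRanges::start(covered),
                               end = IRanges::end(covered),
                               stringsAsFactors = FALSE)
  }
  list(reference = ref, genes = genes, tree = tree, variants = variants,
       masks = masks, leaf_seqs = leaf_seqs)
}

#' Simulate a complete truth-labelled dataset on disk
#'
#' Runs the whole generator at the configured scale and writes every
#' artefact the pipeline stages consume: progenitor and tetraploid genomes
#' (FASTA + GFF3), progenitor read sets (gzipped FASTQ), gene-family count
#' tables and family-to-pathway map, accession variant tables, coverage
#' masks and the generating phylogeny for the chloroplast stage, and the
#' truth tables (`truth/*.tsv`) used only by validation code.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed (default `config$seed`).
#' @return invisibly, a list of the main file paths plus the in-memory truth.
#' @export
simulate_polyploid_dataset <- function(config, out_dir, seed = config$seed) {
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "chloro"), recursive = TRUE, showWarnings = FALSE)
  anc <- simulate_ancestor(config, seed = derive_seed(seed, 1))
  progA <- relabel_genome(anc$genome, anc$genes, "A.")
  div <- diverge(anc$genome, anc$genes, config$target_dS, config$target_dN,
                 seed = derive_seed(seed, 2))
  progB <- relabel_genome(div$genome, div$genes, "B.")
  tet <- build_allotetraploid(progA, progB, config$fractionation_rate,
                              seed = derive_seed(seed, 3),
                              extra_ds = config$extra_ds,
                              extra_dn = config$extra_dn)
  readsA <- simulate_reads(progA$genome, config$coverage, config$read_length,
                           config$error_rate, seed = derive_seed(seed, 4),
                           prefix = "rA")
  readsB <- simulate_reads(progB$genome, config$coverage, config$read_length,
                           config$error_rate, seed = derive_seed(seed, 5),
                           prefix = "rB")
  fams <- simulate_family_counts(config$n_families, config$n_amplified,
                                 seed = derive_seed(seed, 6))
  pathways <- c("ribosome", "spliceosome", "photosynthesis", "glycolysis",
                "proteasome", "dna_repair", "cell_wall", "lipid_metabolism")
  set.seed(derive_seed(seed, 7))
  fam2path <- data.frame(family_id = fams$rows$family_id,
                         pathway = sample(pathways, config$n_families,
                                          replace = TRUE),
                         stringsAsFactors = FALSE)
  acc <- simulate_accession_set(seed = derive_seed(seed, 8))

  p <- function(...) file.path(out_dir, ...)
  write_fasta(progA$genome, p("progenitorA.fa"))
  write_gff_genes(progA$genes, p("progenitorA.gff"))
  write_fasta(progB$genome, p("progenitorB.fa"))
  write_gff_genes(progB$genes, p("progenitorB.gff"))
  write_fasta(tet$genome, p("tetraploid.fa"))
  write_gff_genes(tet$genes, p("tetraploid.gff"))
  write_fastq(readsA, p("readsA.fastq.gz"))
  write_fastq(readsB, p("readsB.fastq.gz"))
  write.table(fams$rows, p("families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fam2path, p("pathways.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # gene -> family annotation over all three genomes; an input (the analogue
  # of a family-database annotation), not a truth table
  write.table(tet$truth$gene_family, p("gene_families_all.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tet$truth$contig_origin, p("truth", "contig_origin.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tet$truth$gene_family, p("truth", "gene_family.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tet$truth$ortholog_pairs, p("truth", "ortholog_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(fams$amplified, p("truth", "amplified_families.txt"))
  write_fasta(acc$reference, p("chloro", "reference.fa"))
  write_gff_genes(acc$genes, p("chloro", "genes.gff"))
  ape::write.tree(acc$tree, p("chloro", "true_tree.nwk"))
  for (a in names(acc$variants)) {
    write_variant_table(acc$variants[[a]], p("chloro", paste0(a, ".vcf.tsv")))
    write.table(acc$masks[[a]], p("chloro", paste0(a, ".mask.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(dir = out_dir, progA = progA, progB = progB, tet = tet,
                 readsA = readsA, readsB = readsB, families = fams,
                 fam2path = fam2path, accessions = acc))
}
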