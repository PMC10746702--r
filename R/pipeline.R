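# End-to-end benchmark on the synthetic preset: simulate -> chloroplast
# consensus/Pi -> NJ/RF -> synteny/Ks -> subgenome partition + DOC ->
# reconciliation -> gene families. Stages communicate only through on-disk
# files in the documented formats, so each stage is independently testable
# and replaceable with real data.

stage_result <- function(ok, value = NULL, error = NULL) {
  list(ok = ok, value = value, error = error)
}

run_stage <- function(name, deps_ok, fun) {
  if (!deps_ok) {
    ad_log("warn", "stage ", name, " skipped (failed dependency)")
    return(stage_result(FALSE, error = "skipped: failed dependency"))
  }
  res <- tryCatch(stage_result(TRUE, value = fun()),
                  error = function(e) {
                    ad_log("error", "stage ", name, " failed: ",
                           conditionMessage(e))
                    stage_result(FALSE, error = conditionMessage(e))
                  })
  res
}

#' Run the desk-scale end-to-end benchmark
#'
#' Simulates a truth-labelled allotetraploid system at the configured scale
#' and runs every analysis stage on the emitted files, measuring parameter
#' recovery against the truth tables: the modal Ks of
#' progenitor-vs-progenitor anchors and of the tetraploid self-synteny
#' blocks, per-gene diversity and the NJ/RF comparison for the chloroplast
#' stage, DOC classification accuracy, Ks-partition accuracy, the agreement
#' of the two subgenome routes, and amplified-family precision/recall.
#'
#' @param config a [sim_config()].
#' @param seed integer seed driving every stage.
#' @param out_dir working directory for all intermediate files.
#' @param bootstrap_reps bootstrap replicates for the chloroplast NJ tree.
#' @param doc_k k-mer size of the read assigner.
#' @param thresholds named list of pass thresholds for the recovery metrics.
#' @return a `RunReport` list: `config`, per-stage results, `metrics`, and
#'   `pass` flags; also written as JSON to `file.path(out_dir, "report.json")`.
#' @export
run_desk_benchmark <- function(config = sim_config(), seed = config$seed,
                               out_dir = tempfile("alloDonorRun"),
                               bootstrap_reps = 100, doc_k = 31,
                               thresholds = list(recovery = 0.95,
                                                 ks_band = c(0.04, 0.06))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  report <- list(config = unclass(config), seed = seed, stages = list(),
                 metrics = list(), pass = list())

  sim <- run_stage("simulate", TRUE, function() {
    simulate_polyploid_dataset(config, out_dir, seed = seed)
    TRUE
  })
  report$stages$simulate <- sim["ok"]

  chloro <- run_stage("chloroplast", sim$ok, function() {
    ref <- read_fasta(p("chloro", "reference.fa"))
    genes <- read_gff_genes(p("chloro", "genes.gff"), ref)
    accs <- sub("\\.vcf\\.tsv$", "",
                basename(Sys.glob(p("chloro", "*.vcf.tsv"))))
    masks <- lapply(setNames(accs, accs), function(a) {
      read.delim(p("chloro", paste0(a, ".mask.tsv")), stringsAsFactors = FALSE)
    })
    consensuses <- vapply(setNames(accs, accs), function(a) {
      v <- read_variant_table(p("chloro", paste0(a, ".vcf.tsv")))
      apply_variants(ref, v, min_qual = 30)
    }, character(1))
    covered <- filter_covered_genes(genes, masks, min_fraction = 1.0)
    pis <- pi_table(consensuses, covered)
    write.table(pis, p("pi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    tree <- bootstrap_support(consensuses, n_reps = bootstrap_reps,
                              seed = derive_seed(seed, 21))
    ape::write.tree(tree, p("consensus_tree.nwk"))
    true_tree <- ape::read.tree(p("chloro", "true_tree.nwk"))
    rf <- rf_metrics(tree, true_tree)
    list(pi = pis, n_genes_covered = nrow(covered), rf = unclass(rf))
  })
  report$stages$chloroplast <- chloro[c("ok", "error")]
  if (chloro$ok) {
    report$metrics$pi_max <- max(chloro$value$pi$pi)
    report$metrics$rf <- chloro$value$rf
  }

  prog_ks <- run_stage("progenitor_ks", sim$ok, function() {
    gA <- read_fasta(p("progenitorA.fa"))
    gB <- read_fasta(p("progenitorB.fa"))
    genesA <- read_gff_genes(p("progenitorA.gff"), gA)
    genesB <- read_gff_genes(p("progenitorB.gff"), gB)
    anchors <- find_anchors(genesA, genesB)
    blocks <- chain_collinear(anchors)
    cds_map <- setNames(c(genesA$cds, genesB$cds),
                        c(genesA$gene_id, genesB$gene_id))
    blocks <- lapply(blocks, block_ks, cds_map = cds_map)
    write_blocks(blocks, p("blocks_AB.tsv"))
    ks_values <- unlist(lapply(blocks, function(b) b$anchors$ks))
    mode <- ks_mode(ks_values)
    list(n_blocks = length(blocks), n_anchor_ks = length(ks_values),
         ks_mode = mode$mode)
  })
  report$stages$progenitor_ks <- prog_ks[c("ok", "error")]
  if (prog_ks$ok) report$metrics$ks_mode_progenitors <- prog_ks$value$ks_mode

  tet_stage <- run_stage("subgenome_ks", sim$ok, function() {
    gT <- read_fasta(p("tetraploid.fa"))
    genesT <- read_gff_genes(p("tetraploid.gff"), gT)
    gA <- read_fasta(p("progenitorA.fa"))
    genesA <- read_gff_genes(p("progenitorA.gff"), gA)
    fam <- read_tsv_map(p("gene_families_all.tsv"))
    # self-synteny of the tetraploid: homoeologous duplicate regions
    self_anchors <- find_anchors(genesT, genesT, self = TRUE)
    self_blocks <- self_synteny(genesT, self_anchors)
    cds_T <- setNames(genesT$cds, genesT$gene_id)
    cds_A <- setNames(genesA$cds, genesA$gene_id)
    self_blocks <- lapply(self_blocks, block_ks, cds_map = cds_T)
    write_blocks(self_blocks, p("blocks_self.tsv"))
    self_ks <- unlist(lapply(self_blocks, function(b) b$anchors$ks))
    self_mode <- ks_mode(self_ks)
    # orthologs of tetraploid genes in progenitor A: best hit + same family
    hits <- find_anchors(genesT, genesA, top_k = 1)
    best <- setNames(hits$gene_b, hits$gene_a)
    orth <- true_orthologs(best, fam)
    ks_to_A <- vapply(seq_len(nrow(orth)), function(i) {
      est <- ks_pair(cds_T[[orth$gene[[i]]]], cds_A[[orth$ortholog[[i]]]])
      if (est$saturated_s) NA_real_ else est$dS
    }, numeric(1))
    names(ks_to_A) <- orth$gene
    ks_labels <- partition_ab(self_blocks, ks_to_A)
    write.table(ks_labels, p("subgenome_ks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- read.delim(p("truth", "contig_origin.tsv"), stringsAsFactors = FALSE)
    truth_of <- setNames(truth$origin, truth$contig_id)
    assigned <- ks_labels$label != "unassigned"
    acc <- mean(ks_labels$label[assigned] ==
                  truth_of[ks_labels$contig_id[assigned]])
    list(n_self_blocks = length(self_blocks), self_ks_mode = self_mode$mode,
         n_orthologs = nrow(orth), ks_labels = ks_labels,
         partition_accuracy = acc,
         assigned_fraction = mean(assigned))
  })
  report$stages$subgenome_ks <- tet_stage[c("ok", "error")]
  if (tet_stage$ok) {
    report$metrics$ks_mode_self <- tet_stage$value$self_ks_mode
    report$metrics$ks_partition_accuracy <- tet_stage$value$partition_accuracy
  }

  doc_stage <- run_stage("doc", sim$ok, function() {
    gT <- read_fasta(p("tetraploid.fa"))
    depthsA <- assign_reads_by_kmer(p("readsA.fastq.gz"), gT, k = doc_k,
                                    sample_name = "progenitor_A")
    depthsB <- assign_reads_by_kmer(p("readsB.fastq.gz"), gT, k = doc_k,
                                    sample_name = "progenitor_B")
    depths <- merge(depthsA, depthsB[c("contig_id", "progenitor_B")],
                    by = "contig_id")
    write_depth_table(depths, p("depths.tsv"))
    cls <- classify_contigs_doc(read_depth_table(p("depths.tsv")),
                                sampleA = "progenitor_A",
                                sampleB = "progenitor_B", threshold = 16)
    write.table(cls$summary, p("doc_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- read.delim(p("truth", "contig_origin.tsv"), stringsAsFactors = FALSE)
    truth_of <- setNames(truth$origin, truth$contig_id)
    acc <- mean(cls$labels$label == truth_of[cls$labels$contig_id])
    list(labels = cls$labels, summary = cls$summary, doc_accuracy = acc)
  })
  report$stages$doc <- doc_stage[c("ok", "error")]
  if (doc_stage$ok) report$metrics$doc_accuracy <- doc_stage$value$doc_accuracy

  rec <- run_stage("reconcile", tet_stage$ok && doc_stage$ok, function() {
    reconcile(tet_stage$value$ks_labels, doc_stage$value$labels)
  })
  report$stages$reconcile <- rec[c("ok", "error")]
  if (rec$ok) report$metrics$reconcile_agreement <- rec$value$agreement

  fam_stage <- run_stage("families", sim$ok, function() {
    rows <- read.delim(p("families.tsv"), stringsAsFactors = FALSE)
    res <- amplified_families(rows)
    found <- res$family_id[res$amplified]
    truth_amp <- readLines(p("truth", "amplified_families.txt"))
    path_map <- read.delim(p("pathways.tsv"), stringsAsFactors = FALSE)
    rollup <- pathway_rollup(found, path_map)
    precision <- if (length(found) > 0) mean(found %in% truth_amp) else NA_real_
    recall <- if (length(truth_amp) > 0) mean(truth_amp %in% found) else NA_real_
    list(n_amplified = length(found), precision = precision, recall = recall,
         rollup = rollup)
  })
  report$stages$families <- fam_stage[c("ok", "error")]
  if (fam_stage$ok) {
    report$metrics$family_precision <- fam_stage$value$precision
    report$metrics$family_recall <- fam_stage$value$recall
  }

  m <- report$metrics
  thr <- thresholds$recovery
  band <- thresholds$ks_band
  report$pass <- list(
    ks_mode_progenitors = isTRUE(m$ks_mode_progenitors >= band[[1]] &&
                                   m$ks_mode_progenitors <= band[[2]]),
    doc_accuracy = isTRUE(m$doc_accuracy >= thr),
    ks_partition_accuracy = isTRUE(m$ks_partition_accuracy >= thr),
    reconcile_agreement = isTRUE(m$reconcile_agreement >= thr),
    family_precision = isTRUE(m$family_precision == 1),
    family_recall = isTRUE(m$family_recall == 1))
  jsonlite::write_json(
    list(config = report$config, seed = seed,
         stages = lapply(report$stages, function(s) s$ok %||% s),
         metrics = report$metrics, pass = report$pass),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Desk benchmark report (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (is.numeric(v) && length(v) == 1) {
      cat(sprintf("  %-24s %.4f\n", nm, v))
    }
  }
  cat("pass:", paste(names(x$pass)[unlist(x$pass)], collapse = ", "), "\n")
  fail <- names(x$pass)[!unlist(x$pass)]
  if (length(fail) > 0) cat("FAIL:", paste(fail, collapse = ", "), "\n")
  invisible(x)
}
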