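# Independent oracles used to validate the package's estimators. These are
# deliberately written from first principles, sharing no code with the
# implementations they check.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  function(codon) unname(gc[[codon]])
})

# --- NG86 oracle: explicit neighbour and path enumeration per codon pair ---

oracle_syn_sites_codon <- function(codon) {
  aa <- oracle_code(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in ORACLE_BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_code(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_paths <- function(c1, c2) {
  # all orders of the differing positions, as list of position vectors
  dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dif) == 0) return(list(integer()))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i])) out[[length(out) + 1]] <- c(v[[i]], rest)
    }
    out
  }
  perm(dif)
}

oracle_diffs_codon <- function(c1, c2) {
  paths <- oracle_paths(c1, c2)
  res <- lapply(paths, function(order) {
    cur <- c1
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (oracle_code(nxt) == "*") through_stop <- TRUE
      if (oracle_code(cur) == oracle_code(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = through_stop)
  })
  ok <- !vapply(res, `[[`, TRUE, "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(sd = mean(vapply(res[ok], `[[`, 0, "sd")),
    nd = mean(vapply(res[ok], `[[`, 0, "nd")))
}

oracle_ng86 <- function(codons1, codons2) {
  S <- mean(c(sum(vapply(codons1, oracle_syn_sites_codon, 0)),
              sum(vapply(codons2, oracle_syn_sites_codon, 0))))
  N <- 3 * length(codons1) - S
  d <- rowSums(vapply(seq_along(codons1), function(i) {
    oracle_diffs_codon(codons1[[i]], codons2[[i]])
  }, c(sd = 0, nd = 0)))
  pS <- d[["sd"]] / S
  pN <- d[["nd"]] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[["sd"]], Nd = d[["nd"]], pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

random_sense_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sample(sense, n, replace = TRUE)
}

# mutate a sense codon into a nearby sense codon (0-3 base changes)
perturb_codons <- function(codons, p_change = 0.3) {
  gc <- Biostrings::GENETIC_CODE
  out <- codons
  for (i in seq_along(out)) {
    cd <- out[[i]]
    for (pos in 1:3) {
      if (runif(1) < p_change) {
        b <- sample(setdiff(ORACLE_BASES, substr(cd, pos, pos)), 1)
        cand <- cd
        substr(cand, pos, pos) <- b
        if (gc[[cand]] != "*") cd <- cand
      }
    }
    out[[i]] <- cd
  }
  out
}

# --- nucleotide diversity oracle: direct double loop over pairs/sites ---

oracle_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  usable <- apply(mat, 2, function(col) all(col %in% ORACLE_BASES))
  mat <- mat[, usable, drop = FALSE]
  L <- ncol(mat)
  if (L == 0) stop("no usable sites")
  n <- nrow(mat)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (s in seq_len(L)) if (mat[i, s] != mat[j, s]) tot <- tot + 1
    }
  }
  tot / choose(n, 2) / L
}

# --- collinear chain oracle: exhaustive enumeration of monotone chains ---

oracle_best_chain_score <- function(anchors, max_gap = 25, gap_penalty = 1.0) {
  n <- nrow(anchors)
  best <- -Inf
  extend <- function(last, score, sign_b) {
    best <<- max(best, score)
    for (nxt in seq_len(n)) {
      da <- anchors$rank_a[[nxt]] - anchors$rank_a[[last]]
      db <- sign_b * (anchors$rank_b[[nxt]] - anchors$rank_b[[last]])
      if (da < 1 || db < 1 || da > max_gap || db > max_gap) next
      extend(nxt, score + anchors$score[[nxt]] -
               gap_penalty * ((da - 1) + (db - 1)), sign_b)
    }
  }
  for (start in seq_len(n)) {
    for (sign_b in c(1, -1)) {
      extend(start, anchors$score[[start]], sign_b)
    }
  }
  best
}

# --- brute-force global affine alignment score (tiny sequences only) ---

oracle_align_score <- function(p1, p2, open = 11, extend = 1) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  # state: 0 = match, 1 = gap in b (consume a), 2 = gap in a (consume b)
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, B[a[[i]], b[[j]]] + rec(i + 1, j + 1, 0))
    }
    if (i <= length(a)) {
      cost <- if (state == 1) extend else open + extend
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(b)) {
      cost <- if (state == 2) extend else open + extend
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# --- naive canonical k-mer recount ---

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_kmer_hist <- function(reads, k) {
  kmers <- character()
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in 1:(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      kmers <- c(kmers, if (km <= rc) km else rc)
    }
  }
  tab <- table(table(kmers))
  data.frame(multiplicity = as.integer(names(tab)), n_kmers = as.integer(tab))
}

# small helper: random DNA string
random_dna_str <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}
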