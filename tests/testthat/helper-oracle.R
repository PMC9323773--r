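# Independent brute-force oracles kept deliberately separate from the package
# implementation. The Smith-Waterman oracle computes the optimal local
# affine-gap score by row-wise dynamic programming with a prefix-max recurrence
# for within-row gaps -- a different algorithmic formulation from the package's
# three-state banded C++ engine.

# Optimal local alignment score over integer-coded sequences.
# Gap convention: a gap of length L costs go + L * ge (first gapped column
# pays go + ge). submat is indexed by code + 1.
oracle_sw_score <- function(qc, sc, submat, go, ge) {
  m <- length(qc); n <- length(sc)
  if (m == 0L || n == 0L) return(0)
  open <- go + ge
  Hprev <- numeric(n + 1L)          # row i-1, index j+1 holds column j
  Fprev <- rep(-Inf, n + 1L)
  best <- 0
  jidx <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- submat[qc[i] + 1L, sc + 1L]
    Fcur <- pmax(Hprev[-1L] - open, Fprev[-1L] - ge)
    diag <- Hprev[jidx] + sub
    H_noE <- pmax(0, diag, Fcur)
    # within-row gap (in query): E[j] = max_{t<j}(H[t] + t*ge) - go - j*ge;
    # extension dominance makes the prefix-max over gap-free H exact
    A <- c(0, H_noE + jidx * ge)
    E <- cummax(A)[jidx] - open - (jidx - 1L) * ge
    H <- pmax(H_noE, E)
    best <- max(best, H)
    Hprev <- c(0, H)
    Fprev <- c(-Inf, Fcur)
  }
  best
}

oracle_sw_score_nt <- function(q, s, match = 1, mismatch = -2, go = 2.5, ge = 2.5) {
  enc <- function(x) match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T", "N")) - 1L
  sub <- matrix(mismatch, 5, 5)
  diag(sub) <- match
  sub[5, 5] <- mismatch   # N-N is never a match
  oracle_sw_score(enc(q), enc(s), sub, go, ge)
}

# Protein oracle over a named substitution matrix (e.g. BLOSUM62 with '*'
# made unalignable), letters indexed by the matrix rownames.
oracle_sw_score_aa <- function(q, s, submat, go = 11, ge = 1) {
  enc <- function(x) {
    i <- match(strsplit(toupper(x), "")[[1]], rownames(submat))
    i[is.na(i)] <- match("X", rownames(submat))
    i - 1L
  }
  oracle_sw_score(enc(q), enc(s), submat, go, ge)
}

# Brute-force all-pairs containment intersection oracle (strand-aware,
# 0-based half-open intervals): every pair is examined, vectorised over the
# full cross product -- no interval index involved.
oracle_containment <- function(hervs, ncrnas) {
  i <- rep(seq_len(nrow(hervs)), times = nrow(ncrnas))
  j <- rep(seq_len(nrow(ncrnas)), each = nrow(hervs))
  ov <- pmin(hervs$end[i], ncrnas$end[j]) - pmax(hervs$start[i], ncrnas$start[j])
  hcov <- 100 * ov / (hervs$end[i] - hervs$start[i])
  rcov <- 100 * ov / (ncrnas$end[j] - ncrnas$start[j])
  keep <- hervs$contig[i] == ncrnas$contig[j] &
    hervs$strand[i] == ncrnas$strand[j] &
    ov >= 1 & (hcov == 100 | rcov == 100)
  data.frame(herv_id = hervs$id[i][keep], ncrna_id = ncrnas$id[j][keep],
             overlap_bp = ov[keep])
}

# Neighbour-joining oracle for LTR clustering: builds an NJ tree from
# independent (Biostrings) local-alignment distances between all LTR records
# and reports, per element, whether its 5p/3p records form a cherry.
oracle_nj_cherries <- function(records) {
  n <- nrow(records)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- Biostrings::pairwiseAlignment(records$sequence[i],
                                         records$sequence[j], type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 2.5, gapExtension = 2.5)
      ncol_aln <- Biostrings::nchar(p)
      pid <- if (ncol_aln == 0) 0 else Biostrings::nmatch(p) / ncol_aln
      # scale identity by the fraction of the shorter record aligned, so
      # short spurious matches do not look close
      cov <- ncol_aln / min(nchar(records$sequence[i]),
                            nchar(records$sequence[j]))
      d[i, j] <- d[j, i] <- 1 - pid * min(1, cov)
    }
  }
  labs <- paste(records$element_id, records$side, sep = ":")
  dimnames(d) <- list(labs, labs)
  tr <- ape::nj(as.dist(d))
  parent_of <- function(lab) {
    tip <- match(lab, tr$tip.label)
    tr$edge[tr$edge[, 2] == tip, 1]
  }
  vapply(unique(records$element_id), function(eid) {
    p5 <- parent_of(paste0(eid, ":5p"))
    p3 <- parent_of(paste0(eid, ":3p"))
    isTRUE(p5 == p3)
  }, TRUE)
}
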