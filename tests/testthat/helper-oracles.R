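# Independent oracles used by the tests. Each reimplements the checked
# operation with a different algorithm than the package code path.

# --- brute-force Smith-Waterman (affine gaps), pure R ----------------------
# Three-state DP kept deliberately simple; scores only.
sw_oracle <- function(query, subject, mat, gap_open = 11, gap_extend = 1) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  gop <- gap_open + gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - gop, Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gop, Iy[i, j - 1] - gap_extend)
      prev <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      M[i, j] <- max(0, prev + mat[q[i - 1], s[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- six-frame ORF scanner, pure position-walking R ------------------------
# Independent of the vectorized caller: walks codons one at a time.
orf_oracle <- function(seq, min_nt = 90) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  gc <- Biostrings::GENETIC_CODE
  scan1 <- function(s) {
    n <- nchar(s)
    out <- list()
    for (f in 0:2) {
      i <- f + 1
      open_at <- NA
      while (i + 2 <= n) {
        cod <- substr(s, i, i + 2)
        if (grepl("[^ACGT]", cod)) {
          open_at <- NA
        } else if (cod %in% stops) {
          if (!is.na(open_at) && (i + 3 - open_at) >= min_nt) {
            cods <- substring(s, seq(open_at, i - 1, by = 3),
                              seq(open_at, i - 1, by = 3) + 2)
            aa <- unname(gc[cods]); aa[1] <- "M"
            out[[length(out) + 1]] <- list(start = open_at - 1, end = i + 2,
                                           protein = paste(aa, collapse = ""))
          }
          open_at <- NA
        } else if (is.na(open_at) && cod %in% starts) {
          open_at <- i
        }
        i <- i + 3
      }
    }
    out
  }
  n <- nchar(seq)
  fwd <- scan1(seq)
  rev <- scan1(alkscan::revcomp(seq))
  rows <- c(lapply(fwd, function(r)
    data.frame(start = r$start, end = r$end, strand = "+",
               protein = r$protein, stringsAsFactors = FALSE)),
    lapply(rev, function(r)
      data.frame(start = n - r$end, end = n - r$start, strand = "-",
                 protein = r$protein, stringsAsFactors = FALSE)))
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# --- exhaustive inverted-repeat search via anti-diagonal sums --------------
# Finds the best TIR pair under the same objective as find_tirs() but with a
# different algorithm: equality matrix + running sums along anti-diagonals.
tir_oracle <- function(seq, cs, ce, min_len = 15, max_len = 45,
                       max_span = 5000, max_mismatch = 2, flank_nt = 400) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  compl <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
  l0 <- max(0L, cs - flank_nt)           # 0-based window bounds
  r1 <- min(n, ce + flank_nt)
  if (cs - l0 < min_len || r1 - ce < min_len) return(NULL)
  lens <- min_len:max_len
  allowed <- ifelse(lens < 20, 0L, ifelse(lens < 26, min(1L, max_mismatch),
                                          as.integer(max_mismatch)))
  li <- (l0 + 1):cs                      # 1-based left positions
  ri <- (ce + 1):r1                      # 1-based right positions
  # E[a, b] <- left char at li[a] equals complement of right char at ri[b]
  E <- outer(chars[li], compl[ri], "==")
  A <- length(li); B <- length(ri)
  best <- NULL
  for (d in seq_len(A + B - 1)) {        # anti-diagonal: a + b = d + 1
    a_idx <- max(1, d - B + 1):min(A, d)
    b_idx <- d + 1 - a_idx
    v <- E[cbind(a_idx, b_idx)]          # ordered by increasing a
    if (length(v) < min_len) next
    cv <- c(0, cumsum(v))
    nv <- length(v)
    for (Lk in seq_along(lens)) {
      L <- lens[Lk]
      if (nv < L) next
      p_all <- seq_len(nv - L + 1)
      mm_all <- L - (cv[p_all + L] - cv[p_all])
      for (p in p_all[mm_all <= allowed[Lk]]) {
        mm <- mm_all[p]
        b_lo <- b_idx[p] - L + 1         # right index paired with a_hi
        if (b_lo < 1) next
        i <- li[a_idx[p]] - 1            # 0-based left start
        j <- ri[b_lo] - 1                # 0-based right start
        if (i + L > cs) next             # left must end before center
        if (j < ce || j + L > r1) next
        if ((j + L) - i > max_span) next
        cand <- c(i = i, j = j, L = L, mm = mm)
        if (is.null(best) ||
            L > best["L"] ||
            (L == best["L"] && (mm < best["mm"] ||
              (mm == best["mm"] && (i < best["i"] ||
                (i == best["i"] && j < best["j"]))))))
          best <- cand
      }
    }
  }
  best
}

# --- random additive trees -------------------------------------------------
random_additive_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}
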