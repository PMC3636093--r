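# Independent oracles used across the suite.

# Exact 1-D total-variation denoising via the box-constrained dual QP,
# solved with base R L-BFGS-B: min_z 0.5||y - B z||^2, |z_k| <= lambda,
# fitted x = y - B z. Independent of the package's direct solver.
tv_oracle <- function(y, lambda) {
  n <- length(y)
  if (n < 2L || lambda <= 0) return(y)
  B <- matrix(0, n, n - 1L)
  for (k in seq_len(n - 1L)) { B[k + 1L, k] <- 1; B[k, k] <- -1 }
  fn <- function(z) { r <- y - B %*% z; 0.5 * sum(r^2) }
  gr <- function(z) as.numeric(-t(B) %*% (y - B %*% z))
  o <- stats::optim(rep(0, n - 1L), fn, gr, method = "L-BFGS-B",
                    lower = -lambda, upper = lambda,
                    control = list(maxit = 20000, factr = 10))
  as.numeric(y - B %*% o$par)
}

# KKT certificate of exact optimality for the TV problem: with
# z = cumsum(y - x), optimality requires z_n = 0, |z_k| <= lambda, and
# z_k pinned at -/+ lambda wherever x jumps up/down.
tv_kkt_ok <- function(y, x, lambda, tol = 1e-8) {
  z <- cumsum(y - x)
  n <- length(y)
  if (abs(z[n]) > tol) return(FALSE)
  zk <- z[-n]
  if (any(abs(zk) > lambda + tol)) return(FALSE)
  d <- diff(x)
  all(abs(zk[d > tol] + lambda) < tol) &&
    all(abs(zk[d < -tol] - lambda) < tol)
}

# Brute-force chimeric-read scan: all ordered exon pairs, all offsets,
# plain substring comparison (fwd and revcomp).
rescue_bruteforce <- function(read, gene5, gene3, tx_seqs, max_mismatches = 2L) {
  tb5 <- exon_tx_bounds(gene5); tb3 <- exon_tx_bounds(gene3)
  tx5 <- tx_seqs[[gene5$gene_id]]; tx3 <- tx_seqs[[gene3$gene_id]]
  rl <- nchar(read); ctx <- rl - 1L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits <- list()
  for (i in seq_len(nrow(tb5))) for (j in seq_len(nrow(tb3))) {
    left <- substr(tx5, max(1L, tb5[i, 2L] - ctx + 1L), tb5[i, 2L])
    right <- substr(tx3, tb3[j, 1L] + 1L, min(nchar(tx3), tb3[j, 1L] + ctx))
    jn <- paste0(left, right)
    cut <- nchar(left)
    for (o in seq_len(nchar(jn))) {
      if (o + rl - 1L > nchar(jn)) break
      if (!(o <= cut && o + rl - 1L >= cut + 1L)) next
      win <- substr(jn, o, o + rl - 1L)
      for (v in c(read, rc)) {
        mm <- sum(strsplit(v, "")[[1L]] != strsplit(win, "")[[1L]])
        if (mm <= max_mismatches)
          hits[[length(hits) + 1L]] <- c(i = i, j = j, mm = mm)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}
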