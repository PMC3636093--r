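# Row-wise two-sample pooled-variance t statistics (genes x samples matrix
# against a binary grouping). Vectorised; cross-checked against t.test in
# the test suite.
row_ttest <- function(X, labels) {
  g1 <- labels == 1L
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, !g1, drop = FALSE])
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, !g1, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2L)
  p[se == 0] <- 1
  list(t = t, p = p, delta = m1 - m2)
}

signature_pass <- function(X, labels, r_min, p_max, fold_min) {
  tt <- row_ttest(X, labels)
  # Pearson correlation of each gene with the binary class variable
  r <- as.numeric(cor(t(X), labels))
  r[is.na(r)] <- 0
  fold <- 2^abs(tt$delta)  # log2 data: fold change of class means
  list(r = r, p = tt$p, fold = fold, delta = tt$delta,
       passes = abs(r) >= r_min & tt$p < p_max & fold >= fold_min)
}

#' Supervised two-class gene signature with permutation FDR
#'
#' Selects genes separating two sample classes on log2 expression by three
#' simultaneous criteria: Pearson correlation with the binary class label
#' `|R| >= r_min`, two-tailed pooled-variance Student t-test `P < p_max`,
#' and fold change (ratio of class means on the linear scale, computed as
#' `2^|difference of log2 means|`) of at least `fold_min`. The false
#' discovery rate is estimated globally by permutation: class labels are
#' shuffled (preserving class sizes) `n_perm` times and the FDR is the mean
#' number of genes passing under permutation divided by the observed passing
#' count. When nothing passes the observed data, the FDR is reported as 1
#' if permutations produce passes and `NA` otherwise.
#'
#' @param matrix numeric gene x sample matrix of log2 expression, with
#'   rownames.
#' @param labels binary vector (0/1, logical, or two-level factor), one per
#'   sample; class "1" is the class of interest.
#' @param r_min,p_max,fold_min the three selection thresholds
#'   (defaults 0.5, 0.001, 2).
#' @param n_perm number of label permutations (default 1000).
#' @param seed seed for the permutation stream (private RNG state).
#' @return object of class `signature_result`: list with `table` (per-gene
#'   data.frame: `gene_id`, `pearson_r`, `t_p`, `fold_change`, `direction`,
#'   `passes`), `fdr_estimate`, `n_pass`, `perm_mean_pass`, `n_perm`.
#' @export
supervised_signature <- function(matrix, labels, r_min = 0.5, p_max = 0.001,
                                 fold_min = 2, n_perm = 1000L, seed = 11L) {
  X <- as.matrix(matrix)
  if (is.factor(labels) || is.character(labels))
    labels <- as.integer(factor(labels)) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(labels) != ncol(X)) stop("one label per sample required")
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("each class needs at least 2 samples")
  obs <- signature_pass(X, labels, r_min, p_max, fold_min)
  n_pass <- sum(obs$passes)
  perm_counts <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sum(signature_pass(X, sample(labels), r_min, p_max, fold_min)$passes)
  }, numeric(1L)))
  perm_mean <- mean(perm_counts)
  fdr <- if (n_pass > 0L) perm_mean / n_pass
         else if (perm_mean > 0) 1 else NA_real_
  tab <- data.frame(
    gene_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    pearson_r = obs$r, t_p = obs$p, fold_change = obs$fold,
    direction = ifelse(obs$delta >= 0, "up_in_class1", "down_in_class1"),
    passes = obs$passes, stringsAsFactors = FALSE)
  structure(list(table = tab, fdr_estimate = fdr, n_pass = n_pass,
                 perm_mean_pass = perm_mean, n_perm = n_perm,
                 thresholds = c(r_min = r_min, p_max = p_max,
                                fold_min = fold_min)),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf(paste0("<signature_result> %d/%d gene(s) pass ",
                     "(|R|>=%g, P<%g, fold>=%g); permutation FDR %.3g ",
                     "(%d perms, mean null passes %.2f)\n"),
              x$n_pass, nrow(x$table), x$thresholds["r_min"],
              x$thresholds["p_max"], x$thresholds["fold_min"],
              x$fdr_estimate, x$n_perm, x$perm_mean_pass))
  invisible(x)
}
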