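soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# maximal-scoring contiguous subsegment (Kadane), ties to the first;
# returns c(start, end) 1-based inclusive
max_subsegment <- function(sc) {
  best <- -Inf; bs <- 1L; be <- 1L; cur <- 0; cs <- 1L
  for (k in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[k]; cs <- k } else cur <- cur + sc[k]
    if (cur > best) { best <- cur; bs <- cs; be <- k }
  }
  c(bs, be)
}

# run expr with a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Total-variation denoising of a numeric signal
#'
#' Solves `min_x 0.5 * sum (x - y)^2 + lambda * sum |x[i+1] - x[i]|`
#' exactly; the solution is piecewise constant.
#'
#' @param y numeric vector.
#' @param lambda non-negative fusion penalty.
#' @return fitted numeric vector of the same length.
#' @export
tv_denoise <- function(y, lambda) {
  stopifnot(is.numeric(y), all(is.finite(y)), lambda >= 0)
  .tv1d_denoise(as.numeric(y), lambda)
}

#' Segment a copy-number track (fused-lasso fit with permutation FDR)
#'
#' Fits a piecewise-constant signal to probe-level log2 ratios by 1-D
#' fused-lasso: total-variation denoising with fusion penalty `lambda2`
#' followed by soft-thresholding with sparsity penalty `lambda1`, which is
#' exactly the fused-lasso solution and sets copy-neutral probes to exactly
#' zero. The fusion penalty is calibrated so that, under a permutation null
#' (probe ratios shuffled within the chromosome, `n_perm` permutations,
#' seeded), the expected fraction of probes fitted non-zero is at most `fdr`;
#' the smallest penalty on a log-spaced grid achieving this is used.
#'
#' @param track a [probe_track()] or numeric vector of log2 ratios.
#' @param fdr target null non-neutral probe rate (default 0.01).
#' @param lambda1 sparsity (soft-threshold) penalty in log2 units
#'   (default 0.1; well below the 0.3 amplitude floor for reportable CNAs,
#'   so it decides neutrality, not segment acceptance).
#' @param lambda_grid optional increasing grid of candidate fusion
#'   penalties; default a half-octave log grid (`2^seq(0.5, 8, 0.5)`) times
#'   the probe-noise scale estimated from first differences — fine enough
#'   that the chosen penalty overshoots the FDR-minimal one by at most
#'   about 40%, which keeps short high-level alterations from being
#'   over-smoothed.
#' @param n_perm permutations for the null calibration.
#' @param perm_seed seed for the permutation stream (uses a private RNG
#'   state; the caller's random stream is untouched).
#' @return numeric fitted vector (same length), with attributes `lambda2`,
#'   `lambda1` and `null_rate` (estimated null non-zero rate at the chosen
#'   penalty).
#' @export
segment_track <- function(track, fdr = 0.01, lambda1 = 0.1,
                          lambda_grid = NULL, n_perm = 20L, perm_seed = 1L) {
  y <- if (inherits(track, "probe_track")) track$ratios else as.numeric(track)
  if (!length(y) || all(is.na(y))) stop("empty or all-missing track")
  if (any(!is.finite(y))) stop("track contains missing/non-finite ratios")
  if (length(y) < 2L) stop("track must have at least 2 probes")
  if (!(fdr > 0 && fdr < 1)) stop("fdr must be in (0, 1)")
  if (is.null(lambda_grid)) {
    s <- stats::mad(diff(y)) / sqrt(2)
    if (s == 0) s <- stats::sd(y)
    if (is.na(s) || s == 0) {
      # constant track: any penalty yields the constant itself
      fit <- soft_threshold(y, lambda1)
      attributes(fit) <- list(lambda2 = 0, lambda1 = lambda1, null_rate = 0)
      return(fit)
    }
    lambda_grid <- s * 2^seq(0.5, 8, by = 0.5)
  }
  lambda_grid <- sort(lambda_grid)
  # the permutation null must be copy-neutral on average: centre the ratios
  # before shuffling so true alteration mass cannot shift the whole null
  # fit away from zero (a near no-op on genuinely neutral tracks)
  y0 <- y - mean(y)
  perms <- with_seed(perm_seed,
                     replicate(n_perm, sample(y0), simplify = FALSE))
  chosen <- lambda_grid[length(lambda_grid)]
  null_rate <- NA_real_
  for (lam in lambda_grid) {
    rate <- mean(vapply(perms, function(p) {
      mean(soft_threshold(.tv1d_denoise(p, lam), lambda1) != 0)
    }, numeric(1L)))
    if (rate <= fdr) { chosen <- lam; null_rate <- rate; break }
    null_rate <- rate
  }
  if (is.na(null_rate) || null_rate > fdr)
    warning("no penalty on the grid met the FDR target; using the largest")
  fit <- soft_threshold(.tv1d_denoise(y, chosen), lambda1)
  attr(fit, "lambda2") <- chosen
  attr(fit, "lambda1") <- lambda1
  attr(fit, "null_rate") <- null_rate
  fit
}

#' Copy-number smoothing: boundary refinement of fitted CNAs
#'
#' Walks each chromosome to turn the fused-lasso fit into "well-defined"
#' copy-number alterations with refined boundaries. Each iteration finds the
#' upper (genomically left) boundary of the next candidate CNA, i.e. the
#' start of the next non-zero same-sign run of the fitted signal. The
#' candidate is accepted when its average absolute raw log2 ratio is at
#' least `theta` over at least `min_len` probes, or at least `high_theta`
#' over at least `high_min_len` probes (high-level CNAs: focal
#' amplifications and deep deletions earn a shorter length floor).
#'
#' The walk then descends to find the lower boundary: the first position
#' whose own fitted value has left the CNA (exactly zero, opposite sign, or
#' differing from the CNA's average by at least `theta`) and where at least
#' `frac` of the `window` fitted values starting there (a shorter
#' `high_window` for high-level CNAs) also qualify — or the chromosome end.
#' Requiring the whole window, not just one probe, to have left the CNA is
#' what merges noise-split segments instead of truncating at every blip.
#' Neutrality is evaluated on the fitted values, which are exactly zero for
#' copy-neutral probes by construction. The segment mean is then recomputed
#' from the raw ratios over the final boundaries.
#'
#' @param fitted fitted vector from [segment_track()].
#' @param track the matching [probe_track()] of raw ratios.
#' @param theta amplitude floor and boundary-shift threshold, log2 units.
#' @param min_len minimum probes for a standard CNA.
#' @param high_theta amplitude defining high-level CNAs.
#' @param high_min_len minimum probes for a high-level CNA.
#' @param frac fraction of the look-ahead window that must have left the CNA.
#' @param window,high_window look-ahead window length in probes.
#' @return data.frame of class `cna_segments`: `sample_id`, `chrom`,
#'   `start_probe`, `end_probe` (0-based half-open probe indices),
#'   `start_pos`, `end_pos` (0-based half-open genomic), `n_probes`,
#'   `mean_log2`, `level` (`standard`/`high`), `sign` (`gain`/`loss`).
#' @export
copy_number_smooth <- function(fitted, track, theta = 0.3, min_len = 50L,
                               high_theta = 1.0, high_min_len = 10L,
                               frac = 0.95, window = 100L, high_window = 50L) {
  stopifnot(inherits(track, "probe_track"),
            length(fitted) == length(track$ratios))
  y <- track$ratios; pos <- track$positions; n <- length(y)
  fitted <- as.vector(fitted)
  sgn <- sign(fitted)
  r <- rle(sgn)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  segs <- list()
  cur <- 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i] == 0 || run_start[i] < cur) next
    s <- r$values[i]
    # refine the candidate's boundaries against the raw ratios: the fused
    # penalty smears short events over neutral neighbours, so the candidate
    # is taken as the maximal-evidence stretch of signed ratio above the
    # amplitude floor within the fitted run
    ks <- max_subsegment(y[run_start[i]:run_end[i]] * s - theta)
    upper <- run_start[i] - 1L + ks[1L]
    btrim <- run_start[i] - 1L + ks[2L]
    len0 <- btrim - upper + 1L
    m0 <- mean(y[upper:btrim])
    is_std <- abs(m0) >= theta && len0 >= min_len
    is_high <- abs(m0) >= high_theta && len0 >= high_min_len
    if (!is_std && !is_high) next
    win <- if (is_high) high_window else window
    # the walk operates on fitted values, so the shift criterion compares
    # them to the fitted (not raw) CNA mean; acceptance above used the raw
    # amplitude
    m_fit <- mean(fitted[upper:btrim])
    qual <- fitted == 0 | sign(fitted) == -s | abs(fitted - m_fit) >= theta
    lower <- n + 1L
    if (upper < n) {
      cq <- c(0, cumsum(qual))
      p <- (upper + 1L):n
      wend <- pmin(p + win - 1L, n)
      wfrac <- (cq[wend + 1L] - cq[p]) / (wend - p + 1L)
      hit <- which(qual[p] & wfrac >= frac)
      if (length(hit)) lower <- p[hit[1L]]
    }
    # the same maximal-evidence refinement fixes the lower boundary of the
    # walked-down region
    walk_end <- lower
    ks2 <- max_subsegment(y[upper:(lower - 1L)] * s - theta)
    upper <- upper - 1L + ks2[1L]
    lower <- upper - ks2[1L] + 1L + ks2[2L]
    if (lower - upper < 1L) { cur <- run_end[i] + 1L; next }
    mean_log2 <- mean(y[upper:(lower - 1L)])
    n_probes <- lower - upper
    level <- if (abs(mean_log2) >= high_theta) "high" else "standard"
    ok <- if (level == "high") n_probes >= high_min_len
          else n_probes >= min_len && abs(mean_log2) >= theta
    if (ok) {
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = track$sample_id, chrom = track$chrom,
        start_probe = upper - 1L, end_probe = lower - 1L,
        start_pos = pos[upper], end_pos = pos[lower - 1L] + 1,
        n_probes = n_probes, mean_log2 = mean_log2, level = level,
        sign = if (mean_log2 > 0) "gain" else "loss",
        stringsAsFactors = FALSE)
    }
    cur <- lower
  }
  out <- if (length(segs)) do.call(rbind, segs)
         else data.frame(sample_id = character(), chrom = character(),
                         start_probe = integer(), end_probe = integer(),
                         start_pos = numeric(), end_pos = numeric(),
                         n_probes = integer(), mean_log2 = numeric(),
                         level = character(), sign = character(),
                         stringsAsFactors = FALSE)
  class(out) <- c("cna_segments", "data.frame")
  out
}

#' @export
print.cna_segments <- function(x, ...) {
  cat(sprintf("<cna_segments> %d segment(s) (%d high-level)\n",
              nrow(x), sum(x$level == "high")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

#' Call intragenic copy-number breakpoints
#'
#' A segment boundary lying strictly inside a gene's genomic span marks a
#' candidate DNA breakpoint: the copy-number transition disrupts the gene,
#' the genomic signature of a rearrangement junction. Boundaries at or
#' outside the span (including segments that contain the whole gene) emit
#' nothing. `boundary_side` records, in transcript orientation, which end of
#' the transcript lies inside the alteration (`upper_5prime` when the 5' end
#' is altered, `lower_3prime` for the 3' end); `transition` records the
#' genomic event at the boundary. Segments spanning fewer than `focal_cap`
#' probes are flagged focal — short, high-contrast alterations are the ones
#' that most often sit at fusion junctions — for prioritisation only.
#'
#' @param segments a `cna_segments` data.frame from [copy_number_smooth()].
#' @param models named list of [gene_model()] objects.
#' @param focal_cap probe-count cap under which a segment is flagged focal.
#' @return data.frame of class `cna_breakpoints`.
#' @export
call_intragenic_breakpoints <- function(segments, models, focal_cap = 1000L) {
  rows <- list()
  empty <- data.frame(gene_id = character(), sample_id = character(),
                      chrom = character(), boundary_pos = numeric(),
                      boundary_side = character(), transition = character(),
                      sign = character(), focal = logical(),
                      seg_start = numeric(), seg_end = numeric(),
                      n_probes = integer(), mean_log2 = numeric(),
                      level = character(), stringsAsFactors = FALSE)
  if (!nrow(segments)) {
    class(empty) <- c("cna_breakpoints", "data.frame"); return(empty)
  }
  spans <- lapply(models, gene_span)
  for (k in seq_len(nrow(segments))) {
    seg <- segments[k, ]
    for (side in c("start", "end")) {
      pos_b <- if (side == "start") seg$start_pos else seg$end_pos
      inside_right <- side == "start"  # which flank of the boundary is altered
      for (gm in models) {
        if (gm$chrom != seg$chrom) next
        sp <- spans[[gm$gene_id]]
        if (!(pos_b > sp[1L] && pos_b < sp[2L])) next
        inside_is_3prime <- inside_right == (gm$strand == "+")
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gm$gene_id, sample_id = seg$sample_id, chrom = seg$chrom,
          boundary_pos = pos_b,
          boundary_side = if (inside_is_3prime) "lower_3prime"
                          else "upper_5prime",
          transition = paste0(seg$sign,
                              if (side == "start") "_starts" else "_ends"),
          sign = seg$sign,
          focal = (seg$end_probe - seg$start_probe) < focal_cap,
          seg_start = seg$start_pos, seg_end = seg$end_pos,
          n_probes = seg$n_probes, mean_log2 = seg$mean_log2,
          level = seg$level, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("cna_breakpoints", "data.frame")
  out
}

#' Directional census filter for copy-number breakpoints
#'
#' Keeps breakpoints whose copy-number orientation matches the gene's known
#' fusion role. A 3'-partner kinase (ABL1-like) is activated by gaining its
#' 3' end or losing its 5' end, so role `three_prime` requires a gain whose
#' altered side holds the transcript 3' end, or a loss whose altered side
#' holds the 5' end; role `five_prime` is the mirror image; `either` passes
#' both orientations. An empty census disables the filter.
#'
#' @param calls a `cna_breakpoints` data.frame.
#' @param census a [read_census()] table.
#' @return the filtered `cna_breakpoints` (calls on genes absent from a
#'   non-empty census are dropped).
#' @export
census_direction_filter <- function(calls, census) {
  if (is.null(census) || nrow(census) == 0L || nrow(calls) == 0L) return(calls)
  role <- setNames(census$fusion_role, census$gene_id)
  r <- role[calls$gene_id]
  gain3 <- calls$sign == "gain" & calls$boundary_side == "lower_3prime"
  loss5 <- calls$sign == "loss" & calls$boundary_side == "upper_5prime"
  gain5 <- calls$sign == "gain" & calls$boundary_side == "upper_5prime"
  loss3 <- calls$sign == "loss" & calls$boundary_side == "lower_3prime"
  keep <- !is.na(r) & ((r == "either") |
                       (r == "three_prime" & (gain3 | loss5)) |
                       (r == "five_prime" & (gain5 | loss3)))
  out <- calls[keep, , drop = FALSE]
  class(out) <- class(calls)
  out
}

#' @export
print.cna_breakpoints <- function(x, ...) {
  cat(sprintf("<cna_breakpoints> %d intragenic breakpoint(s) in %d gene(s)\n",
              nrow(x), length(unique(x$gene_id))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}
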