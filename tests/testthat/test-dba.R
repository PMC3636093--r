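test_that("TV denoising is exactly optimal (KKT) and matches the dual QP", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:150, 1)
    y <- rnorm(n) + 2 * rep(rnorm(3), length.out = n)
    lam <- runif(1, 0.01, 5)
    x <- tv_denoise(y, lam)
    expect_true(tv_kkt_ok(y, x, lam))
    expect_equal(x, tv_oracle(y, lam), tolerance = 1e-5)
  }
  # shrinkage: fitted total variation never exceeds the input's
  set.seed(9)
  for (rep in 1:10) {
    y <- rnorm(80)
    x <- tv_denoise(y, runif(1, 0, 3))
    expect_lte(sum(abs(diff(x))), sum(abs(diff(y))) + 1e-12)
  }
})

test_that("segment_track fits flat and step tracks as expected", {
  # flat zero-noise track: all-zero fit, no change-points
  tr <- probe_track("s", "c", 1:100 * 1000, rep(0, 100))
  fit <- segment_track(tr)
  expect_true(all(fit == 0))
  # planted step (200 at 0, 100 at 0.8, 200 at 0; sd 0.1): the non-zero run
  # of the fit localises the event within +/- 3 probes
  set.seed(7)
  y <- c(rep(0, 200), rep(0.8, 100), rep(0, 200)) + rnorm(500, sd = 0.1)
  tr <- probe_track("s", "c", 1:500 * 1000, y)
  fit <- segment_track(tr)
  runs <- rle(as.vector(fit) != 0)
  nz_start <- cumsum(c(1, runs$lengths))[which(runs$values)][1]
  nz_end <- nz_start + runs$lengths[which(runs$values)][1]
  expect_lte(abs(nz_start - 201), 3)
  expect_lte(abs(nz_end - 301), 3)
  expect_lte(attr(fit, "null_rate"), 0.01)
  # errors
  expect_error(segment_track(probe_track("s", "c", 1, 0)), "2 probes")
  expect_error(segment_track(rep(NA_real_, 5)), "missing")
})

test_that("segmentation is deterministic under a fixed permutation seed", {
  set.seed(1)
  y <- rnorm(300, sd = 0.15)
  tr <- probe_track("s", "c", 1:300, y)
  f1 <- segment_track(tr, perm_seed = 4)
  f2 <- segment_track(tr, perm_seed = 4)
  expect_identical(f1, f2)
})

test_that("copy-number smoothing applies the amplitude/length rules", {
  # 30 probes at 0.5 (below high-level amplitude): rejected
  sim <- make_probe_tracks(n_probes = 300, noise_sd = 0.15,
                           cnas = data.frame(chrom = "cnv1", start_probe = 200,
                                             length = 30, mean_log2 = 0.5),
                           seed = 3)
  tr <- sim$tracks[[1]]
  segs <- copy_number_smooth(segment_track(tr, perm_seed = 3), tr)
  expect_equal(nrow(segs), 0)
  # 12 probes at 1.4: accepted as high-level
  sim <- make_probe_tracks(n_probes = 300, noise_sd = 0.15,
                           cnas = data.frame(chrom = "cnv1", start_probe = 50,
                                             length = 12, mean_log2 = 1.4),
                           seed = 3)
  tr <- sim$tracks[[1]]
  segs <- copy_number_smooth(segment_track(tr, perm_seed = 3), tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$level, "high")
  expect_equal(segs$sign, "gain")
  expect_lte(abs(segs$start_probe - 50), 2)
  expect_lte(abs(segs$end_probe - 62), 2)
})

test_that("noiseless step yields exact boundaries and mean", {
  y <- c(rep(0, 100), rep(0.8, 120), rep(0, 100))
  tr <- probe_track("s", "c", seq_along(y) * 1000, y)
  segs <- copy_number_smooth(tv_denoise(y, 0), tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_probe, 100)
  expect_equal(segs$end_probe, 220)
  expect_equal(segs$mean_log2, 0.8)
  expect_equal(segs$n_probes, 120)
})

test_that("emitted segments always satisfy their level invariants", {
  set.seed(31)
  for (rep in 1:10) {
    sim <- make_probe_tracks(
      n_probes = 400, noise_sd = 0.15,
      cnas = data.frame(chrom = "cnv1", start_probe = c(40, 250),
                        length = c(80, 15), mean_log2 = c(-0.6, 1.8)),
      seed = 100 + rep)
    tr <- sim$tracks[[1]]
    segs <- copy_number_smooth(segment_track(tr, perm_seed = rep), tr)
    if (!nrow(segs)) next
    expect_false(is.unsorted(segs$start_probe))
    expect_true(all(segs$end_probe[-nrow(segs)] <= segs$start_probe[-1]))
    std <- segs$level == "standard"
    expect_true(all(segs$n_probes[std] >= 50))
    expect_true(all(abs(segs$mean_log2[std]) >= 0.3))
    expect_true(all(segs$n_probes[!std] >= 10))
    expect_true(all(abs(segs$mean_log2[!std]) >= 1.0))
    expect_true(all((segs$mean_log2 > 0) == (segs$sign == "gain")))
  }
})

test_that("raising theta never increases the number of segments", {
  set.seed(17)
  sim <- make_probe_tracks(
    n_probes = 500, noise_sd = 0.15,
    cnas = data.frame(chrom = "cnv1", start_probe = c(50, 300),
                      length = c(100, 60), mean_log2 = c(0.35, 0.9)),
    seed = 17)
  tr <- sim$tracks[[1]]
  fit <- segment_track(tr, perm_seed = 17)
  last <- Inf
  for (theta in c(0.2, 0.3, 0.5, 0.8)) {
    n <- nrow(copy_number_smooth(fit, tr, theta = theta))
    expect_lte(n, last)
    last <- n
  }
})

test_that("intragenic boundaries are called with transcript-aware sides", {
  models <- list(
    # plus-strand gene spanning 10000-60000ish
    gp = mk_gene("gp", rep(5000, 5), intron = 6000, start = 10000),
    gm = mk_gene("gm", rep(5000, 5), intron = 6000, start = 200000,
                 strand = "-"))
  segs <- data.frame(sample_id = "s", chrom = "toy",
                     start_probe = 0L, end_probe = 100L,
                     start_pos = 20000, end_pos = 150000,
                     n_probes = 100L, mean_log2 = 0.9, level = "standard",
                     sign = "gain", stringsAsFactors = FALSE)
  class(segs) <- c("cna_segments", "data.frame")
  bp <- call_intragenic_breakpoints(segs, models)
  # start boundary falls inside gp: altered flank is genomically right,
  # which on a plus-strand gene holds the 3' end
  expect_equal(nrow(bp), 1)
  expect_equal(bp$gene_id, "gp")
  expect_equal(bp$boundary_side, "lower_3prime")
  expect_equal(bp$transition, "gain_starts")
  expect_true(bp$focal)
  # same geometry hitting the minus-strand gene: right flank is the 5' end
  segs$start_pos <- 210000; segs$end_pos <- 400000
  bp <- call_intragenic_breakpoints(segs, models)
  expect_equal(bp$gene_id, "gm")
  expect_equal(bp$boundary_side, "upper_5prime")
  # segment fully containing a gene emits nothing
  segs$start_pos <- 1000; segs$end_pos <- 500000
  expect_equal(nrow(call_intragenic_breakpoints(segs, models)), 0)
})

test_that("census direction filter mirrors known fusion-role geometry", {
  mk_call <- function(gene, side, sign) {
    df <- data.frame(gene_id = gene, sample_id = "s", chrom = "c",
                     boundary_pos = 1, boundary_side = side,
                     transition = paste0(sign, "_starts"), sign = sign,
                     focal = TRUE, seg_start = 0, seg_end = 2,
                     n_probes = 60L, mean_log2 = ifelse(sign == "gain", 1, -1),
                     level = "standard", stringsAsFactors = FALSE)
    class(df) <- c("cna_breakpoints", "data.frame")
    df
  }
  cen <- census_list(c("abl_like", "bcr_like", "any"),
                     c("three_prime", "five_prime", "either"))
  # amplification of the 3' end of a 3' partner: retained
  expect_equal(nrow(census_direction_filter(
    mk_call("abl_like", "lower_3prime", "gain"), cen)), 1)
  # amplification of its 5' end: removed
  expect_equal(nrow(census_direction_filter(
    mk_call("abl_like", "upper_5prime", "gain"), cen)), 0)
  # deletion of its 5' end: retained
  expect_equal(nrow(census_direction_filter(
    mk_call("abl_like", "upper_5prime", "loss"), cen)), 1)
  # five_prime role is the mirror image
  expect_equal(nrow(census_direction_filter(
    mk_call("bcr_like", "upper_5prime", "gain"), cen)), 1)
  expect_equal(nrow(census_direction_filter(
    mk_call("bcr_like", "lower_3prime", "gain"), cen)), 0)
  # either role passes any orientation
  for (side in c("upper_5prime", "lower_3prime"))
    for (sgn in c("gain", "loss"))
      expect_equal(nrow(census_direction_filter(mk_call("any", side, sgn),
                                                cen)), 1)
})
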