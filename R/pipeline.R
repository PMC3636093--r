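#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; fields mirror the arguments validated by
#'   [validate_run_config()].
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and input-path existence. Defaults: `alpha`
#' 0.05, `min_group` 2, `fdr` 0.01, `theta` 0.3, `min_len` 50,
#' `high_theta` 1.0, `high_min_len` 10, `insert_range` c(100, 400),
#' `min_support` 2, `seed` 1.
#'
#' @param cfg named list; must provide `models` and at least one of
#'   `expression_matrix` / `copy_number_tracks`; optional `census`,
#'   `reads_sam`, `transcripts`, `anchors`, `out_dir`, `center_expression`.
#' @return the config with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(alpha = 0.05, min_group = 2L, fdr = 0.01, theta = 0.3,
                   min_len = 50L, high_theta = 1.0, high_min_len = 10L,
                   insert_range = c(100, 400), min_support = 2L, seed = 1L,
                   center_expression = FALSE, out_dir = "breakscan_out")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (is.null(cfg$models)) stop("config must name a gene models file")
  if (is.null(cfg$expression_matrix) && is.null(cfg$copy_number_tracks))
    stop("config must provide expression and/or copy-number input")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(cfg$fdr > 0 && cfg$fdr < 1)) stop("fdr must be in (0, 1)")
  if (cfg$theta <= 0 || cfg$high_theta < cfg$theta)
    stop("need 0 < theta <= high_theta")
  if (cfg$min_len < 1 || cfg$high_min_len < 1 ||
      cfg$high_min_len > cfg$min_len)
    stop("need 1 <= high_min_len <= min_len")
  if (length(cfg$insert_range) != 2L ||
      cfg$insert_range[1L] >= cfg$insert_range[2L])
    stop("insert_range must be c(lo, hi) with lo < hi")
  if (cfg$min_support < 1) stop("min_support must be >= 1")
  for (f in c("models", "expression_matrix", "copy_number_tracks", "census",
              "reads_sam", "transcripts")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path does not exist: ", f, " = ", cfg[[f]])
  }
  if (!is.null(cfg$census_filter) && isTRUE(cfg$census_filter) &&
      is.null(cfg$census))
    stop("census filtering enabled but no census file given")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg[order(names(cfg))], file = f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the combined breakpoint-analysis workflow
#'
#' Wires the stages together: expression breakpoint calling (when an exon
#' matrix is configured) and copy-number breakpoint calling (when probe
#' tracks are configured), each followed by the census/direction filters;
#' a merged candidate table flagging gene/sample hits found by both arms;
#' and, when paired-end alignments plus transcript sequences are
#' configured, fusion-partner nomination seeded by each candidate (or
#' explicitly configured) anchor gene. Per-stage TSVs, a SEG file and a run
#' log are written under `out_dir`; every report carries a provenance
#' header (config hash, package version, seed), and re-running with an
#' identical config produces byte-identical outputs.
#'
#' @param config a config list or YAML path (see [validate_run_config()]).
#' @return invisibly, a list with the stage tables and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(sprintf("breakscan %s",
                    as.character(utils::packageVersion("breakscan"))),
            sprintf("config_hash %s", config_hash(cfg)),
            sprintf("seed %d", as.integer(cfg$seed)))
  log_lines <- prov
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }
  models <- read_gene_models(cfg$models)
  census <- if (!is.null(cfg$census)) read_census(cfg$census) else NULL
  out <- list(paths = character())
  rba <- NULL; dba <- NULL
  if (!is.null(cfg$expression_matrix)) {
    profiles <- read_exon_matrix(cfg$expression_matrix, models,
                                 center = isTRUE(cfg$center_expression))
    rba <- call_expression_breakpoints(profiles, census, alpha = cfg$alpha,
                                       min_group = cfg$min_group)
    say("rba: %d raw expression breakpoint call(s)", nrow(rba))
    rba <- direction_filter(rba, census)
    say("rba: %d call(s) after direction filter", nrow(rba))
    p <- file.path(cfg$out_dir, "rba_calls.tsv")
    write_tsv(as.data.frame(rba), p, prov)
    out$paths <- c(out$paths, p)
  }
  if (!is.null(cfg$copy_number_tracks)) {
    tracks <- read_probe_track(cfg$copy_number_tracks)
    seg_all <- list(); bp_all <- list()
    for (s in names(tracks)) for (ch in names(tracks[[s]])) {
      tr <- tracks[[s]][[ch]]
      fit <- segment_track(tr, fdr = cfg$fdr,
                           perm_seed = as.integer(cfg$seed))
      segs <- copy_number_smooth(fit, tr, theta = cfg$theta,
                                 min_len = cfg$min_len,
                                 high_theta = cfg$high_theta,
                                 high_min_len = cfg$high_min_len)
      if (nrow(segs)) seg_all[[paste(s, ch)]] <- segs
      bps <- call_intragenic_breakpoints(segs, models)
      if (nrow(bps)) bp_all[[paste(s, ch)]] <- bps
    }
    segs <- if (length(seg_all)) do.call(rbind, seg_all) else
      copy_number_smooth(numeric(2), probe_track("none", "none", 1:2, c(0, 0)))
    dba <- if (length(bp_all)) do.call(rbind, bp_all) else
      call_intragenic_breakpoints(segs[0, ], models)
    say("dba: %d segment(s), %d intragenic breakpoint(s)",
        nrow(segs), nrow(dba))
    dba <- census_direction_filter(dba, census)
    say("dba: %d breakpoint(s) after census/direction filter", nrow(dba))
    p1 <- file.path(cfg$out_dir, "segments.seg")
    if (nrow(segs)) write_segments(segs, p1) else write_tsv(segs, p1)
    p2 <- file.path(cfg$out_dir, "dba_breakpoints.tsv")
    write_tsv(as.data.frame(dba), p2, prov)
    out$paths <- c(out$paths, p1, p2)
  }
  # merged candidate table across arms
  key <- function(df) if (is.null(df) || !nrow(df)) character()
                      else paste(df$gene_id, df$sample_id, sep = "\t")
  kr <- unique(key(rba)); kd <- unique(key(dba))
  all_k <- union(kr, kd)
  merged <- if (length(all_k)) {
    parts <- do.call(rbind, strsplit(all_k, "\t"))
    data.frame(gene_id = parts[, 1L], sample_id = parts[, 2L],
               source = ifelse(all_k %in% kr & all_k %in% kd, "both",
                               ifelse(all_k %in% kr, "rba", "dba")),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), sample_id = character(),
                    source = character(), stringsAsFactors = FALSE)
  merged <- merged[order(merged$gene_id, merged$sample_id), , drop = FALSE]
  say("merged: %d candidate gene/sample pair(s), %d supported by both arms",
      nrow(merged), sum(merged$source == "both"))
  pm <- file.path(cfg$out_dir, "merged_candidates.tsv")
  write_tsv(merged, pm, prov)
  out$paths <- c(out$paths, pm)
  fus <- NULL
  if (!is.null(cfg$reads_sam) && !is.null(cfg$transcripts)) {
    anchors <- cfg$anchors %||% unique(merged$gene_id)
    anchors <- intersect(anchors, names(models))
    fus_rows <- list()
    for (a in anchors) {
      fc <- fusion_scan(cfg$reads_sam, a, models, cfg$transcripts,
                        min_support = cfg$min_support,
                        insert_range = cfg$insert_range)
      if (nrow(fc)) fus_rows[[a]] <- cbind(anchor = a, as.data.frame(fc))
    }
    fus <- if (length(fus_rows)) do.call(rbind, fus_rows)
           else data.frame(anchor = character())
    say("fusion: %d candidate(s) across %d anchor gene(s)",
        nrow(fus), length(anchors))
    pf <- file.path(cfg$out_dir, "fusion_candidates.tsv")
    write_tsv(fus, pf, prov)
    out$paths <- c(out$paths, pf)
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  out$rba <- rba; out$dba <- dba; out$merged <- merged; out$fusions <- fus
  invisible(out)
}
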