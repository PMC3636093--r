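#' Read an exon-level expression matrix
#'
#' Input is a TSV with columns `gene_id`, `exon` (1-based exon index in
#' transcript order) and one column per sample holding log2 expression. Each
#' gene's rows are validated against its gene model: a gene absent from
#' `gene_models` is dropped with a warning, while an exon-count mismatch for a
#' known gene is a hard error (it means the matrix and the annotation
#' disagree, which would silently shift every junction index).
#'
#' With `center = TRUE` each exon row is mean-centered across the sample set,
#' mirroring how exon-array log2 ratios are usually referenced to the cohort
#' before breakpoint scanning.
#'
#' @param path TSV file.
#' @param gene_models named list of [gene_model()] objects.
#' @param center logical; mean-center each exon row across samples.
#' @return an `exon_profiles` object: a named list of numeric matrices
#'   (exon x sample), one per gene, in transcript exon order.
#' @export
read_exon_matrix <- function(path, gene_models, center = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "exon") %in% names(df)))
    stop("exon matrix needs 'gene_id' and 'exon' columns")
  samples <- setdiff(names(df), c("gene_id", "exon"))
  if (!length(samples)) stop("exon matrix has no sample columns")
  known <- df$gene_id %in% names(gene_models)
  n_drop <- length(unique(df$gene_id[!known]))
  if (n_drop > 0L) {
    warning(sprintf("dropping %d gene(s) absent from gene models", n_drop))
    df <- df[known, , drop = FALSE]
  }
  mats <- lapply(split(df, df$gene_id), function(sub) {
    gid <- sub$gene_id[1L]
    n_exp <- nrow(gene_models[[gid]]$exons)
    if (nrow(sub) != n_exp)
      stop(sprintf("gene '%s': %d exon rows but model has %d exons",
                   gid, nrow(sub), n_exp))
    sub <- sub[order(sub$exon), , drop = FALSE]
    m <- as.matrix(sub[, samples, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- sub$exon
    m
  })
  # keep gene-model order where possible
  ord <- intersect(names(gene_models), names(mats))
  mats <- mats[ord]
  if (center) mats <- lapply(mats, function(m) m - rowMeans(m, na.rm = TRUE))
  exon_profiles(mats)
}

#' Construct an exon-profiles container
#'
#' @param mats named list of exon x sample numeric matrices.
#' @return object of class `exon_profiles`.
#' @export
exon_profiles <- function(mats) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  structure(mats, class = "exon_profiles")
}

#' @export
print.exon_profiles <- function(x, ...) {
  ns <- if (length(x)) ncol(x[[1L]]) else 0L
  cat(sprintf("<exon_profiles> %d gene(s) x %d sample(s); %d-%d exons/gene\n",
              length(x), ns,
              if (length(x)) min(vapply(x, nrow, 1L)) else 0L,
              if (length(x)) max(vapply(x, nrow, 1L)) else 0L))
  invisible(x)
}

#' Extract one exon profile
#'
#' @param profiles an `exon_profiles` object.
#' @param gene_id,sample_id identifiers.
#' @return numeric vector of log2 values in transcript exon order.
#' @export
exon_profile <- function(profiles, gene_id, sample_id) {
  m <- profiles[[gene_id]]
  if (is.null(m)) stop("unknown gene: ", gene_id)
  m[, sample_id]
}

#' One probe-level copy-number track
#'
#' @param sample_id,chrom identifiers.
#' @param positions strictly increasing genomic coordinates.
#' @param ratios log2 copy-number ratios, same length.
#' @return object of class `probe_track`.
#' @export
probe_track <- function(sample_id, chrom, positions, ratios) {
  stopifnot(length(positions) == length(ratios))
  if (is.unsorted(positions, strictly = TRUE))
    stop("probe positions must be strictly increasing")
  structure(list(sample_id = sample_id, chrom = as.character(chrom),
                 positions = as.numeric(positions),
                 ratios = as.numeric(ratios)),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("<probe_track> %s %s: %d probes, %g-%g, mean log2 %.3f\n",
              x$sample_id, x$chrom, length(x$positions),
              min(x$positions), max(x$positions), mean(x$ratios)))
  invisible(x)
}

#' Read probe-level copy-number tracks
#'
#' TSV with columns `chrom`, `position`, then one log2-ratio column per
#' sample. Rows are grouped by chromosome and sorted by position (with a
#' warning if the input was unsorted); duplicated positions keep the first
#' occurrence with a warning.
#'
#' @param path TSV file.
#' @return nested named list: `tracks[[sample]][[chrom]]` is a
#'   [probe_track()].
#' @export
read_probe_track <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "position") %in% names(df)))
    stop("probe track needs 'chrom' and 'position' columns")
  samples <- setdiff(names(df), c("chrom", "position"))
  if (!length(samples)) stop("probe track has no sample columns")
  out <- list()
  for (s in samples) out[[s]] <- list()
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    if (is.unsorted(sub$position)) {
      warning(sprintf("chromosome %s: unsorted positions, sorting", chrom))
      sub <- sub[order(sub$position), , drop = FALSE]
    }
    dup <- duplicated(sub$position)
    if (any(dup)) {
      warning(sprintf("chromosome %s: %d duplicate position(s), keeping first",
                      chrom, sum(dup)))
      sub <- sub[!dup, , drop = FALSE]
    }
    for (s in samples)
      out[[s]][[chrom]] <- probe_track(s, chrom, sub$position, sub[[s]])
  }
  out
}

.census_roles <- c("five_prime", "three_prime", "either")

#' Construct a census table in code
#'
#' @param gene_id character vector of unique gene ids.
#' @param fusion_role `five_prime`, `three_prime` or `either`, recycled.
#' @param notes optional free text.
#' @return data.frame of class `census_list`.
#' @export
census_list <- function(gene_id, fusion_role = "either", notes = "") {
  df <- data.frame(gene_id = as.character(gene_id),
                   fusion_role = rep_len(fusion_role, length(gene_id)),
                   notes = rep_len(notes, length(gene_id)),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$fusion_role), .census_roles)
  if (length(bad)) stop("unknown fusion_role token(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicated census gene ids")
  structure(df, class = c("census_list", "data.frame"))
}

#' Read a cancer-gene list with fusion-role annotations
#'
#' TSV with columns `gene_id` and `fusion_role` (one of `five_prime`,
#' `three_prime`, `either`), plus an optional free-text `notes` column. The
#' role records which side of known oncogenic fusions the gene contributes
#' (e.g. a kinase that is always the 3' partner), and drives the directional
#' filters in both the expression and copy-number arms. Exclusion filtering
#' (fragile sites, passenger partners) is assumed done upstream of this file.
#'
#' @param path TSV file.
#' @return data.frame of class `census_list` with columns `gene_id`,
#'   `fusion_role`, `notes`.
#' @export
read_census <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L)
    return(structure(data.frame(gene_id = character(), fusion_role = character(),
                                notes = character(), stringsAsFactors = FALSE),
                     class = c("census_list", "data.frame")))
  if (!all(c("gene_id", "fusion_role") %in% names(df)))
    stop("census file needs 'gene_id' and 'fusion_role' columns")
  bad <- setdiff(unique(df$fusion_role), .census_roles)
  if (length(bad))
    stop("unknown fusion_role token(s): ", paste(bad, collapse = ", "))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicated census gene(s): ", paste(dup, collapse = ", "))
  if (is.null(df$notes)) df$notes <- ""
  structure(df[, c("gene_id", "fusion_role", "notes")],
            class = c("census_list", "data.frame"))
}

.check_segment_frame <- function(segments) {
  need <- c("sample_id", "chrom", "start_pos", "end_pos", "n_probes",
            "mean_log2")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  segments
}

#' Write copy-number segments in SEG format
#'
#' On-disk SEG uses 1-based inclusive coordinates; internal segments are
#' 0-based half-open, so `start` is written as `start_pos + 1` and `end` as
#' `end_pos`. Overlapping segments within one sample/chromosome are an error.
#'
#' @param segments a data.frame of segments (see [copy_number_smooth()]).
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  segments <- .check_segment_frame(segments)
  for (key in split(segments,
                    paste(segments$sample_id, segments$chrom, sep = "\r"))) {
    key <- key[order(key$start_pos), , drop = FALSE]
    if (nrow(key) > 1L &&
        any(key$start_pos[-1L] < key$end_pos[-nrow(key)]))
      stop("overlapping segments for sample ", key$sample_id[1L],
           " chromosome ", key$chrom[1L])
  }
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start_pos + 1, end = segments$end_pos,
                    num_probes = segments$n_probes,
                    mean_log2 = segments$mean_log2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file back into internal coordinates
#'
#' @param path SEG file written by [write_segments()].
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample_id = as.character(df$sample), chrom = as.character(df$chrom),
             start_pos = df$start - 1, end_pos = df$end,
             n_probes = df$num_probes, mean_log2 = df$mean_log2,
             stringsAsFactors = FALSE)
}
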