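#' Gene model with exon (and optional CDS) structure
#'
#' A `gene_model` holds one transcript's exon structure. Coordinates are
#' internal convention: 0-based, half-open `[start, end)`. Exons are stored in
#' *transcript* order (5' to 3' along the strand), so on the minus strand the
#' first exon is the genomically right-most one. This is what makes
#' "proximal/distal" in the expression breakpoint scan mean 5'/3' of the
#' transcript, and what orients the copy-number direction filter.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end), 0-based half-open,
#'   in transcript order; non-overlapping.
#' @param cds optional two-column matrix of coding intervals, each contained
#'   in an exon, transcript order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L || any(exons[, 2L] <= exons[, 1L]))
    stop("gene_model '", gene_id, "': exons must be non-empty with end > start")
  # transcript order: ascending genomic start on +, descending on -
  ord_ok <- if (strand == "+") !is.unsorted(exons[, 1L], strictly = TRUE)
            else !is.unsorted(rev(exons[, 1L]), strictly = TRUE)
  if (!ord_ok)
    stop("gene_model '", gene_id, "': exons not in transcript order")
  gstart <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(gstart) > 1L && any(gstart[-1L, 1L] < gstart[-nrow(gstart), 2L]))
    stop("gene_model '", gene_id, "': overlapping exons")
  if (!is.null(cds)) {
    cds <- matrix(as.numeric(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1L))
    if (!all(inside))
      stop("gene_model '", gene_id, "': CDS interval outside exons")
  }
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, exons = exons, cds = cds,
                 tx_length = sum(exons[, 2L] - exons[, 1L])),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s), tx %d nt%s\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, nrow(x$exons), x$tx_length,
              if (is.null(x$cds)) "" else ", CDS annotated"))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param gm a [gene_model()].
#' @return numeric `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gm) {
  c(min(gm$exons[, 1L]), max(gm$exons[, 2L]))
}

#' Transcript-coordinate bounds of each exon
#'
#' @param gm a [gene_model()].
#' @return two-column matrix (tx_start, tx_end), 0-based half-open, one row
#'   per exon in transcript order.
#' @export
exon_tx_bounds <- function(gm) {
  len <- gm$exons[, 2L] - gm$exons[, 1L]
  end <- cumsum(len)
  cbind(tx_start = end - len, tx_end = end)
}

#' Map genomic positions to transcript coordinates
#'
#' Positions are 0-based coordinates of a base; intronic/intergenic positions
#' map to `NA`.
#'
#' @param gm a [gene_model()].
#' @param pos numeric vector of genomic base positions.
#' @return numeric vector of 0-based transcript coordinates.
#' @export
genomic_to_tx <- function(gm, pos) {
  tb <- exon_tx_bounds(gm)
  out <- rep(NA_real_, length(pos))
  for (k in seq_len(nrow(gm$exons))) {
    s <- gm$exons[k, 1L]; e <- gm$exons[k, 2L]
    hit <- !is.na(pos) & pos >= s & pos < e
    if (!any(hit)) next
    out[hit] <- if (gm$strand == "+") tb[k, 1L] + (pos[hit] - s)
                else tb[k, 1L] + (e - 1 - pos[hit])
  }
  out
}

#' Map transcript coordinates to genomic positions
#'
#' @param gm a [gene_model()].
#' @param txpos numeric vector of 0-based transcript coordinates.
#' @return numeric vector of 0-based genomic base positions (`NA` out of range).
#' @export
tx_to_genomic <- function(gm, txpos) {
  tb <- exon_tx_bounds(gm)
  out <- rep(NA_real_, length(txpos))
  for (k in seq_len(nrow(gm$exons))) {
    hit <- !is.na(txpos) & txpos >= tb[k, 1L] & txpos < tb[k, 2L]
    if (!any(hit)) next
    off <- txpos[hit] - tb[k, 1L]
    out[hit] <- if (gm$strand == "+") gm$exons[k, 1L] + off
                else gm$exons[k, 2L] - 1 - off
  }
  out
}

#' Transcript-coordinate range of the coding sequence
#'
#' @param gm a [gene_model()].
#' @return `c(start, end)` in 0-based half-open transcript coordinates, or
#'   `NULL` when the model carries no CDS.
#' @export
cds_tx_range <- function(gm) {
  if (is.null(gm$cds) || nrow(gm$cds) == 0L) return(NULL)
  # map first and last coding base of every interval through the exon frame
  firsts <- genomic_to_tx(gm, gm$cds[, 1L])
  lasts  <- genomic_to_tx(gm, gm$cds[, 2L] - 1)
  c(min(c(firsts, lasts)), max(c(firsts, lasts)) + 1)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 models need `exon` (and optionally `CDS`) features carrying a
#' `gene_id` attribute (falling back to `Parent` then `ID`). BED12 blocks
#' become exons and the thick range, when narrower than the whole entry,
#' becomes the CDS. On-disk GFF3 is 1-based inclusive and BED 0-based
#' half-open; both are converted to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed")) "bed" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    gid <- as.character(meta$gene_id %||% NA)
    if (all(is.na(gid)) && !is.null(meta$Parent))
      gid <- vapply(meta$Parent, function(p) as.character(p)[1L], character(1L))
    if (all(is.na(gid)) && !is.null(meta$ID)) gid <- as.character(meta$ID)
    if (anyNA(gid)) stop("GFF3 records without a gene_id/Parent/ID attribute")
    type <- as.character(meta$type)
    keep <- type %in% c("exon", "CDS")
    gr <- gr[keep]; gid <- gid[keep]; type <- type[keep]
    models <- lapply(split(seq_along(gr), gid), function(ii) {
      sub <- gr[ii]; ty <- type[ii]
      strand <- as.character(BiocGenerics::strand(sub))[1L]
      build <- function(g) {
        m <- cbind(BiocGenerics::start(g) - 1L, BiocGenerics::end(g))
        m[order(m[, 1L], decreasing = strand == "-"), , drop = FALSE]
      }
      ex <- build(sub[ty == "exon"])
      cds <- if (any(ty == "CDS")) build(sub[ty == "CDS"]) else NULL
      gene_model(gid[ii][1L], as.character(GenomicRanges::seqnames(sub))[1L],
                 strand, ex, cds)
    })
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    models <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      strand <- as.character(BiocGenerics::strand(g))
      if (!strand %in% c("+", "-")) strand <- "+"
      blocks <- S4Vectors::mcols(g)$blocks
      ex <- if (!is.null(blocks)) {
        b <- blocks[[1L]]  # block starts relative to entry start, 1-based
        cbind(BiocGenerics::start(g) - 1L + BiocGenerics::start(b) - 1L,
              BiocGenerics::start(g) - 1L + BiocGenerics::end(b))
      } else cbind(BiocGenerics::start(g) - 1L, BiocGenerics::end(g))
      ex <- ex[order(ex[, 1L], decreasing = strand == "-"), , drop = FALSE]
      thick <- S4Vectors::mcols(g)$thick
      cds <- NULL
      if (!is.null(thick) && length(thick) == 1L) {
        ts <- BiocGenerics::start(thick) - 1L; te <- BiocGenerics::end(thick)
        if (te > ts && !(ts == min(ex[, 1L]) && te == max(ex[, 2L]))) {
          ov <- ex[pmax(ex[, 1L], ts) < pmin(ex[, 2L], te), , drop = FALSE]
          if (nrow(ov)) cds <- cbind(pmax(ov[, 1L], ts), pmin(ov[, 2L], te))
        }
      }
      gene_model(S4Vectors::mcols(g)$name %||% paste0("bed_", i),
                 as.character(GenomicRanges::seqnames(g)), strand, ex, cds)
    })
    names(models) <- vapply(models, `[[`, character(1L), "gene_id")
  }
  models
}

#' Write gene models as GFF3
#'
#' @param models named list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(gm) {
    ex <- gm$exons[order(gm$exons[, 1L]), , drop = FALSE]
    recs <- data.frame(chrom = gm$chrom, start = ex[, 1L] + 1L, end = ex[, 2L],
                       strand = gm$strand, type = "exon",
                       gene_id = gm$gene_id, stringsAsFactors = FALSE)
    recs$phase <- NA_integer_
    if (!is.null(gm$cds)) {
      # CDS phase: codon offset at each interval start, in transcript order
      lens <- gm$cds[, 2L] - gm$cds[, 1L]
      phase <- (3L - cumsum(c(0, lens[-length(lens)])) %% 3L) %% 3L
      cds_rec <- data.frame(chrom = gm$chrom, start = gm$cds[, 1L] + 1L,
                            end = gm$cds[, 2L], strand = gm$strand,
                            type = "CDS", gene_id = gm$gene_id,
                            phase = phase, stringsAsFactors = FALSE)
      recs <- rbind(recs, cds_rec[order(cds_rec$start), , drop = FALSE])
    }
    recs
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$source <- "breakscan"
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
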