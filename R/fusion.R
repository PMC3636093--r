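#' Read paired-end alignments into mate pairs
#'
#' Reads SAM or BAM via Rsamtools and assembles records into one row per
#' mate pair (read 1 / read 2 by the pairing flags). Internally coordinates
#' are 0-based half-open. Records with malformed pairing (qnames without
#' exactly one first-of-pair and one second-of-pair record) are skipped and
#' counted in `attr(, "skipped_records")`. When an NM tag is present, mapped
#' reads with more than `max_nm` mismatches are demoted to unmapped (keeping
#' their sequence), mirroring an aligner that only reports placements with
#' at most that many mismatches.
#'
#' @param path SAM or BAM file.
#' @param max_nm mismatch cap applied via the NM tag when present.
#' @return data.frame of class `mate_pairs`, one row per pair with
#'   `chrom/start/end/strand/mapped/seq` for each read.
#' @export
read_sam_pairs <- function(path, max_nm = 2L) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  flag <- res$flag
  seqs <- as.character(res$seq)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  mapped <- bitwAnd(flag, 0x4L) == 0L
  mapped[mapped & !is.na(nm) & nm > max_nm] <- FALSE
  first <- bitwAnd(flag, 0x40L) > 0L
  second <- bitwAnd(flag, 0x80L) > 0L
  df <- data.frame(qname = res$qname, first = first, second = second,
                   chrom = as.character(res$rname), pos = res$pos - 1L,
                   qwidth = ifelse(is.na(res$qwidth), nchar(seqs), res$qwidth),
                   strand = ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
                   mapped = mapped, seq = seqs, stringsAsFactors = FALSE)
  ok_rec <- df$first != df$second
  skipped <- sum(!ok_rec)
  df <- df[ok_rec, , drop = FALSE]
  counts <- table(df$qname)
  good <- names(counts)[counts == 2L]
  bad_q <- setdiff(unique(df$qname), good)
  skipped <- skipped + sum(df$qname %in% bad_q)
  df <- df[df$qname %in% good, , drop = FALSE]
  d1 <- df[df$first, , drop = FALSE]
  d2 <- df[df$second, , drop = FALSE]
  d1 <- d1[!duplicated(d1$qname), , drop = FALSE]
  d2 <- d2[!duplicated(d2$qname), , drop = FALSE]
  d2 <- d2[match(d1$qname, d2$qname), , drop = FALSE]
  out <- data.frame(
    qname = d1$qname,
    chrom1 = d1$chrom, start1 = d1$pos, end1 = d1$pos + d1$qwidth,
    strand1 = d1$strand, mapped1 = d1$mapped, seq1 = d1$seq,
    chrom2 = d2$chrom, start2 = d2$pos, end2 = d2$pos + d2$qwidth,
    strand2 = d2$strand, mapped2 = d2$mapped, seq2 = d2$seq,
    stringsAsFactors = FALSE)
  attr(out, "skipped_records") <- skipped
  class(out) <- c("mate_pairs", "data.frame")
  out
}

reads_overlap <- function(gm, chrom, start, end, exons_only = TRUE) {
  hit <- logical(length(start))
  sel <- !is.na(chrom) & chrom == gm$chrom & !is.na(start)
  if (!any(sel)) return(hit)
  iv <- if (exons_only) gm$exons else matrix(gene_span(gm), ncol = 2L)
  for (k in seq_len(nrow(iv)))
    hit[sel] <- hit[sel] | (start[sel] < iv[k, 2L] & end[sel] > iv[k, 1L])
  hit
}

#' Extract mate pairs anchored in a candidate gene
#'
#' Keeps pairs with exactly one read overlapping the anchor gene's exons
#' while the mate maps to a different genomic locus (anywhere outside the
#' anchor gene's span) or is unmapped; unmapped mates are tagged for
#' chimeric junction-read rescue. Pairs with both reads inside the anchor
#' are ordinary concordant fragments and are excluded.
#'
#' @param pairs a `mate_pairs` data.frame from [read_sam_pairs()].
#' @param anchor the anchor [gene_model()].
#' @return data.frame of class `anchored_pairs` with the anchor read in the
#'   `anchor_*` columns, the mate in `partner_*`, and a `rescue` flag for
#'   unmapped mates.
#' @export
extract_anchored_pairs <- function(pairs, anchor) {
  a1 <- pairs$mapped1 & reads_overlap(anchor, pairs$chrom1, pairs$start1,
                                      pairs$end1)
  a2 <- pairs$mapped2 & reads_overlap(anchor, pairs$chrom2, pairs$start2,
                                      pairs$end2)
  span1 <- pairs$mapped1 & reads_overlap(anchor, pairs$chrom1, pairs$start1,
                                         pairs$end1, exons_only = FALSE)
  span2 <- pairs$mapped2 & reads_overlap(anchor, pairs$chrom2, pairs$start2,
                                         pairs$end2, exons_only = FALSE)
  keep1 <- a1 & !span2   # read1 anchored, mate off-anchor or unmapped
  keep2 <- a2 & !span1
  pick <- function(df, suffix_anchor, suffix_partner) {
    data.frame(
      qname = df$qname,
      anchor_chrom = df[[paste0("chrom", suffix_anchor)]],
      anchor_start = df[[paste0("start", suffix_anchor)]],
      anchor_end = df[[paste0("end", suffix_anchor)]],
      anchor_strand = df[[paste0("strand", suffix_anchor)]],
      anchor_seq = df[[paste0("seq", suffix_anchor)]],
      partner_chrom = df[[paste0("chrom", suffix_partner)]],
      partner_start = df[[paste0("start", suffix_partner)]],
      partner_end = df[[paste0("end", suffix_partner)]],
      partner_strand = df[[paste0("strand", suffix_partner)]],
      partner_mapped = df[[paste0("mapped", suffix_partner)]],
      partner_seq = df[[paste0("seq", suffix_partner)]],
      stringsAsFactors = FALSE)
  }
  out <- rbind(pick(pairs[keep1, , drop = FALSE], "1", "2"),
               pick(pairs[keep2, , drop = FALSE], "2", "1"))
  out$rescue <- !out$partner_mapped
  class(out) <- c("anchored_pairs", "data.frame")
  out
}

#' Nominate fusion-partner loci from anchored mate pairs
#'
#' Groups the mapped mates of anchored pairs by the annotated gene whose
#' span they overlap; a mate overlapping several (overlapping) genes is
#' assigned to each and flagged ambiguous. Mates in unannotated territory
#' are grouped into fixed genomic bins and reported as unannotated loci.
#'
#' @param anchored an `anchored_pairs` data.frame.
#' @param models named list of [gene_model()] objects.
#' @param min_cluster informational minimum cluster size; clusters below it
#'   are reported but fall to the downstream support filter.
#' @param bin_size bin width for unannotated loci, nucleotides.
#' @return list of nominations, each a list with `partner` (gene id or bin
#'   label), `type` (`"gene"` or `"bin"`), `ambiguous`, and `pairs` (the
#'   supporting `anchored_pairs` rows).
#' @export
nominate_partners <- function(anchored, models, min_cluster = 2L,
                              bin_size = 1e5) {
  mapped <- anchored[anchored$partner_mapped, , drop = FALSE]
  noms <- list()
  if (nrow(mapped)) {
    assigned <- rep(FALSE, nrow(mapped))
    hits <- lapply(models, function(gm)
      which(reads_overlap(gm, mapped$partner_chrom, mapped$partner_start,
                          mapped$partner_end, exons_only = FALSE)))
    multi <- tabulate(unlist(hits), nbins = nrow(mapped)) > 1L
    for (gid in names(hits)) {
      ii <- hits[[gid]]
      if (!length(ii)) next
      assigned[ii] <- TRUE
      noms[[length(noms) + 1L]] <- list(partner = gid, type = "gene",
                                        ambiguous = any(multi[ii]),
                                        pairs = mapped[ii, , drop = FALSE])
    }
    inter <- which(!assigned)
    if (length(inter)) {
      bin <- floor(mapped$partner_start[inter] / bin_size)
      lab <- sprintf("%s:%d-%d", mapped$partner_chrom[inter],
                     as.integer(bin * bin_size),
                     as.integer((bin + 1) * bin_size))
      for (b in unique(lab)) {
        ii <- inter[lab == b]
        noms[[length(noms) + 1L]] <- list(partner = b, type = "bin",
                                          ambiguous = FALSE,
                                          pairs = mapped[ii, , drop = FALSE])
      }
    }
  }
  noms
}

# TRUE when two genes are immediately adjacent on the same strand with no
# third annotated gene between them (a likely readthrough pair)
is_readthrough_pair <- function(gidA, gidB, models) {
  gA <- models[[gidA]]; gB <- models[[gidB]]
  if (is.null(gA) || is.null(gB)) return(FALSE)
  if (gA$chrom != gB$chrom || gA$strand != gB$strand) return(FALSE)
  sA <- gene_span(gA); sB <- gene_span(gB)
  gap <- c(min(sA[2L], sB[2L]), max(sA[1L], sB[1L]))
  if (gap[1L] > gap[2L]) return(TRUE)  # overlapping genes: adjacent
  for (gm in models) {
    if (gm$gene_id %in% c(gidA, gidB) || gm$chrom != gA$chrom) next
    sp <- gene_span(gm)
    if (sp[1L] < gap[2L] && sp[2L] > gap[1L]) return(FALSE)
  }
  TRUE
}

#' Filter likely readthrough transcripts
#'
#' Transcription running through the end of a gene into its same-strand
#' neighbour produces chimeric RNA without any genomic rearrangement, so
#' nominated pairs of immediately adjacent, same-strand genes (no
#' intervening annotated gene) are removed. Same-strand genes separated by
#' another gene — e.g. a CEP85L/ROS1-like pair ~1 Mb apart — are not
#' adjacent and survive.
#'
#' @param nominations list from [nominate_partners()].
#' @param anchor_id the anchor gene id.
#' @param models named list of [gene_model()] objects.
#' @return the filtered nomination list.
#' @export
readthrough_filter <- function(nominations, anchor_id, models) {
  Filter(function(nom) {
    if (nom$type != "gene") return(TRUE)
    if (nom$partner == anchor_id) return(FALSE)
    !is_readthrough_pair(anchor_id, nom$partner, models)
  }, nominations)
}

# tx-coordinate interval of a mapped read; NA when an end falls outside
# the gene's exons
read_tx_interval <- function(gm, start0, end0) {
  tx <- genomic_to_tx(gm, c(start0, end0 - 1))
  if (anyNA(tx)) return(c(NA_real_, NA_real_))
  c(min(tx), max(tx) + 1)
}

#' Rescue chimeric junction-spanning reads
#'
#' Attempts to align unmapped reads across candidate fusion junctions. For
#' every ordered exon pair (exon `i` of `gene5`, exon `j` of `gene3`) the
#' junction sequence is built from the last `read length - 1` nt of the
#' gene5 transcript up to the end of exon `i`, joined to the first
#' `read length - 1` nt of the gene3 transcript from the start of exon `j`.
#' Each read (and its reverse complement) is aligned ungapped at every
#' offset that covers at least one nucleotide on both sides of the
#' junction; a hit needs at most `max_mismatches` substitutions. Per read
#' the best (fewest-mismatch) exon pair is reported, ties resolved to the
#' lowest `(i, j)`. Reads longer than the available junction context are
#' evaluated on the truncated context and flagged.
#'
#' @param reads named character vector of unmapped read sequences.
#' @param gene5,gene3 [gene_model()] objects for the 5' and 3' partner.
#' @param tx_seqs named character vector (or `DNAStringSet`) of transcript
#'   sequences, 5'->3'.
#' @param max_mismatches mismatch tolerance.
#' @return data.frame with one row per rescued read: `read`, `exon5`,
#'   `exon3`, `mismatches`, `revcomp`, `truncated`.
#' @export
rescue_chimeric_reads <- function(reads, gene5, gene3, tx_seqs,
                                  max_mismatches = 2L) {
  if (methods::is(tx_seqs, "DNAStringSet"))
    tx_seqs <- setNames(as.character(tx_seqs), names(tx_seqs))
  tx5 <- tx_seqs[[gene5$gene_id]]; tx3 <- tx_seqs[[gene3$gene_id]]
  if (is.null(tx5) || is.null(tx3))
    stop("transcript sequence missing for one of the fusion genes")
  tb5 <- exon_tx_bounds(gene5); tb3 <- exon_tx_bounds(gene3)
  empty <- data.frame(read = character(), exon5 = integer(),
                      exon3 = integer(), mismatches = integer(),
                      revcomp = logical(), truncated = logical(),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  rows <- list()
  for (rn in names(reads)) {
    rl <- nchar(reads[[rn]])
    ctx <- rl - 1L
    variants <- list(
      fwd = Biostrings::DNAString(toupper(reads[[rn]])),
      rev = Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(reads[[rn]]))))
    best <- NULL
    for (i in seq_len(nrow(tb5))) {
      left <- substr(tx5, max(1L, tb5[i, 2L] - ctx + 1L), tb5[i, 2L])
      for (j in seq_len(nrow(tb3))) {
        right <- substr(tx3, tb3[j, 1L] + 1L,
                        min(nchar(tx3), tb3[j, 1L] + ctx))
        jct <- Biostrings::DNAString(paste0(left, right))
        cut <- nchar(left)              # junction point within the context
        truncated <- nchar(left) < ctx || nchar(right) < ctx
        n <- length(jct)
        offs <- seq.int(max(0L, cut - rl + 1L), min(cut - 1L, n - rl))
        if (!length(offs) || offs[1L] > offs[length(offs)]) next
        for (vn in names(variants)) {
          mm <- min(Biostrings::neditStartingAt(variants[[vn]], jct,
                                                starting.at = offs + 1L,
                                                with.indels = FALSE))
          if (mm <= max_mismatches &&
              (is.null(best) || mm < best$mismatches)) {
            best <- list(read = rn, exon5 = i, exon3 = j,
                         mismatches = mm, revcomp = vn == "rev",
                         truncated = truncated)
          }
          if (!is.null(best) && best$mismatches == 0L) break
        }
        if (!is.null(best) && best$mismatches == 0L) break
      }
      if (!is.null(best) && best$mismatches == 0L) break
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- as.data.frame(best)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Predict the reading frame of a fusion junction
#'
#' The junction joins the end of `exon5` of the 5' gene to the start of
#' `exon3` of the 3' gene. The fusion is in frame when the coding length
#' contributed by the 5' gene and the coding offset at which the 3' gene is
#' entered agree modulo 3, so the downstream reading frame is preserved.
#' Junctions falling in a UTR on either side (including a 3' gene entered
#' within its 5'UTR, where translation may restart from an internal start
#' codon) return `"unknown"`.
#'
#' @param gene5,gene3 [gene_model()] objects with CDS annotation.
#' @param exon5 last retained exon of the 5' gene.
#' @param exon3 first retained exon of the 3' gene.
#' @return `"in_frame"`, `"out_of_frame"` or `"unknown"`.
#' @export
predict_frame <- function(gene5, gene3, exon5, exon3) {
  cds5 <- cds_tx_range(gene5); cds3 <- cds_tx_range(gene3)
  if (is.null(cds5) || is.null(cds3)) return("unknown")
  J5 <- exon_tx_bounds(gene5)[exon5, 2L]
  J3 <- exon_tx_bounds(gene3)[exon3, 1L]
  if (J5 <= cds5[1L] || J5 > cds5[2L]) return("unknown")
  if (J3 < cds3[1L] || J3 >= cds3[2L]) return("unknown")
  L5 <- J5 - cds5[1L]
  O3 <- J3 - cds3[1L]
  if ((L5 - O3) %% 3 == 0) "in_frame" else "out_of_frame"
}

# evaluate one nominated partner in a fixed 5'/3' orientation
evaluate_orientation <- function(nom, g5, g3, tx_seqs, rescue_reads,
                                 insert_range, max_mismatches) {
  anchor_is_5 <- nom$anchor_id == g5$gene_id
  chim <- rescue_chimeric_reads(rescue_reads, g5, g3, tx_seqs,
                                max_mismatches)
  tb5 <- exon_tx_bounds(g5); tb3 <- exon_tx_bounds(g3)
  # per-pair tx intervals on each side
  p <- nom$pairs
  iv5 <- t(vapply(seq_len(nrow(p)), function(k) {
    if (anchor_is_5) read_tx_interval(g5, p$anchor_start[k], p$anchor_end[k])
    else read_tx_interval(g5, p$partner_start[k], p$partner_end[k])
  }, numeric(2L)))
  iv3 <- t(vapply(seq_len(nrow(p)), function(k) {
    if (anchor_is_5) read_tx_interval(g3, p$partner_start[k], p$partner_end[k])
    else read_tx_interval(g3, p$anchor_start[k], p$anchor_end[k])
  }, numeric(2L)))
  usable <- !is.na(iv5[, 2L]) & !is.na(iv3[, 1L])
  if (nrow(chim)) {
    # consensus junction across chimeric reads: a read with only a few
    # nucleotides beyond the junction can match several exon pairs, so the
    # modal pair (most reads, then fewest total mismatches, then lowest
    # (i, j)) is taken rather than any single read's best hit
    sp <- split(chim, paste(chim$exon5, chim$exon3, sep = ":"))
    n_r <- vapply(sp, nrow, integer(1L))
    mm <- vapply(sp, function(d) sum(d$mismatches), numeric(1L))
    ii <- vapply(sp, function(d) d$exon5[1L], integer(1L))
    jj <- vapply(sp, function(d) d$exon3[1L], integer(1L))
    k <- order(-n_r, mm, ii, jj)[1L]
    i <- ii[k]; j <- jj[k]
  } else {
    if (!any(usable)) return(NULL)
    i <- which(tb5[, 2L] >= max(iv5[usable, 2L]))
    j <- which(tb3[, 1L] <= min(iv3[usable, 1L]))
    if (!length(i) || !length(j)) return(NULL)
    i <- min(i); j <- max(j)
  }
  J5 <- tb5[i, 2L]; J3 <- tb3[j, 1L]
  compat <- usable & iv5[, 2L] <= J5 & iv3[, 1L] >= J3
  inserts <- (J5 - iv5[compat, 2L]) + (iv3[compat, 1L] - J3) +
    (iv5[compat, 2L] - iv5[compat, 1L]) + (iv3[compat, 2L] - iv3[compat, 1L])
  list(gene5 = g5$gene_id, gene3 = g3$gene_id,
       junction_exon5 = i, junction_exon3 = j,
       n_pairs = sum(compat), n_chimeric = nrow(chim),
       support = sum(compat) + nrow(chim),
       median_insert = if (length(inserts)) median(inserts) else NA_real_,
       frame = predict_frame(g5, g3, i, j),
       ambiguous = nom$ambiguous)
}

#' Nominate fusion partners for a candidate gene from paired-end RNA-seq
#'
#' The full partner-discovery arm: extracts mate pairs anchored in the
#' candidate gene, nominates partner loci from the mates, removes likely
#' readthrough pairs, rescues chimeric junction-spanning reads among the
#' unmapped mates, estimates the fusion junction (from chimeric reads when
#' present, else the nearest exon boundaries compatible with all supporting
#' pairs), computes the median predicted insert in fusion-transcript
#' coordinates, and applies the support and insert filters. Both 5'/3'
#' orientations of each partner are evaluated and the better-supported one
#' is kept (ties favour chimeric evidence, then the anchor as 5' partner).
#'
#' @param sam SAM/BAM path, or a `mate_pairs` data.frame.
#' @param anchor_id id of the candidate rearranged gene.
#' @param models named list of [gene_model()] objects.
#' @param tx_seqs named character vector or `DNAStringSet` of transcript
#'   sequences (or a FASTA path).
#' @param min_support minimum supporting evidence (compatible pairs plus
#'   chimeric reads).
#' @param insert_range admissible range for the median predicted insert,
#'   nucleotides.
#' @param max_mismatches chimeric-rescue mismatch tolerance.
#' @param bin_size bin width for unannotated partner loci.
#' @return data.frame of class `fusion_candidates`, ranked by support then
#'   by closeness of the median insert to 300 nt. Unannotated-locus
#'   nominations are reported with `type = "bin"` and no junction.
#' @export
fusion_scan <- function(sam, anchor_id, models, tx_seqs, min_support = 2L,
                        insert_range = c(100, 400), max_mismatches = 2L,
                        bin_size = 1e5) {
  pairs <- if (inherits(sam, "mate_pairs")) sam else read_sam_pairs(sam)
  if (is.character(tx_seqs) && length(tx_seqs) == 1L && file.exists(tx_seqs))
    tx_seqs <- Biostrings::readDNAStringSet(tx_seqs)
  if (methods::is(tx_seqs, "DNAStringSet"))
    tx_seqs <- setNames(as.character(tx_seqs), names(tx_seqs))
  anchor <- models[[anchor_id]]
  if (is.null(anchor)) stop("unknown anchor gene: ", anchor_id)
  anchored <- extract_anchored_pairs(pairs, anchor)
  noms <- nominate_partners(anchored, models, bin_size = bin_size)
  noms <- readthrough_filter(noms, anchor_id, models)
  empty <- data.frame(gene5 = character(), gene3 = character(),
                      type = character(), junction_exon5 = integer(),
                      junction_exon3 = integer(), n_pairs = integer(),
                      n_chimeric = integer(), support = integer(),
                      median_insert = numeric(), frame = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  rows <- list()
  for (nom in noms) {
    if (nom$type == "bin") {
      if (nrow(nom$pairs) >= min_support)
        rows[[length(rows) + 1L]] <- data.frame(
          gene5 = anchor_id, gene3 = nom$partner, type = "bin",
          junction_exon5 = NA_integer_, junction_exon3 = NA_integer_,
          n_pairs = nrow(nom$pairs), n_chimeric = 0L,
          support = nrow(nom$pairs), median_insert = NA_real_,
          frame = "unknown", ambiguous = FALSE, stringsAsFactors = FALSE)
      next
    }
    partner <- models[[nom$partner]]
    nom$anchor_id <- anchor_id
    # unmapped mates of pairs anchored in either gene of the nomination
    resc_a <- anchored[anchored$rescue, , drop = FALSE]
    rescue_reads <- setNames(resc_a$partner_seq, resc_a$qname)
    p_anch <- extract_anchored_pairs(pairs, partner)
    p_resc <- p_anch[p_anch$rescue, , drop = FALSE]
    more <- setNames(p_resc$partner_seq, p_resc$qname)
    rescue_reads <- c(rescue_reads, more[setdiff(names(more),
                                                 names(rescue_reads))])
    cand <- list(
      evaluate_orientation(nom, anchor, partner, tx_seqs, rescue_reads,
                           insert_range, max_mismatches),
      evaluate_orientation(nom, partner, anchor, tx_seqs, rescue_reads,
                           insert_range, max_mismatches))
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) next
    if (length(cand) == 2L) {
      pickfirst <- cand[[1L]]$support > cand[[2L]]$support ||
        (cand[[1L]]$support == cand[[2L]]$support &&
           cand[[1L]]$n_chimeric >= cand[[2L]]$n_chimeric)
      cand <- cand[[if (pickfirst) 1L else 2L]]
    } else cand <- cand[[1L]]
    # support and insert filters
    if (cand$support < min_support) next
    if (!is.na(cand$median_insert) &&
        (cand$median_insert < insert_range[1L] ||
         cand$median_insert > insert_range[2L])) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene5 = cand$gene5, gene3 = cand$gene3, type = "gene",
      junction_exon5 = cand$junction_exon5,
      junction_exon3 = cand$junction_exon3,
      n_pairs = cand$n_pairs, n_chimeric = cand$n_chimeric,
      support = cand$support, median_insert = cand$median_insert,
      frame = cand$frame, ambiguous = cand$ambiguous,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out))
    out <- out[order(-out$support,
                     abs(out$median_insert - 300),
                     method = "radix", na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fusion_candidates", "data.frame")
  out
}

#' @export
print.fusion_candidates <- function(x, ...) {
  cat(sprintf("<fusion_candidates> %d candidate(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}
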