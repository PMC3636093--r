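#' Simulate exon-level expression profiles with planted breakpoints
#'
#' Generates per-gene exon log2 profiles as i.i.d. normal noise around zero
#' (emulating cohort-mean-centred exon-array ratios) and, for each planted
#' break, adds a constant step to every exon distal (3') of the named
#' junction in the named sample — the expression pattern of a 3' fusion
#' partner. All randomness is a pure function of `seed`.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param n_samples number of samples.
#' @param noise_sd exon noise standard deviation, log2 units.
#' @param breaks optional data.frame with columns `gene`, `sample`,
#'   `junction`, `step`: add `step` log2 units to exons `junction+1..m`.
#' @param seed integer seed.
#' @return list with `profiles` (an `exon_profiles` object; genes `G0001`..,
#'   samples `S001`..), `models` (matching [gene_model()] list on a synthetic
#'   chromosome) and `truth` (the planted breaks).
#' @export
make_exon_matrix <- function(n_genes = 306L, exons_per_gene = c(8L, 20L),
                             n_samples = 1L, noise_sd = 0.3, breaks = NULL,
                             seed = 1L) {
  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    n_ex <- sample_range(exons_per_gene[1L], exons_per_gene[2L], n_genes)
    mats <- list()
    models <- list()
    cursor <- 0
    for (i in seq_len(n_genes)) {
      m <- matrix(rnorm(n_ex[i] * n_samples, sd = noise_sd), n_ex[i],
                  dimnames = list(seq_len(n_ex[i]), sample_ids))
      mats[[gene_ids[i]]] <- m
      starts <- cursor + seq(0, by = 1150, length.out = n_ex[i])
      models[[gene_ids[i]]] <- gene_model(gene_ids[i], "simchr", "+",
                                          cbind(starts, starts + 150))
      cursor <- max(starts) + 150 + 5000
    }
    if (!is.null(breaks) && nrow(breaks)) {
      for (k in seq_len(nrow(breaks))) {
        g <- as.character(breaks$gene[k]); s <- as.character(breaks$sample[k])
        j <- breaks$junction[k]
        if (is.null(mats[[g]])) stop("planted break in unknown gene ", g)
        m <- nrow(mats[[g]])
        if (j < 1L || j >= m) stop("junction out of range for gene ", g)
        mats[[g]][(j + 1L):m, s] <- mats[[g]][(j + 1L):m, s] + breaks$step[k]
      }
    }
    list(profiles = exon_profiles(mats), models = models,
         truth = breaks %||% data.frame(gene = character(),
                                        sample = character(),
                                        junction = integer(),
                                        step = numeric()))
  })
}

#' Write exon profiles to the TSV matrix format
#'
#' @param profiles an `exon_profiles` object.
#' @param path output TSV.
#' @export
write_exon_matrix <- function(profiles, path) {
  rows <- lapply(names(profiles), function(g) {
    m <- profiles[[g]]
    cbind(data.frame(gene_id = g, exon = seq_len(nrow(m))),
          as.data.frame(m, check.names = FALSE))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Simulate probe-level copy-number tracks with planted CNAs
#'
#' Builds per-chromosome piecewise-constant log2-ratio tracks (baseline 0)
#' plus Gaussian probe noise, with planted alterations at known probe
#' boundaries.
#'
#' @param n_probes probes per chromosome.
#' @param n_chrom number of chromosomes (`cnv1`..).
#' @param noise_sd probe noise standard deviation, log2 units.
#' @param cnas optional data.frame with columns `chrom`, `start_probe`
#'   (0-based), `length` (probes), `mean_log2`. Overlapping or out-of-bounds
#'   alterations are an error.
#' @param sample_id sample name.
#' @param spacing genomic spacing between probes, nucleotides.
#' @param seed integer seed.
#' @return list with `tracks` (named list of [probe_track()], one per
#'   chromosome) and `truth` (the planted table plus `end_probe`).
#' @export
make_probe_tracks <- function(n_probes = 500L, n_chrom = 1L, noise_sd = 0.15,
                              cnas = NULL, sample_id = "S001",
                              spacing = 1000, seed = 1L) {
  chroms <- sprintf("cnv%d", seq_len(n_chrom))
  if (!is.null(cnas) && nrow(cnas)) {
    cnas$end_probe <- cnas$start_probe + cnas$length
    if (any(cnas$start_probe < 0L | cnas$end_probe > n_probes))
      stop("planted CNA out of probe bounds")
    if (any(!cnas$chrom %in% chroms)) stop("planted CNA on unknown chromosome")
    for (ch in unique(cnas$chrom)) {
      sub <- cnas[cnas$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start_probe), , drop = FALSE]
      if (nrow(sub) > 1L &&
          any(sub$start_probe[-1L] < sub$end_probe[-nrow(sub)]))
        stop("overlapping planted CNAs on ", ch)
    }
  }
  with_seed(seed, {
    tracks <- list()
    for (ch in chroms) {
      mu <- numeric(n_probes)
      if (!is.null(cnas) && nrow(cnas)) {
        sub <- cnas[cnas$chrom == ch, , drop = FALSE]
        for (k in seq_len(nrow(sub)))
          mu[(sub$start_probe[k] + 1L):sub$end_probe[k]] <- sub$mean_log2[k]
      }
      tracks[[ch]] <- probe_track(sample_id, ch,
                                  positions = spacing * seq_len(n_probes),
                                  ratios = mu + rnorm(n_probes, sd = noise_sd))
    }
    list(tracks = tracks,
         truth = if (is.null(cnas))
           data.frame(chrom = character(), start_probe = integer(),
                      length = integer(), mean_log2 = numeric(),
                      end_probe = integer())
         else cnas)
  })
}

#' Write probe tracks to the TSV format
#'
#' @param tracks named list of [probe_track()] (one sample).
#' @param path output TSV.
#' @export
write_probe_tracks <- function(tracks, path) {
  sample_id <- tracks[[1L]]$sample_id
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(chrom = tr$chrom, position = tr$positions)
    df[[sample_id]] <- tr$ratios
    df
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# sample() treats a scalar first argument as 1:x; ranges that collapse to a
# single value must not fall into that trap
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a synthetic annotated transcriptome
#'
#' Random-nucleotide transcripts laid out as multi-exon genes along one
#' synthetic chromosome, with CDS covering the transcript interior (one
#' exon-length UTR trimmed at each end when the gene has enough exons).
#' Intergenic gaps are wide enough that genes are non-adjacent unless
#' `adjacent_pair = TRUE`, which places the first two genes immediately next
#' to each other on the same strand (a readthrough decoy).
#'
#' @param n_genes number of genes (`TX01`..).
#' @param exons_per_gene integer range of exons per gene.
#' @param exon_len integer range of exon lengths, nucleotides.
#' @param strands optional strand vector per gene (default all `+`).
#' @param adjacent_pair place genes 1 and 2 immediately adjacent, same strand.
#' @param seed integer seed.
#' @return list with `models` (named [gene_model()] list, CDS annotated),
#'   `tx_seqs` (named character vector of transcript sequences, 5'->3') and
#'   `chrom_len`.
#' @export
make_transcriptome <- function(n_genes = 6L, exons_per_gene = c(8L, 12L),
                               exon_len = c(100L, 300L), strands = NULL,
                               adjacent_pair = FALSE, seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("TX%02d", seq_len(n_genes))
    if (is.null(strands)) strands <- rep("+", n_genes)
    strands <- rep_len(strands, n_genes)
    models <- list(); seqs <- character()
    cursor <- 1000
    for (i in seq_len(n_genes)) {
      n_ex <- sample_range(exons_per_gene[1L], exons_per_gene[2L], 1L)
      lens <- sample_range(exon_len[1L], exon_len[2L], n_ex)
      introns <- sample_range(200L, 2000L, n_ex - 1L)
      starts <- cursor + cumsum(c(0, lens[-n_ex] + introns))
      ex_genomic <- cbind(starts, starts + lens)  # genomic order
      ex <- if (strands[i] == "+") ex_genomic
            else ex_genomic[n_ex:1L, , drop = FALSE]
      # CDS: trim one exon of UTR at each end when possible
      cds <- if (n_ex >= 4L) {
        keep <- ex[2:(n_ex - 1L), , drop = FALSE]
        keep[order(keep[, 1L], decreasing = strands[i] == "-"), , drop = FALSE]
      } else NULL
      models[[ids[i]]] <- gene_model(ids[i], "fuschr", strands[i], ex, cds)
      seqs[[ids[i]]] <- random_dna(sum(lens))
      gap <- if (adjacent_pair && i == 1L) 300 else sample(20000:40000, 1L)
      if (adjacent_pair && i == 1L) strands[2L] <- strands[1L]
      cursor <- max(ex_genomic[, 2L]) + gap
    }
    list(models = models, tx_seqs = seqs, chrom_len = cursor + 50000)
  })
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Sequence of a transcript interval [txa, txb) as the genome-forward strand
# string, given the transcript sequence and the gene strand.
tx_interval_forward_seq <- function(tx_seq, txa, txb, strand) {
  s <- substr(tx_seq, txa + 1L, txb)
  if (strand == "+") s else revcomp(s)
}

mutate_seq <- function(s, error_rate) {
  if (error_rate <= 0) return(list(seq = s, nm = 0L))
  ch <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(ch)) < error_rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), nm = length(hit))
}

# locate the exon (row index) wholly containing tx interval [txa, txb);
# NA when the interval crosses an exon boundary
containing_exon <- function(tb, txa, txb) {
  k <- which(tb[, 1L] <= txa & txb <= tb[, 2L])
  if (length(k) == 1L) k else NA_integer_
}

#' Simulate paired-end reads from planted fusion transcripts
#'
#' Builds chimeric transcripts (exons 1..`exon5` of `gene5` joined to exons
#' `exon3`..end of `gene3`), samples junction-spanning paired-end fragments
#' with a Gaussian insert-size distribution and per-base substitution
#' errors, adds concordant background pairs from wildtype transcripts, and
#' writes the alignments as minimally valid SAM against the synthetic
#' genome. Reads that cross the fusion junction are written unmapped (with
#' their sequence, placed at the mate's coordinates), exactly the reads the
#' chimeric rescue stage must recover; all other reads are placed within
#' single exons (fragments are redrawn when a read straddles an ordinary
#' splice junction, keeping every CIGAR a simple match).
#'
#' @param txome a [make_transcriptome()] result.
#' @param fusions data.frame with columns `gene5`, `exon5`, `gene3`,
#'   `exon3`, `n_pairs`, `insert_mean`, `insert_sd`, `read_len`,
#'   `error_rate`.
#' @param background_pairs concordant wildtype pairs per gene.
#' @param sam_path,fasta_path output paths (SAM alignments, transcript
#'   FASTA).
#' @param seed integer seed.
#' @return list with `sam_path`, `fasta_path` and `truth` (the fusion
#'   table).
#' @export
make_fusion_reads <- function(txome, fusions, background_pairs = 50L,
                              sam_path = tempfile(fileext = ".sam"),
                              fasta_path = tempfile(fileext = ".fa"),
                              seed = 1L) {
  models <- txome$models
  if (any(fusions$insert_mean < 2 * fusions$read_len))
    stop("insert_mean shorter than two read lengths")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(txome$tx_seqs)), fasta_path)
  recs <- list()
  emit <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
                   seq, nm = NA) {
    fields <- c(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
                seq, strrep("I", nchar(seq)))
    if (!is.na(nm)) fields <- c(fields, paste0("NM:i:", nm))
    recs[[length(recs) + 1L]] <<- paste(fields, collapse = "\t")
  }
  sample_tx_pair <- function(tx_seq, gm_map, insert_mean, insert_sd, read_len,
                             error_rate, span_junction = NA) {
    # gm_map: function(txa, txb) -> list(gene, txa, txb) in gene tx coords
    L <- nchar(tx_seq)
    for (try in 1:80) {
      frag <- round(rnorm(1L, insert_mean, insert_sd))
      if (frag < 2 * read_len || frag > L) next
      if (!is.na(span_junction)) {
        lo <- max(0L, span_junction - frag + 1L)
        hi <- min(span_junction - 1L, L - frag)
        if (hi < lo) next
        u <- sample(lo:hi, 1L)
      } else {
        u <- sample(0:(L - frag), 1L)
      }
      r1 <- c(u, u + read_len)            # tx-forward read
      r2 <- c(u + frag - read_len, u + frag)  # tx-reverse read
      m1 <- gm_map(r1[1L], r1[2L]); m2 <- gm_map(r2[1L], r2[2L])
      ok <- function(m) is.null(m) || !is.na(m$exon)
      if (!ok(m1) || !ok(m2)) next  # read straddles a splice junction
      return(list(u = u, frag = frag, r1 = r1, r2 = r2, m1 = m1, m2 = m2))
    }
    NULL
  }
  place <- function(gm, map, tx_reverse) {
    # genomic placement of a mapped read; returns list(rname,pos,strand)
    tb <- exon_tx_bounds(gm)
    k <- map$exon
    off <- map$txa - tb[k, 1L]
    len <- map$txb - map$txa
    if (gm$strand == "+") {
      pos0 <- gm$exons[k, 1L] + off
      gstrand <- if (tx_reverse) "-" else "+"
    } else {
      pos0 <- gm$exons[k, 2L] - off - len
      gstrand <- if (tx_reverse) "+" else "-"
    }
    list(rname = gm$chrom, pos = pos0 + 1, strand = gstrand)
  }
  write_pair <- function(qname, gmA, mapA, gmB, mapB, tx_seq, r1, r2,
                         read_len, error_rate) {
    # mapA/mapB NULL => that read is unmapped (junction-spanning)
    seq1_tx <- substr(tx_seq, r1[1L] + 1L, r1[2L])
    seq2_tx <- revcomp(substr(tx_seq, r2[1L] + 1L, r2[2L]))
    e1 <- mutate_seq(seq1_tx, error_rate); e2 <- mutate_seq(seq2_tx, error_rate)
    pl1 <- if (!is.null(mapA)) place(gmA, mapA, tx_reverse = FALSE)
    pl2 <- if (!is.null(mapB)) place(gmB, mapB, tx_reverse = TRUE)
    fwd <- function(e, pl, tx_rev) {
      # SEQ is stored on the genome-forward strand
      if (is.null(pl)) e$seq else if (pl$strand == "-") revcomp(e$seq) else e$seq
    }
    f1 <- 0x1 + 0x40; f2 <- 0x1 + 0x80
    if (is.null(pl1)) { f1 <- f1 + 0x4; f2 <- f2 + 0x8 }
    if (is.null(pl2)) { f2 <- f2 + 0x4; f1 <- f1 + 0x8 }
    if (!is.null(pl1) && pl1$strand == "-") { f1 <- f1 + 0x10; f2 <- f2 + 0x20 }
    if (!is.null(pl2) && pl2$strand == "-") { f2 <- f2 + 0x10; f1 <- f1 + 0x20 }
    rn1 <- if (!is.null(pl1)) pl1$rname else pl2$rname
    pp1 <- if (!is.null(pl1)) pl1$pos else pl2$pos
    rn2 <- if (!is.null(pl2)) pl2$rname else pl1$rname
    pp2 <- if (!is.null(pl2)) pl2$pos else pl1$pos
    emit(qname, f1, rn1, pp1, if (is.null(pl1)) 0 else 60,
         if (is.null(pl1)) "*" else paste0(read_len, "M"),
         if (rn2 == rn1) "=" else rn2, pp2, 0, fwd(e1, pl1, FALSE),
         if (is.null(pl1)) NA else e1$nm)
    emit(qname, f2, rn2, pp2, if (is.null(pl2)) 0 else 60,
         if (is.null(pl2)) "*" else paste0(read_len, "M"),
         if (rn1 == rn2) "=" else rn1, pp1, 0, fwd(e2, pl2, TRUE),
         if (is.null(pl2)) NA else e2$nm)
  }
  with_seed(seed, {
    pair_n <- 0L
    for (f in seq_len(nrow(fusions))) {
      g5 <- models[[as.character(fusions$gene5[f])]]
      g3 <- models[[as.character(fusions$gene3[f])]]
      tb5 <- exon_tx_bounds(g5); tb3 <- exon_tx_bounds(g3)
      J5 <- tb5[fusions$exon5[f], 2L]     # fusion junction in tx5 coords
      J3 <- tb3[fusions$exon3[f], 1L]     # gene3 re-entry point
      ftx <- paste0(substr(txome$tx_seqs[[g5$gene_id]], 1L, J5),
                    substr(txome$tx_seqs[[g3$gene_id]], J3 + 1L,
                           nchar(txome$tx_seqs[[g3$gene_id]])))
      gm_map <- function(txa, txb) {
        if (txb <= J5)
          list(gene = g5$gene_id, txa = txa, txb = txb,
               exon = containing_exon(tb5, txa, txb))
        else if (txa >= J5)
          list(gene = g3$gene_id, txa = txa - J5 + J3, txb = txb - J5 + J3,
               exon = containing_exon(tb3, txa - J5 + J3, txb - J5 + J3))
        else NULL  # junction-spanning
      }
      for (p in seq_len(fusions$n_pairs[f])) {
        sp <- sample_tx_pair(ftx, gm_map, fusions$insert_mean[f],
                             fusions$insert_sd[f], fusions$read_len[f],
                             fusions$error_rate[f], span_junction = J5)
        if (is.null(sp)) next
        pair_n <- pair_n + 1L
        qn <- sprintf("fus%d_%05d", f, pair_n)
        mA <- gm_map(sp$r1[1L], sp$r1[2L]); mB <- gm_map(sp$r2[1L], sp$r2[2L])
        gA <- if (!is.null(mA)) models[[mA$gene]]
        gB <- if (!is.null(mB)) models[[mB$gene]]
        write_pair(qn, gA, mA, gB, mB, ftx, sp$r1, sp$r2,
                   fusions$read_len[f], fusions$error_rate[f])
      }
    }
    rl <- fusions$read_len[1L]
    for (gid in names(models)) {
      gm <- models[[gid]]; tb <- exon_tx_bounds(gm)
      tx <- txome$tx_seqs[[gid]]
      gm_map <- function(txa, txb)
        list(gene = gid, txa = txa, txb = txb,
             exon = containing_exon(tb, txa, txb))
      for (p in seq_len(background_pairs)) {
        sp <- sample_tx_pair(tx, gm_map, 250, 30, rl, 0.005)
        if (is.null(sp)) next
        pair_n <- pair_n + 1L
        write_pair(sprintf("bg_%s_%05d", gid, p), gm, sp$m1, gm, sp$m2,
                   tx, sp$r1, sp$r2, rl, 0.005)
      }
    }
    NULL
  })
  chroms <- unique(vapply(models, `[[`, character(1L), "chrom"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      as.integer(txome$chrom_len)))
  writeLines(c(header, unlist(recs)), sam_path)
  list(sam_path = sam_path, fasta_path = fasta_path, truth = fusions)
}
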