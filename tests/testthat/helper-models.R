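# Build a toy gene model from exon lengths; cds_tx is an optional
# c(start, end) range in transcript coordinates (0-based half-open) that is
# mapped back onto the genome through the exon structure.
mk_gene <- function(id, exon_lens, strand = "+", chrom = "toy",
                    start = 1000, intron = 100, cds_tx = NULL) {
  n <- length(exon_lens)
  starts <- start + cumsum(c(0, exon_lens[-n] + intron))
  ex_genomic <- cbind(starts, starts + exon_lens)
  ex <- if (strand == "+") ex_genomic else ex_genomic[n:1, , drop = FALSE]
  gm <- gene_model(id, chrom, strand, ex)
  if (!is.null(cds_tx)) {
    tb <- exon_tx_bounds(gm)
    cds <- NULL
    for (k in seq_len(n)) {
      a <- max(tb[k, 1L], cds_tx[1L]); b <- min(tb[k, 2L], cds_tx[2L])
      if (a >= b) next
      g <- sort(tx_to_genomic(gm, c(a, b - 1)))
      cds <- rbind(cds, c(g[1L], g[2L] + 1))
    }
    cds <- cds[order(cds[, 1L], decreasing = strand == "-"), , drop = FALSE]
    gm <- gene_model(id, chrom, strand, ex, cds)
  }
  gm
}
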