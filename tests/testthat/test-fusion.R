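mk_pairs <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("mate_pairs", "data.frame")
  df
}

pair_row <- function(qname, c1, s1, c2, s2, mapped2 = TRUE, len = 75) {
  mk_pairs(qname = qname,
           chrom1 = c1, start1 = s1, end1 = s1 + len, strand1 = "+",
           mapped1 = TRUE, seq1 = strrep("A", len),
           chrom2 = c2, start2 = s2, end2 = s2 + len, strand2 = "-",
           mapped2 = mapped2, seq2 = strrep("C", len))
}

test_that("anchored-pair extraction keeps discordant and rescue pairs only", {
  anchor <- mk_gene("ANC", rep(200, 4), chrom = "chrA", start = 10000)
  pairs <- rbind(
    pair_row("both_in", "chrA", 10050, "chrA", 10650),   # both in anchor
    pair_row("disc", "chrA", 10050, "chrB", 99000),      # mate elsewhere
    pair_row("resc", "chrA", 10350, "chrA", 10350, mapped2 = FALSE),
    pair_row("intron", "chrA", 10050, "chrA", 10250),    # mate in intron
    pair_row("outside", "chrB", 500, "chrB", 700))       # no anchor read
  class(pairs) <- c("mate_pairs", "data.frame")
  anch <- extract_anchored_pairs(pairs, anchor)
  expect_setequal(anch$qname, c("disc", "resc"))
  expect_equal(anch$rescue[anch$qname == "resc"], TRUE)
  expect_equal(anch$rescue[anch$qname == "disc"], FALSE)
})

test_that("partner nomination counts clusters, flags ambiguity, bins the rest", {
  models <- list(B = mk_gene("B", rep(200, 3), chrom = "chrB", start = 98000),
                 C = mk_gene("C", rep(200, 3), chrom = "chrB", start = 300000),
                 # D overlaps B's span
                 D = mk_gene("D", rep(300, 2), chrom = "chrB", start = 98100))
  anchor <- mk_gene("ANC", rep(200, 4), chrom = "chrA", start = 10000)
  pairs <- rbind(
    pair_row("p1", "chrA", 10050, "chrB", 98050),
    pair_row("p2", "chrA", 10050, "chrB", 98200),
    pair_row("p3", "chrA", 10050, "chrB", 300100),
    pair_row("p4", "chrA", 10050, "chrB", 700000))  # intergenic
  class(pairs) <- c("mate_pairs", "data.frame")
  anch <- extract_anchored_pairs(pairs, anchor)
  noms <- nominate_partners(anch, models)
  by_partner <- setNames(lapply(noms, identity),
                         vapply(noms, `[[`, "", "partner"))
  expect_equal(nrow(by_partner[["B"]]$pairs), 2)
  expect_equal(nrow(by_partner[["C"]]$pairs), 1)
  expect_true(by_partner[["B"]]$ambiguous)   # B reads also stab D
  expect_false(by_partner[["C"]]$ambiguous)
  bins <- Filter(function(n) n$type == "bin", noms)
  expect_equal(length(bins), 1)
  expect_match(bins[[1]]$partner, "chrB:700000-800000")
})

test_that("readthrough filter removes only adjacent same-strand pairs", {
  models <- list(
    A = mk_gene("A", rep(200, 3), chrom = "c", start = 1000),
    B = mk_gene("B", rep(200, 3), chrom = "c", start = 5000),   # adjacent to A
    C = mk_gene("C", rep(200, 3), chrom = "c", start = 9000, strand = "-"),
    D = mk_gene("D", rep(200, 3), chrom = "c", start = 13000))
  nom <- function(p) list(partner = p, type = "gene", ambiguous = FALSE,
                          pairs = data.frame())
  # A-B immediately adjacent, same strand: removed
  expect_equal(length(readthrough_filter(list(nom("B")), "A", models)), 0)
  # B-C adjacent but opposite strand: retained
  expect_equal(length(readthrough_filter(list(nom("C")), "B", models)), 1)
  # A-D same strand but separated by intervening genes: retained
  expect_equal(length(readthrough_filter(list(nom("D")), "A", models)), 1)
  # the anchor itself is never a partner
  expect_equal(length(readthrough_filter(list(nom("A")), "A", models)), 0)
})

test_that("chimeric rescue finds exact junctions and respects the cap", {
  txome <- make_transcriptome(n_genes = 2, exons_per_gene = c(6, 8),
                              seed = 33)
  g5 <- txome$models[[1]]; g3 <- txome$models[[2]]
  tb5 <- exon_tx_bounds(g5); tb3 <- exon_tx_bounds(g3)
  tx5 <- txome$tx_seqs[[g5$gene_id]]; tx3 <- txome$tx_seqs[[g3$gene_id]]
  # read = exact 40+35 split across the exon4/exon2 junction
  read <- paste0(substr(tx5, tb5[4, 2] - 39, tb5[4, 2]),
                 substr(tx3, tb3[2, 1] + 1, tb3[2, 1] + 35))
  hit <- rescue_chimeric_reads(c(r1 = read), g5, g3, txome$tx_seqs)
  expect_equal(hit$exon5, 4)
  expect_equal(hit$exon3, 2)
  expect_equal(hit$mismatches, 0)
  # its reverse complement is found too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hit2 <- rescue_chimeric_reads(c(r1 = rc), g5, g3, txome$tx_seqs)
  expect_equal(hit2[, c("exon5", "exon3", "mismatches")],
               hit[, c("exon5", "exon3", "mismatches")])
  expect_true(hit2$revcomp)
  # three substitutions exceed the 2-mismatch tolerance
  mutate_at <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (i in at) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  expect_equal(nrow(rescue_chimeric_reads(c(r1 = mutate_at(read, c(5, 20, 60))),
                                          g5, g3, txome$tx_seqs)), 0)
  expect_equal(nrow(rescue_chimeric_reads(c(r1 = mutate_at(read, c(5, 20))),
                                          g5, g3, txome$tx_seqs)), 1)
})

test_that("rescue agrees with a brute-force all-offsets scan", {
  txome <- make_transcriptome(n_genes = 2, exons_per_gene = c(5, 6),
                              exon_len = c(80, 120), seed = 44)
  g5 <- txome$models[[1]]; g3 <- txome$models[[2]]
  set.seed(9)
  # random 75-mers: brute force says no junction carries them
  for (rep in 1:5) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE),
                 collapse = "")
    bf <- rescue_bruteforce(rnd, g5, g3, txome$tx_seqs)
    res <- rescue_chimeric_reads(c(r = rnd), g5, g3, txome$tx_seqs)
    expect_equal(nrow(res) > 0, !is.null(bf))
  }
  # a genuine junction read: the package's best hit is among the
  # brute-force minimum-mismatch hits
  tb5 <- exon_tx_bounds(g5); tb3 <- exon_tx_bounds(g3)
  tx5 <- txome$tx_seqs[[g5$gene_id]]; tx3 <- txome$tx_seqs[[g3$gene_id]]
  read <- paste0(substr(tx5, tb5[3, 2] - 29, tb5[3, 2]),
                 substr(tx3, tb3[4, 1] + 1, tb3[4, 1] + 45))
  bf <- rescue_bruteforce(read, g5, g3, txome$tx_seqs)
  res <- rescue_chimeric_reads(c(r = read), g5, g3, txome$tx_seqs)
  expect_equal(res$mismatches, min(bf[, "mm"]))
  best_bf <- bf[bf[, "mm"] == min(bf[, "mm"]), , drop = FALSE]
  expect_true(any(best_bf[, "i"] == res$exon5 & best_bf[, "j"] == res$exon3))
})

test_that("frame prediction follows coding phase arithmetic", {
  # gene5 contributes 360 coding nt up to the end of exon 2
  g5 <- mk_gene("g5", c(200, 220), cds_tx = c(60, 420))   # J5 = 420, L5 = 360
  g3a <- mk_gene("g3a", c(150, 150, 150), cds_tx = c(150, 420),
                 start = 50000)  # exon2 starts at CDS phase 0
  expect_equal(predict_frame(g5, g3a, 2, 2), "in_frame")
  # one extra 5' nucleotide breaks the frame
  g5b <- mk_gene("g5b", c(200, 221), cds_tx = c(60, 421))  # L5 = 361
  expect_equal(predict_frame(g5b, g3a, 2, 2), "out_of_frame")
  # junction inside the 3' gene's 5'UTR: unknown (internal start possible)
  g3b <- mk_gene("g3b", c(150, 150, 150), cds_tx = c(200, 430),
                 start = 90000)
  expect_equal(predict_frame(g5, g3b, 2, 2), "unknown")
  # no CDS annotation: unknown
  g3c <- mk_gene("g3c", c(150, 150), start = 130000)
  expect_equal(predict_frame(g5, g3c, 2, 2), "unknown")
})

test_that("support and insert filters remove under-supported and misspaced candidates", {
  txome <- make_transcriptome(n_genes = 6, seed = 20)
  fus <- data.frame(gene5 = c("TX01", "TX04"), exon5 = c(4, 3),
                    gene3 = c("TX03", "TX05"), exon3 = c(2, 2),
                    n_pairs = c(1, 20), insert_mean = c(250, 500),
                    insert_sd = c(30, 30), read_len = 75, error_rate = 0)
  rd <- make_fusion_reads(txome, fus, background_pairs = 20, seed = 9)
  # single supporting pair: removed by the >=2 support rule
  expect_equal(nrow(fusion_scan(rd$sam_path, "TX03", txome$models,
                                rd$fasta_path)), 0)
  # median insert ~500: outside the 100-400 window
  expect_equal(nrow(fusion_scan(rd$sam_path, "TX05", txome$models,
                                rd$fasta_path)), 0)
})

test_that("a planted fusion is recovered end to end with its junction", {
  txome <- make_transcriptome(n_genes = 6, seed = 10)
  fus <- data.frame(gene5 = "TX01", exon5 = 4, gene3 = "TX03", exon3 = 2,
                    n_pairs = 30, insert_mean = 250, insert_sd = 30,
                    read_len = 75, error_rate = 0.01)
  rd <- make_fusion_reads(txome, fus, background_pairs = 40, seed = 4)
  fc <- fusion_scan(rd$sam_path, "TX03", txome$models, rd$fasta_path)
  expect_gte(nrow(fc), 1)
  top <- fc[1, ]
  expect_equal(top$gene5, "TX01")
  expect_equal(top$gene3, "TX03")
  expect_equal(top$junction_exon5, 4)
  expect_equal(top$junction_exon3, 2)
  expect_gte(top$support, 2)
  expect_true(top$median_insert >= 100 && top$median_insert <= 400)
  # candidate invariants: distinct genes, no adjacent same-strand pair
  expect_true(all(fc$gene5 != fc$gene3))
})
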