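test_that("consensus calling follows the 65% threshold with ties as X", {
  # identical sequences reproduce themselves exactly
  aln_id <- aligned_set(c(a = "MKVLY-", b = "MKVLY-", c = "MKVLY-"))
  expect_equal(consensus_sequence(aln_id)$sequence, "MKVLY-")
  # 2/3 = 0.667 >= 0.65 is called; a 50/50 tie is X
  aln <- aligned_set(c(a = "AA", b = "AG", c = "AG", d = "AA"))
  expect_equal(consensus_sequence(aln)$sequence, "AX")
  aln2 <- aligned_set(c(a = "A", b = "A", c = "G"))
  expect_equal(consensus_sequence(aln2)$sequence, "A")
  # below threshold -> X; gaps count as a callable symbol by default
  aln3 <- aligned_set(c(a = "-A", b = "-G", c = "-T"))
  expect_equal(consensus_sequence(aln3)$sequence, "-X")
  # ignoring gaps, an all-gap column has nothing to call and stays a gap
  expect_equal(consensus_sequence(aln3, count_gaps = FALSE)$sequence, "-X")
  # at threshold 1 only perfectly conserved columns survive
  aln4 <- aligned_set(c(a = "AAAG", b = "AAAG", c = "AAGG"))
  cons4 <- consensus_sequence(aln4, threshold = 1)$sequence
  expect_equal(cons4, "AAXG")
  # unaligned input is rejected
  expect_error(aligned_set(c(a = "AAA", b = "AA")), "unequal")
  expect_error(aligned_set(c(a = "AB")), "Illegal")
})

test_that("consensus equals exhaustive per-column counting on random alignments", {
  set.seed(101)
  for (rep in 1:5) {
    seqs <- vapply(1:6, function(i) {
      s <- sample(c(strsplit("ACDEFG", "")[[1]], "-"), 80, replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:6)
    aln <- aligned_set(seqs)
    for (th in c(0.5, 0.65, 0.9)) {
      expect_equal(consensus_sequence(aln, threshold = th)$sequence,
                   brute_consensus(seqs, th))
      expect_equal(consensus_sequence(aln, th, count_gaps = FALSE)$sequence,
                   brute_consensus(seqs, th, count_gaps = FALSE))
    }
  }
})

test_that("percent identity counts reference columns position by position", {
  aln <- aligned_set(c(hs = "MKV-LY", sp = "MKA-LY", sp2 = "MKA-TY"),
                     reference = "hs")
  cons <- consensus_sequence(aln)  # A called at col 3 (2/3 >= 0.65)
  expect_equal(cons$sequence, "MKA-LY")
  # reference ungapped positions: M1 K2 V3 L4 Y5; col 3 mismatches (A vs V)
  expect_equal(percent_identity(cons, aln), 100 * 4 / 5)
  expect_equal(percent_identity(cons, aln, start = 1, end = 2), 100)
  expect_equal(percent_identity(cons, aln, start = 3, end = 4), 50)
  # all-X consensus scores zero
  cons_x <- structure(list(sequence = "XXXXXX", threshold = 0.65),
                      class = "consensus_seq")
  expect_equal(percent_identity(cons_x, aln), 0)
  expect_error(percent_identity(cons, aln, start = 4, end = 2), "order")
  expect_error(percent_identity(cons, aln, start = 1, end = 99), "length")
})

test_that("percent identity on random alignments equals brute-force counting", {
  set.seed(55)
  for (rep in 1:5) {
    seqs <- vapply(1:5, function(i)
      paste(sample(c(strsplit("ACDEFGH", "")[[1]], "-"), 100, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("s", 1:5)
    # ensure the reference has at least one residue
    substr(seqs[1], 1, 1) <- "A"
    aln <- aligned_set(seqs)
    cons <- consensus_sequence(aln)
    ref <- strsplit(seqs[[1]], "")[[1]]
    cv <- strsplit(cons$sequence, "")[[1]]
    keep <- ref != "-"
    oracle <- 100 * sum(cv[keep] == ref[keep] & cv[keep] != "X") / sum(keep)
    expect_equal(percent_identity(cons, aln), oracle)
  }
})

test_that("percent identity is invariant to appending all-gap columns", {
  seqs <- c(hs = "MKVLY", sp = "MKALY", sp2 = "MKATY")
  aln <- aligned_set(seqs, reference = "hs")
  pid <- percent_identity(consensus_sequence(aln), aln)
  seqs_g <- paste0(seqs, "---")
  names(seqs_g) <- names(seqs)
  aln_g <- aligned_set(seqs_g, reference = "hs")
  expect_equal(percent_identity(consensus_sequence(aln_g), aln_g), pid)
})

test_that("domain identity table recovers planted clade conservation levels", {
  set.seed(77)
  ref <- random_peptide(100)
  mutate_seq <- function(s, keep_prob) {
    ch <- strsplit(s, "")[[1]]
    flip <- runif(length(ch)) > keep_prob
    ch[flip] <- vapply(which(flip), function(i) {
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch[i]), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  mk_clade <- function(keep_prob, n = 4) {
    seqs <- c(hs = ref,
              setNames(vapply(1:n, function(i) mutate_seq(ref, keep_prob),
                              character(1)), paste0("sp", 1:n)))
    aligned_set(seqs, reference = "hs")
  }
  clades <- list(conserved = mk_clade(0.97), divergent = mk_clade(0.2))
  domains <- tibble::tibble(name = c("N-tip", "core"),
                            start = c(1, 41), end = c(40, 100))
  tab <- domain_identity_table(clades, domains)
  expect_equal(nrow(tab), 4)
  cons_vals <- tab$identity_pct[tab$clade == "conserved"]
  div_vals <- tab$identity_pct[tab$clade == "divergent"]
  expect_true(all(cons_vals > 85))
  expect_true(all(div_vals < 40))
  # a single-sequence clade's consensus is that sequence
  solo <- list(solo = aligned_set(c(hs = ref, other = mutate_seq(ref, 0.8)),
                                  reference = "hs"))
  # out-of-order domains rejected
  expect_error(domain_identity_table(clades,
                                     tibble::tibble(name = "bad", start = 10,
                                                    end = 2)), "order")
})

test_that("CRAC/CARC grammar hits match hand-evaluated examples", {
  hits <- scan_motifs("LAYAR", pattern = "CRAC")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$end, 5)
  expect_equal(hits$central, 3)
  expect_equal(hits$match, "LAYAR")
  expect_equal(nrow(scan_motifs("AAAAA")), 0)
  # mirrored CARC form with F as the central aromatic
  hits_c <- scan_motifs("KAFAL", pattern = "CARC")
  expect_equal(hits_c$central, 3)
  # offset maps fragment hits into full-protein coordinates
  hits_o <- scan_motifs("LAYAR", pattern = "CRAC", offset = 760)
  expect_equal(hits_o$central, 763)
  expect_error(scan_motifs("LAY1R"), "Illegal")
})

test_that("motif scan equals brute-force regex enumeration on random peptides", {
  set.seed(11)
  n_seq <- 60
  for (i in seq_len(n_seq)) {
    s <- random_peptide(120)
    for (pat in c("CRAC", "CARC")) {
      expect_equal(normalise_hits(scan_motifs(s, pattern = pat)),
                   normalise_hits(brute_motif_scan(s, pat)))
    }
  }
})

test_that("strict spacer mode only admits nonpolar spacers", {
  # spacers A (nonpolar) pass; spacers with D (polar) fail in strict mode
  expect_equal(nrow(scan_motifs("LAYAR", strict_spacers = TRUE)), 1)
  expect_equal(nrow(scan_motifs("LDYAR", pattern = "CRAC",
                                strict_spacers = TRUE)), 0)
  expect_equal(nrow(scan_motifs("LDYAR", pattern = "CRAC")), 1)
  # strict mode agrees with the strict brute force on random peptides
  set.seed(19)
  for (i in 1:20) {
    s <- random_peptide(100)
    expect_equal(
      normalise_hits(scan_motifs(s, pattern = "CRAC", strict_spacers = TRUE)),
      normalise_hits(brute_motif_scan(s, "CRAC", strict = TRUE)))
  }
})

test_that("construct coordinate arithmetic maps codons exactly", {
  # the TM2 CRAC-mutant tyrosine: residue 785 edits CDS nt 2353-2355
  expect_equal(as.numeric(aa_to_cds(785)[, c("start_nt", "end_nt")]),
               c(2353, 2355))
  # N-terminal tip truncation: residues 1-25 remove nt 1-75
  expect_equal(as.numeric(aa_to_cds(1, 25)[, c("start_nt", "end_nt")]),
               c(1, 75))
  expect_equal(as.numeric(aa_to_cds(1)[, c("start_nt", "end_nt")]), c(1, 3))
  expect_error(aa_to_cds(0), "positive")
  expect_error(aa_to_cds(5, 2), "end_aa")
  # round trip nt -> aa -> nt is the identity
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:1000, 1); b <- a + sample(0:50, 1)
    nt <- aa_to_cds(a, b)
    aa <- cds_to_aa(nt$start_nt, nt$end_nt)
    expect_equal(c(aa$start_aa, aa$end_aa), c(a, b))
  }
  expect_error(cds_to_aa(2, 6), "whole codons")
})

test_that("alignment reader consumes FASTA and rejects ragged input", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">hs", "MKVL-Y", ">mm", "MKAL-Y"), tmp)
  aln <- read_alignment(tmp)
  expect_s3_class(aln, "aligned_set")
  expect_equal(aln$reference, "hs")
  expect_equal(aln$width, 6)
  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKVLY", ">b", "MK"), tmp2)
  expect_error(read_alignment(tmp2))
})
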