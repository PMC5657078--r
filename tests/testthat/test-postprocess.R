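cand_row <- function(read_id, task, contig, start, cigar, tier = 1L) {
  tibble::tibble(read_id = read_id, mate = NA_integer_, task = task,
                 contig = contig, start = start, cigar = cigar,
                 conv_score = NA_integer_, tier = tier)
}

test_that("the three-letter false mapping is exposed and rejected", {
  # AGACCCATG maps onto reference AGATTTATG only because C and T were
  # collapsed; chemistry says T cannot convert to C, so the three read Cs
  # over reference Ts are invalid columns and the placement must fall
  g <- c(c1 = "AGATTTATG")
  reads <- tibble::tibble(read_id = "r1", seq = "AGACCCATG")
  cl <- classify_alignments(cand_row("r1", "OT", "c1", 0L, "9M"), reads, g)
  expect_equal(cl$codes, "...XXX...")
  expect_equal(cl$n_invalid, 3L)
  fl <- filter_alignments(cl, max_invalid = 0)
  expect_false(fl$kept)
  expect_equal(fl$reason, "bisulfite-invalid")

  # the same columns all excused by matching (T -> C) SNP entries are kept
  snps <- tibble::tibble(contig = "c1", pos = 3:5, ref = "T", alt = "C")
  cl_snp <- classify_alignments(cand_row("r1", "OT", "c1", 0L, "9M"),
                                reads, g, snps)
  expect_equal(cl_snp$codes, "...SSS...")
  expect_equal(cl_snp$n_invalid, 0L)
  expect_equal(cl_snp$n_snp_excused, 3L)
  expect_true(filter_alignments(cl_snp)$kept)
})

test_that("column codes follow the bisulfite rule table", {
  g <- c(c1 = "ACGGAT")
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          seq = c("ATGGAT", "ACGGAT"))
  cl <- classify_alignments(
    dplyr::bind_rows(cand_row("r1", "OT", "c1", 0L, "6M"),
                     cand_row("r2", "OT", "c1", 0L, "6M")), reads, g)
  expect_equal(cl$codes, c(".U....", ".M...."))
  expect_equal(cl$valid_score, c(6L, 6L))

  # mirrored rules in the G/A space: OB reads are reverse-complemented
  # before the column walk, so a Crick-strand methylated C shows as G over G
  gb <- c(c1 = "ACGGAT")
  # read from Crick over the full contig, Crick C opposite the G at pos 3
  # retained (methylated), the one opposite pos 2 converted
  crick <- revcomp("ACGGAT")       # ATCCGT
  crick_conv <- "ATCTGT"           # second Crick C (opposite pos 2) -> T
  reads_b <- tibble::tibble(read_id = "b1", seq = crick_conv)
  cl_b <- classify_alignments(cand_row("b1", "OB", "c1", 0L, "6M"),
                              reads_b, gb)
  expect_equal(cl_b$codes, "..UM..")

  # ordinary mismatch and the mismatch budget
  reads_x <- tibble::tibble(read_id = "x1", seq = "AAGGAT")
  cl_x <- classify_alignments(cand_row("x1", "OT", "c1", 0L, "6M"),
                              reads_x, g)
  expect_equal(cl_x$codes, ".x....")
  expect_equal(cl_x$valid_score, 5L - 2L)
  expect_equal(filter_alignments(cl_x, max_mismatch = 0)$reason,
               "mismatch-budget")
})

test_that("indels are penalized and coded consistently", {
  g <- c(c1 = "AAGGTTAAGG")
  # read skips the reference base at position 4 (deletion)
  reads <- tibble::tibble(read_id = "d1", seq = "AAGGTAAGG")
  cl <- classify_alignments(cand_row("d1", "OT", "c1", 0L, "4M1D5M"),
                            reads, g)
  expect_equal(nchar(cl$codes), 9L)
  expect_equal(cl$n_mismatch, 0L)
  # 9 good columns minus one length-1 gap (5 + 3)
  expect_equal(cl$valid_score, 9L - 8L)
  # insertion: extra read base is a coded mismatch column
  reads_i <- tibble::tibble(read_id = "i1", seq = "AAGGCTTAAGG")
  cl_i <- classify_alignments(cand_row("i1", "OT", "c1", 0L, "4M1I6M"),
                              reads_i, g)
  expect_equal(nchar(cl_i$codes), 11L)
  expect_equal(substr(cl_i$codes, 5, 5), "x")
  expect_error(
    classify_alignments(cand_row("i1", "OT", "c1", 0L, "4M"), reads_i, g),
    "inconsistent")
})

test_that("resolution deduplicates loci and calls unique/ambiguous/unmapped", {
  g <- c(c1 = "ACGGATTTACGGATTT")
  reads <- tibble::tibble(read_id = "r1", seq = "ACGGAT")
  # same locus reached twice (tier 1 OT, tier 2 OT) plus a distinct locus
  cands <- dplyr::bind_rows(
    cand_row("r1", "OT", "c1", 0L, "6M", tier = 1L),
    cand_row("r1", "OT", "c1", 0L, "6M", tier = 2L),
    cand_row("r1", "OT", "c1", 8L, "6M", tier = 1L))
  cl <- filter_alignments(classify_alignments(cands, reads, g))
  v <- resolve_reads(cl, reads)
  expect_equal(v$status, "ambiguous") # two loci tie at 6
  expect_equal(v$n_alternates, 1L)
  expect_equal(nrow(v$alternates[[1]]), 1L)

  # distinct loci with different scores: unique at the better one
  g2 <- c(c1 = "ACGGATTTACGGTTTT")
  cl2 <- filter_alignments(classify_alignments(
    dplyr::bind_rows(cand_row("r1", "OT", "c1", 0L, "6M"),
                     cand_row("r1", "OT", "c1", 8L, "6M")), reads, g2))
  v2 <- resolve_reads(cl2, reads)
  expect_equal(v2$status, "unique")
  expect_equal(v2$start, 0L)

  # no surviving candidate: unmapped with the rejection reason surfaced
  g3 <- c(c1 = "ATGGATTT")
  reads3 <- tibble::tibble(read_id = "r1", seq = "ACGGAT")
  cl3 <- filter_alignments(classify_alignments(
    cand_row("r1", "OT", "c1", 0L, "6M"), reads3, g3))
  expect_false(cl3$kept) # read C over ref T
  v3 <- resolve_reads(cl3, reads3)
  expect_equal(v3$status, "unmapped")
  expect_error(resolve_reads(dplyr::mutate(cl, read_id = c("a", "b", "a")),
                             NULL),
               NA) # distinct ids resolve independently, no error

  # duplicate-set resolution is a fixed point
  common <- setdiff(intersect(names(v), names(v$alternates[[1]])),
                    c("kept", "reason"))
  survivors <- dplyr::bind_rows(v$alternates[[1]][, common], v[, common])
  v_again <- resolve_reads(survivors, reads)
  expect_equal(v_again$status, v$status)
  expect_equal(v_again$start, v$start)
})

test_that("enlarging the SNP set never hurts a candidate", {
  withr::with_seed(71, {
    g <- c(c1 = random_seq(500))
    for (case in 1:25) {
      s <- sample(0:(500 - 40), 1)
      read <- substr(g, s + 1, s + 40)
      # plant 2 substitutions
      for (p in sample(1:40, 2)) {
        substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(read, p, p)), 1)
      }
      reads <- tibble::tibble(read_id = "r", seq = read)
      cand <- cand_row("r", "OT", "c1", as.integer(s), "40M")
      base <- classify_alignments(cand, reads, g)
      # SNP set explaining every observed substitution at this locus
      rd <- strsplit(read, "")[[1]]
      rf <- strsplit(substr(g, s + 1, s + 40), "")[[1]]
      mm <- which(rd != rf)
      snps <- tibble::tibble(contig = "c1", pos = s + mm - 1L,
                             ref = rf[mm], alt = rd[mm])
      excused <- classify_alignments(cand, reads, g, snps)
      expect_gte(excused$valid_score, base$valid_score)
      expect_equal(excused$n_invalid, 0L)
      if (filter_alignments(base)$kept) {
        expect_true(filter_alignments(excused)$kept)
      }
    }
  })
})

test_that("decoy loci with pre-converted cytosines are always rejected", {
  # for a read carrying methylated (retained) Cs, a decoy locus identical
  # except T at those positions is chemically impossible; the true locus
  # must survive and the decoy must fall
  withr::with_seed(72, {
    n_cases <- 100
    for (case in seq_len(n_cases)) {
      core <- random_seq(60)
      while (!grepl("C", core)) core <- random_seq(60)
      cpos <- which(strsplit(core, "")[[1]] == "C")
      meth <- sample(cpos, max(1, length(cpos) %/% 3))
      read <- core
      for (p in setdiff(cpos, meth)) substr(read, p, p) <- "T"
      decoy <- convert_c2t(core)
      g <- c(c1 = paste0(core, strrep("A", 10), decoy))
      reads <- tibble::tibble(read_id = "r", seq = read)
      cl <- filter_alignments(classify_alignments(
        dplyr::bind_rows(cand_row("r", "OT", "c1", 0L, "60M"),
                         cand_row("r", "OT", "c1", 70L, "60M")),
        reads, g), max_invalid = 0)
      expect_true(cl$kept[1])
      expect_false(cl$kept[2])
      expect_equal(cl$reason[2], "bisulfite-invalid")
    }
  })
})
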