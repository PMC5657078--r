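# Tiny references used across aligner tests.
tiny_ref <- function(seqs) build_index(prepare_reference(seqs), 4L)

test_that("build_index enumerates k-mers and respects the N rule", {
  ref <- prepare_reference(c(c1 = "ATGTA"))
  ref <- build_index(ref, 3L)
  idx <- ref$index[["CT.3"]]
  expect_setequal(ls(idx$env), c("ATG", "TGT", "GTA"))
  expect_equal(idx$off[idx$env[["TGT"]]], 1L)

  ref2 <- build_index(prepare_reference(c(c1 = "ANGT")), 2L)
  idx2 <- ref2$index[["CT.2"]]
  expect_false(any(c("AN", "NG") %in% ls(idx2$env)))
  expect_true("GT" %in% ls(idx2$env))

  expect_error(build_index(prepare_reference(c(c1 = "ACG")), 10L),
               "shortest contig")
  expect_error(prepare_reference(character(0)), "no contigs")
})

test_that("seed_and_extend finds the placements brute force confirms", {
  # contig whose CT copy is ATGGATTTGT; brute force over all 5 offsets of
  # the 10-base contig says offset 0 is the unique 0-mismatch placement
  ref <- tiny_ref(c(c1 = "ATGGATTTGT"))
  p <- align_params(k = 8, max_mismatches = 0)
  p$k <- 4L # short test sequences; k floor is enforced at construction
  ref <- build_index(ref, 4L)
  orc <- oracle_best_score("ATGGAT", "ATGGATTTGT")
  expect_equal(orc$offsets, 0L)
  expect_equal(orc$mm, 0L)
  cand <- seed_and_extend("ATGGAT", "CT", "forward", ref, p, "r1")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 0L)
  expect_equal(cand$cigar, "6M")
  expect_equal(cand$conv_score, orc$score)

  # two-repeat contig: brute force finds two equal-best offsets; the
  # aligner reports both, tied on score, ordered by start
  rep_ref <- tiny_ref(c(c1 = "ATGGATAACCATGGATAACC"))
  orc2 <- oracle_best_score("ATGGAT",
                            convert_c2t("ATGGATAACCATGGATAACC"))
  expect_equal(orc2$offsets, c(0L, 10L))
  cand2 <- seed_and_extend("ATGGAT", "CT", "forward", rep_ref, p, "r1")
  expect_equal(cand2$start, c(0L, 10L))
  expect_equal(cand2$conv_score, rep(orc2$score, 2))

  # all-N read: no seed can anchor
  expect_warning(out <- seed_and_extend("NNN", "CT", "forward", ref, p),
                 "shorter than seed")
  expect_equal(nrow(out), 0)
  cand3 <- seed_and_extend("NNNNNNNN", "CT", "forward", ref, p)
  expect_equal(nrow(cand3), 0)
})

test_that("gapped extension recovers a deletion the strict tier cannot", {
  g <- withr::with_seed(5, random_seq(400))
  # read copies a 41-base window with the base at window offset 20 deleted
  win <- substr(convert_c2t(g), 101, 141)
  read <- paste0(substr(win, 1, 20), substr(win, 22, 41))
  ref <- build_index(prepare_reference(c(c1 = g)), 12L)
  strictp <- align_params(k = 12, max_mismatches = 2, allow_gaps = FALSE)
  perm <- align_params(k = 12, max_mismatches = 5, allow_gaps = TRUE)
  cand_s <- seed_and_extend(read, "CT", "forward", ref, strictp)
  cand_p <- seed_and_extend(read, "CT", "forward", ref, perm)
  expect_false(100 %in% cand_s$start && any(grepl("D", cand_s$cigar)))
  hit <- cand_p[cand_p$start == 100, ]
  expect_equal(nrow(hit), 1)
  # one single-base deletion; its exact placement may shift within a run of
  # identical bases without changing the score
  expect_match(hit$cigar, "^[0-9]+M1D[0-9]+M$")
  # 40 matches, one deletion of length 1: 40 - (5 + 3)
  expect_equal(hit$conv_score, 32L)
})

test_that("strand tasks route simulated reads to their true loci", {
  cfg <- sim_config(genome_length = 4000, n_reads = 40, read_length = 60,
                    conversion_failure = 0, error_rate_start = 0,
                    error_rate_end = 0, directional = FALSE, seed = 21)
  d <- simulate_dataset(cfg)
  conv_ref <- build_index(prepare_reference(d$genome), 20L)
  p <- strict_params()
  for (i in seq_len(nrow(d$reads))) {
    cand <- align_read_all_tasks(d$reads$read_id[i], d$reads$seq[i],
                                 conv_ref, p, "non-directional")
    at_locus <- cand[cand$start == d$truth$start[i] &
                       cand$task == d$truth$task[i], ]
    expect_gte(nrow(at_locus), 1)
  }
  # a CTOB-origin read is invisible to directional search at its locus
  ctob <- which(d$truth$task == "CTOB")[1]
  expect_false(is.na(ctob))
  cand_dir <- align_read_all_tasks(d$reads$read_id[ctob], d$reads$seq[ctob],
                                   conv_ref, p, "directional")
  expect_false(any(cand_dir$start == d$truth$start[ctob] &
                     cand_dir$task == d$truth$task[ctob]))
})

test_that("tier 2 runs only for tier-1-unmapped reads and never mixes", {
  g <- withr::with_seed(31, random_seq(3000))
  conv_ref <- prepare_reference(c(c1 = g))
  clean <- substr(g, 501, 575)
  noisy <- clean
  # plant 3 substitutions: above the strict budget (2), within permissive (5)
  for (p in c(10, 30, 50)) {
    old <- substr(noisy, p, p)
    substr(noisy, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  unalignable <- withr::with_seed(32, random_seq(75))
  reads <- tibble::tibble(read_id = c("clean", "noisy", "junk"),
                          seq = c(clean, noisy, unalignable))
  cands <- two_tier_align(reads, conv_ref, mode = "directional")
  expect_true(all(cands$tier[cands$read_id == "clean"] == 1L))
  noisy_c <- cands[cands$read_id == "noisy", ]
  expect_true(all(noisy_c$tier == 2L))
  expect_true(500 %in% noisy_c$start)
  expect_equal(nrow(cands[cands$read_id == "junk", ]), 0)
  expect_false(any(tapply(cands$tier, cands$read_id,
                          function(x) length(unique(x))) > 1))

  # tier monotonicity: disabling tier 2 never changes tier-1 output
  cands1 <- two_tier_align(reads, conv_ref, mode = "directional",
                           tier2 = FALSE)
  expect_equal(cands1, cands[cands$tier == 1L, ])

  # strict preset must not exceed the permissive one
  expect_error(
    two_tier_align(reads, conv_ref, strict = permissive_params(),
                   permissive = strict_params()),
    "more permissive")
})

test_that("identical inputs give byte-identical candidate lists", {
  cfg <- sim_config(genome_length = 3000, n_reads = 25, seed = 9)
  d <- simulate_dataset(cfg)
  conv_ref <- prepare_reference(d$genome)
  a <- two_tier_align(d$reads, conv_ref, mode = "non-directional")
  b <- two_tier_align(d$reads, conv_ref, mode = "non-directional")
  expect_identical(a, b)
})

test_that("mates pair only with consistent geometry inside the window", {
  cfg <- sim_config(genome_length = 6000, n_reads = 12, paired = TRUE,
                    insert_mean = 275, insert_sd = 0,
                    conversion_failure = 0, error_rate_start = 0,
                    error_rate_end = 0, seed = 33)
  d <- simulate_dataset(cfg)
  conv_ref <- build_index(prepare_reference(d$genome), 20L)
  p <- strict_params()
  r1 <- d$reads[d$reads$mate == 0L, ][1, ]
  r2 <- d$reads[d$reads$mate == 1L, ][1, ]
  c1 <- align_read_all_tasks(r1$read_id, r1$seq, conv_ref, p, "directional")
  c2 <- align_read_all_tasks(r2$read_id, r2$seq, conv_ref, p, "directional")
  pairs <- pair_mates(c1, c2, 100, 500)
  t1 <- d$truth[d$truth$mate == 0L, ][1, ]
  t2 <- d$truth[d$truth$mate == 1L, ][1, ]
  expect_gte(nrow(pairs), 1)
  expect_equal(pairs$start1[1], t1$start)
  expect_equal(pairs$start2[1], t2$start)
  expect_equal(pairs$span[1], 275L)
  # window excluding the true span: no proper pair
  expect_equal(nrow(pair_mates(c1, c2, 100, 150)), 0)
  # unmapped mate: empty pair list
  expect_equal(nrow(pair_mates(c1, c2[0, ], 100, 500)), 0)
})
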