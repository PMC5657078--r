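#' Simulation configuration
#'
#' Defines the study conditions for the bundled bisulfite read simulator:
#' Illumina-like short reads (75 or 100 bp) drawn uniformly from a random
#' genome, bisulfite-converted with a small conversion-failure rate
#' (unmethylated cytosines that escape conversion; 1% by default) and
#' per-cycle substitution errors interpolated linearly across the read.
#' Methylation is planted independently per cytosine at per-context levels;
#' the defaults (CpG 0.70, CHG and CHH 0.02) are mammalian-like stand-ins.
#'
#' @param genome_length,gc_fraction Simulated genome size and GC content.
#' @param n_reads Number of reads (read pairs when `paired`).
#' @param read_length Read length in bases.
#' @param paired Generate mate pairs.
#' @param insert_mean,insert_sd Template length distribution (normal,
#'   truncated below at `read_length`).
#' @param level_cpg,level_chg,level_chh Per-context methylation
#'   probabilities.
#' @param conversion_failure Probability an unmethylated C escapes
#'   conversion (retained as C but recorded unmethylated in truth).
#' @param error_rate_start,error_rate_end Per-base substitution error rate
#'   at the first and last sequencing cycle.
#' @param directional Restrict read origin to the OT/OB strands.
#' @param seed Integer seed; fully determines the output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 50000L, gc_fraction = 0.42,
                       n_reads = 2000L, read_length = 75L, paired = FALSE,
                       insert_mean = 250, insert_sd = 25,
                       level_cpg = 0.7, level_chg = 0.02, level_chh = 0.02,
                       conversion_failure = 0.01,
                       error_rate_start = 0.001, error_rate_end = 0.006,
                       directional = TRUE, seed = 1L) {
  probs <- c(gc_fraction, level_cpg, level_chg, level_chh,
             conversion_failure, error_rate_start, error_rate_end)
  stopifnot(all(probs >= 0 & probs <= 1), genome_length >= 1,
            read_length >= 1, read_length <= genome_length, n_reads >= 0,
            insert_sd >= 0)
  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction, n_reads = as.integer(n_reads),
         read_length = as.integer(read_length), paired = isTRUE(paired),
         insert_mean = insert_mean, insert_sd = insert_sd,
         level_cpg = level_cpg, level_chg = level_chg,
         level_chh = level_chh, conversion_failure = conversion_failure,
         error_rate_start = error_rate_start,
         error_rate_end = error_rate_end, directional = isTRUE(directional),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`; deterministic per seed.
#'
#' @param length Genome length in bases.
#' @param gc_fraction GC content.
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return Named character vector of one contig.
#' @export
simulate_genome <- function(length, gc_fraction = 0.42, seed = 1L,
                            contig = "sim1") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  bases <- withr::with_seed(seed, sample(
    c("A", "T", "G", "C"), length, replace = TRUE,
    prob = c((1 - gc_fraction) / 2, (1 - gc_fraction) / 2,
             gc_fraction / 2, gc_fraction / 2)))
  stats::setNames(paste(bases, collapse = ""), contig)
}

#' Plant methylation states on every cytosine
#'
#' Each cytosine — C on the Watson strand, G (a Crick-strand C) on the
#' Crick strand — is independently methylated with its context's
#' probability; context comes from the original reference trinucleotide.
#'
#' @param genome Genome to annotate.
#' @param level_cpg,level_chg,level_chh Context methylation probabilities.
#' @param seed Integer seed.
#' @return Tibble `contig`, `pos` (0-based), `strand`, `context`,
#'   `methylated`.
#' @export
assign_methylation <- function(genome, level_cpg = 0.7, level_chg = 0.02,
                               level_chh = 0.02, seed = 1L) {
  genome <- validate_genome(genome)
  rows <- lapply(names(genome), function(cn) {
    ch <- strsplit(genome[[cn]], "")[[1]]
    plus <- which(ch == "C") - 1L
    minus <- which(ch == "G") - 1L
    tibble::tibble(
      contig = cn,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))))
  })
  sites <- dplyr::bind_rows(rows)
  sites$context <- cytosine_context(genome, sites$contig, sites$pos,
                                    sites$strand)
  p <- c(CpG = level_cpg, CHG = level_chg, CHH = level_chh)[sites$context]
  sites$methylated <- withr::with_seed(
    seed, stats::runif(nrow(sites)) < p)
  dplyr::arrange(sites, .data$contig, .data$pos)
}

# Fast per-contig lookup vectors: TRUE methylated, FALSE unmethylated,
# NA not a cytosine site on that strand.
state_vectors <- function(genome, states) {
  out <- list()
  for (cn in names(genome)) {
    L <- nchar(genome[[cn]])
    plus <- rep(NA, L); minus <- rep(NA, L)
    st <- states[states$contig == cn, , drop = FALSE]
    sp <- st[st$strand == "+", ]; sm <- st[st$strand == "-", ]
    plus[sp$pos + 1L] <- sp$methylated
    minus[sm$pos + 1L] <- sm$methylated
    out[[cn]] <- list(plus = plus, minus = minus)
  }
  out
}

comp_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Bisulfite-convert one fragment given per-base methylation states
# (fragment orientation), returning the product and methylated offsets.
bisulfite_product <- function(chars, meth, failure) {
  cpos <- which(chars == "C")
  if (!length(cpos)) {
    return(list(chars = chars, meth_offsets = integer(0)))
  }
  m <- meth[cpos]
  m[is.na(m)] <- FALSE # C sites always have a state; guard anyway
  escaped <- !m & stats::runif(length(cpos)) < failure
  convert <- !m & !escaped
  chars[cpos[convert]] <- "T"
  list(chars = chars, meth_offsets = cpos[m] - 1L)
}

#' Simulate bisulfite reads with ground truth
#'
#' Draws each read (or pair) from a uniform random locus and strand task —
#' OT/OB only when directional, all four otherwise. The fragment is taken
#' from the task's physical strand, every unmethylated C on that strand is
#' converted to T except with probability `conversion_failure` (escape:
#' retained as C, recorded unmethylated in truth), methylated Cs are
#' retained, and per-cycle substitution errors are applied at a linearly
#' interpolated rate. PCR-complement tasks (CTOT/CTOB) reverse-complement
#' the converted product. Paired mode draws the template length from the
#' configured normal distribution (truncated at `read_length`) and places
#' the mate pair as forward-task-left / partner-task-right.
#'
#' @param genome Genome from [simulate_genome()] (or any genome).
#' @param states Methylation states from [assign_methylation()].
#' @param config A [sim_config()].
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`, `mate`) and
#'   `truth` (tibble `read_id`, `mate`, `contig`, `start` 0-based, `task`,
#'   `methylated_offsets` comma-joined read offsets).
#' @export
simulate_reads <- function(genome, states, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- validate_genome(genome)
  sv <- state_vectors(genome, states)
  withr::with_seed(config$seed, simulate_reads_impl(genome, sv, config))
}

simulate_reads_impl <- function(genome, sv, config) {
  rl <- config$read_length
  n <- config$n_reads
  tasks <- if (config$directional) c("OT", "OB") else
    c("OT", "OB", "CTOT", "CTOB")
  partner <- c(OT = "OB", OB = "OT", CTOT = "CTOB", CTOB = "CTOT")
  clens <- nchar(genome)
  contig_of <- sample(names(genome), n, replace = TRUE,
                      prob = clens / sum(clens))
  task_of <- sample(tasks, n, replace = TRUE)
  err_rate <- seq(config$error_rate_start, config$error_rate_end,
                  length.out = rl)

  one_read <- function(cn, s, task) {
    chars <- strsplit(substr(genome[[cn]], s + 1L, s + rl), "")[[1]]
    phys_plus <- task %in% c("OT", "CTOT")
    if (phys_plus) {
      meth <- sv[[cn]]$plus[s + seq_len(rl)]
      bp <- bisulfite_product(chars, meth, config$conversion_failure)
      prod <- bp$chars; offs <- bp$meth_offsets
    } else {
      crick <- rev(unname(comp_chars[chars]))
      # crick offset j-1 <-> watson position s + rl - j
      meth <- sv[[cn]]$minus[s + rl - seq_len(rl) + 1L]
      bp <- bisulfite_product(crick, meth, config$conversion_failure)
      prod <- bp$chars; offs <- bp$meth_offsets
    }
    if (task %in% c("CTOT", "CTOB")) {
      prod <- rev(unname(comp_chars[prod]))
      offs <- rl - 1L - offs
    }
    err <- stats::runif(rl) < err_rate
    if (any(err)) {
      for (p in which(err)) {
        prod[p] <- sample(setdiff(c("A", "C", "G", "T"), prod[p]), 1L)
      }
    }
    list(seq = paste(prod, collapse = ""),
         offsets = paste(sort(offs), collapse = ","))
  }

  if (!config$paired) {
    starts <- unname(vapply(clens[contig_of] - rl,
                            function(m) sample.int(m + 1L, 1L) - 1L,
                            integer(1)))
    seqs <- character(n); offsets <- character(n)
    for (i in seq_len(n)) {
      r <- one_read(contig_of[i], starts[i], task_of[i])
      seqs[i] <- r$seq; offsets[i] <- r$offsets
    }
    ids <- paste0("sim", seq_len(n))
    reads <- tibble::tibble(read_id = ids, seq = seqs,
                            qual = strrep("I", rl), mate = NA_integer_)
    truth <- tibble::tibble(read_id = ids, mate = NA_integer_,
                            contig = contig_of, start = starts,
                            task = task_of, methylated_offsets = offsets)
    return(list(reads = reads, truth = truth))
  }

  ids <- paste0("sim", seq_len(n))
  r_id <- character(2 * n); r_seq <- character(2 * n)
  r_mate <- integer(2 * n)
  t_contig <- character(2 * n); t_start <- integer(2 * n)
  t_task <- character(2 * n); t_off <- character(2 * n)
  for (i in seq_len(n)) {
    cn <- contig_of[i]; L <- clens[[cn]]
    ins <- NA_integer_
    for (try in 1:100) {
      cand <- as.integer(round(stats::rnorm(1, config$insert_mean,
                                            config$insert_sd)))
      if (cand >= rl && cand <= L) { ins <- cand; break }
    }
    if (is.na(ins)) stop("could not sample an insert length within bounds",
                         call. = FALSE)
    s <- sample.int(L - ins + 1L, 1L) - 1L
    t1 <- task_of[i]; t2 <- partner[[t1]]
    fwd_first <- task_orientation(t1) == "forward"
    s1 <- if (fwd_first) s else s + ins - rl
    s2 <- if (fwd_first) s + ins - rl else s
    r1 <- one_read(cn, s1, t1)
    r2 <- one_read(cn, s2, t2)
    j <- 2L * i - 1L
    r_id[j:(j + 1L)] <- ids[i]
    r_seq[j] <- r1$seq; r_seq[j + 1L] <- r2$seq
    r_mate[j] <- 0L; r_mate[j + 1L] <- 1L
    t_contig[j:(j + 1L)] <- cn
    t_start[j] <- s1; t_start[j + 1L] <- s2
    t_task[j] <- t1; t_task[j + 1L] <- t2
    t_off[j] <- r1$offsets; t_off[j + 1L] <- r2$offsets
  }
  list(
    reads = tibble::tibble(read_id = r_id, seq = r_seq,
                           qual = strrep("I", rl), mate = r_mate),
    truth = tibble::tibble(read_id = r_id, mate = r_mate, contig = t_contig,
                           start = t_start, task = t_task,
                           methylated_offsets = t_off)
  )
}

#' Simulate a complete dataset
#'
#' Convenience wrapper deriving sub-seeds from `config$seed` for the
#' genome, the methylation states and the reads, so one seed determines the
#' whole dataset.
#'
#' @param config A [sim_config()].
#' @return List `genome`, `states`, `reads`, `truth`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config$genome_length, config$gc_fraction,
                            seed = config$seed)
  states <- assign_methylation(genome, config$level_cpg, config$level_chg,
                               config$level_chh, seed = config$seed + 1L)
  sim <- simulate_reads(genome, states, config)
  c(list(genome = genome, states = states), sim)
}

#' Write simulator ground truth as TSV
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a ground-truth TSV
#'
#' @param path Path written by [write_truth()].
#' @return Truth tibble.
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                          colClasses = c(methylated_offsets = "character"))
  tibble::as_tibble(df)
}

#' Score mapping results against simulator truth
#'
#' Computes the two evaluation metrics: mappability — the percentage of
#' reads uniquely mapped over all reads — and correct mappability, the
#' percentage of reads whose unique mapping is correct. A unique verdict is
#' correct when the contig matches, the reported start is within
#' `tolerance` bases of the true start, and the reported original strand
#' equals the truth task's strand (a CTOT report for an OT read is the same
#' original strand, hence correct).
#'
#' @param verdicts Verdict tibble (or `bs_alignment`).
#' @param truth Truth tibble.
#' @param tolerance Allowed start offset in bases (default 0, exact).
#' @return A `mapping_stats` object; `glance()` gives the one-row tibble
#'   (`n_reads`, `n_unique`, `n_unique_correct`, `mappability`,
#'   `correct_mappability`, `precision`, all percentages on the 0-100
#'   scale).
#' @export
evaluate_mapping <- function(verdicts, truth, tolerance = 0L) {
  if (inherits(verdicts, "bs_alignment")) verdicts <- verdicts$verdicts
  vu <- read_uid(verdicts); tu <- read_uid(truth)
  if (any(!(vu %in% tu))) {
    stop("verdict for unknown read '", vu[!(vu %in% tu)][1], "'",
         call. = FALSE)
  }
  m <- match(vu, tu)
  uniq <- verdicts$status == "unique"
  correct <- uniq &
    verdicts$contig == truth$contig[m] &
    abs(verdicts$start - truth$start[m]) <= tolerance &
    task_original_strand(verdicts$task) ==
      task_original_strand(truth$task[m])
  correct[is.na(correct)] <- FALSE
  n_reads <- nrow(truth)
  stats <- list(n_reads = n_reads, n_unique = sum(uniq),
                n_unique_correct = sum(correct),
                mappability = 100 * sum(uniq) / n_reads,
                correct_mappability = 100 * sum(correct) / n_reads,
                precision = if (sum(uniq) > 0) {
                  100 * sum(correct) / sum(uniq)
                } else NA_real_)
  structure(stats, class = "mapping_stats")
}

#' @export
glance.mapping_stats <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.mapping_stats <- function(x, ...) {
  tibble::tibble(metric = names(unclass(x)),
                 value = as.numeric(unclass(x)))
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf(
    "<mapping_stats> %d reads: mappability %.1f%%, correct %.1f%% (%d/%d unique correct)\n",
    x$n_reads, x$mappability, x$correct_mappability, x$n_unique_correct,
    x$n_unique))
  invisible(x)
}
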