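#' Classify candidate alignments under bisulfite chemistry
#'
#' Re-evaluates each converted-space candidate on the ORIGINAL read and
#' ORIGINAL reference. Bisulfite conversion is one-directional — an
#' unmethylated C becomes T, but a T can never become C — so after
#' three-letter alignment every column can be classified:
#'
#' * `.` matching non-cytosine base
#' * `M` reference C, read C: methylated cytosine (read C over ref G in the
#'   G-to-A space)
#' * `U` reference C, read T: unmethylated, converted (ref G / read A in the
#'   G-to-A space)
#' * `x` ordinary mismatch (insertions are coded `x` too)
#' * `X` bisulfite-invalid match: read C over reference T (read G over ref A
#'   in the G-to-A space) — impossible under the chemistry, the signature of
#'   a false mapping created by the conversion
#' * `S` a mismatch (including `X`) excused because the SNP set contains a
#'   variant whose alt allele explains the observed read base at that
#'   position
#'
#' Codes are stored in reference orientation (for reverse-strand tasks the
#' read is reverse-complemented before the column walk), column-aligned with
#' the SAM SEQ field. Deleted reference bases contribute no code but are
#' penalized. The validated score is `+1` per `.`/`M`/`U`/`S`, `-2` per `x`,
#' `-8` per `X`, minus `gap_open + gap_extend * length` per gap run: a
#' chemistry-violating column is penalized far harder than an ordinary
#' mismatch so false mappings lose even when tolerated.
#'
#' @param candidates Candidate tibble from [two_tier_align()] (columns
#'   `read_id`, `task`, `contig`, `start`, `cigar`, `conv_score`, `tier`;
#'   optional `mate`).
#' @param reads Reads tibble supplying the original `seq` per `read_id` (and
#'   `mate`).
#' @param genome The original (unconverted) genome.
#' @param snps Optional SNP tibble from [read_snps()].
#' @param gap_open,gap_extend Gap penalties applied to the validated score.
#' @return The candidate tibble with `codes`, `n_invalid`, `n_mismatch`,
#'   `n_snp_excused`, `valid_score` columns added.
#' @export
classify_alignments <- function(candidates, reads, genome, snps = NULL,
                                gap_open = 5L, gap_extend = 3L) {
  genome <- validate_genome(genome)
  snp_keys <- if (!is.null(snps) && nrow(snps) > 0) {
    paste(snps$contig, snps$pos, snps$ref, snps$alt)
  } else character(0)
  seq_by_uid <- stats::setNames(reads$seq, read_uid(reads))
  cand_uid <- read_uid(candidates)
  n <- nrow(candidates)
  codes <- character(n); n_x <- integer(n); n_xx <- integer(n)
  n_s <- integer(n); vscore <- integer(n)
  for (i in seq_len(n)) {
    seq_i <- seq_by_uid[[cand_uid[i]]]
    if (is.null(seq_i) || is.na(seq_i)) {
      stop("candidate read '", cand_uid[i], "' absent from reads",
           call. = FALSE)
    }
    cl <- classify_one(seq_i, candidates$task[i], candidates$contig[i],
                       candidates$start[i], candidates$cigar[i],
                       genome, snp_keys, gap_open, gap_extend)
    codes[i] <- cl$codes; n_x[i] <- cl$n_mismatch; n_xx[i] <- cl$n_invalid
    n_s[i] <- cl$n_snp; vscore[i] <- cl$valid_score
  }
  dplyr::mutate(candidates, codes = codes, n_invalid = n_xx,
                n_mismatch = n_x, n_snp_excused = n_s, valid_score = vscore)
}

read_uid <- function(tbl) {
  mate <- if ("mate" %in% names(tbl)) tbl$mate else
    rep(NA_integer_, nrow(tbl))
  ifelse(is.na(mate), tbl$read_id, paste0(tbl$read_id, "/", mate + 1L))
}

classify_one <- function(seq, task, contig, start, cigar, genome, snp_keys,
                         gap_open, gap_extend) {
  orientation <- task_orientation(task)
  space <- ifelse(task %in% c("OT", "CTOT"), "CT", "GA")
  oriented <- if (orientation == "reverse") revcomp(seq) else seq
  ops <- parse_cigar(cigar)
  L <- nchar(oriented)
  if (sum(ops$len[ops$op %in% c("M", "I")]) != L) {
    stop("CIGAR '", cigar, "' inconsistent with read length ", L,
         call. = FALSE)
  }
  span <- sum(ops$len[ops$op %in% c("M", "D")])
  if (start < 0 || start + span > nchar(genome[[contig]])) {
    stop("alignment at ", contig, ":", start, " exceeds contig bounds",
         call. = FALSE)
  }
  rd <- strsplit(oriented, "")[[1]]
  gap_pen <- 0L
  if (length(ops$op) == 1L && ops$op == "M") {
    rf <- strsplit(substr(genome[[contig]], start + 1L, start + L), "")[[1]]
    rpos <- start + seq_len(L) - 1L
  } else {
    rf <- character(L); rpos <- integer(L)
    ins <- logical(L)
    ri <- 0L; gi <- start
    for (j in seq_along(ops$op)) {
      len <- ops$len[j]
      switch(ops$op[j],
        M = {
          rf[ri + seq_len(len)] <-
            strsplit(substr(genome[[contig]], gi + 1L, gi + len), "")[[1]]
          rpos[ri + seq_len(len)] <- gi + seq_len(len) - 1L
          ri <- ri + len; gi <- gi + len
        },
        I = {
          ins[ri + seq_len(len)] <- TRUE
          rpos[ri + seq_len(len)] <- NA_integer_
          ri <- ri + len
          gap_pen <- gap_pen + gap_open + gap_extend * len
        },
        D = {
          gi <- gi + len
          gap_pen <- gap_pen + gap_open + gap_extend * len
        })
    }
    rf[ins] <- "-" # insertion columns have no reference base
  }
  code <- classify_columns(rf, rd, space)
  if (length(snp_keys)) {
    cand <- which(code %in% c("x", "X") & rf != "-" & !is.na(rpos))
    if (length(cand)) {
      hit <- paste(contig, rpos[cand], rf[cand], rd[cand]) %in% snp_keys
      code[cand[hit]] <- "S"
    }
  }
  good <- sum(code %in% c(".", "M", "U", "S"))
  nx <- sum(code == "x"); nX <- sum(code == "X"); nS <- sum(code == "S")
  list(codes = paste(code, collapse = ""),
       n_mismatch = nx, n_invalid = nX, n_snp = nS,
       valid_score = good - 2L * nx - 8L * nX - gap_pen)
}

# Per-column bisulfite code; rf == "-" marks insertion columns (always 'x').
classify_columns <- function(rf, rd, space) {
  code <- rep("x", length(rf))
  if (space == "CT") {
    code[rf == "C" & rd == "C"] <- "M"
    code[rf == "C" & rd == "T"] <- "U"
    code[rf == "T" & rd == "C"] <- "X"
    code[rf == rd & rf != "C" & rf != "N"] <- "."
  } else {
    code[rf == "G" & rd == "G"] <- "M"
    code[rf == "G" & rd == "A"] <- "U"
    code[rf == "A" & rd == "G"] <- "X"
    code[rf == rd & rf != "G" & rf != "N"] <- "."
  }
  code
}

#' Filter classified alignments on chemistry and mismatch budgets
#'
#' Rejects an alignment as `"bisulfite-invalid"` when its count of
#' impossible columns (`X`) exceeds `max_invalid` (default 0: a single read
#' C over reference T is disqualifying, since T cannot convert to C), and as
#' `"mismatch-budget"` when ordinary mismatches (`x`) exceed `max_mismatch`.
#' SNP-excused columns (`S`) count against neither budget.
#'
#' @param classified Output of [classify_alignments()].
#' @param max_invalid Maximum tolerated `X` columns (default 0).
#' @param max_mismatch Maximum tolerated `x` columns (default 3).
#' @return `classified` with logical `kept` and character `reason`
#'   (`NA` when kept) columns.
#' @export
filter_alignments <- function(classified, max_invalid = 0L,
                              max_mismatch = 3L) {
  reason <- rep(NA_character_, nrow(classified))
  reason[classified$n_mismatch > max_mismatch] <- "mismatch-budget"
  reason[classified$n_invalid > max_invalid] <- "bisulfite-invalid"
  dplyr::mutate(classified, kept = is.na(reason), reason = reason)
}

#' Merge, deduplicate and resolve candidates to per-read verdicts
#'
#' The three-letter search can reach the same locus several times for one
#' read (e.g. through different tiers or through a task pair that collapses
#' to the same original strand); such repeats are duplicates — keyed by
#' (contig, start, original strand) — and only the best-scoring copy is
#' kept. After deduplication a read is `unique` iff exactly one candidate
#' attains the maximal validated score (with at least `min_score_gap` over
#' the runner-up), `ambiguous` when several tie, and `unmapped` when nothing
#' survives.
#'
#' @param classified Classified candidates that survived
#'   [filter_alignments()] (rows with `kept == FALSE` are dropped here).
#' @param reads Optional full reads tibble so reads without surviving
#'   candidates appear as `unmapped` verdicts (with their rejection reason
#'   when candidates existed).
#' @param min_score_gap Minimal score margin for a unique call (default 0).
#' @return A verdict tibble: one row per read with `status`, the best
#'   alignment's columns, and an `alternates` list-column holding the other
#'   equal-best alignments when ambiguous.
#' @export
resolve_reads <- function(classified, reads = NULL, min_score_gap = 0L) {
  surv <- if ("kept" %in% names(classified)) {
    classified[classified$kept, , drop = FALSE]
  } else classified
  if (!"mate" %in% names(surv)) surv$mate <- rep(NA_integer_, nrow(surv))
  uid <- read_uid(surv)
  groups <- split(seq_len(nrow(surv)), uid)
  ng <- length(groups)
  lead_idx <- integer(ng); status <- character(ng)
  n_alt <- integer(ng); alts <- vector("list", ng)
  strand_all <- task_original_strand(surv$task)
  key_all <- paste(surv$contig, surv$start, strand_all)
  task_rank <- match(surv$task, c("OT", "OB", "CTOT", "CTOB"))
  for (gi in seq_len(ng)) {
    ix <- groups[[gi]]
    # duplicates (same contig/start/original strand) keep the best copy;
    # locus keys in the ordering make tie-breaks order-independent
    o <- ix[order(-surv$valid_score[ix], surv$tier[ix], surv$contig[ix],
                  surv$start[ix], task_rank[ix])]
    o <- o[!duplicated(key_all[o])]
    vs <- surv$valid_score[o]
    best <- vs[1]
    top <- which(vs == best)
    second <- if (length(o) > length(top)) vs[length(top) + 1L] else -Inf
    status[gi] <- if (length(top) == 1L && best - second >= min_score_gap) {
      "unique"
    } else "ambiguous"
    lead_idx[gi] <- o[1]
    n_alt[gi] <- length(top) - 1L
    if (n_alt[gi] > 0L) alts[[gi]] <- surv[o[top[-1]], , drop = FALSE]
  }
  out <- surv[lead_idx, setdiff(names(surv), c("kept", "reason")),
              drop = FALSE]
  out$status <- status
  out$n_alternates <- n_alt
  out$alternates <- alts
  out <- dplyr::relocate(out, "status", .after = "mate")
  if (!is.null(reads)) {
    roster_uid <- read_uid(reads)
    missing <- !(roster_uid %in% names(groups))
    if (any(missing)) {
      mate <- if ("mate" %in% names(reads)) reads$mate else
        rep(NA_integer_, nrow(reads))
      unm <- tibble::tibble(
        read_id = reads$read_id[missing], mate = mate[missing],
        status = "unmapped", task = NA_character_, contig = NA_character_,
        start = NA_integer_, cigar = NA_character_, conv_score = NA_integer_,
        tier = NA_integer_, codes = NA_character_, n_invalid = NA_integer_,
        n_mismatch = NA_integer_, n_snp_excused = NA_integer_,
        valid_score = NA_integer_, n_alternates = 0L,
        alternates = vector("list", sum(missing))
      )
      out <- dplyr::bind_rows(out, unm)
    }
    out <- out[match(roster_uid, read_uid(out)), , drop = FALSE]
    if ("seq" %in% names(reads)) out$seq <- reads$seq
    if ("qual" %in% names(reads)) out$qual <- reads$qual
  }
  out
}

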