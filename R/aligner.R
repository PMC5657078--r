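#' Alignment parameter sets
#'
#' The mapper runs in two tiers. The strict tier mirrors a conservative
#' end-to-end short-read aligner: long seeds, a small converted-space
#' mismatch budget, no gaps. The permissive tier, applied only to reads the
#' strict tier leaves unmapped, mirrors a high-recall aligner: shorter
#' seeds, a larger mismatch budget, and gapped extension. Scoring in
#' converted space is `match_reward` per match, `-mismatch_penalty` per
#' mismatch, and `-(gap_open + gap_extend * length)` per gap run; a
#' candidate is kept when its score reaches the floor implied by
#' `max_mismatches` (i.e. `read_length * match_reward - max_mismatches *
#' (match_reward + mismatch_penalty)`).
#'
#' @param k Seed length in bases (>= 8). Seeds are placed non-overlapping at
#'   stride `k` from the read start, plus one final seed flush with the read
#'   end, so a clean seed exists whenever the mismatch count is below
#'   `floor(read_length / k)`.
#' @param max_mismatches Converted-space mismatch budget.
#' @param allow_gaps Whether extension may open insertions/deletions.
#' @param gap_open,gap_extend Gap penalties (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @param mismatch_penalty,match_reward Per-column scores.
#' @param band Half-width of the reference window slack used for gapped
#'   extension; bounds the largest recoverable gap.
#' @param max_candidates Per-read cap on reported candidates (best-scoring
#'   kept).
#' @return An `align_params` list.
#' @export
align_params <- function(k = 20L, max_mismatches = 2L, allow_gaps = FALSE,
                         gap_open = 5L, gap_extend = 3L,
                         mismatch_penalty = 2L, match_reward = 1L,
                         band = 8L, max_candidates = 10L) {
  stopifnot(k >= 8, max_mismatches >= 0, gap_open >= 0, gap_extend >= 0,
            mismatch_penalty >= 0, match_reward >= 1, band >= 1,
            max_candidates >= 1)
  p <- list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
            allow_gaps = isTRUE(allow_gaps), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            mismatch_penalty = as.integer(mismatch_penalty),
            match_reward = as.integer(match_reward), band = as.integer(band),
            max_candidates = as.integer(max_candidates))
  p$submat <- score_matrix(p$match_reward, p$mismatch_penalty)
  class(p) <- "align_params"
  p
}

#' @rdname align_params
#' @export
strict_params <- function() align_params(k = 20L, max_mismatches = 2L,
                                         allow_gaps = FALSE)

#' @rdname align_params
#' @export
permissive_params <- function() align_params(k = 12L, max_mismatches = 5L,
                                             allow_gaps = TRUE)

# ACGTN substitution matrix; N never rewards a match.
score_matrix <- function(match, mispen) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-mispen, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- -mispen
  m
}

#' Build k-mer indexes over the converted reference copies
#'
#' Indexes every k-mer of the C-to-T and G-to-A reference copies to its
#' (contig, 0-based offset) occurrences. K-mers containing `N` are excluded,
#' so `N` positions never anchor a seed. Indexes for several seed lengths
#' can coexist (the two tiers use different `k`).
#'
#' @param conv_ref A [prepare_reference()] object.
#' @param k Seed length; must not exceed the shortest contig.
#' @return `conv_ref` with the `CT` and `GA` indexes for this `k` filled in.
#' @export
build_index <- function(conv_ref, k) {
  stopifnot(inherits(conv_ref, "converted_reference"))
  k <- as.integer(k)
  if (k > min(nchar(conv_ref$original))) {
    stop("k = ", k, " exceeds the shortest contig (",
         min(nchar(conv_ref$original)), " bases)", call. = FALSE)
  }
  for (space in c("CT", "GA")) {
    key <- paste0(space, ".", k)
    if (is.null(conv_ref$index[[key]])) {
      conv_ref$index[[key]] <-
        kmer_index(if (space == "CT") conv_ref$ct else conv_ref$ga, k)
    }
  }
  conv_ref
}

kmer_index <- function(genome, k) {
  ci <- integer(0); off <- integer(0); km <- character(0)
  for (i in seq_along(genome)) {
    L <- nchar(genome[[i]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km_i <- substring(genome[[i]], starts, starts + k - 1L)
    keep <- !grepl("N", km_i, fixed = TRUE)
    km <- c(km, km_i[keep])
    off <- c(off, starts[keep] - 1L)
    ci <- c(ci, rep.int(i, sum(keep)))
  }
  env <- list2env(split(seq_along(km), km), envir = new.env(hash = TRUE))
  list(k = k, env = env, ci = ci, off = off, contigs = names(genome))
}

# Converted-space mismatch count; N mismatches everything, including N.
mismatch_count <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- as.raw(78L)
  sum(ra != rb) + sum(ra == n & rb == n)
}

#' Seed-and-extend alignment of one converted read
#'
#' Places non-overlapping seeds at stride `k` (plus one flush with the read
#' end), looks each seed up in the k-mer index of the requested reference
#' space, and extends every distinct candidate diagonal: ungapped by direct
#' column comparison, or (when `params$allow_gaps`) by gapped end-to-end
#' extension of the read against a reference window widened by
#' `params$band` on each side. The aligner itself never searches reverse
#' complements: `orientation = "reverse"` means the caller's strand task
#' requires the read string to be reverse-complemented before seeding, and
#' coordinates are reported against the forward reference.
#'
#' @param conv_read Converted read string (already C-to-T or G-to-A).
#' @param space `"CT"` or `"GA"`: which converted reference copy to search.
#' @param orientation `"forward"` or `"reverse"`.
#' @param conv_ref A [build_index()]-prepared reference.
#' @param params An [align_params()] object.
#' @param read_id Read identifier carried into the result.
#' @return A tibble of candidates: `read_id`, `contig`, `start` (0-based),
#'   `cigar` (`M`/`I`/`D` runs), `conv_score`, sorted by score (desc), then
#'   contig, then start, capped at `params$max_candidates`.
#' @export
seed_and_extend <- function(conv_read, space, orientation, conv_ref, params,
                            read_id = NA_character_) {
  res <- seed_and_extend_core(conv_read, space, orientation, conv_ref, params)
  tibble::tibble(read_id = read_id, contig = res$contig, start = res$start,
                 cigar = res$cigar, conv_score = res$score)
}

seed_and_extend_core <- function(conv_read, space, orientation, conv_ref,
                                 params) {
  empty <- list(contig = character(0), start = integer(0),
                cigar = character(0), score = integer(0))
  k <- params$k
  oriented <- if (orientation == "reverse") revcomp(conv_read) else conv_read
  L <- nchar(oriented)
  if (L < k) {
    warning("read shorter than seed length (", L, " < ", k, "); skipped",
            call. = FALSE)
    return(empty)
  }
  idx <- conv_ref$index[[paste0(space, ".", k)]]
  if (is.null(idx)) stop("index for space ", space, ", k = ", k,
                         " not built; call build_index()", call. = FALSE)
  seeds <- unique(c(seq(0L, L - k, by = k), L - k))
  hit_ci <- integer(0); hit_start <- integer(0)
  for (s in seeds) {
    kmer <- substr(oriented, s + 1L, s + k)
    if (grepl("N", kmer, fixed = TRUE)) next
    rows <- idx$env[[kmer]]
    if (is.null(rows)) next
    hit_ci <- c(hit_ci, idx$ci[rows])
    hit_start <- c(hit_start, idx$off[rows] - s)
  }
  if (!length(hit_ci)) return(empty)
  ref_all <- if (space == "CT") conv_ref$ct else conv_ref$ga
  clens <- conv_ref$lens %||% nchar(ref_all)
  ok <- hit_start >= 0L & hit_start + L <= clens[hit_ci]
  hit_ci <- hit_ci[ok]; hit_start <- hit_start[ok]
  if (!length(hit_ci)) return(empty)
  dup <- duplicated(hit_ci * 1e9 + hit_start)
  hit_ci <- hit_ci[!dup]; hit_start <- hit_start[!dup]

  floor_score <- L * params$match_reward -
    params$max_mismatches * (params$match_reward + params$mismatch_penalty)
  out_ci <- integer(0); out_start <- integer(0)
  out_cigar <- character(0); out_score <- integer(0)
  for (j in seq_along(hit_ci)) {
    ci <- hit_ci[j]; st <- hit_start[j]
    window <- substr(ref_all[[ci]], st + 1L, st + L)
    mm <- mismatch_count(oriented, window)
    if (mm <= params$max_mismatches) {
      out_ci <- c(out_ci, ci); out_start <- c(out_start, st)
      out_cigar <- c(out_cigar, paste0(L, "M"))
      out_score <- c(out_score,
                     (L - mm) * params$match_reward -
                       mm * params$mismatch_penalty)
    } else if (params$allow_gaps) {
      g <- gapped_extend(oriented, ref_all[[ci]], st, L, params)
      if (!is.null(g) && g$score >= floor_score) {
        out_ci <- c(out_ci, ci); out_start <- c(out_start, g$start)
        out_cigar <- c(out_cigar, g$cigar)
        out_score <- c(out_score, g$score)
      }
    }
  }
  if (!length(out_ci)) return(empty)
  # gapped hits from nearby diagonals can converge on one locus
  o <- order(-out_score, out_ci, out_start)
  out_ci <- out_ci[o]; out_start <- out_start[o]
  out_cigar <- out_cigar[o]; out_score <- out_score[o]
  dup <- duplicated(out_ci * 1e9 + out_start)
  keep <- which(!dup)[seq_len(min(sum(!dup), params$max_candidates))]
  list(contig = idx$contigs[out_ci[keep]], start = out_start[keep],
       cigar = out_cigar[keep], score = out_score[keep])
}

# Gapped end-to-end extension: read global, reference window local.
gapped_extend <- function(oriented, contig_seq, st, L, params) {
  wstart <- max(0L, st - params$band)
  wend <- min(nchar(contig_seq), st + L + params$band)
  window <- substr(contig_seq, wstart + 1L, wend)
  pa <- Biostrings::pairwiseAlignment(
    pattern = oriented, subject = window, type = "global-local",
    substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  p_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ops <- ifelse(p_aln == "-", "D", ifelse(s_aln == "-", "I", "M"))
  r <- rle(ops)
  list(start = wstart + BiocGenerics::start(Biostrings::subject(pa)) - 1L,
       cigar = paste0(r$lengths, r$values, collapse = ""),
       score = as.integer(round(Biostrings::score(pa))))
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MID]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("unparseable CIGAR '", cigar, "'", call. = FALSE)
  }
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1, nchar(toks) - 1L)))
}

cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D")])
}

#' Align one read across all enabled strand tasks
#'
#' Converts the read both ways (C-to-T and G-to-A) and runs
#' [seed_and_extend()] once per enabled strand task — OT and OB in
#' directional mode, all four in non-directional mode — each against its
#' matching converted reference copy and orientation.
#'
#' @param read_id,seq Read identifier and original base string.
#' @param conv_ref Indexed reference.
#' @param params [align_params()].
#' @param mode `"non-directional"` or `"directional"`.
#' @return Candidate tibble with a `task` column.
#' @export
align_read_all_tasks <- function(read_id, seq, conv_ref, params,
                                 mode = c("non-directional", "directional")) {
  mode <- match.arg(mode)
  tasks <- strand_tasks(mode)
  out <- vector("list", nrow(tasks))
  conv <- c(CT = convert_c2t(seq), GA = convert_g2a(seq))
  for (i in seq_len(nrow(tasks))) {
    res <- seed_and_extend_core(conv[[tasks$read_conversion[i]]],
                                tasks$ref_space[i], tasks$orientation[i],
                                conv_ref, params)
    out[[i]] <- tibble::tibble(read_id = read_id, task = tasks$task[i],
                               contig = res$contig, start = res$start,
                               cigar = res$cigar, conv_score = res$score)
  }
  dplyr::bind_rows(out)
}

#' Two-tier alignment of a read set
#'
#' Tier 1 aligns every read with the strict parameters; only reads that tier
#' 1 leaves without a single candidate are re-aligned with the permissive
#' parameters and tagged tier 2. A read's candidate list therefore never
#' mixes tiers, and enabling tier 2 can only add mappings for reads tier 1
#' could not place.
#'
#' @param reads Reads tibble (`read_id`, `seq`, optional `mate`).
#' @param conv_ref A [prepare_reference()] object; missing indexes are built.
#' @param strict,permissive [align_params()] for the two tiers; `strict`
#'   must not exceed `permissive` in mismatch budget or gap allowance.
#' @param mode `"non-directional"` or `"directional"`.
#' @param tier2 Set `FALSE` to disable the permissive pass.
#' @return Candidate tibble with columns `read_id`, `mate`, `task`,
#'   `contig`, `start`, `cigar`, `conv_score`, `tier`.
#' @export
two_tier_align <- function(reads, conv_ref,
                           strict = strict_params(),
                           permissive = permissive_params(),
                           mode = c("non-directional", "directional"),
                           tier2 = TRUE) {
  mode <- match.arg(mode)
  if (strict$max_mismatches > permissive$max_mismatches ||
      (strict$allow_gaps && !permissive$allow_gaps)) {
    stop("strict params must not be more permissive than permissive params",
         call. = FALSE)
  }
  conv_ref <- build_index(conv_ref, strict$k)
  if (tier2) conv_ref <- build_index(conv_ref, permissive$k)
  tasks <- strand_tasks(mode)
  mate <- if ("mate" %in% names(reads)) reads$mate else
    rep(NA_integer_, nrow(reads))
  n <- nrow(reads)
  # plain-vector accumulation: the inner loop is the pipeline's hot path
  a_idx <- vector("list", n); a_task <- vector("list", n)
  a_contig <- vector("list", n); a_start <- vector("list", n)
  a_cigar <- vector("list", n); a_score <- vector("list", n)
  tier_of <- integer(n)
  for (i in seq_len(n)) {
    seq_i <- reads$seq[i]
    conv <- c(CT = convert_c2t(seq_i), GA = convert_g2a(seq_i))
    run_tasks <- function(params) {
      tk <- character(0); cg <- character(0); st <- integer(0)
      ci <- character(0); sc <- integer(0)
      for (t in seq_len(nrow(tasks))) {
        res <- seed_and_extend_core(conv[[tasks$read_conversion[t]]],
                                    tasks$ref_space[t], tasks$orientation[t],
                                    conv_ref, params)
        nh <- length(res$contig)
        if (nh) {
          tk <- c(tk, rep.int(tasks$task[t], nh))
          ci <- c(ci, res$contig); st <- c(st, res$start)
          cg <- c(cg, res$cigar); sc <- c(sc, res$score)
        }
      }
      list(task = tk, contig = ci, start = st, cigar = cg, score = sc)
    }
    acc <- run_tasks(strict)
    tier_of[i] <- 1L
    if (!length(acc$task) && tier2) {
      acc <- run_tasks(permissive)
      tier_of[i] <- 2L
    }
    if (length(acc$task)) {
      a_idx[[i]] <- rep.int(i, length(acc$task))
      a_task[[i]] <- acc$task; a_contig[[i]] <- acc$contig
      a_start[[i]] <- acc$start; a_cigar[[i]] <- acc$cigar
      a_score[[i]] <- acc$score
    }
  }
  idx <- unlist(a_idx)
  tibble::tibble(
    read_id = reads$read_id[idx],
    mate = mate[idx],
    task = unlist(a_task) %||% character(0),
    contig = unlist(a_contig) %||% character(0),
    start = unlist(a_start) %||% integer(0),
    cigar = unlist(a_cigar) %||% character(0),
    conv_score = unlist(a_score) %||% integer(0),
    tier = tier_of[idx]
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pair mate candidates into proper pairs
#'
#' A candidate pair is proper when both mates hit the same contig, their
#' strand tasks imply opposite physical strands (OT with OB, CTOT with
#' CTOB), the forward-oriented alignment lies leftmost, and the
#' leftmost-to-rightmost span falls inside the insert window.
#'
#' @param cands1,cands2 Candidate tibbles for mate 1 and mate 2 of one
#'   template.
#' @param insert_min,insert_max Allowed template span in bases.
#' @return Tibble of proper pairs (`contig`, `start1`, `task1`, `start2`,
#'   `task2`, `span`, `pair_score`), sorted by combined score; zero rows
#'   when no proper pair exists.
#' @export
pair_mates <- function(cands1, cands2, insert_min, insert_max) {
  partner <- c(OT = "OB", OB = "OT", CTOT = "CTOB", CTOB = "CTOT")
  empty <- tibble::tibble(contig = character(), start1 = integer(),
                          task1 = character(), start2 = integer(),
                          task2 = character(), span = integer(),
                          pair_score = integer())
  if (nrow(cands1) == 0 || nrow(cands2) == 0) return(empty)
  g <- tidyr::crossing(i = seq_len(nrow(cands1)), j = seq_len(nrow(cands2)))
  a <- cands1[g$i, ]; b <- cands2[g$j, ]
  ok <- a$contig == b$contig & partner[a$task] == b$task
  a <- a[ok, ]; b <- b[ok, ]
  if (nrow(a) == 0) return(empty)
  a_fwd <- task_orientation(a$task) == "forward"
  f_start <- ifelse(a_fwd, a$start, b$start)
  r_start <- ifelse(a_fwd, b$start, a$start)
  r_end <- r_start + ifelse(a_fwd,
                            vapply(b$cigar, cigar_ref_span, integer(1)),
                            vapply(a$cigar, cigar_ref_span, integer(1)))
  span <- r_end - f_start
  ok <- f_start <= r_start & span >= insert_min & span <= insert_max
  if (!any(ok)) return(empty)
  out <- tibble::tibble(contig = a$contig[ok], start1 = a$start[ok],
                        task1 = a$task[ok], start2 = b$start[ok],
                        task2 = b$task[ok], span = as.integer(span[ok]),
                        pair_score = a$conv_score[ok] + b$conv_score[ok])
  dplyr::arrange(out, dplyr::desc(.data$pair_score), .data$contig,
                 .data$start1)
}
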