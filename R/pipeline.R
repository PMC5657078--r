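#' Run the full bisulfite alignment pipeline
#'
#' Chains the whole method: three-letter conversion of the reference,
#' two-tier strand-restricted seed-and-extend alignment in converted space,
#' chemistry classification and SNP-tolerant filtering on the original
#' sequences, and merge/deduplication to one verdict per read.
#'
#' @param reads Reads tibble from [read_reads()] or [simulate_reads()].
#' @param genome Named character vector of contigs ([read_fasta()] /
#'   [simulate_genome()]).
#' @param snps Optional SNP tibble ([read_snps()]) for SNP-tolerant
#'   filtering.
#' @param mode `"non-directional"` (default; all four strand tasks) or
#'   `"directional"` (OT/OB only).
#' @param strict,permissive Tier parameter sets; see [align_params()].
#' @param tier2 Disable the permissive rescue tier with `FALSE`.
#' @param max_invalid,max_mismatch Filtering budgets; see
#'   [filter_alignments()].
#' @param min_score_gap Margin required for a unique call.
#' @return A `bs_alignment` object: list with `verdicts` (per-read tibble),
#'   `classified` (all classified candidates with filter columns), and the
#'   run settings. Use [tidy()][tidy.bs_alignment] for the verdict tibble
#'   and [glance()][glance.bs_alignment] for one-row summary counts.
#' @examples
#' g <- simulate_genome(2000, seed = 4)
#' st <- assign_methylation(g, seed = 5)
#' sim <- simulate_reads(g, st, sim_config(n_reads = 20, genome_length = 2000,
#'                                         seed = 6))
#' fit <- bs_align(sim$reads, g, mode = "directional")
#' glance(fit)
#' @export
bs_align <- function(reads, genome, snps = NULL,
                     mode = c("non-directional", "directional"),
                     strict = strict_params(), permissive = permissive_params(),
                     tier2 = TRUE, max_invalid = 0L, max_mismatch = 3L,
                     min_score_gap = 0L) {
  mode <- match.arg(mode)
  genome <- validate_genome(genome)
  conv_ref <- prepare_reference(genome)
  cands <- two_tier_align(reads, conv_ref, strict, permissive, mode, tier2)
  classified <- classify_alignments(cands, reads, genome, snps,
                                    gap_open = permissive$gap_open,
                                    gap_extend = permissive$gap_extend)
  classified <- filter_alignments(classified, max_invalid, max_mismatch)
  verdicts <- resolve_reads(classified, reads, min_score_gap)
  verdicts <- annotate_rejections(verdicts, classified)
  structure(
    list(verdicts = verdicts, classified = classified, genome = genome,
         settings = list(mode = mode, strict = strict,
                         permissive = permissive, tier2 = tier2,
                         max_invalid = max_invalid,
                         max_mismatch = max_mismatch,
                         min_score_gap = min_score_gap)),
    class = "bs_alignment"
  )
}

# For unmapped reads that did have candidates, record why the best was lost.
annotate_rejections <- function(verdicts, classified) {
  reason <- rep(NA_character_, nrow(verdicts))
  unm <- which(verdicts$status == "unmapped")
  if (length(unm) && nrow(classified)) {
    rej <- classified[!classified$kept, , drop = FALSE]
    if (nrow(rej)) {
      rej <- rej[order(-rej$valid_score), , drop = FALSE]
      first <- rej[!duplicated(read_uid(rej)), , drop = FALSE]
      m <- match(read_uid(verdicts)[unm], read_uid(first))
      reason[unm] <- ifelse(is.na(m), "no-candidate", first$reason[m])
    } else {
      reason[unm] <- "no-candidate"
    }
  } else {
    reason[unm] <- "no-candidate"
  }
  verdicts$reason <- reason
  verdicts
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bisulfite alignment result
#'
#' @param x A `bs_alignment` object.
#' @param ... Unused.
#' @return The per-read verdict tibble.
#' @export
tidy.bs_alignment <- function(x, ...) {
  x$verdicts
}

#' One-row summary of a bisulfite alignment run
#'
#' @param x A `bs_alignment` object.
#' @param ... Unused.
#' @return Tibble with read counts by status and the percentage of reads
#'   uniquely mapped (`mappability`, on the 0-100 scale).
#' @export
glance.bs_alignment <- function(x, ...) {
  v <- x$verdicts
  tibble::tibble(
    n_reads = nrow(v),
    n_unique = sum(v$status == "unique"),
    n_ambiguous = sum(v$status == "ambiguous"),
    n_unmapped = sum(v$status == "unmapped"),
    n_tier2 = sum(v$tier == 2L, na.rm = TRUE),
    mappability = 100 * sum(v$status == "unique") / nrow(v)
  )
}

#' @export
print.bs_alignment <- function(x, ...) {
  g <- glance(x)
  cat("<bs_alignment> ", g$n_reads, " reads: ", g$n_unique, " unique, ",
      g$n_ambiguous, " ambiguous, ", g$n_unmapped, " unmapped (mappability ",
      sprintf("%.1f%%", g$mappability), ", mode ", x$settings$mode, ")\n",
      sep = "")
  invisible(x)
}

#' Write the per-read audit log
#'
#' TSV with one row per read: verdict status, the rejection reason for
#' unmapped reads whose candidates were filtered, and the chemistry
#' bookkeeping counts of the reported alignment.
#'
#' @param x A `bs_alignment` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(x, path) {
  v <- x$verdicts
  out <- data.frame(read_id = read_uid(v), status = v$status,
                    reason = ifelse(is.na(v$reason), ".", v$reason),
                    n_invalid = v$n_invalid, n_mismatch = v$n_mismatch,
                    n_snp_excused = v$n_snp_excused)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
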