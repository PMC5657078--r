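#' Read a reference genome from FASTA
#'
#' Loads a (possibly multi-line, possibly lowercase) FASTA file into a named
#' character vector of uppercase contig sequences. Characters outside
#' `A,C,G,T,N` and duplicate or empty contig names are rejected with the
#' offending line number. All internal coordinates in this package are
#' 0-based half-open; 1-based conventions (SAM POS, VCF POS) are converted
#' exactly once, at I/O.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences (a "genome").
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[[1]], ">")) {
    stop("not a FASTA file (line 1 does not start with '>'): ", path,
         call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    stop("empty FASTA header at line ", which(hdr)[!nzchar(ids)][1],
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate contig name '", dup, "' at line ",
         which(hdr)[ids == dup][2], call. = FALSE)
  }
  grp <- cumsum(hdr)
  body <- !hdr
  bad <- body & grepl("[^ACGTNacgtn]", lines)
  if (any(bad)) {
    stop("illegal character in sequence at line ", which(bad)[1],
         call. = FALSE)
  }
  seqs <- vapply(split(lines[body], grp[body]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop("empty sequence for contig '", ids[!nzchar(out)][1], "'",
         call. = FALSE)
  }
  validate_genome(out)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' Autodetects the format from the first character (`@` FASTQ, `>` FASTA).
#' With a second path the files are treated as mate pairs in file order:
#' trailing `/1`, `/2` (or ` 1`, ` 2`) id suffixes are stripped, ids must
#' match pairwise, and records are returned interleaved with `mate` 0/1.
#'
#' @param path1 Path to the (first) reads file.
#' @param path2 Optional path to the mate file for paired-end data.
#' @return A tibble with columns `read_id`, `seq`, `qual` (`NA` for FASTA
#'   input), `mate` (0, 1, or `NA` for single-end).
#' @export
read_reads <- function(path1, path2 = NULL) {
  r1 <- read_reads_one(path1)
  if (is.null(path2)) {
    r1$mate <- NA_integer_
    return(r1)
  }
  r2 <- read_reads_one(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate files differ in read count (", nrow(r1), " vs ", nrow(r2), ")",
         call. = FALSE)
  }
  strip <- function(x) sub("[/ _][12]$", "", x)
  id1 <- strip(r1$read_id); id2 <- strip(r2$read_id)
  if (!all(id1 == id2)) {
    i <- which(id1 != id2)[1]
    stop("mate id mismatch at record ", i, ": '", r1$read_id[i], "' vs '",
         r2$read_id[i], "'", call. = FALSE)
  }
  r1$read_id <- id1; r2$read_id <- id2
  r1$mate <- 0L; r2$mate <- 1L
  out <- dplyr::bind_rows(r1, r2)
  out[order(rep(seq_len(nrow(r1)), 2), out$mate), , drop = FALSE]
}

read_reads_one <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = character()))
  }
  first <- substr(lines[[1]], 1, 1)
  if (first == "@") {
    if (length(lines) %% 4 != 0) {
      stop("truncated FASTQ: ", path, call. = FALSE)
    }
    ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
    ids <- sub("\\s.*$", "", ids)
    seqs <- toupper(lines[seq(2, length(lines), by = 4)])
    quals <- lines[seq(4, length(lines), by = 4)]
    bad <- which(nchar(quals) != nchar(seqs))
    if (length(bad)) {
      stop("FASTQ record ", bad[1], " ('", ids[bad[1]],
           "'): quality length differs from sequence length", call. = FALSE)
    }
    tibble::tibble(read_id = ids, seq = seqs, qual = quals)
  } else if (first == ">") {
    g <- read_fasta_reads(path)
    tibble::tibble(read_id = names(g), seq = unname(g), qual = NA_character_)
  } else {
    stop("cannot detect read format (first character '", first, "'): ", path,
         call. = FALSE)
  }
}

# FASTA reads: like read_fasta but duplicate ids are allowed and the
# alphabet is not restricted to the genome alphabet beyond ACGTN.
read_fasta_reads <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!length(lines) || !hdr[1]) stop("not FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- character(length(ids)); names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  out
}

#' Read known variants for SNP-tolerant filtering
#'
#' Accepts either a VCF (lines starting with `#` are headers) or a 4-column
#' TSV `contig, 1-based position, ref, alt`. Only biallelic single-nucleotide
#' records are loaded; other VCF records (indels, multiallelic sites) are
#' skipped and counted. Positions are converted to 0-based on load.
#'
#' @param path Path to the variant file.
#' @return A tibble with columns `contig`, `pos` (0-based), `ref`, `alt`;
#'   attribute `n_skipped` carries the skipped-record count.
#' @export
read_snps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  data <- lines[!startsWith(lines, "#")]
  n_skipped <- 0L
  rows <- vector("list", length(data))
  for (i in seq_along(data)) {
    f <- strsplit(data[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 8 || (length(f) >= 5 && grepl("^[0-9]+$", f[2]))) {
      # VCF body line: CHROM POS ID REF ALT ...
      if (length(f) < 5) stop("unparseable variant line ", i, call. = FALSE)
      contig <- f[1]; pos <- f[2]; ref <- f[4]; alt <- f[5]
    } else if (length(f) == 4) {
      contig <- f[1]; pos <- f[2]; ref <- f[3]; alt <- f[4]
    } else {
      stop("unparseable variant line ", i, ": expected VCF or 4-column TSV",
           call. = FALSE)
    }
    if (!grepl("^[0-9]+$", pos)) {
      stop("unparseable position on variant line ", i, call. = FALSE)
    }
    ref <- toupper(ref); alt <- toupper(alt)
    snv <- nchar(ref) == 1 && nchar(alt) == 1 &&
      ref %in% c("A", "C", "G", "T") && alt %in% c("A", "C", "G", "T") &&
      ref != alt
    if (!snv) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- tibble::tibble(contig = contig,
                                pos = as.integer(pos) - 1L,
                                ref = ref, alt = alt)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character())
  }
  out <- dplyr::distinct(out)
  if (n_skipped > 0) {
    message(n_skipped, " non-SNV variant record(s) skipped")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

sam_flag <- function(orientation, status, mate = NA_integer_) {
  flag <- ifelse(status == "unmapped", 4L,
                 ifelse(orientation == "reverse", 16L, 0L))
  paired <- !is.na(mate)
  flag + ifelse(paired, 1L + ifelse(mate == 0L, 64L, 128L), 0L)
}

#' Write alignment verdicts to SAM
#'
#' Emits a valid SAM file: `@HD`/`@SQ` headers from the genome, 1-based POS,
#' reverse-strand alignments (tasks OB and CTOT) with FLAG 0x10 and SEQ
#' reverse-complemented, unmapped reads with FLAG 0x4. Three custom tags are
#' written: `XM:Z` the per-column methylation string (codes `.`/`M`/`U`/`x`/
#' `S`, reference orientation, column-aligned with SEQ), `XG:Z` the strand
#' task label, and `NM:i` the count of ordinary mismatches plus inserted and
#' deleted bases. Unique alignments get MAPQ 42; ambiguous reads are written
#' at their first equal-best locus with MAPQ 0.
#'
#' @param verdicts A verdict tibble from [resolve_reads()] / [bs_align()].
#' @param genome The genome the verdicts refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(verdicts, genome, path) {
  genome <- validate_genome(genome)
  mapped <- verdicts$status != "unmapped"
  if (any(mapped & !(verdicts$contig %in% names(genome)))) {
    bad <- verdicts$contig[mapped & !(verdicts$contig %in% names(genome))][1]
    stop("record references unknown contig '", bad, "'", call. = FALSE)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)),
           "@PG\tID:bisulfitr\tPN:bisulfitr")
  mate <- if ("mate" %in% names(verdicts)) verdicts$mate else
    rep(NA_integer_, nrow(verdicts))
  orient <- ifelse(mapped, task_orientation(verdicts$task), "forward")
  flag <- sam_flag(orient, verdicts$status, mate)
  qual <- if ("qual" %in% names(verdicts)) verdicts$qual else
    rep(NA_character_, nrow(verdicts))
  qual <- ifelse(is.na(qual), "*", qual)
  seq_out <- ifelse(orient == "reverse", revcomp(verdicts$seq), verdicts$seq)
  qual_out <- ifelse(orient == "reverse" & qual != "*",
                     vapply(strsplit(qual, ""), function(x)
                       paste(rev(x), collapse = ""), character(1)),
                     qual)
  mapq <- ifelse(verdicts$status == "unique", 42L,
                 ifelse(verdicts$status == "ambiguous", 0L, 0L))
  nm <- verdicts$n_mismatch + cigar_indel_bases(verdicts$cigar)
  body <- paste(
    verdicts$read_id,
    flag,
    ifelse(mapped, verdicts$contig, "*"),
    ifelse(mapped, verdicts$start + 1L, 0L),
    ifelse(mapped, mapq, 0L),
    ifelse(mapped, verdicts$cigar, "*"),
    "*", 0L, 0L,
    seq_out,
    qual_out,
    sep = "\t"
  )
  tags <- ifelse(
    mapped,
    paste0("\tNM:i:", nm, "\tXM:Z:", verdicts$codes, "\tXG:Z:", verdicts$task),
    ""
  )
  writeLines(c(hdr, paste0(body, tags)), path)
  invisible(path)
}

task_orientation <- function(task) {
  ifelse(task %in% c("OB", "CTOT"), "reverse", "forward")
}

cigar_indel_bases <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("I", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse a SAM file written by [write_sam()]
#'
#' Minimal SAM reader for round-tripping this package's own output: returns
#' the alignment records with 0-based `start`, the strand implied by FLAG
#' 0x10, and the `XM`/`XG`/`NM` tags.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `read_id`, `flag`, `contig`, `start`,
#'   `mapq`, `cigar`, `seq`, `qual`, `nm`, `codes`, `task`, `strand`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(x, tag) {
    hit <- x[startsWith(x, tag)]
    if (length(hit)) sub(tag, "", hit[1]) else NA_character_
  }
  tibble::tibble(
    read_id = vapply(f, `[[`, character(1), 1),
    flag = as.integer(vapply(f, `[[`, character(1), 2)),
    contig = vapply(f, `[[`, character(1), 3),
    start = as.integer(vapply(f, `[[`, character(1), 4)) - 1L,
    mapq = as.integer(vapply(f, `[[`, character(1), 5)),
    cigar = vapply(f, `[[`, character(1), 6),
    seq = vapply(f, `[[`, character(1), 10),
    qual = vapply(f, `[[`, character(1), 11),
    nm = as.integer(vapply(f, get_tag, character(1), "NM:i:")),
    codes = vapply(f, get_tag, character(1), "XM:Z:"),
    task = vapply(f, get_tag, character(1), "XG:Z:")
  ) |>
    dplyr::mutate(
      contig = ifelse(.data$contig == "*", NA_character_, .data$contig),
      start = ifelse(is.na(.data$contig), NA_integer_, .data$start),
      strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+")
    )
}

#' Write reads as FASTQ
#'
#' @param reads A reads tibble (`read_id`, `seq`, `qual`); missing qualities
#'   are written as `I` (Phred 40).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    rep(NA_character_, nrow(reads))
  qual[is.na(qual)] <- strrep("I", nchar(reads$seq[is.na(qual)]))
  writeLines(c(rbind(paste0("@", reads$read_id), reads$seq, "+", qual)), path)
  invisible(path)
}
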