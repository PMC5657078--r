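#' Per-read methylation string
#'
#' The methylation string is the classified code string restricted to the
#' post-filter alphabet `.`/`M`/`U`/`x`/`S`, emitted as the SAM `XM:Z` tag
#' column-aligned with SEQ (reference orientation). A bisulfite-invalid
#' column (`X`) must have been filtered out before this point, so its
#' presence is an error.
#'
#' @param codes Character vector of classified code strings.
#' @return The code strings, unchanged.
#' @export
methylation_string <- function(codes) {
  bad <- grepl("X", codes, fixed = TRUE)
  if (any(bad)) {
    stop("code string contains bisulfite-invalid column(s) 'X'; ",
         "filter before calling methylation", call. = FALSE)
  }
  codes
}

#' Aggregate per-position methylation across uniquely mapped reads
#'
#' Every `M` (methylated) and `U` (unmethylated, converted) observation in a
#' unique read is assigned to its reference cytosine: a C on the Watson
#' strand for CT-space tasks (OT/CTOT), a G — i.e. a Crick-strand cytosine —
#' for GA-space tasks (OB/CTOB). The trinucleotide context is taken from the
#' original reference: CpG when the next base (strand-appropriately) is G,
#' CHG when the base after next is G, CHH otherwise. Ambiguous and unmapped
#' reads contribute nothing.
#'
#' @param x A `bs_alignment` object or a verdict tibble.
#' @param genome The original genome (taken from `x` when it is a
#'   `bs_alignment`).
#' @param contexts Contexts to report.
#' @param min_coverage Drop rows with fewer than this many observations.
#' @param one_based Emit 1-based positions instead of the 0-based default.
#' @return A `methylation_report` tibble: `contig`, `pos`, `strand`,
#'   `context`, `n_methylated`, `n_unmethylated`,
#'   `level = n_methylated / (n_methylated + n_unmethylated)`, sorted by
#'   (contig, pos).
#' @export
methylation_report <- function(x, genome = NULL,
                               contexts = c("CpG", "CHG", "CHH"),
                               min_coverage = 0L, one_based = FALSE) {
  if (inherits(x, "bs_alignment")) {
    genome <- x$genome
    v <- x$verdicts
  } else {
    v <- x
    if (is.null(genome)) stop("genome required", call. = FALSE)
    genome <- validate_genome(genome)
  }
  v <- v[v$status == "unique", , drop = FALSE]
  obs_contig <- character(0); obs_pos <- integer(0)
  obs_strand <- character(0); obs_meth <- logical(0)
  for (i in seq_len(nrow(v))) {
    code <- strsplit(v$codes[i], "")[[1]]
    hit <- code %in% c("M", "U")
    if (!any(hit)) next
    rpos <- code_ref_positions(v$cigar[i], v$start[i])
    obs_contig <- c(obs_contig, rep(v$contig[i], sum(hit)))
    obs_pos <- c(obs_pos, rpos[hit])
    obs_strand <- c(obs_strand,
                    rep(task_original_strand(v$task[i]), sum(hit)))
    obs_meth <- c(obs_meth, code[hit] == "M")
  }
  if (!length(obs_pos)) {
    out <- tibble::tibble(contig = character(), pos = integer(),
                          strand = character(), context = character(),
                          n_methylated = integer(),
                          n_unmethylated = integer(), level = double())
    return(structure(out, class = c("methylation_report", class(out))))
  }
  agg <- tibble::tibble(contig = obs_contig, pos = obs_pos,
                        strand = obs_strand, meth = obs_meth) |>
    dplyr::summarise(n_methylated = sum(.data$meth),
                     n_unmethylated = sum(!.data$meth),
                     .by = c("contig", "pos", "strand")) |>
    dplyr::mutate(
      context = cytosine_context(genome, .data$contig, .data$pos,
                                 .data$strand),
      level = .data$n_methylated /
        (.data$n_methylated + .data$n_unmethylated)
    ) |>
    dplyr::filter(.data$context %in% contexts,
                  .data$n_methylated + .data$n_unmethylated >=
                    min_coverage) |>
    dplyr::arrange(.data$contig, .data$pos) |>
    dplyr::select("contig", "pos", "strand", "context", "n_methylated",
                  "n_unmethylated", "level")
  if (one_based) agg$pos <- agg$pos + 1L
  structure(agg, class = c("methylation_report", class(agg)))
}

# 0-based reference position of each read column; NA for insertions.
code_ref_positions <- function(cigar, start) {
  ops <- parse_cigar(cigar)
  if (length(ops$op) == 1L && ops$op == "M") {
    return(start + seq_len(ops$len) - 1L)
  }
  rpos <- integer(0); gi <- start
  for (j in seq_along(ops$op)) {
    len <- ops$len[j]
    if (ops$op[j] == "M") {
      rpos <- c(rpos, gi + seq_len(len) - 1L); gi <- gi + len
    } else if (ops$op[j] == "I") {
      rpos <- c(rpos, rep(NA_integer_, len))
    } else {
      gi <- gi + len
    }
  }
  rpos
}

# Trinucleotide context of a reference cytosine (+: C; -: G, looking left).
# Positions running off the contig default to CHH.
cytosine_context <- function(genome, contig, pos, strand) {
  out <- character(length(pos))
  clen <- nchar(genome)[contig]
  base_at <- function(p) {
    b <- rep(NA_character_, length(p))
    ok <- !is.na(p) & p >= 0 & p < clen
    b[ok] <- substr(genome[contig[ok]], p[ok] + 1L, p[ok] + 1L)
    b
  }
  plus <- strand == "+"
  n1 <- ifelse(plus, pos + 1L, pos - 1L)
  n2 <- ifelse(plus, pos + 2L, pos - 2L)
  b1 <- base_at(n1); b2 <- base_at(n2)
  want1 <- ifelse(plus, "G", "C")
  out <- ifelse(!is.na(b1) & b1 == want1, "CpG",
                ifelse(!is.na(b2) & b2 == want1, "CHG", "CHH"))
  out
}

#' Write a methylation report as TSV
#'
#' bedGraph-like tab-separated table with a header line; positions are
#' 0-based unless the report was built with `one_based = TRUE`.
#'
#' @param report A [methylation_report()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a methylation report
#'
#' Histogram of per-site methylation levels, faceted by context.
#'
#' @param object A `methylation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methylation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = 21, fill = "grey30") +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "methylation level", y = "cytosines") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
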