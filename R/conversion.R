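#' Three-letter base conversions
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil, read as
#' thymine after PCR. Collapsing C to T (and, for the complementary strand,
#' G to A) in both reads and reference removes the conversion-induced
#' mismatches before alignment. `convert_c2t()` replaces every `C` with `T`;
#' `convert_g2a()` replaces every `G` with `A`; `revcomp()` is the
#' Watson-Crick reverse complement with `N` mapping to `N`. All three are
#' vectorised over character vectors and preserve string length.
#'
#' @param seq Character vector of base strings over `A,C,G,T,N`.
#' @return Character vector of the same length and element widths.
#' @examples
#' convert_c2t("AGACCCATG") # "AGATTTATG"
#' convert_g2a("AGACCCATG") # "AAACCCATA"
#' revcomp("AAC")           # "GTT"
#' @export
convert_c2t <- function(seq) {
  chartr("C", "T", seq)
}

#' @rdname convert_c2t
#' @export
convert_g2a <- function(seq) {
  chartr("G", "A", seq)
}

#' @rdname convert_c2t
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' The four bisulfite strand tasks
#'
#' A bisulfite library can produce reads from four distinct strands: the
#' bisulfite-converted Watson strand (OT, "original top"), the converted
#' Crick strand (OB, "original bottom"), and the PCR reverse complements of
#' each (CTOT, CTOB). Each task fixes three things: which converted copy of
#' the *read* is searched (C-to-T or G-to-A), which converted copy of the
#' *reference* it is searched against, and whether the read string is
#' reverse-complemented before seeding. The low-level aligner never searches
#' reverse complements on its own; orientation is handled only through this
#' table, which enforces the strand restriction that a converted read maps
#' into a converted reference copy of the same strand.
#'
#' @param mode `"non-directional"` (all four tasks, the default) or
#'   `"directional"` (OT and OB only, for directional protocols).
#' @return A tibble with columns `task`, `read_conversion` (`CT`/`GA`),
#'   `ref_space` (`CT`/`GA`), `orientation` (`forward`/`reverse`).
#' @examples
#' strand_tasks("directional")
#' @export
strand_tasks <- function(mode = c("non-directional", "directional")) {
  mode <- match.arg(mode)
  tab <- tibble::tibble(
    task            = c("OT", "OB", "CTOT", "CTOB"),
    read_conversion = c("CT", "CT", "GA", "GA"),
    ref_space       = c("CT", "GA", "CT", "GA"),
    orientation     = c("forward", "reverse", "reverse", "forward")
  )
  if (mode == "directional") tab <- tab[tab$task %in% c("OT", "OB"), ]
  tab
}

# Original strand a task reads out: CT reference space <=> Watson (+).
task_original_strand <- function(task) {
  ifelse(task %in% c("OT", "CTOT"), "+", "-")
}

#' Prepare a converted reference
#'
#' Builds the two three-letter copies of a genome: one with every C replaced
#' by T and one with every G replaced by A. The original sequences are
#' retained because post-alignment chemistry validation and methylation
#' calling are done on unconverted bases. K-mer indexes over the converted
#' copies are added later by [build_index()].
#'
#' @param genome A genome as returned by [read_fasta()] or
#'   [simulate_genome()]: a named character vector of uppercase contig
#'   sequences.
#' @return An object of class `converted_reference`: a list with elements
#'   `original`, `ct` (no C remains), `ga` (no G remains), and `index`
#'   (empty until [build_index()] is called).
#' @examples
#' ref <- prepare_reference(c(chr1 = "ACGT"))
#' ref$ct # "ATGT"
#' ref$ga # "ACAT"
#' @export
prepare_reference <- function(genome) {
  genome <- validate_genome(genome)
  structure(
    list(
      original = genome,
      ct = convert_c2t(genome),
      ga = convert_g2a(genome),
      lens = nchar(genome),
      index = list()
    ),
    class = "converted_reference"
  )
}

#' @export
print.converted_reference <- function(x, ...) {
  cat("<converted_reference> ", length(x$original), " contig(s), ",
      sum(nchar(x$original)), " bases; indexes built: ",
      if (length(x$index)) paste(names(x$index), collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

validate_genome <- function(genome) {
  if (length(genome) == 0) stop("genome has no contigs", call. = FALSE)
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("contig names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  genome <- toupper(genome)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop("contig ", nm[bad][1], " contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  genome
}
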