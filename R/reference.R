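#' Reference model: hairpin precursors with mature-arm coordinates
#'
#' A `mirna_reference` holds the hairpin (precursor) sequences and the
#' coordinates of each mature miRNA on its hairpin. All coordinates are
#' 0-based half-open (`[start, end)`) internally; 1-based external formats
#' (miRBase GFF3) are converted at the I/O boundary. RNA input (U) is stored
#' as DNA (T), uppercase.
#'
#' @param hairpins named character vector of hairpin sequences
#'   (names = hairpin ids).
#' @param matures data.frame with columns `mature_id`, `hairpin_id`,
#'   `start`, `end` (0-based half-open on the hairpin) and `arm`
#'   (`"5p"`, `"3p"` or `"unassigned"`).
#' @return An object of class `mirna_reference`: a list with elements
#'   `hairpins` (named uppercase DNA character vector) and `matures`
#'   (validated data.frame).
#' @examples
#' ref <- mirna_reference(
#'   hairpins = c(hp1 = "acguACGUacguACGUacguACGU"),
#'   matures  = data.frame(mature_id = "hp1-5p", hairpin_id = "hp1",
#'                         start = 2L, end = 22L, arm = "5p")
#' )
#' mature_sequence(ref, "hp1-5p")
#' @export
mirna_reference <- function(hairpins, matures) {
  if (length(hairpins) == 0L || is.null(names(hairpins)) ||
      any(!nzchar(names(hairpins))))
    stop("hairpins must be a non-empty named character vector")
  if (anyDuplicated(names(hairpins)))
    stop("duplicate hairpin ids")
  hairpins <- vapply(hairpins, normalize_seq, character(1))
  if (any(!nzchar(hairpins))) stop("empty hairpin sequence")
  bad <- grepl("[^ACGTN]", hairpins)
  if (any(bad))
    stop("hairpin sequences restricted to A/C/G/T/U/N: ",
         paste(names(hairpins)[bad], collapse = ", "))

  need <- c("mature_id", "hairpin_id", "start", "end", "arm")
  if (!all(need %in% names(matures)))
    stop("mature table must have columns: ", paste(need, collapse = ", "))
  matures <- as.data.frame(matures)[, need]
  matures$mature_id <- as.character(matures$mature_id)
  matures$hairpin_id <- as.character(matures$hairpin_id)
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  matures$arm <- as.character(matures$arm)
  if (anyDuplicated(matures$mature_id))
    stop("duplicate mature_ids: ",
         paste(unique(matures$mature_id[duplicated(matures$mature_id)]),
               collapse = ", "))
  missing_hp <- setdiff(matures$hairpin_id, names(hairpins))
  if (length(missing_hp))
    stop("reference integrity: matures reference unknown hairpins: ",
         paste(missing_hp, collapse = ", "))
  hplen <- nchar(hairpins)[matures$hairpin_id]
  ok <- matures$start >= 0L & matures$start < matures$end &
    matures$end <= hplen
  if (any(!ok))
    stop("mature coordinates out of hairpin range: ",
         paste(matures$mature_id[!ok], collapse = ", "))
  mlen <- matures$end - matures$start
  if (any(mlen < 15L | mlen > 30L))
    stop("mature length outside 15-30 nt: ",
         paste(matures$mature_id[mlen < 15L | mlen > 30L], collapse = ", "))
  if (any(!matures$arm %in% c("5p", "3p", "unassigned")))
    stop("arm must be one of 5p/3p/unassigned")
  rownames(matures) <- NULL
  structure(list(hairpins = hairpins, matures = matures),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("mirna_reference:", length(x$hairpins), "hairpins,",
      nrow(x$matures), "mature miRNAs\n")
  invisible(x)
}

normalize_seq <- function(s) {
  chartr("U", "T", toupper(as.character(s)))
}

#' Load a hairpin FASTA plus mature coordinate table
#'
#' Reads a miRBase-style reference: a FASTA of precursor (hairpin) sequences
#' and a 5-column TSV (`mature_id`, `hairpin_id`, `start`, `end`, `arm`;
#' header required; 0-based half-open coordinates) locating each mature
#' miRNA on its hairpin.
#'
#' @param hairpin_fasta path to the hairpin FASTA (RNA or DNA; gzip ok).
#' @param mature_table path to the mature coordinate TSV.
#' @return A [mirna_reference] object.
#' @seealso [read_mirbase_gff3()] for the miRBase GFF3 dialect,
#'   [write_reference()] for the round-trip writer.
#' @export
load_reference <- function(hairpin_fasta, mature_table) {
  hp <- Biostrings::readDNAStringSet(hairpin_fasta)
  hairpins <- setNames(as.character(hp), sub("\\s.*$", "", names(hp)))
  matures <- read.delim(mature_table, stringsAsFactors = FALSE)
  mirna_reference(hairpins, matures)
}

#' Write a reference back to FASTA + TSV
#'
#' Inverse of [load_reference()]; the round trip is bit-exact on sequences
#' and coordinates.
#'
#' @param ref a [mirna_reference].
#' @param hairpin_fasta,mature_table output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, hairpin_fasta, mature_table) {
  stopifnot(inherits(ref, "mirna_reference"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$hairpins), hairpin_fasta)
  write.table(ref$matures, mature_table, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(hairpin_fasta, mature_table))
}

#' Read mature annotations from a miRBase-dialect GFF3
#'
#' Convenience reader for miRBase `miRNA`-type rows (1-based inclusive
#' coordinates, `ID=`/`Derives_from=` attributes). Coordinates are taken
#' relative to the hairpin named in the `Derives_from` attribute, i.e. the
#' GFF3 must be in hairpin space, and are converted to the package's
#' 0-based half-open convention.
#'
#' @param gff3 path to the GFF3 file.
#' @return A mature-annotation data.frame suitable for [mirna_reference()].
#' @export
read_mirbase_gff3 <- function(gff3) {
  ln <- readLines(gff3)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "miRNA", logical(1))
  f <- f[keep]
  if (!length(f))
    return(data.frame(mature_id = character(), hairpin_id = character(),
                      start = integer(), end = integer(), arm = character()))
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  rows <- lapply(f, function(x) {
    id <- attr1(x[9], "Name")
    if (is.na(id)) id <- attr1(x[9], "ID")
    data.frame(mature_id = id,
               hairpin_id = attr1(x[9], "Derives_from"),
               start = as.integer(x[4]) - 1L,  # 1-based -> 0-based
               end = as.integer(x[5]),         # inclusive -> half-open
               arm = if (grepl("-5p$", id)) "5p"
                     else if (grepl("-3p$", id)) "3p" else "unassigned")
  })
  do.call(rbind, rows)
}

#' Extract a mature miRNA sequence from the reference
#'
#' @param ref a [mirna_reference].
#' @param mature_id mature miRNA identifier.
#' @return The mature sequence (hairpin slice `[start, end)`).
#' @export
mature_sequence <- function(ref, mature_id) {
  stopifnot(inherits(ref, "mirna_reference"))
  i <- match(mature_id, ref$matures$mature_id)
  if (is.na(i)) stop("unknown mature_id: ", mature_id)
  m <- ref$matures[i, ]
  substr(ref$hairpins[[m$hairpin_id]], m$start + 1L, m$end)
}

#' Extract the seed (nucleotides 2-8) of a mature miRNA
#'
#' The seed is the primary determinant of target specificity; 5'-end shifts
#' change it.
#'
#' @inheritParams mature_sequence
#' @return 7-nt seed string, `mature[2..8]`.
#' @export
seed_sequence <- function(ref, mature_id) {
  substr(mature_sequence(ref, mature_id), 2L, 8L)
}
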