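#' Classify aligned reads into canonical and isomiR classes
#'
#' Adds the end-variation class and seed flags to an alignment table.
#' Classes partition all non-canonical calls:
#' \describe{
#'   \item{canonical}{no end offsets, no tail, no substitutions.}
#'   \item{"3"}{3' variation only (3' offset and/or non-templated tail).}
#'   \item{"5"}{5' offset only.}
#'   \item{"53"}{5' offset plus 3' variation.}
#'   \item{"0"}{both ends canonical but internal substitutions present.}
#' }
#' Non-templated tails count as 3' variation, not as substitutions.
#' `seed_altered` is `TRUE` iff the 5' offset is nonzero or any
#' substitution falls at mature-relative positions 1-7 (0-based; mature
#' nucleotides 2-8).
#'
#' @param aln alignment data.frame from [align_to_hairpins()].
#' @return The table with `class_code`, `canonical` and `seed_altered`
#'   columns added.
#' @export
classify_alignments <- function(aln) {
  n <- nrow(aln)
  has3 <- aln$offset3 != 0L | nzchar(aln$nta_tail)
  has5 <- aln$offset5 != 0L
  canonical <- !has3 & !has5 & aln$n_subst == 0L
  class_code <- character(n)
  class_code[!has5 & has3] <- "3"
  class_code[has5 & !has3] <- "5"
  class_code[has5 & has3] <- "53"
  class_code[!has5 & !has3 & aln$n_subst > 0L] <- "0"
  class_code[canonical] <- "canonical"
  seed_sub <- vapply(aln$substitutions, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    pos <- as.integer(sub(":.*", "",
                          strsplit(s, ",", fixed = TRUE)[[1]]))
    any(pos >= 1L & pos <= 7L)
  }, logical(1), USE.NAMES = FALSE)
  aln$class_code <- class_code
  aln$canonical <- canonical
  aln$seed_altered <- has5 | seed_sub
  aln
}

#' Build the isomiR catalog with deterministic dotted names
#'
#' Distinct non-canonical sequences of each parent mature are assigned
#' serial numbers and named on the grammar
#' `"{parent}.{class}.P{n_subst}.S.{serial}"` (e.g.
#' `hsa-miR-451a.3.P0.S.2`). Canonical sequences carry the plain parent id
#' as name. Serials are ranks within a parent under the chosen order, so
#' identical input always yields identical names.
#'
#' @param calls classified alignment rows pooled over samples (output of
#'   [classify_alignments()], possibly row-bound across samples; the
#'   `multiplicity` column is summed per distinct sequence).
#' @param order `"abundance"` (total multiplicity descending, ties by
#'   sequence) or `"lexicographic"` (sequence order).
#' @return Catalog data.frame: `name`, `parent`, `class_code`, `offset5`,
#'   `offset3`, `nta_tail`, `n_subst`, `seed_altered`, `sequence`,
#'   `total_multiplicity`, `serial` (NA for canonical rows).
#' @export
assign_names <- function(calls, order = c("abundance", "lexicographic")) {
  order <- match.arg(order)
  if (nrow(calls) == 0L) {
    return(data.frame(name = character(), parent = character(),
                      class_code = character(), offset5 = integer(),
                      offset3 = integer(), nta_tail = character(),
                      n_subst = integer(), seed_altered = logical(),
                      canonical = logical(), sequence = character(),
                      total_multiplicity = integer(),
                      serial = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(calls$mature_id, calls$sequence, sep = "\r")
  mult <- tapply(calls$multiplicity, key, sum)
  first <- !duplicated(key)
  cat_df <- data.frame(
    parent = calls$mature_id[first], class_code = calls$class_code[first],
    offset5 = calls$offset5[first], offset3 = calls$offset3[first],
    nta_tail = calls$nta_tail[first], n_subst = calls$n_subst[first],
    seed_altered = calls$seed_altered[first],
    canonical = calls$canonical[first],
    sequence = calls$sequence[first],
    total_multiplicity = as.integer(mult[key[first]]),
    stringsAsFactors = FALSE)
  ord <- if (order == "abundance")
    with(cat_df, order(parent, canonical, -total_multiplicity, sequence))
  else with(cat_df, order(parent, canonical, sequence))
  # canonical == FALSE sorts first, so variants precede the canonical row
  cat_df <- cat_df[ord, , drop = FALSE]
  serial <- integer(nrow(cat_df))
  serial[!cat_df$canonical] <- stats::ave(
    seq_len(sum(!cat_df$canonical)),
    cat_df$parent[!cat_df$canonical], FUN = seq_along)
  cat_df$serial <- ifelse(cat_df$canonical, NA_integer_, serial)
  cat_df$name <- ifelse(
    cat_df$canonical, cat_df$parent,
    sprintf("%s.%s.P%d.S.%d", cat_df$parent, cat_df$class_code,
            cat_df$n_subst, cat_df$serial))
  if (anyDuplicated(cat_df$name))
    stop("internal error: duplicate isomiR names")
  rownames(cat_df) <- NULL
  cat_df[, c("name", "parent", "class_code", "offset5", "offset3",
             "nta_tail", "n_subst", "seed_altered", "canonical",
             "sequence", "total_multiplicity", "serial")]
}

#' Parse a dotted isomiR name back into its components
#'
#' @param name character vector of isomiR names.
#' @return data.frame with `parent`, `class_code`, `n_subst`, `serial`;
#'   a name without the dotted suffix is returned as a canonical parent
#'   (class `"canonical"`, `n_subst` 0, serial `NA`).
#' @export
parse_isomir_name <- function(name) {
  pat <- "^(.+)\\.(0|3|5|53)\\.P([0-9]+)\\.S\\.([0-9]+)$"
  hit <- grepl(pat, name)
  out <- data.frame(parent = name,
                    class_code = rep("canonical", length(name)),
                    n_subst = rep(0L, length(name)),
                    serial = rep(NA_integer_, length(name)),
                    stringsAsFactors = FALSE)
  out$parent[hit] <- sub(pat, "\\1", name[hit])
  out$class_code[hit] <- sub(pat, "\\2", name[hit])
  out$n_subst[hit] <- as.integer(sub(pat, "\\3", name[hit]))
  out$serial[hit] <- as.integer(sub(pat, "\\4", name[hit]))
  out
}

#' Summarize an isomiR catalog by class and substitution stratum
#'
#' @param catalog catalog from [assign_names()].
#' @param counts optional isomiR-level [mir_counts()] matrix; when given,
#'   per-sample read-weighted class fractions are included.
#' @return List with `by_class` (distinct non-canonical isomiRs per class:
#'   `n`, `fraction`), `by_subst` (per `P{n}` stratum) and, when `counts`
#'   is supplied, `per_sample` (class x sample read fractions).
#' @export
catalog_summary <- function(catalog, counts = NULL) {
  iso <- catalog[!catalog$canonical, , drop = FALSE]
  mk <- function(f) {
    if (nrow(iso) == 0L)
      return(data.frame(stratum = character(), n = integer(),
                        fraction = numeric()))
    tab <- table(f)
    data.frame(stratum = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / nrow(iso),
               stringsAsFactors = FALSE)
  }
  out <- list(by_class = mk(iso$class_code),
              by_subst = mk(paste0("P", iso$n_subst)))
  if (!is.null(counts)) {
    m <- counts$counts[rownames(counts$counts) %in% iso$name, ,
                       drop = FALSE]
    if (nrow(m)) {
      cls <- iso$class_code[match(rownames(m), iso$name)]
      agg <- rowsum(m, cls)
      out$per_sample <- sweep(agg, 2, pmax(1, colSums(agg)), "/")
    } else {
      out$per_sample <- matrix(numeric(0), 0, ncol(counts$counts),
                               dimnames = list(NULL,
                                               colnames(counts$counts)))
    }
  }
  out
}
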