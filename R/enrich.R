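#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members....
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  setNames(lapply(f, function(x) unique(x[-(1:2)])),
           vapply(f, `[`, character(1), 1L))
}

#' Hypergeometric over-representation of feature sets
#'
#' For each set, with population = |universe|, successes =
#' |set intersect universe| and draws = |query|, the p-value is the upper
#' hypergeometric tail P(X >= found). BH adjustment across sets. This is a
#' generic over-representation statistic for user-supplied target sets
#' (e.g. miRNA target genes against pathway sets).
#'
#' @param query feature id set (must be contained in `universe`).
#' @param universe background id set.
#' @param sets named list of id sets (e.g. from [read_gmt()]); each is
#'   intersected with the universe.
#' @return data.frame: `set_name`, `entities_found`, `entities_total`,
#'   `p_value`, `fdr`, `overlap_ids` (comma-joined).
#' @export
overrepresentation <- function(query, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- if (length(s) == 0L) 1 else
      phyper(k - 1L, length(s), length(universe) - length(s),
             length(query), lower.tail = FALSE)
    data.frame(set_name = nm, entities_found = k,
               entities_total = length(s), p_value = p,
               overlap_ids = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out[, c("set_name", "entities_found", "entities_total", "p_value",
          "fdr", "overlap_ids")]
}
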