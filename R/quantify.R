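#' Count matrix container
#'
#' Features (canonical matures or isomiR names) by samples, raw integer
#' counts. Library sizes are the per-sample totals of miRNA-assigned
#' counts, i.e. the column sums: normalization is within the miRNA
#' compartment, so per-group shares sum to 100% across miRNAs.
#'
#' @param counts non-negative integer matrix with feature rownames and
#'   sample colnames.
#' @param level `"canonical"` or `"isomir"`.
#' @return A `mir_counts` object: list with `counts`, `library_sizes`,
#'   `level`.
#' @export
mir_counts <- function(counts, level = c("canonical", "isomir")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (any(counts < 0)) stop("negative counts")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 library_sizes = colSums(counts),
                 level = level),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts [", x$level, "]: ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples; median library ",
      stats::median(x$library_sizes), "\n", sep = "")
  invisible(x)
}

#' Aggregate classified calls into a count matrix
#'
#' At the canonical level, the default policy credits every read assigned
#' to a mature (canonical sequence plus all of its isomiRs) to that
#' mature's row; `strict = TRUE` counts exact canonical sequences only.
#' At the isomiR level there is one row per catalog name.
#'
#' @param calls_per_sample named list (by sample id) of classified
#'   alignment tables ([classify_alignments()]).
#' @param catalog catalog from [assign_names()] built over the pooled
#'   calls; required for `level = "isomir"` and used to keep naming
#'   consistent across samples.
#' @param level `"canonical"` or `"isomir"`.
#' @param strict canonical level only: count exact canonical sequences
#'   only, excluding isomiR reads.
#' @return A [mir_counts()] object.
#' @export
build_matrix <- function(calls_per_sample, catalog = NULL,
                         level = c("canonical", "isomir"),
                         strict = FALSE) {
  level <- match.arg(level)
  samples <- names(calls_per_sample)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("calls_per_sample must be a named list of per-sample call tables")
  if (level == "isomir" && is.null(catalog))
    stop("isomir-level counting requires a catalog")
  if (level == "isomir") {
    feat <- catalog$name
    key_of <- function(df) {
      i <- match(paste(df$mature_id, df$sequence, sep = "\r"),
                 paste(catalog$parent, catalog$sequence, sep = "\r"))
      if (anyNA(i))
        stop("integrity error: calls contain sequences absent from catalog")
      catalog$name[i]
    }
  } else {
    feat <- sort(unique(unlist(lapply(calls_per_sample,
                                      function(df) df$mature_id))))
    key_of <- function(df) df$mature_id
  }
  m <- matrix(0L, length(feat), length(samples),
              dimnames = list(feat, samples))
  for (s in samples) {
    df <- calls_per_sample[[s]]
    if (level == "canonical" && strict)
      df <- df[df$canonical, , drop = FALSE]
    if (nrow(df) == 0L) next
    agg <- tapply(df$multiplicity, key_of(df), sum)
    m[names(agg), s] <- as.integer(agg)
  }
  mir_counts(m, level)
}

#' Counts per million
#'
#' `CPM[f, s] = counts[f, s] / library_size[s] * 1e6`. Samples with zero
#' library size are dropped with a warning.
#'
#' @param x a [mir_counts()] object.
#' @return Numeric CPM matrix (same dimnames, minus any dropped samples).
#' @export
cpm <- function(x) {
  stopifnot(inherits(x, "mir_counts"))
  zero <- x$library_sizes == 0
  if (any(zero)) {
    warning("dropping zero-library samples: ",
            paste(names(x$library_sizes)[zero], collapse = ", "))
  }
  m <- x$counts[, !zero, drop = FALSE]
  sweep(m, 2, x$library_sizes[!zero], "/") * 1e6
}

#' Mean-percentage expression threshold
#'
#' A feature is kept iff its mean over all samples of
#' `count / library_size * 100` exceeds `min_mean_percent`. The default
#' 0.001% is the abundance floor used to call a miRNA or isomiR
#' "expressed".
#'
#' @param x a [mir_counts()] object.
#' @param min_mean_percent threshold on the mean percentage share.
#' @return List with `kept` (feature ids), `n_kept`, and the per-feature
#'   `mean_percent` vector.
#' @export
expression_filter <- function(x, min_mean_percent = 0.001) {
  stopifnot(inherits(x, "mir_counts"))
  pct <- sweep(x$counts, 2, pmax(1, x$library_sizes), "/") * 100
  mp <- rowMeans(pct)
  kept <- rownames(x$counts)[mp > min_mean_percent]
  list(kept = kept, n_kept = length(kept), mean_percent = mp)
}

#' Per-group abundance shares of the top features
#'
#' Share of feature f in group g is the pooled-count share:
#' `sum_s counts[f, s] / sum_s library_size[s] * 100` over the samples of
#' the group, i.e. calculated on the total miRNAs identified in each
#' group. `mean_of_shares = TRUE` averages per-sample shares instead (a
#' sensitivity alternative).
#'
#' @param x a [mir_counts()] object.
#' @param groups factor/character of group labels, named by or aligned to
#'   the samples of `x`.
#' @param top_n number of top features to report per group.
#' @param mean_of_shares use the mean of per-sample shares instead of
#'   pooled counts.
#' @return data.frame with `group`, `rank`, `feature_id`, `share_percent`,
#'   `cumulative_percent`.
#' @export
abundance_shares <- function(x, groups, top_n = 20L,
                             mean_of_shares = FALSE) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- align_groups(groups, colnames(x$counts))
  out <- lapply(levels(groups), function(g) {
    cols <- which(groups == g)
    share <- if (mean_of_shares) {
      rowMeans(sweep(x$counts[, cols, drop = FALSE], 2,
                     pmax(1, x$library_sizes[cols]), "/")) * 100
    } else {
      rowSums(x$counts[, cols, drop = FALSE]) /
        max(1, sum(x$library_sizes[cols])) * 100
    }
    ord <- order(-share, names(share))
    k <- min(top_n, length(share))
    data.frame(group = g, rank = seq_len(k),
               feature_id = names(share)[ord][seq_len(k)],
               share_percent = share[ord][seq_len(k)],
               cumulative_percent = cumsum(share[ord])[seq_len(k)],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

align_groups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    if (!all(sample_ids %in% names(groups)))
      stop("group labels missing for: ",
           paste(setdiff(sample_ids, names(groups)), collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("groups must be named by sample or match the sample count")
  }
  droplevels(as.factor(groups))
}

#' Read a sample-to-group manifest
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Named factor of group labels.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(m)))
    stop("manifest must have columns sample_id, group")
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  setNames(factor(m$group), m$sample_id)
}
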