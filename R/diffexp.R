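#' Log2 fold-change of group-mean CPM
#'
#' The reported effect size is the log2 ratio of arithmetic group means of
#' per-sample CPM, comparison group over reference group — the arithmetic
#' behind the published per-feature tables. Features with a zero group
#' mean under `pseudocount = 0` come back infinite/NaN and are flagged.
#'
#' @param mean_a,mean_b group-mean CPM vectors (reference group A,
#'   comparison group B).
#' @param pseudocount added to both means before the ratio (default 0).
#' @return Numeric vector `log2((mean_b + pc) / (mean_a + pc))`.
#' @export
log2fc_from_means <- function(mean_a, mean_b, pseudocount = 0) {
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Per-feature group means and log2 fold-change from a count matrix
#'
#' @param x a [mir_counts()] object.
#' @param groups two-level factor over the samples of `x` (named or
#'   aligned); the first level is the reference group A.
#' @param pseudocount passed to [log2fc_from_means()].
#' @return data.frame: `feature_id`, `mean_cpm_A`, `mean_cpm_B`,
#'   `mean_cpm_all`, `log2fc`, `finite` (FALSE where a zero group mean
#'   made the ratio infinite/undefined).
#' @export
group_log2fc <- function(x, groups, pseudocount = 0) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- align_groups(groups, colnames(x$counts))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  cp <- cpm(x)
  a <- levels(groups)[1]
  mean_a <- rowMeans(cp[, groups == a, drop = FALSE])
  mean_b <- rowMeans(cp[, groups != a, drop = FALSE])
  lfc <- log2fc_from_means(mean_a, mean_b, pseudocount)
  data.frame(feature_id = rownames(cp),
             mean_cpm_A = mean_a, mean_cpm_B = mean_b,
             mean_cpm_all = rowMeans(cp), log2fc = lfc,
             finite = is.finite(lfc), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Quantile adjustment of counts to a common (geometric-mean) library size
# under NB(mu, phi): each observation is mapped through its mid-P
# cumulative probability at the input mean to the matching quantile at the
# output mean. Equal input libraries are returned unchanged.
equalize_lib_sizes <- function(counts, lib_sizes, phi) {
  if (max(lib_sizes) - min(lib_sizes) < 1e-9) return(counts)
  out_lib <- exp(mean(log(lib_sizes)))
  p_feat <- rowSums(counts) / sum(lib_sizes)
  pseudo <- counts
  for (s in seq_len(ncol(counts))) {
    mu_in <- p_feat * lib_sizes[s]
    mu_out <- p_feat * out_lib
    x <- counts[, s]
    nz <- mu_in > 0
    if (phi > 0) {
      size <- 1 / phi
      pm <- pnbinom(x[nz] - 1, mu = mu_in[nz], size = size) +
        0.5 * dnbinom(x[nz], mu = mu_in[nz], size = size)
      pseudo[nz, s] <- qnbinom(pmin(pm, 1 - 1e-12),
                               mu = mu_out[nz], size = size)
    } else {
      pm <- ppois(x[nz] - 1, mu_in[nz]) + 0.5 * dpois(x[nz], mu_in[nz])
      pseudo[nz, s] <- qpois(pmin(pm, 1 - 1e-12), mu_out[nz])
    }
  }
  pseudo
}

# Conditional log-likelihood of dispersion phi for count rows with equal
# library sizes, summed over the two groups (terms constant in phi
# dropped). Returns a vector over features.
cond_loglik <- function(counts, groups, phi) {
  r <- 1 / phi
  ll <- numeric(nrow(counts))
  for (g in levels(groups)) {
    y <- counts[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + rowSums(lgamma(y + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r)
  }
  ll
}

#' Estimate common and tagwise NB dispersion by conditional likelihood
#'
#' Counts are quantile-adjusted to the geometric-mean library size, then
#' the common dispersion maximizes the across-feature mean conditional
#' log-likelihood on a log-phi grid spanning `[1e-6, 10]` (spline
#' interpolated). Tagwise dispersions maximize the weighted conditional
#' likelihood `CL_feature(phi) + prior_df * mean CL(phi)`, shrinking each
#' feature toward the common value; as `prior_df` grows the tagwise
#' estimates collapse onto the common one.
#'
#' @param x a [mir_counts()] object.
#' @param groups two-level factor over samples.
#' @param prior_df shrinkage weight toward the common likelihood.
#' @return List with `common_phi`, `tagwise_phi` (named per feature) and
#'   `pseudo_counts` (library-size-equalized matrix used downstream).
#' @export
estimate_dispersion <- function(x, groups, prior_df = 10) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- align_groups(groups, colnames(x$counts))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  counts <- x$counts
  if (all(counts == 0)) {
    warning("all-zero count matrix; dispersion set to 0")
    return(list(common_phi = 0,
                tagwise_phi = setNames(rep(0, nrow(counts)),
                                       rownames(counts)),
                pseudo_counts = counts))
  }
  lgrid <- seq(log(1e-6), log(10), length.out = 60L)
  phi_c <- 0.1
  pseudo <- counts
  for (it in 1:2) {                      # equalize <-> estimate
    pseudo <- equalize_lib_sizes(counts, x$library_sizes, phi_c)
    clmat <- vapply(lgrid,
                    function(lp) cond_loglik(pseudo, groups, exp(lp)),
                    numeric(nrow(counts)))
    clbar <- colMeans(clmat)
    sbar <- splinefun(lgrid, clbar)
    opt <- optimize(sbar, range(lgrid), maximum = TRUE, tol = 1e-10)
    phi_c <- exp(opt$maximum)
  }
  tag <- vapply(seq_len(nrow(pseudo)), function(f) {
    row <- pseudo[f, , drop = FALSE]
    if (all(row == 0)) return(phi_c)
    w <- optimize(function(lp) cond_loglik(row, groups, exp(lp)) +
                    prior_df * sbar(lp),
                  range(lgrid), maximum = TRUE, tol = 1e-10)
    exp(w$maximum)
  }, numeric(1))
  list(common_phi = phi_c,
       tagwise_phi = setNames(tag, rownames(counts)),
       pseudo_counts = pseudo)
}

# Two-sided exact NB p-value for one feature: condition on the total count
# z across both groups (equal per-sample means after equalization); the
# group-A sum follows the NB convolution NB(nA*mu, size nA/phi). The
# p-value sums the probabilities of all splits at most as probable as the
# observed one (small-probability summation, no doubling).
exact_test_one <- function(za, z, n_a, n_b, phi) {
  if (z == 0) return(1)
  mu <- z / (n_a + n_b)
  a <- 0:z
  if (phi > 0) {
    lp <- dnbinom(a, mu = n_a * mu, size = n_a / phi, log = TRUE) +
      dnbinom(z - a, mu = n_b * mu, size = n_b / phi, log = TRUE)
  } else {
    lp <- dpois(a, n_a * mu, log = TRUE) +
      dpois(z - a, n_b * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[za + 1] * (1 + 1e-7)])
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Library sizes are equalized by quantile adjustment (see
#' [estimate_dispersion()], whose pseudo-counts are reused when supplied),
#' then each feature is tested conditionally on its total count.
#'
#' @param x a [mir_counts()] object.
#' @param groups two-level factor over samples.
#' @param dispersion result of [estimate_dispersion()], or a single phi
#'   (>= 0) recycled over features, or a per-feature vector.
#' @return Numeric vector of two-sided p-values, named by feature.
#' @export
exact_test <- function(x, groups, dispersion) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- align_groups(groups, colnames(x$counts))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (is.list(dispersion)) {
    phi <- dispersion$tagwise_phi
    pseudo <- dispersion$pseudo_counts
  } else {
    phi <- dispersion
    pseudo <- equalize_lib_sizes(x$counts, x$library_sizes,
                                 max(mean(phi), 1e-6))
  }
  phi <- rep_len(phi, nrow(pseudo))
  n_a <- sum(groups == levels(groups)[1])
  n_b <- sum(groups != levels(groups)[1])
  za <- rowSums(pseudo[, groups == levels(groups)[1], drop = FALSE])
  z <- rowSums(pseudo)
  p <- vapply(seq_len(nrow(pseudo)), function(f)
    exact_test_one(za[f], z[f], n_a, n_b, phi[f]), numeric(1))
  setNames(pmin(p, 1), rownames(pseudo))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] step-up BH; preserves input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Two-group differential abundance analysis
#'
#' Applies the mean-CPM expression floor, estimates dispersion, runs the
#' exact test, adjusts by BH and attaches group-mean CPM log2 fold-changes
#' — yielding one row per tested feature in the shape of the published
#' per-feature tables.
#'
#' @param x a [mir_counts()] object.
#' @param groups two-level factor over samples; first level = reference A.
#' @param min_mean_cpm features with mean CPM over all samples below this
#'   are discarded before testing (default 10).
#' @param prior_df tagwise shrinkage weight for [estimate_dispersion()].
#' @param fdr_threshold significance threshold on BH FDR (default 0.1).
#' @param pseudocount for [log2fc_from_means()].
#' @return data.frame: `feature_id`, `mean_cpm_A`, `mean_cpm_B`,
#'   `mean_cpm_all`, `log2fc`, `finite`, `p_value`, `fdr_bh`,
#'   `significant`; attribute `common_phi`.
#' @export
de_analysis <- function(x, groups, min_mean_cpm = 10, prior_df = 10,
                        fdr_threshold = 0.1, pseudocount = 0) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- align_groups(groups, colnames(x$counts))
  keep <- rowMeans(cpm(x)) >= min_mean_cpm
  xf <- mir_counts(x$counts[keep, , drop = FALSE], x$level)
  xf$library_sizes <- x$library_sizes   # keep compartment-wide normalization
  disp <- estimate_dispersion(xf, groups, prior_df)
  p <- exact_test(xf, groups, disp)
  res <- group_log2fc(xf, groups, pseudocount)
  res$p_value <- unname(p[res$feature_id])
  res$fdr_bh <- bh_adjust(res$p_value)
  res$significant <- res$fdr_bh < fdr_threshold
  attr(res, "common_phi") <- disp$common_phi
  attr(res, "n_A") <- sum(groups == levels(groups)[1])
  attr(res, "n_B") <- sum(groups != levels(groups)[1])
  res
}

#' Select strongly modulated features
#'
#' Keeps features whose mean CPM over all samples passes the expression
#' floor and whose |log2FC| strictly exceeds the threshold, sorted by
#' log2FC descending. The significance flag (BH FDR) is carried along but
#' is not a selection criterion.
#'
#' @param results data.frame from [de_analysis()] or [group_log2fc()]
#'   (columns `feature_id`, `mean_cpm_A`, `mean_cpm_B`, `log2fc`; optional
#'   `mean_cpm_all`, `fdr_bh`).
#' @param lfc_threshold strong-modulation threshold on |log2FC|
#'   (strict inequality; default 2).
#' @param fdr_threshold threshold for the `significant` flag (default 0.1).
#' @param min_mean_cpm expression floor on mean CPM over all samples
#'   (default 10); when `mean_cpm_all` is absent it is reconstructed from
#'   the group means weighted by `n_A`/`n_B`.
#' @param n_A,n_B group sizes used for that reconstruction (defaults taken
#'   from `results` attributes when present).
#' @return The selected rows, sorted by `log2fc` descending, with
#'   `direction` (`"up"`/`"down"`) and `significant` columns; attributes
#'   `n_up` and `n_down`.
#' @export
select_strong <- function(results, lfc_threshold = 2, fdr_threshold = 0.1,
                          min_mean_cpm = 10,
                          n_A = attr(results, "n_A"),
                          n_B = attr(results, "n_B")) {
  res <- results
  if (is.null(res$mean_cpm_all)) {
    if (is.null(n_A) || is.null(n_B))
      stop("need mean_cpm_all or group sizes n_A/n_B")
    res$mean_cpm_all <- (n_A * res$mean_cpm_A + n_B * res$mean_cpm_B) /
      (n_A + n_B)
  }
  res <- res[res$mean_cpm_all >= min_mean_cpm, , drop = FALSE]
  res <- res[is.finite(res$log2fc) & abs(res$log2fc) > lfc_threshold, ,
             drop = FALSE]
  res <- res[order(-res$log2fc), , drop = FALSE]
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  if (!is.null(res$fdr_bh)) res$significant <- res$fdr_bh < fdr_threshold
  rownames(res) <- NULL
  attr(res, "n_up") <- sum(res$direction == "up")
  attr(res, "n_down") <- sum(res$direction == "down")
  res
}

#' Cross-cohort concordance classification
#'
#' Each discovery-cohort feature is placed in exactly one category against
#' a validation cohort: `not_expressed` if it fails the validation
#' expression threshold; `no_difference` if its validation |log2FC| is
#' below `lfc_min`; `confirmed` if the validation log2FC has the same sign
#' as in discovery; `opposite` otherwise.
#'
#' @param discovery data.frame with `feature_id`, `log2fc` (discovery).
#' @param validation data.frame with `feature_id`, `log2fc` (validation;
#'   same id namespace).
#' @param expressed_in_validation character vector of features passing the
#'   validation expression threshold.
#' @param lfc_min minimum validation |log2FC| to call a difference
#'   (default 0.5).
#' @return data.frame: `feature_id`, `discovery_log2fc`,
#'   `validation_log2fc` (NA when not expressed), `category`; attribute
#'   `category_counts`.
#' @export
classify_concordance <- function(discovery, validation,
                                 expressed_in_validation, lfc_min = 0.5) {
  if (anyDuplicated(discovery$feature_id) ||
      anyDuplicated(validation$feature_id))
    stop("integrity error: duplicate feature ids")
  v_lfc <- setNames(validation$log2fc, validation$feature_id)
  out <- data.frame(feature_id = discovery$feature_id,
                    discovery_log2fc = discovery$log2fc,
                    validation_log2fc = NA_real_,
                    category = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    id <- out$feature_id[i]
    if (!id %in% expressed_in_validation) {
      out$category[i] <- "not_expressed"
      next
    }
    vl <- if (id %in% names(v_lfc)) v_lfc[[id]] else 0
    out$validation_log2fc[i] <- vl
    out$category[i] <-
      if (abs(vl) < lfc_min) "no_difference"
      else if (sign(vl) == sign(out$discovery_log2fc[i])) "confirmed"
      else "opposite"
  }
  lev <- c("not_expressed", "no_difference", "confirmed", "opposite")
  attr(out, "category_counts") <- table(factor(out$category, levels = lev))
  out
}
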