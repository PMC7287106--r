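#' Process one sample: clean, de-contaminate, align, classify
#'
#' @param fastq FASTQ/FASTA path.
#' @param ref a [mirna_reference].
#' @param decoys optional decoy FASTA path or sequence vector.
#' @param params [align_params()] bounds.
#' @param min_len,max_len,adapter passed to [clean_reads()].
#' @param decoy_max_mismatch passed to [filter_contaminants()].
#' @return List with `calls` (classified alignment table), `qc` (named
#'   tallies: raw, length-filtered, contaminant, aligned, unaligned) and
#'   `sample_id`.
#' @export
process_sample <- function(fastq, ref, decoys = NULL,
                           params = align_params(), min_len = 15L,
                           max_len = 40L, adapter = NULL,
                           decoy_max_mismatch = 1L) {
  batch <- clean_reads(fastq, min_len, max_len, adapter)
  if (!is.null(decoys))
    batch <- filter_contaminants(batch, decoys, decoy_max_mismatch)
  aln <- align_to_hairpins(batch, ref, params)
  calls <- classify_alignments(aln$alignments)
  list(calls = calls,
       qc = c(raw = batch$n_raw, len_filtered = batch$n_len_filtered,
              contaminant = batch$n_contaminant,
              aligned = sum(calls$multiplicity),
              unaligned = aln$n_unaligned),
       sample_id = batch$sample_id)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> clean -> de-contaminate -> align ->
#' isomiR catalog -> count matrices (canonical and isomiR level) ->
#' expression threshold -> exact-test differential analysis -> strong
#' selection, writing every stage artifact as TSV/JSON under `out_dir`.
#' Deterministic given the config seed.
#'
#' @param config named list (or YAML path) with elements:
#'   `simulate` (logical; when TRUE a synthetic cohort is generated from
#'   `sim` sub-config passed to [sim_config()]), or `fastq` (named vector
#'   of per-sample paths), `hairpin_fasta` + `mature_table`,
#'   `decoy_fasta` (optional), `manifest` (TSV path) or `groups` (named
#'   vector); thresholds `min_mean_cpm`, `lfc_threshold`, `fdr_threshold`,
#'   `min_mean_percent`, `prior_df`; alignment bounds under `align`
#'   (passed to [align_params()]); `seed`.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the main in-memory artifacts: `ref`,
#'   `catalog`, `canonical` and `isomir` matrices, `de_canonical`,
#'   `de_isomir`, `strong_canonical`, `strong_isomir`, `qc`, and the
#'   output paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("simulate", "sim", "fastq", "hairpin_fasta", "mature_table",
             "decoy_fasta", "manifest", "groups", "min_mean_cpm",
             "lfc_threshold", "fdr_threshold", "min_mean_percent",
             "prior_df", "align", "adapter", "min_len", "max_len", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  get <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  if (!isTRUE(config$simulate)) {
    for (field in c("hairpin_fasta", "mature_table", "fastq"))
      if (is.null(config[[field]]))
        stop("config error: missing field '", field, "'")
    if (is.null(config$manifest) && is.null(config$groups))
      stop("config error: missing field 'manifest' (or 'groups')")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  params <- do.call(align_params, as.list(get("align", list())))

  if (isTRUE(config$simulate)) {
    cfg <- do.call(sim_config, as.list(get("sim", list())))
    ref <- simulate_reference(cfg$n_mirnas, cfg$seed, cfg$shift5_indel_base)
    sim <- simulate_counts(cfg, ref)
    em <- emit_reads(sim, ref, cfg, file.path(out_dir, "reads"))
    fastq <- em$fastq
    decoys <- em$decoy_fasta
    groups <- sim$groups
    write_reference(ref, file.path(out_dir, "hairpins.fa"),
                    file.path(out_dir, "matures.tsv"))
  } else {
    ref <- load_reference(config$hairpin_fasta, config$mature_table)
    fastq <- unlist(config$fastq)
    if (is.null(names(fastq)) || any(!nzchar(names(fastq))))
      stop("config error: 'fastq' must be a named sample -> path map")
    decoys <- config$decoy_fasta
    groups <- if (!is.null(config$manifest)) read_manifest(config$manifest)
              else if (!is.null(config$groups))
                setNames(factor(unlist(config$groups)),
                         names(unlist(config$groups)))
              else stop("config error: missing field 'manifest' (or 'groups')")
  }

  proc <- lapply(names(fastq), function(s) {
    p <- process_sample(fastq[[s]], ref, decoys, params,
                        min_len = get("min_len", 15L),
                        max_len = get("max_len", 40L),
                        adapter = get("adapter", NULL))
    p$sample_id <- s
    p
  })
  names(proc) <- names(fastq)
  calls <- lapply(proc, `[[`, "calls")
  qc <- do.call(rbind, lapply(proc, `[[`, "qc"))
  write_json_file(apply(qc, 1, as.list), file.path(out_dir, "qc.json"))

  catalog <- assign_names(do.call(rbind, calls))
  write.table(catalog, file.path(out_dir, "isomir_catalog.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  mats <- list(canonical = build_matrix(calls, catalog, "canonical"),
               isomir = build_matrix(calls, catalog, "isomir"))
  results <- list(ref = ref, catalog = catalog, qc = qc,
                  canonical = mats$canonical, isomir = mats$isomir)
  for (lv in names(mats)) {
    m <- mats[[lv]]
    write.table(data.frame(feature_id = rownames(m$counts), m$counts,
                           check.names = FALSE),
                file.path(out_dir, paste0("counts_", lv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    expr <- expression_filter(m, get("min_mean_percent", 0.001))
    keep <- expr$kept
    mk <- mir_counts(m$counts[keep, , drop = FALSE], m$level)
    mk$library_sizes <- m$library_sizes
    de <- de_analysis(mk, groups,
                      min_mean_cpm = get("min_mean_cpm", 10),
                      prior_df = get("prior_df", 10),
                      fdr_threshold = get("fdr_threshold", 0.1))
    strong <- select_strong(de, get("lfc_threshold", 2),
                            get("fdr_threshold", 0.1),
                            get("min_mean_cpm", 10))
    write.table(de, file.path(out_dir, paste0("diffexp_", lv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(strong, file.path(out_dir, paste0("strong_", lv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results[[paste0("expressed_", lv)]] <- expr
    results[[paste0("de_", lv)]] <- de
    results[[paste0("strong_", lv)]] <- strong
  }
  shares <- abundance_shares(results$canonical, groups)
  write.table(shares, file.path(out_dir, "abundance_shares.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$shares <- shares
  results$groups <- groups

  tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  writeLines(paste(tools::md5sum(tsvs), basename(tsvs)),
             file.path(out_dir, "MANIFEST"))
  results$out_dir <- out_dir
  invisible(results)
}

write_json_file <- function(x, path) {
  # minimal writer for the QC tallies (flat lists of scalars)
  esc <- function(s) gsub('"', '\\"', s, fixed = TRUE)
  enc <- function(v) {
    if (is.list(v))
      paste0("{", paste(sprintf('"%s": %s', esc(names(v)),
                                vapply(v, enc, character(1))),
                        collapse = ", "), "}")
    else if (is.numeric(v)) format(v, digits = 15)
    else paste0('"', esc(as.character(v)), '"')
  }
  writeLines(enc(as.list(x)), path)
  invisible(path)
}

#' Render figure analogues from pipeline outputs
#'
#' Writes, for each figure, both the numeric table behind it (TSV) and a
#' PNG: per-group abundance pie of the top features, the strong-feature
#' log2FC bar chart at canonical level, and the isomiR log2FC bar chart.
#' Every number drawn comes from a table on disk.
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(out_dir) {
  paths <- character(0)
  shares <- read.delim(file.path(out_dir, "abundance_shares.tsv"))
  for (g in unique(shares$group)) {
    s <- shares[shares$group == g, ]
    png_path <- file.path(out_dir, sprintf("fig_abundance_%s.png", g))
    grDevices::png(png_path, 720, 720)
    graphics::pie(s$share_percent,
                  labels = sprintf("%s (%.1f%%)", s$feature_id,
                                   s$share_percent),
                  main = sprintf("Top miRNAs, group %s", g))
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  for (lv in c("canonical", "isomir")) {
    f <- file.path(out_dir, paste0("strong_", lv, ".tsv"))
    if (!file.exists(f)) next
    st <- read.delim(f)
    png_path <- file.path(out_dir, sprintf("fig_log2fc_%s.png", lv))
    grDevices::png(png_path, 960, 640)
    if (nrow(st)) {
      graphics::par(mar = c(12, 4, 2, 1))
      graphics::barplot(st$log2fc, names.arg = st$feature_id, las = 2,
                        cex.names = 0.6, ylab = "log2FC (B vs A)",
                        main = sprintf("Strongly modulated (%s)", lv))
    } else graphics::plot.new()
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
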