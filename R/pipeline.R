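#' Run the full audit pipeline end to end
#'
#' Reads (or simulates) a barcode community, audits it, and writes the
#' complete report bundle to a directory. Validation problems (missing
#' files, malformed input) raise errors; analytical outcomes such as a
#' low success rate are results, not errors. Outputs are byte-stable for
#' identical inputs and configuration.
#'
#' @param fasta,metadata input paths (see [read_dataset()]); ignored when
#'   `sim` is given.
#' @param sim optional `sim_community` (from [simulate_community()]) to
#'   audit instead of files.
#' @param out_dir output directory, created if needed.
#' @param threshold,min_len,comparable_floor,bin_width,outgroup passed to
#'   [barcode_audit()]; when `sim` is given and `outgroup` is `NULL`, the
#'   simulated outgroup is used.
#' @param write_distances also export the full distance matrix TSV
#'   (large; off by default).
#' @param label_template optional Newick leaf-label template using the
#'   placeholders `{specimen_id}`, `{genus}`, `{species}`, `{region}`.
#' @return Invisibly, the `barcode_audit` object.
#' @export
run_pipeline <- function(fasta = NULL, metadata = NULL, sim = NULL,
                         out_dir, threshold = 3, min_len = 500,
                         comparable_floor = 400, bin_width = 1,
                         outgroup = NULL, write_distances = FALSE,
                         label_template = NULL) {
  if (is.null(sim)) {
    if (is.null(fasta) || is.null(metadata))
      stop("input stage: supply fasta + metadata paths, or sim")
    data <- read_dataset(fasta, metadata)
  } else {
    stopifnot(inherits(sim, "sim_community"))
    data <- sim$dataset
    if (is.null(outgroup)) outgroup <- sim$outgroup
  }
  audit <- barcode_audit(data, threshold = threshold, min_len = min_len,
                         comparable_floor = comparable_floor,
                         bin_width = bin_width, outgroup = outgroup)
  write_audit_reports(audit, out_dir, write_distances = write_distances,
                      label_template = label_template)
  invisible(audit)
}

#' Write the audit report bundle
#'
#' Emits the machine-readable analogues of a barcode-library audit:
#' `qc_report.tsv`, `assessments.tsv` (species, n, condition, congeners),
#' `deep_splits.tsv` (cluster sizes as `"a/b/c"`), `histogram.tsv` (per
#' bin: intraspecific and congeneric counts), `regression.tsv` +
#' `regression_points.tsv`, `tree.nwk` (rooted), `summary.json`, and
#' optionally `distance_matrix.tsv` (proportions). Column orders are
#' fixed so repeated runs diff cleanly.
#'
#' @param audit a `barcode_audit`.
#' @param out_dir output directory, created if needed.
#' @param write_distances export the distance matrix too.
#' @param label_template optional leaf-label template, see
#'   [run_pipeline()].
#' @return Invisibly, the vector of files written.
#' @export
write_audit_reports <- function(audit, out_dir, write_distances = FALSE,
                                label_template = NULL) {
  stopifnot(inherits(audit, "barcode_audit"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  files <- character()

  tsv(audit$qc, "qc_report.tsv"); files <- c(files, "qc_report.tsv")
  tsv(audit$assessments[, c("species", "n_specimens", "condition",
                            "congeners_involved")],
      "assessments.tsv"); files <- c(files, "assessments.tsv")
  tsv(audit$deep_splits, "deep_splits.tsv")
  files <- c(files, "deep_splits.tsv")

  h <- audit$divergence$histogram
  k <- length(h$edges) - 1L
  tsv(data.frame(bin_low_pct = h$edges[-(k + 1L)],
                 bin_high_pct = h$edges[-1L],
                 intraspecific = h$intra_counts,
                 congeneric = h$congeneric_counts),
      "histogram.tsv"); files <- c(files, "histogram.tsv")

  if (!is.null(audit$regression)) {
    r <- audit$regression
    tsv(data.frame(slope = r$slope, intercept = r$intercept,
                   r_squared = r$r_squared, p_value = r$p_value,
                   n_points = r$n_points), "regression.tsv")
    tsv(r$points, "regression_points.tsv")
    files <- c(files, "regression.tsv", "regression_points.tsv")
  }

  tr <- audit$rooted_tree
  if (!is.null(label_template)) {
    rec <- audit$data$records
    ix <- match(tr$tip.label, rec$specimen_id)
    lab <- label_template
    lab <- rep(lab, length(ix))
    for (f in c("specimen_id", "genus", "species", "region"))
      lab <- mapply(gsub, pattern = paste0("{", f, "}"),
                    replacement = rec[[f]][ix], x = lab,
                    MoreArgs = list(fixed = TRUE), USE.NAMES = FALSE)
    tr$tip.label <- lab
  }
  write_newick(tr, p("tree.nwk")); files <- c(files, "tree.nwk")

  if (write_distances) {
    write_distance_matrix(audit$dist, p("distance_matrix.tsv"))
    files <- c(files, "distance_matrix.tsv")
  }

  a <- audit$assessments
  g <- audit$divergence$global
  cond <- as.list(table(factor(a$condition, levels = CONDITION_LEVELS)))
  summary <- list(
    package_version = as.character(packageVersion("bcaudit")),
    n_specimens = nrow(audit$data$records),
    n_species = nrow(a),
    n_genera = length(unique(a$genus)),
    alignment_length = audit$data$alignment_length,
    n_multi_specimen_species = g$n_multi_species,
    success = audit$success,
    condition_counts = cond,
    mean_intra_pct = g$mean_intra_pct,
    range_intra_pct = g$range_intra_pct,
    mean_congeneric_pct = g$mean_congeneric_pct,
    range_congeneric_pct = g$range_congeneric_pct,
    n_intra_comparisons = g$n_intra_comparisons,
    n_congeneric_comparisons = g$n_congeneric_comparisons,
    n_deep_split_species = sum(audit$deep_splits$flagged),
    threshold_pct = audit$params$threshold,
    min_len = audit$params$min_len,
    comparable_floor = audit$params$comparable_floor,
    rooting = audit$params$rooting,
    outgroup = audit$params$outgroup
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, "summary.json")
  invisible(file.path(out_dir, files))
}
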