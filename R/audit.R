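#' Audit a barcode reference library
#'
#' The one-call entry point: runs the full species-discrimination audit
#' on an aligned barcode dataset and returns a classed result holding
#' every stage's output. Stages: quality flags ([qc_flags()]), pairwise
#' K2P distances ([distance_matrix()]), neighbour-joining tree
#' ([build_nj()], rooted on the outgroup when given, else midpoint),
#' per-species diagnosability ([classify_species()]), divergence and
#' barcode-gap summaries ([divergence_summary()]), deep-split flags
#' ([flag_deep_splits()]) and the sampling-bias regression
#' ([sampling_regression()]).
#'
#' @param data a [barcode_dataset] (see also [read_dataset()] and
#'   [simulate_community()]).
#' @param threshold deep-split divergence threshold in percent (strict
#'   `>`; default 3).
#' @param min_len minimum unambiguous length for the quality flag
#'   (default 500).
#' @param comparable_floor minimum comparable sites for haplotype
#'   identity (default 400).
#' @param bin_width histogram bin width in percent (default 1).
#' @param outgroup optional outgroup species name(s) (`"Genus epithet"`);
#'   used for rooting and excluded from species assessments.
#' @return An object of class `barcode_audit` with elements `data`, `qc`,
#'   `dist`, `tree` (unrooted), `rooted_tree`, `assessments`, `success`,
#'   `divergence`, `deep_splits`, `regression` (`NULL` when fewer than 3
#'   multi-specimen species), `params` and `call`.
#' @examples
#' sim <- simulate_community(n_genera = 6, n_shared_haplotype = 1,
#'                           n_paraphyly = 1, n_deep_split_2 = 1,
#'                           n_deep_split_3 = 0, seed = 7)
#' a <- barcode_audit(sim$dataset, outgroup = sim$outgroup)
#' summary(a)
#' @export
barcode_audit <- function(data, threshold = 3, min_len = 500,
                          comparable_floor = 400, bin_width = 1,
                          outgroup = NULL) {
  stopifnot(inherits(data, "barcode_dataset"))
  qc <- qc_flags(data, min_len = min_len)
  m <- distance_matrix(data)
  tree <- build_nj(m)
  assessments <- classify_species(tree, data, dist = m,
                                  outgroup = outgroup,
                                  comparable_floor = comparable_floor)
  og_tips <- if (!is.null(outgroup))
    data$records$specimen_id[
      paste(data$records$genus, data$records$species) %in% outgroup]
    else character()
  rooted <- if (length(og_tips) && length(og_tips) < ape::Ntip(tree) &&
                is_monophyletic(tree, og_tips))
    root_tree(tree, og_tips) else .root_midpoint(tree)
  div <- divergence_summary(m, data, bin_width = bin_width)
  splits <- flag_deep_splits(m, data, threshold = threshold)
  reg <- if (nrow(div$per_species) >= 3L &&
             var(div$per_species$n_specimens) > 0)
    sampling_regression(div) else NULL
  structure(list(
    data = data, qc = qc, dist = m, tree = tree, rooted_tree = rooted,
    assessments = assessments, success = success_rate(assessments),
    divergence = div, deep_splits = splits, regression = reg,
    params = list(threshold = threshold, min_len = min_len,
                  comparable_floor = comparable_floor,
                  bin_width = bin_width, outgroup = outgroup,
                  rooting = attr(assessments, "rooting")),
    call = match.call()
  ), class = "barcode_audit")
}

#' @export
print.barcode_audit <- function(x, ...) {
  a <- x$assessments
  s <- x$success
  cat("Barcode library audit\n")
  cat(sprintf("  %d specimens, %d species, %d genera; alignment %d bp\n",
              nrow(x$data$records), nrow(a), length(unique(a$genus)),
              x$data$alignment_length))
  cat(sprintf("  diagnosable species: %d/%d (%.1f%%)\n",
              s$n_success, s$n_total, 100 * s$proportion))
  cat(sprintf("  deep splits (>%g%%): %d species\n",
              x$params$threshold, sum(x$deep_splits$flagged)))
  invisible(x)
}

#' @export
summary.barcode_audit <- function(object, ...) {
  structure(list(audit = object), class = "summary.barcode_audit")
}

#' @export
print.summary.barcode_audit <- function(x, ...) {
  a <- x$audit
  print(a)
  cat("\nConditions:\n")
  tb <- table(factor(a$assessments$condition, levels = CONDITION_LEVELS))
  for (nm in names(tb)) if (tb[[nm]] > 0)
    cat(sprintf("  %-26s %d\n", nm, tb[[nm]]))
  cat("\n")
  print(a$divergence)
  if (!is.null(a$regression)) {
    cat("\nSampling-bias regression (mean intraspecific % ~ n):\n  ")
    print(a$regression)
  }
  flagged <- a$deep_splits[a$deep_splits$flagged, , drop = FALSE]
  if (nrow(flagged)) {
    cat("\nDeep intraspecific splits:\n")
    print(flagged[, c("species", "n_specimens", "cluster_sizes",
                      "mean_intra_pct")], row.names = FALSE)
  }
  cat(sprintf("\nQC: %d/%d records meet the %d-bp standard (advisory)\n",
              sum(a$qc$meets_standard), nrow(a$qc), a$params$min_len))
  invisible(x)
}

#' @export
coef.barcode_audit <- function(object, ...) {
  if (is.null(object$regression)) return(NULL)
  coef(object$regression)
}

#' Plot a barcode audit
#'
#' Two panels: the barcode-gap histogram (intraspecific vs congeneric
#' K2P divergence) and the sampling-bias scatter of mean intraspecific
#' divergence against sample size with the fitted OLS line.
#'
#' @param x a `barcode_audit`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.barcode_audit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  h <- x$divergence$histogram
  mids <- h$edges[-length(h$edges)] + diff(h$edges) / 2
  ylim <- c(0, max(c(h$intra_counts, h$congeneric_counts, 1)))
  plot(mids, h$intra_counts, type = "h", lwd = 4, col = "grey40",
       xlab = "K2P divergence (%)", ylab = "comparisons",
       ylim = ylim, main = "Barcode gap", ...)
  lines(mids + 0.25, h$congeneric_counts, type = "h", lwd = 4,
        col = "grey70")
  legend("topright", legend = c("intraspecific", "congeneric"),
         fill = c("grey40", "grey70"), bty = "n")
  ps <- x$divergence$per_species
  plot(ps$n_specimens, ps$mean_intra_pct,
       xlab = "individuals sampled", ylab = "mean intraspecific K2P (%)",
       main = "Sampling bias", ...)
  if (!is.null(x$regression))
    abline(coef(x$regression)[1], coef(x$regression)[2], lty = 2)
  invisible(x)
}
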