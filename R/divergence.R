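#' Histogram of divergence values
#'
#' Bins percent divergences into left-closed, right-open intervals
#' starting at zero, the convention used for barcode-gap histograms.
#'
#' @param values non-negative numeric vector (percent divergences).
#' @param bin_width bin width in percent (default 1).
#' @return List with `edges` (length `k + 1`) and `counts` (length `k`);
#'   counts always sum to `length(values)`.
#' @export
divergence_histogram <- function(values, bin_width = 1.0) {
  stopifnot(is.numeric(values), bin_width > 0)
  if (any(values < 0)) stop("divergence values must be non-negative")
  if (length(values) == 0L)
    return(list(edges = c(0, bin_width), counts = 0L))
  top <- bin_width * (floor(max(values) / bin_width) + 1L)
  edges <- seq(0, top, by = bin_width)
  bins <- findInterval(values, edges, rightmost.closed = FALSE)
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  list(edges = edges, counts = counts)
}

#' Intra- and interspecific divergence summary (the barcode gap)
#'
#' Partitions all specimen pairs into intraspecific, congeneric
#' interspecific (different species, same genus) and other (cross-genus,
#' excluded from both distributions), and summarises the first two: the
#' separation of these distributions is the "barcode gap" that makes
#' barcode identification possible.
#'
#' @param m a `k2p_dist` from [distance_matrix()].
#' @param d the matching [barcode_dataset].
#' @param bin_width histogram bin width in percent.
#' @return An object of class `divergence_summary`: list with
#'   `per_species` (data frame: species, genus, n, mean/max intraspecific
#'   percent divergence, for species with >= 2 specimens), `intra_values`
#'   and `congeneric_values` (percent), `global` (means, ranges and
#'   comparison counts) and `histogram` (shared edges plus both count
#'   vectors).
#' @export
divergence_summary <- function(m, d, bin_width = 1.0) {
  stopifnot(inherits(m, "k2p_dist"), inherits(d, "barcode_dataset"))
  rec <- d$records
  stopifnot(identical(m$ids, rec$specimen_id))
  sp <- paste(rec$genus, rec$species)
  gen <- rec$genus
  ut <- upper.tri(m$d)
  same_sp <- outer(sp, sp, "==")
  same_gen <- outer(gen, gen, "==")
  pct <- m$d * 100
  intra <- pct[ut & same_sp]
  inter <- pct[ut & same_gen & !same_sp]
  n_other <- sum(ut) - length(intra) - length(inter)

  multi <- names(which(table(sp) >= 2))
  per_species <- do.call(rbind, lapply(multi, function(s) {
    ix <- which(sp == s)
    v <- pct[ix, ix][upper.tri(diag(length(ix)))]
    data.frame(species = s, genus = gen[ix[1]], n_specimens = length(ix),
               mean_intra_pct = mean(v), max_intra_pct = max(v),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_species))
    per_species <- data.frame(species = character(), genus = character(),
                              n_specimens = integer(),
                              mean_intra_pct = numeric(),
                              max_intra_pct = numeric(),
                              stringsAsFactors = FALSE)
  per_species <- per_species[order(per_species$species), , drop = FALSE]
  rownames(per_species) <- NULL

  all_vals <- c(intra, inter)
  top <- if (length(all_vals)) max(all_vals) else 0
  h_edges <- seq(0, bin_width * (floor(top / bin_width) + 1L),
                 by = bin_width)
  hist_one <- function(v) {
    if (!length(v)) return(integer(length(h_edges) - 1L))
    tabulate(findInterval(v, h_edges), nbins = length(h_edges) - 1L)
  }
  rng <- function(v) if (length(v)) range(v) else c(NA_real_, NA_real_)
  structure(list(
    per_species = per_species,
    intra_values = intra,
    congeneric_values = inter,
    global = list(
      mean_intra_pct = if (length(intra)) mean(intra) else NA_real_,
      range_intra_pct = rng(intra),
      n_intra_comparisons = length(intra),
      n_multi_species = nrow(per_species),
      mean_congeneric_pct = if (length(inter)) mean(inter) else NA_real_,
      range_congeneric_pct = rng(inter),
      n_congeneric_comparisons = length(inter),
      n_other_comparisons = n_other
    ),
    histogram = list(edges = h_edges, intra_counts = hist_one(intra),
                     congeneric_counts = hist_one(inter))
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  g <- x$global
  cat("Divergence summary (K2P, %)\n")
  cat(sprintf("  intraspecific: mean %.2f%% (range %.2f-%.2f), %d comparisons in %d species\n",
              g$mean_intra_pct, g$range_intra_pct[1], g$range_intra_pct[2],
              g$n_intra_comparisons, g$n_multi_species))
  cat(sprintf("  congeneric:    mean %.2f%% (range %.2f-%.2f), %d comparisons\n",
              g$mean_congeneric_pct, g$range_congeneric_pct[1],
              g$range_congeneric_pct[2], g$n_congeneric_comparisons))
  if (!is.na(g$mean_intra_pct) && g$mean_intra_pct > 0)
    cat(sprintf("  fold ratio (congeneric/intraspecific): %.1f\n",
                g$mean_congeneric_pct / g$mean_intra_pct))
  invisible(x)
}

#' Single-linkage divergence clusters within a specimen set
#'
#' Groups specimens so that members of a cluster are connected by a chain
#' of pairwise divergences at or below the threshold (single-linkage
#' agglomeration, equivalently connected components of the
#' threshold graph). Used to count the distinct barcode lineages inside a
#' species.
#'
#' @param m a `k2p_dist`.
#' @param members specimen IDs to cluster (>= 1).
#' @param threshold chaining threshold in percent (default 3).
#' @return List of character vectors (cluster members), ordered by first
#'   appearance of a member.
#' @export
split_clusters <- function(m, members, threshold = 3.0) {
  stopifnot(inherits(m, "k2p_dist"), length(members) >= 1L,
            all(members %in% m$ids))
  if (length(members) == 1L) return(list(members))
  sub <- m$d[members, members, drop = FALSE] * 100
  hc <- hclust(as.dist(sub), method = "single")
  grp <- cutree(hc, h = threshold)
  split(members, factor(grp, levels = unique(grp)))
}

#' Flag species with deep intraspecific divergence
#'
#' Reports, for every species with two or more specimens, its
#' single-linkage clusters at the divergence threshold. A species is
#' flagged when it breaks into two or more clusters — i.e. when some
#' intraspecific divergence strictly exceeds the threshold even after
#' chaining. Deep splits of this kind are candidate cryptic species (or
#' misidentifications) deserving taxonomic scrutiny; 3% is the
#' conventional threshold, which generally falls inside the barcode gap.
#'
#' @param m a `k2p_dist`.
#' @param d the matching [barcode_dataset].
#' @param threshold percent divergence threshold (strict `>`; default 3).
#' @return A data frame of class `deep_split_report` with one row per
#'   multi-specimen species: `species`, `n_specimens`, `n_clusters`,
#'   `cluster_sizes` (`"a/b/c"` style), `mean_intra_pct` (mean over all
#'   intraspecific pairs), `flagged`.
#' @export
flag_deep_splits <- function(m, d, threshold = 3.0) {
  stopifnot(inherits(m, "k2p_dist"), inherits(d, "barcode_dataset"))
  rec <- d$records
  sp <- paste(rec$genus, rec$species)
  multi <- names(which(table(sp) >= 2))
  out <- do.call(rbind, lapply(sort(multi), function(s) {
    ids <- rec$specimen_id[sp == s]
    cl <- split_clusters(m, ids, threshold)
    ix <- match(ids, m$ids)
    v <- m$d[ix, ix][upper.tri(diag(length(ix)))] * 100
    data.frame(species = s, n_specimens = length(ids),
               n_clusters = length(cl),
               cluster_sizes = paste(lengths(cl), collapse = "/"),
               mean_intra_pct = mean(v),
               flagged = length(cl) >= 2L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(species = character(), n_specimens = integer(),
                      n_clusters = integer(), cluster_sizes = character(),
                      mean_intra_pct = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "mean_definition") <-
    "mean over all intraspecific pairs (not between-cluster only)"
  class(out) <- c("deep_split_report", "data.frame")
  out
}
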