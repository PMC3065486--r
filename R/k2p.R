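#' Kimura 2-parameter distance between two aligned sequences
#'
#' The K2P model distinguishes transitions (A<->G, C<->T) from
#' transversions (all other changes). With P and Q the proportions of
#' comparable sites differing by a transition and a transversion,
#' respectively, the distance (expected substitutions per site) is
#' \deqn{d = -\tfrac{1}{2}\ln\bigl((1 - 2P - Q)\sqrt{1 - 2Q}\bigr).}
#' Comparable sites are those where *both* sequences carry an unambiguous
#' A/C/G/T (pairwise deletion); gaps, N and the other IUPAC ambiguity
#' codes are skipped per pair, so full-length and mini-barcode records can
#' be compared without discarding whole columns.
#'
#' @param seq_a,seq_b aligned sequences of equal length (IUPAC strings).
#' @return A list with `distance` (proportion, not percent) and `sites`
#'   (the number of comparable sites used).
#' @section Errors: zero comparable sites raise an undefined-distance
#'   error; a pair beyond the model's validity range (the log argument
#'   non-positive) raises a saturation error rather than returning `NaN`.
#' @examples
#' k2p_pair("ACGTACGTAC", "ACGTACGTAC")          # d = 0, 10 sites
#' k2p_pair("ACGTACGTAC", "GCGTACGTAC")$distance # one transition in 10
#' @export
k2p_pair <- function(seq_a, seq_b) {
  d <- barcode_dataset(c("a", "b"), c("G", "G"), c("x", "y"), c("", ""),
                       c(seq_a, seq_b))
  m <- distance_matrix(d)
  list(distance = m$d[1, 2], sites = m$sites[1, 2])
}

#' Pairwise K2P distance matrix for a dataset
#'
#' Computes all pairwise Kimura 2-parameter distances (see [k2p_pair()]
#' for the model and the pairwise-deletion convention) in metadata order.
#' Distances are stored as proportions; reports render them as percent.
#'
#' @param d a [barcode_dataset] with at least two records.
#' @return An object of class `k2p_dist`: list with `ids` (specimen IDs),
#'   `d` (symmetric numeric matrix of distances, zero diagonal) and
#'   `sites` (symmetric integer matrix of comparable-site counts; the
#'   diagonal holds each record's unambiguous length).
#' @export
distance_matrix <- function(d) {
  stopifnot(inherits(d, "barcode_dataset"))
  if (nrow(d$records) < 2L)
    stop("at least 2 records are required for a distance matrix")
  enc <- .encode_sequences(d)
  res <- .k2p_engine(enc)
  ids <- d$records$specimen_id
  dm <- res$d
  sm <- res$sites
  dimnames(dm) <- dimnames(sm) <- list(ids, ids)
  bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined distance: no comparable sites between ",
         ids[bad[1, 1]], " and ", ids[bad[1, 2]])
  sat <- which(dm < 0 & upper.tri(dm), arr.ind = TRUE)
  if (nrow(sat))
    stop("saturation: K2P distance undefined for pair ",
         ids[sat[1, 1]], " / ", ids[sat[1, 2]],
         " (substitution proportions exceed the model's range)")
  structure(list(ids = ids, d = dm, sites = sm), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat("K2P distance matrix: ", n, " specimens, ", length(off),
      " pairs\n", sep = "")
  if (length(off))
    cat(sprintf("  mean %.4f  range %.4f-%.4f (proportions)\n",
                mean(off), min(off), max(off)))
  invisible(x)
}

#' Export a distance matrix as square TSV
#'
#' Writes the distances (proportions) as a square tab-separated matrix
#' with a header row and leading column of specimen IDs, readable as a
#' standard distance-matrix dialect.
#'
#' @param m a `k2p_dist` object.
#' @param path output path.
#' @return Invisibly, `m`.
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(inherits(m, "k2p_dist"))
  df <- data.frame(specimen_id = m$ids, m$d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
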