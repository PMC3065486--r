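# all bipartition keys of an (unrooted) tree; a leaf subset is
# monophyletic iff its sorted-index key or its complement's key is present
.bipart_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  vapply(pp, function(v) paste(sort(v), collapse = "."), character(1))
}

.subset_key <- function(idx) paste(sort(idx), collapse = ".")

.is_mono_idx <- function(idx, ntip, keys) {
  k <- length(idx)
  # singletons and complements of singletons split off a terminal edge
  if (k <= 1L || k >= ntip - 1L) return(TRUE)
  .subset_key(idx) %in% keys ||
    .subset_key(setdiff(seq_len(ntip), idx)) %in% keys
}

#' Test monophyly of a leaf subset on an unrooted tree
#'
#' A subset is monophyletic on an unrooted tree iff removing some single
#' edge bipartitions the leaves into exactly the subset and its
#' complement — equivalently, the subset is a clade under some rooting
#' outside it. Singletons are monophyletic by convention.
#'
#' @param tree a `phylo` tree.
#' @param leaf_subset non-empty character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, leaf_subset) {
  stopifnot(inherits(tree, "phylo"), length(leaf_subset) >= 1L)
  idx <- match(leaf_subset, tree$tip.label)
  if (anyNA(idx))
    stop("unknown leaves: ",
         paste(leaf_subset[is.na(idx)], collapse = ", "))
  .is_mono_idx(unique(idx), ape::Ntip(tree), .bipart_keys(tree))
}

#' Find identical haplotypes shared across species boundaries
#'
#' Two specimens share a haplotype when their sequences agree at every
#' site where both are unambiguous *and* they have at least
#' `comparable_floor` comparable sites — the floor prevents short
#' mini-barcode fragments from "matching" everything they overlap.
#' Within-species sharing is normal and is not reported; only
#' cross-species pairs preclude barcode diagnosis.
#'
#' @param d a [barcode_dataset].
#' @param comparable_floor minimum comparable sites for a match
#'   (default 400).
#' @param dist optional precomputed [distance_matrix()] for `d` (identity
#'   is equivalent to a K2P distance of exactly zero).
#' @return A data frame of cross-species identical pairs with columns
#'   `specimen_a`, `specimen_b`, `species_a`, `species_b`. Attribute
#'   `excluded_short` lists identical pairs suppressed by the floor.
#' @export
haplotype_sharing <- function(d, comparable_floor = 400, dist = NULL) {
  stopifnot(inherits(d, "barcode_dataset"))
  rec <- d$records
  if (nrow(rec) < 2L) {
    out <- data.frame(specimen_a = character(), specimen_b = character(),
                      species_a = character(), species_b = character(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded_short") <- out
    return(out)
  }
  if (is.null(dist)) dist <- distance_matrix(d)
  sp <- paste(rec$genus, rec$species)
  ident <- dist$d == 0 & upper.tri(dist$d)
  cross <- ident & outer(sp, sp, "!=")
  deep <- dist$sites >= comparable_floor
  keep <- which(cross & deep, arr.ind = TRUE)
  shallow <- which(cross & !deep, arr.ind = TRUE)
  as_df <- function(ix) data.frame(
    specimen_a = rec$specimen_id[ix[, 1]],
    specimen_b = rec$specimen_id[ix[, 2]],
    species_a = sp[ix[, 1]],
    species_b = sp[ix[, 2]],
    stringsAsFactors = FALSE)
  out <- as_df(keep)
  attr(out, "excluded_short") <- as_df(shallow)
  out
}

CONDITION_LEVELS <- c("DISTINCT", "SINGLETON_DISTINCT", "PARAPHYLETIC",
                      "POLYPHYLETIC", "IDENTICAL_SHARED", "OVERLAPPING",
                      "IDENTICAL_AND_OVERLAPPING")

#' Classify each species' diagnosability by barcode
#'
#' A species is successfully differentiated when its barcodes form a
#' monophyletic cluster on the tree and are not shared with any other
#' species. Failures are assigned one of five conditions via a fixed
#' decision cascade (an operationalization of the verbal definitions used
#' in barcode-library audits; see the methods vignette):
#'
#' 1. single specimen, no cross-species identical haplotype ->
#'    `SINGLETON_DISTINCT` (a success, but untested by replication);
#' 2. monophyletic, no sharing -> `DISTINCT`;
#' 3. cross-species sharing *and* still non-monophyletic after removing
#'    every specimen involved in cross-species identical pairs ->
#'    `IDENTICAL_AND_OVERLAPPING`;
#' 4. cross-species sharing only -> `IDENTICAL_SHARED`;
#' 5. otherwise non-monophyletic: on the rooted tree take the MRCA of the
#'    species' leaves and collect the other species with leaves inside
#'    it; exactly one such species, itself monophyletic ->
#'    `PARAPHYLETIC`; two or more -> `POLYPHYLETIC`; exactly one with
#'    mutual non-monophyly -> `OVERLAPPING`.
#'
#' Rooting (needed only for the MRCA step) uses the designated outgroup
#' when given, else midpoint rooting; the choice is recorded in the
#' `rooting` attribute because it can shift PARA/POLY labels in
#' pathological cases.
#'
#' @param tree unrooted `phylo` tree whose tips are the dataset's
#'   specimen IDs.
#' @param d the [barcode_dataset].
#' @param dist optional precomputed [distance_matrix()].
#' @param outgroup optional species name(s) (`"Genus epithet"`) used to
#'   root the tree and excluded from the assessments.
#' @param comparable_floor haplotype-identity floor, see
#'   [haplotype_sharing()].
#' @return A data frame of class `species_assessments` with columns
#'   `species`, `genus`, `n_specimens`, `condition`,
#'   `congeners_involved`, `shares_haplotype_with` (the last two are
#'   `";"`-separated species lists, empty when not applicable).
#' @export
classify_species <- function(tree, d, dist = NULL, outgroup = NULL,
                             comparable_floor = 400) {
  stopifnot(inherits(tree, "phylo"), inherits(d, "barcode_dataset"))
  rec <- d$records
  if (!setequal(tree$tip.label, rec$specimen_id))
    stop("tree leaves and dataset specimens do not match")
  if (is.null(dist)) dist <- distance_matrix(d)
  sp_of <- setNames(paste(rec$genus, rec$species), rec$specimen_id)
  genus_of <- setNames(rec$genus, rec$specimen_id)
  sharing <- haplotype_sharing(d, comparable_floor = comparable_floor,
                               dist = dist)

  species <- unique(unname(sp_of))
  assess_sp <- setdiff(species, outgroup)
  ntip <- ape::Ntip(tree)
  tip_sp <- sp_of[tree$tip.label]
  keys <- .bipart_keys(tree)
  idx_of <- split(seq_len(ntip), tip_sp)
  mono <- vapply(species, function(s)
    .is_mono_idx(idx_of[[s]], ntip, keys), logical(1))
  names(mono) <- species

  shares_with <- lapply(species, function(s) {
    w <- unique(c(sharing$species_b[sharing$species_a == s],
                  sharing$species_a[sharing$species_b == s]))
    sort(w)
  })
  names(shares_with) <- species
  shared_specimens <- unique(c(sharing$specimen_a, sharing$specimen_b))

  # rooted view for the MRCA-based congener count
  og_tips <- if (!is.null(outgroup))
    rec$specimen_id[sp_of[rec$specimen_id] %in% outgroup] else character()
  if (length(og_tips) && is_monophyletic(tree, og_tips) &&
      length(og_tips) < ntip) {
    rooted <- root_tree(tree, og_tips)
    rooting <- "outgroup"
  } else {
    rooted <- .root_midpoint(tree)
    rooting <- if (length(og_tips)) "midpoint (outgroup not edge-separable)"
               else "midpoint"
  }
  rt_sp <- sp_of[rooted$tip.label]

  # residual monophyly once shared-haplotype specimens are removed
  resid_mono <- function(s) {
    rem_tips <- setdiff(rec$specimen_id[sp_of == s], shared_specimens)
    if (length(rem_tips) <= 1L) return(TRUE)
    keep <- setdiff(tree$tip.label,
                    intersect(shared_specimens, tree$tip.label))
    if (length(keep) < 3L) return(TRUE)
    pruned <- ape::keep.tip(tree, keep)
    is_monophyletic(pruned, rem_tips)
  }

  mrca_others <- function(s) {
    tips <- which(rt_sp == s)
    if (length(tips) <= 1L) return(character())
    node <- ape::getMRCA(rooted, tips)
    inside <- rt_sp[phangorn::Descendants(rooted, node, "tips")[[1]]]
    sort(unique(inside[inside != s]))
  }

  res <- lapply(assess_sp, function(s) {
    n <- length(idx_of[[s]])
    shared <- shares_with[[s]]
    cong <- character()
    if (n == 1L && length(shared) == 0L) {
      cond <- "SINGLETON_DISTINCT"
    } else if (mono[s] && length(shared) == 0L) {
      cond <- "DISTINCT"
    } else if (length(shared) > 0L) {
      if (!mono[s] && !resid_mono(s)) {
        cond <- "IDENTICAL_AND_OVERLAPPING"
        cong <- sort(unique(c(shared, mrca_others(s))))
      } else {
        cond <- "IDENTICAL_SHARED"
        cong <- shared
      }
    } else {
      others <- mrca_others(s)
      cong <- others
      if (length(others) >= 2L) {
        cond <- "POLYPHYLETIC"
      } else if (length(others) == 1L) {
        cond <- if (mono[others]) "PARAPHYLETIC" else "OVERLAPPING"
      } else {
        # non-monophyletic under bipartitions yet MRCA holds no other
        # species: only possible through rooting pathologies
        cond <- "OVERLAPPING"
      }
    }
    data.frame(species = s,
               genus = unname(genus_of[rec$specimen_id[match(s, sp_of)]]),
               n_specimens = n,
               condition = cond,
               congeners_involved = paste(cong, collapse = ";"),
               shares_haplotype_with = paste(shared, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "rooting") <- rooting
  attr(out, "comparable_floor") <- comparable_floor
  class(out) <- c("species_assessments", "data.frame")
  out
}

#' Overall barcode success rate
#'
#' Success means the species' barcodes are diagnosable: condition
#' `DISTINCT` or `SINGLETON_DISTINCT` (singletons cannot fail by
#' replication, only by sharing a haplotype).
#'
#' @param assessments a `species_assessments` data frame from
#'   [classify_species()].
#' @return List with `n_success`, `n_total` and `proportion`.
#' @export
success_rate <- function(assessments) {
  if (!is.data.frame(assessments) || nrow(assessments) == 0L)
    stop("no species assessments supplied")
  ok <- assessments$condition %in% c("DISTINCT", "SINGLETON_DISTINCT")
  list(n_success = sum(ok), n_total = nrow(assessments),
       proportion = sum(ok) / nrow(assessments))
}
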