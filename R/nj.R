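#' Neighbour-joining tree from a distance matrix
#'
#' Agglomerative neighbour joining: at each step the pair `(i, j)`
#' minimising `Q(i,j) = (r-2) d(i,j) - R_i - R_j` over the `r` active
#' nodes is joined, with branch lengths
#' `v_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))` and reduced distances
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. Ties on `Q` are broken by the
#' lexicographically smallest active-node index pair so runs are
#' reproducible. Negative branch lengths (possible in NJ) are clamped to
#' zero with the deficit transferred to the sister branch; the pre-clamp
#' values are returned in the `negative_branches` attribute.
#'
#' For an additive input matrix the leaf-to-leaf path lengths of the
#' result reproduce the matrix exactly.
#'
#' @param m a `k2p_dist` object from [distance_matrix()], or a symmetric
#'   numeric matrix with row/column names.
#' @return An unrooted `phylo` tree (class from \pkg{ape}) whose tip
#'   labels are the specimen IDs; `n = 2` and `n = 3` degenerate to a
#'   single edge and a star. Attribute `negative_branches` holds any
#'   pre-clamp negative branch lengths.
#' @export
build_nj <- function(m) {
  if (inherits(m, "k2p_dist")) {
    ids <- m$ids
    dm <- m$d
  } else {
    dm <- as.matrix(m)
    if (is.null(rownames(dm)))
      rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
    ids <- rownames(dm)
  }
  n <- nrow(dm)
  if (n < 2L) stop("neighbour joining needs at least 2 taxa")
  stopifnot(ncol(dm) == n, all(is.finite(dm)), all(dm >= 0),
            isTRUE(all.equal(dm, t(dm))))
  res <- .nj_engine(dm)
  tr <- ape::read.tree(text = res$newick)
  tr$tip.label <- ids[as.integer(sub("^t", "", tr$tip.label))]
  attr(tr, "negative_branches") <- res$negative_branches
  tr
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the edge separating the outgroup
#' leaves from the rest of the tree. Barcode surveys typically carry one
#' representative of a sister lineage for this purpose; rooting only
#' affects reporting — the diagnosability logic works on bipartitions of
#' the unrooted tree.
#'
#' @param tree a `phylo` tree.
#' @param outgroup_ids tip labels forming the outgroup; must be
#'   separable from the remaining leaves by a single edge and a strict
#'   subset of the leaves.
#' @return A rooted `phylo` tree.
#' @export
root_tree <- function(tree, outgroup_ids) {
  stopifnot(inherits(tree, "phylo"))
  outgroup_ids <- as.character(outgroup_ids)
  if (!all(outgroup_ids %in% tree$tip.label))
    stop("unknown outgroup leaves: ",
         paste(setdiff(outgroup_ids, tree$tip.label), collapse = ", "))
  if (length(outgroup_ids) >= length(tree$tip.label))
    stop("outgroup cannot contain all leaves")
  if (length(tree$tip.label) == 2L)
    return(tree)  # already a single edge rooted at its midpoint
  if (!is_monophyletic(tree, outgroup_ids))
    stop("rooting error: outgroup is not separable by a single edge")
  rt <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
                  edgelabel = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  ce <- which(rt$edge[, 1] == root_node)
  if (length(ce) == 2L) {
    tot <- sum(rt$edge.length[ce])
    rt$edge.length[ce] <- tot / 2
  }
  rt
}

# midpoint rooting fallback used when no outgroup is designated
.root_midpoint <- function(tree) {
  if (ape::Ntip(tree) == 2L) return(tree)
  tryCatch(phangorn::midpoint(tree),
           error = function(e) ape::root(tree, outgroup = tree$tip.label[1],
                                         resolve.root = TRUE))
}

.newick_quote <- function(x) {
  needs <- grepl("[](){}:;,'\\[ \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree to Newick
#'
#' Writes branch lengths and single-quotes any label containing
#' Newick-reserved characters (parentheses, commas, colons, semicolons,
#' quotes or whitespace), which `ape::read.tree()` parses back verbatim.
#'
#' @param tree a `phylo` tree.
#' @param file optional path; when given the string is also written there.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # iterative post-order assembly (deep trees would overflow recursion)
  po <- ape::reorder.phylo(tree, "postorder")
  str_of <- character(ntip + nnode)
  str_of[seq_len(ntip)] <- .newick_quote(tree$tip.label)
  parts <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    if (ch > ntip)
      str_of[ch] <- paste0("(", paste(parts[[ch]], collapse = ","), ")")
    parts[[p]] <- c(parts[[p]], paste0(
      str_of[ch], ":", sprintf("%.*g", digits, po$edge.length[e])))
  }
  s <- paste0("(", paste(parts[[root]], collapse = ","), ");")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}
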