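# Independent oracles used to cross-check the implementation.

# literal K2P: count transitions/transversions over comparable sites and
# apply the closed form directly
k2p_oracle <- function(a, b) {
  sa <- strsplit(toupper(a), "")[[1]]
  sb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(sa) == length(sb))
  acgt <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  comp <- which(sa %in% acgt & sb %in% acgt)
  ts <- 0L; tv <- 0L
  for (k in comp) {
    if (sa[k] == sb[k]) next
    if ((sa[k] %in% purine) == (sb[k] %in% purine)) ts <- ts + 1L
    else tv <- tv + 1L
  }
  P <- ts / length(comp); Q <- tv / length(comp)
  list(distance = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
       sites = length(comp), P = P, Q = Q)
}

random_seq <- function(len, ambig = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, len, replace = TRUE)
  if (ambig > 0) {
    k <- rbinom(1, len, ambig)
    if (k > 0) s[sample(len, k)] <- sample(c("N", "-", "R", "Y"), k,
                                           replace = TRUE)
  }
  paste(s, collapse = "")
}

# naive O(n^3) neighbour joining, written directly from the agglomerative
# recipe; emits Newick (no negative-branch clamping)
nj_oracle <- function(D) {
  labs <- rownames(D)
  Dm <- D
  frag <- labs
  while (nrow(Dm) > 3) {
    r <- nrow(Dm)
    R <- rowSums(Dm)
    best <- Inf; bi <- bj <- NA
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      q <- (r - 2) * Dm[i, j] - R[i] - R[j]
      if (q < best) { best <- q; bi <- i; bj <- j }
    }
    li <- Dm[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (r - 2))
    lj <- Dm[bi, bj] - li
    newrow <- (Dm[bi, ] + Dm[bj, ] - Dm[bi, bj]) / 2
    nf <- sprintf("(%s:%.12g,%s:%.12g)", frag[bi], li, frag[bj], lj)
    keep <- setdiff(seq_len(r), c(bi, bj))
    D2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    frag <- c(frag[keep], nf)
    rownames(D2) <- colnames(D2) <- frag
    Dm <- D2
  }
  if (nrow(Dm) == 2) {
    s <- sprintf("(%s:%.12g,%s:%.12g);", frag[1], Dm[1, 2] / 2,
                 frag[2], Dm[1, 2] / 2)
  } else {
    a <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
    b <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
    c3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
    s <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], a, frag[2], b, frag[3], c3)
  }
  ape::read.tree(text = s)
}

# brute-force monophyly: enumerate every edge's bipartition by graph
# traversal with that edge removed
mono_oracle <- function(tree, tips) {
  ntip <- ape::Ntip(tree)
  target <- sort(match(tips, tree$tip.label))
  if (length(target) <= 1L || length(target) == ntip) return(TRUE)
  edges <- tree$edge
  nn <- max(edges)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    seen <- logical(nn)
    seen[b] <- TRUE
    stack <- b
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      for (w in adj[[v]]) {
        if ((v == b && w == a) || (v == a && w == b)) next
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    side <- which(seen[seq_len(ntip)])
    if (identical(sort(side), target) ||
        identical(sort(setdiff(seq_len(ntip), side)), target))
      return(TRUE)
  }
  FALSE
}

# connected components of the <= threshold graph, by repeated expansion
cc_oracle <- function(pct_matrix, members, threshold) {
  adj <- pct_matrix[members, members, drop = FALSE] <= threshold
  n <- length(members)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    front <- s
    comp[s] <- cid
    while (length(front)) {
      nxt <- which(apply(adj[front, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cid
      front <- nxt
    }
  }
  split(members, comp)
}

# matrix-algebra least squares with the slope t-test
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  n <- length(x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) * solve(XtX)[2, 2])
  tval <- beta[2] / se
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - rss / tss,
       p_value = 2 * stats::pt(-abs(tval), n - 2))
}

# additive matrix from a random unrooted binary tree with its tree
random_additive <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.05, 1)))
  list(tree = tr, D = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
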