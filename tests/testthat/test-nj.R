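test_that("tiny cases reduce to their closed forms", {
  # n = 2: single edge of the pairwise distance
  D2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- build_nj(D2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sum(t2$edge.length), 0.1)
  # n = 3: star with a = (dAB + dAC - dBC)/2 etc.
  D3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D3["A", "B"] <- D3["B", "A"] <- 3
  D3["A", "C"] <- D3["C", "A"] <- 5
  D3["B", "C"] <- D3["C", "B"] <- 6
  t3 <- build_nj(D3)
  cp <- ape::cophenetic.phylo(t3)[LETTERS[1:3], LETTERS[1:3]]
  expect_equal(unname(cp), unname(D3))
  expect_error(build_nj(matrix(0, 1, 1)), "at least 2")
})

test_that("the additive 4-taxon matrix is reconstructed exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> dAB=3 dAC=5 dAD=6 dBC=6 dBD=7 dCD=7
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj(D)
  # split AB|CD present
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  # path lengths reproduce the matrix (additivity)
  cp <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(cp), unname(D), tolerance = 1e-12)
  # leaf branches 1,2,3,4 and internal edge 1
  leaf_edges <- tr$edge.length[tr$edge[, 2] <= 4][
    order(tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])]
  expect_equal(leaf_edges, 1:4, tolerance = 1e-12)
})

test_that("NJ recovers random additive trees (consistency property)", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    ra <- random_additive(n)
    tr <- build_nj(ra$D)
    expect_true(same_topology(tr, ra$tree))
    cp <- ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)]
    expect_equal(unname(cp), unname(ra$D), tolerance = 1e-8)
  }
})

test_that("implementation matches the naive NJ oracle on noisy matrices", {
  set.seed(91)
  for (rep in 1:10) {
    n <- sample(8:25, 1)
    ra <- random_additive(n)
    noise <- matrix(runif(n * n, 0, 0.02), n, n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    D <- ra$D + noise
    tr <- build_nj(D)
    expect_true(same_topology(tr, nj_oracle(D)))
  }
})

test_that("total tree length is invariant under leaf permutation", {
  set.seed(5)
  ra <- random_additive(9)
  noise <- matrix(runif(81, 0, 0.01), 9, 9)
  D <- ra$D + (noise + t(noise)) / 2
  diag(D) <- 0
  t1 <- build_nj(D)
  perm <- sample(9)
  t2 <- build_nj(D[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
  expect_true(same_topology(t1, t2))
})

test_that("negative branch lengths are clamped and logged", {
  # triangle-inequality violation forces a negative closed-form branch
  D <- matrix(c(0, 1, 1,
                1, 0, 4,
                1, 4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- build_nj(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(length(attr(tr, "negative_branches")) >= 1)
  expect_true(all(attr(tr, "negative_branches") < 0))
})

test_that("outgroup rooting splits the root edge at its midpoint", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj(D)
  rt <- root_tree(tr, "D")
  expect_true(ape::is.rooted(rt))
  kids <- rt$edge[rt$edge[, 1] == ape::Ntip(rt) + 1L, 2]
  side <- lapply(kids, function(k)
    if (k <= 4) rt$tip.label[k]
    else rt$tip.label[phangorn::Descendants(rt, k, "tips")[[1]]])
  expect_true(any(vapply(side, identical, TRUE, "D")))
  # root edges are the halves of D's original terminal branch (length 4)
  ce <- which(rt$edge[, 1] == ape::Ntip(rt) + 1L)
  expect_equal(rt$edge.length[ce], c(2, 2))
})

test_that("rooting errors: non-clade outgroup and outgroup = all leaves", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj(D)
  expect_error(root_tree(tr, c("A", "C")), "not separable")
  expect_error(root_tree(tr, LETTERS[1:4]), "all leaves")
  expect_error(root_tree(tr, "Z"), "unknown")
})

test_that("newick round-trips with identical bipartitions and lengths", {
  set.seed(13)
  ra <- random_additive(10)
  tr <- build_nj(ra$D)
  back <- ape::read.tree(text = write_newick(tr))
  expect_true(same_topology(tr, back))
  expect_equal(sum(back$edge.length), sum(tr$edge.length),
               tolerance = 1e-8)
  cp1 <- ape::cophenetic.phylo(tr)
  cp2 <- ape::cophenetic.phylo(back)[rownames(cp1), colnames(cp1)]
  expect_equal(cp2, cp1, tolerance = 1e-8)
})

test_that("labels with reserved characters are quoted", {
  D2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2,
               dimnames = list(c("X sp. (1)", "B"), c("X sp. (1)", "B")))
  s <- write_newick(build_nj(D2))
  expect_match(s, "'X sp. (1)'", fixed = TRUE)
  back <- ape::read.tree(text = s)
  # ape keeps the quotes literally; the label content survives either way
  expect_true(any(gsub("'", "", back$tip.label) == "X sp. (1)"))
})
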