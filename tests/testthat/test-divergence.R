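test_that("pair partition counts are exact on a tiny constructed case", {
  # genus with species A (2 specimens) and B (1): 1 intra, 2 congeneric
  b <- BASE600
  d <- make_dataset(list(
    sp("a1", "Alpha", "aa", b),
    sp("a2", "Alpha", "aa", mutseq(b, 1:6)),     # 1% intra
    sp("b1", "Alpha", "bb", mutseq(b, 101:160)),
    sp("c1", "Gamma", "cc", mutseq(b, 301:400))  # cross-genus: excluded
  ))
  m <- distance_matrix(d)
  ds <- divergence_summary(m, d)
  expect_equal(ds$global$n_intra_comparisons, 1L)
  expect_equal(ds$global$n_congeneric_comparisons, 2L)
  expect_equal(ds$global$n_other_comparisons, 3L)
  expect_equal(ds$global$mean_intra_pct,
               100 * k2p_oracle(b, mutseq(b, 1:6))$distance)
  expect_equal(ds$per_species$n_specimens, 2L)
  expect_equal(ds$per_species$species, "Alpha aa")
})

test_that("comparison counts conserve n(n-1)/2 on simulated data", {
  sim <- simulate_community(n_genera = 8, n_shared_haplotype = 1,
                            n_paraphyly = 1, n_deep_split_2 = 1,
                            n_deep_split_3 = 0, seed = 8)
  m <- distance_matrix(sim$dataset)
  ds <- divergence_summary(m, sim$dataset)
  n <- nrow(sim$dataset$records)
  expect_equal(ds$global$n_intra_comparisons +
                 ds$global$n_congeneric_comparisons +
                 ds$global$n_other_comparisons, n * (n - 1) / 2)
  expect_equal(sum(ds$histogram$intra_counts),
               ds$global$n_intra_comparisons)
  expect_equal(sum(ds$histogram$congeneric_counts),
               ds$global$n_congeneric_comparisons)
})

test_that("generator hits its divergence targets and shows a barcode gap", {
  intra_means <- numeric(5)
  cong_means <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_community(n_genera = 15, intra_pct = 0.5,
                              congeneric_pct = 9,
                              n_shared_haplotype = 0, n_paraphyly = 0,
                              n_deep_split_2 = 0, n_deep_split_3 = 0,
                              seed = 400 + s)
    ds <- divergence_summary(distance_matrix(sim$dataset), sim$dataset)
    intra_means[s] <- ds$global$mean_intra_pct
    cong_means[s] <- ds$global$mean_congeneric_pct
  }
  expect_lt(abs(mean(intra_means) - 0.5), 0.15)
  expect_gt(mean(cong_means) / mean(intra_means), 10)
})

test_that("single-linkage clusters equal threshold-graph components", {
  # chaining: a-b 2.9, b-c 2.9, a-c 5 -> one cluster
  b <- BASE600
  chain <- make_dataset(list(
    sp("a", "G", "x", b),
    sp("b", "G", "x", mutseq(b, seq(1, 97, by = 6))),       # ~2.9% from a
    sp("c", "G", "x", mutseq(b, c(seq(1, 97, by = 6),
                                  seq(202, 298, by = 6))))   # ~2.9% from b
  ))
  m <- distance_matrix(chain)
  expect_gt(m$d["a", "c"] * 100, 3)
  expect_lt(m$d["a", "b"] * 100, 3)
  cl <- split_clusters(m, c("a", "b", "c"), threshold = 3)
  expect_length(cl, 1L)
  # agreement with the brute-force components oracle on random data
  set.seed(55)
  sim <- simulate_community(n_genera = 6, n_shared_haplotype = 0,
                            n_paraphyly = 0, n_deep_split_2 = 3,
                            n_deep_split_3 = 2, seed = 56)
  ms <- distance_matrix(sim$dataset)
  spn <- paste(sim$dataset$records$genus, sim$dataset$records$species)
  for (s in unique(spn)) {
    ids <- sim$dataset$records$specimen_id[spn == s]
    if (length(ids) < 2) next
    got <- split_clusters(ms, ids, threshold = 3)
    want <- cc_oracle(ms$d * 100, ids, 3)
    expect_setequal(unname(lapply(got, sort)), unname(lapply(want, sort)))
  }
})

test_that("deep-split flags use strict > at the threshold", {
  b <- BASE600
  # two specimens ~2.9% apart: not flagged
  near <- make_dataset(list(
    sp("a", "G", "x", b),
    sp("b", "G", "x", mutseq(b, seq(1, 97, by = 6)))
  ))
  r <- flag_deep_splits(distance_matrix(near), near)
  expect_false(r$flagged)
  expect_equal(r$n_clusters, 1L)
  # two clear clusters, sizes 1/2
  far <- make_dataset(list(
    sp("a", "G", "x", b),
    sp("b", "G", "x", mutseq(b, 1)),
    sp("c", "G", "x", mutseq(b, seq(2, 170, by = 6)))
  ))
  r2 <- flag_deep_splits(distance_matrix(far), far)
  expect_true(r2$flagged)
  expect_equal(r2$cluster_sizes, "2/1")
  # singletons never appear
  single <- make_dataset(list(sp("a", "G", "x", b),
                              sp("z", "H", "y", mutseq(b, 400:440))))
  expect_equal(nrow(flag_deep_splits(distance_matrix(single), single)), 0L)
})

test_that("injected multi-cluster species yield the injected sizes", {
  sim <- simulate_community(n_genera = 10, n_shared_haplotype = 0,
                            n_paraphyly = 0, n_deep_split_2 = 3,
                            n_deep_split_3 = 2, seed = 123)
  m <- distance_matrix(sim$dataset)
  r <- flag_deep_splits(m, sim$dataset)
  truth <- sim$truth[sim$truth$true_clusters > 1, ]
  got <- r$n_clusters[match(truth$species, r$species)]
  expect_equal(got, truth$true_clusters)
})

test_that("histogram bins are left-closed right-open from zero", {
  h <- divergence_histogram(numeric(0))
  expect_equal(sum(h$counts), 0L)
  h2 <- divergence_histogram(c(0, 0.5, 1.0), bin_width = 1)
  expect_equal(h2$counts, c(2L, 1L))
  expect_error(divergence_histogram(-1), "non-negative")
  # brute-force binning oracle on random values
  set.seed(6)
  v <- runif(500, 0, 18)
  h3 <- divergence_histogram(v, bin_width = 1)
  brute <- vapply(seq_len(length(h3$edges) - 1L), function(i)
    sum(v >= h3$edges[i] & v < h3$edges[i + 1L]), integer(1))
  expect_equal(h3$counts, brute)
  expect_equal(sum(h3$counts), 500L)
})
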