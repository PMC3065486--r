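test_that("monophyly on the unrooted tree follows bipartition semantics", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj(D)   # split AB|CD
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))          # singleton convention
  expect_error(is_monophyletic(tr, "Z"), "unknown")
})

test_that("is_monophyletic agrees with the edge-enumeration oracle", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(6:50, 1)
    tr <- ape::unroot(ape::rtree(n))
    for (k in 1:8) {
      subset <- sample(tr$tip.label, sample(2:(n - 1), 1))
      expect_identical(is_monophyletic(tr, subset),
                       mono_oracle(tr, subset))
    }
  }
})

test_that("haplotype sharing reports cross-species identity only", {
  d <- scenario_shared()
  sh <- haplotype_sharing(d)
  expect_equal(nrow(sh), 1L)
  expect_setequal(c(sh$species_a, sh$species_b),
                  c("Alpha dona", "Alpha reca"))
  # conspecific identity is not sharing
  b <- BASE600
  d2 <- barcode_dataset(c("x", "y"), c("G", "G"), c("a", "a"), c("", ""),
                        c(b, b))
  expect_equal(nrow(haplotype_sharing(d2)), 0L)
})

test_that("short fragments below the comparable floor never match", {
  b <- BASE600
  frag <- paste0(substr(b, 1, 238), paste(rep("N", 362), collapse = ""))
  d <- barcode_dataset(c("full", "mini"), c("G", "G"), c("a", "b"),
                       c("", ""), c(b, frag))
  sh <- haplotype_sharing(d, comparable_floor = 400)
  expect_equal(nrow(sh), 0L)
  expect_equal(nrow(attr(sh, "excluded_short")), 1L)
  # and with the floor below the fragment it does match
  expect_equal(nrow(haplotype_sharing(d, comparable_floor = 200)), 1L)
})

classify_fixture <- function(d) {
  m <- distance_matrix(d)
  tr <- build_nj(m)
  classify_species(tr, d, dist = m, outgroup = "Beta remota")
}
cond_of <- function(a, s) a$condition[a$species == s]

test_that("clean clusters are DISTINCT; singletons are flagged as such", {
  d <- scenario_paraphyly()
  a <- classify_fixture(d)
  expect_equal(cond_of(a, "Alpha plaina"), "DISTINCT")
  expect_false("Beta remota" %in% a$species)   # outgroup excluded
  sim <- simulate_community(n_genera = 6, n_shared_haplotype = 0,
                            n_paraphyly = 0, n_deep_split_2 = 0,
                            n_deep_split_3 = 0, seed = 21)
  aa <- barcode_audit(sim$dataset, outgroup = sim$outgroup)$assessments
  expect_true(all(aa$condition %in% c("DISTINCT", "SINGLETON_DISTINCT")))
  expect_equal(aa$condition == "SINGLETON_DISTINCT",
               aa$n_specimens == 1L)
})

test_that("a nested congener renders its host paraphyletic", {
  a <- classify_fixture(scenario_paraphyly())
  expect_equal(cond_of(a, "Alpha hosta"), "PARAPHYLETIC")
  expect_equal(a$congeners_involved[a$species == "Alpha hosta"],
               "Alpha nesta")
  expect_equal(cond_of(a, "Alpha nesta"), "DISTINCT")
})

test_that("interleaving with two congeners is polyphyly", {
  a <- classify_fixture(scenario_polyphyly())
  expect_equal(cond_of(a, "Alpha waldoa"), "POLYPHYLETIC")
  expect_setequal(strsplit(a$congeners_involved[
    a$species == "Alpha waldoa"], ";")[[1]],
    c("Alpha unoa", "Alpha duoa"))
})

test_that("mutually blended species pairs are OVERLAPPING", {
  a <- classify_fixture(scenario_overlap())
  expect_equal(cond_of(a, "Alpha mixa"), "OVERLAPPING")
  expect_equal(cond_of(a, "Alpha mixb"), "OVERLAPPING")
})

test_that("identical haplotypes alone give IDENTICAL_SHARED, symmetrically", {
  a <- classify_fixture(scenario_shared())
  expect_equal(cond_of(a, "Alpha dona"), "IDENTICAL_SHARED")
  expect_equal(cond_of(a, "Alpha reca"), "IDENTICAL_SHARED")
  expect_equal(a$shares_haplotype_with[a$species == "Alpha dona"],
               "Alpha reca")
  expect_equal(a$shares_haplotype_with[a$species == "Alpha reca"],
               "Alpha dona")
})

test_that("identity plus residual blending is IDENTICAL_AND_OVERLAPPING", {
  a <- classify_fixture(scenario_shared_overlap())
  expect_equal(cond_of(a, "Alpha mela"), "IDENTICAL_AND_OVERLAPPING")
  expect_equal(cond_of(a, "Alpha melb"), "IDENTICAL_AND_OVERLAPPING")
})

test_that("every species gets exactly one condition and counts partition", {
  sim <- simulate_community(n_genera = 12, n_shared_haplotype = 2,
                            n_paraphyly = 2, n_deep_split_2 = 2,
                            n_deep_split_3 = 1, seed = 99)
  a <- barcode_audit(sim$dataset, outgroup = sim$outgroup)$assessments
  expect_equal(nrow(a), nrow(sim$truth))
  expect_equal(anyDuplicated(a$species), 0L)
  expect_true(all(a$condition %in% bcaudit:::CONDITION_LEVELS))
  expect_equal(sum(table(a$condition)), nrow(a))
  # symmetry of sharing lists
  sh <- a[a$shares_haplotype_with != "", ]
  for (i in seq_len(nrow(sh)))
    for (p in strsplit(sh$shares_haplotype_with[i], ";")[[1]])
      expect_true(grepl(sh$species[i],
                        a$shares_haplotype_with[a$species == p],
                        fixed = TRUE))
})

test_that("success rate counts DISTINCT and unshared singletons", {
  a <- data.frame(condition = c(rep("DISTINCT", 3),
                                "SINGLETON_DISTINCT", "PARAPHYLETIC"))
  s <- success_rate(a)
  expect_equal(s$n_success, 4L)
  expect_equal(s$proportion, 0.8)
  expect_error(success_rate(a[0, , drop = FALSE]), "no species")
})
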