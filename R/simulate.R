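#' Evolve a sequence under the Kimura 2-parameter process
#'
#' Applies independent-site substitution along a branch with transition
#' rate `kappa` times each transversion rate, the generating process
#' whose pairwise distances the K2P estimator recovers consistently.
#' Branch length is in expected substitutions per site. Ambiguous sites
#' (anything other than A/C/G/T) are left unchanged; no indels.
#'
#' @param ancestor IUPAC sequence string.
#' @param branch_length expected substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio (default 4, a typical
#'   mitochondrial value).
#' @return The derived sequence (same length).
#' @export
evolve_sequence <- function(ancestor, branch_length, kappa = 4) {
  stopifnot(is.character(ancestor), length(ancestor) == 1L, kappa > 0)
  if (branch_length < 0) stop("branch_length must be non-negative")
  s <- strsplit(toupper(ancestor), "")[[1]]
  code <- match(s, c("A", "C", "G", "T"))
  ok <- which(!is.na(code))
  if (length(ok) == 0L || branch_length == 0) return(paste(s, collapse = ""))
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  t <- branch_length                    # rates normalised: alpha + 2 beta = 1
  e4b <- exp(-4 * beta * t)
  e2ab <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv <- 0.25 - 0.25 * e4b             # each of the two transversions
  # substitution targets by current base (A,C,G,T)
  ts_to <- c(3L, 4L, 1L, 2L)
  tv1_to <- c(2L, 1L, 2L, 1L)
  tv2_to <- c(4L, 3L, 4L, 3L)
  u <- runif(length(ok))
  cur <- code[ok]
  new <- cur
  new[u < p_ts] <- ts_to[cur[u < p_ts]]
  i2 <- u >= p_ts & u < p_ts + p_tv
  new[i2] <- tv1_to[cur[i2]]
  i3 <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  new[i3] <- tv2_to[cur[i3]]
  s[ok] <- c("A", "C", "G", "T")[new]
  paste(s, collapse = "")
}

.random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# lognormal branch-scatter with unit mean
.scatter <- function(n, sdlog = 0.35) rlnorm(n, -sdlog^2 / 2, sdlog)

# random composition of n into k positive parts
.composition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample(seq_len(n - 1L), k - 1L))
  diff(c(0L, cuts, n))
}

#' Simulate a barcode community with ground truth
#'
#' Generates an aligned COI-like barcode community with the statistical
#' structure of a regional reference library: genera containing a few
#' species each, species sampled with strongly skewed effort, low
#' intraspecific divergence far below congeneric divergence, and an
#' optional deep outgroup lineage. Diagnosability failure scenarios are
#' injected last and recorded in a ground-truth table, so classification
#' and deep-split detection can be validated against known labels.
#'
#' Species ancestors radiate star-like from each genus ancestor at the
#' congeneric scale; specimens radiate from the species ancestor at the
#' intraspecific scale; per-branch lognormal scatter (unit mean) spreads
#' the realised divergences. Injections:
#' \describe{
#'   \item{shared haplotype}{one specimen's sequence is copied into a
#'     congener (both species become undiagnosable by identity).}
#'   \item{paraphyly}{a congener's radiation is nested inside a widened
#'     host radiation: the host becomes paraphyletic, the nested species
#'     stays monophyletic.}
#'   \item{deep split (2 or 3 clusters)}{intraspecific subclusters
#'     separated by well over the 3% flagging threshold.}
#' }
#'
#' @param n_genera number of genera.
#' @param species_per_genus_mean mean species per genus (1 + Poisson).
#' @param specimens_mean,specimens_max specimens per species: 1 +
#'   geometric with this mean, truncated at the maximum.
#' @param seq_length alignment length (bp).
#' @param kappa transition/transversion rate ratio of the generator.
#' @param intra_pct target mean intraspecific divergence, percent.
#' @param congeneric_pct target mean congeneric divergence, percent.
#' @param n_shared_haplotype,n_paraphyly number of injected
#'   shared-haplotype / paraphyly species pairs (each pair uses one genus
#'   with >= 2 species).
#' @param n_deep_split_2,n_deep_split_3 number of species injected with
#'   2 / 3 deep intraspecific clusters.
#' @param include_outgroup add one deeply divergent outgroup specimen
#'   (genus `"Outgroupus"`, species `"simulatus"`), as barcode surveys do
#'   for rooting.
#' @param seed optional integer seed (sets the R RNG).
#' @return A list of class `sim_community`: `dataset` (a
#'   [barcode_dataset]), `truth` (data frame: `species`, `genus`,
#'   `n_specimens`, `true_condition`, `true_clusters`,
#'   `shares_haplotype_with`), `outgroup` (species name or `NULL`) and
#'   `config`.
#' @export
simulate_community <- function(n_genera = 125,
                               species_per_genus_mean = 3.2,
                               specimens_mean = 6,
                               specimens_max = 46,
                               seq_length = 658,
                               kappa = 4,
                               intra_pct = 0.56,
                               congeneric_pct = 9,
                               n_shared_haplotype = 5,
                               n_paraphyly = 8,
                               n_deep_split_2 = 22,
                               n_deep_split_3 = 4,
                               include_outgroup = TRUE,
                               seed = NULL) {
  stopifnot(n_genera >= 1, specimens_mean >= 1, seq_length >= 1,
            intra_pct > 0, congeneric_pct > 0,
            n_shared_haplotype >= 0, n_paraphyly >= 0,
            n_deep_split_2 >= 0, n_deep_split_3 >= 0)
  if (!is.null(seed)) set.seed(seed)

  n_sp_per_gen <- 1L + rpois(n_genera, species_per_genus_mean - 1)
  genera <- sprintf("Genus%03d", seq_len(n_genera))
  sp_tab <- do.call(rbind, lapply(seq_len(n_genera), function(g) {
    data.frame(genus = genera[g],
               epithet = sprintf("sp%02d", seq_len(n_sp_per_gen[g])),
               stringsAsFactors = FALSE)
  }))
  sp_tab$species <- paste(sp_tab$genus, sp_tab$epithet)
  ns <- nrow(sp_tab)
  sp_tab$n <- pmin(1L + rgeom(ns, 1 / specimens_mean), specimens_max)
  sp_tab$scenario <- "none"
  sp_tab$partner <- NA_character_
  sp_tab$clusters <- 1L
  sp_tab$derived_anc <- NA_character_

  # ---- choose injection targets ------------------------------------------
  pair_genera_needed <- n_shared_haplotype + n_paraphyly
  multi_genera <- unique(sp_tab$genus[duplicated(sp_tab$genus)])
  if (length(multi_genera) < pair_genera_needed)
    stop("config error: not enough genera with >= 2 species for the ",
         "requested pair injections")
  pick_g <- sample(multi_genera, pair_genera_needed)
  assign_pair <- function(g, scen) {
    rows <- which(sp_tab$genus == g)[1:2]
    sp_tab$partner[rows] <<- sp_tab$species[rev(rows)]
    if (scen == "paraphyly") {
      sp_tab$scenario[rows] <<- c("paraphyly_host", "paraphyly_nested")
      sp_tab$n[rows[1]] <<- max(sp_tab$n[rows[1]], 5L)
      sp_tab$n[rows[2]] <<- max(sp_tab$n[rows[2]], 3L)
    } else {
      sp_tab$scenario[rows] <<- c("shared_donor", "shared_recipient")
      sp_tab$n[rows[1]] <<- max(sp_tab$n[rows[1]], 2L)
    }
  }
  gi <- 0L
  for (k in seq_len(n_shared_haplotype)) assign_pair(pick_g[gi <- gi + 1L],
                                                     "shared")
  for (k in seq_len(n_paraphyly)) assign_pair(pick_g[gi <- gi + 1L],
                                              "paraphyly")
  free <- which(sp_tab$scenario == "none")
  need_ds <- n_deep_split_2 + n_deep_split_3
  if (length(free) < need_ds)
    stop("config error: not enough uninjected species for deep splits")
  ds_rows <- sample(free, need_ds)
  if (n_deep_split_2 > 0) {
    r2 <- ds_rows[seq_len(n_deep_split_2)]
    sp_tab$scenario[r2] <- "deep_split"
    sp_tab$clusters[r2] <- 2L
    sp_tab$n[r2] <- pmax(sp_tab$n[r2], 3L)
  }
  if (n_deep_split_3 > 0) {
    r3 <- ds_rows[n_deep_split_2 + seq_len(n_deep_split_3)]
    sp_tab$scenario[r3] <- "deep_split"
    sp_tab$clusters[r3] <- 3L
    sp_tab$n[r3] <- pmax(sp_tab$n[r3], 4L)
  }

  # ---- generate sequences -------------------------------------------------
  b_cong <- congeneric_pct / 100 / 2    # species-ancestor branch
  b_intra <- intra_pct / 100 / 2        # specimen branch
  b_genus <- 0.08                       # genus branch from the family root
  seqs <- vector("list", ns)
  host_anc <- character(ns)             # species ancestors (for paraphyly)
  root_seq <- .random_sequence(seq_length)
  for (g in seq_len(n_genera)) {
    rows <- which(sp_tab$genus == genera[g])
    ganc <- evolve_sequence(root_seq, b_genus * .scatter(1, 0.2),
                            kappa = kappa)
    for (r in rows)
      host_anc[r] <- evolve_sequence(ganc, b_cong * .scatter(1),
                                     kappa = kappa)
    # paraphyly pairs: re-anchor the nested species close to its host's
    # ancestor, widen the host radiation, tighten the nested one
    for (r in rows) {
      scen <- sp_tab$scenario[r]
      n <- sp_tab$n[r]
      if (scen == "paraphyly_host") {
        # basal subgroup + a derived lineage that will also carry the
        # nested congener, so the host brackets it on the tree
        n1 <- ceiling(n / 2)
        deriv <- evolve_sequence(host_anc[r], 0.008, kappa = kappa)
        sp_tab$derived_anc[r] <- deriv
        seqs[[r]] <- c(
          vapply(seq_len(n1), function(i)
            evolve_sequence(host_anc[r], 0.008 * .scatter(1, 0.2),
                            kappa = kappa), character(1)),
          vapply(seq_len(n - n1), function(i)
            evolve_sequence(deriv, 0.004 * .scatter(1, 0.2),
                            kappa = kappa), character(1)))
      } else if (scen == "paraphyly_nested") {
        pr <- which(sp_tab$species == sp_tab$partner[r])
        banc <- evolve_sequence(sp_tab$derived_anc[pr], 0.008,
                                kappa = kappa)
        seqs[[r]] <- vapply(seq_len(n), function(i)
          evolve_sequence(banc, 0.0015 * .scatter(1, 0.2),
                          kappa = kappa), character(1))
      } else if (scen == "deep_split") {
        k <- sp_tab$clusters[r]
        sizes <- .composition(n, k)
        seqs[[r]] <- unlist(lapply(seq_len(k), function(j) {
          canc <- evolve_sequence(host_anc[r], 0.030, kappa = kappa)
          vapply(seq_len(sizes[j]), function(i)
            evolve_sequence(canc, 0.0015 * .scatter(1, 0.2),
                            kappa = kappa), character(1))
        }))
      } else {
        seqs[[r]] <- vapply(seq_len(n), function(i)
          evolve_sequence(host_anc[r], b_intra * .scatter(1),
                          kappa = kappa), character(1))
      }
    }
    # shared haplotypes: copy a donor specimen into the recipient
    for (r in rows) {
      if (sp_tab$scenario[r] == "shared_donor") {
        pr <- which(sp_tab$species == sp_tab$partner[r])
        seqs[[pr]][1L] <- seqs[[r]][1L]
      }
    }
  }

  rec <- data.frame(
    genus = rep(sp_tab$genus, sp_tab$n),
    epithet = rep(sp_tab$epithet, sp_tab$n),
    stringsAsFactors = FALSE
  )
  rec$sequence <- unlist(seqs)
  outgroup_name <- NULL
  if (include_outgroup) {
    og <- evolve_sequence(root_seq, 0.15, kappa = kappa)
    rec <- rbind(rec, data.frame(genus = "Outgroupus",
                                 epithet = "simulatus",
                                 sequence = og,
                                 stringsAsFactors = FALSE))
    outgroup_name <- "Outgroupus simulatus"
  }
  rec$specimen_id <- sprintf("SIM%05d", seq_len(nrow(rec)))
  region_pool <- c("BC", "AB", "YT", "AK", "WA", "ID")
  rec$region <- sample(region_pool, nrow(rec), replace = TRUE,
                       prob = c(0.55, 0.12, 0.06, 0.06, 0.14, 0.07))

  dataset <- barcode_dataset(rec$specimen_id, rec$genus, rec$epithet,
                             rec$region, rec$sequence)

  truth <- data.frame(
    species = sp_tab$species,
    genus = sp_tab$genus,
    n_specimens = sp_tab$n,
    true_condition = ifelse(
      sp_tab$scenario %in% c("shared_donor", "shared_recipient"),
      "IDENTICAL_SHARED",
      ifelse(sp_tab$scenario == "paraphyly_host", "PARAPHYLETIC",
             ifelse(sp_tab$n == 1L, "SINGLETON_DISTINCT", "DISTINCT"))),
    true_clusters = sp_tab$clusters,
    shares_haplotype_with = ifelse(
      sp_tab$scenario %in% c("shared_donor", "shared_recipient"),
      sp_tab$partner, ""),
    stringsAsFactors = FALSE
  )

  structure(list(dataset = dataset, truth = truth,
                 outgroup = outgroup_name,
                 config = list(n_genera = n_genera,
                               species_per_genus_mean = species_per_genus_mean,
                               specimens_mean = specimens_mean,
                               specimens_max = specimens_max,
                               seq_length = seq_length, kappa = kappa,
                               intra_pct = intra_pct,
                               congeneric_pct = congeneric_pct,
                               n_shared_haplotype = n_shared_haplotype,
                               n_paraphyly = n_paraphyly,
                               n_deep_split_2 = n_deep_split_2,
                               n_deep_split_3 = n_deep_split_3,
                               include_outgroup = include_outgroup,
                               seed = seed)),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat("Simulated barcode community\n")
  print(x$dataset)
  tb <- table(x$truth$true_condition)
  cat("  truth: ", paste(names(tb), tb, sep = "=", collapse = ", "),
      "; deep splits: ",
      sum(x$truth$true_clusters >= 2), "\n", sep = "")
  invisible(x)
}
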