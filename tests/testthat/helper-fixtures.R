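# Handcrafted deterministic fixtures for the classification scenarios.

BASE600 <- paste(rep(c("A", "C", "G", "T"), 150), collapse = "")

# substitute transitions (A<->G, C<->T) at the given positions
mutseq <- function(base, pos) {
  s <- strsplit(base, "")[[1]]
  s[pos] <- chartr("ACGT", "GTAC", s[pos])
  paste(s, collapse = "")
}

make_dataset <- function(specs) {
  # specs: list of list(id, genus, species, seq)
  barcode_dataset(
    vapply(specs, `[[`, "", 1),
    vapply(specs, `[[`, "", 2),
    vapply(specs, `[[`, "", 3),
    rep("BC", length(specs)),
    vapply(specs, `[[`, "", 4)
  )
}

sp <- function(id, genus, species, seq) list(id, genus, species, seq)

# A genus engineered to exhibit paraphyly, plus a clean species and a
# distant second genus (anchors the deepest split for rooting).
# The host species "hosta" carries a basal pair (pp1, pp2) and a derived
# lineage (stem 411:416) holding pp3 and, nested inside it with its own
# stem (431:434), the congener "nesta" — so hosta brackets nesta.
scenario_paraphyly <- function() {
  h <- mutseq(BASE600, 1:10)          # host-clade stem
  hd <- mutseq(h, 411:416)            # derived host lineage
  qa <- mutseq(hd, 431:434)           # nested species ancestor
  make_dataset(list(
    sp("pp1", "Alpha", "hosta", mutseq(h, 401:403)),
    sp("pp2", "Alpha", "hosta", mutseq(h, 406:408)),
    sp("pp3", "Alpha", "hosta", mutseq(hd, 421:422)),
    sp("qq1", "Alpha", "nesta", qa),
    sp("qq2", "Alpha", "nesta", mutseq(qa, 441)),
    sp("dd1", "Alpha", "plaina", mutseq(BASE600, 301:340)),
    sp("dd2", "Alpha", "plaina", mutseq(BASE600, c(301:340, 400))),
    sp("og1", "Beta", "remota", mutseq(BASE600, 501:580))
  ))
}

# species waldo interleaved with two congeners' clusters
scenario_polyphyly <- function() {
  b <- BASE600
  c1 <- mutseq(b, 101:112)   # congener 1 core
  c2 <- mutseq(b, 201:212)   # congener 2 core
  make_dataset(list(
    sp("c1a", "Alpha", "unoa", c1),
    sp("c1b", "Alpha", "unoa", mutseq(c1, 1)),
    sp("w1",  "Alpha", "waldoa", mutseq(c1, 2)),
    sp("c2a", "Alpha", "duoa", c2),
    sp("c2b", "Alpha", "duoa", mutseq(c2, 1)),
    sp("w2",  "Alpha", "waldoa", mutseq(c2, 2)),
    sp("og1", "Beta", "remota", mutseq(b, 501:580))
  ))
}

# two species whose haplotypes form two mixed clusters (no identity)
scenario_overlap <- function() {
  b <- BASE600
  k1 <- mutseq(b, 101:110)
  k2 <- mutseq(b, 201:210)
  make_dataset(list(
    sp("a1", "Alpha", "mixa", mutseq(k1, 1)),
    sp("b1", "Alpha", "mixb", mutseq(k1, 2)),
    sp("a2", "Alpha", "mixa", mutseq(k2, 1)),
    sp("b2", "Alpha", "mixb", mutseq(k2, 2)),
    sp("og1", "Beta", "remota", mutseq(b, 501:580))
  ))
}

# cross-species identical haplotype, otherwise clean clusters
scenario_shared <- function() {
  b <- BASE600
  make_dataset(list(
    sp("a1", "Alpha", "dona", b),
    sp("a2", "Alpha", "dona", mutseq(b, 1)),
    sp("b1", "Alpha", "reca", b),                 # identical to a1
    sp("b2", "Alpha", "reca", mutseq(b, 2)),
    sp("og1", "Beta", "remota", mutseq(b, 501:580))
  ))
}

# identity plus residual blending beyond the shared pair
scenario_shared_overlap <- function() {
  b <- BASE600
  beta <- mutseq(b, 201:215)
  make_dataset(list(
    sp("a1", "Alpha", "mela", b),
    sp("a2", "Alpha", "mela", mutseq(b, 1)),
    sp("a3", "Alpha", "mela", mutseq(beta, 2)),
    sp("b1", "Alpha", "melb", b),                 # identical to a1
    sp("b2", "Alpha", "melb", mutseq(b, 3)),
    sp("b3", "Alpha", "melb", mutseq(beta, 4)),
    sp("og1", "Beta", "remota", mutseq(b, 501:580))
  ))
}

write_fixture_files <- function(d, dir = tempfile("bcfix")) {
  dir.create(dir)
  fa <- file.path(dir, "seqs.fasta")
  md <- file.path(dir, "meta.tsv")
  write_dataset(d, fa, md)
  list(dir = dir, fasta = fa, metadata = md)
}
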