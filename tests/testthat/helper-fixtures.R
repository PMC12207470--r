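# In-code fixtures: tiny variant tables, random tables for oracle
# comparisons, and small tree sets. No files are read from disk.

## Polarized table straight from a dosage matrix (sites x individuals).
## Individual ids "<pop>_<k>" are generated from `pops` (one label per
## column). Positions are spaced `spacing` bp apart.
make_vt <- function(dosage, pops, spacing = 1L, polarized = TRUE) {
  dosage <- as.matrix(dosage)
  ids <- paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                      FUN = seq_along))
  colnames(dosage) <- ids
  ns <- nrow(dosage)
  variant_table(rep("chr1", ns), seq_len(ns) * spacing,
                ref = rep("A", ns), alt = rep("C", ns),
                dosage = dosage, populations = setNames(pops, ids),
                polarized = polarized,
                anc = if (polarized) rep("A", ns),
                der = if (polarized) rep("C", ns))
}

## Random small polarized table for brute-force oracle comparisons.
random_small_vt <- function(n_sites, pops_sizes, miss_rate = 0) {
  pops <- rep(names(pops_sizes), times = pops_sizes)
  d <- matrix(sample(0:2, n_sites * length(pops), replace = TRUE),
              nrow = n_sites)
  if (miss_rate > 0)
    d[runif(length(d)) < miss_rate] <- NA_integer_
  ## ensure at least one derived somewhere per site (keeps tables tidy)
  for (i in seq_len(n_sites))
    if (all(d[i, ] == 0L | is.na(d[i, ]))) d[i, sample(ncol(d), 1)] <- 1L
  make_vt(d, pops)
}

## Brute-force per-site private-pattern oracle over ALL individuals.
oracle_private <- function(vt) {
  pops <- unique(vt$populations)
  pres <- sapply(pops, function(pl) {
    cols <- names(vt$populations)[vt$populations == pl]
    apply(vt$dosage[, cols, drop = FALSE], 1L,
          function(d) any(d > 0, na.rm = TRUE))
  })
  pres <- matrix(pres, ncol = length(pops), dimnames = list(NULL, pops))
  seg <- rowSums(pres) > 0
  vapply(pops, function(pl)
    sum(pres[, pl] & rowSums(pres) == 1) / sum(seg), numeric(1))
}

## Brute-force pairwise-concordance AUC with ties counted one half.
oracle_auc <- function(scores, labels, smaller_is_positive = FALSE) {
  s <- if (smaller_is_positive) -scores else scores
  sp <- s[labels]; sn <- s[!labels]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## Additive tree distance matrices with known topologies.
additive_fixtures <- function() {
  d4 <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  diag(d4) <- 0
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

  t5 <- ape::read.tree(
    text = "(((A:1,B:2):1,C:3):1,(D:2,E:1):2);")
  d5 <- ape::cophenetic.phylo(t5)

  ## a second, asymmetric 5-taxon tree
  t5b <- ape::read.tree(
    text = "((((A:1,B:1):1,C:1):1,D:1):1,E:5);")
  d5b <- ape::cophenetic.phylo(t5b)
  list(list(d = d4, tree = t4),
       list(d = d5, tree = t5),
       list(d = d5b, tree = t5b))
}

## 20-tree newick fixture: 15 trees contain the clade (S1,S2), 5 break it.
tree_fixture_20 <- function() {
  with_clade <- "((S1:1,S2:1):1,(B:1,(L:1,A:1):1):1,O:3);"
  without <- "((S1:1,B:1):1,(S2:1,(L:1,A:1):1):1,O:3);"
  trees <- c(rep(with_clade, 15), rep(without, 5))
  lapply(trees, function(s) ape::read.tree(text = s))
}
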