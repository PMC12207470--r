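#' Window tiling specification
#'
#' @param length window length in bp (default 1 Mbp).
#' @param gap gap between adjacent windows in bp (default 0.5 Mbp).
#' @param offset start of the first window on each chromosome (0-based).
#' @return A `window_spec`.
#' @export
window_spec <- function(length = 1000000L, gap = 500000L, offset = 0L) {
  stopifnot(length > 0, gap >= 0, offset >= 0)
  structure(list(length = as.integer(length), gap = as.integer(gap),
                 offset = as.integer(offset)), class = "window_spec")
}

#' Tile fixed-length windows along chromosomes
#'
#' Windows are half-open `[start, start + length)` in 0-based
#' coordinates, starting at `spec$offset` and stepping
#' `length + gap`; trailing partial windows are discarded.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param spec a [window_spec()].
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(chr) {
    starts <- seq.int(spec$offset, by = spec$length + spec$gap,
                      length.out = max(0L, 1L + (chrom_lengths[[chr]] -
                        spec$offset - spec$length) %/%
                        (spec$length + spec$gap)))
    if (chrom_lengths[[chr]] - spec$offset < spec$length)
      starts <- integer(0)
    data.frame(chrom = rep(chr, length(starts)), start = starts,
               end = starts + spec$length)
  })
  do.call(rbind, out)
}

#' Haploidize genotypes within a window
#'
#' One haploid sequence per individual over the variant sites of a
#' window: sites with any missing genotype are excluded; homozygotes
#' emit their allele; heterozygotes emit one of the two alleles uniformly
#' at random (seeded). Sites where all emitted alleles coincide are
#' moved to the sampling-turned-invariant tally.
#'
#' @param vt a polarized [variant_table()].
#' @param window optional single-row window (list or data.frame with
#'   `chrom`, `start`, `end`, 0-based half-open); `NULL` uses all sites.
#' @param seed integer seed for heterozygote sampling.
#' @return A `window_alignment`: list with `haplotypes` (0/1 matrix,
#'   variable sites x individuals), `alleles` (data.frame `chrom`,
#'   `pos`, `anc`, `der` of the variable sites), `n_variable`,
#'   `n_turned_invariant`, `n_excluded_missing`, `window`, `seed`.
#' @export
haploidize <- function(vt, window = NULL, seed = 1L) {
  if (!vt$polarized) stop("haploidize requires a polarized table")
  keep <- rep(TRUE, n_sites(vt))
  if (!is.null(window))
    keep <- vt$chrom == window$chrom & vt$pos > window$start &
      vt$pos <= window$end
  sub <- subset_sites(vt, keep)
  has_missing <- rowSums(is.na(sub$dosage)) > 0L
  sub <- subset_sites(sub, !has_missing)
  set.seed(seed)
  hap <- matrix(0L, nrow = n_sites(sub), ncol = n_individuals(sub),
                dimnames = list(NULL, colnames(sub$dosage)))
  hap[sub$dosage == 2L] <- 1L
  het <- sub$dosage == 1L
  hap[het] <- rbinom(sum(het), 1L, 0.5)
  mono <- rowSums(hap) %in% c(0L, ncol(hap))
  structure(list(
    haplotypes = hap[!mono, , drop = FALSE],
    alleles = data.frame(chrom = sub$chrom, pos = sub$pos,
                         anc = sub$anc, der = sub$der)[!mono, ,
                                                       drop = FALSE],
    n_variable = sum(!mono),
    n_turned_invariant = sum(mono),
    n_excluded_missing = sum(has_missing),
    window = window, seed = seed), class = "window_alignment")
}

#' Mask-based invariant-site count for a window
#'
#' `invariant = (positively masked bp in the window) - (variable sites
#' after haploid sampling)`; sites turned invariant by allele sampling
#' therefore augment the invariant count. A negative result signals a
#' mask inconsistent with the variants and is an error.
#'
#' @param window single-row window (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param positive a [genome_mask()].
#' @param alignment a `window_alignment` from [haploidize()].
#' @return integer invariant-site count.
#' @export
count_invariants <- function(window, positive, alignment) {
  bp <- suppressWarnings(
    mask_bp_in_window(positive, window$chrom, window$start, window$end))
  inv <- bp - alignment$n_variable
  if (inv < 0)
    stop("mask inconsistent with variants: ", bp, " masked bp < ",
         alignment$n_variable, " variable sites")
  as.integer(inv)
}

#' Neighbour-joining tree from a window alignment
#'
#' Deliberately simple stand-in for external maximum-likelihood window
#' trees: pairwise distance = haplotype mismatches divided by
#' `(variable + invariant)` sites (invariant-count dilution in place of a
#' model-based ascertainment correction), neighbour-joining via
#' [ape::nj()], negative branch lengths clamped to zero, and zero-length
#' internal edges collapsed. Taxa are ordered by label before inference
#' so ties break deterministically.
#'
#' @param alignment a `window_alignment` (>= 3 sequences).
#' @param n_invariant invariant-site count from [count_invariants()]
#'   (default 0: distances over variable sites only).
#' @return An [ape::phylo] (unrooted).
#' @export
infer_tree_nj <- function(alignment, n_invariant = 0L) {
  hap <- alignment$haplotypes
  if (ncol(hap) < 3L) stop("need at least 3 sequences")
  hap <- hap[, order(colnames(hap)), drop = FALSE]
  denom <- alignment$n_variable + n_invariant
  n <- ncol(hap)
  d <- matrix(0, n, n, dimnames = list(colnames(hap), colnames(hap)))
  if (nrow(hap) > 0L && denom > 0L) {
    cross <- crossprod(hap)                      # shared derived
    ones <- crossprod(1L - hap)                  # shared ancestral
    mism <- nrow(hap) - cross - ones
    d <- mism / denom
  }
  nj_from_dist(d)
}

#' Neighbour-joining from an explicit distance matrix
#'
#' @param d symmetric distance matrix with taxon labels.
#' @return An [ape::phylo] with negative branch lengths clamped to zero
#'   and zero-length internal edges collapsed.
#' @export
nj_from_dist <- function(d) {
  d <- as.matrix(d)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  if (all(d == 0)) {   # star tree
    tr <- ape::read.tree(text = paste0(
      "(", paste(rownames(d), collapse = ","), ");"))
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::di2multi(tr, tol = 1e-12)
}

## Clade leaf sets of one tree as sorted comma-joined label strings.
tree_clades <- function(tr) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  unique(vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ","),
                character(1)))
}

#' Monophyly and clade support over a set of window trees
#'
#' Optionally samples `sample_size` trees uniformly without replacement
#' (seeded), roots each tree on the outgroup's attachment edge, prunes
#' the outgroup, and summarizes: the fraction of trees in which the
#' focal taxon set is exactly the leaf set of a clade, and per-clade
#' support fractions with a strict-majority flag (fraction > 0.5).
#' Trees missing a focal taxon, missing the outgroup, or with a
#' non-monophyletic outgroup are skipped with a log entry.
#'
#' @param trees a `multiPhylo`, list of [ape::phylo], or path to a
#'   newick file (one tree per line).
#' @param focal character vector, the focal taxon set.
#' @param outgroup character vector of outgroup taxa used for rooting
#'   then removed; `NULL` treats trees as already rooted.
#' @param sample_size number of trees to sample; `>=` available uses all.
#' @param seed integer seed for sampling.
#' @return A `monophyly_summary`: list with `n_trees`, `n_skipped`,
#'   `skip_log`, `focal_fraction`, `focal_monophyletic_count`, and
#'   `clades` (data.frame `clade`, `count`, `fraction`, `majority`).
#' @export
clade_support <- function(trees, focal, outgroup = NULL,
                          sample_size = 500L, seed = 1L) {
  if (is.character(trees) && length(trees) == 1L)
    trees <- ape::read.tree(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  set.seed(seed)
  if (length(trees) > sample_size)
    trees <- trees[sort(sample.int(length(trees), sample_size))]

  skip_log <- character(0)
  clade_sets <- list()
  focal_key <- paste(sort(focal), collapse = ",")
  n_mono <- 0L
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!all(focal %in% tr$tip.label)) {
      skip_log <- c(skip_log, sprintf("tree %d: focal taxon absent", i))
      next
    }
    if (!is.null(outgroup)) {
      if (!all(outgroup %in% tr$tip.label)) {
        skip_log <- c(skip_log, sprintf("tree %d: outgroup absent", i))
        next
      }
      rooted <- tryCatch(
        ape::root(tr, outgroup = outgroup, resolve.root = TRUE),
        error = function(e) NULL)
      if (is.null(rooted)) {
        skip_log <- c(skip_log,
                      sprintf("tree %d: outgroup not monophyletic", i))
        next
      }
      tr <- ape::drop.tip(rooted, outgroup)
    }
    sets <- tree_clades(tr)
    if (focal_key %in% sets) n_mono <- n_mono + 1L
    clade_sets[[length(clade_sets) + 1L]] <- sets
  }
  n_used <- length(clade_sets)
  if (n_used == 0L) stop("no usable trees")
  tab <- table(unlist(clade_sets))
  clades <- data.frame(clade = names(tab), count = as.integer(tab),
                       fraction = as.integer(tab) / n_used,
                       stringsAsFactors = FALSE)
  clades$majority <- clades$fraction > 0.5
  clades <- clades[order(-clades$count, clades$clade), , drop = FALSE]
  rownames(clades) <- NULL
  structure(list(n_trees = n_used, n_skipped = length(skip_log),
                 skip_log = skip_log,
                 focal_fraction = n_mono / n_used,
                 focal_monophyletic_count = n_mono,
                 clades = clades), class = "monophyly_summary")
}

#' @export
print.monophyly_summary <- function(x, ...) {
  cat("monophyly_summary:", x$n_trees, "trees (", x$n_skipped,
      "skipped );",
      sprintf("focal monophyly %.1f%% (%d/%d)\n", 100 * x$focal_fraction,
              x$focal_monophyletic_count, x$n_trees))
  invisible(x)
}

#' Write a window alignment as FASTA
#'
#' Haplotype 0/1 states are mapped back to the ancestral/derived
#' nucleotides of each site.
#'
#' @param alignment a `window_alignment`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  hap <- alignment$haplotypes
  anc <- alignment$alleles$anc
  der <- alignment$alleles$der
  con <- file(path, "w")
  on.exit(close(con))
  for (id in colnames(hap)) {
    seqc <- ifelse(hap[, id] == 1L, der, anc)
    writeLines(c(paste0(">", id), paste(seqc, collapse = "")), con)
  }
  invisible(path)
}
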