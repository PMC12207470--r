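#' Population model for the genotype simulator
#'
#' A rooted population split tree with a per-branch drift coefficient
#' `F` in `[0, 1)`. Along each branch the allele frequency `p` is replaced
#' by a Beta draw with mean `p` and variance `F * p * (1 - p)`
#' (Balding-Nichols). Optional admixture pulses mix tip frequencies:
#' a pulse of intensity `i` from donor to recipient sets the recipient
#' frequency to `(1 - i) * p_recipient + i * p_donor`.
#'
#' This is an explicit stand-in for a real demographic history: it has no
#' coalescent genealogy, recombination or mutation model, but its analytic
#' first two moments make generator behaviour testable.
#'
#' @param branches data.frame with columns `parent`, `child`, `F`; the
#'   root is the unique parent that never appears as a child. Tips are
#'   children that never appear as parents; population labels are the tips.
#' @param outgroup tip label of the single outgroup population; its
#'   individuals are emitted homozygous ancestral and never missing.
#' @param pulses optional list of admixture pulses, each
#'   `list(from =, to =, intensity =, t0 =, t1 =)`; times are fractions of
#'   total tree depth and must fall inside `[0, depth]`.
#' @param spectrum length-2 numeric, bounds of the uniform ancestral
#'   frequency spectrum (default `c(0.05, 0.95)` so boundary fixation does
#'   not dominate private-allele counts).
#' @param depth nominal tree depth used only to validate pulse windows.
#' @return A `pop_model` object.
#' @export
pop_model <- function(branches, outgroup, pulses = list(),
                      spectrum = c(0.05, 0.95), depth = 1) {
  stopifnot(is.data.frame(branches),
            all(c("parent", "child", "F") %in% names(branches)))
  if (any(branches$F < 0 | branches$F >= 1))
    stop("drift coefficient F must lie in [0, 1) on every branch")
  tips <- setdiff(branches$child, branches$parent)
  if (length(outgroup) != 1L || !outgroup %in% tips)
    stop("exactly one outgroup tip must be named")
  for (p in pulses) {
    stopifnot(all(c("from", "to", "intensity") %in% names(p)))
    if (p$intensity < 0 || p$intensity > 1)
      stop("pulse intensities must lie in [0, 1]")
    t0 <- if (is.null(p$t0)) 0 else p$t0
    t1 <- if (is.null(p$t1)) t0 else p$t1
    if (t0 < 0 || t1 > depth)
      stop("pulse window outside tree depth")
    if (!all(c(p$from, p$to) %in% tips))
      stop("pulse populations must be tips")
  }
  structure(list(branches = branches, tips = tips, outgroup = outgroup,
                 pulses = pulses, spectrum = spectrum, depth = depth),
            class = "pop_model")
}

#' Default five-population ringed seal style model
#'
#' One deeply drifted focal population (`saimaa`), three mildly drifted
#' relatives sharing an internal branch, and an outgroup (`spotted`) used
#' only for polarization.
#'
#' @param focal_F drift on the focal terminal branch.
#' @param other_F drift on each non-focal terminal branch.
#' @param shared_F drift on the internal branch joining the non-focal
#'   populations.
#' @return A [pop_model()].
#' @export
seal_model <- function(focal_F = 0.5, other_F = 0.05, shared_F = 0.02) {
  branches <- data.frame(
    parent = c("ROOT", "ROOT", "INGROUP", "INGROUP",
               "OTHERS", "OTHERS", "OTHERS", "OTHERS"),
    child  = c("spotted", "INGROUP", "saimaa", "OTHERS",
               "ladoga", "baltic", "arctic", "okhotsk"),
    F      = c(0, 0, focal_F, shared_F,
               other_F, other_F, other_F, other_F))
  pop_model(branches, outgroup = "spotted")
}

#' Simulation dimensions and rates
#'
#' @param n_sites number of biallelic sites to simulate (> 0).
#' @param n_per_pop diploid individuals per population (> 0); scalar or a
#'   named vector over population labels.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param missing_rate i.i.d. probability that an ingroup genotype is
#'   missing; the outgroup is never missing.
#' @param seed integer random seed; the same seed yields byte-identical
#'   output files.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_sites, n_per_pop,
                       chrom_lengths = c(chr1 = 50000000L),
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_sites > 0, all(n_per_pop > 0), all(chrom_lengths > 0),
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_sites = as.integer(n_sites), n_per_pop = n_per_pop,
                 chrom_lengths = chrom_lengths,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

## Balding-Nichols transition: Beta with mean p, variance F p (1-p).
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  lambda <- (1 - F) / F
  rbeta(length(p), lambda * p, lambda * (1 - p))
}

#' Simulate diploid genotypes under per-branch drift
#'
#' Draws an ancestral frequency per site from the model's uniform
#' spectrum, propagates it down the split tree with Balding-Nichols
#' branch transitions, applies admixture pulses to tip frequencies, and
#' emits diploid genotypes `Binomial(2, p_pop)` per individual. The
#' outgroup is homozygous ancestral at every site. REF/ALT orientation is
#' randomized per site so downstream polarization is exercised.
#'
#' @param model a [pop_model()].
#' @param cfg a [sim_config()].
#' @return list with elements `variants` (an unpolarized
#'   [variant_table()] including the outgroup individuals) and `truth`
#'   (per-site ancestral allele, true per-population frequencies, and the
#'   REF-is-ancestral flag).
#' @export
simulate_genotypes <- function(model, cfg) {
  stopifnot(inherits(model, "pop_model"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  pops <- model$tips

  ## frequencies down the tree, root first
  freq <- list(ROOT = runif(n, model$spectrum[1], model$spectrum[2]))
  br <- model$branches
  remaining <- seq_len(nrow(br))
  while (length(remaining)) {
    ready <- remaining[br$parent[remaining] %in% names(freq)]
    if (!length(ready)) stop("branch table is not a connected rooted tree")
    for (i in ready)
      freq[[br$child[i]]] <- bn_draw(freq[[br$parent[i]]], br$F[i])
    remaining <- setdiff(remaining, ready)
  }
  for (p in model$pulses)
    freq[[p$to]] <- (1 - p$intensity) * freq[[p$to]] +
      p$intensity * freq[[p$from]]

  ## positions: uniform without replacement within chromosomes
  lens <- cfg$chrom_lengths
  chrom_of <- sort(sample(names(lens), n, replace = TRUE,
                          prob = lens / sum(lens)))
  pos <- integer(n)
  for (chr in names(lens)) {
    idx <- which(chrom_of == chr)
    pos[idx] <- sort(sample.int(lens[[chr]], length(idx)))
  }

  ## genotypes per population, derived-dosage orientation first
  npp <- cfg$n_per_pop
  if (is.null(names(npp))) npp <- setNames(rep(npp[1], length(pops)), pops)
  ids <- unlist(lapply(pops, function(pl)
    paste0(pl, "_", seq_len(npp[[pl]]))))
  pop_of <- setNames(rep(pops, times = npp[pops]), ids)
  der <- matrix(0L, nrow = n, ncol = length(ids),
                dimnames = list(NULL, ids))
  for (pl in pops) {
    cols <- which(pop_of == pl)
    if (pl == model$outgroup) next  # homozygous ancestral
    der[, cols] <- rbinom(n * length(cols), 2L, rep(freq[[pl]],
                                                    length(cols)))
  }
  if (cfg$missing_rate > 0) {
    ing <- which(pop_of != model$outgroup)
    drop <- matrix(runif(n * length(ing)) < cfg$missing_rate,
                   nrow = n)
    der[, ing][drop] <- NA_integer_
  }

  ## allele identities and randomized REF orientation
  nts <- c("A", "C", "G", "T")
  anc <- sample(nts, n, replace = TRUE)
  dlt <- sample(nts[-1], n, replace = TRUE)  # offset into remaining three
  dnuc <- vapply(seq_len(n), function(i) setdiff(nts, anc[i])[
    match(dlt[i], nts[-1])], character(1))
  ref_is_anc <- runif(n) < 0.5
  refa <- ifelse(ref_is_anc, anc, dnuc)
  alta <- ifelse(ref_is_anc, dnuc, anc)
  alt_dosage <- der
  alt_dosage[!ref_is_anc, ] <- 2L - der[!ref_is_anc, , drop = FALSE]

  vt <- variant_table(chrom_of, pos, refa, alta, alt_dosage, pop_of)
  ord <- order(chrom_of, pos)
  truth <- list(
    anc = anc[ord], ref_is_anc = ref_is_anc[ord],
    freq = do.call(cbind, lapply(freq[pops], function(f) f[ord])),
    model = model, cfg = cfg)
  list(variants = vt, truth = truth)
}
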