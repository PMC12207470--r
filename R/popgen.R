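#' Derived-allele presence patterns
#'
#' For a chosen sample of individuals per population, records per site
#' whether the derived allele is observed in at least one sampled
#' chromosome of each population. Sites where no sampled population shows
#' the derived allele are excluded.
#'
#' @param vt a polarized [variant_table()].
#' @param subsample named list mapping population label to the individual
#'   ids sampled from it; every population needs at least one id.
#' @return A `pattern_table`: logical matrix (retained sites x
#'   populations) with attributes `site` (site ids) and `unique_pop`
#'   (population name for sites whose pattern has exactly one bit set,
#'   else `NA`).
#' @export
derived_patterns <- function(vt, subsample) {
  if (!vt$polarized) stop("derived_patterns requires a polarized table")
  if (any(vapply(subsample, length, 1L) == 0L))
    stop("empty subsample for a population")
  ids <- unlist(subsample)
  missing_ids <- setdiff(ids, colnames(vt$dosage))
  if (length(missing_ids))
    stop("individuals absent from table: ",
         paste(missing_ids, collapse = ", "))
  pres <- vapply(subsample, function(cols) {
    rowSums(vt$dosage[, cols, drop = FALSE] > 0L, na.rm = TRUE) > 0L
  }, logical(n_sites(vt)))
  if (n_sites(vt) == 1L) pres <- matrix(pres, nrow = 1L,
                                        dimnames = list(NULL,
                                                        names(subsample)))
  keep <- rowSums(pres) > 0L
  pres <- pres[keep, , drop = FALSE]
  nbits <- rowSums(pres)
  uniq <- rep(NA_character_, nrow(pres))
  one <- nbits == 1L
  uniq[one] <- colnames(pres)[max.col(pres[one, , drop = FALSE])]
  structure(pres, site = site_ids(vt)[keep], unique_pop = uniq,
            class = c("pattern_table", "matrix"))
}

#' Private derived-allele pattern proportions across subsample sizes
#'
#' For each subsample size `n` in `n_range`, draws `replicates`
#' independent uniform samples of `n` individuals per population,
#' computes presence patterns, and reports per population the proportion
#' of retained sites whose pattern is unique to it. The denominator is
#' the number of sites with at least one presence bit within the
#' subsample (set `denominator = "all"` to divide by all table sites
#' instead).
#'
#' @param vt a polarized [variant_table()].
#' @param n_range integer vector of per-population sample sizes.
#' @param replicates independent draws per `n`.
#' @param seed integer seed.
#' @param denominator `"segregating"` (default) or `"all"`.
#' @return data.frame `population`, `n`, `mean`, `sd`, `replicates`,
#'   `seed`.
#' @export
private_proportions <- function(vt, n_range = 1:5, replicates = 20L,
                                seed = 1L,
                                denominator = c("segregating", "all")) {
  denominator <- match.arg(denominator)
  pops <- split(colnames(vt$dosage), vt$populations[colnames(vt$dosage)])
  sizes <- vapply(pops, length, 1L)
  if (max(n_range) > min(sizes))
    stop("n exceeds the size of population ",
         names(pops)[which.min(sizes)])
  set.seed(seed)
  res <- expand.grid(population = names(pops), n = n_range,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$mean <- NA_real_; res$sd <- NA_real_
  props <- array(NA_real_, c(length(pops), length(n_range), replicates),
                 dimnames = list(names(pops), NULL, NULL))
  for (k in seq_along(n_range)) {
    n <- n_range[k]
    for (r in seq_len(replicates)) {
      sub <- lapply(pops, function(idv) sample(idv, n))
      pt <- derived_patterns(vt, sub)
      denom <- if (denominator == "segregating") nrow(pt) else n_sites(vt)
      cnt <- table(factor(attr(pt, "unique_pop"), levels = names(pops)))
      props[, k, r] <- as.numeric(cnt) / denom
    }
  }
  for (i in seq_len(nrow(res))) {
    k <- match(res$n[i], n_range)
    v <- props[res$population[i], k, ]
    res$mean[i] <- mean(v)
    res$sd[i] <- if (replicates >= 2) sd(v) else NA_real_
  }
  res$replicates <- replicates
  res$seed <- seed
  res
}

#' Count fixed private derived alleles of a focal population
#'
#' A site counts iff every called focal chromosome carries the derived
#' allele and no called non-focal chromosome does. With
#' `either_allele = TRUE` a site also counts when the focal population is
#' fixed ancestral while every other population carries only derived
#' alleles.
#'
#' @param vt a polarized [variant_table()].
#' @param focal focal population label.
#' @param either_allele count fixation of either allele (default derived
#'   only).
#' @return integer count.
#' @export
fixed_private_count <- function(vt, focal, either_allele = FALSE) {
  if (!vt$polarized) stop("fixed_private_count requires a polarized table")
  if (!focal %in% vt$populations) stop("unknown population: ", focal)
  fc <- names(vt$populations)[vt$populations == focal]
  oc <- setdiff(colnames(vt$dosage), fc)
  f <- vt$dosage[, fc, drop = FALSE]
  o <- vt$dosage[, oc, drop = FALSE]
  f_called <- rowSums(!is.na(f)) > 0L
  o_called <- rowSums(!is.na(o)) > 0L
  focal_fixed_der <- rowSums(f != 2L, na.rm = TRUE) == 0L & f_called
  others_no_der <- rowSums(o > 0L, na.rm = TRUE) == 0L & o_called
  n <- sum(focal_fixed_der & others_no_der)
  if (either_allele) {
    focal_fixed_anc <- rowSums(f != 0L, na.rm = TRUE) == 0L & f_called
    others_all_der <- rowSums(o != 2L, na.rm = TRUE) == 0L & o_called
    n <- n + sum(focal_fixed_anc & others_all_der)
  }
  as.integer(n)
}

#' Covariance PCA of genotype dosages
#'
#' Individuals x sites dosage matrix, columns mean-centred but NOT
#' variance-normalized (the smartpca `usenorm: NO` convention); missing
#' dosages are mean-imputed per site before centring. Coordinates come
#' from the singular value decomposition; each component's sign is fixed
#' so that its largest-magnitude loading is positive.
#'
#' @param vt a polarized [variant_table()].
#' @param individuals ids to include (default all).
#' @return list with `coords` (individuals x PCs), `loadings`
#'   (sites x PCs), `eigenvalues` (non-increasing), `var_prop`
#'   (proportion of variance per retained PC), `populations`,
#'   `dropped_sites` (ids of all-missing sites removed).
#' @export
pca_genotypes <- function(vt, individuals = colnames(vt$dosage)) {
  if (length(individuals) < 2L) stop("need at least two individuals")
  x <- t(vt$dosage[, individuals, drop = FALSE]) * 1.0
  all_missing <- colSums(!is.na(x)) == 0L
  dropped <- site_ids(vt)[all_missing]
  x <- x[, !all_missing, drop = FALSE]
  if (ncol(x) == 0L) stop("no sites left after dropping all-missing sites")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  xc <- sweep(x, 2L, colMeans(x))
  s <- svd(xc)
  npc <- max(min(nrow(xc) - 1L, ncol(xc)), 1L)  # centring kills one dof
  d <- s$d[seq_len(npc)]
  coords <- s$u[, seq_len(npc), drop = FALSE] %*% diag(d, npc)
  load <- s$v[, seq_len(npc), drop = FALSE]
  for (k in seq_len(npc)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) { load[, k] <- -load[, k]; coords[, k] <- -coords[, k] }
  }
  ev <- d^2 / (nrow(xc) - 1L)
  rownames(coords) <- individuals
  colnames(coords) <- paste0("PC", seq_len(npc))
  list(coords = coords, loadings = load, eigenvalues = ev,
       var_prop = ev / sum(ev),
       populations = vt$populations[individuals],
       dropped_sites = dropped)
}

#' Mean silhouette of one population on a single PC axis
#'
#' Simple separation diagnostic: for the focal individuals' coordinates
#' on one axis, silhouette = (b - a) / max(a, b) with `a` the mean
#' within-focal distance and `b` the mean distance to non-focal
#' individuals, averaged over focal individuals. Positive values mean
#' the focal cluster is separated along that axis.
#'
#' @param pca result of [pca_genotypes()].
#' @param focal focal population label.
#' @param axis PC index (default 1).
#' @return numeric silhouette in `[-1, 1]`.
#' @export
pc_silhouette <- function(pca, focal, axis = 1L) {
  v <- pca$coords[, axis]
  is_f <- pca$populations == focal
  if (sum(is_f) < 2L || sum(!is_f) < 1L)
    stop("need >=2 focal and >=1 non-focal individuals")
  sil <- vapply(which(is_f), function(i) {
    a <- mean(abs(v[i] - v[is_f][-match(i, which(is_f))]))
    b <- mean(abs(v[i] - v[!is_f]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
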