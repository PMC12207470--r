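#' Filtering parameters for the SNP chain
#'
#' @param max_missing maximum tolerated missing-genotype fraction per site,
#'   computed over individuals; sites strictly above it are dropped.
#' @param min_dist minimum physical distance (bp) between retained sites in
#'   the thinning step; distance equal to `min_dist` qualifies.
#' @param maf derived-allele frequency threshold; the minimum passing
#'   derived count is `ceiling(maf * 2N)` over total ingroup chromosomes
#'   (with the defaults and N = 46 diploids this is 5 of 92).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_missing = 0.10, min_dist = 1000L, maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_dist >= 0,
            maf >= 0, maf <= 1)
  structure(list(max_missing = max_missing, min_dist = as.integer(min_dist),
                 maf = maf), class = "filter_config")
}

#' Polarize genotypes against an outgroup
#'
#' Identifies the ancestral allele at each site as the allele carried
#' homozygously by every called outgroup individual, recodes dosages to
#' derived-allele counts, and removes the outgroup columns. Sites where the
#' outgroup is heterozygous, discordant across individuals, or entirely
#' missing are dropped.
#'
#' @param vt an unpolarized [variant_table()].
#' @param outgroup character vector of outgroup individual ids.
#' @return A polarized `variant_table` without the outgroup individuals.
#' @export
polarize <- function(vt, outgroup) {
  if (length(outgroup) == 0L) stop("no outgroup individuals named")
  miss <- setdiff(outgroup, colnames(vt$dosage))
  if (length(miss)) stop("outgroup individuals absent: ",
                         paste(miss, collapse = ", "))
  if (vt$polarized) stop("table is already polarized")

  og <- vt$dosage[, outgroup, drop = FALSE]
  any_het <- apply(og, 1L, function(d) any(d == 1L, na.rm = TRUE))
  n00 <- rowSums(og == 0L, na.rm = TRUE)
  n22 <- rowSums(og == 2L, na.rm = TRUE)
  all_missing <- rowSums(!is.na(og)) == 0L
  discordant <- n00 > 0L & n22 > 0L
  keep <- !any_het & !discordant & !all_missing
  anc_is_ref <- n00 > 0L   # unanimous homozygous REF outgroup

  ing <- setdiff(colnames(vt$dosage), outgroup)
  out <- subset_sites(vt, keep)
  out$dosage <- out$dosage[, ing, drop = FALSE]
  out$populations <- vt$populations[ing]
  flip <- !anc_is_ref[keep]
  out$dosage[flip, ] <- 2L - out$dosage[flip, , drop = FALSE]
  out$anc <- ifelse(anc_is_ref[keep], out$ref, out$alt)
  out$der <- ifelse(anc_is_ref[keep], out$alt, out$ref)
  out$polarized <- TRUE

  reason <- rep(NA_character_, n_sites(vt))
  reason[any_het] <- "outgroup heterozygous"
  reason[discordant] <- "outgroup discordant"
  reason[all_missing] <- "outgroup missing"
  log_filter(vt, out, site_ids(vt)[!keep], "polarize", reason[!keep])
}

#' Apply positive and repeat masks
#'
#' Keeps a site iff its position falls inside the positive (callable) mask
#' and outside the repeat mask.
#'
#' @param vt a [variant_table()].
#' @param positive a [genome_mask()] with role `"positive"`.
#' @param repeats optional [genome_mask()] with role `"repeat"`; `NULL`
#'   skips repeat exclusion.
#' @return Filtered `variant_table`.
#' @export
apply_masks <- function(vt, positive, repeats = NULL) {
  unknown <- setdiff(
    as.character(GenomicRanges::seqnames(positive$ranges)), unique(vt$chrom))
  if (length(unknown))
    warning("mask chromosomes absent from variants (ignored): ",
            paste(unique(unknown), collapse = ", "))
  keep <- suppressWarnings(mask_covers(positive, vt$chrom, vt$pos))
  reason <- rep("outside positive mask", n_sites(vt))
  if (!is.null(repeats)) {
    in_rep <- suppressWarnings(mask_covers(repeats, vt$chrom, vt$pos))
    reason[keep & in_rep] <- "inside repeat mask"
    keep <- keep & !in_rep
  }
  out <- subset_sites(vt, keep)
  log_filter(vt, out, site_ids(vt)[!keep], "apply_masks", reason[!keep])
}

#' Drop high-missingness and invariant sites
#'
#' Removes sites whose missing fraction (over individuals) strictly exceeds
#' `cfg$max_missing`, and sites invariant among the ingroup (all called
#' dosages equal).
#'
#' @param vt a polarized [variant_table()].
#' @param cfg a [filter_config()].
#' @return Filtered `variant_table`.
#' @export
filter_missing_invariant <- function(vt, cfg = filter_config()) {
  if (n_sites(vt) == 0L) return(vt)
  n <- n_individuals(vt)
  miss_frac <- rowSums(is.na(vt$dosage)) / n
  rng <- suppressWarnings(t(apply(vt$dosage, 1L, range, na.rm = TRUE)))
  invariant <- !is.finite(rng[, 1L]) | rng[, 1L] == rng[, 2L]
  too_missing <- miss_frac > cfg$max_missing
  keep <- !too_missing & !invariant
  reason <- ifelse(too_missing, sprintf("missing fraction %.4f > %.2f",
                                        miss_frac, cfg$max_missing),
                   "invariant among ingroup")
  out <- subset_sites(vt, keep)
  log_filter(vt, out, site_ids(vt)[!keep], "missing_invariant",
             reason[!keep])
}

#' Thin sites by physical distance
#'
#' Greedy left-to-right scan per chromosome: the first site is kept and
#' each subsequent site is kept iff its distance to the last kept site is
#' at least `cfg$min_dist` bp. Deterministic and seed-free.
#'
#' @inheritParams filter_missing_invariant
#' @return Thinned `variant_table`.
#' @export
thin_variants <- function(vt, cfg = filter_config()) {
  keep <- logical(n_sites(vt))
  for (chr in unique(vt$chrom)) {
    idx <- which(vt$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (vt$pos[i] - last >= cfg$min_dist) {
        keep[i] <- TRUE
        last <- vt$pos[i]
      }
    }
  }
  out <- subset_sites(vt, keep)
  log_filter(vt, out, site_ids(vt)[!keep], "thin",
             sprintf("< %d bp from previous kept site", cfg$min_dist))
}

#' Derived-allele count (MAF) filter
#'
#' Keeps a site iff its derived-allele count, over called chromosomes,
#' reaches `ceiling(maf * 2N)` where `N` is the total number of ingroup
#' individuals. With `called_denominator = TRUE` the threshold is instead
#' computed per site on called chromosomes only.
#'
#' @inheritParams filter_missing_invariant
#' @param called_denominator logical; see Details.
#' @return Filtered `variant_table`.
#' @export
maf_filter <- function(vt, cfg = filter_config(),
                       called_denominator = FALSE) {
  if (!vt$polarized) stop("maf_filter requires a polarized table")
  count <- rowSums(vt$dosage, na.rm = TRUE)
  if (called_denominator) {
    denom <- 2L * rowSums(!is.na(vt$dosage))
  } else {
    denom <- 2L * n_individuals(vt)
  }
  min_count <- rep_len(ceiling(cfg$maf * denom), n_sites(vt))
  keep <- count >= min_count
  out <- subset_sites(vt, keep)
  log_filter(vt, out, site_ids(vt)[!keep], "maf",
             sprintf("derived count %d < %d", count[!keep],
                     min_count[!keep]))
}

#' Minimum passing derived-allele count for a MAF threshold
#'
#' @param n_individuals number of diploid ingroup individuals.
#' @param maf frequency threshold.
#' @return `ceiling(maf * 2 * n_individuals)`.
#' @export
maf_min_count <- function(n_individuals, maf = 0.05) {
  as.integer(ceiling(maf * 2L * n_individuals))
}

#' Run the full filter chain
#'
#' Applies, in order: [polarize()], [apply_masks()],
#' [filter_missing_invariant()], [thin_variants()], [maf_filter()].
#'
#' @inheritParams polarize
#' @inheritParams apply_masks
#' @inheritParams filter_missing_invariant
#' @return Filtered, polarized `variant_table` with a cumulative filter log.
#' @export
filter_chain <- function(vt, outgroup, positive = NULL, repeats = NULL,
                         cfg = filter_config()) {
  vt <- polarize(vt, outgroup)
  if (!is.null(positive)) vt <- apply_masks(vt, positive, repeats)
  vt <- filter_missing_invariant(vt, cfg)
  vt <- thin_variants(vt, cfg)
  maf_filter(vt, cfg)
}
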