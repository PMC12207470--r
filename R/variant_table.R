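#' Diploid variant table
#'
#' In-memory container for biallelic diploid SNP genotypes. Genotypes are
#' stored as allele dosages in `{0, 1, 2, NA}`: before polarization the
#' dosage counts ALT alleles (VCF orientation); after [polarize()] it counts
#' derived alleles. Sites are sorted and unique within chromosome.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character allele identities per site.
#' @param dosage integer matrix, sites in rows and individuals in columns;
#'   values 0/1/2 or `NA` for missing. Column names are individual ids.
#' @param populations named character vector mapping individual id to
#'   population label; must cover every column of `dosage`.
#' @param polarized logical; `TRUE` once dosages count derived alleles.
#' @param anc,der ancestral/derived allele per site (polarized tables only).
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, dosage, populations,
                          polarized = FALSE, anc = NULL, der = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage),
            length(ref) == nrow(dosage), length(alt) == nrow(dosage))
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have individual ids as column names")
  if (!all(colnames(dosage) %in% names(populations)))
    stop("every individual must have a population label")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"

  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- as.integer(pos[ord])
  ref <- ref[ord]; alt <- alt[ord]
  dosage <- dosage[ord, , drop = FALSE]
  if (!is.null(anc)) anc <- anc[ord]
  if (!is.null(der)) der <- der[ord]
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) stop("duplicate positions within chromosome")

  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         dosage = dosage,
         populations = populations[colnames(dosage)],
         polarized = isTRUE(polarized), anc = anc, der = der),
    filter_log = data.frame(site = character(), stage = character(),
                            reason = character(), stringsAsFactors = FALSE),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", n_sites(x), "sites,", n_individuals(x),
      "individuals in", length(unique(x$populations)), "populations;",
      if (x$polarized) "polarized" else "unpolarized", "\n")
  invisible(x)
}

#' @rdname variant_table
#' @param vt a `variant_table`.
#' @export
n_sites <- function(vt) length(vt$pos)

#' @rdname variant_table
#' @export
n_individuals <- function(vt) ncol(vt$dosage)

site_ids <- function(vt) paste0(vt$chrom, ":", vt$pos)

## Append rows to the per-table filter log, preserving earlier entries.
log_filter <- function(vt, new, sites, stage, reason) {
  lg <- attr(vt, "filter_log")
  if (length(sites))
    lg <- rbind(lg, data.frame(site = sites, stage = stage, reason = reason,
                               stringsAsFactors = FALSE))
  attr(new, "filter_log") <- lg
  new
}

#' Retrieve the filter log of a variant table
#'
#' Each filtering operation appends one row per dropped site
#' (site id, stage, reason).
#'
#' @param vt a `variant_table`.
#' @return data.frame with columns `site`, `stage`, `reason`.
#' @export
filter_log <- function(vt) attr(vt, "filter_log")

## Keep a subset of sites (logical or integer index), carrying metadata.
subset_sites <- function(vt, keep) {
  out <- vt
  out$chrom <- vt$chrom[keep]; out$pos <- vt$pos[keep]
  out$ref <- vt$ref[keep]; out$alt <- vt$alt[keep]
  out$dosage <- vt$dosage[keep, , drop = FALSE]
  if (!is.null(vt$anc)) out$anc <- vt$anc[keep]
  if (!is.null(vt$der)) out$der <- vt$der[keep]
  attr(out, "filter_log") <- attr(vt, "filter_log")
  out
}

#' Read a VCF into a variant table
#'
#' Reads GT fields from a VCF 4.x file (uncompressed or bgzipped).
#' Multi-allelic and non-SNP records are dropped with a logged reason.
#'
#' @param path VCF file path.
#' @param populations named character vector mapping sample id to
#'   population label. Samples absent from the mapping cause an error.
#' @return An unpolarized [variant_table()] (dosage = ALT-allele count).
#' @export
read_variant_vcf <- function(path, populations) {
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  nalt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(nalt))
  alt[nalt == 1L] <- as.character(unlist(altl[nalt == 1L]))
  ok <- nalt == 1L & nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)

  dosage <- matrix(NA_integer_, nrow = sum(ok), ncol = ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  g <- gt[ok, , drop = FALSE]
  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
            "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage[] <- code[g]
  vt <- variant_table(chrom[ok], pos[ok], ref[ok], alt[ok], dosage,
                      populations)
  dropped <- paste0(chrom[!ok], ":", pos[!ok])
  log_filter(vt, vt, dropped, "read_vcf", "multi-allelic or non-SNP")
}

#' Write a variant table as VCF 4.2
#'
#' Emits a minimal GT-only VCF. For polarized tables REF/ALT are written as
#' ancestral/derived and the ancestral allele is recorded in `INFO/AA`.
#'
#' @param vt a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  ref <- if (vt$polarized) vt$anc else vt$ref
  alt <- if (vt$polarized) vt$der else vt$alt
  info <- if (vt$polarized) paste0("AA=", vt$anc) else rep(".", n_sites(vt))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(vt), ncol = n_individuals(vt))
  called <- !is.na(vt$dosage)
  gt[called] <- gt_code[vt$dosage[called] + 1L]

  con <- file(path, "w")
  on.exit(close(con))
  lens <- tapply(vt$pos, vt$chrom, max)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phocidist",
    if (vt$polarized)
      "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    paste0("##contig=<ID=", names(lens), ",length=", lens + 1L, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$dosage)), collapse = "\t")), con)
  body <- cbind(vt$chrom, vt$pos, ".", ref, alt, ".", "PASS", info, "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
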