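ZYGOSITY_LEVELS <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

#' Construct a set of biallelic InDel variants
#'
#' An `indel_set` bundles a table of biallelic InDel sites with a matrix of
#' per-accession diploid genotypes coded as alternate-allele dosages. It is
#' the in-memory form of a multi-sample VCF restricted to length
#' polymorphisms: every record has exactly one REF and one ALT allele of
#' different lengths. Coordinates are 1-based, VCF-style (POS is the anchor
#' base of the indel).
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (uppercase DNA strings; `nchar(ref) != nchar(alt)`).
#' @param geno integer matrix, one row per variant, one column per
#'   accession; entries are alternate-allele dosages 0 (ref/ref),
#'   1 (ref/alt), 2 (alt/alt) or `NA` (missing).
#' @return An object of class `indel_set`.
#' @export
indel_set <- function(variants, geno) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stop("genotype matrix must have one row per variant")
  if (is.null(colnames(geno)))
    stop("genotype matrix must carry accession ids as column names")
  if (anyDuplicated(colnames(geno)))
    stop("duplicated accession ids")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  same <- nchar(variants$ref) == nchar(variants$alt)
  if (any(same))
    stop("ref and alt must differ in length for an InDel: ",
         paste(variants$id[same], collapse = ", "))
  variants$id <- as.character(variants$id)
  rownames(geno) <- variants$id
  structure(list(variants = variants, geno = geno), class = "indel_set")
}

#' @export
print.indel_set <- function(x, ...) {
  cat(sprintf("indel_set: %d biallelic InDel sites x %d accessions\n",
              nrow(x$variants), ncol(x$geno)))
  lens <- indel_length(x)
  cat(sprintf("  insertions: %d  deletions: %d  |length| range: %d-%d bp\n",
              sum(lens > 0), sum(lens < 0),
              min(abs(lens)), max(abs(lens))))
  invisible(x)
}

#' Accessions typed in an indel_set
#' @param x an `indel_set`
#' @return character vector of accession ids.
#' @export
accessions <- function(x) {
  stopifnot(inherits(x, "indel_set"))
  colnames(x$geno)
}

#' Read biallelic InDels from a VCF file
#'
#' Reads a VCF 4.x file, keeps only records where REF and ALT lengths
#' differ (i.e. true length polymorphisms; SNPs and same-length MNPs are
#' dropped), and decomposes multi-allelic records into one biallelic record
#' per alternate allele. For a decomposed record, genotype alleles equal to
#' the retained ALT map to the alternate, `0` maps to the reference, and
#' any other alternate allele is treated as missing for that record.
#'
#' Both `/` and `|` genotype separators are accepted; a GT that is not
#' diploid raises an error, and a malformed GT is recorded as missing with
#' a warning.
#'
#' @param path path to a VCF file.
#' @param accessions optional character vector of sample names to keep, in
#'   this order; an absent sample is an error naming it. Default: all
#'   samples in the file.
#' @return An [indel_set], ordered by (chrom, pos).
#' @export
read_variants <- function(path, accessions = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2)
    stop("VCF carries no sample genotype columns")
  samples <- colnames(gt_raw)[-1]
  if (is.null(accessions)) accessions <- samples
  absent <- setdiff(accessions, samples)
  if (length(absent))
    stop("sample(s) not present in VCF: ", paste(absent, collapse = ", "))

  fmt <- gt_raw[, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("VCF FORMAT lacks GT field")

  out_var <- list(); out_gen <- list(); k <- 0L
  n_malformed <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    ## parse GT once per record
    cells <- gt_raw[i, accessions]
    gtf <- vapply(strsplit(cells, ":", fixed = TRUE), function(v) {
      j <- gt_idx[i]
      if (length(v) >= j) v[j] else NA_character_
    }, character(1))
    al <- strsplit(gtf, "[/|]")
    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (nchar(alt) == nchar(ref)) next  # SNP/MNP: not an InDel
      if (!grepl("^[ACGT]+$", alt) || !grepl("^[ACGT]+$", ref)) next
      dose <- vapply(al, function(v) {
        if (length(v) == 1 && (is.na(v) || v == "."))
          return(NA_integer_)
        if (length(v) != 2) {
          if (all(v %in% c(".", NA))) return(NA_integer_)
          stop("non-diploid GT encountered: ", paste(v, collapse = "/"))
        }
        if (any(v == ".")) return(NA_integer_)
        suppressWarnings(iv <- as.integer(v))
        if (anyNA(iv)) return(-1L)  # malformed sentinel
        if (any(!iv %in% c(0L, a))) return(NA_integer_)  # other alt allele
        sum(iv == a)
      }, integer(1))
      if (any(!is.na(dose) & dose == -1L)) {
        n_malformed <- n_malformed + sum(dose == -1L, na.rm = TRUE)
        dose[!is.na(dose) & dose == -1L] <- NA_integer_
      }
      k <- k + 1L
      out_var[[k]] <- data.frame(
        id = if ("ID" %in% colnames(fix) && !is.na(fix[i, "ID"]) &&
                 fix[i, "ID"] != ".")
               paste0(fix[i, "ID"], if (length(alts) > 1) paste0("_", a) else "")
             else sprintf("%s_%s_%d", fix[i, "CHROM"], fix[i, "POS"], a),
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, stringsAsFactors = FALSE)
      out_gen[[k]] <- dose
    }
  }
  if (n_malformed > 0)
    warning(sprintf("%d malformed GT value(s) recorded as missing",
                    n_malformed))
  if (k == 0L)
    return(indel_set(
      data.frame(id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(integer(), 0, length(accessions),
             dimnames = list(NULL, accessions))))
  variants <- do.call(rbind, out_var)
  geno <- do.call(rbind, out_gen)
  colnames(geno) <- accessions
  ord <- order(variants$chrom, variants$pos)
  indel_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}

#' Write an indel_set to a minimal VCF 4.2 file
#'
#' Emits one biallelic record per variant with a GT-only FORMAT column.
#' Round-trips through [read_variants()].
#'
#' @param x an [indel_set]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  stopifnot(inherits(x, "indel_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=indelbarcode",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", accessions(x)),
                     collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(x$variants))) {
    g <- x$geno[i, ]
    gs <- ifelse(is.na(g), "./.", code[g + 1L])
    writeLines(paste(c(x$variants$chrom[i], x$variants$pos[i],
                       x$variants$id[i], x$variants$ref[i],
                       x$variants$alt[i], ".", "PASS", ".", "GT", gs),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Signed InDel length
#'
#' Length of the alternate allele minus length of the reference allele:
#' positive for insertions relative to the reference, negative for
#' deletions.
#'
#' @param x an [indel_set], or a data.frame with `ref`/`alt` columns.
#' @return integer vector of signed lengths in bp.
#' @export
indel_length <- function(x) {
  v <- if (inherits(x, "indel_set")) x$variants else x
  len <- nchar(v$alt) - nchar(v$ref)
  if (any(len == 0)) stop("record with equal ref/alt lengths is not an InDel")
  as.integer(len)
}

#' Classify genotypes of one accession by zygosity
#'
#' Maps diploid genotype codes to the four zygosity classes: ref/ref is
#' `HOM_REF` (identical to the reference variety), ref/alt is `HET` (one
#' allele matches the reference, the other the alternate), alt/alt is
#' `HOM_ALT` (both alleles match the alternate), and an uncalled genotype
#' is `MISSING`.
#'
#' @param x an [indel_set]
#' @param accession a single accession id present in `x`
#' @return factor over all variants with levels
#'   `HOM_REF, HET, HOM_ALT, MISSING`.
#' @export
classify_zygosity <- function(x, accession) {
  stopifnot(inherits(x, "indel_set"), length(accession) == 1)
  if (!accession %in% accessions(x))
    stop("unknown accession: ", accession)
  g <- x$geno[, accession]
  z <- ZYGOSITY_LEVELS[ifelse(is.na(g), 4L, g + 1L)]
  factor(z, levels = ZYGOSITY_LEVELS)
}

#' Per-accession homozygous-alternate and heterozygous counts
#'
#' Counts, for each accession, the variants called homozygous-alternate
#' and heterozygous, and reports the heterozygous rate
#' `het / (het + hom_alt)`. Sites where the accession is missing or
#' identical to the reference do not enter the denominator (the rate is a
#' fraction of variants that differ from the reference variety). An
#' accession with no non-reference call gets rate 0 and `undefined_rate =
#' TRUE`.
#'
#' @param x an [indel_set]
#' @return data.frame with columns `accession`, `hom_alt`, `het`,
#'   `het_rate`, `undefined_rate`.
#' @export
zygosity_counts <- function(x) {
  stopifnot(inherits(x, "indel_set"))
  acc <- accessions(x)
  hom <- colSums(x$geno == 2L, na.rm = TRUE)
  het <- colSums(x$geno == 1L, na.rm = TRUE)
  denom <- hom + het
  rate <- ifelse(denom == 0, 0, het / denom)
  data.frame(accession = acc, hom_alt = as.integer(hom),
             het = as.integer(het), het_rate = as.numeric(rate),
             undefined_rate = denom == 0, row.names = NULL)
}

#' Histogram of absolute InDel lengths
#'
#' Bins `|indel_length|` into intervals defined by `breaks`, interpreted
#' as lower bin edges: bin k covers `[breaks[k], breaks[k+1] - 1]` and the
#' last bin is open-ended. Counts conserve the total number of variants.
#'
#' @param x an [indel_set] (or an integer vector of signed lengths)
#' @param breaks strictly increasing integer vector of lower bin edges;
#'   the first edge must not exceed the smallest absolute length.
#' @return named integer vector of counts.
#' @export
length_spectrum <- function(x, breaks = c(1L, 5L, 10L)) {
  lens <- if (inherits(x, "indel_set")) indel_length(x) else as.integer(x)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  a <- abs(lens)
  if (length(a) && min(a) < breaks[1])
    stop("smallest |length| falls below the first bin edge")
  idx <- findInterval(a, breaks)
  nb <- length(breaks)
  counts <- tabulate(idx, nbins = nb)
  lab <- c(paste0(breaks[-nb], "-", breaks[-1] - 1L),
           paste0(">=", breaks[nb]))
  stats::setNames(as.integer(counts), lab)
}
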