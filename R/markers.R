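#' Marker selection configuration
#'
#' Thresholds for the candidate-marker filter chain. Defaults follow the
#' study design this package implements: InDels of 10-20 bp absolute
#' length, amplicons of 150-231 bp so allele sizes separate on a 3%
#' agarose gel, homozygous calls across the panel (co-dominant scoring
#' without ambiguous single-band heterozygotes), at least one accession on
#' each side of the polymorphism, and exact primer binding.
#'
#' @param min_abs_len minimum `|indel length|` in bp (default 10)
#' @param max_abs_len maximum `|indel length|` in bp (default 20)
#' @param amplicon_min minimum amplicon size in bp (default 150)
#' @param amplicon_max maximum amplicon size in bp (default 231)
#' @param require_homozygous_panel drop sites with any heterozygous panel
#'   call (default TRUE)
#' @param require_polymorphic require at least one HOM_ALT and one HOM_REF
#'   accession in the panel (default TRUE)
#' @param max_primer_mismatch maximum Hamming mismatches per primer in
#'   in-silico PCR (default 0)
#' @param max_products maximum number of reference amplicons tolerated per
#'   primer pair (default 1, strict single-product)
#' @return list of class `selection_config`.
#' @export
selection_config <- function(min_abs_len = 10L, max_abs_len = 20L,
                             amplicon_min = 150L, amplicon_max = 231L,
                             require_homozygous_panel = TRUE,
                             require_polymorphic = TRUE,
                             max_primer_mismatch = 0L,
                             max_products = 1L) {
  stopifnot(min_abs_len <= max_abs_len, amplicon_min <= amplicon_max,
            max_primer_mismatch >= 0, max_products >= 1)
  structure(list(min_abs_len = as.integer(min_abs_len),
                 max_abs_len = as.integer(max_abs_len),
                 amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 require_homozygous_panel = isTRUE(require_homozygous_panel),
                 require_polymorphic = isTRUE(require_polymorphic),
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 max_products = as.integer(max_products)),
            class = "selection_config")
}

#' Filter InDel variants down to marker candidates
#'
#' Applies the fixed filter chain length -> panel zygosity ->
#' polymorphism. A survivor has `min_abs_len <= |indel length| <=
#' max_abs_len`; no heterozygous call in the panel (when
#' `require_homozygous_panel`); and both homozygous classes present in the
#' panel (when `require_polymorphic`) so the marker actually separates
#' accessions from the reference variety. The filters are a conjunction of
#' per-site predicates, so the surviving set does not depend on stage
#' order; the fixed order only determines which rule a rejected site is
#' attributed to.
#'
#' @param x an [indel_set]
#' @param panel character vector of accession ids to evaluate the
#'   zygosity/polymorphism rules on (default: all accessions in `x`)
#' @param cfg a [selection_config]
#' @return the surviving [indel_set], with attributes `filter_log`
#'   (data.frame stage/survivors) and `rejections` (data.frame id/rule,
#'   first failed rule per rejected site).
#' @export
filter_candidates <- function(x, panel = accessions(x),
                              cfg = selection_config()) {
  stopifnot(inherits(x, "indel_set"), length(panel) >= 1)
  bad <- setdiff(panel, accessions(x))
  if (length(bad)) stop("unknown panel accession(s): ",
                        paste(bad, collapse = ", "))
  n <- nrow(x$variants)
  if (n == 0) {
    out <- x
    attr(out, "filter_log") <- data.frame(
      stage = c("input", "length", "zygosity", "polymorphism"),
      survivors = c(0L, 0L, 0L, 0L))
    attr(out, "rejections") <- data.frame(id = character(),
                                          rule = character())
    return(out)
  }
  lens <- abs(indel_length(x))
  g <- x$geno[, panel, drop = FALSE]
  pass_len <- lens >= cfg$min_abs_len & lens <= cfg$max_abs_len
  any_het <- rowSums(g == 1L, na.rm = TRUE) > 0L
  pass_zyg <- if (cfg$require_homozygous_panel) !any_het else rep(TRUE, n)
  has_alt <- rowSums(g == 2L, na.rm = TRUE) > 0L
  has_ref <- rowSums(g == 0L, na.rm = TRUE) > 0L
  pass_poly <- if (cfg$require_polymorphic) has_alt & has_ref else rep(TRUE, n)

  keep <- pass_len & pass_zyg & pass_poly
  rule <- rep(NA_character_, n)
  rule[!pass_len] <- "length"
  rule[is.na(rule) & !pass_zyg] <- "heterozygous_in_panel"
  rule[is.na(rule) & !pass_poly] <- "not_polymorphic"

  out <- indel_set(x$variants[keep, , drop = FALSE],
                   x$geno[keep, , drop = FALSE])
  attr(out, "filter_log") <- data.frame(
    stage = c("input", "length", "zygosity", "polymorphism"),
    survivors = c(n, sum(pass_len), sum(pass_len & pass_zyg), sum(keep)))
  attr(out, "rejections") <- data.frame(
    id = x$variants$id[!keep], rule = rule[!keep], row.names = NULL)
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Hamming scan of `pattern` along `tmpl` (both char vectors).
## anchor_at: index within pattern that must match exactly when max_mm > 0
## (the primer 3' terminus). Returns 1-based start positions and mismatch
## counts.
.primer_sites <- function(tmpl, pattern, max_mm, anchor_at) {
  lp <- length(pattern); lt <- length(tmpl)
  if (lt < lp) return(data.frame(start = integer(), mm = integer()))
  starts <- integer(); mms <- integer()
  for (i in seq_len(lt - lp + 1L)) {
    seg <- tmpl[i:(i + lp - 1L)]
    mm <- sum(seg != pattern)
    if (mm <= max_mm && (max_mm == 0L || seg[anchor_at] == pattern[anchor_at]))
      { starts <- c(starts, i); mms <- c(mms, mm) }
  }
  data.frame(start = starts, mm = mms)
}

#' In-silico PCR on a template sequence
#'
#' Locates every amplicon a primer pair would produce on the plus strand
#' of `template`: the forward primer matching the plus strand and the
#' reverse-complement of the reverse primer matching downstream, each with
#' at most `max_mismatch` Hamming mismatches. Primer binding admits no
#' indels, and when `max_mismatch > 0` the 3'-terminal base of each primer
#' must still match exactly (extension from a mismatched 3' end is
#' assumed to fail). Product length spans the forward primer 5' end to the
#' reverse primer 5' end, both primers included; coordinates are 1-based
#' inclusive.
#'
#' @param forward,reverse primer sequences, 5'->3', A/C/G/T; the reverse
#'   primer is given as synthesized (reverse-complement of the plus
#'   strand at its binding site)
#' @param template plus-strand template DNA string
#' @param max_mismatch maximum Hamming mismatches per primer (default 0)
#' @return data.frame sorted by `start` with columns `start`, `end`,
#'   `length`, `forward_mismatches`, `reverse_mismatches`; zero rows when
#'   no site exists.
#' @export
epcr <- function(forward, reverse, template, max_mismatch = 0L) {
  stopifnot(nchar(template) > 0, nchar(forward) >= 1, nchar(reverse) >= 1)
  if (!grepl("^[ACGT]+$", forward) || !grepl("^[ACGT]+$", reverse))
    stop("primers must be uppercase A/C/G/T")
  tmpl <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  f <- strsplit(forward, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(reverse), "", fixed = TRUE)[[1]]
  ## forward 3' end = last base; reverse 3' end = first base of its
  ## plus-strand (revcomp) footprint
  fs <- .primer_sites(tmpl, f, max_mismatch, anchor_at = length(f))
  rs <- .primer_sites(tmpl, rc, max_mismatch, anchor_at = 1L)
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    forward_mismatches = integer(),
                    reverse_mismatches = integer())
  if (nrow(fs) == 0 || nrow(rs) == 0) return(out)
  lf <- length(f); lr <- length(rc)
  for (i in seq_len(nrow(fs))) {
    dn <- rs[rs$start >= fs$start[i] + lf, , drop = FALSE]
    if (nrow(dn) == 0) next
    out <- rbind(out, data.frame(
      start = fs$start[i], end = dn$start + lr - 1L,
      length = dn$start + lr - fs$start[i],
      forward_mismatches = fs$mm[i], reverse_mismatches = dn$mm))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Predict reference- and alternate-allele amplicon sizes
#'
#' Runs [epcr()] on the reference haplotype around a marker, requires a
#' single product (or at most `max_products`, first taken) containing the
#' indel, then substitutes the alternate allele into the template and
#' re-amplifies. The two product sizes differ by exactly the absolute
#' indel length: this is what makes the marker co-dominantly scorable by
#' product size.
#'
#' @param template reference-haplotype DNA string carrying the locus
#' @param pos 1-based position of the indel anchor base on `template`
#' @param ref_allele,alt_allele VCF-style REF/ALT alleles (anchored,
#'   different lengths)
#' @param forward,reverse primer pair (see [epcr()])
#' @param max_mismatch per-primer mismatch allowance (default 0)
#' @param max_products reference amplicon count tolerated (default 1)
#' @param marker_id optional id used in error messages
#' @return named numeric vector `c(ref = , alt = )` of product sizes (bp).
#' @export
predict_allele_amplicons <- function(template, pos, ref_allele, alt_allele,
                                     forward, reverse, max_mismatch = 0L,
                                     max_products = 1L, marker_id = NULL) {
  id <- if (is.null(marker_id)) "<unnamed>" else marker_id
  if (nchar(ref_allele) == nchar(alt_allele))
    stop("marker ", id, ": ref and alt alleles have equal length")
  if (substr(template, pos, pos + nchar(ref_allele) - 1L) != ref_allele)
    stop("marker ", id, ": ref allele does not match the template at pos ",
         pos)
  hits <- epcr(forward, reverse, template, max_mismatch)
  if (nrow(hits) == 0)
    stop("marker ", id, ": primers produce no amplicon on the reference")
  if (nrow(hits) > max_products)
    stop("marker ", id, ": primers produce ", nrow(hits),
         " reference amplicons (max_products = ", max_products, ")")
  amp <- hits[1, ]
  ind_end <- pos + nchar(ref_allele) - 1L
  if (pos < amp$start || ind_end > amp$end)
    stop("marker ", id, ": indel lies outside the predicted amplicon")
  alt_template <- paste0(substr(template, 1L, pos - 1L), alt_allele,
                         substr(template, ind_end + 1L, nchar(template)))
  alt_hits <- epcr(forward, reverse, alt_template, max_mismatch)
  if (nrow(alt_hits) == 0)
    stop("marker ", id, ": no amplicon on the alternate haplotype")
  c(ref = as.numeric(amp$length), alt = as.numeric(alt_hits$length[1]))
}

#' Keep marker loci whose both allele amplicons fit the size window
#'
#' @param loci data.frame with numeric columns `ref_amplicon_bp` and
#'   `alt_amplicon_bp` (one row per marker locus)
#' @param cfg a [selection_config]; the window is
#'   `[amplicon_min, amplicon_max]`, both alleles must fit.
#' @return the surviving rows of `loci`, with a `rejections` attribute
#'   listing dropped marker ids.
#' @export
amplicon_size_filter <- function(loci, cfg = selection_config()) {
  stopifnot(is.data.frame(loci))
  if (nrow(loci) == 0) {
    attr(loci, "rejections") <- character()
    return(loci)
  }
  keep <- loci$ref_amplicon_bp >= cfg$amplicon_min &
    loci$ref_amplicon_bp <= cfg$amplicon_max &
    loci$alt_amplicon_bp >= cfg$amplicon_min &
    loci$alt_amplicon_bp <= cfg$amplicon_max
  out <- loci[keep, , drop = FALSE]
  attr(out, "rejections") <- if ("marker_id" %in% names(loci))
    loci$marker_id[!keep] else rownames(loci)[!keep]
  out
}

#' Read a primer-pair table
#'
#' Expects a TSV with at least the columns `marker_id`, `forward`,
#' `reverse`, and optionally `chrom` and `pos` locating the targeted
#' indel.
#'
#' @param path TSV file path
#' @return data.frame of primer pairs.
#' @export
read_primers <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "forward", "reverse")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("primer table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ok <- grepl("^[ACGT]{15,}$", p$forward) & grepl("^[ACGT]{15,}$", p$reverse)
  if (!all(ok))
    stop("invalid primer sequence(s) for: ",
         paste(p$marker_id[!ok], collapse = ", "))
  p
}

#' Build the selected-marker panel table
#'
#' Ties together the filtered variants, primer pairs and reference
#' sequences: for each candidate surviving [filter_candidates()], predicts
#' both allele amplicons ([predict_allele_amplicons()]) and applies
#' [amplicon_size_filter()]. Candidates without a primer pair are dropped
#' (logged); surviving markers are labelled `TB1..TBn` in genomic order
#' unless the primer table already names them.
#'
#' @param x an [indel_set] of filter survivors
#' @param primers primer data.frame (see [read_primers()]); matched to
#'   variants by `marker_id` == variant id, or by `chrom` + `pos`
#' @param ref_seqs named character vector (or `Biostrings::DNAStringSet`)
#'   of reference sequences keyed by chrom
#' @param cfg a [selection_config]
#' @param relabel assign TB labels in (chrom, pos) order (default TRUE)
#' @return data.frame (one row per selected marker): `marker_id`, `chrom`,
#'   `pos`, `indel_length`, `ref_amplicon_bp`, `alt_amplicon_bp`,
#'   `forward`, `reverse`; attributes `rejections` (amplicon-window drops)
#'   and `no_primer` (candidates lacking primers).
#' @export
build_marker_panel <- function(x, primers, ref_seqs,
                               cfg = selection_config(), relabel = TRUE) {
  stopifnot(inherits(x, "indel_set"))
  if (methods::is(ref_seqs, "DNAStringSet"))
    ref_seqs <- stats::setNames(as.character(ref_seqs), names(ref_seqs))
  v <- x$variants
  key_var <- paste(v$chrom, v$pos)
  idx <- match(v$id, primers$marker_id)
  if (all(c("chrom", "pos") %in% names(primers))) {
    key_pr <- paste(primers$chrom, primers$pos)
    idx2 <- match(key_var, key_pr)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  no_primer <- v$id[is.na(idx)]
  rows <- which(!is.na(idx))
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]; j <- idx[i]
    tmpl <- ref_seqs[[v$chrom[i]]]
    if (is.null(tmpl)) stop("reference sequence missing for ", v$chrom[i])
    sizes <- predict_allele_amplicons(
      tmpl, v$pos[i], v$ref[i], v$alt[i],
      primers$forward[j], primers$reverse[j],
      max_mismatch = cfg$max_primer_mismatch,
      max_products = cfg$max_products, marker_id = v$id[i])
    out[[k]] <- data.frame(
      marker_id = v$id[i], chrom = v$chrom[i], pos = v$pos[i],
      indel_length = nchar(v$alt[i]) - nchar(v$ref[i]),
      ref_amplicon_bp = sizes[["ref"]], alt_amplicon_bp = sizes[["alt"]],
      forward = primers$forward[j], reverse = primers$reverse[j],
      stringsAsFactors = FALSE)
  }
  loci <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_id = character(), chrom = character(),
               pos = integer(), indel_length = integer(),
               ref_amplicon_bp = numeric(), alt_amplicon_bp = numeric(),
               forward = character(), reverse = character())
  loci <- amplicon_size_filter(loci, cfg)
  rej <- attr(loci, "rejections")
  if (relabel && nrow(loci)) {
    ord <- order(loci$chrom, loci$pos)
    loci <- loci[ord, , drop = FALSE]
    loci$source_id <- loci$marker_id
    loci$marker_id <- paste0("TB", seq_len(nrow(loci)))
  }
  rownames(loci) <- NULL
  attr(loci, "rejections") <- rej
  attr(loci, "no_primer") <- no_primer
  loci
}
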