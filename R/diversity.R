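#' Band-pattern frequencies at one marker
#'
#' Each accession contributes one pattern (its call, `a`, `b` or `h`);
#' missing calls are excluded from the denominator. Frequencies are
#' returned at full precision, sorted decreasing, named by pattern.
#'
#' @param m genotype matrix (see [validate_genotype_matrix()])
#' @param marker_id a marker (column) id
#' @return named numeric frequency vector summing to 1, with attribute
#'   `n` (accessions counted).
#' @export
pattern_frequencies <- function(m, marker_id) {
  validate_genotype_matrix(m)
  if (!marker_id %in% colnames(m)) stop("unknown marker: ", marker_id)
  col <- m[, marker_id]
  col <- col[col != "-"]
  if (length(col) == 0) stop("all calls missing at marker ", marker_id)
  tab <- sort(table(col), decreasing = TRUE)
  f <- as.numeric(tab) / length(col)
  names(f) <- names(tab)
  attr(f, "n") <- length(col)
  f
}

check_freqs <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  invisible(freqs)
}

#' Polymorphism information content, simple form
#'
#' `PIC = 1 - sum(p_j^2)` over the pattern frequencies of a marker (this
#' equals the Gini-Simpson diversity of the pattern distribution).
#'
#' @param freqs numeric frequency vector summing to 1
#' @return value in `[0, 1)`.
#' @export
pic_simple <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Polymorphism information content, Botstein form
#'
#' `PIC = 1 - sum(p_j^2) - sum_{j<k} 2 p_j^2 p_k^2` (Botstein et al.
#' 1980), the expected informativeness of a marker for linkage accounting
#' for matings between like heterozygotes. Always less than or equal to
#' the simple form, with equality only for a monomorphic marker. For a
#' biallelic marker this form is strictly decreasing in the major-pattern
#' frequency on (0.5, 1], so a panel's PIC range endpoints are attained
#' by the loci with the most extreme major-pattern frequencies.
#'
#' @inheritParams pic_simple
#' @return value in `[0, 1)`.
#' @export
pic_botstein <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)  # (sum p^2)^2 - sum p^4 = 2 * sum_{j<k} p_j^2 p_k^2
}

#' Per-locus statistics table
#'
#' One row per marker: number of patterns, major-pattern frequency, both
#' PIC forms, and the missing-call count.
#'
#' @param m genotype matrix
#' @return data.frame with columns `marker_id`, `n_patterns`,
#'   `major_freq`, `pic_simple`, `pic_botstein`, `missing_count`.
#' @export
locus_stats <- function(m) {
  validate_genotype_matrix(m)
  rows <- lapply(colnames(m), function(mk) {
    f <- pattern_frequencies(m, mk)
    data.frame(marker_id = mk, n_patterns = length(f),
               major_freq = f[[1]], pic_simple = pic_simple(f),
               pic_botstein = pic_botstein(f),
               missing_count = sum(m[, mk] == "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean pairwise marker difference
#'
#' Mean Hamming count over all unordered accession pairs; markers where
#' either profile is missing are excluded from that pair's count.
#'
#' @param m genotype matrix with at least 2 accessions
#' @return mean number of differing markers per pair.
#' @export
mean_pairwise_difference <- function(m) {
  validate_genotype_matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 accessions")
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- m[i, ] != "-" & m[j, ] != "-"
    tot <- tot + sum(m[i, use] != m[j, use])
    np <- np + 1L
  }
  tot / np
}

#' Panel discrimination power
#'
#' Counts distinct marker profiles and the fraction of unordered
#' accession pairs separated by at least one marker; pairs with identical
#' profiles are listed by accession id.
#'
#' @param m genotype matrix
#' @return list: `unique_profile_count`, `resolved_pair_fraction`,
#'   `unresolved_pairs` (data.frame accession_1/accession_2).
#' @export
discrimination_power <- function(m) {
  validate_genotype_matrix(m)
  prof <- apply(m, 1, paste, collapse = "")
  n <- nrow(m)
  unres <- data.frame(accession_1 = character(),
                      accession_2 = character())
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (prof[i] == prof[j])
        unres <- rbind(unres, data.frame(accession_1 = rownames(m)[i],
                                         accession_2 = rownames(m)[j]))
  }
  npairs <- n * (n - 1) / 2
  list(unique_profile_count = length(unique(prof)),
       resolved_pair_fraction = if (npairs == 0) NA_real_ else
         1 - nrow(unres) / npairs,
       unresolved_pairs = unres)
}

#' Panel-level summary statistics
#'
#' Aggregates per-locus statistics and panel discrimination: mean PIC
#' (unweighted over loci, in the chosen form), the PIC range and the loci
#' attaining it, unique-profile count, resolved-pair fraction, mean
#' pairwise marker difference, and each accession's difference from the
#' reference profile (all-`a` by construction).
#'
#' @param m genotype matrix
#' @param pic_variant `"botstein"` (default; matches the convention of
#'   published InDel panel statistics) or `"simple"`
#' @return object of class `panel_stats`.
#' @export
panel_summary <- function(m, pic_variant = c("botstein", "simple")) {
  pic_variant <- match.arg(pic_variant)
  validate_genotype_matrix(m)
  ls <- locus_stats(m)
  pic <- if (pic_variant == "botstein") ls$pic_botstein else ls$pic_simple
  dp <- discrimination_power(m)
  ref_diff <- apply(m, 1, function(p) sum(p != "a" & p != "-"))
  structure(list(
    locus_stats = ls,
    pic_variant = pic_variant,
    mean_pic = mean(pic),
    pic_range = range(pic),
    pic_range_markers = ls$marker_id[c(which.min(pic), which.max(pic))],
    unique_profile_count = dp$unique_profile_count,
    resolved_pair_fraction = dp$resolved_pair_fraction,
    unresolved_pairs = dp$unresolved_pairs,
    mean_pairwise_difference = if (nrow(m) >= 2)
      mean_pairwise_difference(m) else NA_real_,
    reference_difference = ref_diff,
    n_accessions = nrow(m), n_markers = ncol(m)),
    class = "panel_stats")
}

#' @export
print.panel_stats <- function(x, ...) {
  cat(sprintf("Marker panel: %d markers x %d accessions\n",
              x$n_markers, x$n_accessions))
  cat(sprintf("  mean PIC (%s): %.4f  range: %.4f (%s) - %.4f (%s)\n",
              x$pic_variant, x$mean_pic, x$pic_range[1],
              x$pic_range_markers[1], x$pic_range[2],
              x$pic_range_markers[2]))
  cat(sprintf("  major-pattern frequency range: %.4f - %.4f\n",
              min(x$locus_stats$major_freq),
              max(x$locus_stats$major_freq)))
  cat(sprintf("  unique profiles: %d / %d  resolved pairs: %.3f\n",
              x$unique_profile_count, x$n_accessions,
              x$resolved_pair_fraction))
  cat(sprintf("  mean pairwise difference: %.2f markers;",
              x$mean_pairwise_difference),
      sprintf("mean difference vs reference: %.2f\n",
              mean(x$reference_difference)))
  invisible(x)
}

#' @export
summary.panel_stats <- function(object, ...) {
  print(object)
  invisible(object$locus_stats)
}

#' Write the per-locus statistics TSV
#'
#' Mirrors a published locus-statistics supplementary table: marker id,
#' major-pattern frequency and PIC, rounded to 4 decimals.
#'
#' @param ps a `panel_stats` object
#' @param path output TSV path
#' @export
write_locus_stats <- function(ps, path) {
  stopifnot(inherits(ps, "panel_stats"))
  ls <- ps$locus_stats
  out <- data.frame(marker_id = ls$marker_id,
                    major_allele_frequency = round(ls$major_freq, 4),
                    pic_simple = round(ls$pic_simple, 4),
                    pic_botstein = round(ls$pic_botstein, 4),
                    missing = ls$missing_count)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
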