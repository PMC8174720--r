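#' Configuration for the synthetic germplasm-panel generator
#'
#' Defaults emulate the structure of a crop germplasm resequencing study:
#' 73 accessions typed at 50 biallelic InDel markers of 10-20 bp, PCR
#' amplicons of 150-231 bp, heterozygous calls at about 10% of
#' non-reference genotypes, and per-locus major-pattern frequencies drawn
#' from 0.55-0.99.
#'
#' @param n_accessions accessions in the panel (default 73)
#' @param n_markers markers planted to pass every selection rule
#'   (default 50)
#' @param n_decoy_variants decoy variants, each violating at least one
#'   selection rule (default 500)
#' @param het_probability probability that a non-reference genotype is
#'   heterozygous (default 0.10); planted marker loci themselves carry no
#'   heterozygote (they must pass the homozygous-panel rule), decoys and
#'   generic variant sets do
#' @param major_freq_range range the per-locus major-pattern frequency is
#'   drawn from (default `c(0.55, 0.99)`)
#' @param indel_length_range absolute indel length range in bp for
#'   planted markers (default `c(10, 20)`)
#' @param amplicon_range amplicon size window in bp (default
#'   `c(150, 231)`)
#' @param fragment_length reference fragment length per marker region in
#'   bp (default 400)
#' @param primer_length primer length in nt (default 20)
#' @param rng_seed integer seed; the same seed reproduces every emitted
#'   file byte-identically
#' @return list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_accessions = 73L, n_markers = 50L,
                                   n_decoy_variants = 500L,
                                   het_probability = 0.10,
                                   major_freq_range = c(0.55, 0.99),
                                   indel_length_range = c(10L, 20L),
                                   amplicon_range = c(150L, 231L),
                                   fragment_length = 400L,
                                   primer_length = 20L,
                                   rng_seed = 1L) {
  stopifnot(n_accessions >= 2, n_markers >= 1,
            het_probability >= 0, het_probability <= 1,
            diff(major_freq_range) >= 0, major_freq_range[1] >= 0.5,
            major_freq_range[2] <= 1,
            indel_length_range[1] >= 1,
            diff(indel_length_range) >= 0,
            amplicon_range[1] <= amplicon_range[2])
  if (amplicon_range[1] < 2 * primer_length + indel_length_range[2] + 2)
    stop("infeasible config: minimum amplicon shorter than primers + indel")
  if (fragment_length < amplicon_range[2] + 20)
    stop("infeasible config: fragment too short for the amplicon window")
  structure(list(n_accessions = as.integer(n_accessions),
                 n_markers = as.integer(n_markers),
                 n_decoy_variants = as.integer(n_decoy_variants),
                 het_probability = het_probability,
                 major_freq_range = major_freq_range,
                 indel_length_range = as.integer(indel_length_range),
                 amplicon_range = as.integer(amplicon_range),
                 fragment_length = as.integer(fragment_length),
                 primer_length = as.integer(primer_length),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_panel_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

default_accession_ids <- function(n) sprintf("HLB%04d", 1000L + seq_len(n))

## Draw homozygous genotypes for one planted locus: dosage 0 with the
## major-pattern probability, else 2; guaranteed polymorphic.
.planted_genotypes <- function(n, p_major) {
  g <- ifelse(stats::runif(n) < p_major, 0L, 2L)
  if (all(g == 0L)) g[sample.int(n, 1)] <- 2L
  if (all(g == 2L)) g[sample.int(n, 1)] <- 0L
  g
}

#' Generate a synthetic germplasm panel bundle
#'
#' Emits, into `dir`, the full set of files the pipeline consumes:
#' `reference.fasta` (one fragment per primer-carrying locus plus a decoy
#' contig), `variants.vcf` (multi-sample VCF of planted markers and
#' decoys), `primers.tsv`, `genotypes.csv` (a/b call matrix over the
#' planted markers), and `truth.json` (the planted truth: indel lengths,
#' amplicon sizes, target and realized major-pattern frequencies, decoy
#' classes). Each planted marker carries an InDel inside a primer-flanked
#' amplicon within the configured window and homozygous polymorphic panel
#' genotypes, so it survives the whole selection chain. Each decoy
#' violates exactly one rule, cycling over four classes: out-of-range
#' length, heterozygous panel call, monomorphic, and amplicon outside the
#' size window (the last class gets its own fragment and primer pair so
#' that only the amplicon filter can remove it).
#'
#' @param cfg a [synthetic_panel_config]
#' @param dir output directory (created if needed)
#' @return invisible list: file `paths` and the `truth` list.
#' @export
generate_panel <- function(cfg = synthetic_panel_config(),
                           dir = tempfile("synthpanel")) {
  stopifnot(inherits(cfg, "synthetic_panel_config"))
  set.seed(cfg$rng_seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- default_accession_ids(cfg$n_accessions)
  pl <- cfg$primer_length
  amin <- cfg$amplicon_range[1]; amax <- cfg$amplicon_range[2]

  frag_seqs <- character(); frag_names <- character()
  var_rows <- list(); gen_rows <- list(); primer_rows <- list()
  truth_markers <- list()

  plant_locus <- function(name, s, out_of_window = FALSE) {
    ## s: signed indel length (alt - ref). Reference fragment carries the
    ## ref allele. Returns a list describing the planted locus.
    if (out_of_window) {
      ## amplicon size outside the window on at least one allele
      A <- if (stats::runif(1) < 0.5)
        sample(seq(2 * pl + abs(s) + 2, amin - 1L), 1) else
        sample(seq(amax + 1L, amax + 30L), 1)
    } else {
      lo <- max(amin, amin - s); hi <- min(amax, amax - s)
      A <- sample(seq(lo, hi), 1)
    }
    flen <- max(cfg$fragment_length, A + 40L)
    frag <- rand_dna(flen)
    off <- sample.int(flen - A + 1L, 1)        # amplicon start, 1-based
    fwd <- substr(frag, off, off + pl - 1L)
    rev_site <- substr(frag, off + A - pl, off + A - 1L)
    rev <- revcomp(rev_site)
    ## indel anchor strictly between the primer footprints
    lo_p <- off + pl
    hi_p <- off + A - pl - 1L - max(0L, -s) - 1L
    p <- sample(seq(lo_p, hi_p), 1)
    if (s < 0) {  # deletion: fragment carries the long (ref) allele
      ref_allele <- substr(frag, p, p - s)     # 1 + |s| bases
      alt_allele <- substr(frag, p, p)
    } else {     # insertion
      ref_allele <- substr(frag, p, p)
      alt_allele <- paste0(ref_allele, rand_dna(s))
    }
    list(frag = frag, name = name, A = A, fwd = fwd, rev = rev, pos = p,
         ref = ref_allele, alt = alt_allele)
  }

  ## ---- planted markers -------------------------------------------------
  for (i in seq_len(cfg$n_markers)) {
    s <- sample(c(-1L, 1L), 1) *
      sample(seq(cfg$indel_length_range[1], cfg$indel_length_range[2]), 1)
    name <- sprintf("MK%03d", i)
    loc <- plant_locus(paste0(name, "_frag"), s)
    p_major <- stats::runif(1, cfg$major_freq_range[1],
                            cfg$major_freq_range[2])
    g <- .planted_genotypes(cfg$n_accessions, p_major)
    frag_names <- c(frag_names, loc$name)
    frag_seqs <- c(frag_seqs, loc$frag)
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      id = name, chrom = loc$name, pos = loc$pos, ref = loc$ref,
      alt = loc$alt, stringsAsFactors = FALSE)
    gen_rows[[length(gen_rows) + 1L]] <- g
    primer_rows[[length(primer_rows) + 1L]] <- data.frame(
      marker_id = name, forward = loc$fwd, reverse = loc$rev,
      chrom = loc$name, pos = loc$pos, stringsAsFactors = FALSE)
    truth_markers[[name]] <- list(
      marker_id = name, chrom = loc$name, pos = loc$pos,
      indel_length = s, ref_amplicon_bp = loc$A,
      alt_amplicon_bp = loc$A + s, target_major_freq = p_major,
      realized_major_freq = mean(g == 0L),
      genotypes = stats::setNames(call_from_zygosity(
        ZYGOSITY_LEVELS[g + 1L]), acc))
  }

  ## ---- decoys ----------------------------------------------------------
  decoy_classes <- character(cfg$n_decoy_variants)
  if (cfg$n_decoy_variants > 0) {
    decoy_contig <- rand_dna(max(2000L,
                                 60L * cfg$n_decoy_variants + 100L))
    frag_names <- c(frag_names, "decoy_contig")
    frag_seqs <- c(frag_seqs, decoy_contig)
    classes <- c("length", "heterozygous_in_panel", "not_polymorphic",
                 "amplicon_window")
    for (k in seq_len(cfg$n_decoy_variants)) {
      cls <- classes[(k - 1L) %% 4L + 1L]
      decoy_classes[k] <- cls
      name <- sprintf("DC%04d", k)
      good_len <- sample(c(-1L, 1L), 1) *
        sample(seq(cfg$indel_length_range[1],
                   cfg$indel_length_range[2]), 1)
      if (cls == "amplicon_window") {
        loc <- plant_locus(paste0(name, "_frag"), good_len,
                           out_of_window = TRUE)
        g <- .planted_genotypes(cfg$n_accessions, 0.7)
        frag_names <- c(frag_names, loc$name)
        frag_seqs <- c(frag_seqs, loc$frag)
        primer_rows[[length(primer_rows) + 1L]] <- data.frame(
          marker_id = name, forward = loc$fwd, reverse = loc$rev,
          chrom = loc$name, pos = loc$pos, stringsAsFactors = FALSE)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          id = name, chrom = loc$name, pos = loc$pos, ref = loc$ref,
          alt = loc$alt, stringsAsFactors = FALSE)
        gen_rows[[length(gen_rows) + 1L]] <- g
        next
      }
      ## VCF-only decoys live on the decoy contig
      s <- switch(cls,
        length = {
          short <- cfg$indel_length_range[1] > 1L
          if (short && stats::runif(1) < 0.7)
            sample(c(-1L, 1L), 1) *
              sample.int(cfg$indel_length_range[1] - 1L, 1)
          else sample(c(-1L, 1L), 1) *
            (cfg$indel_length_range[2] + sample.int(10L, 1))
        },
        good_len)
      p <- 60L * k
      if (s < 0) {
        ref_allele <- substr(decoy_contig, p, p - s)
        alt_allele <- substr(decoy_contig, p, p)
      } else {
        ref_allele <- substr(decoy_contig, p, p)
        alt_allele <- paste0(ref_allele, rand_dna(s))
      }
      g <- switch(cls,
        heterozygous_in_panel = {
          gg <- .planted_genotypes(cfg$n_accessions, 0.7)
          gg[sample.int(cfg$n_accessions,
                        max(1L, round(cfg$het_probability *
                                        cfg$n_accessions)))] <- 1L
          gg
        },
        not_polymorphic = rep(2L, cfg$n_accessions),
        .planted_genotypes(cfg$n_accessions, 0.7))
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        id = name, chrom = "decoy_contig", pos = p, ref = ref_allele,
        alt = alt_allele, stringsAsFactors = FALSE)
      gen_rows[[length(gen_rows) + 1L]] <- g
    }
  }

  variants <- do.call(rbind, var_rows)
  geno <- do.call(rbind, gen_rows)
  colnames(geno) <- acc
  ord <- order(variants$chrom, variants$pos)
  x <- indel_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])

  paths <- list(fasta = file.path(dir, "reference.fasta"),
                vcf = file.path(dir, "variants.vcf"),
                primers = file.path(dir, "primers.tsv"),
                genotypes = file.path(dir, "genotypes.csv"),
                truth = file.path(dir, "truth.json"))
  seqs <- Biostrings::DNAStringSet(stats::setNames(frag_seqs, frag_names))
  Biostrings::writeXStringSet(seqs, paths$fasta)
  write_variants(x, paths$vcf)
  primers <- do.call(rbind, primer_rows)
  utils::write.table(primers, paths$primers, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  gm <- do.call(cbind, lapply(truth_markers,
                              function(t) unname(t$genotypes)))
  rownames(gm) <- acc
  colnames(gm) <- names(truth_markers)
  write_genotype_matrix(gm, paths$genotypes)

  truth <- list(config = unclass(cfg),
                accessions = acc,
                planted_marker_ids = names(truth_markers),
                markers = truth_markers,
                decoy_ids = if (cfg$n_decoy_variants > 0)
                  sprintf("DC%04d", seq_len(cfg$n_decoy_variants)) else
                  character(),
                decoy_classes = decoy_classes)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, variants = x,
                 genotype_matrix = gm))
}

#' Generate a genotype matrix with planted pattern frequencies
#'
#' In `"sample"` mode each cell is independently the major pattern `a`
#' with the locus frequency; the minor share splits between `b` and `h`
#' with `het_probability` going to `h`. In `"exact"` mode exactly
#' `round(p * n)` accessions carry `a` (seeded random placement), which
#' reproduces printed count-based frequencies such as 41/73 = 0.5616
#' exactly.
#'
#' @param freqs numeric vector of per-locus major-pattern frequencies in
#'   `[0.5, 1]`
#' @param n_accessions number of accessions (default 73)
#' @param rng_seed integer seed
#' @param mode `"sample"` or `"exact"`
#' @param het_probability fraction of the minor share called
#'   heterozygous (default 0)
#' @param marker_ids optional marker labels (default `TB1..TBn`)
#' @return genotype matrix with attribute `truth` (the planted
#'   frequencies).
#' @export
generate_matrix <- function(freqs, n_accessions = 73L, rng_seed = 1L,
                            mode = c("sample", "exact"),
                            het_probability = 0,
                            marker_ids = NULL) {
  mode <- match.arg(mode)
  if (any(freqs < 0.5 | freqs > 1))
    stop("major-pattern frequencies must lie in [0.5, 1]")
  set.seed(rng_seed)
  n <- as.integer(n_accessions)
  L <- length(freqs)
  if (is.null(marker_ids)) marker_ids <- paste0("TB", seq_len(L))
  m <- matrix("a", n, L,
              dimnames = list(default_accession_ids(n), marker_ids))
  for (l in seq_len(L)) {
    if (mode == "exact") {
      k <- as.integer(round(freqs[l] * n))
      minor_idx <- sample.int(n)[seq_len(n - k)]
    } else {
      minor_idx <- which(stats::runif(n) >= freqs[l])
    }
    if (length(minor_idx)) {
      sym <- ifelse(stats::runif(length(minor_idx)) < het_probability,
                    "h", "b")
      m[minor_idx, l] <- sym
    }
  }
  attr(m, "truth") <- list(freqs = freqs, mode = mode,
                           het_probability = het_probability,
                           rng_seed = rng_seed)
  m
}

#' Generate a generic set of InDel variants
#'
#' A lighter-weight generator (no files, no primers) for testing zygosity
#' accounting and length spectra at scale: each variant gets a signed
#' length drawn so that `short_fraction` of variants are at most
#' `short_max` bp, and each accession's genotype is reference with
#' probability `ref_probability`, otherwise heterozygous with probability
#' `het_probability` and homozygous-alternate otherwise.
#'
#' @param n_variants number of variants
#' @param n_accessions number of accessions
#' @param het_probability P(het | non-reference) (default 0.10)
#' @param ref_probability P(genotype = ref/ref) (default 0.3)
#' @param short_fraction fraction of variants with `|length| <=
#'   short_max` (default 0.8)
#' @param short_max boundary of the short class in bp (default 4)
#' @param max_len maximum absolute length in bp (default 20)
#' @param rng_seed integer seed
#' @return an [indel_set].
#' @export
generate_variants <- function(n_variants, n_accessions = 26L,
                              het_probability = 0.10,
                              ref_probability = 0.3,
                              short_fraction = 0.8, short_max = 4L,
                              max_len = 20L, rng_seed = 1L) {
  set.seed(rng_seed)
  n <- as.integer(n_variants)
  acc <- default_accession_ids(n_accessions)
  short <- stats::runif(n) < short_fraction
  alen <- ifelse(short, sample.int(short_max, n, replace = TRUE),
                 sample(seq(short_max + 1L, max_len), n, replace = TRUE))
  s <- ifelse(stats::runif(n) < 0.5, -1L, 1L) * alen
  anchor <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ref <- ifelse(s < 0, paste0(anchor, vapply(abs(s), rand_dna, "")),
                anchor)
  alt <- ifelse(s < 0, anchor,
                paste0(anchor, vapply(abs(s), rand_dna, "")))
  variants <- data.frame(id = sprintf("V%05d", seq_len(n)),
                         chrom = "chr1", pos = 100L * seq_len(n),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  u <- matrix(stats::runif(n * n_accessions), n, n_accessions)
  v <- matrix(stats::runif(n * n_accessions), n, n_accessions)
  g <- ifelse(u < ref_probability, 0L,
              ifelse(v < het_probability, 1L, 2L))
  colnames(g) <- acc
  indel_set(variants, g)
}
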