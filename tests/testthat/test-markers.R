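test_that("filter chain applies length, zygosity and polymorphism rules in order", {
  # six candidates: +3 (too short); +12 all-HOM_ALT (monomorphic);
  # -11 polymorphic homozygous; +15 with one HET; +25 (too long);
  # -10 polymorphic homozygous
  long <- function(k) paste0("A", paste(rep("T", k), collapse = ""))
  alleles <- list(c("A", long(3)), c("A", long(12)), c(long(11), "A"),
                  c("A", long(15)), c("A", long(25)), c(long(10), "A"))
  d <- rbind(c(0L, 2L, 2L), c(2L, 2L, 2L), c(0L, 2L, 2L),
             c(0L, 1L, 2L), c(0L, 2L, 2L), c(2L, 0L, 2L))
  x <- toy_indel_set(alleles, d, ids = paste0("c", 1:6))
  out <- filter_candidates(x)
  expect_setequal(out$variants$id, c("c3", "c6"))
  log <- attr(out, "filter_log")
  expect_equal(log$survivors, c(6L, 4L, 3L, 2L))
  rej <- attr(out, "rejections")
  expect_equal(rej$rule[rej$id == "c1"], "length")
  expect_equal(rej$rule[rej$id == "c2"], "not_polymorphic")
  expect_equal(rej$rule[rej$id == "c4"], "heterozygous_in_panel")
  # empty input passes through
  empty <- indel_set(x$variants[0, ], x$geno[0, , drop = FALSE])
  expect_equal(nrow(filter_candidates(empty)$variants), 0)
})

test_that("filter outcome is a conjunction: stage order cannot change survivors", {
  x <- generate_variants(400, n_accessions = 6, rng_seed = 17,
                         short_fraction = 0.5)
  cfg <- selection_config()
  out <- filter_candidates(x, cfg = cfg)
  # independent predicate evaluation, no staging
  lens <- abs(indel_length(x))
  g <- x$geno
  keep <- lens >= cfg$min_abs_len & lens <= cfg$max_abs_len &
    rowSums(g == 1L, na.rm = TRUE) == 0 &
    rowSums(g == 2L, na.rm = TRUE) > 0 &
    rowSums(g == 0L, na.rm = TRUE) > 0
  expect_setequal(out$variants$id, x$variants$id[keep])
})

test_that("epcr finds a constructed amplicon of the expected size", {
  set.seed(101)
  f <- random_dna(10)
  r <- random_dna(10)
  template <- paste0("GGGGG", f, random_dna(25), rc(r), "GGGGG")
  hits <- epcr(f, r, template, max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length, 45)
  expect_equal(hits$start, 6)
  # primers absent -> no product
  expect_equal(nrow(epcr("ACGTACGTACGTACG", "TTTTAAAACCCCGGG",
                         template)), 0)
})

test_that("epcr equals the brute-force all-positions oracle on random templates", {
  set.seed(13)
  for (rep in 1:60) {
    template <- random_dna(sample(60:160, 1))
    mm <- sample(0:2, 1)
    if (runif(1) < 0.5) {
      # plant a real site (possibly with mismatches elsewhere)
      i <- sample.int(nchar(template) - 45, 1)
      f <- substr(template, i, i + 14)
      r <- rc(substr(template, i + 30, i + 44))
    } else {
      f <- random_dna(15); r <- random_dna(15)
    }
    got <- epcr(f, r, template, max_mismatch = mm)
    exp <- epcr_oracle(f, r, template, max_mismatch = mm)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("raising the mismatch allowance never loses predictions", {
  set.seed(23)
  for (rep in 1:20) {
    template <- random_dna(120)
    i <- sample.int(60, 1)
    f <- substr(template, i, i + 14)
    r <- rc(substr(template, i + 40, i + 54))
    n0 <- nrow(epcr(f, r, template, 0))
    n1 <- nrow(epcr(f, r, template, 1))
    n2 <- nrow(epcr(f, r, template, 2))
    expect_true(n0 <= n1 && n1 <= n2)
  }
})

test_that("allele amplicon sizes differ by exactly the indel length", {
  set.seed(31)
  # 180-bp reference amplicon spanning an 11-bp deletion -> (180, 169)
  build <- function(amp_len, s) {
    flank <- random_dna(20)
    inner <- random_dna(amp_len - 40)
    template <- paste0(flank, random_dna(20), inner, random_dna(20),
                       random_dna(15))
    f <- substr(template, 21, 40)
    rev <- rc(substr(template, 20 + amp_len - 19, 20 + amp_len))
    pos <- 61
    if (s < 0) {
      ref_a <- substr(template, pos, pos - s); alt_a <- substr(template,
                                                               pos, pos)
    } else {
      ref_a <- substr(template, pos, pos)
      alt_a <- paste0(ref_a, random_dna(s))
    }
    list(template = template, f = f, r = rev, pos = pos, ref = ref_a,
         alt = alt_a)
  }
  del <- build(180, -11)
  expect_equal(unname(predict_allele_amplicons(
    del$template, del$pos, del$ref, del$alt, del$f, del$r)), c(180, 169))
  ins <- build(170, +10)
  expect_equal(unname(predict_allele_amplicons(
    ins$template, ins$pos, ins$ref, ins$alt, ins$f, ins$r)), c(170, 180))
  # conservation: |ref - alt| = |indel length| over random constructions
  for (rep in 1:25) {
    s <- sample(c(-1, 1), 1) * sample(10:20, 1)
    amp <- sample(160:220, 1)
    cc <- build(amp, s)
    sizes <- predict_allele_amplicons(cc$template, cc$pos, cc$ref,
                                      cc$alt, cc$f, cc$r)
    expect_equal(abs(sizes[["ref"]] - sizes[["alt"]]), abs(s))
  }
})

test_that("an indel outside the amplicon is rejected", {
  set.seed(41)
  template <- random_dna(250)
  f <- substr(template, 21, 40)
  r <- rc(substr(template, 161, 180))
  # indel planted downstream of the reverse primer
  expect_error(predict_allele_amplicons(
    template, 200, substr(template, 200, 211), substr(template, 200, 200),
    f, r, marker_id = "TBX"), "outside the predicted amplicon")
  # and primers with no site at all
  expect_error(predict_allele_amplicons(
    template, 50, substr(template, 50, 61), substr(template, 50, 50),
    "ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA", marker_id = "TBY"),
    "no amplicon")
})

test_that("amplicon size window keeps only fully in-range marker loci", {
  loci <- data.frame(marker_id = c("m1", "m2", "m3"),
                     ref_amplicon_bp = c(150, 145, 225),
                     alt_amplicon_bp = c(161, 156, 236))
  out <- amplicon_size_filter(loci)
  expect_equal(out$marker_id, "m1")
  expect_setequal(attr(out, "rejections"), c("m2", "m3"))
  expect_equal(nrow(amplicon_size_filter(loci[0, ])), 0)
  # survivors equal an exhaustive window check on a generated panel
  set.seed(51)
  big <- data.frame(marker_id = paste0("x", 1:200),
                    ref_amplicon_bp = sample(120:260, 200, replace = TRUE))
  big$alt_amplicon_bp <- big$ref_amplicon_bp +
    sample(c(-1, 1), 200, TRUE) * sample(10:20, 200, TRUE)
  out <- amplicon_size_filter(big)
  manual <- big$marker_id[
    pmin(big$ref_amplicon_bp, big$alt_amplicon_bp) >= 150 &
      pmax(big$ref_amplicon_bp, big$alt_amplicon_bp) <= 231]
  expect_setequal(out$marker_id, manual)
})
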