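test_that("the generator is byte-identical under a fixed seed", {
  cfg <- synthetic_panel_config(n_accessions = 8, n_markers = 4,
                                n_decoy_variants = 12, rng_seed = 7)
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  generate_panel(cfg, dir = d1)
  generate_panel(cfg, dir = d2)
  for (f in c("reference.fasta", "variants.vcf", "primers.tsv",
              "genotypes.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("every emitted VCF record round-trips and matches the truth table", {
  cfg <- synthetic_panel_config(n_accessions = 3, n_markers = 20,
                                n_decoy_variants = 0, rng_seed = 7)
  b <- generate_panel(cfg, dir = file.path(tempdir(), "gen_rt"))
  x <- read_variants(b$paths$vcf)
  expect_equal(nrow(x$variants), 20)
  expect_setequal(x$variants$id, b$truth$planted_marker_ids)
  for (mk in b$truth$planted_marker_ids) {
    info <- b$truth$markers[[mk]]
    row <- which(x$variants$id == mk)
    expect_equal(nchar(x$variants$alt[row]) - nchar(x$variants$ref[row]),
                 info$indel_length)
    got <- call_from_zygosity(
      vapply(accessions(x), function(a)
        as.character(classify_zygosity(x, a)[row]), ""))
    expect_equal(unname(got), unname(unlist(info$genotypes)))
  }
})

test_that("planted markers pass and decoys fail the selection chain, by rule", {
  cfg <- synthetic_panel_config(n_accessions = 12, n_markers = 10,
                                n_decoy_variants = 40, rng_seed = 21)
  b <- generate_panel(cfg, dir = file.path(tempdir(), "gen_funnel"))
  x <- read_variants(b$paths$vcf)
  surv <- filter_candidates(x)
  primers <- read_primers(b$paths$primers)
  ref <- Biostrings::readDNAStringSet(b$paths$fasta)
  names(ref) <- sub(" .*", "", names(ref))
  panel <- build_marker_panel(surv, primers, ref, relabel = FALSE)
  expect_setequal(panel$marker_id, b$truth$planted_marker_ids)
  # every decoy is rejected and attributed to its planted violation class
  rej <- attr(surv, "rejections")
  classes <- setNames(b$truth$decoy_classes, b$truth$decoy_ids)
  vcf_stage <- classes[classes != "amplicon_window"]
  expect_setequal(rej$id, names(vcf_stage))
  expect_equal(unname(classes[rej$id]), rej$rule)
  amp_decoys <- names(classes)[classes == "amplicon_window"]
  expect_true(all(amp_decoys %in% attr(panel, "rejections")))
})

test_that("exact-count matrices hit printed count frequencies, sampling mode recovers them", {
  m <- generate_matrix(c(41 / 73, 72 / 73), n_accessions = 73,
                       rng_seed = 5, mode = "exact")
  f1 <- pattern_frequencies(m, "TB1")
  f2 <- pattern_frequencies(m, "TB2")
  expect_equal(unname(f1[[1]]), 41 / 73)
  expect_equal(unname(f2[[1]]), 72 / 73)
  expect_equal(round(unname(f1[[1]]), 4), 0.5616)
  expect_equal(round(unname(f2[[1]]), 4), 0.9863)
  # frequencies of 1 give an all-'a' matrix with zero information
  m1 <- generate_matrix(c(1, 1), n_accessions = 10, rng_seed = 1,
                        mode = "exact")
  expect_true(all(m1 == "a"))
  expect_equal(panel_summary(m1)$mean_pic, 0)
  # sampling mode: estimator recovery within the 3-sigma binomial bound
  ms <- generate_matrix(0.7, n_accessions = 1000, rng_seed = 5,
                        mode = "sample")
  phat <- mean(ms[, 1] == "a")
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
})

test_that("panel genotype frequencies track their drawn targets", {
  cfg <- synthetic_panel_config(n_accessions = 73, n_markers = 25,
                                n_decoy_variants = 0, rng_seed = 42)
  b <- generate_panel(cfg, dir = file.path(tempdir(), "gen_freq"))
  for (mk in b$truth$planted_marker_ids) {
    info <- b$truth$markers[[mk]]
    p <- info$target_major_freq
    emp <- mean(unlist(info$genotypes) == "a")
    expect_lte(abs(emp - p), 3 * sqrt(p * (1 - p) / 73) + 2 / 73)
  }
  # the genotype CSV is consistent with the truth table
  m <- read_genotype_matrix(b$paths$genotypes)
  expect_equal(unname(m[, "MK001"]),
               unname(unlist(b$truth$markers$MK001$genotypes)))
})

test_that("het_probability zero yields no heterozygous call anywhere", {
  x <- generate_variants(500, n_accessions = 6, het_probability = 0,
                         rng_seed = 9)
  zc <- zygosity_counts(x)
  expect_true(all(zc$het == 0))
  expect_true(all(zc$het_rate == 0))
})

test_that("infeasible generator configurations are rejected up front", {
  expect_error(synthetic_panel_config(amplicon_range = c(40, 60)),
               "infeasible")
  expect_error(synthetic_panel_config(fragment_length = 100),
               "infeasible")
  expect_error(generate_matrix(0.3), "\\[0.5, 1\\]")
})

test_that("pipeline closure: simulate, select, type, summarize without manual input", {
  cfg <- synthetic_panel_config(n_accessions = 20, n_markers = 8,
                                n_decoy_variants = 20, rng_seed = 15)
  b <- generate_panel(cfg, dir = file.path(tempdir(), "gen_pipe"))
  x <- read_variants(b$paths$vcf)
  surv <- filter_candidates(x)
  primers <- read_primers(b$paths$primers)
  ref <- Biostrings::readDNAStringSet(b$paths$fasta)
  names(ref) <- sub(" .*", "", names(ref))
  panel <- build_marker_panel(surv, primers, ref)
  expect_equal(nrow(panel), 8)
  expect_equal(panel$marker_id, paste0("TB", 1:8))
  expect_equal(abs(panel$ref_amplicon_bp - panel$alt_amplicon_bp),
               abs(panel$indel_length))
  m <- genotype_calls(x, marker_ids = panel$source_id,
                      marker_labels = panel$marker_id)
  ps <- panel_summary(m)
  expect_equal(ps$n_markers, 8)
  expect_true(ps$mean_pic > 0 && ps$mean_pic < 0.5)
  d <- simple_matching_distance(m)
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, rownames(m))
})
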