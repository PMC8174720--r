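test_that("simple-matching distance reflects marker differences", {
  p <- rep("a", 50)
  q <- p; q[1:7] <- "b"
  m <- rbind(A = p, B = q, C = ifelse(p == "a", "b", "a"))
  colnames(m) <- paste0("TB", 1:50)
  d <- simple_matching_distance(m)
  expect_equal(d["A", "A"], 0)
  expect_equal(d["A", "B"], 0.14)
  expect_equal(d["A", "C"], 1.0)
  expect_equal(d, t(d))
  # a pair with no comparable marker is an error naming the pair
  m2 <- rbind(X = c("a", "-"), Y = c("-", "b"))
  colnames(m2) <- c("TB1", "TB2")
  expect_error(simple_matching_distance(m2), "X / Y")
})

test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "not symmetric")
})

test_that("NJ recovers additive trees exactly, topology and lengths", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n, br = runif)
    true$edge.length <- true$edge.length + 0.05  # keep branches positive
    d <- ape::cophenetic.phylo(true)
    d <- d[order(rownames(d)), order(colnames(d))]
    tr <- nj_tree(d)
    # exact topology: RF distance 0 to the generating tree
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(true), tr)), 0)
    # exact lengths: path distances on the NJ tree equal the input
    dd <- ape::cophenetic.phylo(tr)
    dd <- dd[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-6)
    expect_equal(attr(tr, "negative_branch_deficit"), 0)
  }
})

test_that("NJ topology agrees with the ape reference on random matrices", {
  set.seed(47)
  for (rep in 1:50) {
    n <- 8
    x <- matrix(runif(n * 6), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("T", 1:n), paste0("T", 1:n))
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(phangorn::RF.dist(mine, ape::unroot(ref))), 0)
  }
})

test_that("newick serialization round-trips", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- to_newick(nj_tree(d3))
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(grepl("A:1", nwk) && grepl("C:3", nwk))
  # 2-leaf cherry edge case
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_match(to_newick(nj_tree(d2)), "^\\(A:0\\.15,B:0\\.15\\);$")
  set.seed(53)
  for (rep in 1:60) {
    tr <- ape::rtree(sample(4:10, 1))
    back <- ape::read.tree(text = to_newick(tr))
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr),
                                              ape::unroot(back))), 0)
    expect_setequal(back$tip.label, tr$tip.label)
  }
})

test_that("accession order only permutes NJ labels, not the topology", {
  set.seed(59)
  m <- generate_matrix(runif(30, 0.55, 0.9), n_accessions = 10,
                       rng_seed = 61, mode = "sample")
  d <- simple_matching_distance(m)
  perm <- sample(nrow(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(phangorn::RF.dist(t1, t2)), 0)
})

test_that("PCA coordinates behave on degenerate and random matrices", {
  # identical accessions land on identical coordinates
  m <- gm_from_strings(c(a1 = "abab", a2 = "abab", a3 = "babb"))
  pc <- pca_coordinates(m, 2)
  expect_equal(pc$coordinates[1, -1], pc$coordinates[2, -1],
               ignore_attr = TRUE)
  # a single variable locus puts all variance on PC1
  m1 <- gm_from_strings(c(a1 = "aaaa", a2 = "aaab", a3 = "aaab"))
  pc1 <- pca_coordinates(m1, 2)
  expect_equal(pc1$explained_variance[1], 1.0)
  expect_error(pca_coordinates(m1, 5), "fewer accessions")
})

test_that("PCA matches a dense eigensolver up to sign", {
  set.seed(67)
  for (rep in 1:5) {
    m <- generate_matrix(runif(50, 0.55, 0.95), n_accessions = 20,
                         rng_seed = rep + 100, mode = "sample",
                         het_probability = 0.1)
    pc <- pca_coordinates(m, 3)
    num <- matrix(0, nrow(m), ncol(m))
    num[m == "b"] <- 1; num[m == "h"] <- 0.5
    xc <- scale(num, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(xc) / (nrow(m) - 1), symmetric = TRUE)
    for (k in 1:3) {
      ref <- xc %*% ev$vectors[, k]
      got <- pc$coordinates[[k + 1]]
      expect_equal(abs(got), abs(as.numeric(ref)), tolerance = 1e-8)
      expect_equal(pc$explained_variance[k],
                   ev$values[k] / sum(ev$values), tolerance = 1e-8)
    }
  }
})

test_that("STRUCTURE export writes two allele rows per accession", {
  m <- gm_from_strings(c(a1 = "ab", a2 = "h-"))
  path <- file.path(tempdir(), "structure.txt")
  write_structure(m, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)
  expect_equal(lines[1], "a1 1 2")
  expect_equal(lines[2], "a1 1 2")
  expect_equal(lines[3], "a2 1 -9")
  expect_equal(lines[4], "a2 2 -9")
})
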