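#' Simple-matching distance matrix
#'
#' Pairwise `d(i, j) = 1 - homology(i, j)`: the fraction of compared
#' markers at which two accessions differ. Missing calls are handled per
#' [homology()]; a pair with no comparable marker is an error naming the
#' pair. The simple-matching distance is bounded in `[0, 1]` but need not
#' satisfy the triangle inequality.
#'
#' @param m genotype matrix with >= 2 accessions
#' @param missing_policy passed to [homology()]
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   accession id.
#' @export
simple_matching_distance <- function(m,
                                     missing_policy = c("exclude",
                                                        "strict")) {
  missing_policy <- match.arg(missing_policy)
  validate_genotype_matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 accessions")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- tryCatch(homology(m[i, ], m[j, ], missing_policy),
                  error = function(e)
                    stop("pair ", rownames(m)[i], " / ", rownames(m)[j],
                         ": ", conditionMessage(e), call. = FALSE))
    d[i, j] <- d[j, i] <- 1 - as.numeric(h)
  }
  d
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler
#' Q-criterion `Q(i,j) = (r - 2) d(i,j) - R_i - R_j`. Ties in Q (within
#' 1e-12 relative tolerance) are broken deterministically by the
#' lexicographically smallest sorted label pair. Negative branch lengths
#' are clamped to zero and the total clamped deficit is recorded in the
#' `negative_branch_deficit` attribute. The input need not satisfy the
#' triangle inequality; on an additive distance matrix the generating
#' tree is recovered exactly.
#'
#' @param d symmetric numeric matrix (or `dist`) with labels and zero
#'   diagonal; at least 2 taxa (>= 3 for an unrooted topology)
#' @return an [ape::phylo] tree (unrooted for >= 3 taxa), with attributes
#'   `method = "canonical_nj"` and `negative_branch_deficit`.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix or dist")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 taxa")
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt_bl(clamp(d[1, 2] / 2)),
                   labels[2], fmt_bl(clamp(d[1, 2] / 2)))
    tr <- ape::read.tree(text = nwk)
    attr(tr, "method") <- "canonical_nj"
    attr(tr, "negative_branch_deficit") <- deficit
    return(tr)
  }
  ## active clusters: newick fragments + smallest contained label for
  ## tie-breaking
  sub <- labels
  minlab <- labels
  D <- d
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt_bl(li),
                      sub[j], fmt_bl(lj))
    newmin <- min(minlab[i], minlab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    minlab <- c(minlab[keep], newmin)
    dimnames(D2) <- NULL
    D <- D2
  }
  ## final three clusters join at the central node
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt_bl(l1),
                 sub[2], fmt_bl(l2), sub[3], fmt_bl(l3))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "method") <- "canonical_nj"
  attr(tr, "negative_branch_deficit") <- deficit
  tr
}

#' Serialize a tree to newick
#'
#' Standard newick with branch lengths at 6 significant digits;
#' `ape::read.tree()` on the output reproduces the tree.
#'
#' @param tree an `ape::phylo` object
#' @param digits significant digits for branch lengths (default 6)
#' @return single newick string.
#' @export
to_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Principal component coordinates of a genotype matrix
#'
#' Codes calls as alternate-allele dosage fractions (`a` = 0, `b` = 1,
#' `h` = 0.5), mean-imputes missing calls per locus, centers columns, and
#' computes the principal components of the accession x locus matrix.
#' Each component's sign is fixed so its largest-magnitude locus loading
#' is positive, making coordinates reproducible across eigensolvers.
#'
#' @param m genotype matrix
#' @param n_components number of components to return (default 2); must
#'   not exceed the number of accessions
#' @return list: `coordinates` (data.frame, accession + PC columns),
#'   `explained_variance` (fraction of total variance per returned
#'   component), `loadings` (locus x component matrix).
#' @export
pca_coordinates <- function(m, n_components = 2L) {
  validate_genotype_matrix(m)
  if (n_components > nrow(m))
    stop("fewer accessions (", nrow(m), ") than requested components (",
         n_components, ")")
  num <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  num[m == "a"] <- 0; num[m == "b"] <- 1; num[m == "h"] <- 0.5
  for (k in seq_len(ncol(num))) {
    mis <- is.na(num[, k])
    if (all(mis)) stop("all calls missing at marker ", colnames(m)[k])
    if (any(mis)) num[mis, k] <- mean(num[!mis, k])
  }
  pc <- stats::prcomp(num, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (c_ in seq_len(k)) {
    top <- which.max(abs(load[, c_]))
    if (load[top, c_] < 0) {
      load[, c_] <- -load[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  total_var <- sum(pc$sdev^2)
  expl <- if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else
    rep(0, k)
  coords <- data.frame(accession = rownames(m), scores,
                       check.names = FALSE, stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  list(coordinates = coords, explained_variance = expl, loadings = load)
}

#' Export a genotype matrix in STRUCTURE format
#'
#' Two rows per accession (one allele per row): `a` -> 1/1, `b` -> 2/2,
#' `h` -> 1/2, missing -> -9/-9; first column is the accession id.
#'
#' @param m genotype matrix
#' @param path output path (whitespace-delimited text)
#' @return `path`, invisibly.
#' @export
write_structure <- function(m, path) {
  validate_genotype_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  a1 <- c(a = 1L, b = 2L, h = 1L, `-` = -9L)
  a2 <- c(a = 1L, b = 2L, h = 2L, `-` = -9L)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], a1[m[i, ]]), collapse = " "), con)
    writeLines(paste(c(rownames(m)[i], a2[m[i, ]]), collapse = " "), con)
  }
  invisible(path)
}

#' Write a labelled square distance matrix as CSV
#'
#' @param d labelled symmetric matrix (e.g. from
#'   [simple_matching_distance()])
#' @param path output CSV path
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(data.frame(accession = rownames(d), d,
                              check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
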