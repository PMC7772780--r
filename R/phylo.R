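#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned FASTA (protein or nucleotide; gaps as `-` or `.`).
#' @return named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  aln <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment taxa must be uniquely named")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must all have the same length")
  invisible(aln)
}

.aln_matrix <- function(aln) {
  validate_alignment(aln)
  do.call(rbind, strsplit(toupper(aln), ""))
}

#' Pairwise p-distances from an alignment
#'
#' For each taxon pair, the proportion of mismatching sites over the columns
#' where neither row has a gap. An optional Poisson correction
#' `-ln(1 - p)` accounts for multiple substitutions per site.
#'
#' @param aln named character vector of aligned sequences (see
#'   [read_alignment()]).
#' @param correction "none" (raw p-distance, default) or "poisson".
#' @return symmetric distance matrix with zero diagonal, dimnames = taxa.
#' @export
p_distance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("p_distance requires at least 2 taxa")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp))
      stop("zero comparable sites between ", names(aln)[i], " and ",
           names(aln)[j])
    p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    if (correction == "poisson") {
      if (p >= 1) stop("p-distance of 1 cannot be Poisson-corrected")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, assign branch lengths, and reduce the matrix; the final three
#' lineages are resolved by the closed-form three-taxon formulas, yielding an
#' unrooted tree. Q-criterion ties are broken toward the lexicographically
#' first taxon pair (each internal node is represented by its alphabetically
#' first descendant taxon), and negative branch lengths are clamped to zero
#' with the deficit transferred to the sister branch so path lengths are
#' preserved.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("nj_tree requires at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must carry taxon names")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  taxa <- rownames(dm)
  nwk <- taxa                 # newick fragment per active node
  rep_lab <- taxa             # tie-break representative: min contained taxon
  D <- dm
  while (length(nwk) > 3L) {
    k <- nrow(D)
    R <- rowSums(D)
    Q <- (k - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], li, nwk[j], lj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    dimnames(D2) <- list(seq_along(nwk), seq_along(nwk))
    D <- D2
  }
  dxy <- D[1L, 2L]; dxz <- D[1L, 3L]; dyz <- D[2L, 3L]
  lx <- max((dxy + dxz - dyz) / 2, 0)
  ly <- max((dxy + dyz - dxz) / 2, 0)
  lz <- max((dxz + dyz - dxy) / 2, 0)
  s <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
               nwk[1L], lx, nwk[2L], ly, nwk[3L], lz)
  ape::read.tree(text = s)
}

#' Canonical bipartitions (splits) of an unrooted tree
#'
#' Each internal edge partitions the taxa in two; the split is keyed by the
#' sorted labels of the side not containing the alphabetically first taxon,
#' making keys invariant to rooting and taxon input order. Trivial splits
#' (one side smaller than 2) are dropped.
#'
#' @param tree an `ape::phylo` tree.
#' @return character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(clade) .split_key(tree$tip.label[clade],
                                                tree$tip.label), "")
  unique(keys[!is.na(keys)])
}

.split_key <- function(side, all_taxa) {
  ref <- min(all_taxa)
  if (ref %in% side) side <- setdiff(all_taxa, side)
  if (length(side) < 2L || length(side) > length(all_taxa) - 2L)
    return(NA_character_)
  paste(sort(side), collapse = "|")
}

#' Bootstrap split support for a neighbor-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `B` times, rebuilds a tree per pseudoreplicate,
#' and labels each internal node of the original tree with the percentage of
#' replicates containing its split.
#'
#' @param aln named character vector of aligned sequences.
#' @param B number of pseudoreplicates (default 100).
#' @param seed integer seed for column resampling.
#' @param correction distance correction, passed to [p_distance()].
#' @return the original NJ tree with bootstrap percentages (0-100) as
#'   internal node labels (the root label is empty).
#' @export
bootstrap_support <- function(aln, B = 100L, seed = 1L,
                              correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (B < 1L) stop("B must be >= 1")
  validate_alignment(aln)
  tree <- nj_tree(p_distance(aln, correction))
  L <- nchar(aln[[1L]])
  m <- .aln_matrix(aln)
  rep_splits <- with_seed(seed, {
    lapply(seq_len(B), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      tree_splits(nj_tree(p_distance(stats::setNames(res, names(aln)),
                                     correction)))
    })
  })
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- vapply(seq_along(pp), function(k) {
    key <- .split_key(tree$tip.label[pp[[k]]], tree$tip.label)
    if (is.na(key)) return("")
    sup <- 100 * mean(vapply(rep_splits, function(s) key %in% s, TRUE))
    format(sup)
  }, "")
  tree$node.label <- labels
  tree
}
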