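test_that("p-distance counts mismatches over gap-free columns", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance(c(a = "A-CG", b = "AACG"))["a", "b"], 0)
  expect_error(p_distance(c(a = "--A", b = "A--")), "comparable")
})

test_that("p-distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    aln <- setNames(vapply(seq_len(n), function(j) random_dna(40), ""),
                    LETTERS[seq_len(n)])
    d <- p_distance(aln)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, n))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("the Poisson correction expands distances monotonically", {
  aln <- c(a = "AAAATTTT", b = "AAAATTTA", c = "ACGTACGT")
  raw <- p_distance(aln)
  cor <- p_distance(aln, correction = "poisson")
  off <- upper.tri(raw)
  expect_true(all(cor[off] >= raw[off]))
  expect_equal(cor["a", "b"], -log(1 - raw["a", "b"]))
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "at least 3")
  bad <- dm; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers additive four-taxon trees to numerical precision", {
  # tree ((A:1,B:2):0.5,C:1.5,D:2.5) gives an additive distance matrix
  taxa <- c("A", "B", "C", "D")
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 3    # 1 + 0.5 + 1.5
  dm["A", "D"] <- dm["D", "A"] <- 4
  dm["B", "C"] <- dm["C", "B"] <- 4
  dm["B", "D"] <- dm["D", "B"] <- 5
  dm["C", "D"] <- dm["D", "C"] <- 4
  tr <- nj_tree(dm)
  expect_setequal(tree_splits(tr), "C|D")   # the A,B | C,D bipartition
  pd <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(pd, dm, tolerance = 1e-9)
})

test_that("Q-criterion ties join the lexicographically first taxon pair", {
  taxa <- c("A", "B", "C", "D")
  dm <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  diag(dm) <- 0
  tr <- nj_tree(dm)   # fully tied: deterministic (A,B) cherry expected
  expect_true("C|D" %in% tree_splits(tr))
})

test_that("NJ recovers random additive topologies generated by ape", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      tip.label = sample(LETTERS, n))
    ref$edge.length <- runif(length(ref$edge.length), 0.05, 1)
    dm <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(dm[sort(rownames(dm)), sort(rownames(dm))])
    expect_setequal(tree_splits(tr), tree_splits(ref))
  }
})

test_that("bootstrap supports are deterministic, bounded and order-free", {
  set.seed(61)
  aln <- setNames(c(paste0(strrep("A", 30), random_dna(20)),
                    paste0(strrep("A", 30), random_dna(20)),
                    paste0(strrep("C", 30), random_dna(20)),
                    paste0(strrep("C", 30), random_dna(20)),
                    paste0(strrep("G", 30), random_dna(20))),
                  c("t1", "t2", "t3", "t4", "t5"))
  b1 <- bootstrap_support(aln, B = 50, seed = 9)
  b2 <- bootstrap_support(aln, B = 50, seed = 9)
  expect_equal(to_newick(b1), to_newick(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  perm <- aln[c(3, 1, 5, 2, 4)]
  b3 <- bootstrap_support(perm, B = 50, seed = 9)
  lab1 <- setNames(b1$node.label, vapply(ape::prop.part(b1), function(p)
    paste(sort(b1$tip.label[p]), collapse = "|"), ""))
  lab3 <- setNames(b3$node.label, vapply(ape::prop.part(b3), function(p)
    paste(sort(b3$tip.label[p]), collapse = "|"), ""))
  shared <- intersect(names(lab1), names(lab3))
  expect_true(length(shared) >= 1)
  expect_equal(lab1[shared], lab3[shared])
  expect_error(bootstrap_support(aln, B = 0), "B must be")
})

test_that("a perfectly congruent alignment yields full support", {
  aln <- c(A = strrep("A", 12), B = strrep("A", 12),
           C = strrep("C", 12), D = strrep("C", 12))
  bt <- bootstrap_support(aln, B = 40, seed = 3)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_equal(sup[!is.na(sup)], 100)
})
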