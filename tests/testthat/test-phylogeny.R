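test_that("p-distances follow the mismatch/compared-columns definition", {
  s <- random_dna(100, seed = 1)
  ## 3 substitutions over 100 columns -> 0.03
  v <- strsplit(s, "")[[1]]
  w <- v
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  for (p in c(10, 50, 90)) w[p] <- flip(w[p])
  panel <- tiny_panel(c(s, s), c(paste(w, collapse = ""), paste(w, collapse = "")))
  dm <- distance_matrix(panel)
  expect_equal(unname(dm["Rf1", "Rf2"]), 0)
  expect_equal(unname(dm["Rf1", "Wf1"]), 0.03)
  expect_true(isSymmetric(unclass(dm)))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("neighbor joining recovers additive 4-taxon trees with exact lengths", {
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj_tree(dm)
  ## split AB|CD and tree distances reproduce the matrix (additivity)
  ct <- ape::cophenetic.phylo(tr)
  expect_equal(ct[rownames(dm), colnames(dm)], dm, tolerance = 1e-9,
               ignore_attr = TRUE)
  sp <- check_group_split(tr, c(A = "Rf", B = "Rf", C = "Wf", D = "Wf"))
  expect_true(sp$split)
  ## enumerated alternative additive matrices: AC|BD and AD|BC topologies
  make_quartet <- function(pairs) {
    ## leaves a,b on one side; internal edge length 2; pendant lengths 1..4
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    pl <- c(A = 1, B = 2, C = 3, D = 4)
    same <- function(x, y) (x %in% pairs[[1]] && y %in% pairs[[1]]) ||
                           (x %in% pairs[[2]] && y %in% pairs[[2]])
    for (x in LETTERS[1:4]) for (y in LETTERS[1:4]) {
      if (x == y) next
      d[x, y] <- pl[x] + pl[y] + if (same(x, y)) 0 else 2
    }
    d
  }
  for (pp in list(list(c("A", "C"), c("B", "D")),
                  list(c("A", "D"), c("B", "C")),
                  list(c("A", "B"), c("C", "D")))) {
    d <- make_quartet(pp)
    tr <- build_nj_tree(d)
    ct <- ape::cophenetic.phylo(tr)
    expect_equal(ct[LETTERS[1:4], LETTERS[1:4]], d, tolerance = 1e-9,
                 ignore_attr = TRUE)
    groups <- setNames(rep("Wf", 4), LETTERS[1:4])
    groups[pp[[1]]] <- "Rf"
    expect_true(check_group_split(tr, groups)$split)
  }
})

test_that("three taxa resolve with closed-form branch lengths", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(dm)
  ct <- ape::cophenetic.phylo(tr)
  expect_equal(ct[rownames(dm), colnames(dm)], dm, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("taxon input order does not change the recovered topology", {
  panel <- fixture_panel(2)
  dm <- distance_matrix(panel)
  tr1 <- suppressWarnings(build_nj_tree(dm))   # clone pairs -> tiny negative edges, clamped
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  tr2 <- suppressWarnings(build_nj_tree(dm[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("group split detection distinguishes clean and interleaved trees", {
  t1 <- ape::read.tree(text = "((Rf1:1,Rf2:1):1,(Wf1:1,Wf2:1):1);")
  t2 <- ape::read.tree(text = "((Rf1:1,Wf1:1):1,(Rf2:1,Wf2:1):1);")
  g <- c(Rf1 = "Rf", Rf2 = "Rf", Wf1 = "Wf", Wf2 = "Wf")
  expect_true(check_group_split(t1, g)$split)
  expect_false(check_group_split(t2, g)$split)
  expect_error(check_group_split(t1, g[1:3]), "label")
})

test_that("synthetic panels separate by flesh-color group", {
  for (seed in c(1, 6, 13)) {
    panel <- fixture_panel(seed)
    phy <- suppressWarnings(allele_phylogeny(panel))  # clamped NJ edges expected
    ## diagnostic variants dominate: within-group closer than between-group
    dm <- phy$distances
    grp <- setNames(panel$allele_info$group, panel$allele_info$allele_id)
    within <- c(); between <- c()
    ids <- rownames(dm)
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      if (grp[ids[i]] == grp[ids[j]]) within <- c(within, dm[i, j])
      else between <- c(between, dm[i, j])
    }
    expect_lt(mean(within), mean(between))
    expect_true(phy$split$split, info = paste("seed", seed))
  }
})
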