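test_that("p and JC69 distances follow their closed forms", {
  r1 <- paste(rep("A", 100), collapse = "")
  r2 <- paste(c(rep("A", 97), "C", "G", "U"), collapse = "")
  d <- distance_matrix(c(a = r1, b = r2), model = "p")
  expect_equal(d["a", "b"], 0.03)
  expect_equal(d["a", "a"], 0)

  dj <- distance_matrix(c(a = r1, b = r2), model = "jc69")
  expect_equal(dj["a", "b"], -0.75 * log(1 - 4 * 0.03 / 3),
               tolerance = 1e-12)
  expect_equal(dj["a", "b"], 0.0306165, tolerance = 1e-6)

  same <- distance_matrix(c(a = r1, b = r1), model = "jc69")
  expect_equal(same["a", "b"], 0)
})

test_that("distances agree with ape::dist.dna on random alignments", {
  withr::local_seed(420)
  strip <- function(m) {
    attr(m, "model") <- NULL
    unname(m)
  }
  for (i in 1:10) {
    n <- sample(3:6, 1)
    len <- 60
    # family diverged from a common ancestor, well below saturation
    anc <- strsplit(random_rna(len), "")[[1]]
    rows <- setNames(vapply(seq_len(n), function(k) {
      ch <- anc
      at <- sample(len, 9)
      ch[at] <- vapply(ch[at], function(b) {
        sample(setdiff(c("A", "C", "G", "U"), b), 1)
      }, character(1))
      paste(ch, collapse = "")
    }, character(1)), paste0("t", seq_len(n)))
    mat <- do.call(rbind, lapply(rows, function(s) {
      tolower(gsub("U", "t", strsplit(s, "")[[1]]))
    }))
    bin <- ape::as.DNAbin(mat)
    expect_equal(strip(distance_matrix(rows, "p")),
                 unname(as.matrix(ape::dist.dna(bin, model = "raw"))),
                 tolerance = 1e-12)
    expect_equal(strip(distance_matrix(rows, "jc69")),
                 unname(as.matrix(ape::dist.dna(bin, model = "JC69"))),
                 tolerance = 1e-12)
  }
})

test_that("gap handling compares only mutually occupied columns", {
  rows <- c(a = "ACGUACGU", b = "ACG-ACGG", c = "--GUACGU")
  d <- distance_matrix(rows, model = "p")
  expect_equal(d["a", "b"], 1 / 7)   # 7 shared columns, 1 mismatch
  expect_equal(d["a", "c"], 0)       # 6 shared columns, identical
  dc <- distance_matrix(rows, model = "p", deletion = "complete")
  expect_equal(dc["a", "b"], 1 / 5)  # columns 3,5,6,7,8 remain
})

test_that("saturated divergence is flagged under JC69", {
  r1 <- paste(rep(c("A", "C", "G", "U"), 10), collapse = "")
  r2 <- paste(rep(c("C", "G", "U", "A"), 10), collapse = "")
  d <- distance_matrix(c(a = r1, b = r2), model = "jc69")
  expect_true(is.infinite(d["a", "b"]))
  expect_error(distance_matrix(c(a = r1, b = r2), model = "jc69",
                               strict = TRUE), "jc69 undefined")
  expect_true(all(distance_matrix(c(a = r1, b = r2), model = "p") <= 1))
})

test_that("jc69 dominates p elementwise where finite", {
  withr::local_seed(421)
  rows <- setNames(vapply(1:5, function(k) random_rna(80), character(1)),
                   paste0("t", 1:5))
  dp <- distance_matrix(rows, "p")
  dj <- distance_matrix(rows, "jc69")
  finite <- is.finite(dj)
  expect_true(all(dj[finite] >= dp[finite]))
})

test_that("NJ recovers a known additive 4-taxon tree", {
  # leaf edges a=2, b=3, c=4, d=5; internal edge 1
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("a", "b", "c", "d")))
  tr <- nj_tree(d)
  expect_equal(unname(stats::cophenetic(tr)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-9)
  # a and b are siblings in the recovered topology
  rep <- patristic_report(tr, "a")
  expect_equal(rep$leaf[2], "b")
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ reproduces patristic distances of random additive trees", {
  withr::local_seed(422)
  for (i in 1:30) {
    k <- sample(4:8, 1)
    tr <- ape::rtree(k, br = function(n) runif(n, 0.1, 2))
    d <- stats::cophenetic(tr)
    back <- nj_tree(d)
    expect_equal(unname(stats::cophenetic(back)[rownames(d), colnames(d)]),
                 unname(d), tolerance = 1e-9, info = paste("tree", i))
  }
})

test_that("patristic reports sum branch lengths along tree paths", {
  t2 <- read_newick("(A:1,B:2);")
  rep <- patristic_report(t2, "A")
  expect_equal(rep$distance[rep$leaf == "A"], 0)
  expect_equal(rep$distance[rep$leaf == "B"], 3)

  t3 <- read_newick("((A:1,B:1):1,C:2);")
  rep3 <- patristic_report(t3, "A")
  expect_equal(rep3$distance[rep3$leaf == "C"], 4)
  expect_equal(rep3$distance[rep3$leaf == "B"], 2)
  expect_error(patristic_report(t3, "Z"), "unknown leaf")
})

test_that("patristic distances satisfy metric axioms on random trees", {
  withr::local_seed(423)
  for (i in 1:10) {
    tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 1))
    dm <- stats::cophenetic(tr)
    expect_true(all(abs(dm - t(dm)) < 1e-12))
    expect_true(all(diag(dm) == 0))
    for (a in 1:6) for (b in 1:6) for (c in 1:6) {
      expect_lte(dm[a, b], dm[a, c] + dm[c, b] + 1e-9)
    }
  }
})

test_that("alignment-to-report pipeline runs end to end", {
  a <- make_alignment(6, seed = 13, divergence = 0.2)
  d <- distance_matrix(a, model = "jc69")
  tr <- nj_tree(d)
  rep <- patristic_report(tr, "fam_001")
  expect_equal(nrow(rep), 6)
  expect_equal(rep$distance[1], 0)
  expect_true(all(rep$distance >= 0))
})
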