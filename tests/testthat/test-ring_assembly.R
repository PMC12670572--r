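cross_pair_panel <- data.frame(name = c("A/i", "I/a"),
                               rh = c("AGGA", "UCCU"),
                               lh = c("AGGA", "UCCU"))

test_that("pairing graph edges follow the loop-pairing rules", {
  g1 <- build_pairing_graph(data.frame(name = "A/a", rh = "GGAC",
                                       lh = "GUCC"))
  expect_true(g1$adjacency["A/a", "A/a"])  # self-complementary

  g2 <- build_pairing_graph(cross_pair_panel)
  expect_true(g2$adjacency["A/i", "I/a"])
  expect_true(g2$adjacency["I/a", "A/i"])
  expect_false(g2$adjacency["A/i", "A/i"])
  expect_false(g2$adjacency["I/a", "I/a"])

  g3 <- build_pairing_graph(cross_pair_panel[1, ])
  expect_false(any(g3$adjacency))

  expect_error(build_pairing_graph(
    data.frame(name = c("x", "x"), rh = "GG", lh = "CC")), "duplicate")
})

test_that("feasible ring sizes are closed-walk lengths", {
  g2 <- build_pairing_graph(cross_pair_panel)
  expect_equal(feasible_ring_sizes(g2, max_n = 12),
               c(2L, 4L, 6L, 8L, 10L, 12L))

  tri <- make_loop_panel("cross_triplet", seed = 1)
  g3 <- build_pairing_graph(tri$species[, c("name", "rh", "lh")])
  expect_equal(feasible_ring_sizes(g3, max_n = 12), c(3L, 6L, 9L, 12L))

  gs <- build_pairing_graph(data.frame(name = "S", rh = "GGAC",
                                       lh = "GUCC"))
  expect_equal(feasible_ring_sizes(gs, max_n = 5), 1:5)
})

test_that("walk lengths agree with explicit enumeration on small graphs", {
  withr::local_seed(408)
  fake_graph <- function(adj) {
    structure(list(species = NULL, adjacency = adj),
              class = "pairing_graph")
  }
  for (i in 1:20) {
    k <- sample(2:3, 1)
    adj <- matrix(runif(k * k) < 0.4, k, k)
    sizes <- feasible_ring_sizes(fake_graph(adj), max_n = 8)
    for (n in 1:8) {
      expect_equal(n %in% sizes, walk_oracle(adj, n),
                   info = paste("n =", n))
    }
  }
  # single directed p-cycles give exactly the multiples of p
  for (p in 2:5) {
    adj <- matrix(FALSE, p, p)
    for (u in seq_len(p)) adj[u, (u %% p) + 1L] <- TRUE
    expect_equal(feasible_ring_sizes(fake_graph(adj), max_n = 12),
                 seq(p, 12, by = p))
  }
})

test_that("hexamer verdicts reproduce the complementation experiments", {
  v1 <- hexamer_verdict(cross_pair_panel[1, ])
  expect_false(v1$hexamer_active)
  expect_true(is.na(v1$minimal_cycle))

  v2 <- hexamer_verdict(cross_pair_panel)
  expect_true(v2$hexamer_active)
  expect_equal(v2$minimal_cycle, 2L)

  tri <- make_loop_panel("cross_triplet", seed = 1)
  v3 <- hexamer_verdict(tri$species[, c("name", "rh", "lh")])
  expect_true(v3$hexamer_active)
  expect_equal(v3$minimal_cycle, 3L)
  for (k in 1:3) {
    expect_false(hexamer_verdict(
      tri$species[k, c("name", "rh", "lh")])$hexamer_active)
  }
})

test_that("adding a non-pairing species never changes feasible sizes", {
  tri <- make_loop_panel("cross_triplet", seed = 3)
  panel <- tri$species[, c("name", "rh", "lh")]
  before <- feasible_ring_sizes(build_pairing_graph(panel))
  panel2 <- rbind(panel, data.frame(name = "inert", rh = "AAAA",
                                    lh = "AAAA"))
  expect_equal(feasible_ring_sizes(build_pairing_graph(panel2)), before)
})

test_that("hexamer verdict agrees with exhaustive 6-ring enumeration", {
  withr::local_seed(409)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    panel <- data.frame(
      name = paste0("s", seq_len(k)),
      rh = vapply(seq_len(k), function(j) random_rna(4), character(1)),
      lh = vapply(seq_len(k), function(j) random_rna(4), character(1)))
    g <- build_pairing_graph(panel)
    v <- hexamer_verdict(panel)
    # enumerate every length-6 species sequence and test ring closure
    combos <- expand.grid(rep(list(seq_len(k)), 6))
    closed <- apply(combos, 1, function(w) {
      all(g$adjacency[cbind(w, c(w[-1], w[1]))])
    })
    expect_equal(v$hexamer_active, any(closed), info = paste("panel", i))
  }
})

test_that("smallest_common_ring recovers the hexamer from 2+3 periods", {
  tri <- make_loop_panel("cross_triplet", seed = 1)
  expect_equal(smallest_common_ring(list(
    cross_pair_panel, tri$species[, c("name", "rh", "lh")])), 6L)

  expect_equal(smallest_common_ring(list(
    data.frame(name = "S", rh = "GGAC", lh = "GUCC"))), 1L)

  # find a panel of four loop species realizing a pure 4-cycle, then
  # check the common ring of a period-2 and a period-4 mixture
  withr::local_seed(410)
  want4 <- matrix(FALSE, 4, 4)
  for (u in 1:4) want4[u, (u %% 4) + 1L] <- TRUE
  panel4 <- NULL
  for (t in 1:5000) {
    rh <- vapply(1:4, function(j) random_rna(4), character(1))
    lh <- vapply(rh[c(4, 1, 2, 3)], rna_revcomp, character(1),
                 USE.NAMES = FALSE)
    cand <- data.frame(name = paste0("q", 1:4), rh = rh, lh = lh)
    if (identical(unname(build_pairing_graph(cand)$adjacency), want4)) {
      panel4 <- cand
      break
    }
  }
  expect_false(is.null(panel4))
  expect_equal(feasible_ring_sizes(build_pairing_graph(panel4)),
               c(4L, 8L, 12L))
  expect_equal(smallest_common_ring(list(cross_pair_panel, panel4)), 4L)
  expect_error(smallest_common_ring(list(cross_pair_panel), max_n = 1),
               "no feasible|no common")
})
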