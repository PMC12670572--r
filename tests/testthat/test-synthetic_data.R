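test_that("generator outputs are deterministic given the seed", {
  p1 <- sample_prna(seed = 5)
  p2 <- sample_prna(seed = 5)
  expect_identical(p1$record$residues, p2$record$residues)
  expect_identical(p1$structure$pairs, p2$structure$pairs)

  d1 <- diverge(p1, 0.3, seed = 8)
  d2 <- diverge(p1, 0.3, seed = 8)
  expect_identical(d1$record$residues, d2$record$residues)

  g1 <- plant_in_genome(list(p1), 1500, seed = 4)
  g2 <- plant_in_genome(list(p1), 1500, seed = 4)
  expect_identical(g1$genome$residues, g2$genome$residues)
  expect_identical(g1$truth, g2$truth)

  pl1 <- make_loop_panel(c("cross_pair", "gc_only"), seed = 6)
  pl2 <- make_loop_panel(c("cross_pair", "gc_only"), seed = 6)
  expect_identical(pl1$species, pl2$species)
})

test_that("sampled scaffolds fold back to the designed architecture", {
  for (s in c(2, 7, 12, 23, 31)) {
    p <- sample_prna(seed = s)
    folded <- fold_max_pairing(p$record)
    rep <- parse_junctions(folded)
    expect_true(rep$has_3wj, info = paste("seed", s))
    hp <- rep$hairpins
    expect_true(any(hp$start0 == p$annotation$rh_loop0[1] &
                      hp$end0 == p$annotation$rh_loop0[2]))
    expect_true(any(hp$start0 == p$annotation$lh_loop0[1] &
                      hp$end0 == p$annotation$lh_loop0[2]))
    blk <- max_complementary_block(p$annotation$rh_block,
                                   p$annotation$lh_block)
    expect_true(predict_activity(blk)$active)
    # designed helices are exact reverse complements
    pt <- p$annotation$pairs
    chars <- strsplit(p$record$residues, "")[[1]]
    for (i in which(pt > seq_along(pt))) {
      expect_equal(chars[pt[i]],
                   unname(c(A = "U", U = "A", G = "C", C = "G")[chars[i]]))
    }
  }
  # a loop shorter than the designed block is unrealizable
  expect_error(prna_scaffold(rh_loop = 3L, block_len = 4L))
})

test_that("divergence respects rate and covariation mode", {
  p <- sample_prna(seed = 3)
  expect_identical(diverge(p, 0, seed = 1)$record$residues,
                   p$record$residues)

  d <- diverge(p, 0.3, compensatory = TRUE, seed = 2)
  expect_true(prnascreen:::.validates(d))
  # designed pairs remain complementary
  pt <- p$annotation$pairs
  chars <- strsplit(d$record$residues, "")[[1]]
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (i in which(pt > seq_along(pt))) {
    expect_equal(chars[pt[i]], unname(comp[chars[i]]))
  }

  # non-compensatory divergence breaks helices in most draws
  nbroken <- 0
  for (s in 1:10) {
    dn <- diverge(p, 0.3, compensatory = FALSE, seed = s)
    chn <- strsplit(dn$record$residues, "")[[1]]
    ok <- all(vapply(which(pt > seq_along(pt)), function(i) {
      chn[pt[i]] == comp[chn[i]]
    }, logical(1)))
    if (!ok) nbroken <- nbroken + 1
  }
  expect_gt(nbroken, 5)
})

test_that("planting records truth and leaves the background intact", {
  p <- sample_prna(seed = 2)
  pg <- plant_in_genome(list(p), genome_len = 5000, seed = 6)
  expect_equal(nrow(pg$truth), 1)
  expect_equal(pg$truth$end - pg$truth$start, nchar(p$record$residues))
  expect_equal(substr(pg$genome$residues, pg$truth$start + 1,
                      pg$truth$end), p$record$residues)
  expect_equal(nchar(pg$genome$residues), 5000)

  empty <- plant_in_genome(list(), genome_len = 300, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(nchar(empty$genome$residues), 300)

  minus <- plant_in_genome(list(p), genome_len = 2000, seed = 6,
                           strand = "minus")
  expect_equal(minus$truth$strand, "-")
  expect_equal(substr(minus$genome$residues, minus$truth$start + 1,
                      minus$truth$end), rna_revcomp(p$record$residues))

  expect_error(plant_in_genome(list(p, p, p), genome_len = 150, seed = 1),
               "genome length")
})

test_that("alignments are aligned by construction with exact features", {
  a <- make_alignment(12, seed = 4)
  widths <- vapply(a$rows, function(r) nchar(r$residues), integer(1))
  expect_equal(length(unique(widths)), 1L)
  expect_equal(existence_rate(a, "Bulge1"), 100)
  expect_equal(similarity_rate(a, "Bulge1"), 0)
  expect_equal(similarity_rate(a, "Bulge3"), 0)
  expect_equal(similarity_rate(a, "critical_G"), 100)

  k_of_n <- make_alignment(10, seed = 4, occupancy = list(Bulge3 = 4))
  expect_equal(existence_rate(k_of_n, "Bulge3"), 40)

  ident <- make_alignment(2, seed = 4, divergence = 0)
  expect_equal(similarity_rate(ident, "Bulge1"), 100)
})

test_that("loop panels realize their pattern tags", {
  pl <- make_loop_panel(c("self_complementary", "cross_pair",
                          "cross_triplet", "unpaired", "gc_only",
                          "au_only"), seed = 5)
  exp <- pl$expected
  want_mix <- c(self_complementary = TRUE, cross_pair = TRUE,
                cross_triplet = TRUE, unpaired = FALSE, gc_only = TRUE,
                au_only = FALSE)
  expect_equal(exp$mixture_active, unname(want_mix[exp$tag]))
  expect_equal(exp$minimal_cycle[exp$tag == "cross_pair"], 2L)
  expect_equal(exp$minimal_cycle[exp$tag == "cross_triplet"], 3L)
  expect_false(exp$individual_active[exp$tag == "cross_pair"])
  expect_false(exp$individual_active[exp$tag == "cross_triplet"])
  expect_error(make_loop_panel("nonsense", seed = 1))
})
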