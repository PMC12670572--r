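overlaps_truth <- function(cands, truth) {
  any(vapply(cands, function(x) {
    min(x$end, truth$end) - max(x$start, truth$start) > 0
  }, logical(1)))
}

test_that("planted pRNAs are recovered at divergence 0", {
  for (s in 1:3) {
    p <- sample_prna(seed = s)
    pg <- plant_in_genome(list(p), genome_len = 2000, seed = s + 50)
    cands <- scan_genome(pg$genome,
                         template_len = nchar(p$record$residues))
    expect_true(overlaps_truth(cands, pg$truth), info = paste("seed", s))
    # every candidate re-validates against the thresholds
    cfg <- screen_config()
    for (x in cands) {
      expect_true(x$has_3wj)
      expect_lte(x$fold_score, cfg$score_threshold)
      expect_gte(x$coverage, cfg$min_coverage)
      expect_gte(x$loop_pair$length, cfg$min_block_len)
      expect_true(predict_activity(x$loop_pair)$active)
    }
  }
})

test_that("destroying LH/RH complementarity suppresses the planted hit", {
  # scan the molecule as one template-sized window, so the verdict
  # reflects the designed loops rather than background false positives
  p <- sample_prna(seed = 21)
  len <- nchar(p$record$residues)
  cfg <- screen_config(window_len = len, step = 1)
  ci <- scan_genome(p$record, template_len = len, cfg = cfg)
  expect_true(overlaps_truth(ci, data.frame(start = 0, end = len)))

  ann <- p$annotation
  chars <- strsplit(p$record$residues, "")[[1]]
  # overwrite the LH block with a copy of the RH block (one-sided change)
  chars[(ann$lh_block0[1] + 1):ann$lh_block0[2]] <-
    strsplit(ann$rh_block, "")[[1]]
  broken <- seq_record("gb", paste(chars, collapse = ""))
  cb <- scan_genome(broken, template_len = len, cfg = cfg)
  expect_false(overlaps_truth(cb, data.frame(start = 0, end = len)))
})

test_that("random genomes yield a measurable false-positive count", {
  withr::local_seed(425)
  for (s in 1:2) {
    g <- seq_record(paste0("null", s), random_rna(1000))
    cands <- scan_genome(g, template_len = 120)
    merged <- merge_candidates(cands)
    expect_gte(length(cands), length(merged))
    expect_true(is.data.frame(screen_report(cands)))
  }
})

test_that("minus-strand hits score identically to plus-strand hits", {
  p <- sample_prna(seed = 4)
  pad <- substr(paste(rep("A", 60), collapse = ""), 1,
                (120 - nchar(p$record$residues)) %/% 2)
  gplus <- seq_record("g+", paste0(pad, p$record$residues, pad, "AA"))
  gminus <- seq_record("g-", rna_revcomp(gplus$residues))
  cfg <- screen_config(window_len = nchar(gplus$residues), step = 1)
  cp <- scan_genome(gplus, template_len = nchar(gplus$residues), cfg)
  cm <- scan_genome(gminus, template_len = nchar(gplus$residues), cfg)
  sp <- screen_report(cp)
  sm <- screen_report(cm)
  expect_true(any(sp$strand == "+"))
  expect_true(any(sm$strand == "-"))
  expect_equal(sort(sp$fold_score), sort(sm$fold_score))
})

test_that("candidate merging keeps one representative per locus", {
  mk <- function(start, end, score) {
    structure(list(genome_id = "g", start = start, end = end,
                   strand = "+", fold_score = score, coverage = 1,
                   loop_pair = max_complementary_block("GGAA", "UUCC"),
                   pattern = classify_pattern(
                     max_complementary_block("GGAA", "UUCC")),
                   has_3wj = TRUE), class = "prna_candidate")
  }
  same <- merge_candidates(list(mk(0, 120, -30), mk(0, 120, -40)))
  expect_length(same, 1)
  expect_equal(same[[1]]$fold_score, -40)

  apart <- merge_candidates(list(mk(0, 120, -30), mk(500, 620, -40)))
  expect_length(apart, 2)

  chain <- merge_candidates(list(mk(0, 120, -30), mk(40, 160, -45),
                                 mk(80, 200, -35)))
  expect_length(chain, 1)
  expect_equal(chain[[1]]$start, 40)
})

test_that("screen reports round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- screen_report(list())
  expect_equal(nrow(empty), 0L)
  write_screen_tsv(empty, f)
  expect_equal(nrow(read_screen_tsv(f)), 0L)

  p <- sample_prna(seed = 2)
  pg <- plant_in_genome(list(p), genome_len = 1500, seed = 31)
  cands <- merge_candidates(scan_genome(pg$genome,
                                        nchar(p$record$residues)))
  rep <- screen_report(cands)
  expect_gte(nrow(rep), 1L)
  write_screen_tsv(rep, f)
  back <- read_screen_tsv(f)
  expect_equal(back$start, rep$start)
  expect_equal(back$end, rep$end)
  expect_equal(back$strand, rep$strand)
})

test_that("naive exact search finds exact copies on both strands", {
  p <- sample_prna(seed = 6)
  pg <- plant_in_genome(list(p), genome_len = 1500, seed = 41,
                        strand = "minus")
  hits <- naive_sequence_search(pg$genome, p$record$residues)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$start == pg$truth$start & hits$strand == "-"))
  none <- naive_sequence_search(seq_record("bg", random_rna(500)),
                                p$record$residues)
  expect_equal(nrow(none), 0L)
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  withr::local_seed(411)
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:20) {
    s <- random_rna(sample(20:80, 1))
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_equal(sort(names(dinucs(sh))), sort(names(dinucs(s))))
    expect_equal(as.integer(dinucs(sh)[names(dinucs(s))]),
                 as.integer(dinucs(s)), info = s)
    expect_equal(dinucleotide_shuffle(s, seed = i), sh)  # deterministic
  }
})

test_that("the shuffle null ranks designed structures as stable", {
  p <- sample_prna(seed = 8)
  frac <- window_score_percentile(p$record$residues, n_shuffles = 30,
                                  seed = 3)
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})
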