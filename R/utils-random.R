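# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the session RNG.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Sample one random RNA base (optionally excluding some), GC-weighted.
.sample_base <- function(n = 1L, gc = 0.5, exclude = NULL) {
  bases <- c("A", "C", "G", "U")
  w <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (!is.null(exclude)) {
    keep <- !bases %in% exclude
    bases <- bases[keep]
    w <- w[keep]
  }
  sample(bases, n, replace = TRUE, prob = w / sum(w))
}

.wc_complement <- function(b) {
  c(A = "U", U = "A", G = "C", C = "G")[b]
}
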