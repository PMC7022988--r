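# Fixtures are built in code; nothing is read from disk.

WT_CONSENSUS <- "CTGACCGATCGGTCAG"   # a perfect reverse-complement palindrome

# cassettes with the consensus embedded at a random offset in random background
make_planted_pool <- function(n = 500, consensus = WT_CONSENSUS,
                              cassette_length = 24, seed = 1) {
  set.seed(seed)
  w <- nchar(consensus)
  vapply(seq_len(n), function(i) {
    pos <- sample.int(cassette_length - w + 1L, 1)
    bg <- random_dna(cassette_length)
    paste0(substr(bg, 1, pos - 1), consensus,
           substr(bg, pos + w, cassette_length))
  }, "")
}

# pure random cassettes
make_random_pool <- function(n = 500, cassette_length = 24, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) random_dna(cassette_length), "")
}

# random Dirichlet-ish PWM
make_random_pwm <- function(width, seed = 1, conc = 1) {
  set.seed(seed)
  p <- matrix(stats::rgamma(4 * width, shape = conc), nrow = width)
  new_pwm(p / rowSums(p))
}

# point-mass PWM on a literal sequence (entries exactly 0/1)
point_mass_pwm <- function(seq) {
  codes <- dna_codes(seq)
  p <- matrix(0, nrow = length(codes), ncol = 4)
  p[cbind(seq_along(codes), codes)] <- 1
  new_pwm(p)
}

# independent brute-force oracle for match p-values: enumerate all 4^w
# sequences, score them on the model's integer grid, sum background mass of
# those scoring at least as high
brute_force_pvalues <- function(model, background, scores_int) {
  w <- model$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (i in seq_len(w)) {
    sc <- sc + model$s_int[i, grid[, i]]
    pr <- pr * background[grid[, i]]
  }
  vapply(scores_int, function(s) sum(pr[sc >= s]), 0)
}

# build an in-memory read list around given cassettes
make_reads <- function(cassettes, left, right, q = 30L) {
  seqs <- paste0(left, cassettes, right)
  list(id = sprintf("r%04d", seq_along(seqs)), sequence = seqs,
       qualities = lapply(nchar(seqs), function(L) rep(q, L)))
}
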