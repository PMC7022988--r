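#' Construct a position-weight matrix (letter-probability form)
#'
#' A PWM describes, for each position of a fixed-width motif, the probability
#' of observing each base. Rows are motif positions, columns are the bases
#' A, C, G, T. Each row must sum to one.
#'
#' @param prob numeric matrix, width x 4, rows summing to 1. Column order
#'   A, C, G, T (column names, if present, are checked).
#' @param background length-4 base probabilities of the background model
#'   (default uniform).
#' @param pseudocount pseudocount per base used when the matrix was estimated
#'   (stored for provenance; not applied here).
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(prob, background = rep(0.25, 4), pseudocount = 0) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (!is.null(colnames(prob)) && !identical(colnames(prob), DNA_BASES)) {
    prob <- prob[, DNA_BASES, drop = FALSE]
  }
  if (any(prob < 0)) stop("PWM probabilities must be non-negative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-9)) stop("each PWM position must sum to 1")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  background <- as.numeric(background)
  names(background) <- DNA_BASES
  colnames(prob) <- DNA_BASES
  rownames(prob) <- NULL
  structure(
    list(prob = prob, background = background, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM, width %d (consensus %s)\n", pwm_width(x), pwm_top_string(x)))
  print(round(x$prob, 3))
  invisible(x)
}

#' Motif width of a PWM
#' @param pwm a [new_pwm()] object.
#' @return integer width.
#' @export
pwm_width <- function(pwm) nrow(pwm$prob)

#' Most-probable-base string of a PWM
#' @param pwm a [new_pwm()] object.
#' @return single DNA string of the per-position argmax bases.
#' @export
pwm_top_string <- function(pwm) {
  paste(DNA_BASES[max.col(pwm$prob, ties.method = "first")], collapse = "")
}

#' PWM from a literal consensus sequence
#'
#' Builds a soft point-mass PWM: the consensus base gets `match_prob`, the
#' other three bases share the remainder equally.
#'
#' @param consensus DNA string.
#' @param match_prob probability of the consensus base at each position.
#' @param background background base probabilities.
#' @return a `pwm` object.
#' @export
literal_pwm <- function(consensus, match_prob = 0.7, background = rep(0.25, 4)) {
  stopifnot_dna(consensus, "consensus")
  codes <- dna_codes(toupper(consensus))
  w <- length(codes)
  prob <- matrix((1 - match_prob) / 3, nrow = w, ncol = 4)
  prob[cbind(seq_len(w), codes)] <- match_prob
  new_pwm(prob, background = background)
}

#' Impose reverse-complement (palindromic) symmetry on a PWM
#'
#' Averages each position with the complementary base of the mirror position:
#' `p'[i, b] = (p[i, b] + p[w + 1 - i, comp(b)]) / 2`. The result equals its
#' own reverse-complement matrix exactly, the appropriate shape for a site
#' bound by a homodimer. The background is symmetrized the same way so that
#' log-odds scores of a sequence and its reverse complement coincide.
#'
#' @param pwm a `pwm` object.
#' @return a palindromic `pwm` object.
#' @export
palindromize <- function(pwm) {
  p <- pwm$prob
  w <- nrow(p)
  rc <- p[rev(seq_len(w)), COMP_IDX, drop = FALSE]
  bg <- (pwm$background + pwm$background[COMP_IDX]) / 2
  out <- new_pwm((p + rc) / 2, background = bg / sum(bg),
                 pseudocount = pwm$pseudocount)
  out
}

# reverse-complement a PWM (used for minus-strand scanning)
pwm_revcomp <- function(pwm) {
  p <- unname(pwm$prob)
  new_pwm(p[rev(seq_len(nrow(p))), COMP_IDX, drop = FALSE],
          background = pwm$background, pseudocount = pwm$pseudocount)
}

#' Shannon information content of a PWM
#'
#' Per-column information in bits relative to a uniform background:
#' `ic[i] = 2 + sum_b p[i,b] * log2 p[i,b]` (0 log 0 taken as 0).
#'
#' @param pwm a `pwm` object.
#' @return list with `ic` (bits per column) and `total` (their sum).
#' @export
information_content <- function(pwm) {
  p <- pwm$prob
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + rowSums(plogp)
  list(ic = as.numeric(ic), total = sum(ic))
}

#' Consensus-notation thresholds
#'
#' Controls the mixed-case consensus string derived from a PWM: a single base
#' is written in upper case when it dominates its column; purine/pyrimidine
#' pairs become `R`/`Y` (strong) or `r`/`y` (weak); mixed pairs become
#' `(b1/b2)` ordered by frequency, upper-cased only when nearly exhaustive;
#' uninformative columns become `n`.
#'
#' @param single_base_threshold minimum top-base probability for a plain
#'   upper-case call.
#' @param pair_strong_threshold minimum top-two mass for an upper-case R/Y.
#' @param pair_weak_threshold minimum top-two mass for any pair call.
#' @param uppercase_pair_threshold minimum top-two mass for upper-case letters
#'   inside a mixed `(b1/b2)` pair.
#' @return a list of thresholds, class `consensus_notation_config`.
#' @export
consensus_notation_config <- function(single_base_threshold = 0.75,
                                      pair_strong_threshold = 0.90,
                                      pair_weak_threshold = 0.75,
                                      uppercase_pair_threshold = 0.95) {
  if (pair_weak_threshold > pair_strong_threshold) {
    stop("pair_weak_threshold must be <= pair_strong_threshold")
  }
  th <- c(single_base_threshold, pair_strong_threshold, pair_weak_threshold,
          uppercase_pair_threshold)
  if (any(th <= 0 | th > 1)) stop("thresholds must lie in (0, 1]")
  structure(list(single_base_threshold = single_base_threshold,
                 pair_strong_threshold = pair_strong_threshold,
                 pair_weak_threshold = pair_weak_threshold,
                 uppercase_pair_threshold = uppercase_pair_threshold),
            class = "consensus_notation_config")
}

#' Mixed-case consensus notation for a PWM
#'
#' @param pwm a `pwm` object.
#' @param cfg thresholds from [consensus_notation_config()].
#' @return a single consensus string, e.g. `"(a/c)Y(g/t)A..."`.
#' @export
consensus_string <- function(pwm, cfg = consensus_notation_config()) {
  p <- pwm$prob
  purines <- c("A", "G")
  out <- vapply(seq_len(nrow(p)), function(i) {
    ord <- order(p[i, ], decreasing = TRUE)
    b1 <- DNA_BASES[ord[1]]; b2 <- DNA_BASES[ord[2]]
    p1 <- p[i, ord[1]]; p12 <- p1 + p[i, ord[2]]
    if (p1 >= cfg$single_base_threshold) return(b1)
    same_class <- (b1 %in% purines) == (b2 %in% purines)
    if (same_class) {
      code <- if (b1 %in% purines) "R" else "Y"
      if (p12 >= cfg$pair_strong_threshold) return(code)
      if (p12 >= cfg$pair_weak_threshold) return(tolower(code))
      return("n")
    }
    if (p12 >= cfg$pair_weak_threshold) {
      pair <- c(b1, b2)
      if (p12 < cfg$uppercase_pair_threshold) pair <- tolower(pair)
      return(sprintf("(%s/%s)", pair[1], pair[2]))
    }
    "n"
  }, character(1))
  paste(out, collapse = "")
}

#' Number of distinct double-stranded k-mers
#'
#' Counts reverse-complement equivalence classes of DNA k-mers, i.e. the
#' number of distinct duplex sequences a randomized cassette of width k can
#' present: `(4^k + 4^(k/2)) / 2` for even k (palindromes are their own
#' partner), `4^k / 2` for odd k (no odd-length palindromes).
#'
#' @param k k-mer width in base pairs.
#' @return the count (double; exact for k <= 26).
#' @export
distinct_duplex_kmers <- function(k) {
  if (!is_scalar_number(k) || k < 1 || k != floor(k)) {
    stop("k must be a positive integer")
  }
  if (k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm a `pwm` object.
#' @param path output file.
#' @param name motif name.
#' @param nsites number of contributing sites (metadata).
#' @param evalue significance to record (metadata).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif_1", nsites = 20, evalue = 0) {
  bg <- pwm$background
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
    "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
            pwm_width(pwm), nsites, evalue),
    apply(pwm$prob, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                           r[1], r[2], r[3], r[4]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read the first motif from a MEME minimal motif file
#'
#' @param path MEME minimal format file written by [write_meme()] or the MEME
#'   suite.
#' @return a `pwm` object (rows renormalized to machine precision).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)][1:4]
  }
  mi <- grep("^letter-probability matrix", lines)
  if (!length(mi)) stop("no letter-probability matrix block in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mi[1]]))
  rows <- lines[(mi[1] + 1):(mi[1] + w)]
  prob <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  prob <- prob / rowSums(prob)
  new_pwm(prob, background = bg / sum(bg))
}
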