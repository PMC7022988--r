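#' Log-odds score of a single motif-width sequence
#'
#' `sum_i log2(p[i, seq_i] / background[seq_i])`.
#'
#' @param pwm a `pwm` object.
#' @param seq DNA string of exactly the motif width.
#' @param background optional length-4 base probabilities; defaults to the
#'   PWM's stored background.
#' @return log2 odds score.
#' @export
score_sequence <- function(pwm, seq, background = NULL) {
  if (is.null(background)) background <- pwm$background
  codes <- dna_codes(toupper(seq))
  w <- pwm_width(pwm)
  if (length(codes) != w || anyNA(codes)) {
    stop("seq must be an unambiguous DNA string of the motif width")
  }
  sum(log2(pwm$prob[cbind(seq_len(w), codes)]) - log2(background[codes]))
}

#' Integerized score model with exact background score distribution
#'
#' Rounds the per-position log2-odds scores onto a grid of `granularity` bins
#' per log2 unit, then convolves the per-column background distributions of
#' the integerized scores into the exact null distribution of the total score
#' of a random background sequence. Finer granularity tightens the gap between
#' integerized and true scores (bounded by `w / (2 * granularity)`).
#'
#' @param pwm a `pwm` object.
#' @param background length-4 base probabilities (default: PWM background).
#' @param granularity bins per log2 score unit.
#' @return a `score_model` with the integer matrix, the granularity, and the
#'   tail probabilities of the null score distribution.
#' @export
score_model <- function(pwm, background = NULL, granularity = 1000) {
  if (is.null(background)) background <- pwm$background
  background <- as.numeric(background)
  w <- pwm_width(pwm)
  s <- log2(pwm$prob) - rep(log2(background), each = w)  # true scores
  s_int <- round(s * granularity)
  mins <- apply(s_int, 1, min)
  maxs <- apply(s_int, 1, max)
  # column-wise convolution of the null distribution over integer scores
  dist <- 1
  offset <- 0                       # dist[j] = P(S = offset + j - 1)
  for (i in seq_len(w)) {
    span <- maxs[i] - mins[i]
    newdist <- numeric(length(dist) + span)
    for (b in 1:4) {
      sh <- s_int[i, b] - mins[i]
      newdist[(1 + sh):(length(dist) + sh)] <-
        newdist[(1 + sh):(length(dist) + sh)] + background[b] * dist
    }
    dist <- newdist
    offset <- offset + mins[i]
  }
  tail_p <- rev(cumsum(rev(dist)))
  structure(list(s_int = s_int, granularity = granularity, offset = offset,
                 dist = dist, tail_p = tail_p, width = w,
                 background = background),
            class = "score_model")
}

#' Exact match p-value of a score
#'
#' Probability that a random background sequence of the motif width attains an
#' integerized score at least as large as `score`. The minimum achievable
#' score has p-value 1; scores above the maximum achievable return the point
#' probability of the maximum (never 0).
#'
#' @param model a [score_model()].
#' @param score either a log2-odds score (`integer_score = FALSE`, default) or
#'   an integerized score on the model grid.
#' @param integer_score whether `score` is already on the integer grid.
#' @return p-value(s) in (0, 1].
#' @export
hit_pvalue <- function(model, score, integer_score = FALSE) {
  si <- if (integer_score) score else round(score * model$granularity)
  j <- si - model$offset + 1
  nmax <- length(model$tail_p)
  p <- numeric(length(j))
  p[j <= 1] <- 1
  over <- j > nmax
  p[over] <- model$dist[nmax]       # P(S = max), never 0
  mid <- j >= 1 & j <= nmax
  p[mid] <- model$tail_p[j[mid]]
  p
}

# integer window scores of one strand: score[j] = sum_i s_int[i, codes[j+i-1]]
strand_window_scores <- function(codes, s_int) {
  w <- nrow(s_int)
  L <- length(codes)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + s_int[i, codes[i:(i + n - 1L)]]
  }
  sc
}

#' Scan sequences on both strands with a PWM
#'
#' Scores every window of every sequence on both strands, converts scores to
#' exact match p-values via [hit_pvalue()], keeps windows with `p <=
#' p_threshold`, and attaches Benjamini-Hochberg q-values computed over the
#' emitted hit list. For a palindromic PWM the two strands of a locus score
#' identically and both strand records are emitted; set `collapse_palindromic
#' = TRUE` to keep only the plus-strand record of such duplicated loci.
#'
#' @param pwm a `pwm` object.
#' @param sequences a named character vector of DNA sequences, a
#'   [Biostrings::DNAStringSet], or the path of a FASTA file.
#' @param p_threshold match p-value cutoff (default 5.10e-6).
#' @param background `"sequence"` (0-order, estimated strand-symmetrically
#'   from the scanned sequences) or `"uniform"`, or a length-4 numeric vector.
#' @param granularity score bins per log2 unit.
#' @param collapse_palindromic drop minus-strand duplicates of two-strand
#'   ties at one locus.
#' @return data.frame of hits: `seqid`, `start`, `end` (1-based inclusive),
#'   `strand`, `score` (log2), `p`, `q`, `site_sequence` (strand-oriented).
#' @export
scan_sequences <- function(pwm, sequences, p_threshold = 5.10e-6,
                           background = "sequence", granularity = 1000,
                           collapse_palindromic = FALSE) {
  seqs <- load_sequences(sequences)
  w <- pwm_width(pwm)
  short <- nchar(seqs) < w
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than the motif width skipped")
    seqs <- seqs[!short]
  }
  if (is.numeric(background)) {
    bg <- background / sum(background)
  } else if (identical(background, "uniform")) {
    bg <- rep(0.25, 4)
  } else if (identical(background, "sequence")) {
    cnt <- tabulate(dna_codes(paste(seqs, collapse = "")), nbins = 4)
    cnt <- cnt + cnt[COMP_IDX]      # strand-symmetric 0-order background
    bg <- cnt / sum(cnt)
  } else stop("unknown background specification")

  model_f <- score_model(pwm, bg, granularity)
  model_r <- score_model(pwm_revcomp(pwm), bg, granularity)

  res <- list()
  for (nm in names(seqs)) {
    codes <- dna_codes(seqs[[nm]])
    codes[is.na(codes)] <- 0L       # ambiguous bases never match
    sc_f <- strand_window_scores_na(codes, model_f$s_int)
    sc_r <- strand_window_scores_na(codes, model_r$s_int)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sc_f else sc_r
      model <- if (strand == "+") model_f else model_r
      ok <- !is.na(sc)
      p <- rep(NA_real_, length(sc))
      p[ok] <- hit_pvalue(model, sc[ok], integer_score = TRUE)
      hit <- which(ok & p <= p_threshold)
      if (!length(hit)) next
      sitestr <- substring(seqs[[nm]], hit, hit + w - 1L)
      if (strand == "-") sitestr <- revcomp(sitestr)
      res[[length(res) + 1L]] <- data.frame(
        seqid = nm, start = hit, end = hit + w - 1L, strand = strand,
        score = sc[hit] / granularity, p = p[hit],
        site_sequence = sitestr, stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), p = numeric(0),
               site_sequence = character(0))
  if (collapse_palindromic && nrow(hits)) {
    key <- paste(hits$seqid, hits$start, hits$end)
    dupminus <- duplicated(key) & hits$strand == "-"
    hits <- hits[!dupminus, , drop = FALSE]
  }
  hits$q <- if (nrow(hits)) bh_adjust(hits$p) else numeric(0)
  hits <- hits[order(hits$p, hits$seqid, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("seqid", "start", "end", "strand", "score", "p", "q",
           "site_sequence")]
}

# window scores where windows containing ambiguous bases (code 0) become NA
strand_window_scores_na <- function(codes, s_int) {
  w <- nrow(s_int)
  L <- length(codes)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  bad <- logical(n)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n - 1L)]
    zero <- ci == 0L
    bad <- bad | zero
    ci[zero] <- 1L
    sc <- sc + s_int[i, ci]
  }
  sc[bad] <- NA_real_
  sc
}

load_sequences <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    x <- Biostrings::readDNAStringSet(sequences)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else if (methods::is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else if (is.character(sequences)) {
    seqs <- toupper(sequences)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else stop("sequences must be a FASTA path, DNAStringSet, or character")
  seqs
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Shared FDR step for motif hits and differential expression:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order (the step-up procedure, via [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Annotate motif hits relative to translation starts
#'
#' For each hit and each gene on the same sequence within `max_distance`,
#' reports the gene-oriented signed offset of the hit's 5'-most base from the
#' first base of the start codon. Offsets that would be >= 0 are shifted by +1
#' so that position 0 does not exist (the base at the start codon itself is
#' +1; the base immediately upstream is -1). `intergenic` flags hits lying
#' wholly outside every annotated gene span.
#'
#' @param hits data.frame from [scan_sequences()].
#' @param annotation data.frame with columns `gene_id`, `seqid`, `start`,
#'   `end`, `strand` and optionally `translation_start` (defaults to `start`
#'   for `+` genes, `end` for `-` genes), e.g. from [read_annotation()].
#' @param max_distance maximum |offset| (bases) for a hit-gene pairing.
#' @param convention `"five-prime"` (offset of the hit's 5'-most base in gene
#'   orientation; default) or `"proximal-edge"` (offset of the hit edge
#'   nearest the start codon).
#' @param keep_unassigned keep hits with no gene within range (gene = NA).
#' @return data.frame of annotated hits: the hit columns plus `gene`,
#'   `location`, `intergenic`.
#' @export
annotate_hits <- function(hits, annotation, max_distance = 300,
                          convention = c("five-prime", "proximal-edge"),
                          keep_unassigned = TRUE) {
  convention <- match.arg(convention)
  req <- c("gene_id", "seqid", "start", "end", "strand")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(annotation$strand %in% c("+", "-"))
  if (any(bad)) {
    stop("annotation record(s) without strand: ",
         paste(annotation$gene_id[bad], collapse = ", "))
  }
  if (is.null(annotation$translation_start)) {
    annotation$translation_start <-
      ifelse(annotation$strand == "+", annotation$start, annotation$end)
  }
  if (anyNA(annotation$translation_start)) {
    stop("annotation record(s) without translation start: ",
         paste(annotation$gene_id[is.na(annotation$translation_start)],
               collapse = ", "))
  }
  out <- list()
  for (h in seq_len(nrow(hits))) {
    hit <- hits[h, ]
    genes <- annotation[annotation$seqid == hit$seqid, , drop = FALSE]
    # intergenic: the hit overlaps no annotated coding span at all
    intergenic <- !any(genes$start <= hit$end & genes$end >= hit$start)
    assigned <- FALSE
    for (g in seq_len(nrow(genes))) {
      ts <- genes$translation_start[g]
      if (genes$strand[g] == "+") {
        off <- if (convention == "five-prime") hit$start - ts else
          (if (hit$end < ts) hit$end - ts else hit$start - ts)
      } else {
        off <- if (convention == "five-prime") ts - hit$end else
          (if (hit$start > ts) ts - hit$start else ts - hit$end)
      }
      loc <- if (off >= 0) off + 1 else off
      if (abs(loc) > max_distance) next
      assigned <- TRUE
      out[[length(out) + 1L]] <- cbind(
        hit,
        data.frame(gene = genes$gene_id[g], location = loc,
                   intergenic = intergenic, stringsAsFactors = FALSE)
      )
    }
    if (!assigned && keep_unassigned) {
      out[[length(out) + 1L]] <- cbind(
        hit,
        data.frame(gene = NA_character_, location = NA_real_,
                   intergenic = intergenic, stringsAsFactors = FALSE)
      )
    }
  }
  if (!length(out)) {
    return(cbind(hits[0, , drop = FALSE],
                 data.frame(gene = character(0), location = numeric(0),
                            intergenic = logical(0))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read gene annotation from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based inclusive) dialects are both
#' accepted; coordinates are normalized to 1-based inclusive. Gene identity is
#' taken from the BED name column or from GFF3 `ID`/`Name`/`gene_id`
#' attributes. The translation start is derived from strand (`start` of `+`
#' genes, `end` of `-` genes).
#'
#' @param path BED or GFF3 file (`.bed`, `.gff`, `.gff3`).
#' @return data.frame with `gene_id`, `seqid`, `start`, `end`, `strand`,
#'   `translation_start`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  id <- df$name
  if (is.null(id)) id <- df$ID
  if (is.null(id)) id <- df$Name
  if (is.null(id)) id <- df$gene_id
  if (is.null(id)) stop("annotation has no gene identifier column in ", path)
  strand <- as.character(df$strand)
  out <- data.frame(
    gene_id = as.character(id), seqid = as.character(df$seqnames),
    start = df$start, end = df$end, strand = strand,
    stringsAsFactors = FALSE
  )
  if (any(!out$strand %in% c("+", "-"))) {
    bad <- out$gene_id[!out$strand %in% c("+", "-")]
    stop("annotation record(s) without strand: ", paste(bad, collapse = ", "))
  }
  out$translation_start <- ifelse(out$strand == "+", out$start, out$end)
  out
}

#' Write a hit table as TSV
#' @param hits data.frame of (annotated) hits.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
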