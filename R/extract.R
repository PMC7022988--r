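REJECT_REASONS <- c("no_left_flank", "no_right_flank", "bad_length",
                    "ambiguous_base", "low_quality")

#' Read a FASTQ file into id/sequence/quality records
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @return list with `id` (character), `sequence` (character), `qualities`
#'   (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # Biostrings moves qualities out of mcols and warns about it; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  list(id = names(x), sequence = as.character(x),
       qualities = as.list(quals))
}

#' Write read records to FASTQ
#'
#' @param reads list as returned by [read_fastq()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  qual <- Biostrings::PhredQuality(vapply(reads$qualities, function(q) {
    intToUtf8(q + 33L)
  }, ""))
  x <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  # Biostrings warns about dropping (empty) mcols on write; not informative
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

# positions p where flank matches s with <= max_mm substitutions
# (sliding-window Hamming; indels are not considered)
flank_positions <- function(scodes, fcodes, max_mm) {
  nf <- length(fcodes)
  n <- length(scodes) - nf + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (i in seq_len(nf)) {
    mm <- mm + (scodes[i:(i + n - 1L)] != fcodes[i])
  }
  which(mm <= max_mm)
}

# Stage reached by one read orientation. Higher stages pass more filters:
# 0 no left flank, 1 no right flank, 2 bad length, 3 ambiguous base,
# 4 low quality, 5 retained. Returns the stage and (if retained) the cassette.
orientation_stage <- function(scodes, quals, lf, rf, clen, max_mm, min_q) {
  nl <- length(lf); nr <- length(rf)
  sc <- scodes
  sc[is.na(sc)] <- 0L
  lpos <- flank_positions(sc, lf, max_mm)
  if (!length(lpos)) return(list(stage = 0L))
  # any right flank downstream of some left flank?
  rpos <- flank_positions(sc, rf, max_mm)
  rany <- FALSE
  for (p in lpos) if (any(rpos >= p + nl)) { rany <- TRUE; break }
  if (!rany) return(list(stage = 1L))
  # exact-spacing pair: right flank at p + nl + clen
  good <- lpos[(lpos + nl + clen) %in% rpos]
  if (!length(good)) return(list(stage = 2L))
  p <- good[1]
  cas_idx <- (p + nl):(p + nl + clen - 1L)
  cas_codes <- scodes[cas_idx]
  if (anyNA(cas_codes)) return(list(stage = 3L))
  if (mean(quals[cas_idx]) < min_q) return(list(stage = 4L))
  list(stage = 5L, cassette = codes_to_dna(cas_codes))
}

#' Extract randomized cassettes from sequencing reads
#'
#' Recovers the fixed-length randomized cassette between two constant flanks
#' from each read. A read is retained iff, in the read or its reverse
#' complement, both flanks are found with at most `max_flank_mismatch`
#' substitutions each, exactly `cassette_length` unambiguous bases lie between
#' them, and the mean Phred quality over those bases is at least `min_mean_q`.
#' Cassettes are reported in cassette orientation (left-flank side first).
#' Rejections are counted by the first filter that failed, taking the
#' orientation that got furthest (so a pool and its read-wise reverse
#' complement give identical results).
#'
#' @param reads FASTQ path, or a list with `id`, `sequence`, `qualities` as
#'   from [read_fastq()] (qualities optional: Q40 assumed).
#' @param left_flank,right_flank constant flanking sequences (A/C/G/T).
#' @param cassette_length expected cassette length in bases.
#' @param max_flank_mismatch allowed substitutions per flank.
#' @param min_mean_q minimum mean Phred quality over the cassette.
#' @param both_orientations also try the reverse complement of each read.
#' @param dedup drop duplicate cassettes (off by default: duplicate abundance
#'   is the selection signal).
#' @return a `cassette_pool`: `cassettes` (character), `n_input`,
#'   `n_retained`, `reject_counts` (named by reason), and the extraction
#'   parameters.
#' @export
extract_cassettes <- function(reads, left_flank, right_flank, cassette_length,
                              max_flank_mismatch = 1, min_mean_q = 20,
                              both_orientations = TRUE, dedup = FALSE) {
  stopifnot_dna(left_flank, "left_flank")
  stopifnot_dna(right_flank, "right_flank")
  if (!is_scalar_number(cassette_length) || cassette_length < 1) {
    stop("cassette_length must be a positive count")
  }
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n <- length(reads$sequence)
  if (is.null(reads$qualities)) {
    reads$qualities <- lapply(nchar(reads$sequence), function(L) rep(40L, L))
  }
  lf <- dna_codes(toupper(left_flank))
  rf <- dna_codes(toupper(right_flank))
  cassettes <- character(0)
  rejects <- stats::setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  for (i in seq_len(n)) {
    scodes <- dna_codes(reads$sequence[i])
    quals <- reads$qualities[[i]]
    fwd <- orientation_stage(scodes, quals, lf, rf, cassette_length,
                             max_flank_mismatch, min_mean_q)
    best <- fwd
    if (both_orientations) {
      rcodes <- rev(5L - scodes)
      rev_res <- orientation_stage(rcodes, rev(quals), lf, rf,
                                   cassette_length, max_flank_mismatch,
                                   min_mean_q)
      if (rev_res$stage > best$stage) best <- rev_res
      if (rev_res$stage == 5L && fwd$stage == 5L &&
          rev_res$cassette < fwd$cassette) {
        best <- rev_res  # deterministic, orientation-symmetric tie-break
      }
    }
    if (best$stage == 5L) {
      cassettes <- c(cassettes, best$cassette)
    } else {
      reason <- REJECT_REASONS[best$stage + 1L]
      rejects[reason] <- rejects[reason] + 1L
    }
  }
  n_retained <- length(cassettes)   # before any dedup: conservation holds
  if (dedup) cassettes <- unique(cassettes)
  structure(list(
    cassettes = cassettes,
    n_input = n,
    n_retained = n_retained,
    reject_counts = rejects,
    cassette_length = cassette_length,
    left_flank = toupper(left_flank),
    right_flank = toupper(right_flank),
    dedup = dedup
  ), class = "cassette_pool")
}

#' @export
print.cassette_pool <- function(x, ...) {
  cat(sprintf("cassette_pool: %d/%d reads retained (length %d)\n",
              x$n_retained, x$n_input, x$cassette_length))
  rej <- x$reject_counts[x$reject_counts > 0]
  if (length(rej)) {
    cat("rejections:", paste(names(rej), rej, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a cassette pool to disk
#'
#' One cassette per line, plus a JSON sidecar (`<path>.stats.json`) with the
#' retention accounting.
#'
#' @param pool a `cassette_pool`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_cassettes <- function(pool, path) {
  writeLines(pool$cassettes, path)
  stats <- list(n_input = pool$n_input, n_retained = pool$n_retained,
                reject_counts = as.list(pool$reject_counts),
                cassette_length = pool$cassette_length,
                left_flank = pool$left_flank, right_flank = pool$right_flank)
  jsonlite::write_json(stats, paste0(path, ".stats.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
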