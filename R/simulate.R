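# Synthetic-data generators. Every generator is a pure function of its config
# (including the seed) and emits a ground-truth table sufficient to score the
# downstream stage that consumes its output.

#' Configuration for the selection-round read simulator
#'
#' Emulates iterative in-vitro selection (REPSA-style): a randomized cassette
#' pool is carried through `rounds` of resampling in which each cassette's
#' retention weight is `exp(stringency * best-window log2-odds)` under the
#' motif model (a Boltzmann weight on the best match on either strand).
#' `stringency = 0` is no selection; larger values sharpen enrichment.
#'
#' @param motif_model a `pwm`, or a literal consensus string (converted with
#'   [literal_pwm()] at match probability 0.7).
#' @param cassette_length randomized-cassette length (bases); must be at least
#'   the motif width.
#' @param left_flank,right_flank constant flanks added around the cassette in
#'   read orientation.
#' @param n_reads reads per round (resampling conserves this count).
#' @param rounds number of selection rounds after round 0.
#' @param stringency selection sharpness beta >= 0 (unitless).
#' @param planted_fraction fraction of round-0 cassettes carrying the exact
#'   consensus at a random offset. A real selection library oversamples the
#'   full sequence space, so matching molecules are guaranteed to exist; a
#'   simulated pool of a few thousand reads is not, and this fraction stands
#'   in for that coverage. Set to 0 for a pure random start.
#' @param per_base_error per-base substitution probability applied to reads.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented.
#' @param base_quality constant Phred quality of read bases.
#' @param low_q_tail_fraction fraction of reads given a Q10 3' tail over the
#'   cassette half, to exercise the quality filter.
#' @param seed integer seed.
#' @return a `selection_sim_config` list.
#' @export
selection_sim_config <- function(motif_model = "CTGACCGATCGGTCAG",
                                 cassette_length = 24,
                                 left_flank = "GCAGTTCACGGTACCA",
                                 right_flank = "TGGACCTGAACGGTCT",
                                 n_reads = 1000, rounds = 6, stringency = 0.1,
                                 planted_fraction = 0.02,
                                 per_base_error = 0.002,
                                 revcomp_fraction = 0.5,
                                 base_quality = 30L,
                                 low_q_tail_fraction = 0,
                                 seed = 1L) {
  if (is.character(motif_model)) motif_model <- literal_pwm(motif_model)
  stopifnot_dna(left_flank, "left_flank")
  stopifnot_dna(right_flank, "right_flank")
  if (cassette_length < pwm_width(motif_model)) {
    stop("cassette_length must be >= motif width")
  }
  if (stringency < 0) stop("stringency must be >= 0")
  if (n_reads < 1) stop("n_reads must be positive")
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("planted_fraction must be in [0,1]")
  }
  structure(list(motif_model = motif_model,
                 cassette_length = as.integer(cassette_length),
                 left_flank = toupper(left_flank),
                 right_flank = toupper(right_flank),
                 n_reads = as.integer(n_reads), rounds = as.integer(rounds),
                 stringency = stringency,
                 planted_fraction = planted_fraction,
                 per_base_error = per_base_error,
                 revcomp_fraction = revcomp_fraction,
                 base_quality = as.integer(base_quality),
                 low_q_tail_fraction = low_q_tail_fraction,
                 seed = as.integer(seed)),
            class = "selection_sim_config")
}

#' Simulate selection-round read pools
#'
#' Round 0 cassettes are uniform random; each subsequent round resamples
#' `n_reads` cassettes (with replacement) from the previous round with
#' probability proportional to `exp(stringency * best-window log2-odds)`.
#' Reads are `left_flank + cassette + right_flank`, a configurable fraction
#' reverse-complemented, with i.i.d. substitution errors. Identical configs
#' (including seed) produce byte-identical FASTQ output.
#'
#' @param cfg a [selection_sim_config()].
#' @param dir output directory for `round_<r>.fastq` files and `truth.tsv`
#'   (created if needed); `NULL` keeps everything in memory.
#' @return list with `cassettes` (list of character vectors, rounds 0..R),
#'   `truth` (per-read data.frame: round, read id, cassette, strand,
#'   has_consensus flag, best log-odds), and `fastq_paths` (if written).
#' @export
gen_repsa_pool <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "selection_sim_config"))
  set.seed(cfg$seed)
  pwm <- cfg$motif_model
  w <- pwm_width(pwm)
  consensus <- pwm_top_string(pwm)
  L <- cfg$cassette_length
  n <- cfg$n_reads

  pool <- vapply(seq_len(n), function(i) random_dna(L), "")
  if (cfg$planted_fraction > 0) {
    carriers <- which(stats::runif(n) < cfg$planted_fraction)
    for (i in carriers) {
      at <- sample.int(L - w + 1L, 1)
      substr(pool[i], at, at + w - 1L) <- consensus
    }
  }
  rounds <- vector("list", cfg$rounds + 1L)
  rounds[[1]] <- pool
  for (r in seq_len(cfg$rounds)) {
    lo <- best_window_logodds(pool, pwm)
    wgt <- exp(cfg$stringency * (lo - max(lo)))   # stable renormalization
    pool <- pool[sample.int(n, n, replace = TRUE, prob = wgt)]
    rounds[[r + 1]] <- pool
  }

  truth <- list()
  fastq_paths <- character(0)
  all_reads <- list()
  for (r in 0:cfg$rounds) {
    cas <- rounds[[r + 1]]
    reads <- paste0(cfg$left_flank, cas, cfg$right_flank)
    flip <- stats::runif(n) < cfg$revcomp_fraction
    reads[flip] <- revcomp(reads[flip])
    # uniform substitution errors
    if (cfg$per_base_error > 0) {
      reads <- vapply(reads, function(s) {
        codes <- dna_codes(s)
        err <- which(stats::runif(length(codes)) < cfg$per_base_error)
        if (length(err)) {
          codes[err] <- ((codes[err] - 1L +
                            sample(1:3, length(err), replace = TRUE)) %% 4L) + 1L
        }
        codes_to_dna(codes)
      }, "", USE.NAMES = FALSE)
    }
    rl <- nchar(reads[1])
    quals <- lapply(seq_len(n), function(i) rep(cfg$base_quality, rl))
    if (cfg$low_q_tail_fraction > 0) {
      lowq <- which(stats::runif(n) < cfg$low_q_tail_fraction)
      for (i in lowq) {
        quals[[i]][(rl - floor(L / 2) + 1):rl] <- 10L
      }
    }
    ids <- sprintf("round%d_read%06d", r, seq_len(n))
    lo <- best_window_logodds(cas, pwm)
    truth[[r + 1]] <- data.frame(
      round = r, id = ids, cassette = cas,
      strand = ifelse(flip, "-", "+"),
      has_consensus = grepl(consensus, cas, fixed = TRUE) |
        grepl(consensus, revcomp(cas), fixed = TRUE),
      best_logodds = lo, stringsAsFactors = FALSE
    )
    all_reads[[r + 1]] <- list(id = ids, sequence = reads, qualities = quals)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, sprintf("round_%d.fastq", r))
      write_fastq(all_reads[[r + 1]], p)
      fastq_paths <- c(fastq_paths, p)
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(cassettes = rounds, reads = all_reads, truth = truth,
       fastq_paths = fastq_paths, config = cfg)
}

#' Configuration for the synthetic genome generator
#'
#' @param length genome length in bases.
#' @param gc_fraction GC content of the i.i.d. background (default 0.69,
#'   a thermophile-like composition).
#' @param planted_sites data.frame with columns `sequence`, `position`
#'   (1-based start), `strand` (`"+"`/`"-"`); sites must fit in bounds and not
#'   overlap one another.
#' @param genes data.frame with columns `id`, `strand`, `start`, `end` and
#'   optionally `translation_start` (default: strand-appropriate span end).
#' @param seed integer seed.
#' @return a `genome_sim_config` list.
#' @export
genome_sim_config <- function(length = 5e4, gc_fraction = 0.69,
                              planted_sites = NULL, genes = NULL, seed = 1L) {
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  if (!is.null(planted_sites) && nrow(planted_sites)) {
    ends <- planted_sites$position + nchar(planted_sites$sequence) - 1L
    if (any(planted_sites$position < 1) || any(ends > length)) {
      stop("planted site out of genome bounds")
    }
    o <- order(planted_sites$position)
    ps <- planted_sites[o, ]
    pe <- ends[o]
    if (nrow(ps) > 1 && any(ps$position[-1] <= pe[-nrow(ps)])) {
      stop("planted sites overlap")
    }
  }
  if (!is.null(genes) && nrow(genes)) {
    ts <- genes$translation_start
    if (is.null(ts)) ts <- ifelse(genes$strand == "+", genes$start, genes$end)
    if (any(ts < 1 | ts > length)) stop("translation start out of bounds")
  }
  structure(list(length = as.integer(length), gc_fraction = gc_fraction,
                 planted_sites = planted_sites, genes = genes,
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

#' Generate a synthetic genome with planted motif sites
#'
#' Background bases are i.i.d. with the configured GC fraction; planted
#' sequences are written verbatim at their stated positions (reverse
#' complemented for `-` strand plants). Gene annotation records strand and
#' translation start.
#'
#' @param cfg a [genome_sim_config()].
#' @param dir output directory for `genome.fasta`, `genes.gff3`, `genes.bed`,
#'   and `sites_truth.tsv`; `NULL` keeps everything in memory.
#' @return list with `sequence` (named character), `annotation` (data.frame as
#'   [read_annotation()] returns), `truth` (planted-site table with 1-based
#'   inclusive coordinates), and file paths when written.
#' @export
gen_genome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  gc <- cfg$gc_fraction
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- sample.int(4L, cfg$length, replace = TRUE, prob = p)
  truth <- data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  ps <- cfg$planted_sites
  if (!is.null(ps) && nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      s <- toupper(ps$sequence[i])
      ins <- if (ps$strand[i] == "-") revcomp(s) else s
      at <- ps$position[i]
      codes[at:(at + nchar(ins) - 1L)] <- dna_codes(ins)
    }
    truth <- data.frame(sequence = toupper(ps$sequence),
                        start = as.integer(ps$position),
                        end = as.integer(ps$position + nchar(ps$sequence) - 1L),
                        strand = ps$strand, stringsAsFactors = FALSE)
  }
  seqstr <- codes_to_dna(codes)
  names(seqstr) <- "synthetic_genome"

  annotation <- NULL
  if (!is.null(cfg$genes) && nrow(cfg$genes)) {
    g <- cfg$genes
    ts <- g$translation_start
    if (is.null(ts)) ts <- ifelse(g$strand == "+", g$start, g$end)
    annotation <- data.frame(gene_id = g$id, seqid = "synthetic_genome",
                             start = g$start, end = g$end, strand = g$strand,
                             translation_start = ts, stringsAsFactors = FALSE)
  }

  paths <- list()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "genome.fasta")
    x <- Biostrings::DNAStringSet(seqstr)
    Biostrings::writeXStringSet(x, fasta)
    paths$fasta <- fasta
    if (!is.null(annotation)) {
      gr <- GenomicRanges::GRanges(
        seqnames = annotation$seqid,
        ranges = IRanges::IRanges(annotation$start, annotation$end),
        strand = annotation$strand
      )
      gr$type <- "gene"
      gr$ID <- annotation$gene_id
      gr$Name <- annotation$gene_id
      gff <- file.path(dir, "genes.gff3")
      rtracklayer::export(gr, gff, format = "gff3")
      gr$name <- annotation$gene_id
      gr$score <- 0
      bed <- file.path(dir, "genes.bed")
      rtracklayer::export(gr, bed, format = "bed")
      paths$gff3 <- gff
      paths$bed <- bed
    }
    tp <- file.path(dir, "sites_truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- tp
  }
  list(sequence = seqstr, annotation = annotation, truth = truth,
       paths = paths, config = cfg)
}

#' Configuration for the sensorgram simulator
#'
#' Defaults follow a label-free (biolayer interferometry) assay design: five
#' analyte concentrations spanning 3.7-300 nM, 300 s association and
#' dissociation phases sampled every 1.6 s, and kinetic constants of a
#' high-affinity protein-DNA interaction (kon 2.739e5 1/(M*s), koff 5.746e-4
#' 1/s, i.e. KD ~ 2.1 nM).
#'
#' @param kon association rate constant (1/(M*s)).
#' @param koff dissociation rate constant (1/s).
#' @param Rmax maximal response (response units).
#' @param concentrations analyte concentrations (M).
#' @param t_assoc,t_dissoc phase durations (s).
#' @param dt sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed integer seed.
#' @return a `sensorgram_sim_config` list.
#' @export
sensorgram_sim_config <- function(kon = 2.739e5, koff = 5.746e-4, Rmax = 1,
                                  concentrations = c(3.7, 11, 33, 100, 300) * 1e-9,
                                  t_assoc = 300, t_dissoc = 300, dt = 1.6,
                                  noise_sd = 0.01, seed = 1L) {
  if (kon <= 0 || koff <= 0 || Rmax <= 0) stop("rates and Rmax must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  structure(list(kon = kon, koff = koff, Rmax = Rmax,
                 concentrations = concentrations, t_assoc = t_assoc,
                 t_dissoc = t_dissoc, dt = dt, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sensorgram_sim_config")
}

#' Simulate association-then-dissociation sensorgrams
#'
#' The noiseless mean follows [model_response()] exactly; homoscedastic
#' Gaussian noise of sd `noise_sd` is added pointwise. Sampling runs from 0 to
#' `t_assoc + t_dissoc` in steps of `dt`.
#'
#' @param cfg a [sensorgram_sim_config()].
#' @param dir optional output directory; one CSV per concentration
#'   (`trace_<i>.csv`, header `time_s,response,conc_M,phase`) plus
#'   `kinetics_truth.json`.
#' @return list with `traces` (combined data.frame), `truth` (kon, koff, Rmax,
#'   KD), `paths`.
#' @export
gen_sensorgrams <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sensorgram_sim_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$t_assoc + cfg$t_dissoc, by = cfg$dt)
  out <- lapply(cfg$concentrations, function(C) {
    mu <- model_response(cfg$kon, cfg$koff, cfg$Rmax, C, t, cfg$t_assoc)
    resp <- mu + stats::rnorm(length(t), sd = cfg$noise_sd)
    data.frame(time_s = t, response = resp, conc_M = C,
               phase = ifelse(t <= cfg$t_assoc, "assoc", "dissoc"),
               stringsAsFactors = FALSE)
  })
  traces <- do.call(rbind, out)
  truth <- list(kon = cfg$kon, koff = cfg$koff, Rmax = cfg$Rmax,
                KD = compute_kd(cfg$kon, cfg$koff))
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(out)) {
      p <- file.path(dir, sprintf("trace_%d.csv", i))
      utils::write.csv(out[[i]], p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    jsonlite::write_json(truth, file.path(dir, "kinetics_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(traces = traces, truth = truth, paths = paths, config = cfg)
}

#' Configuration for the expression-matrix simulator
#'
#' Emulates a two-group (wild-type vs factor-deficient), three-replicate
#' log2-intensity microarray comparison. The default planted effects are a
#' strongly downregulated gene (the disrupted regulator itself, logFC -8.51)
#' and two moderately derepressed targets (+1.95, +1.83) among nulls.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per group (>= 2).
#' @param baseline_mean,baseline_sd log2 units of the per-gene baselines.
#' @param residual_sd within-group log2 noise sd.
#' @param planted_effects named numeric vector: gene id -> true logFC
#'   (perturbed - reference). Names must be among the generated gene ids
#'   `gene00001...`.
#' @param seed integer seed.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 2000, n_per_group = 3,
                                  baseline_mean = 8, baseline_sd = 1.5,
                                  residual_sd = 0.25,
                                  planted_effects = c(gene00001 = -8.51,
                                                      gene00002 = 1.95,
                                                      gene00003 = 1.83),
                                  seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 residual_sd = residual_sd,
                 planted_effects = planted_effects,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a two-group log2 expression matrix
#'
#' `value = baseline_g + group * planted_logFC_g + N(0, residual_sd^2)`;
#' genes without a planted effect have true logFC 0.
#'
#' @param cfg an [expression_sim_config()].
#' @param dir optional output directory for `expression.tsv` (first column
#'   gene), `groups.tsv` (sample, group), `logfc_truth.tsv`.
#' @return list with `values` (matrix), `groups`, `truth` (gene, true_logfc),
#'   `paths`.
#' @export
gen_expression <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  k <- cfg$n_per_group
  genes <- sprintf("gene%05d", seq_len(G))
  effects <- stats::setNames(numeric(G), genes)
  pe <- cfg$planted_effects
  if (length(pe)) {
    unknown <- setdiff(names(pe), genes)
    if (length(unknown)) stop("planted effect for unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    effects[names(pe)] <- pe
  }
  baseline <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  groups <- rep(c("reference", "perturbed"), each = k)
  mu <- outer(baseline, rep(1, 2 * k)) +
    outer(effects, as.numeric(groups == "perturbed"))
  values <- mu + matrix(stats::rnorm(G * 2 * k, sd = cfg$residual_sd),
                        nrow = G)
  colnames(values) <- c(paste0("ref", seq_len(k)), paste0("pert", seq_len(k)))
  rownames(values) <- genes
  truth <- data.frame(gene = genes, true_logfc = unname(effects),
                      stringsAsFactors = FALSE)
  paths <- list()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ep <- file.path(dir, "expression.tsv")
    utils::write.table(data.frame(gene = genes, values,
                                  check.names = FALSE),
                       ep, sep = "\t", quote = FALSE, row.names = FALSE)
    gp <- file.path(dir, "groups.tsv")
    utils::write.table(data.frame(sample = colnames(values), group = groups),
                       gp, sep = "\t", quote = FALSE, row.names = FALSE)
    tp <- file.path(dir, "logfc_truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- list(expression = ep, groups = gp, truth = tp)
  }
  list(values = values, groups = groups, truth = truth, paths = paths,
       config = cfg)
}

#' Simulate an EMSA titration
#'
#' Noiseless fraction bound follows the binding isotherm
#' `theta(C) = C / (C + kd)`; Gaussian noise is added and the result clipped
#' to [0, 1].
#'
#' @param kd equilibrium dissociation constant (M).
#' @param concentrations protein concentrations (M).
#' @param noise_sd Gaussian noise sd on the fraction bound.
#' @param seed optional integer seed.
#' @return data.frame with `conc_M`, `fraction_bound`, `theta_true`.
#' @export
gen_emsa_titration <- function(kd, concentrations, noise_sd = 0,
                               seed = NULL) {
  if (kd <= 0) stop("kd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  theta <- concentrations / (concentrations + kd)
  fb <- theta + stats::rnorm(length(theta), sd = noise_sd)
  data.frame(conc_M = concentrations,
             fraction_bound = pmin(pmax(fb, 0), 1),
             theta_true = theta)
}
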