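#' Join binding sites, affinities, and expression into a regulon report
#'
#' One record per (gene, site) from the annotated hit table, merged with
#' kinetic classifications (when available) and differential-expression
#' results (when available). Sites with weak or nonspecific affinity are
#' flagged `less_likely`; genes with a high- or intermediate-affinity site
#' that are significantly upregulated in the factor-deficient condition are
#' flagged `candidate_repressed` (the signature of losing a repressor). Hits
#' that enter the join without a gene assignment are returned in the
#' `excluded` attribute, never silently dropped.
#'
#' @param annotated_hits data.frame from [annotate_hits()].
#' @param fits optional named list of `kinetic_fit` objects (or KD values in
#'   molar), keyed by gene id.
#' @param de optional `de_result` from [de_analyze()].
#' @param adj_p_cutoff significance cutoff on adjusted p for the candidate
#'   flag.
#' @return a `regulon_record` data.frame; attribute `excluded` holds hits with
#'   no gene.
#' @export
regulon_report <- function(annotated_hits, fits = NULL, de = NULL,
                           adj_p_cutoff = 0.05) {
  hits <- annotated_hits
  excluded <- hits[is.na(hits$gene), , drop = FALSE]
  rec <- hits[!is.na(hits$gene), , drop = FALSE]
  rec$kd <- NA_real_
  rec$affinity_class <- NA_character_
  if (!is.null(fits) && length(fits) && nrow(rec)) {
    kd <- vapply(fits, function(f) {
      if (inherits(f, "kinetic_fit")) f$KD else as.numeric(f)
    }, 0)
    idx <- match(rec$gene, names(kd))
    rec$kd <- unname(kd[idx])
    rec$affinity_class[!is.na(rec$kd)] <-
      classify_affinity(rec$kd[!is.na(rec$kd)])
  }
  rec$logFC <- NA_real_
  rec$adj_p <- NA_real_
  if (!is.null(de) && nrow(rec)) {
    idx <- match(rec$gene, de$gene)
    rec$logFC <- de$logFC[idx]
    rec$adj_p <- de$adj.P.Val[idx]
  }
  rec$less_likely <- !is.na(rec$affinity_class) &
    rec$affinity_class %in% c("weak", "nonspecific")
  rec$candidate_repressed <- !rec$less_likely &
    !is.na(rec$affinity_class) &
    rec$affinity_class %in% c("high", "intermediate") &
    !is.na(rec$adj_p) & rec$adj_p <= adj_p_cutoff &
    !is.na(rec$logFC) & rec$logFC > 0
  rec <- rec[order(rec$p, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "excluded") <- excluded
  class(rec) <- c("regulon_record", "data.frame")
  rec
}

#' Co-regulation view: overlap-join two factors' hit tables
#'
#' Lists the intervals where hits of two transcription factors overlap on the
#' same sequence (any strand), the signature of a shared (possibly
#' co-regulated) site.
#'
#' @param hits_a,hits_b hit data.frames (from [scan_sequences()] or
#'   [annotate_hits()]).
#' @return data.frame with the shared interval and both factors' coordinates,
#'   p-values, and (when present) genes.
#' @export
coregulation_view <- function(hits_a, hits_b) {
  if (!nrow(hits_a) || !nrow(hits_b)) {
    return(data.frame(seqid = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0)))
  }
  gra <- GenomicRanges::GRanges(hits_a$seqid,
                                IRanges::IRanges(hits_a$start, hits_a$end))
  grb <- GenomicRanges::GRanges(hits_b$seqid,
                                IRanges::IRanges(hits_b$start, hits_b$end))
  ov <- GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(ov)
  j <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    seqid = hits_a$seqid[i],
    start_a = hits_a$start[i], end_a = hits_a$end[i],
    p_a = hits_a$p[i],
    start_b = hits_b$start[j], end_b = hits_b$end[j],
    p_b = hits_b$p[j],
    stringsAsFactors = FALSE
  )
  if ("gene" %in% names(hits_a)) out$gene_a <- hits_a$gene[i]
  if ("gene" %in% names(hits_b)) out$gene_b <- hits_b$gene[j]
  # one row per unique overlapping locus pair (strand duplicates collapse)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Run the full inference pipeline from one configuration
#'
#' Stages, in dependency order: input synthesis (or loading), cassette
#' extraction from the final selection round, EM motif discovery, genome
#' scanning, hit annotation, kinetic fitting (optional), differential
#' expression (optional), and the regulon-report join. Every intermediate is
#' written under `output_dir` together with a manifest (inputs, parameters,
#' seed, package version); rerunning the same config reproduces the outputs.
#'
#' @param config a nested list or YAML file path. Recognized blocks:
#'   `seed`; `simulate` with optional `selection`, `genome`, `sensorgrams`,
#'   `expression` sub-lists of generator parameters; `inputs` with paths
#'   `reads` (FASTQ), `genome` (FASTA), `annotation` (BED/GFF3), `traces`
#'   (CSV; single path or named by gene), `matrix` + `groups` (TSV);
#'   `extraction`, `motif`, `scan`, `kinetics`, `de` parameter lists passed to
#'   the respective stage functions.
#' @param output_dir report directory (created).
#' @return list with the stage results (`pool`, `motif`, `hits`,
#'   `annotated_hits`, `fits`, `de`, `report`) and the manifest, invisibly
#'   written under `output_dir`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "repsatk",
                   version = as.character(utils::packageVersion("repsatk")),
                   seed = seed, config = config, stages = list())
  sim <- config$simulate
  inputs <- config$inputs

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  }

  # --- inputs -------------------------------------------------------------
  reads_path <- inputs$reads
  genome_seq <- NULL
  annotation <- NULL
  traces <- inputs$traces
  expr_values <- NULL
  expr_groups <- NULL
  site_truth <- NULL

  if (!is.null(sim$selection)) {
    cfg <- do.call(selection_sim_config,
                   c(sim$selection, list(seed = derive_seed(seed, 1))))
    simsel <- stage("simulate_selection",
                    gen_repsa_pool(cfg, file.path(output_dir, "reads")))
    reads_path <- simsel$fastq_paths[length(simsel$fastq_paths)]
    manifest$stages$simulate_selection <-
      list(n_reads = cfg$n_reads, rounds = cfg$rounds,
           stringency = cfg$stringency)
    sel_cfg <- cfg
  } else sel_cfg <- NULL

  if (!is.null(sim$genome)) {
    gcfg <- sim$genome
    if (!is.null(gcfg$planted_sites)) {
      gcfg$planted_sites <- as.data.frame(gcfg$planted_sites)
    }
    if (!is.null(gcfg$genes)) gcfg$genes <- as.data.frame(gcfg$genes)
    cfg <- do.call(genome_sim_config,
                   c(gcfg, list(seed = derive_seed(seed, 2))))
    simg <- stage("simulate_genome",
                  gen_genome(cfg, file.path(output_dir, "genome")))
    genome_seq <- simg$sequence
    annotation <- simg$annotation
    site_truth <- simg$truth
    manifest$stages$simulate_genome <-
      list(length = cfg$length, gc = cfg$gc_fraction,
           n_planted = nrow(simg$truth))
  } else if (!is.null(inputs$genome)) {
    genome_seq <- load_sequences(inputs$genome)
    if (!is.null(inputs$annotation)) {
      annotation <- read_annotation(inputs$annotation)
    }
  }

  if (!is.null(sim$sensorgrams)) {
    cfg <- do.call(sensorgram_sim_config,
                   c(sim$sensorgrams, list(seed = derive_seed(seed, 3))))
    simk <- stage("simulate_sensorgrams",
                  gen_sensorgrams(cfg, file.path(output_dir, "traces")))
    traces <- simk$traces
    manifest$stages$simulate_sensorgrams <-
      list(n_conc = length(cfg$concentrations), noise_sd = cfg$noise_sd)
  }

  if (!is.null(sim$expression)) {
    ecfg <- sim$expression
    if (!is.null(ecfg$planted_effects)) {
      ecfg$planted_effects <- unlist(ecfg$planted_effects)
    }
    cfg <- do.call(expression_sim_config,
                   c(ecfg, list(seed = derive_seed(seed, 4))))
    sime <- stage("simulate_expression",
                  gen_expression(cfg, file.path(output_dir, "expression")))
    expr_values <- sime$values
    expr_groups <- sime$groups
    manifest$stages$simulate_expression <-
      list(n_genes = cfg$n_genes, n_per_group = cfg$n_per_group)
  } else if (!is.null(inputs$matrix)) {
    expr_values <- inputs$matrix
    expr_groups <- inputs$groups
  }

  # --- cassette extraction -------------------------------------------------
  pool <- NULL
  if (!is.null(reads_path)) {
    ex <- config$extraction
    if (is.null(ex)) ex <- list()
    if (!is.null(sel_cfg)) {
      ex$left_flank <- ex$left_flank %||% sel_cfg$left_flank
      ex$right_flank <- ex$right_flank %||% sel_cfg$right_flank
      ex$cassette_length <- ex$cassette_length %||% sel_cfg$cassette_length
    }
    pool <- stage("extract",
                  do.call(extract_cassettes, c(list(reads = reads_path), ex)))
    write_cassettes(pool, file.path(output_dir, "cassettes.txt"))
    manifest$stages$extract <- list(n_input = pool$n_input,
                                    n_retained = pool$n_retained,
                                    reject_counts = as.list(pool$reject_counts))
  }

  # --- motif discovery ------------------------------------------------------
  motif <- NULL
  if (!is.null(pool)) {
    mo <- config$motif
    if (is.null(mo)) mo <- list()
    mo$width <- mo$width %||% 16L
    mo$palindromic <- mo$palindromic %||% TRUE
    mo$seed <- mo$seed %||% derive_seed(seed, 5)
    motif <- stage("discover", do.call(em_fit, c(list(pool = pool), mo)))
    write_meme(motif$pwm, file.path(output_dir, "motif.meme"),
               name = "discovered", nsites = motif$n_sites)
    utils::write.table(
      data.frame(position = seq_along(motif$ic$ic), ic_bits = motif$ic$ic),
      file.path(output_dir, "motif_ic.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(c(motif$consensus, pwm_top_string(motif$pwm)),
               file.path(output_dir, "consensus.txt"))
    manifest$stages$discover <- list(width = mo$width,
                                     palindromic = mo$palindromic,
                                     n_sites = motif$n_sites,
                                     consensus = motif$consensus)
  }

  # --- genome scan + annotation --------------------------------------------
  hits <- NULL
  annotated <- NULL
  if (!is.null(motif) && !is.null(genome_seq)) {
    sc <- config$scan
    if (is.null(sc)) sc <- list()
    hits <- stage("scan", do.call(scan_sequences,
                                  c(list(pwm = motif$pwm,
                                         sequences = genome_seq), sc)))
    write_hits(hits, file.path(output_dir, "hits.tsv"))
    manifest$stages$scan <- list(n_hits = nrow(hits),
                                 p_threshold = sc$p_threshold %||% 5.10e-6)
    if (!is.null(annotation)) {
      annotated <- stage("annotate", annotate_hits(hits, annotation))
      write_hits(annotated, file.path(output_dir, "annotated_hits.tsv"))
      manifest$stages$annotate <- list(n_records = nrow(annotated))
    }
  }

  # --- kinetics -------------------------------------------------------------
  fits <- NULL
  if (!is.null(traces)) {
    kin <- config$kinetics
    if (is.null(kin)) kin <- list()
    if (is.data.frame(traces) || (is.character(traces) &&
                                  is.null(names(traces)))) {
      fit1 <- stage("fitkinetics",
                    do.call(fit_global, c(list(traces = traces), kin)))
      fits <- list(consensus = fit1)
    } else {
      fits <- lapply(traces, function(tr) {
        stage("fitkinetics", do.call(fit_global, c(list(traces = tr), kin)))
      })
    }
    fitjson <- lapply(fits, function(f) {
      list(kon = f$kon, koff = f$koff, Rmax = f$Rmax, KD = f$KD, r2 = f$r2,
           converged = f$converged,
           affinity = if (is.finite(f$KD)) classify_affinity(f$KD) else NA)
    })
    jsonlite::write_json(fitjson, file.path(output_dir, "kinetic_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$fitkinetics <- list(n_fits = length(fits))
  } else {
    warning("no binding traces provided: report will omit affinity columns")
  }

  # --- differential expression ----------------------------------------------
  de <- NULL
  if (!is.null(expr_values)) {
    dcfg <- config$de
    if (is.null(dcfg)) dcfg <- list()
    de <- stage("de", do.call(de_analyze,
                              c(list(values = expr_values,
                                     groups = expr_groups), dcfg)))
    utils::write.table(de_toptable(de), file.path(output_dir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$de <- list(n_genes = nrow(de),
                               d0 = unname(attr(de, "d0")))
  }

  # --- regulon report --------------------------------------------------------
  report <- NULL
  if (!is.null(annotated)) {
    gene_fits <- fits
    if (!is.null(fits) && identical(names(fits), "consensus")) {
      # a single consensus-probe fit applies to every gene with a site
      genes <- unique(annotated$gene[!is.na(annotated$gene)])
      gene_fits <- stats::setNames(rep(fits, length(genes)), genes)
    }
    report <- stage("report", regulon_report(annotated, gene_fits, de))
    write_hits(report, file.path(output_dir, "regulon_report.tsv"))
    jsonlite::write_json(report, file.path(output_dir, "regulon_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    excl <- attr(report, "excluded")
    if (!is.null(excl) && nrow(excl)) {
      write_hits(excl, file.path(output_dir, "excluded_hits.tsv"))
    }
    manifest$stages$report <- list(n_records = nrow(report),
                                   n_excluded = if (is.null(excl)) 0L else
                                     nrow(excl))
  }

  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pool = pool, motif = motif, hits = hits,
                 annotated_hits = annotated, fits = fits, de = de,
                 report = report, site_truth = site_truth,
                 manifest = manifest, output_dir = output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
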