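#' Spike-in design
#'
#' A template carrying 2-3 engineered co-occurring substitutions mixed into
#' the library at a known frequency. Co-occurrence is what distinguishes true
#' spiked templates from coincidental amplification/sequencing errors.
#'
#' @param mutations data.frame with columns `cdna_pos`, `alt` (coding strand),
#'   2-3 rows.
#' @param present_frequency mutant templates per total templates, in (0, 1].
#' @return object of class `spikein_design`.
#' @export
spikein_design <- function(mutations, present_frequency) {
  stopifnot(is.data.frame(mutations),
            all(c("cdna_pos", "alt") %in% names(mutations)))
  if (nrow(mutations) < 2L || nrow(mutations) > 3L)
    stop2("a spike-in design carries 2 or 3 co-occurring mutations")
  if (present_frequency <= 0 || present_frequency > 1)
    stop2("present_frequency must be in (0, 1]")
  structure(list(mutations = mutations,
                 present_frequency = present_frequency),
            class = "spikein_design")
}

#' Simulation configuration for an MDS library
#'
#' Generative parameters for a barcoded amplicon library: templates are
#' tagged with one random barcode each, linearly copied (errors on a linear
#' copy are inherited by every read descending from it), then sequenced with
#' independent per-read errors.
#'
#' @param amplicon a [reference_amplicon()].
#' @param n_templates number of template molecules.
#' @param barcode_len random barcode length (default 14).
#' @param index_assignments named character vector sample -> index sequence
#'   (0-7 nt; `""` allowed for one sample).
#' @param spikeins list of [spikein_design()] objects.
#' @param background_mutations optional data.frame (`cdna_pos`, `alt`,
#'   `prob`): each template independently carries each mutation with `prob`.
#' @param lambda_linear mean linear copies per template (Poisson, truncated
#'   at >= 1).
#' @param p_linear_error per-base substitution probability per linear copy.
#' @param lambda_reads mean sequenced reads per template (family size).
#' @param p_seq_error per-base sequencing substitution probability.
#' @param quality_mean,quality_sd Phred quality model (clipped to 2..40);
#'   errors are placed independently of emitted qualities.
#' @param primer gene-specific forward primer placed between barcode and
#'   target in the read layout.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(amplicon, n_templates, barcode_len = 14L,
                              index_assignments = c(sample1 = "ACGT"),
                              spikeins = list(),
                              background_mutations = NULL,
                              lambda_linear = 10, p_linear_error = 1e-5,
                              lambda_reads = 5, p_seq_error = 1e-3,
                              quality_mean = 37, quality_sd = 3,
                              primer = "TCAGTCAGGACGTACCGTTA",
                              seed = 1L) {
  stopifnot(inherits(amplicon, "reference_amplicon"))
  if (n_templates < 1L) stop2("n_templates must be >= 1")
  if (barcode_len < 1L) stop2("barcode_len must be >= 1")
  for (p in c(p_linear_error, p_seq_error))
    if (p < 0 || p > 1) stop2("error probabilities must lie in [0, 1]")
  if (lambda_linear <= 0 || lambda_reads <= 0)
    stop2("lambda_linear and lambda_reads must be positive")
  if (is.null(names(index_assignments)) || anyDuplicated(index_assignments))
    stop2("index_assignments must be a named vector of distinct indexes")
  if (any(nchar(index_assignments) > 7L))
    stop2("sample indexes are 0-7 nt")
  if (inherits(spikeins, "spikein_design")) spikeins <- list(spikeins)
  for (s in spikeins) {
    stopifnot(inherits(s, "spikein_design"))
    if (any(s$mutations$cdna_pos < amplicon$cdna_lo |
            s$mutations$cdna_pos > amplicon$cdna_hi))
      stop2("spike-in mutation position outside the amplicon")
  }
  structure(list(amplicon = amplicon, n_templates = as.integer(n_templates),
                 barcode_len = as.integer(barcode_len),
                 index_assignments = index_assignments, spikeins = spikeins,
                 background_mutations = background_mutations,
                 lambda_linear = lambda_linear,
                 p_linear_error = p_linear_error,
                 lambda_reads = lambda_reads, p_seq_error = p_seq_error,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 primer = primer, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read layout implied by a simulation config
#' @param config a [simulation_config()].
#' @return a [layout_spec()].
#' @export
layout_from_config <- function(config) {
  layout_spec(index_assignments = config$index_assignments,
              barcode_len = config$barcode_len, primer = config$primer,
              target_len = config$amplicon$length)
}

# discretized clipped-normal Phred distribution on 2..40
quality_probs <- function(mean, sd) {
  q <- 2:40
  p <- stats::dnorm(q, mean, sd)
  p / sum(p)
}

# Poisson truncated at >= 1 via inverse cdf
rtpois1 <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# apply substitutions (read index, position, alt base), tolerating several
# events on one read
apply_substitutions <- function(x, ri, pos, alt) {
  if (length(ri) == 0L) return(x)
  rank <- stats::ave(ri, ri, FUN = seq_along)
  for (k in seq_len(max(rank))) {
    sel <- rank == k
    i <- ri[sel]
    substr(x[i], pos[sel], pos[sel]) <- alt[sel]
  }
  x
}

# random base different from `cur`
random_alt <- function(cur) {
  off <- sample.int(3L, length(cur), replace = TRUE)
  DNA_BASES[(match(cur, DNA_BASES) + off - 1L) %% 4L + 1L]
}

#' Simulate an MDS amplicon library
#'
#' Draws templates (with spike-in and background mutations), tags each with a
#' random barcode, applies the two-stage error model -- linear-copy errors
#' shared by all reads descending from one linear copy, then independent
#' per-read sequencing errors -- and emits reads in the layout
#' `[index][barcode][primer][target]`.
#'
#' `emit = "fastq"` returns full FASTQ-ready records (id, sequence, Phred+33
#' quality string). `emit = "records"` skips text serialisation for large
#' runs: it returns post-error `(sample, barcode, target)` tuples with the
#' 90%/Q20 quality filter applied from the same quality model (the count of
#' sub-Q20 bases is binomially distributed per read), which is the state of
#' the data after [process_reads()].
#'
#' @param config a [simulation_config()].
#' @param emit `"fastq"` or `"records"`.
#' @return list with elements `reads` (data.frame: `id`, `sequence`,
#'   `quality` for `"fastq"`; `sample`, `barcode`, `target`, `pass_qc` for
#'   `"records"`) and `manifest` (data.frame: `template_id`, `sample`,
#'   `barcode`, `mutations`, `n_reads`).
#' @export
simulate_library <- function(config, emit = c("fastq", "records")) {
  emit <- match.arg(emit)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  amp <- config$amplicon
  n <- config$n_templates
  L <- amp$length

  ## -- templates ------------------------------------------------------------
  samples <- names(config$index_assignments)
  tpl_sample <- if (length(samples) == 1L) rep(samples, n) else
    sample(samples, n, replace = TRUE)
  tpl_target <- rep(amp$sequence, n)
  tpl_muts <- character(n)  # coding-notation labels, "+"-joined

  add_mutation <- function(tpl_idx, cdna_pos, alt_coding) {
    if (alt_coding == coding_base(amp, cdna_pos))
      stop2(sprintf("mutation %d>%s equals the reference base", cdna_pos,
                    alt_coding))
    read_pos <- cdna_to_read(amp, cdna_pos)
    alt_read <- if (amp$read_strand == "non_transcribed") alt_coding
                else comp_base(alt_coding)
    ref_coding <- coding_base(amp, cdna_pos)
    substr(tpl_target[tpl_idx], read_pos, read_pos) <<- alt_read
    lab <- sprintf("%d%s>%s", cdna_pos, ref_coding, alt_coding)
    tpl_muts[tpl_idx] <<- ifelse(tpl_muts[tpl_idx] == "", lab,
                                 paste(tpl_muts[tpl_idx], lab, sep = "+"))
    invisible(NULL)
  }

  available <- seq_len(n)
  for (s in config$spikeins) {
    n_mut <- round(s$present_frequency * n)
    if (s$present_frequency * n < 1)
      warning(sprintf(
        "spike-in expected mutant template count %.3g is below one",
        s$present_frequency * n))
    if (n_mut == 0L) next
    idx <- available[sample.int(length(available), n_mut)]
    available <- setdiff(available, idx)
    for (j in seq_len(nrow(s$mutations)))
      add_mutation(idx, s$mutations$cdna_pos[j], s$mutations$alt[j])
  }
  bg <- config$background_mutations
  if (!is.null(bg)) {
    for (j in seq_len(nrow(bg))) {
      hit <- which(stats::runif(n) < bg$prob[j])
      if (length(hit)) add_mutation(hit, bg$cdna_pos[j], bg$alt[j])
    }
  }

  barcodes <- random_strings(n, config$barcode_len)
  n_linear <- rtpois1(n, config$lambda_linear)
  n_reads <- stats::rpois(n, config$lambda_reads)

  manifest <- data.frame(template_id = seq_len(n), sample = tpl_sample,
                         barcode = barcodes, mutations = tpl_muts,
                         n_reads = n_reads, stringsAsFactors = FALSE)

  ## -- reads ----------------------------------------------------------------
  tpl_of_read <- rep.int(seq_len(n), n_reads)
  R <- length(tpl_of_read)
  target <- tpl_target[tpl_of_read]

  ## linear-copy errors, inherited by reads drawn from the mutated copy
  n_events <- stats::rbinom(n, n_linear * L, config$p_linear_error)
  ev_tpl <- which(n_events > 0L)
  if (length(ev_tpl)) {
    read_start <- c(0L, cumsum(n_reads))  # reads of template t:
    li <- integer(0); lp <- integer(0); la <- character(0)
    for (t in ev_tpl) {
      rd <- read_start[t] + seq_len(n_reads[t])
      if (!length(rd)) next
      copy_of_read <- sample.int(n_linear[t], n_reads[t], replace = TRUE)
      for (e in seq_len(n_events[t])) {
        cp <- sample.int(n_linear[t], 1L)
        hit <- rd[copy_of_read == cp]
        if (!length(hit)) next
        pos <- sample.int(L, 1L)
        cur <- substr(tpl_target[t], pos, pos)
        alt <- random_alt(cur)
        li <- c(li, hit); lp <- c(lp, rep.int(pos, length(hit)))
        la <- c(la, rep.int(alt, length(hit)))
      }
    }
    target <- apply_substitutions(target, li, lp, la)
  }

  qprob <- quality_probs(config$quality_mean, config$quality_sd)

  if (emit == "records") {
    ## sequencing errors over barcode + target
    bc <- barcodes[tpl_of_read]
    Lr <- config$barcode_len + L
    n_err <- stats::rbinom(R, Lr, config$p_seq_error)
    ri <- rep.int(seq_len(R), n_err)
    if (length(ri)) {
      pos <- sample.int(Lr, length(ri), replace = TRUE)
      in_bc <- pos <= config$barcode_len
      if (any(in_bc)) {
        cur <- substring(bc[ri[in_bc]], pos[in_bc], pos[in_bc])
        bc <- apply_substitutions(bc, ri[in_bc], pos[in_bc], random_alt(cur))
      }
      if (any(!in_bc)) {
        tp <- pos[!in_bc] - config$barcode_len
        cur <- substring(target[ri[!in_bc]], tp, tp)
        target <- apply_substitutions(target, ri[!in_bc], tp, random_alt(cur))
      }
    }
    p_low <- sum(qprob[(2:40) < 20L])
    full_len <- nchar(config$index_assignments[tpl_sample[tpl_of_read]]) +
      nchar(config$primer) + Lr
    n_low <- stats::rbinom(R, full_len, p_low)
    pass_qc <- (full_len - n_low) / full_len >= 0.90
    reads <- data.frame(sample = tpl_sample[tpl_of_read], barcode = bc,
                        target = target, pass_qc = pass_qc,
                        stringsAsFactors = FALSE)
    return(list(reads = reads, manifest = manifest))
  }

  ## full FASTQ records
  index <- config$index_assignments[tpl_sample[tpl_of_read]]
  seqs <- paste0(index, barcodes[tpl_of_read], config$primer, target)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(R, lens, config$p_seq_error)
  ri <- rep.int(seq_len(R), n_err)
  if (length(ri)) {
    pos <- (sample.int(.Machine$integer.max, length(ri),
                       replace = TRUE) - 1L) %% lens[ri] + 1L
    cur <- substring(seqs[ri], pos, pos)
    seqs <- apply_substitutions(seqs, ri, pos, random_alt(cur))
  }
  qual <- character(R)
  qalpha <- vapply(2:40 + 33L, function(i) rawToChar(as.raw(i)), character(1))
  for (len in unique(lens)) {
    sel <- lens == len
    qual[sel] <- random_strings(sum(sel), len, alphabet = qalpha,
                                prob = qprob)
  }
  reads <- data.frame(
    id = sprintf("tpl%08d_r%d", tpl_of_read,
                 stats::ave(tpl_of_read, tpl_of_read, FUN = seq_along)),
    sequence = seqs, quality = qual, stringsAsFactors = FALSE)
  list(reads = reads, manifest = manifest)
}

#' Write simulated reads as Phred+33 FASTQ
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path (`.gz` accepted).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  txt <- paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality)
  writeLines(txt, con)
  invisible(path)
}

#' Simulate one ddPCR well
#'
#' Droplet occupancy is Poisson: a droplet is mutant-positive if it received
#' at least one mutant copy, and DNA-positive if it received at least one
#' copy of either allele.
#'
#' @param n_droplets total droplets in the well.
#' @param mutant_conc mutant copies per droplet.
#' @param total_conc total (mutant + wild-type) copies per droplet.
#' @param seed optional integer seed.
#' @return a [ddpcr_well()].
#' @export
simulate_ddpcr_well <- function(n_droplets, mutant_conc, total_conc,
                                seed = NULL) {
  if (mutant_conc < 0 || total_conc < 0)
    stop2("concentrations must be non-negative")
  if (mutant_conc > total_conc)
    stop2("mutant_conc cannot exceed total_conc")
  if (!is.null(seed)) set.seed(seed)
  mut <- stats::rpois(n_droplets, mutant_conc)
  wt <- stats::rpois(n_droplets, total_conc - mutant_conc)
  ddpcr_well(n = n_droplets, nmu = sum(mut >= 1L),
             nDNAconc = sum(mut + wt >= 1L))
}

#' Simulate expression and per-tumor strand-wise mutation tables
#'
#' Emulates the inputs of the expression-quartile strand-bias analysis: a
#' gene-expression table (FPKM with replicates) and a per-tumor table of
#' CAN>CTN mutation counts per gene and strand. `strand_rate_model` maps each
#' gene's expression rank fraction (0 = lowest, 1 = highest) to the expected
#' per-tumor mutation count on each strand; counts are Poisson.
#'
#' @param n_genes number of genes (>= 4).
#' @param n_tumors number of tumors.
#' @param strand_rate_model function(rank_frac) returning a list/vector with
#'   elements `non_transcribed` and `transcribed` (vectorised over
#'   `rank_frac`).
#' @param n_reps expression replicates.
#' @param seed integer seed.
#' @return list with `expression` (gene, fpkm_rep*), `mutations` (tumor,
#'   gene, strand, class, count) and `truth` (per-gene expected rates).
#' @export
simulate_expression_wes <- function(n_genes, n_tumors,
                                    strand_rate_model = function(r)
                                      list(non_transcribed = 0.5 + 0 * r,
                                           transcribed = 0.5 + 0 * r),
                                    n_reps = 3L, seed = 1L) {
  if (n_genes < 4L) stop2("need at least 4 genes to form quartiles")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  base_expr <- sort(stats::rlnorm(n_genes, meanlog = 2, sdlog = 1.5))
  expr <- matrix(stats::rlnorm(n_genes * n_reps,
                               meanlog = log(base_expr), sdlog = 0.1),
                 nrow = n_genes)
  expression <- data.frame(gene = genes, expr)
  names(expression)[-1] <- paste0("fpkm_rep", seq_len(n_reps))
  rank_frac <- (seq_len(n_genes) - 1) / (n_genes - 1)
  rates <- strand_rate_model(rank_frac)
  truth <- data.frame(gene = genes, rank_frac = rank_frac,
                      rate_non_transcribed = rates$non_transcribed,
                      rate_transcribed = rates$transcribed)
  grid <- expand.grid(tumor = sprintf("tumor%02d", seq_len(n_tumors)),
                      gene = genes, strand = c("non_transcribed",
                                               "transcribed"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$tumor, grid$gene, grid$strand), ]
  lambda <- ifelse(grid$strand == "non_transcribed",
                   truth$rate_non_transcribed[match(grid$gene, truth$gene)],
                   truth$rate_transcribed[match(grid$gene, truth$gene)])
  grid$class <- "CAN>CTN"
  grid$count <- stats::rpois(nrow(grid), lambda)
  rownames(grid) <- NULL
  list(expression = expression,
       mutations = grid[, c("tumor", "gene", "strand", "class", "count")],
       truth = truth)
}
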