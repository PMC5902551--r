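#' Motif model for planted editing-site context
#'
#' Describes the sequence context planted around simulated editing sites:
#' the ADAR nearest-neighbour preference (G depleted immediately 5' of the
#' edited adenosine, G enriched immediately 3') plus a class-informative
#' positional bias that decays linearly with distance from the site out to
#' `decay_halfwidth` bases. `signal_strength` interpolates every planted
#' probability between the genomic background (0) and its target value (1).
#'
#' Published analyses give the direction of these preferences, not their
#' size; the default probabilities are conventions chosen so a model can
#' provably recover the structure (see the methods vignette).
#'
#' @param p_g_minus1_pos,p_g_plus1_pos Probability of G at the -1 / +1
#'   neighbour of a planted editing site (at full signal strength).
#' @param p_g_minus1_neg,p_g_plus1_neg The same for negatives; `NULL` means
#'   the genomic background frequency (no planting).
#' @param decay_halfwidth Extent of the decaying positional signal (bp).
#' @param signal_strength Overall signal scale in `[0, 1]`.
#' @return An object of class `editnet_motif`.
#' @export
motif_model <- function(p_g_minus1_pos = 0.05, p_g_plus1_pos = 0.70,
                        p_g_minus1_neg = NULL, p_g_plus1_neg = NULL,
                        decay_halfwidth = 25L, signal_strength = 1) {
  probs <- c(p_g_minus1_pos, p_g_plus1_pos, p_g_minus1_neg, p_g_plus1_neg,
             signal_strength)
  if (any(probs < 0 | probs > 1)) stop_("motif probabilities must lie in [0, 1]")
  structure(
    list(p_g_minus1_pos = p_g_minus1_pos, p_g_plus1_pos = p_g_plus1_pos,
         p_g_minus1_neg = p_g_minus1_neg, p_g_plus1_neg = p_g_plus1_neg,
         decay_halfwidth = as.integer(decay_halfwidth),
         signal_strength = signal_strength),
    class = "editnet_motif"
  )
}

#' Simulation configuration
#'
#' Defaults emulate the composition of the gold-standard sets the
#' classifier is designed for: editing sites are a minority class
#' (1000 vs 3000 SNPs and 6000 other artifacts), 86.3% of positives and
#' 34.8% of negatives carry the A>G mismatch, and windows are taken at
#' flank 100 (201 bp).
#'
#' @param genome_length Length of each simulated contig (bp).
#' @param n_contigs Number of contigs.
#' @param gc_content GC fraction of the i.i.d. background sequence.
#' @param n_positives,n_snps,n_others Class counts.
#' @param frac_a2g_positive,frac_a2g_negative A>G mismatch fraction in the
#'   positive / negative classes.
#' @param flank Window flank every candidate must support.
#' @param coverage_mean,coverage_size Negative-binomial read-coverage knob
#'   (mean/size), present only to exercise [coverage_filter()].
#' @param master_seed Single seed from which all generator randomness flows.
#' @return An object of class `editnet_sim_config`.
#' @export
sim_config <- function(genome_length = 500000L, n_contigs = 8L,
                       gc_content = 0.5,
                       n_positives = 1000L, n_snps = 3000L, n_others = 6000L,
                       frac_a2g_positive = 0.863, frac_a2g_negative = 0.348,
                       flank = 100L, coverage_mean = 20, coverage_size = 5,
                       master_seed = 1L) {
  if (any(c(n_positives, n_snps, n_others) < 1)) stop_("class counts must be positive")
  if (frac_a2g_positive < 0 || frac_a2g_positive > 1 ||
      frac_a2g_negative < 0 || frac_a2g_negative > 1) {
    stop_("A>G fractions must lie in [0, 1]")
  }
  if (gc_content < 0 || gc_content > 1) stop_("gc_content must lie in [0, 1]")
  if (genome_length < 2 * flank + 1) {
    stop_("genome_length must be at least 2 * flank + 1")
  }
  structure(
    list(genome_length = as.integer(genome_length),
         n_contigs = as.integer(n_contigs), gc_content = gc_content,
         n_positives = as.integer(n_positives), n_snps = as.integer(n_snps),
         n_others = as.integer(n_others),
         frac_a2g_positive = frac_a2g_positive,
         frac_a2g_negative = frac_a2g_negative,
         flank = as.integer(flank), coverage_mean = coverage_mean,
         coverage_size = coverage_size,
         master_seed = as.integer(master_seed)),
    class = "editnet_sim_config"
  )
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, T = (1 - gc) / 2, C = gc / 2, G = gc / 2)
}

#' Simulate a background genome
#'
#' I.i.d. bases at the configured GC content, one contig per
#' `n_contigs`, fully reproducible from `master_seed`.
#'
#' @param config An [sim_config()].
#' @return An `editnet_genome`.
#' @export
simulate_genome <- function(config) {
  p <- base_probs(config$gc_content)
  contigs <- with_seed(derive_seed(config$master_seed, 100L), {
    vapply(seq_len(config$n_contigs), function(i) {
      paste(sample(BASES, config$genome_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  names(contigs) <- paste0("sim", seq_len(config$n_contigs))
  as_genome(contigs)
}

# Interpolate a planted probability toward background by signal strength,
# with an additional linear distance decay for |offset| >= 2.
planted_prob <- function(target, bg, strength, offset = 1L, halfwidth = 25L) {
  decay <- pmax(0, 1 - (abs(offset) - 1) / halfwidth)
  bg + (target - bg) * strength * decay
}

# Draw one base per slot: G with probability p_g, otherwise a background
# base among A/C/T (background-renormalised).
draw_biased_base <- function(n, p_g, bg) {
  non_g <- c("A", "T", "C")
  p_non <- bg[non_g] / sum(bg[non_g])
  is_g <- stats::runif(n) < p_g
  out <- character(n)
  out[is_g] <- "G"
  if (any(!is_g)) {
    out[!is_g] <- sample(non_g, sum(!is_g), replace = TRUE, prob = p_non)
  }
  out
}

#' Plant editing-site context at given positions
#'
#' Writes the positive-class sequence context into the genome at each
#' position: the centre base becomes the edited adenosine (ref A; alt G
#' with probability `frac_a2g_positive`, otherwise C or T), the -1 / +1
#' neighbours follow the motif's G-depletion / G-enrichment probabilities,
#' and positions at offsets 2..`decay_halfwidth` on each side carry a
#' G-bias (enriched 3', depleted 5') that decays linearly with distance,
#' all scaled by `signal_strength`.
#'
#' @param genome An `editnet_genome`.
#' @param contig Contig name.
#' @param pos Integer vector of 1-based positions (each with `flank` room).
#' @param motif An [motif_model()].
#' @param config An [sim_config()].
#' @param seed Integer seed.
#' @return `list(genome = <edited genome>, candidates = <tibble>)`.
#' @export
plant_positive <- function(genome, contig, pos, motif = motif_model(),
                           config = sim_config(), seed = 1L) {
  if (!contig %in% names(genome)) stop_("unknown contig: ", contig)
  L <- nchar(genome[[contig]])
  hw <- motif$decay_halfwidth
  if (any(pos - config$flank < 1 | pos + config$flank > L)) {
    stop_("position(s) without enough flanking sequence")
  }
  n <- length(pos)
  bg <- base_probs(config$gc_content)
  s <- motif$signal_strength
  chars <- strsplit(genome[[contig]], "", fixed = TRUE)[[1]]
  alt <- with_seed(seed, {
    chars[pos] <- "A"
    # nearest neighbours: the ADAR preference
    p_m1 <- planted_prob(motif$p_g_minus1_pos, bg[["G"]], s)
    p_p1 <- planted_prob(motif$p_g_plus1_pos, bg[["G"]], s)
    chars[pos - 1L] <- draw_biased_base(n, p_m1, bg)
    chars[pos + 1L] <- draw_biased_base(n, p_p1, bg)
    # decaying positional signal, offsets 2..halfwidth
    if (hw >= 2) {
      for (d in 2:hw) {
        p_up <- planted_prob(0.08, bg[["G"]], s, d, hw)    # 5' depletion
        p_dn <- planted_prob(0.55, bg[["G"]], s, d, hw)    # 3' enrichment
        chars[pos - d] <- draw_biased_base(n, p_up, bg)
        chars[pos + d] <- draw_biased_base(n, p_dn, bg)
      }
    }
    a2g <- stats::runif(n) < config$frac_a2g_positive
    alt <- character(n)
    alt[a2g] <- "G"
    if (any(!a2g)) alt[!a2g] <- sample(c("C", "T"), sum(!a2g), replace = TRUE)
    alt
  })
  genome[[contig]] <- paste(chars, collapse = "")
  list(
    genome = as_genome(unclass(genome)),
    candidates = tibble::tibble(contig = contig, pos = as.integer(pos),
                                ref = "A", alt = alt, label = "EDITING")
  )
}

#' Plant negative candidates (SNPs and artifacts)
#'
#' Negatives get no motif: their neighbourhood stays background. Only the
#' centre base is written so the ref allele is controlled: with probability
#' `frac_a2g_negative` the candidate is an A>G mismatch, otherwise a
#' (ref, alt) pair drawn uniformly from the 11 non-A>G mismatch types.
#' SNP and OTHER negatives are distributionally identical by default;
#' `snp_transition_prob` biases SNP draws toward transitions to make the
#' three-class problem non-degenerate.
#'
#' @inheritParams plant_positive
#' @param class `"SNP"` or `"OTHER"`.
#' @param snp_transition_prob Optional probability that a non-A>G SNP draw
#'   is a transition (G>A, C>T, T>C).
#' @return `list(genome = <genome>, candidates = <tibble>)`.
#' @export
plant_negative <- function(genome, contig, pos, class = c("SNP", "OTHER"),
                           config = sim_config(), seed = 1L,
                           snp_transition_prob = NULL) {
  class <- match.arg(class)
  if (!contig %in% names(genome)) stop_("unknown contig: ", contig)
  L <- nchar(genome[[contig]])
  if (any(pos - config$flank < 1 | pos + config$flank > L)) {
    stop_("position(s) without enough flanking sequence")
  }
  n <- length(pos)
  non_a2g <- setdiff(mismatch_types(), "A>G")
  transitions <- intersect(non_a2g, c("G>A", "C>T", "T>C"))
  chars <- strsplit(genome[[contig]], "", fixed = TRUE)[[1]]
  res <- with_seed(seed, {
    a2g <- stats::runif(n) < config$frac_a2g_negative
    mm <- character(n)
    mm[a2g] <- "A>G"
    n_rest <- sum(!a2g)
    if (n_rest > 0) {
      if (class == "SNP" && !is.null(snp_transition_prob)) {
        take_ti <- stats::runif(n_rest) < snp_transition_prob
        draw <- character(n_rest)
        draw[take_ti] <- sample(transitions, sum(take_ti), replace = TRUE)
        draw[!take_ti] <- sample(setdiff(non_a2g, transitions), sum(!take_ti),
                                 replace = TRUE)
        mm[!a2g] <- draw
      } else {
        mm[!a2g] <- sample(non_a2g, n_rest, replace = TRUE)
      }
    }
    mm
  })
  ref <- substr(res, 1L, 1L)
  alt <- substr(res, 3L, 3L)
  chars[pos] <- ref
  genome[[contig]] <- paste(chars, collapse = "")
  list(
    genome = as_genome(unclass(genome)),
    candidates = tibble::tibble(contig = contig, pos = as.integer(pos),
                                ref = ref, alt = alt, label = class)
  )
}

#' Generate a complete labeled synthetic dataset
#'
#' Simulates a background genome, selects non-overlapping candidate
#' positions (overlapping planted windows are re-drawn by rejection
#' sampling up to a retry limit), plants positives with the motif and
#' negatives without, attaches negative-binomial read coverage, and
#' returns genome + labeled candidates + a manifest recording the full
#' configuration. Everything is reproducible from `config$master_seed`.
#'
#' @param config An [sim_config()].
#' @param motif An [motif_model()].
#' @param n_gold_sets Optionally partition candidates into this many
#'   class-stratified gold sets (adds a `gold_set` column), to exercise
#'   component training across multiple cell-type-like sets.
#' @param snp_transition_prob Passed to [plant_negative()] for SNPs.
#' @return An object of class `editnet_dataset`:
#'   `list(genome, candidates, manifest)`; `candidates` carries `label`,
#'   coverage columns and (optionally) `gold_set`.
#' @export
generate_dataset <- function(config = sim_config(), motif = motif_model(),
                             n_gold_sets = 1L, snp_transition_prob = NULL) {
  genome <- simulate_genome(config)
  n_total <- config$n_positives + config$n_snps + config$n_others
  sites <- draw_site_positions(config, n_total)
  labels <- rep(c("EDITING", "SNP", "OTHER"),
                c(config$n_positives, config$n_snps, config$n_others))
  labels <- with_seed(derive_seed(config$master_seed, 102L), sample(labels))
  cand_list <- list()
  for (ct in unique(sites$contig)) {
    on_ct <- sites$contig == ct
    for (cl in c("EDITING", "SNP", "OTHER")) {
      take <- on_ct & labels == cl
      if (!any(take)) next
      seed <- derive_seed(config$master_seed, 103L, match(ct, names(genome)),
                          match(cl, CLASS_LEVELS))
      res <- if (cl == "EDITING") {
        plant_positive(genome, ct, sites$pos[take], motif, config, seed)
      } else {
        plant_negative(genome, ct, sites$pos[take], cl, config, seed,
                       snp_transition_prob)
      }
      genome <- res$genome
      cand_list[[length(cand_list) + 1L]] <- res$candidates
    }
  }
  candidates <- dplyr::bind_rows(cand_list)
  candidates <- dplyr::arrange(candidates, .data$contig, .data$pos)
  candidates <- with_seed(derive_seed(config$master_seed, 104L), {
    n <- nrow(candidates)
    cov_total <- stats::rnbinom(n, size = config$coverage_size,
                                mu = config$coverage_mean) + 1L
    cov_alt <- stats::rbinom(n, cov_total, 0.45)
    out <- dplyr::mutate(candidates,
                         total_coverage = as.integer(cov_total),
                         alt_coverage = as.integer(cov_alt))
    out[sample.int(n), , drop = FALSE]
  })
  if (n_gold_sets > 1) {
    candidates <- with_seed(derive_seed(config$master_seed, 105L), {
      gs <- integer(nrow(candidates))
      for (cl in CLASS_LEVELS) {
        pool <- which(candidates$label == cl)
        gs[pool] <- sample(rep_len(seq_len(n_gold_sets), length(pool)))
      }
      dplyr::mutate(candidates, gold_set = gs)
    })
  }
  structure(
    list(genome = genome, candidates = candidates,
         manifest = list(config = unclass(config), motif = unclass(motif),
                         n_gold_sets = as.integer(n_gold_sets),
                         generator = "editnet",
                         package_version =
                           as.character(utils::packageVersion("editnet")))),
    class = "editnet_dataset"
  )
}

# Non-overlapping candidate positions: uniform draws per contig, conflicts
# (centres closer than one window width) re-drawn up to a retry limit.
draw_site_positions <- function(config, n_total, max_retries = 200L) {
  flank <- config$flank
  min_gap <- 2L * flank + 1L
  slots_per_contig <- (config$genome_length - 2L * flank) %/% min_gap
  if (slots_per_contig * config$n_contigs < n_total) {
    stop_("genome too small for ", n_total, " non-overlapping windows")
  }
  with_seed(derive_seed(config$master_seed, 101L), {
    per_contig <- as.vector(stats::rmultinom(
      1L, n_total, rep(1 / config$n_contigs, config$n_contigs)))
    # cap any contig at its slot capacity, spilling the excess round-robin
    while (any(per_contig > slots_per_contig)) {
      over <- which(per_contig > slots_per_contig)[1]
      spill <- per_contig[over] - slots_per_contig
      per_contig[over] <- slots_per_contig
      room <- which(per_contig < slots_per_contig)
      add <- rep_len(room, spill)
      for (i in add) per_contig[i] <- per_contig[i] + 1L
    }
    out <- vector("list", config$n_contigs)
    for (ci in seq_len(config$n_contigs)) {
      need <- per_contig[ci]
      if (need == 0) next
      kept <- integer(0)
      for (try in seq_len(max_retries)) {
        # oversample the deficit: near jamming density most draws conflict
        n_draw <- max(4L * (need - length(kept)), 256L)
        draw <- sort(unique(sample(
          seq.int(flank + 1L, config$genome_length - flank),
          n_draw, replace = TRUE)))
        # insertion-only: a new point must clear every already-kept point ...
        if (length(kept) > 0) {
          left <- findInterval(draw, kept)
          ok_left <- left == 0L | draw - kept[pmax(left, 1L)] >= min_gap
          ok_right <- left == length(kept) |
            kept[pmin(left + 1L, length(kept))] - draw >= min_gap
          draw <- draw[ok_left & ok_right]
        }
        # ... and its accepted predecessors (greedy left-to-right)
        while (length(draw) > 0 && any(diff(draw) < min_gap)) {
          draw <- draw[c(TRUE, diff(draw) >= min_gap)]
        }
        kept <- sort(c(kept, draw))
        if (length(kept) >= need) {
          kept <- kept[seq_len(need)]
          break
        }
      }
      if (length(kept) < need) {
        stop_("could not place non-overlapping windows after ", max_retries,
              " retries")
      }
      out[[ci]] <- tibble::tibble(contig = paste0("sim", ci), pos = kept)
    }
    dplyr::bind_rows(out)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome (FASTA), candidates (TSV: contig, pos, ref, alt,
#' total_coverage, alt_coverage), truth labels (TSV: contig, pos, ref, alt,
#' label) and the manifest (JSON). Outputs are byte-identical for identical
#' configurations (same `master_seed`).
#'
#' @param dataset An `editnet_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "editnet_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    candidates = file.path(dir, "candidates.tsv"),
    labels = file.path(dir, "labels.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  dss <- Biostrings::DNAStringSet(unclass(dataset$genome))
  Biostrings::writeXStringSet(dss, paths[["genome"]], width = 70L)
  cand <- dataset$candidates
  utils::write.table(
    cand[, c("contig", "pos", "ref", "alt", "total_coverage", "alt_coverage")],
    paths[["candidates"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cand[, c("contig", "pos", "ref", "alt", "label")],
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(dataset$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read truth labels written by [write_dataset()]
#'
#' @param path Path to a labels TSV (header: contig, pos, ref, alt, label).
#' @return A tibble.
#' @export
read_labels <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(raw)
}
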