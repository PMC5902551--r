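# Shared in-code fixtures: tiny genomes, candidate tables and datasets.

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]])
  })), path)
  path
}

tiny_candidates <- function() {
  tibble::tibble(
    contig = c("c1", "c1", "c2"),
    pos = c(3L, 5L, 2L),
    ref = c("A", "C", "G"),
    alt = c("G", "T", "A"),
    total_coverage = c(10L, 5L, 4L),
    alt_coverage = c(4L, 3L, 3L)
  )
}

# Small labeled synthetic dataset with windows attached.
small_examples <- function(seed = 7, n = 60, flank = 15, signal = 0.9) {
  cfg <- sim_config(genome_length = 12000 + n * (2 * flank + 2), n_contigs = 2,
                    n_positives = n, n_snps = n, n_others = n,
                    flank = flank, master_seed = seed)
  ds <- generate_dataset(cfg, motif_model(signal_strength = signal,
                                          decay_halfwidth = min(flank, 25L)))
  extract_windows(ds$genome, ds$candidates, flank)
}

fast_cfg <- function(epochs = 5L) train_config(epochs = epochs, batch_size = 64L)

small_net_spec <- function(flank = 10L) net_spec(flank, hidden_sizes = c(16L))

# Brute-force all-pairs Mann-Whitney oracle (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep oracle for the PR step integral.
pr_auc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    pred <- scores >= t
    precision <- sum(pred & labels) / sum(pred)
    recall <- sum(pred & labels) / sum(labels)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Plug-in mutual information (nats) between base identity and class label.
mutual_information <- function(base, label) {
  tab <- table(base, label)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}
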