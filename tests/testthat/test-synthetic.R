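test_that("simulated genomes hit the configured GC content, reproducibly", {
  cfg <- sim_config(genome_length = 100000, n_contigs = 1, gc_content = 0.5,
                    master_seed = 3)
  g <- simulate_genome(cfg)
  bases <- strsplit(g[[1]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_gte(gc, 0.49); expect_lte(gc, 0.51)
  expect_identical(unclass(simulate_genome(cfg)), unclass(g))
  cfg0 <- sim_config(genome_length = 5000, n_contigs = 1, gc_content = 0,
                     master_seed = 3)
  expect_true(all(strsplit(simulate_genome(cfg0)[[1]], "")[[1]] %in% c("A", "T")))
  expect_error(sim_config(genome_length = 10, flank = 100), "genome_length")
})

test_that("positive planting writes the neighbour motif at the stated rates", {
  cfg <- sim_config(genome_length = 30000, n_contigs = 1, flank = 30,
                    gc_content = 0.5, master_seed = 5)
  g <- simulate_genome(cfg)
  pos <- seq(31L, 30000L - 31L, by = 7L)[1:4000]
  res <- plant_positive(g, "sim1", pos, motif_model(signal_strength = 1,
                                                    decay_halfwidth = 2L),
                        cfg, seed = 8)
  chars <- strsplit(res$genome[[1]], "")[[1]]
  expect_true(all(chars[pos] == "A"))
  g_plus1 <- mean(chars[pos + 1L] == "G")
  g_minus1 <- mean(chars[pos - 1L] == "G")
  expect_equal(g_plus1, 0.70, tolerance = 0.02 / 0.70)
  expect_equal(g_minus1, 0.05, tolerance = 0.02 / 0.05)
  expect_equal(mean(res$candidates$alt == "G"), 0.863, tolerance = 0.03)
  # zero signal: neighbours stay at genomic background
  res0 <- plant_positive(g, "sim1", pos, motif_model(signal_strength = 0,
                                                     decay_halfwidth = 2L),
                         cfg, seed = 8)
  chars0 <- strsplit(res0$genome[[1]], "")[[1]]
  expect_equal(mean(chars0[pos + 1L] == "G"), 0.25, tolerance = 0.1)
  expect_equal(mean(chars0[pos - 1L] == "G"), 0.25, tolerance = 0.1)
  # reproducible
  res_b <- plant_positive(g, "sim1", pos, motif_model(signal_strength = 1,
                                                      decay_halfwidth = 2L),
                          cfg, seed = 8)
  expect_identical(res_b$candidates, res$candidates)
  expect_error(plant_positive(g, "sim1", 5L, motif_model(), cfg, 1),
               "flanking")
})

test_that("negative planting hits the configured A>G fraction without motif", {
  cfg <- sim_config(genome_length = 30000, n_contigs = 1, flank = 30,
                    master_seed = 5)
  g <- simulate_genome(cfg)
  pos <- seq(31L, 30000L - 31L, by = 7L)[1:4000]
  res <- plant_negative(g, "sim1", pos, "SNP", cfg, seed = 9)
  expect_equal(mean(res$candidates$ref == "A" & res$candidates$alt == "G"),
               0.348, tolerance = 0.05)
  # neighbours untouched: background G frequency
  chars <- strsplit(res$genome[[1]], "")[[1]]
  expect_equal(mean(chars[pos + 1L] == "G"), 0.25, tolerance = 0.1)
  # centre matches the recorded ref
  expect_true(all(chars[pos] == res$candidates$ref))
  res_b <- plant_negative(g, "sim1", pos, "SNP", cfg, seed = 9)
  expect_identical(res_b$candidates, res$candidates)
  # transition-biased SNP spectrum knob
  res_ti <- plant_negative(g, "sim1", pos, "SNP", cfg, seed = 9,
                           snp_transition_prob = 1)
  mm <- paste0(res_ti$candidates$ref, ">", res_ti$candidates$alt)
  expect_true(all(mm %in% c("A>G", "G>A", "C>T", "T>C")))
})

test_that("generate_dataset delivers exact class counts and valid windows", {
  cfg <- sim_config(genome_length = 30000, n_contigs = 3, flank = 20,
                    n_positives = 100, n_snps = 300, n_others = 600,
                    master_seed = 13)
  ds <- generate_dataset(cfg, motif_model(signal_strength = 0.9,
                                          decay_halfwidth = 20L))
  tab <- table(ds$candidates$label)
  expect_equal(unname(tab[c("EDITING", "SNP", "OTHER")]), c(100L, 300L, 600L),
               ignore_attr = TRUE)
  # every window extractable at the configured flank; centre equals ref
  w <- extract_windows(ds$genome, ds$candidates, cfg$flank)
  expect_true(all(nchar(w$seq) == 2 * cfg$flank + 1))
  expect_true(all(w$centre_ref == w$ref))
  expect_false(any(grepl("N", w$seq, fixed = TRUE)))
  # planted windows do not overlap
  by_contig <- split(ds$candidates$pos, ds$candidates$contig)
  for (p in by_contig) {
    expect_true(all(diff(sort(p)) >= 2 * cfg$flank + 1))
  }
  # coverage fields present to exercise the filter
  expect_true(all(ds$candidates$alt_coverage <= ds$candidates$total_coverage))
  # gold-set partition is class-stratified
  ds2 <- generate_dataset(cfg, motif_model(signal_strength = 0.9,
                                           decay_halfwidth = 20L),
                          n_gold_sets = 2)
  per_set <- table(ds2$candidates$gold_set, ds2$candidates$label)
  expect_equal(unname(per_set[1, "EDITING"]), 50)
  expect_error(generate_dataset(sim_config(genome_length = 500, n_contigs = 1,
                                           flank = 100, n_positives = 100,
                                           n_snps = 100, n_others = 100)),
               "too small")
})

test_that("dataset files are byte-identical under the master seed", {
  cfg <- sim_config(genome_length = 8000, n_contigs = 1, flank = 15,
                    n_positives = 30, n_snps = 30, n_others = 30,
                    master_seed = 23)
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  p1 <- write_dataset(generate_dataset(cfg, motif_model(decay_halfwidth = 15L)), d1)
  p2 <- write_dataset(generate_dataset(cfg, motif_model(decay_halfwidth = 15L)), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # round trip through the readers reproduces the dataset
  ds <- generate_dataset(cfg, motif_model(decay_halfwidth = 15L))
  g_back <- read_reference(p1[["genome"]])
  expect_identical(unclass(g_back), unclass(ds$genome))
  cand_back <- read_candidates(p1[["candidates"]])
  expect_equal(cand_back$pos, ds$candidates$pos)
  expect_equal(cand_back$ref, ds$candidates$ref)
  lab_back <- read_labels(p1[["labels"]])
  expect_equal(lab_back$label, ds$candidates$label)
})

test_that("label information decays with distance from the candidate site", {
  cfg <- sim_config(genome_length = 220000, n_contigs = 2, flank = 25,
                    n_positives = 1500, n_snps = 1500, n_others = 1500,
                    master_seed = 31)
  ds <- generate_dataset(cfg, motif_model(signal_strength = 0.9))
  w <- extract_windows(ds$genome, ds$candidates, 25)
  y <- w$label == "EDITING"
  chars <- matrix(unlist(strsplit(w$seq, ""), use.names = FALSE),
                  nrow = nrow(w), byrow = TRUE)
  mi <- vapply(seq_len(51), function(p) mutual_information(chars[, p], y), 0)
  offset <- seq_len(51) - 26
  band <- function(lo, hi) mean(mi[abs(offset) >= lo & abs(offset) <= hi])
  expect_gt(band(3, 10), band(11, 18))
  expect_gt(band(11, 18), band(19, 25))
  # A>G composition differs between classes as configured
  expect_equal(mean(w$alt[y] == "G"), 0.863, tolerance = 0.03)
  expect_equal(mean(w$ref[!y] == "A" & w$alt[!y] == "G"), 0.348,
               tolerance = 0.06)
})
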