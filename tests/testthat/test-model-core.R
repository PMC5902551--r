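test_that("balanced bootstrap draws exactly equal class counts, reproducibly", {
  ex <- tibble::tibble(
    seq = strrep("A", 21),
    label = rep(c("EDITING", "SNP", "OTHER"), c(100, 500, 2000))
  )
  boot <- balanced_bootstrap(ex, n_per_class = 100, seed = 5)
  expect_equal(unname(table(boot$label)[c("EDITING", "OTHER", "SNP")]),
               c(100L, 100L, 100L), ignore_attr = TRUE)
  expect_equal(nrow(boot), 300)
  # min-class default
  boot2 <- balanced_bootstrap(ex, seed = 5)
  expect_equal(nrow(boot2), 300)
  expect_identical(balanced_bootstrap(ex, 50, seed = 9),
                   balanced_bootstrap(ex, 50, seed = 9))
  expect_equal(nrow(balanced_bootstrap(ex, 1, seed = 1)), 3)
  expect_error(balanced_bootstrap(ex[ex$label != "SNP", ], 10, seed = 1),
               "SNP")
})

test_that("individual net has the derived input dimension and simplex output", {
  # (2*50+1)*4 = 404 and (2*20+1)*4 = 164
  ex50 <- small_examples(seed = 3, n = 15, flank = 50)
  net <- train_individual_net(ex50, net_spec(50, hidden_sizes = c(8)),
                              fast_cfg(2), seed = 1)
  expect_equal(net$d_in, 404)
  expect_equal(nrow(net$layers[[1]]$W), 404)
  ex20 <- dplyr::mutate(ex50, seq = editnet:::crop_windows(seq, 50, 20))
  net20 <- train_individual_net(ex20, net_spec(20, hidden_sizes = c(8)),
                                fast_cfg(2), seed = 1)
  expect_equal(net20$d_in, 164)
  probs <- predict(net, ex50)
  expect_equal(rowSums(as.matrix(probs)), rep(1, nrow(ex50)), tolerance = 1e-9)
  expect_true(all(as.matrix(probs) >= 0))
  # training is deterministic under fixed seeds
  net_b <- train_individual_net(ex50, net_spec(50, hidden_sizes = c(8)),
                                fast_cfg(2), seed = 1)
  expect_identical(net$layers, net_b$layers)
  expect_error(train_individual_net(ex50, net_spec(10), fast_cfg(2)),
               "does not match")
  expect_error(train_individual_net(ex50[0, ], net_spec(50), fast_cfg(2)),
               "empty|absent")
})

test_that("probability averaging is the componentwise mean", {
  t1 <- tibble::tibble(p_editing = c(0.2, 0.4), p_snp = c(0.3, 0.1),
                       p_other = c(0.5, 0.5))
  t2 <- tibble::tibble(p_editing = c(0.4, 0.2), p_snp = c(0.1, 0.3),
                       p_other = c(0.5, 0.5))
  avg <- average_probabilities(list(t1, t2))
  expect_equal(avg$p_editing, c(0.3, 0.3))
  expect_equal(avg$p_snp, c(0.2, 0.2))
  expect_identical(average_probabilities(list(t1)), t1)
  expect_equal(average_probabilities(list(t1, t1, t1)), t1)
  expect_equal(average_probabilities(list(c(0.2, 0.3, 0.5), c(0.4, 0.1, 0.5))),
               c(0.3, 0.2, 0.5))
  expect_error(average_probabilities(list()), "empty")
})

test_that("hierarchy levels average their children; order does not matter", {
  ex <- small_examples(seed = 11, n = 30, flank = 12)
  mspec <- module_spec(c(10L, 5L), n_members = 2,
                       member_spec = net_spec(hidden_sizes = c(8)))
  mod <- train_module(ex, mspec, fast_cfg(3), seed = 2)
  expect_length(mod$ensembles, 2)
  expect_length(mod$ensembles[[1]]$members, 2)
  # module prediction = mean of per-scale ensemble predictions
  per_scale <- lapply(mod$ensembles, predict, newdata = ex)
  expect_equal(predict(mod, ex), average_probabilities(per_scale),
               tolerance = 1e-12)
  # component prediction = mean over modules; permutation-invariant
  comp <- train_component(list(ex, ex[seq(1, nrow(ex), 2), ]), mspec,
                          fast_cfg(3), seed = 4)
  per_mod <- lapply(comp$modules, predict, newdata = ex)
  expect_equal(predict(comp, ex), average_probabilities(per_mod),
               tolerance = 1e-12)
  comp_rev <- comp
  comp_rev$modules <- rev(comp_rev$modules)
  expect_equal(predict(comp_rev, ex), predict(comp, ex), tolerance = 1e-12)
  # final model: average of the two components, symmetric
  comp2 <- train_component(list(ex), mspec, fast_cfg(3), seed = 9)
  m <- assemble_model(comp, comp2)
  expect_equal(predict(m, ex),
               average_probabilities(list(predict(comp, ex),
                                          predict(comp2, ex))),
               tolerance = 1e-12)
  m_swapped <- assemble_model(comp2, comp)
  expect_equal(predict(m_swapped, ex), predict(m, ex), tolerance = 1e-12)
  # identical components degenerate to either one
  m_same <- assemble_model(comp, comp)
  expect_equal(predict(m_same, ex), predict(comp, ex), tolerance = 1e-12)
  # scale mismatch is rejected
  comp_narrow <- train_component(list(ex), module_spec(7L, 1,
                                 net_spec(hidden_sizes = c(8))),
                                 fast_cfg(2), seed = 1)
  expect_error(assemble_model(comp, comp_narrow), "incompatible scales")
})

test_that("nested averaging equals the induced weighted mean of leaves", {
  # module 1 holds one leaf, module 2 holds three; averaging members then
  # modules must weight leaves (1/2, 1/6, 1/6, 1/6)
  leaves <- list(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3),
                 c(0.1, 0.1, 0.8), c(0.3, 0.4, 0.3))
  nested <- average_probabilities(list(
    average_probabilities(leaves[1]),
    average_probabilities(leaves[2:4])
  ))
  by_hand <- 0.5 * leaves[[1]] + (1 / 6) * (leaves[[2]] + leaves[[3]] + leaves[[4]])
  expect_equal(nested, by_hand, tolerance = 1e-12)
})

test_that("ensembles: single member degenerates, distinct seeds differ", {
  ex <- small_examples(seed = 13, n = 25, flank = 10)
  e1 <- train_ensemble(ex, ensemble_spec(1, small_net_spec()), fast_cfg(3),
                       seed = 5)
  expect_equal(predict(e1, ex), predict(e1$members[[1]], ex),
               tolerance = 1e-12)
  e2 <- train_ensemble(ex, ensemble_spec(2, small_net_spec()), fast_cfg(3),
                       seed = 5)
  w1 <- e2$members[[1]]$layers[[1]]$W
  w2 <- e2$members[[2]]$layers[[1]]$W
  expect_false(isTRUE(all.equal(w1, w2)))
  # deterministic end to end
  e2b <- train_ensemble(ex, ensemble_spec(2, small_net_spec()), fast_cfg(3),
                        seed = 5)
  expect_identical(predict(e2, ex), predict(e2b, ex))
})

test_that("score_candidates preserves order; repeated windows score equally", {
  ex <- small_examples(seed = 17, n = 20, flank = 10)
  net <- train_individual_net(ex, small_net_spec(), fast_cfg(3), seed = 2)
  scored <- score_candidates(net, ex)
  expect_equal(scored$pos, ex$pos)
  expect_equal(nrow(scored), nrow(ex))
  dup <- ex[c(1, 1, 1), ]
  sdup <- score_candidates(net, dup)
  expect_equal(sdup$p_editing, rep(sdup$p_editing[1], 3))
  empty <- predict(net, character())
  expect_equal(nrow(empty), 0)
  expect_error(predict(net, strrep("A", 7)), "narrower")
})

test_that("editing-site calling uses a strict cutoff", {
  scored <- tibble::tibble(contig = "c1", pos = 1:4, ref = "A",
                           alt = c("G", "G", "C", "T"),
                           p_editing = c(0.9, 0.5, 0.2, 1.0))
  expect_equal(nrow(call_editing_sites(scored, 1.0)), 0)
  expect_equal(nrow(call_editing_sites(scored, 0.0)), 4)
  called <- call_editing_sites(scored, 0.5)
  expect_equal(called$pos, c(1L, 4L))  # exactly-equal score excluded
  expect_true(all(c("mismatch", "is_a_to_i") %in% names(called)))
  expect_error(call_editing_sites(scored, 1.5), "cutoff")
  expect_error(call_editing_sites(scored, -0.1), "cutoff")
})

test_that("stratified k-fold split partitions and balances classes", {
  ex <- tibble::tibble(
    seq = strrep("A", 5),
    label = rep(c("EDITING", "SNP", "OTHER"), c(40, 30, 30))
  )
  folds <- kfold_split(ex, k = 5, seed = 3)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_len(100))
  expect_equal(vapply(tests, length, 1L), rep(20L, 5))
  for (f in folds) {
    expect_equal(sort(c(f$train, f$test)), seq_len(100))
    tab <- table(ex$label[f$test])
    expect_equal(unname(tab[["EDITING"]]), 8)  # 40/5
  }
  # reproducible; warns on degenerate stratification
  expect_identical(kfold_split(ex, 5, seed = 3), kfold_split(ex, 5, seed = 3))
  ex_small <- tibble::tibble(seq = "A", label = c("EDITING", "EDITING",
                                                  "SNP", "SNP", "OTHER"))
  expect_warning(kfold_split(ex_small, 2, seed = 1), "degenerate")
  expect_error(kfold_split(ex, 1, seed = 1), "k must")
})

test_that("model archives reload bit-exactly and detect corruption", {
  ex <- small_examples(seed = 19, n = 20, flank = 10)
  mod <- train_module(ex, module_spec(c(10L, 5L), 1, small_net_spec()),
                      fast_cfg(2), seed = 6)
  path <- tempfile(fileext = ".editnet")
  save_model(mod, path)
  back <- load_model(path)
  expect_identical(predict(back, ex), predict(mod, ex))
  # tampering with the stored specs must be caught by the hash check
  archive <- readRDS(path)
  archive$manifest$specs$seed <- 999L
  saveRDS(archive, path)
  expect_error(load_model(path), "spec hash|corrupt")
  expect_error(load_model(tempfile()), "not found")
  expect_error(save_model(list(), tempfile()), "not a trained")
})

test_that("tidy/glance expose the hierarchy structure", {
  ex <- small_examples(seed = 23, n = 20, flank = 10)
  mspec <- module_spec(c(10L, 5L), 2, small_net_spec())
  comp <- train_component(list(ex, ex), mspec, fast_cfg(2), seed = 2)
  m <- assemble_model(comp, comp)
  leaves <- tidy(m)
  # 2 components x 2 modules x 2 scales x 2 members = 16 leaf nets
  expect_equal(nrow(leaves), 16)
  expect_setequal(unique(leaves$component), c("separate", "pooled"))
  g <- glance(m)
  expect_equal(g$n_nets, 16)
  expect_equal(g$n_modules, 4)
  expect_equal(glance(comp)$n_modules, 2)
})
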