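test_that("gold standard counts, degenerate configs and determinism", {
  cfg <- sim_config(n_classes = 3, n_tfs_per_class = 2, targets_per_tf = 5,
                    n_background_genes = 50, samples_per_class = 5,
                    decoy_pairs = 4, seed = 7)
  gs <- generate_gold_standard(cfg)
  expect_equal(nrow(gs$gold_standard), 3 * 2 * 5 + 4)  # enumeration
  expect_equal(sum(grepl("^BG", gs$gold_standard$tf)), 4)
  expect_false(any(gs$gold_standard$tf == gs$gold_standard$target))
  expect_false(anyDuplicated(paste(gs$gold_standard$tf,
                                   gs$gold_standard$target)) > 0)
  # every planted pair appears
  planted <- unlist(lapply(names(gs$truth$tf_targets), function(tf)
    paste(tf, gs$truth$tf_targets[[tf]])))
  expect_true(all(planted %in%
                    paste(gs$gold_standard$tf, gs$gold_standard$target)))

  empty <- generate_gold_standard(
    sim_config(n_classes = 2, n_tfs_per_class = 0, targets_per_tf = 3,
               n_background_genes = 10, samples_per_class = 3,
               decoy_pairs = 0, seed = 1))
  expect_equal(nrow(empty$gold_standard), 0)

  gs2 <- generate_gold_standard(cfg)
  expect_identical(gs$gold_standard, gs2$gold_standard)

  expect_error(sim_config(hub_effect = 0.5), "hub_effect")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_classes = -1), "counts")
})

test_that("corpus dimensions, positivity, determinism and planted means", {
  cfg <- sim_config(n_classes = 3, n_tfs_per_class = 2, targets_per_tf = 5,
                    n_background_genes = 50, samples_per_class = 6,
                    decoy_pairs = 4, seed = 11)
  gs <- generate_gold_standard(cfg)
  corpus <- simulate_corpus(cfg, gs$truth)
  expect_equal(dim(corpus$expr), c(3 * 2 * (1 + 5) + 50, 3 * 6))
  expect_true(all(corpus$expr > 0))
  expect_equal(corpus$sample_table$sample_id, colnames(corpus$expr))
  expect_setequal(unique(corpus$sample_table$description), gs$truth$classes)
  corpus2 <- simulate_corpus(cfg, gs$truth)
  expect_identical(corpus$expr, corpus2$expr)

  # noise-free case: planted genes exactly baseline*hub_effect in own class
  cfg0 <- sim_config(n_classes = 2, n_tfs_per_class = 1, targets_per_tf = 2,
                     n_background_genes = 5, samples_per_class = 3,
                     hub_effect = 4, noise_sd = 0, decoy_pairs = 0,
                     baseline = 100, seed = 1)
  gs0 <- generate_gold_standard(cfg0)
  c0 <- simulate_corpus(cfg0, gs0$truth)
  own <- c0$expr["TF_c01_01", c0$sample_table$description == "class01"]
  other <- c0$expr["TF_c01_01", c0$sample_table$description == "class02"]
  expect_equal(unname(own), rep(400, 3))
  expect_equal(unname(other), rep(100, 3))
  expect_equal(unname(c0$expr["BG_0001", ]), rep(100, 6))

  # lognormal mean: E[X] = 100*4*exp(noise_sd^2/2), checked at 3 s.e.
  cfg1 <- sim_config(n_classes = 2, n_tfs_per_class = 1, targets_per_tf = 2,
                     n_background_genes = 5, samples_per_class = 50,
                     hub_effect = 4, noise_sd = 0.5, decoy_pairs = 0,
                     seed = 21)
  gs1 <- generate_gold_standard(cfg1)
  c1 <- simulate_corpus(cfg1, gs1$truth)
  x <- c1$expr["TF_c01_01", c1$sample_table$description == "class01"]
  m_theory <- 100 * 4 * exp(0.5^2 / 2)
  se_theory <- m_theory * sqrt(exp(0.25) - 1) / sqrt(50)
  expect_lt(abs(mean(x) - m_theory), 3 * se_theory)
})

test_that("hub_effect = 1 yields a null corpus (nominal t rejection rate)", {
  cfg <- sim_config(n_classes = 2, n_tfs_per_class = 1, targets_per_tf = 3,
                    n_background_genes = 20, samples_per_class = 10,
                    hub_effect = 1, noise_sd = 0.5, decoy_pairs = 0, seed = 3)
  gs <- generate_gold_standard(cfg)
  set.seed(99)
  rej <- replicate(200, {
    cfg_i <- sim_config(n_classes = 2, n_tfs_per_class = 1, targets_per_tf = 3,
                        n_background_genes = 20, samples_per_class = 10,
                        hub_effect = 1, noise_sd = 0.5, decoy_pairs = 0,
                        seed = sample.int(1e6, 1))
    co <- simulate_corpus(cfg_i, gs$truth)
    cls <- co$sample_table$description
    g <- sample(rownames(co$expr), 1)
    t.test(log(co$expr[g, cls == "class01"]),
           log(co$expr[g, cls == "class02"]))$p.value < 0.05
  })
  # binomial 3 s.e. band around 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("planted pairs out-correlate decoys (brute-force ranking)", {
  w <- small_world()
  gold <- w$gold
  planted <- !grepl("^BG", gold$tf)
  rho <- vapply(seq_len(nrow(gold)), function(k)
    cor(w$expr[gold$tf[k], ], w$expr[gold$target[k], ]), 0)
  thr <- quantile(rho[!planted], 0.95)
  expect_true(all(rho[planted] > thr))
})

test_that("simulate_query endpoints and errors", {
  w <- small_world()
  expect_error(simulate_query(w$cfg, w$truth, "nosuch"), "unknown class")
  q1 <- simulate_query(w$cfg, w$truth, "class01", attenuation = 1,
                       n = 30, seed = 8)
  cg <- planted_genes_of(w$truth, "class01")
  # attenuation 1: planted genes near baseline*hub_effect on the log scale
  expect_lt(abs(mean(log(q1[cg, ])) - log(400)), 3 * 0.5 / sqrt(30 * length(cg)))
  q0 <- simulate_query(w$cfg, w$truth, "class01", attenuation = 0,
                       n = 30, seed = 8)
  expect_lt(abs(mean(log(q0[cg, ])) - log(100)), 3 * 0.5 / sqrt(30 * length(cg)))
  # identical seed -> identical output
  expect_identical(q1, simulate_query(w$cfg, w$truth, "class01", 1, 30, 8))
})

test_that("simulate_survival respects censoring and hazard structure", {
  expect_error(survival_sim_config(n_patients = 1), "n_patients")
  expect_error(survival_sim_config(censor_rate = 1), "censor_rate")

  d0 <- simulate_survival(survival_sim_config(n_patients = 100, beta = 1,
                                              censor_rate = 0, seed = 4))
  expect_true(all(d0$event == 1L))
  expect_true(all(d0$time > 0))
  expect_identical(d0, simulate_survival(
    survival_sim_config(n_patients = 100, beta = 1, censor_rate = 0, seed = 4)))

  # beta = 1, no censoring: median survival ratio high/low ~ exp(-1)
  d <- simulate_survival(survival_sim_config(n_patients = 4000, beta = 1,
                                             censor_rate = 0,
                                             true_cutoff = 100, seed = 9))
  hi <- d$expression > 100
  ratio <- median(d$time[hi]) / median(d$time[!hi])
  expect_lt(abs(ratio - exp(-1)), 0.06)

  # censor fraction near its nominal rate under beta = 0
  dc <- simulate_survival(survival_sim_config(n_patients = 2000, beta = 0,
                                              censor_rate = 0.3, seed = 10))
  expect_lt(abs(mean(dc$event == 0) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("serialization round-trips", {
  w <- small_world()
  tmp <- tempfile(fileext = ".tsv")
  write_expression(w$expr[1:10, 1:5], tmp)
  back <- read_expression(tmp)
  expect_equal(back, w$expr[1:10, 1:5], tolerance = 1e-12)

  tg <- tempfile(fileext = ".tsv")
  write_gold_standard(w$gold, tg)
  expect_equal(read_gold_standard(tg), w$gold)

  d <- simulate_survival(survival_sim_config(n_patients = 20, seed = 2))
  ts <- tempfile(fileext = ".csv")
  write_survival_data(d, ts)
  back_s <- read_survival_data(ts)
  expect_equal(back_s$time, d$time, tolerance = 1e-12)
  expect_equal(back_s$event, d$event)

  ty <- tempfile(fileext = ".yaml")
  write_ground_truth(w$truth, ty)
  y <- yaml::read_yaml(ty)
  expect_equal(sort(unlist(y$class_tfs)), sort(unlist(w$truth$class_tfs)))
})
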