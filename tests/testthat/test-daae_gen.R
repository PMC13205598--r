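# Desk-scale configuration shared by the generator tests: a small comorbidity
# catalog, 10-year age bands, short sequences.
toy_daae_cfg <- function(...) {
  daae_config(age_band_width = 10, max_len = 16, batch_size = 64,
              latent_dim = 4, ...)
}

toy_train_cohort <- function(n = 200)
  simulate_cohort(sim_config(n_patients = n, diseases = default_diseases(10),
                             seed = 5))

test_that("cohort encoding produces the documented token layout", {
  co <- toy_cohort(list(
    list(id = "p1", sex = "female",
         visits = list(list(age = 50, codes = "HTN"),
                       list(age = 57, codes = c("DM", "CKD"))))),
    vocabulary = c("DM", "HTN", "CKD"))
  cfg <- daae_config(age_band_width = 5, max_len = 8)
  seqs <- encode_cohort(co, cfg)
  lay <- seqs$layout
  # visit (50, {HTN}) with 5-year bands -> tokens {HTN, age band 10}
  on1 <- which(seqs$X[1, 1, ] == 1)
  expect_setequal(lay$tokens[on1], c("HTN", "AGE10", "SEX_F"))
  on2 <- which(seqs$X[1, 2, ] == 1)
  expect_setequal(lay$tokens[on2], c("DM", "CKD", "AGE11"))
  # end-of-sequence token immediately after the last visit; mask covers it
  expect_equal(lay$tokens[which(seqs$X[1, 3, ] == 1)], "EOS")
  expect_equal(seqs$mask[1, ], c(1, 1, 1, rep(0, 5)))
  # empty cohort
  e <- encode_cohort(cohort(list(), c("DM")), cfg)
  expect_equal(dim(e$X)[1], 0)
  # unknown codes are rejected by the cohort constructor already; encoding a
  # cohort against a narrower generator vocabulary fails in reconstruct()
  gen_narrow <- list(layout = synthehr:::token_layout("DM", 5))
  expect_error(encode_cohort(toy_cohort(list(list(id = "a", sex = "male",
    visits = list(list(age = 50, codes = "XX"))))), cfg),
    "outside vocabulary")
})

test_that("long records are truncated to max_len with the oldest tail dropped", {
  vs <- lapply(1:20, function(k) list(age = 30 + k, codes = "HTN"))
  co <- toy_cohort(list(list(id = "p", sex = "male", visits = vs)),
                   vocabulary = c("DM", "HTN"))
  seqs <- encode_cohort(co, daae_config(age_band_width = 10, max_len = 8))
  expect_equal(sum(seqs$mask[1, ]), 8)
  expect_equal(seqs$layout$tokens[which(seqs$X[1, 8, ] == 1)], "EOS")
})

test_that("training runs the fixed number of epochs and logs finite losses", {
  co <- toy_train_cohort(60)
  gen <- daae(co, toy_daae_cfg(epochs = 5, seed = 2))
  expect_equal(nrow(gen$loss_trace), 5)
  expect_true(all(is.finite(as.matrix(gen$loss_trace))))
  gen0 <- daae(co, toy_daae_cfg(epochs = 0))
  expect_equal(nrow(gen0$loss_trace), 0)
})

test_that("dp clipping at a vanishing norm freezes the parameters", {
  co <- simulate_cohort(sim_config(n_patients = 16,
                                   diseases = default_diseases(5), seed = 5))
  cfg <- daae_config(age_band_width = 10, max_len = 16, latent_dim = 4,
                     epochs = 3, seed = 1, batch_size = 16,
                     dp_enabled = TRUE, dp_clip_norm = 1e-8,
                     dp_noise_multiplier = 0, adv_weight_latent = 0,
                     adv_weight_data = 0)
  gen <- daae(co, cfg)
  set.seed(1)
  p0 <- synthehr:::daae_init_params(length(gen$layout$tokens), cfg)
  expect_lt(max(abs(gen$params$out$W - p0$out$W)), 1e-3)
  expect_error(daae_config(dp_enabled = TRUE), "dp_clip_norm")
})

test_that("with adversarial weights 0 the model memorizes a tiny cohort", {
  co <- simulate_cohort(sim_config(n_patients = 20,
                                   diseases = default_diseases(5), seed = 3))
  cfg <- daae_config(epochs = 300, seed = 1, age_band_width = 10, max_len = 12,
                     batch_size = 20, adv_weight_latent = 0,
                     adv_weight_data = 0, latent_noise_sd = 0, l2_weight = 0,
                     latent_dim = 8)
  gen <- daae(co, cfg)
  final <- utils::tail(gen$loss_trace$reconstruction, 1)
  expect_lt(final, 0.05)
  expect_lt(final, gen$loss_trace$reconstruction[1] / 10)
  # round trip through the deterministic decoder path reproduces the code sets
  rec <- reconstruct(gen, co)
  hit <- vapply(seq_along(co$records), function(i)
    setequal(unlist(lapply(co$records[[i]]$visits, `[[`, "codes")),
             unlist(lapply(rec$records[[i]]$visits, `[[`, "codes"))), TRUE)
  expect_gte(mean(hit), 0.8)
})

test_that("sampling is deterministic, size-checked, and yields raw cohorts", {
  co <- toy_train_cohort(60)
  gen <- daae(co, toy_daae_cfg(epochs = 10, seed = 2))
  expect_error(sample_cohort(gen, -1), ">= 0")
  expect_length(sample_cohort(gen, 0)$records, 0)
  a <- sample_cohort(gen, 50, seed = 9)
  b <- sample_cohort(gen, 50, seed = 9)
  expect_true(synthehr:::cohorts_equal(a, b))
  expect_false(synthehr:::cohorts_equal(a, sample_cohort(gen, 50, seed = 10)))
  # simulate() generic maps to sampling
  s <- simulate(gen, nsim = 5, seed = 9)
  expect_length(s$records, 5)
  expect_true(synthehr:::cohorts_equal(s, sample_cohort(gen, 5, seed = 9)))
})

test_that("trained samples beat a permutation-destroyed baseline on KSS and CoC", {
  co <- toy_train_cohort(200)
  gen <- daae(co, toy_daae_cfg(epochs = 50, seed = 1))
  synth <- refine_cohort(sample_cohort(gen, 400, seed = 2))$cohort
  expect_gte(length(synth$records), 100)
  # baseline: visit order permuted within records and all visit ages permuted
  # across the cohort (destroys temporal precedence and age-code assignment)
  set.seed(3)
  ev <- lapply(synth$records, synthehr:::record_events)
  all_ages <- sample(unlist(lapply(ev, `[[`, "ages")))
  k <- 0
  base_recs <- lapply(seq_along(synth$records), function(i) {
    codes <- sample(ev[[i]]$codes)
    ages <- all_ages[k + seq_along(codes)]
    k <<- k + length(codes)
    rec <- synth$records[[i]]
    vs <- lapply(seq_along(codes), function(j) visit(ages[j], codes[j]))
    rec$visits <- vs
    rec
  })
  baseline <- cohort(base_recs, synth$vocabulary, synth$anchor_code,
                     synth$endpoint_code)
  ft_real <- flatten(co)
  kss_model <- ks_complement(ft_real, flatten(synth))$score
  kss_base <- ks_complement(ft_real, flatten(baseline))$score
  expect_gt(kss_model, kss_base)
  coc_model <- cooccurrence_correlation(co, synth)$score
  coc_base <- cooccurrence_correlation(co, baseline)$score
  expect_gt(coc_model, coc_base)
})
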