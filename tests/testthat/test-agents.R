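# Decision models: state updates, action selection, latent trajectories.

test_that("hybrid update matches direct substitution into the update rules", {
  p <- model_params("FQ_RPE_CK", alpha = 0.5, alpha_k = 0.2,
                    beta = 1, beta_k = 1)
  st <- update_state(agent_state(), "L", 1, p)
  expect_equal(st$q_left, 0.5)
  expect_equal(st$q_right, 0)
  expect_equal(st$k_left, 0.2)
  expect_equal(st$k_right, 0)
})

test_that("forgetting update decays the unchosen value", {
  p <- model_params("FQ_RPE", alpha = 0.25, beta = 1)
  st <- update_state(agent_state(q_left = 0.8, q_right = 0.4), "R", 0, p)
  expect_equal(st$q_left, 0.6)   # (1 - alpha) * 0.8
  expect_equal(st$q_right, 0.3)  # 0.4 + 0.25 * (0 - 0.4)

  # plain Q-learning leaves the unchosen value alone
  q <- model_params("Q_RPE", alpha = 0.25, beta = 1)
  st2 <- update_state(agent_state(q_left = 0.8, q_right = 0.4), "R", 0, q)
  expect_equal(st2$q_left, 0.8)
  expect_equal(st2$q_right, 0.3)
})

test_that("differential update moves unrewarded values toward 1 as defined", {
  p <- model_params("DQ_RPE", alpha_r = 0.3, alpha_u = 0.1, beta = 1)
  st <- update_state(agent_state(q_left = 0.2, q_right = 0.2), "L", 0, p)
  expect_equal(st$q_left, 0.28)  # 0.2 + 0.1 * (1 - 0.2), toward 1
  expect_equal(st$q_right, 0.2)

  p0 <- model_params("DQ_RPE", alpha_r = 0.3, alpha_u = 0.1, beta = 1,
                     dq_unrewarded_toward_zero = TRUE)
  st0 <- update_state(agent_state(q_left = 0.2, q_right = 0.2), "L", 0, p0)
  expect_equal(st0$q_left, 0.18)  # documented toward-0 variant
})

test_that("MISS trials leave agent state unchanged", {
  p <- model_params("FQ_RPE_CK", alpha = 0.5, alpha_k = 0.2,
                    beta = 1, beta_k = 1)
  st <- agent_state(0.4, 0.3, 0.2, 0.1)
  expect_identical(update_state(st, "MISS", 0, p), st)
})

test_that("action probabilities are symmetric and weight-sum driven", {
  for (m in list(model_params("Q_RPE", alpha = .5, beta = 3),
                 model_params("FQ_RPE", alpha = .5, beta = 3),
                 model_params("DQ_RPE", alpha_r = .5, alpha_u = .2, beta = 3),
                 model_params("FQ_RPE_CK", alpha = .5, alpha_k = .2,
                              beta = 3, beta_k = 2))) {
    expect_equal(action_probability(agent_state(0.3, 0.3, 0.7, 0.7), m), 0.5)
  }
  # equal weighted sums despite unequal components
  m <- model_params("FQ_RPE_CK", alpha = .5, alpha_k = .2, beta = 2, beta_k = 2)
  expect_equal(action_probability(agent_state(1, 0, 0, 1), m), 0.5)

  # invariance to adding a constant to both weighted sums
  m2 <- model_params("FQ_RPE", alpha = .5, beta = 2)
  p1 <- action_probability(agent_state(0.9, 0.4), m2)
  p2 <- action_probability(agent_state(0.9 + 3, 0.4 + 3), m2)
  expect_equal(p1, p2)
  # extreme weights stay finite thanks to max-subtraction
  m3 <- model_params("FQ_RPE", alpha = .5, beta = 100)
  expect_true(is.finite(action_probability(agent_state(1, 0), m3)))
})

test_that("WSLS probabilities follow stay-if-rewarded / switch-if-not", {
  p <- model_params("WSLS", p_wsls = 0.9)
  st <- agent_state()
  expect_equal(action_probability(st, p), 0.5)  # first trial
  expect_equal(action_probability(st, p, "L", 1), 0.9)
  expect_equal(action_probability(st, p, "L", 0), 0.1)
  expect_equal(action_probability(st, p, "R", 1), 0.1)
  expect_equal(action_probability(st, p, "R", 0), 0.9)
})

test_that("latent trajectory reproduces a hand-computed five-trial forward pass", {
  p <- model_params("FQ_RPE_CK", alpha = 0.5, alpha_k = 0.2,
                    beta = 1, beta_k = 1)
  s <- toy_session(c("L", "L", "R", "L", "R"), c(1, 0, 1, 1, 0))
  tr <- latent_trajectory(p, s)
  # frozen values from explicit hand simulation of the update equations
  expect_equal(tr$pL, c(0.5, plogis(0.7), plogis(0.61), plogis(-0.287),
                        plogis(0.5829)), tolerance = 1e-12)
  expect_equal(tr$rpe, c(1, -0.5, 1, 0.875, -0.25))
  expect_equal(tr$cke, c(1, 0.8, 1, 0.712, 0.84))
  expect_equal(tr$qL[4], 0.125)
  expect_equal(tr$kL[4], 0.288)
})

test_that("zero learning rates freeze the latent variables", {
  p <- model_params("FQ_RPE_CK", alpha = 0, alpha_k = 0, beta = 2, beta_k = 2)
  s <- toy_session(sample(c("L", "R"), 30, replace = TRUE),
                   sample(0:1, 30, replace = TRUE))
  tr <- latent_trajectory(p, s)
  expect_true(all(tr$qL == 0 & tr$qR == 0 & tr$kL == 0 & tr$kR == 0))
  expect_true(all(tr$pL == 0.5))
})

test_that("single-trial trajectory carries the defining RPE/CKE values", {
  p <- model_params("FQ_RPE", alpha = 0.6, beta = 1)
  tr <- latent_trajectory(p, toy_session("L", 1))
  expect_equal(tr$rpe, 1)
  expect_equal(tr$pL, 0.5)
  st <- update_state(agent_state(), "L", 1, p)
  expect_equal(st$q_left, 0.6)
})

test_that("values and kernels stay in [0, 1] for every model (induction property)", {
  set.seed(42)
  models <- list(
    model_params("Q_RPE", alpha = runif(1), beta = 1),
    model_params("FQ_RPE", alpha = runif(1), beta = 1),
    model_params("DQ_RPE", alpha_r = runif(1), alpha_u = runif(1), beta = 1),
    model_params("FQ_RPE_CK", alpha = runif(1), alpha_k = runif(1),
                 beta = 1, beta_k = 1))
  s <- toy_session(sample(c("L", "R"), 200, replace = TRUE),
                   sample(0:1, 200, replace = TRUE))
  for (m in models) {
    tr <- latent_trajectory(m, s)
    expect_true(all(tr$qL >= 0 & tr$qL <= 1 & tr$qR >= 0 & tr$qR <= 1))
    expect_true(all(tr$kL >= 0 & tr$kL <= 1 & tr$kR >= 0 & tr$kR <= 1))
    expect_true(all(tr$pL > 0 & tr$pL < 1))
    expect_true(all(abs(tr$rpe) <= 1))
  }
})

test_that("trajectory recomputation is bit-stable and MISS trials are skipped", {
  p <- model_params("FQ_RPE_CK", alpha = .4, alpha_k = .1, beta = 1, beta_k = 2)
  s <- mp_session(c("L", "MISS", "R", "R"), c(1, 0, 0, 1))
  tr1 <- latent_trajectory(p, s)
  tr2 <- latent_trajectory(p, s)
  expect_identical(tr1, tr2)
  expect_true(is.na(tr1$rpe[2]))
  # state on trial 3 reflects only trial 1's update
  expect_equal(tr1$qL[3], 0.4)
  expect_equal(tr1$qL[2], tr1$qL[3])
})

test_that("model params validate their constraint box", {
  expect_error(model_params("FQ_RPE", alpha = 1.2, beta = 1), "\\[0, 1\\]")
  expect_error(model_params("FQ_RPE", alpha = 0.5, beta = -1), "non-negative")
  expect_error(model_params("WSLS"), "requires parameter")
  # YAML round trip
  p <- model_params("FQ_RPE_CK", alpha = .6, alpha_k = .13,
                    beta = .52, beta_k = 1.63)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  expect_equal(read_params(f), p)
})
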