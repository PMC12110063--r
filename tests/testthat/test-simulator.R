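test_that("winner-takes-all dominance uses canonical tie-breaking", {
  expect_equal(dominant_thoughtseed(named_alpha(breath_focus = 0.9,
                                                equanimity = 0.1)),
               "breath_focus")
  expect_equal(dominant_thoughtseed(named_alpha(equanimity = 0.4,
                                                pending_tasks = 0.4)),
               "equanimity")
  a <- named_alpha(breath_focus = 0.3, equanimity = 0.3, pain_discomfort = 0.3,
                   pending_tasks = 0.3, self_reflection = 0.3)
  expect_equal(dominant_thoughtseed(a), "breath_focus")
  # order of the input vector does not matter
  expect_equal(dominant_thoughtseed(rev(named_alpha(self_reflection = 1))),
               "self_reflection")
})

test_that("network-coupled targets follow the additive form and stay bounded", {
  p <- quiet_profile("expert", list(
    meta_coupling_beta = stats::setNames(rep(0, 5), thoughtseeds())))
  W <- new_weight_fixture()
  z <- matrix(0, 5, 5, dimnames = list(thoughtseeds(), thoughtseeds()))
  # zero interactions, zero beta: weight row plus the +0.1 attractor bias
  tg <- compute_target(named_alpha(), "meta_awareness", 0.9, W, z, p)
  expect_equal(unname(tg["pending_tasks"]), 0.1)           # non-attractor
  expect_equal(unname(tg["self_reflection"]), 1.0)         # 1.0 + bias, clipped
  # a single facilitatory edge j -> i adds W_ji * alpha_j
  z2 <- z; z2["equanimity", "pending_tasks"] <- 0.5
  a <- named_alpha(equanimity = 1)
  tg2 <- compute_target(a, "meta_awareness", 0.9, W, z2, p)
  expect_equal(unname(tg2["pending_tasks"]), 0.1 + 0.5)
  # meta-awareness couples through beta
  pb <- quiet_profile("expert")
  tg3 <- compute_target(named_alpha(), "meta_awareness", 0.8, W, z, pb)
  expect_equal(unname(tg3["equanimity"]),
               0.1 + 0.8 * pb$meta_coupling_beta[["equanimity"]])
  # clipping fuzz: targets never leave [0, 1]
  set.seed(12)
  for (i in 1:1000) {
    aa <- stats::setNames(runif(5), thoughtseeds())
    WW <- matrix(runif(25, -1, 1), 5, 5,
                 dimnames = list(thoughtseeds(), thoughtseeds()))
    diag(WW) <- 0
    st <- sample(meditation_states(), 1)
    tt <- compute_target(aa, st, runif(1), W, WW, pb)
    expect_true(all(tt >= 0 & tt <= 1))
  }
})

test_that("momentum steps contract toward the target at rate (1 - r)", {
  expect_equal(step_activation(0, 1, 0.75), 0.75)
  expect_equal(step_activation(0.4, 0.4, 0.6), 0.4)  # fixed point
  expect_equal(step_activation(0.2, 0.9, 1), 0.9)    # full responsiveness
  # exact geometric contraction over many steps
  x <- 0.05; r <- 0.72; target <- 0.8
  for (t in 1:30) x <- step_activation(x, target, r)
  expect_equal(target - x, (target - 0.05) * (1 - r)^30, tolerance = 1e-14)
})

test_that("hybrid transition rule: stay, natural capture, forced exit", {
  p <- make_profile("expert")
  m <- train(p, n_steps = 150, seed = 5)
  # below dwell minimum: stay regardless of activations
  out <- transition_step("mind_wandering", named_alpha(breath_focus = 1), 1,
                         m, p)
  expect_equal(out$kind, "none")
  expect_equal(out$state, "mind_wandering")
  # natural capture once dwell minimum reached
  dmin <- p$dwell_limits$mind_wandering["min"]
  out2 <- transition_step("mind_wandering", named_alpha(breath_focus = 1),
                          dmin, m, p)
  expect_equal(out2$kind, "natural")
  expect_equal(out2$state, "breath_control")
  # dwell cap reached without crossing: forced, never the current state
  set.seed(8)
  for (i in 1:25) {
    out3 <- transition_step("breath_control", named_alpha(), 16, m, p,
                            dwell_cap = 16)
    expect_equal(out3$kind, "forced")
    expect_false(out3$state == "breath_control")
  }
  # theta = 0: any dominating support triggers a natural transition
  p0 <- make_profile("expert", overrides = list(
    transition_threshold = stats::setNames(rep(0, 4), meditation_states())))
  out4 <- transition_step("breath_control", named_alpha(self_reflection = 0.2),
                          p0$dwell_limits$breath_control["min"], m, p0)
  expect_equal(out4$kind, "natural")
  expect_equal(out4$state, "meta_awareness")
})

test_that("simulation traces are reproducible, bounded and well-formed", {
  m <- train(make_profile("expert"), n_steps = 150, seed = 2)
  net <- extract_network(m$trace)
  tr1 <- run_simulation(m, net, n_steps = 150, seed = 77)
  tr2 <- run_simulation(m, net, n_steps = 150, seed = 77)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_equal(nrow(tr1), 150)
  A <- trace_activations(tr1)
  expect_true(all(A >= 0 & A <= 1))
  # meta-awareness floor holds across the whole trace
  expect_true(all(tr1$mu >= 0.55 - 1e-12))
  # winner-takes-all consistency: recorded dominant equals recomputation
  recomputed <- apply(A, 1, function(a) dominant_thoughtseed(a))
  expect_equal(tr1$dominant, unname(recomputed))
  # states change exactly at recorded transition events
  trans <- attr(tr1, "transitions")
  changes <- which(tr1$state[-1] != tr1$state[-150])
  expect_equal(trans$t, changes)
  expect_true(all(trans$kind %in% c("natural", "forced")))
  # no episode exceeds the state's hard dwell cap + 1
  ep <- episode_durations(tr1)$episodes
  p <- m$profile
  for (i in seq_len(nrow(ep)))
    expect_lte(ep$duration[i], p$dwell_limits[[ep$state[i]]]["max"] + 1)
  expect_error(run_simulation(m, net, n_steps = 0),
               class = "vipassim_validation_error")
})

test_that("expertise ordering emerges in simulated ensembles", {
  seeds <- 1:10
  mw <- lapply(c("novice", "expert"), function(lvl) {
    unlist(lapply(seeds, function(s) {
      m <- train(make_profile(lvl), n_steps = 200, seed = s)
      net <- extract_network(m$trace)
      tr <- run_simulation(m, net, n_steps = 200, seed = 1000 + s)
      ep <- episode_durations(tr)$episodes
      ep$duration[ep$state == "mind_wandering"]
    }))
  })
  expect_lt(mean(mw[[2]]), mean(mw[[1]]))
  # every state is reached somewhere in each ensemble
  for (lvl in c("novice", "expert")) {
    visited <- unique(unlist(lapply(seeds, function(s) {
      m <- train(make_profile(lvl), n_steps = 200, seed = s)
      unique(m$trace$state)
    })))
    expect_setequal(visited, meditation_states())
  }
})
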