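test_that("affinity and matching follow the Hamming rule", {
  expect_equal(affinity(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(affinity(c(1, 0, 1, 0), c(0, 1, 0, 1)), 0)
  expect_equal(affinity(c(1, 0, 1, 0), c(1, 0, 1, 1)), 0.75)
  expect_error(affinity(c(1, 0), c(1, 0, 1)))

  expect_equal(f_match(c(1, 1), c(1, 1), 0.5), 1L)
  expect_equal(f_match(c(1, 0, 1, 1), c(1, 0, 1, 0), 0.75), 0L) # strict
  expect_equal(f_match(c(1, 0, 1, 1), c(1, 0, 1, 0), 0.7), 1L)
})

test_that("tolerance step deletes self-matchers and matures survivors", {
  self <- list(c(1L, 1L, 1L, 1L))
  pop <- qais_population(
    immature = list(
      detector(c(1L, 1L, 1L, 0L)), # affinity 0.75 > gamma 0.7: deleted
      detector(c(0L, 0L, 0L, 1L), t = 0L),
      detector(c(0L, 0L, 1L, 1L), t = 2L) # t reaches alpha = 3: matures
    ),
    self_set = self, alpha = 3, gamma = 0.7
  )
  out <- tolerance_step(pop)
  expect_length(out$immature, 1)
  expect_equal(out$immature[[1]]$ab, c(0L, 0L, 0L, 1L))
  expect_equal(out$immature[[1]]$t, 1L)
  expect_length(out$mature, 1)
  expect_equal(out$mature[[1]]$ab, c(0L, 0L, 1L, 1L))

  # Empty self set: nothing deleted, every tolerance counter incremented.
  pop2 <- qais_population(
    immature = list(detector(c(1L, 0L)), detector(c(0L, 1L))),
    alpha = 5
  )
  out2 <- tolerance_step(pop2)
  expect_length(out2$immature, 2)
  expect_true(all(vapply(out2$immature, function(d) d$t, integer(1)) == 1L))
})

test_that("clone counts are rank-proportional", {
  expect_equal(clone_count(10, 10, 6), 0L)
  expect_equal(clone_count(0, 10, 6), 6L)
  expect_equal(clone_count(3, 10, 10), 7L)
})

test_that("clonal selection clones by rank and removes cloned parents", {
  pop <- qais_population(
    mature = list(detector(c(1L, 1L, 0L, 0L), p = 1)),
    xi = 2
  )
  out <- clonal_selection(pop, antigens = list())
  expect_length(out$mature, 2)
  expect_true(all(vapply(out$mature, function(d) {
    identical(d$ab, c(1L, 1L, 0L, 0L))
  }, logical(1))))

  pop0 <- qais_population(mature = list(detector(c(1L, 0L))), xi = 0)
  expect_identical(clonal_selection(pop0, list()), pop0)

  # Disjoint-set bookkeeping after a mixed call.
  pop3 <- qais_population(
    immature = list(detector(c(0L, 0L, 0L, 0L), t = 1L)),
    mature = list(detector(c(1L, 1L, 0L, 0L), p = 2),
                  detector(c(1L, 0L, 1L, 0L), p = 1)),
    memory = list(detector(c(1L, 1L, 1L, 0L), p = 3)),
    xi = 2
  )
  out3 <- clonal_selection(pop3, antigens = list(c(1L, 1L, 1L, 1L)))
  total <- length(out3$immature) + length(out3$mature) + length(out3$memory)
  expect_equal(length(out3$immature), 1)
  expect_equal(length(out3$memory), 1)
  expect_gte(total, 3)
})

test_that("immune mutation only flips antigen-mismatched bits", {
  d <- detector(c(1L, 0L, 1L, 0L))
  ag <- c(1L, 0L, 1L, 0L)
  expect_equal(immune_mutation(d, ag, p_mut = 0.9, seed = 1)$ab, d$ab)

  ag2 <- c(0L, 1L, 0L, 1L)
  expect_equal(immune_mutation(d, ag2, p_mut = 1, seed = 1)$ab, ag2)
  expect_equal(immune_mutation(d, ag2, p_mut = 0, seed = 1)$ab, d$ab)

  # Partial mismatch: matched bits never change.
  ag3 <- c(1L, 1L, 1L, 1L)
  out <- immune_mutation(d, ag3, p_mut = 1, seed = 2)
  expect_equal(out$ab[c(1, 3)], c(1L, 1L))
  expect_equal(out$ab, c(1L, 1L, 1L, 1L))
})

test_that("promotion and reinforcement follow the strict activation rule", {
  pop <- qais_population(
    mature = list(detector(c(1L, 0L), cnt = 5L), # cnt == beta_act: stays
                  detector(c(0L, 1L), cnt = 6L)), # cnt > beta_act: promoted
    beta_act = 5, eta1 = 1, eta2 = 0.5
  )
  out <- promote_and_reinforce(pop, antigens = list())
  expect_length(out$mature, 1)
  expect_equal(out$mature[[1]]$cnt, 5L)
  expect_length(out$memory, 1)
  expect_equal(out$memory[[1]]$p, 1)
  expect_equal(out$memory[[1]]$age, 0L)

  # Re-matched memory: p <- eta1 + eta2 * p = 1 + 0.5 * 2 = 2.
  pop2 <- qais_population(
    memory = list(detector(c(1L, 1L), p = 2, age = 4L)),
    eta1 = 1, eta2 = 0.5, gamma = 0.7
  )
  out2 <- promote_and_reinforce(pop2, antigens = list(c(1L, 1L)))
  expect_equal(out2$memory[[1]]$p, 2)
  expect_equal(out2$memory[[1]]$age, 0L)
})

test_that("concentration decay ages detectors toward zero", {
  d <- detector(c(1L), p = 10, age = 1L)
  out <- concentration_decay(d, theta_decay = 5)
  expect_equal(out$p, 10 * (1 - 1 / 4))
  expect_equal(out$p, 7.5)
  expect_equal(out$age, 2L)

  d2 <- detector(c(1L), p = 3, age = 4L)
  expect_equal(concentration_decay(d2, 5)$p, 0)
  d3 <- detector(c(1L), p = 3, age = 9L)
  expect_equal(concentration_decay(d3, 5)$p, 0)
})

test_that("schedules decay linearly across the iteration budget", {
  expect_equal(inertial_weight(0, 10), 0.9)
  expect_equal(inertial_weight(10, 10), 0.1)
  expect_equal(inertial_weight(5, 10), 0.5)
  expect_error(inertial_weight(11, 10))

  expect_equal(cbest(0, 10), 2)
  expect_equal(cbest(10, 10), 0)
  expect_equal(cbest(5, 10), 1)

  w <- vapply(0:20, inertial_weight, numeric(1), MI = 20)
  cb <- vapply(0:20, cbest, numeric(1), MI = 20)
  expect_true(all(diff(w) < 0))
  expect_true(all(diff(cb) < 0))
})

test_that("position update attracts toward gbest and respects bounds", {
  b <- list(lower = -1, upper = 1)
  expect_equal(position_update(0.4, 0.4, 3, 10, b, alpha_rand = 0), 0.4)
  expect_equal(position_update(0, 1, 0, 10, b, alpha_rand = 0), 0.9)
  expect_equal(position_update(0, 1, 10, 10, b, alpha_rand = 0), 0.1)

  set.seed(8)
  for (k in 1:20) {
    X <- matrix(runif(10, -1, 1), 5, 2)
    out <- position_update(X, c(0.5, -0.5), sample(0:9, 1), 10,
                           list(lower = c(-1, -1), upper = c(1, 1)),
                           alpha_rand = 2)
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("optimizer is elitist and solves the 8-bit toy exactly", {
  r <- qais_optimize(function(x) sum(x^2),
                     bounds = list(lower = c(-1, -1), upper = c(1, 1)),
                     pop_size = 40, iters = 15, seed = 2)
  expect_true(all(diff(r$trace) <= 1e-12))
  expect_lte(r$value, 0.05)

  # Additive 8-bit feature-selection toy against exhaustive enumeration.
  weights <- c(3, 2, 1.5, -1, -1, -1, -1, -1)
  obj <- function(bits) sum(bits * weights)
  r2 <- qais_optimize(obj, length = 8, pop_size = 100, iters = 10, seed = 5,
                      minimize = FALSE)
  masks <- as.matrix(expand.grid(rep(list(0:1), 8)))
  expect_equal(r2$value, max(apply(masks, 1, obj)))
  expect_true(all(diff(-r2$trace) <= 1e-12)) # maximization trace monotone

  # Negative selection honours a forbidden self pattern.
  r3 <- qais_optimize(obj, length = 8, pop_size = 60, iters = 5, seed = 3,
                      minimize = FALSE,
                      self = list(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)))
  expect_lte(affinity(r3$best, c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)), 0.7)
})

test_that("decision-layer tuning is elitist over the identity model", {
  ds <- small_dataset(n = 6, seed = 17, size = 48, noise = 25)
  model <- dsnn_train(ds, small_net_config(seed = 17))
  val <- ds[model$train_idx[3:4]]

  id <- tune_decision_layer(model, val, seed = 1, iters = 0)
  t0 <- attr(id, "tuning")
  expect_true(t0$identity)
  expect_equal(t0$tuned_dice, t0$untuned_dice)
  expect_identical(id$beta, model$beta)

  tuned <- tune_decision_layer(model, val, seed = 1, pop_size = 30, iters = 3)
  tt <- attr(tuned, "tuning")
  expect_gte(tt$tuned_dice, tt$untuned_dice)
  expect_error(tune_decision_layer(model, list(), seed = 1), "empty")
})

test_that("qais mask search matches exhaustive search on an 8-feature model", {
  ds <- small_dataset(n = 6, seed = 29, size = 48, noise = 30)
  cfg <- net_config(n_filters1 = 2, n_filters2 = 2, n_hidden = 8,
                    pixels_per_image = 400, seed = 29)
  model <- dsnn_train(ds, cfg)
  val <- ds[model$train_idx[3:4]]

  # Independent exhaustive oracle over all 2^8 feature masks.
  G <- crossprod(model$train_H)
  R <- crossprod(model$train_H, model$train_Y)
  val_H <- lapply(val, function(ph) {
    X <- extract_features(ph$noisy, model$config, model$bank)
    hidden_map(X, model$W, model$b, function(z) 1 / (1 + exp(-z)))
  })
  score_mask <- function(mask) {
    if (!any(mask)) return(0)
    beta <- solve(G[mask, mask, drop = FALSE] +
                    cfg$ridge * diag(sum(mask)), R[mask, , drop = FALSE])
    mean(vapply(seq_along(val), function(i) {
      S <- val_H[[i]][, mask, drop = FALSE] %*% beta
      lab <- model$classes[max.col(S, ties.method = "first")]
      dice(matrix(lab %in% 2:4, 48, 48), region_masks(val[[i]]$labels)$WT)
    }, numeric(1)))
  }
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  best_exhaustive <- max(apply(masks, 1, score_mask))

  tuned <- tune_decision_layer(model, val, seed = 4, pop_size = 60, iters = 6)
  expect_gte(attr(tuned, "tuning")$tuned_dice, best_exhaustive - 0.02)
})
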