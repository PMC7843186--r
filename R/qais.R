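# Quantum Artificial Immune System (QAIS) optimizer.
#
# Detector populations over bit strings with negative selection (tolerance
# against a self set), clonal selection with rank-proportional clone counts,
# immune mutation restricted to antigen-mismatched bits, memory promotion and
# reinforcement, and concentration decay. Continuous problems use the
# schedule updates: a linearly decaying inertial weight on [0.1, 0.9], the
# decaying exploration coefficient C_best = 2 (1 - J / MI), and a
# gbest-attraction position update with bound-relative randomization.

#' Bit-string affinity
#'
#' Fraction of matching bits (1 - normalized Hamming distance).
#'
#' @param ab,ag Equal-length 0/1 integer vectors (antibody, antigen).
#' @return Value in [0, 1].
#' @export
affinity <- function(ab, ag) {
  if (length(ab) != length(ag)) {
    stop("antibody and antigen lengths differ")
  }
  mean(ab == ag)
}

#' Match predicate
#'
#' 1 iff `affinity(ab, ag) > gamma` (strictly); equality does not match.
#'
#' @param ag,ab Equal-length bit vectors.
#' @param gamma Correlation threshold in [0, 1].
#' @return 0 or 1.
#' @export
f_match <- function(ag, ab, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  as.integer(affinity(ab, ag) > gamma)
}

#' Immune detector record
#'
#' @param ab 0/1 integer vector (antibody).
#' @param p Concentration (>= 0).
#' @param t Tolerance counter.
#' @param age Age since last reinforcement.
#' @param cnt Match count.
#' @return List of class `detector`.
#' @export
detector <- function(ab, p = 0, t = 0L, age = 0L, cnt = 0L) {
  stopifnot(all(ab %in% c(0L, 1L)), p >= 0, t >= 0, age >= 0, cnt >= 0)
  structure(list(ab = as.integer(ab), p = p, t = as.integer(t),
                 age = as.integer(age), cnt = as.integer(cnt)),
            class = "detector")
}

#' Detector population
#'
#' Holds the three pairwise-disjoint detector sets (immature, mature,
#' memory), the self/non-self antigen sets and the immune thresholds.
#'
#' @param immature,mature,memory Lists of [detector()]s.
#' @param self_set,nonself_set Lists of bit vectors (antigens); must be
#'   disjoint.
#' @param alpha Tolerance threshold (exposures before maturation).
#' @param lam_life Detector life cycle (ages).
#' @param beta_act Activation threshold: matures with `cnt > beta_act` are
#'   promoted to memory.
#' @param gamma Affinity threshold of [f_match()].
#' @param eta1,eta2 Memory reinforcement constants.
#' @param theta_decay Concentration decay horizon (ages).
#' @param xi Clone constant of [clone_count()].
#' @return List of class `qais_population`.
#' @export
qais_population <- function(immature = list(), mature = list(),
                            memory = list(), self_set = list(),
                            nonself_set = list(), alpha = 3, lam_life = 30,
                            beta_act = 5, gamma = 0.7, eta1 = 1.0,
                            eta2 = 0.5, theta_decay = 20, xi = 8) {
  stopifnot(alpha >= 1, beta_act >= 0, gamma >= 0, gamma <= 1,
            theta_decay > 0, xi >= 0)
  if (length(self_set) && length(nonself_set)) {
    for (s in self_set) {
      for (ns in nonself_set) {
        if (length(s) == length(ns) && all(s == ns)) {
          stop("self and nonself antigen sets must be disjoint")
        }
      }
    }
  }
  structure(
    list(immature = immature, mature = mature, memory = memory,
         self_set = self_set, nonself_set = nonself_set,
         alpha = alpha, lam_life = lam_life, beta_act = beta_act,
         gamma = gamma, eta1 = eta1, eta2 = eta2,
         theta_decay = theta_decay, xi = xi),
    class = "qais_population"
  )
}

#' @export
print.qais_population <- function(x, ...) {
  cat(sprintf("<qais_population> immature %d | mature %d | memory %d\n",
              length(x$immature), length(x$mature), length(x$memory)))
  invisible(x)
}

#' Negative-selection tolerance step
#'
#' Immature detectors matching any self antigen are deleted; survivors get
#' `t <- t + 1`, and detectors reaching `t >= alpha` graduate from the
#' immature to the mature set.
#'
#' @param pop A [qais_population()].
#' @return Updated population.
#' @export
tolerance_step <- function(pop) {
  stopifnot(inherits(pop, "qais_population"))
  keep <- list()
  for (d in pop$immature) {
    matches_self <- any(vapply(pop$self_set, function(s) {
      length(s) == length(d$ab) && f_match(s, d$ab, pop$gamma) == 1L
    }, logical(1)))
    if (matches_self) next
    d$t <- d$t + 1L
    if (d$t >= pop$alpha) {
      pop$mature[[length(pop$mature) + 1L]] <- d
    } else {
      keep[[length(keep) + 1L]] <- d
    }
  }
  pop$immature <- keep
  pop
}

#' Rank-proportional clone count
#'
#' `round(xi * (1 - n_d / N_d))`, floored at zero: the best-ranked detector
#' (`n_d = 0`) receives `round(xi)` clones, the worst none.
#'
#' @param rank_nd Affinity rank of the detector (0 = best).
#' @param total_Nd Size of the ranked set (>= 1).
#' @param xi Clone constant (>= 0).
#' @return Non-negative integer.
#' @export
clone_count <- function(rank_nd, total_Nd, xi) {
  stopifnot(rank_nd >= 0, total_Nd >= 1, rank_nd <= total_Nd, xi >= 0)
  max(0L, as.integer(round(xi * (1 - rank_nd / total_Nd))))
}

# Rank detectors (0 = best) by max affinity to antigens, else concentration.
rank_detectors <- function(detectors, antigens) {
  score <- vapply(detectors, function(d) {
    if (length(antigens)) {
      max(vapply(antigens, function(ag) affinity(d$ab, ag), numeric(1)))
    } else {
      d$p
    }
  }, numeric(1))
  ord <- order(score, decreasing = TRUE)
  rank <- integer(length(detectors))
  rank[ord] <- seq_along(detectors) - 1L
  rank
}

#' Clonal selection
#'
#' Clones mature and memory detectors in proportion to their affinity rank
#' ([clone_count()] over `N_d` = mature plus memory); the clone sets are
#' added to the mature pool and cloned mature parents are removed, so a
#' single mature parent with `xi = 2` is replaced by its two clones.
#'
#' @param pop A [qais_population()].
#' @param antigens List of antigen bit vectors used for affinity ranking
#'   (when empty, ranking falls back to detector concentration).
#' @return Updated population.
#' @export
clonal_selection <- function(pop, antigens = pop$nonself_set) {
  stopifnot(inherits(pop, "qais_population"))
  if (pop$xi == 0) {
    return(pop)
  }
  nd <- c(pop$mature, pop$memory)
  if (!length(nd)) {
    return(pop)
  }
  from_mature <- c(rep(TRUE, length(pop$mature)), rep(FALSE, length(pop$memory)))
  rank <- rank_detectors(nd, antigens)
  total <- length(nd)
  clones <- list()
  cloned_mature <- logical(length(pop$mature))
  for (i in seq_along(nd)) {
    cn <- clone_count(rank[i], total, pop$xi)
    if (cn > 0L) {
      for (k in seq_len(cn)) {
        clones[[length(clones) + 1L]] <- nd[[i]]
      }
      if (from_mature[i]) {
        cloned_mature[i] <- TRUE
      }
    }
  }
  pop$mature <- c(pop$mature[!cloned_mature], clones)
  pop
}

#' Immune mutation
#'
#' Only the bits where detector and antigen disagree are eligible; each
#' eligible bit flips (toward the antigen) independently with probability
#' `p_mut`. Matched bits never change, so `p_mut = 1` returns the antigen
#' and `p_mut = 0` the unchanged detector.
#'
#' @param d A [detector()].
#' @param ag Antigen bit vector of the same length.
#' @param p_mut Per-bit flip probability in [0, 1].
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return Mutated detector.
#' @export
immune_mutation <- function(d, ag, p_mut = 0.1, seed = NULL) {
  stopifnot(inherits(d, "detector"), p_mut >= 0, p_mut <= 1,
            length(ag) == length(d$ab))
  local_seed(seed, {
    eligible <- which(d$ab != ag)
    if (length(eligible)) {
      flip <- eligible[stats::runif(length(eligible)) < p_mut]
      d$ab[flip] <- as.integer(ag[flip])
    }
    d
  })
}

#' Memory promotion and reinforcement
#'
#' Mature detectors with `cnt > beta_act` (strictly) move to the memory set
#' with concentration `eta1` and age 0. Memory detectors re-matched by any
#' antigen of the current batch are reinforced:
#' `p <- eta1 + eta2 * p`, `age <- 0`.
#'
#' @param pop A [qais_population()].
#' @param antigens Current antigen batch deciding which memory detectors are
#'   re-matched (default: the population's non-self set).
#' @return Updated population.
#' @export
promote_and_reinforce <- function(pop, antigens = pop$nonself_set) {
  stopifnot(inherits(pop, "qais_population"))
  staying <- list()
  for (d in pop$mature) {
    if (d$cnt > pop$beta_act) {
      d$p <- pop$eta1
      d$age <- 0L
      pop$memory[[length(pop$memory) + 1L]] <- d
    } else {
      staying[[length(staying) + 1L]] <- d
    }
  }
  pop$mature <- staying
  if (length(antigens)) {
    pop$memory <- lapply(pop$memory, function(d) {
      rematched <- any(vapply(antigens, function(ag) {
        length(ag) == length(d$ab) && f_match(ag, d$ab, pop$gamma) == 1L
      }, logical(1)))
      if (rematched) {
        d$p <- pop$eta1 + pop$eta2 * d$p
        d$age <- 0L
      }
      d
    })
  }
  pop
}

#' Concentration decay
#'
#' Ages the detector by one step; while the new age stays below the horizon
#' `theta_decay` the concentration decays as
#' `p <- p * (1 - 1 / (theta_decay - age_old))`, otherwise it drops to zero.
#'
#' @param d A [detector()].
#' @param theta_decay Decay horizon (> 0).
#' @return Aged detector.
#' @export
concentration_decay <- function(d, theta_decay) {
  stopifnot(inherits(d, "detector"), theta_decay > 0)
  age_old <- d$age
  d$age <- d$age + 1L
  d$p <- if (d$age < theta_decay) {
    d$p * (1 - 1 / (theta_decay - age_old))
  } else {
    0
  }
  d
}

#' Linearly decaying inertial weight
#'
#' `0.9 - (0.9 - 0.1) / MI * J`: 0.9 at the first iteration (exploration),
#' 0.1 at the last (exploitation).
#'
#' @param J Current iteration, `0 <= J <= MI`.
#' @param MI Maximum iterations (>= 1).
#' @return Weight in [0.1, 0.9].
#' @export
inertial_weight <- function(J, MI) {
  stopifnot(MI >= 1)
  if (J < 0 || J > MI) {
    stop("J must lie in [0, MI]")
  }
  0.9 - (0.9 - 0.1) / MI * J
}

#' Decaying exploration coefficient
#'
#' `C_best = 2 * (1 - J / MI)`, from 2 down to 0.
#'
#' @inheritParams inertial_weight
#' @return Value in [0, 2].
#' @export
cbest <- function(J, MI) {
  stopifnot(MI >= 1, J >= 0, J <= MI)
  2 * (1 - J / MI)
}

#' Schedule-driven position update
#'
#' Moves positions toward the global best with the inertial weight and adds
#' bound-relative randomization: with step scale
#' `Delta = cbest(J, MI) * mean(UB - LB)`,
#' `X' = X + w(J) (X_gbest - X) + alpha_rand * Delta * (U - 0.5)`,
#' clipped to the bounds per coordinate.
#'
#' @param X Numeric vector or `pop x NV` matrix of positions.
#' @param X_gbest Global-best position (length NV).
#' @param J,MI Iteration schedule (see [inertial_weight()]).
#' @param bounds List with numeric vectors `lower`, `upper` (length NV).
#' @param alpha_rand Randomization amplitude (>= 0).
#' @param seed Optional seed for the uniform draws.
#' @return Updated positions, same shape as `X`, within bounds.
#' @export
position_update <- function(X, X_gbest, J, MI, bounds, alpha_rand = 0.5,
                            seed = NULL) {
  vec <- !is.matrix(X)
  if (vec) {
    X <- matrix(X, nrow = 1)
  }
  nv <- ncol(X)
  lower <- rep_len(bounds$lower, nv)
  upper <- rep_len(bounds$upper, nv)
  stopifnot(all(lower < upper), length(X_gbest) == nv, alpha_rand >= 0)
  X <- pmin(pmax(X, matrix(lower, nrow(X), nv, byrow = TRUE)),
            matrix(upper, nrow(X), nv, byrow = TRUE))
  w <- inertial_weight(J, MI)
  delta <- cbest(J, MI) * mean(upper - lower)
  out <- local_seed(seed, {
    G <- matrix(X_gbest, nrow(X), nv, byrow = TRUE)
    U <- matrix(stats::runif(length(X)), nrow(X), nv)
    X + w * (G - X) + alpha_rand * delta * (U - 0.5)
  })
  out <- pmin(pmax(out, matrix(lower, nrow(X), nv, byrow = TRUE)),
              matrix(upper, nrow(X), nv, byrow = TRUE))
  if (vec) out[1, ] else out
}

#' QAIS optimization
#'
#' Minimizes (or maximizes) a user objective by the immune cycle: tolerance,
#' clonal selection, immune mutation, memory promotion and concentration
#' decay per iteration, with the schedule updates
#' ([inertial_weight()], [cbest()], [position_update()]) driving continuous
#' variables. The search is elitist: the best solution seen is never lost.
#'
#' Two problem encodings are supported: continuous (supply `bounds`) and
#' bit-string (supply `length`). Bit-string mode keeps a full detector
#' population; mutation is directed toward the current best antibody
#' (exploitation) with additional random flips and immigrant detectors for
#' diversity, and a `self` set of forbidden patterns is honoured by negative
#' selection.
#'
#' @param objective Function mapping a numeric vector (continuous) or 0/1
#'   integer vector (bit-string) to a scalar score.
#' @param bounds List with `lower`, `upper` vectors for continuous problems.
#' @param length Bit-string length for discrete problems.
#' @param pop_size Population size (default 200).
#' @param clone_rate Colonial rate; the clone constant is
#'   `xi = max(1, round(clone_rate * pop_size))` (default 0.04).
#' @param iters Immune cycles (default 10).
#' @param seed Integer seed.
#' @param minimize Minimize (`TRUE`, default) or maximize.
#' @param p_mut Immune-mutation per-bit flip probability.
#' @param alpha_rand Randomization amplitude of the position update.
#' @param self Optional list of forbidden bit patterns (bit-string mode).
#' @return List with `best` (solution), `value` (its objective), and
#'   `trace`, the per-iteration best-so-far objective (monotone).
#' @examples
#' res <- qais_optimize(function(x) sum((x - 0.3)^2),
#'                      bounds = list(lower = -1, upper = 1),
#'                      pop_size = 50, iters = 10, seed = 1)
#' res$best
#' @export
qais_optimize <- function(objective, bounds = NULL, length = NULL,
                          pop_size = 200, clone_rate = 0.04, iters = 10,
                          seed = 1, minimize = TRUE, p_mut = 0.1,
                          alpha_rand = 0.5, self = list()) {
  stopifnot(pop_size >= 2, iters >= 0, xor(is.null(bounds), is.null(length)))
  sgn <- if (minimize) 1 else -1
  f <- function(x) sgn * objective(x)
  if (!is.null(bounds)) {
    optimize_continuous(f, bounds, pop_size, clone_rate, iters, seed,
                        alpha_rand, sgn)
  } else {
    optimize_bits(f, length, pop_size, clone_rate, iters, seed, p_mut,
                  self, sgn)
  }
}

optimize_continuous <- function(f, bounds, pop_size, clone_rate, iters, seed,
                                alpha_rand, sgn) {
  nv <- max(length(bounds$lower), length(bounds$upper))
  lower <- rep_len(bounds$lower, nv)
  upper <- rep_len(bounds$upper, nv)
  xi <- max(1L, as.integer(round(clone_rate * pop_size)))
  local_seed(seed, {
    X <- matrix(stats::runif(pop_size * nv), pop_size, nv)
    X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
    fit <- apply(X, 1, f)
    bi <- which.min(fit)
    gbest <- X[bi, ]
    gval <- fit[bi]
    trace <- numeric(iters)
    if (iters > 0) {
      for (J in seq_len(iters)) {
        # Clonal expansion: the top-ranked positions spawn jittered clones.
        ord <- order(fit)
        clones <- list()
        for (r in seq_len(min(pop_size, 2L * xi))) {
          cn <- clone_count(r - 1L, pop_size, xi)
          if (cn == 0L) next
          parent <- X[ord[r], ]
          for (k in seq_len(cn)) {
            jitter <- stats::rnorm(nv, 0, 0.1 * (upper - lower) * (1 - (J - 1) / iters))
            clones[[length(clones) + 1L]] <- pmin(pmax(parent + jitter, lower), upper)
          }
        }
        if (length(clones)) {
          Xc <- do.call(rbind, clones)
          fc <- apply(Xc, 1, f)
          X <- rbind(X, Xc)
          fit <- c(fit, fc)
        }
        # Schedule-driven move toward gbest, then survivor selection.
        X <- position_update(X, gbest, J - 1, iters, list(lower = lower, upper = upper),
                             alpha_rand)
        fit <- apply(X, 1, f)
        keep <- order(fit)[seq_len(pop_size)]
        X <- X[keep, , drop = FALSE]
        fit <- fit[keep]
        if (fit[1] < gval) {
          gval <- fit[1]
          gbest <- X[1, ]
        }
        # Elitism: re-inject the best-so-far.
        X[pop_size, ] <- gbest
        fit[pop_size] <- gval
        trace[J] <- gval
      }
    }
    list(best = gbest, value = sgn * gval, trace = sgn * trace)
  })
}

optimize_bits <- function(f, l, pop_size, clone_rate, iters, seed, p_mut,
                          self, sgn) {
  xi <- max(1L, as.integer(round(clone_rate * pop_size)))
  local_seed(seed, {
    pop <- qais_population(self_set = self, xi = xi, alpha = 1)
    pop$immature <- lapply(seq_len(pop_size), function(i) {
      detector(as.integer(stats::runif(l) < 0.5))
    })
    pop <- tolerance_step(pop) # negative selection against forbidden patterns
    cache <- new.env(parent = emptyenv())
    f_cached <- function(bits) {
      key <- paste(bits, collapse = "")
      got <- cache[[key]]
      if (is.null(got)) {
        got <- f(bits)
        cache[[key]] <- got
      }
      got
    }
    evaluate <- function(dets) vapply(dets, function(d) f_cached(d$ab), numeric(1))
    fit <- evaluate(pop$mature)
    if (!length(fit)) {
      stop("no detector survived negative selection")
    }
    bi <- which.min(fit)
    gbest <- pop$mature[[bi]]$ab
    gval <- fit[bi]
    trace <- numeric(iters)
    if (iters > 0) {
      for (J in seq_len(iters)) {
        # Concentration encodes fitness so clonal ranking follows quality.
        rk <- rank(fit, ties.method = "first") # 1 = best (lowest internal fit)
        for (i in seq_along(pop$mature)) {
          pop$mature[[i]]$p <- (length(fit) - rk[i] + 1) / length(fit)
        }
        pop <- clonal_selection(pop, antigens = list())
        # Immune mutation of the clones toward the best antibody, plus
        # undirected background flips for diversity.
        if (length(pop$mature) > 0) {
          pop$mature <- lapply(pop$mature, function(d) {
            d <- immune_mutation(d, gbest, p_mut)
            flips <- which(stats::runif(l) < 0.02)
            d$ab[flips] <- 1L - d$ab[flips]
            d
          })
        }
        # Negative-selection soundness: mutated/cloned detectors matching a
        # forbidden self pattern are culled from the working set too.
        if (length(pop$self_set)) {
          ok <- vapply(pop$mature, function(d) {
            !any(vapply(pop$self_set, function(s) {
              length(s) == length(d$ab) && f_match(s, d$ab, pop$gamma) == 1L
            }, logical(1)))
          }, logical(1))
          if (any(ok)) {
            pop$mature <- pop$mature[ok]
          }
        }
        # Immigrants: fresh immature detectors pass negative selection.
        pop$immature <- lapply(seq_len(max(2L, pop_size %/% 20L)), function(i) {
          detector(as.integer(stats::runif(l) < 0.5))
        })
        pop <- tolerance_step(pop)
        fit <- evaluate(pop$mature)
        # Promotion / decay bookkeeping.
        best_now <- which.min(fit)
        pop$mature[[best_now]]$cnt <- pop$mature[[best_now]]$cnt + 1L
        pop <- promote_and_reinforce(pop, antigens = list())
        pop$memory <- lapply(pop$memory, concentration_decay,
                             theta_decay = pop$theta_decay)
        fit <- evaluate(pop$mature)
        # Survivor selection back to pop_size, elitist.
        keep <- order(fit)[seq_len(min(pop_size, length(fit)))]
        pop$mature <- pop$mature[keep]
        fit <- fit[keep]
        if (fit[1] < gval) {
          gval <- fit[1]
          gbest <- pop$mature[[1]]$ab
        }
        pop$mature[[length(pop$mature)]] <- detector(gbest)
        fit[length(fit)] <- gval
        trace[J] <- gval
      }
    }
    list(best = gbest, value = sgn * gval, trace = sgn * trace)
  })
}

#' Immune tuning of the decision layer
#'
#' Uses QAIS to tune a trained segmentation model against validation
#' phantoms: a bit mask over the hidden features (output weights re-solved on
#' the masked features per candidate) followed by per-class logit offsets,
#' both maximizing the mean validation whole-tumor Dice. The identity
#' configuration (all features, zero offsets) is always a candidate, so the
#' tuned validation Dice never falls below the untuned one.
#'
#' @param model A trained `seg_model` (must carry the cached training
#'   design).
#' @param val_set Non-empty list of phantoms with ground-truth labels.
#' @param seed Integer seed.
#' @param pop_size,clone_rate,iters QAIS settings (defaults 200, 0.04, 10).
#' @param offset_range Half-width of the logit-offset search box.
#' @return The tuned `seg_model`, with attributes `tuning` (list with the
#'   untuned and tuned validation Dice and the optimizer traces).
#' @export
tune_decision_layer <- function(model, val_set, seed = 1, pop_size = 200,
                                clone_rate = 0.04, iters = 10,
                                offset_range = 1) {
  stopifnot(inherits(model, "seg_model"))
  if (!length(val_set)) {
    stop("validation set is empty")
  }
  m <- ncol(model$train_H)
  g <- activation_fn(model$config$activation)
  # Cache validation hidden activations and truth masks once.
  val_H <- lapply(val_set, function(ph) {
    X <- extract_features(model_channels(ph), model$config, model$bank)
    hidden_map(X, model$W, model$b, g)
  })
  val_truth <- lapply(val_set, function(ph) region_masks(ph$labels)$WT)
  val_shape <- lapply(val_set, function(ph) dim(ph$labels))

  # Precomputed normal-equation blocks: masked solves then cost O(|mask|^3),
  # independent of the number of training pixels.
  G <- crossprod(model$train_H)
  R <- crossprod(model$train_H, model$train_Y)
  ridge <- model$config$ridge

  masked_solve <- function(mask) {
    if (ridge > 0) {
      solve(G[mask, mask, drop = FALSE] + ridge * diag(sum(mask)),
            R[mask, , drop = FALSE])
    } else {
      solve_output_weights(model$train_H[, mask, drop = FALSE],
                           model$train_Y, 0)
    }
  }

  score_candidate <- function(mask, offsets) {
    if (!any(mask)) {
      return(0)
    }
    beta <- masked_solve(mask)
    mean(vapply(seq_along(val_set), function(i) {
      S <- val_H[[i]][, mask, drop = FALSE] %*% beta
      S <- sweep(S, 2, offsets, "+")
      lab <- model$classes[max.col(S, ties.method = "first")]
      pred_wt <- matrix(lab %in% c(2L, 3L, 4L), val_shape[[i]][1],
                        val_shape[[i]][2])
      dice(pred_wt, val_truth[[i]])
    }, numeric(1)))
  }

  zero_off <- rep(0, length(model$classes))
  untuned <- score_candidate(rep(TRUE, m), zero_off)
  if (iters == 0) {
    attr(model, "tuning") <- list(untuned_dice = untuned,
                                  tuned_dice = untuned, identity = TRUE)
    return(model)
  }

  # Phase 1: feature mask (bit-string QAIS; identity mask seeds elitism).
  mask_obj <- function(bits) score_candidate(bits == 1L, zero_off)
  res_mask <- qais_optimize(mask_obj, length = m, pop_size = pop_size,
                            clone_rate = clone_rate, iters = iters,
                            seed = derive_seed(seed, 1L), minimize = FALSE)
  best_mask <- if (res_mask$value >= untuned) res_mask$best == 1L else rep(TRUE, m)
  mask_dice <- max(res_mask$value, untuned)

  # Phase 2: per-class logit offsets (continuous QAIS; zero is a candidate).
  off_obj <- function(x) score_candidate(best_mask, x)
  res_off <- qais_optimize(off_obj,
                           bounds = list(lower = rep(-offset_range, length(zero_off)),
                                         upper = rep(offset_range, length(zero_off))),
                           pop_size = max(20L, pop_size %/% 4L),
                           clone_rate = clone_rate, iters = iters,
                           seed = derive_seed(seed, 2L), minimize = FALSE)
  best_off <- if (res_off$value >= mask_dice) res_off$best else zero_off
  tuned <- max(res_off$value, mask_dice)

  model$feature_mask <- best_mask
  model$logit_offsets <- best_off
  model$beta <- matrix(0, m, length(model$classes))
  model$beta[best_mask, ] <- masked_solve(best_mask)
  attr(model, "tuning") <- list(
    untuned_dice = untuned, tuned_dice = tuned,
    mask_trace = res_mask$trace, offset_trace = res_off$trace,
    n_features = sum(best_mask)
  )
  model
}
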