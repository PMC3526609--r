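# a small fully-specified fixture: 2 miRs, 2 genes, 3 stages (chain A->B
# plus branch A->C), 2 samples per stage, 2 replicates each
core_fixture <- function(seed = 101) {
  set.seed(seed)
  order <- partial_order(
    c("A", "B", "C"), parents = list(B = "A", C = "A"),
    members = list(A = c("sA1", "sA2"), B = c("sB1", "sB2"),
                   C = c("sC1", "sC2")))
  preds <- prediction_set(data.frame(
    mir = c("m1", "m2", "m1"), gene = c("G1", "G1", "G2"),
    algorithm = "alg", score = c(-0.4, -0.9, -0.2)))
  stages <- c("A", "B", "C")
  x <- matrix(rnorm(6), 2, 3, dimnames = list(c("m1", "m2"), stages))
  y <- matrix(rnorm(6), 2, 3, dimnames = list(c("G1", "G2"), stages))
  state <- latent_state(
    x = x, y = y,
    tau = c(m1 = 0.4, m2 = -0.2),
    lambda_mir = c(m1 = 3, m2 = 5), lambda_mrna = c(G1 = 2, G2 = 4),
    delta_mir = c("A->B" = 0.8, "A->C" = 1.3),
    delta_mrna = c("A->B" = 1.1, "A->C" = 0.7),
    r = c(-0.6, 0.2, -0.3), beta = c(-0.5, 1),
    phi_r = 4, phi_set_mir = 5, phi_set_mrna = 6,
    phi_rep_mir = 9, phi_rep_mrna = 7)
  samples <- unlist(order$members)
  obs <- expand.grid(rep = 1:2, sample = samples, stringsAsFactors = FALSE)
  obs_ids <- sprintf("%s_r%d", obs$sample, obs$rep)
  ann <- data.frame(observation_id = obs_ids, sample_id = obs$sample,
                    stage = rep(rep(stages, each = 2), each = 2),
                    replicate_id = as.character(obs$rep),
                    stringsAsFactors = FALSE)
  sos <- c(sA1 = "A", sA2 = "A", sB1 = "B", sB2 = "B", sC1 = "C", sC2 = "C")
  zm <- x[, sos[obs$sample]] + matrix(rnorm(2 * 12, 0, 0.3), 2)
  zr <- y[, sos[obs$sample]] + matrix(rnorm(2 * 12, 0, 0.3), 2)
  colnames(zm) <- colnames(zr) <- obs_ids
  data <- expression_dataset(expression_matrix(zm, platform = "miR"),
                             expression_matrix(zr, platform = "mRNA"), ann)
  list(order = order, preds = preds, state = state, data = data)
}

test_that("miR stage prior implements the inverse-development weighting", {
  fx <- core_fixture()
  st <- fx$state
  # one parent: mean = x_parent + tau * delta, precision = lambda / delta
  st$x["m1", "A"] <- 1.0
  st$tau["m1"] <- 0.5
  st$delta_mir["A->B"] <- 2
  pr <- mir_stage_prior("m1", "B", st, fx$order)
  expect_equal(pr[["mean"]], 1.0 + 0.5 * 2)
  expect_equal(pr[["precision"]], st$lambda_mir[["m1"]] / 2)

  # two parents with equal developments and zero trend average equally
  ord2 <- partial_order(c("A", "B", "C"),
                        parents = list(C = c("A", "B")))
  st2 <- st
  st2$tau["m1"] <- 0
  st2$delta_mir <- c("A->C" = 1.5, "B->C" = 1.5)
  a <- st2$x["m1", "A"]; b <- st2$x["m1", "B"]
  pr2 <- mir_stage_prior("m1", "C", st2, ord2)
  expect_equal(pr2[["mean"]], (a + b) / 2)

  # a distant parent's influence on the mean vanishes, and precision
  # drops to that of the remaining parent alone
  st3 <- st2
  st3$delta_mir <- c("A->C" = 1e6, "B->C" = 1.5)
  pr3 <- mir_stage_prior("m1", "C", st3, ord2)
  expect_equal(pr3[["mean"]], b, tolerance = 1e-5)
  expect_equal(pr3[["precision"]],
               st3$lambda_mir[["m1"]] * (1 / 1.5 + 1e-6), tolerance = 1e-9)

  # initial stage: vague zero-centred prior
  pr0 <- mir_stage_prior("m1", "A", st, fx$order)
  expect_equal(pr0[["mean"]], 0)
  expect_equal(pr0[["precision"]],
               default_hyperparameters()$normal_prior_precision)
})

test_that("mRNA stage prior swaps the trend for the interaction effect", {
  fx <- core_fixture()
  st <- fx$state
  # zero interactions reduce the mean to the miR formula with tau = 0
  st0 <- st; st0$r <- c(0, 0, 0)
  pr <- mrna_stage_prior("G1", "B", st0, fx$order, fx$preds)
  d <- st$delta_mrna[["A->B"]]
  expect_equal(pr[["mean"]], st$y["G1", "A"])
  expect_equal(pr[["precision"]], st$lambda_mrna[["G1"]] / d)

  # one parent: mean = y_parent + (r . x_child) * delta
  dot <- sum(st$r[1:2] * st$x[c("m1", "m2"), "B"])
  pr1 <- mrna_stage_prior("G1", "B", st, fx$order, fx$preds)
  expect_equal(pr1[["mean"]], st$y["G1", "A"] + dot * d)

  # hand evaluation with a forced dot product of -0.7 and y_parent = 0
  st2 <- st
  st2$y["G1", "A"] <- 0
  st2$delta_mrna[["A->B"]] <- 1
  st2$r <- c(-0.7, 0, 0)
  st2$x["m1", "B"] <- 1
  pr2 <- mrna_stage_prior("G1", "B", st2, fx$order, fx$preds)
  expect_equal(pr2[["mean"]], -0.7)

  # two equal-delta parents: mean (a+b)/2 + dot * delta
  ord2 <- partial_order(c("A", "B", "C"), parents = list(C = c("A", "B")))
  st3 <- st
  st3$delta_mrna <- c("A->C" = 1.2, "B->C" = 1.2)
  dot3 <- sum(st3$r[1:2] * st3$x[c("m1", "m2"), "C"])
  pr3 <- mrna_stage_prior("G1", "C", st3, ord2, fx$preds)
  expect_equal(pr3[["mean"]],
               mean(st3$y["G1", c("A", "B")]) + dot3 * 1.2)
})

test_that("stage-prior weights are convex and precision rises as a development shrinks", {
  fx <- core_fixture()
  ord2 <- partial_order(c("A", "B", "C"), parents = list(C = c("A", "B")))
  st <- fx$state
  st$tau["m1"] <- 0
  grid <- c(0.3, 0.7, 1.9)
  for (d1 in grid) for (d2 in grid) {
    st$delta_mir <- c("A->C" = d1, "B->C" = d2)
    w <- (1 / c(d1, d2)) / sum(1 / c(d1, d2))
    pr <- mir_stage_prior("m1", "C", st, ord2)
    expect_equal(pr[["mean"]], sum(w * st$x["m1", c("A", "B")]))
    # shrinking one development strictly increases the precision
    st_small <- st
    st_small$delta_mir["A->C"] <- d1 / 2
    expect_gt(mir_stage_prior("m1", "C", st_small, ord2)[["precision"]],
              pr[["precision"]])
  }
  # single parent at delta = 1: precision is exactly lambda
  st$delta_mir <- c("A->B" = 1, "A->C" = 1)
  expect_equal(mir_stage_prior("m1", "B", st, fx$order)[["precision"]],
               st$lambda_mir[["m1"]])
})

test_that("observation likelihood matches numerical integration over set latents", {
  fx <- core_fixture()
  # quadrature oracle for one set: integrate the set latent numerically
  quad_set <- function(z, latent, phi_set, phi_rep) {
    integrand <- function(u) {
      sapply(u, function(ui) {
        exp(sum(dnorm(z, ui, 1 / sqrt(phi_rep), log = TRUE)) +
              dnorm(ui, latent, 1 / sqrt(phi_set), log = TRUE))
      })
    }
    log(integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value)
  }
  set.seed(33)
  for (rep in 1:5) {
    z <- rnorm(3, 0.4, 0.8)
    direct <- mirord:::set_marginal_loglik(z, 0.2, 2.5, 7)
    expect_equal(direct, quad_set(z, 0.2, 2.5, 7), tolerance = 1e-8)
  }
  # as the set-level precision grows, the marginal collapses to
  # independent replicate noise around the stage latent
  z <- c(0.1, -0.2)
  tight <- mirord:::set_marginal_loglik(z, 0, 1e12, 3)
  expect_equal(tight, sum(dnorm(z, 0, 1 / sqrt(3), log = TRUE)),
               tolerance = 1e-6)

  # full-dataset value equals the sum of per-set marginals (2 sets x 3
  # replicate toy cross-checked against quadrature)
  ord <- partial_order("A", members = list(A = c("s1", "s2")))
  ann <- data.frame(observation_id = sprintf("o%d", 1:6),
                    sample_id = rep(c("s1", "s2"), each = 3),
                    stage = "A", replicate_id = as.character(rep(1:3, 2)))
  zm <- matrix(rnorm(6), 1, 6, dimnames = list("m1", ann$observation_id))
  zr <- matrix(rnorm(6), 1, 6, dimnames = list("G1", ann$observation_id))
  data <- expression_dataset(expression_matrix(zm, platform = "miR"),
                             expression_matrix(zr, platform = "mRNA"), ann)
  state <- latent_state(
    x = matrix(0.3, 1, 1, dimnames = list("m1", "A")),
    y = matrix(-0.1, 1, 1, dimnames = list("G1", "A")),
    tau = c(m1 = 0), lambda_mir = c(m1 = 1), lambda_mrna = c(G1 = 1),
    delta_mir = numeric(), delta_mrna = numeric(),
    r = -0.5, beta = c(0, 0), phi_r = 1,
    phi_set_mir = 3, phi_set_mrna = 2, phi_rep_mir = 6, phi_rep_mrna = 5)
  ll <- observation_loglik(data, state, ord)
  oracle <- quad_set(zm[1, 1:3], 0.3, 3, 6) + quad_set(zm[1, 4:6], 0.3, 3, 6) +
    quad_set(zr[1, 1:3], -0.1, 2, 5) + quad_set(zr[1, 4:6], -0.1, 2, 5)
  expect_equal(ll, oracle, tolerance = 1e-8)

  # unmapped stage errors
  bad_ord <- partial_order("A", members = list(A = "s1"))
  expect_error(observation_loglik(data, state, bad_ord), "not assigned")
})

test_that("interaction prior density is a proper normal in the coefficient", {
  expect_equal(interaction_prior_logdensity(0.3, c(1, -0.5, 0, 0),
                                            rep(0, 4), 2),
               dnorm(0.3, 0, 1 / sqrt(2), log = TRUE))
  # prior mean is the feature/coefficient dot product
  expect_equal(interaction_prior_logdensity(-2, c(1, -0.5, 0, 0),
                                            c(-1, 2, 0, 0), 1),
               dnorm(-2, -2, 1, log = TRUE))
  expect_error(interaction_prior_logdensity(0, c(1, 0), c(1, 0, 0), 1),
               "length")
  # integrates to one over the coefficient
  f <- function(r) {
    sapply(r, function(ri) {
      exp(interaction_prior_logdensity(ri, c(1, -0.4), c(-0.5, 1), 3))
    })
  }
  expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
})

test_that("joint log density equals an independent term-by-term summation", {
  fx <- core_fixture()
  hyper <- default_hyperparameters()
  val <- joint_log_density(fx$data, fx$state, fx$order, fx$preds, hyper)

  # independent re-summation written from the model definition
  st <- fx$state
  p0 <- hyper$normal_prior_precision
  total <- observation_loglik(fx$data, st, fx$order)
  # stage priors, written out longhand per stage
  for (i in c("m1", "m2")) {
    total <- total + dnorm(st$x[i, "A"], 0, 1 / sqrt(p0), log = TRUE)
    for (s in c("B", "C")) {
      d <- st$delta_mir[[paste0("A->", s)]]
      total <- total + dnorm(st$x[i, s],
                             st$x[i, "A"] + st$tau[[i]] * d,
                             1 / sqrt(st$lambda_mir[[i]] / d), log = TRUE)
    }
  }
  cand <- list(G1 = c("m1", "m2"), G2 = "m1")
  rmap <- list(G1 = st$r[1:2], G2 = st$r[3])
  for (g in c("G1", "G2")) {
    total <- total + dnorm(st$y[g, "A"], 0, 1 / sqrt(p0), log = TRUE)
    for (s in c("B", "C")) {
      d <- st$delta_mrna[[paste0("A->", s)]]
      dot <- sum(rmap[[g]] * st$x[cand[[g]], s])
      total <- total + dnorm(st$y[g, s], st$y[g, "A"] + dot * d,
                             1 / sqrt(st$lambda_mrna[[g]] / d), log = TRUE)
    }
  }
  # interaction priors
  feats <- rbind(c(1, -0.4), c(1, -0.9), c(1, -0.2))
  for (p in 1:3) {
    total <- total + dnorm(st$r[p], sum(feats[p, ] * st$beta),
                           1 / sqrt(st$phi_r), log = TRUE)
  }
  total <- total + sum(dnorm(st$tau, 0, 1 / sqrt(p0), log = TRUE)) +
    sum(dnorm(st$beta, 0, 1 / sqrt(p0), log = TRUE))
  a0 <- hyper$gamma_shape; b0 <- hyper$gamma_rate
  total <- total + sum(dgamma(c(st$lambda_mir, st$lambda_mrna, st$phi_r,
                                st$phi_set_mir, st$phi_set_mrna,
                                st$phi_rep_mir, st$phi_rep_mrna),
                              a0, rate = b0, log = TRUE))
  total <- total + sum(dgamma(c(st$delta_mir, st$delta_mrna), 1, 1,
                              log = TRUE))
  expect_equal(val, unname(total), tolerance = 1e-10)

  # additivity: removing one observation changes the density by exactly
  # that observation's marginal contribution
  data1 <- fx$data
  keep <- fx$data$annotation$observation_id != "sC2_r2"
  ann1 <- fx$data$annotation[keep, ]
  data1 <- expression_dataset(
    expression_matrix(fx$data$mir$values[, ann1$observation_id],
                      platform = "miR"),
    expression_matrix(fx$data$mrna$values[, ann1$observation_id],
                      platform = "mRNA"), ann1)
  v1 <- joint_log_density(data1, st, fx$order, fx$preds, hyper)
  del <- (observation_loglik(fx$data, st, fx$order) -
            observation_loglik(data1, st, fx$order))
  expect_equal(val - v1, del, tolerance = 1e-10)

  # shift equivariance: adding a constant c to the mRNA latents and mRNA
  # observations leaves every difference-based term unchanged, so the
  # density changes only through the initial-stage mRNA priors, by the
  # closed-form normal density shift
  cshift <- 0.7
  st_s <- st
  st_s$y <- st$y + cshift
  data_s <- expression_dataset(
    fx$data$mir,
    expression_matrix(fx$data$mrna$values + cshift, platform = "mRNA"),
    fx$data$annotation)
  v_s <- joint_log_density(data_s, st_s, fx$order, fx$preds, hyper)
  shift_terms <- sum(dnorm(st$y[, "A"] + cshift, 0, 1 / sqrt(p0), log = TRUE) -
                       dnorm(st$y[, "A"], 0, 1 / sqrt(p0), log = TRUE))
  expect_equal(v_s - val, shift_terms, tolerance = 1e-9)

  # non-positive precision is rejected
  st_bad <- st; st_bad$phi_r <- -1
  expect_error(joint_log_density(fx$data, st_bad, fx$order, fx$preds, hyper),
               "non-positive")
})
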