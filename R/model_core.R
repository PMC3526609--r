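#' Model hyperparameters and structural flags
#'
#' Collects the fixed hyperparameters of the hierarchical model and the
#' structural variants that the model definition leaves open.
#'
#' * `normal_prior_precision` - precision of the vague zero-mean normal
#'   priors on trends, prediction coefficients, and initial-stage latent
#'   expressions (default 0.01, i.e. prior sd 10 on z-scaled data).
#' * `gamma_shape`, `gamma_rate` - shape/rate of the vague gamma priors on
#'   every precision parameter.  The default is shape 1, rate 0.001 (an
#'   exponential prior with mean 1000): diffuse over the precisions a
#'   z-scaled study can produce, but - unlike a shape below 1 - without a
#'   density singularity at zero.  A sub-1 shape creates a degenerate
#'   direction in which all development distances and stage-wise
#'   precisions shrink jointly (the likelihood only constrains their
#'   ratio) while the prior mass diverges, and coordinate ascent
#'   collapses there; see the methods vignette.
#' * `development_shape`, `development_rate` - gamma prior on the per-edge
#'   development distances; both default to 1, which fixes the otherwise
#'   arbitrary common scale of developments and stage-wise precisions.
#' * `precision_form` - how a stage's prior precision combines the inverse
#'   developments of several parents: `"sum"` (default; `lambda * sum(1/delta)`,
#'   additive information, reduces to `lambda/delta` for one parent) or
#'   `"average"` (`lambda * sum(1/delta^2)/sum(1/delta)`, a weighted
#'   average of inverse developments).
#' * `interaction_stage` - whether the interaction effect on an mRNA's
#'   stage-to-stage change uses the miR latent expression at the `"child"`
#'   stage (default) or at the `"parent"` stage.
#'
#' @param normal_prior_precision,gamma_shape,gamma_rate Positive reals.
#' @param development_shape,development_rate Positive reals.
#' @param precision_form `"sum"` or `"average"`.
#' @param interaction_stage `"child"` or `"parent"`.
#' @return A list of class `mirord_hyper`.
#' @export
default_hyperparameters <- function(normal_prior_precision = 0.01,
                                    gamma_shape = 1, gamma_rate = 0.001,
                                    development_shape = 1,
                                    development_rate = 1,
                                    precision_form = c("sum", "average"),
                                    interaction_stage = c("child", "parent")) {
  stopifnot(normal_prior_precision > 0, gamma_shape > 0, gamma_rate > 0,
            development_shape > 0, development_rate > 0)
  structure(list(normal_prior_precision = normal_prior_precision,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 development_shape = development_shape,
                 development_rate = development_rate,
                 precision_form = match.arg(precision_form),
                 interaction_stage = match.arg(interaction_stage)),
            class = "mirord_hyper")
}

#' Edge list of a partial order
#' @param order A `partial_order`.
#' @return Data frame with columns `parent`, `child`, `key`
#'   (`"parent->child"`).
#' @export
order_edges <- function(order) {
  rows <- lapply(order$stages, function(s) {
    ps <- order$parents[[s]]
    if (length(ps)) data.frame(parent = ps, child = s,
                               stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE)
  }
  out$key <- paste(out$parent, out$child, sep = "->")
  out
}

edge_key <- function(parent, child) paste(parent, child, sep = "->")

#' Construct a full latent state of the generative model
#'
#' A point value for every model parameter and latent variable; used by
#' the synthetic-data generator (forward simulation) and by
#' [joint_log_density()] (oracle checks).  All precisions and development
#' distances must be strictly positive.
#'
#' @param x,y Numeric matrices of latent stage-level log expression:
#'   miR probes x stages and mRNA probesets x stages (dimnames required).
#' @param tau Named numeric vector of per-miR trends.
#' @param lambda_mir,lambda_mrna Named vectors of stage-wise precisions.
#' @param delta_mir,delta_mrna Named vectors of per-edge development
#'   distances (names `"parent->child"`).
#' @param r Numeric vector of interaction coefficients, one per candidate
#'   pair, aligned with the rows of the prediction set's pair table.
#' @param beta Numeric vector of prediction-feature coefficients.
#' @param phi_r,phi_set_mir,phi_set_mrna,phi_rep_mir,phi_rep_mrna Positive
#'   scalars: interaction prior precision and the four technical
#'   precisions.
#' @return A list of class `latent_state`.
#' @export
latent_state <- function(x, y, tau, lambda_mir, lambda_mrna,
                         delta_mir, delta_mrna, r, beta, phi_r,
                         phi_set_mir, phi_set_mrna,
                         phi_rep_mir, phi_rep_mrna) {
  state <- list(x = x, y = y, tau = tau, lambda_mir = lambda_mir,
                lambda_mrna = lambda_mrna, delta_mir = delta_mir,
                delta_mrna = delta_mrna, r = r, beta = beta, phi_r = phi_r,
                phi_set_mir = phi_set_mir, phi_set_mrna = phi_set_mrna,
                phi_rep_mir = phi_rep_mir, phi_rep_mrna = phi_rep_mrna)
  pos <- c(state$lambda_mir, state$lambda_mrna, state$delta_mir,
           state$delta_mrna, state$phi_r, state$phi_set_mir,
           state$phi_set_mrna, state$phi_rep_mir, state$phi_rep_mrna)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all precisions and developments must be strictly positive")
  }
  structure(state, class = "latent_state")
}

stage_prior_precision_factor <- function(inv_delta, form) {
  if (form == "sum") sum(inv_delta) else sum(inv_delta^2) / sum(inv_delta)
}

#' Stage prior of a miR latent expression
#'
#' The prior for miR `i` at a non-initial stage `s` is normal with mean
#' the inverse-development-weighted average of the parents'
#' trend-shifted values,
#' `mean = sum_p (1/delta_ps) (x_ip + tau_i * delta_ps) / sum_p (1/delta_ps)`,
#' and precision `lambda_i * sum_p (1/delta_ps)` (default form).  A parent
#' at small development distance dominates the mean and raises the
#' precision; as its distance grows its influence vanishes.  Initial
#' stages get the vague `Normal(0, normal_prior_precision)` prior.
#'
#' @param i miR probe id (row of `state$x`).
#' @param s Stage id.
#' @param state A `latent_state`.
#' @param order A `partial_order`.
#' @param hyper Hyperparameters from [default_hyperparameters()].
#' @return Named numeric vector `c(mean, precision)`.
#' @export
mir_stage_prior <- function(i, s, state, order,
                            hyper = default_hyperparameters()) {
  parents <- order$parents[[s]]
  if (!length(parents)) {
    return(c(mean = 0, precision = hyper$normal_prior_precision))
  }
  delta <- state$delta_mir[edge_key(parents, s)]
  inv <- 1 / delta
  w <- sum(inv)
  mean <- sum(inv * (state$x[i, parents] + state$tau[i] * delta)) / w
  prec <- state$lambda_mir[i] *
    stage_prior_precision_factor(inv, hyper$precision_form)
  c(mean = unname(mean), precision = unname(prec))
}

#' Stage prior of an mRNA latent expression
#'
#' Identical in structure to [mir_stage_prior()], with the developmental
#' trend term exchanged for the interaction effect: the dot product of the
#' gene's interaction coefficients with the latent miR expressions of its
#' candidate miRs (at the child stage by default), scaled by the edge's
#' development distance.
#'
#' @param g mRNA probeset id (row of `state$y`).
#' @inheritParams mir_stage_prior
#' @param predictions A `prediction_set`; defines the gene's candidate
#'   miRs and the alignment of `state$r`.
#' @return Named numeric vector `c(mean, precision)`.
#' @export
mrna_stage_prior <- function(g, s, state, order, predictions,
                             hyper = default_hyperparameters()) {
  parents <- order$parents[[s]]
  if (!length(parents)) {
    return(c(mean = 0, precision = hyper$normal_prior_precision))
  }
  delta <- state$delta_mrna[edge_key(parents, s)]
  inv <- 1 / delta
  w <- sum(inv)
  idx <- which(predictions$pairs$gene == g)
  mirs <- predictions$pairs$mir[idx]
  dot_at <- function(stage) {
    if (!length(idx)) 0 else sum(state$r[idx] * state$x[mirs, stage])
  }
  contrib <- if (hyper$interaction_stage == "child") {
    rep(dot_at(s), length(parents))
  } else {
    vapply(parents, dot_at, numeric(1))
  }
  mean <- sum(inv * (state$y[g, parents] + contrib * delta)) / w
  prec <- state$lambda_mrna[g] *
    stage_prior_precision_factor(inv, hyper$precision_form)
  c(mean = unname(mean), precision = unname(prec))
}

# exact marginal log density of the replicates of one probe in one
# expression set, integrating the set-level latent out of the two-level
# normal hierarchy
set_marginal_loglik <- function(z, latent, phi_set, phi_rep) {
  n <- length(z)
  zbar <- mean(z)
  sse <- sum((z - zbar)^2)
  prec_mean <- n * phi_rep * phi_set / (n * phi_rep + phi_set)
  (n / 2) * log(phi_rep / (2 * pi)) + 0.5 * log(phi_set / (2 * pi)) -
    phi_rep * sse / 2 + 0.5 * log(2 * pi / (n * phi_rep + phi_set)) -
    prec_mean * (zbar - latent)^2 / 2
}

#' Exact marginal log likelihood of the observed expression data
#'
#' The two-level technical noise hierarchy places a set-level latent
#' between each stage latent and its replicate observations: the set
#' latent is normal around the stage latent with the set-level precision,
#' and each replicate is normal around the set latent with the
#' replicate-level precision.  This function integrates the set-level
#' latents out analytically (normal-normal convolution) and returns the
#' exact marginal log likelihood of all observations given the stage
#' latents and the four technical precisions in `state`.
#'
#' @param data An `expression_dataset`.
#' @param state A `latent_state`.
#' @param order A `partial_order` assigning each sample to a stage.
#' @return A single number, the marginal log likelihood.
#' @export
observation_loglik <- function(data, state, order) {
  ann <- data$annotation
  sos <- stage_of_sample(order)
  stage <- sos[ann$sample_id]
  if (anyNA(stage)) {
    stop("observation(s) whose sample is not assigned to any stage: ",
         paste(utils::head(ann$observation_id[is.na(stage)], 5L),
               collapse = ", "))
  }
  total <- 0
  sets <- split(seq_len(nrow(ann)), ann$sample_id)
  for (k in names(sets)) {
    obs <- ann$observation_id[sets[[k]]]
    s <- stage[sets[[k]][1L]]
    for (i in rownames(state$x)) {
      total <- total + set_marginal_loglik(
        data$mir$values[i, obs], state$x[i, s],
        state$phi_set_mir, state$phi_rep_mir)
    }
    for (g in rownames(state$y)) {
      total <- total + set_marginal_loglik(
        data$mrna$values[g, obs], state$y[g, s],
        state$phi_set_mrna, state$phi_rep_mrna)
    }
  }
  total
}

#' Log density of an interaction coefficient under its score-informed prior
#'
#' Each candidate pair's interaction coefficient is normal with mean
#' `c . beta` (prediction feature vector times estimated coefficients) and
#' precision `phi_r`.  Both signs are permitted: the model does not
#' restrict interactions to repression.
#'
#' @param r_value Interaction coefficient (scalar).
#' @param features Numeric feature vector `c` of the pair.
#' @param beta Coefficient vector (same length as `features`).
#' @param phi_r Prior precision (> 0).
#' @return Normal log density at `r_value`.
#' @export
interaction_prior_logdensity <- function(r_value, features, beta, phi_r) {
  if (length(features) != length(beta)) {
    stop("feature vector and beta have different lengths")
  }
  stopifnot(phi_r > 0)
  stats::dnorm(r_value, mean = sum(features * beta),
               sd = 1 / sqrt(phi_r), log = TRUE)
}

dgamma_log <- function(x, shape, rate) {
  stats::dgamma(x, shape = shape, rate = rate, log = TRUE)
}

#' Log joint density of data and a full latent state
#'
#' Sums every term of the hierarchical model: the marginal observation
#' likelihood, the stage priors of all latent miR and mRNA expressions,
#' the score-informed interaction priors, and the hyperpriors (vague
#' normals on trends, coefficients and initial-stage latents are part of
#' the stage priors; vague gammas on all precisions; the
#' scale-fixing gamma prior on all development distances).
#'
#' @param data An `expression_dataset`.
#' @param state A `latent_state`.
#' @param order A `partial_order`.
#' @param predictions A `prediction_set`.
#' @param hyper Hyperparameters.
#' @return A single finite number (errors on non-positive precisions or
#'   developments, which the `latent_state` constructor also rejects).
#' @export
joint_log_density <- function(data, state, order, predictions,
                              hyper = default_hyperparameters()) {
  pos <- c(state$lambda_mir, state$lambda_mrna, state$delta_mir,
           state$delta_mrna, state$phi_r, state$phi_set_mir,
           state$phi_set_mrna, state$phi_rep_mir, state$phi_rep_mrna)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("non-positive precision or development in state")
  }
  total <- observation_loglik(data, state, order)
  for (s in order$stages) {
    for (i in rownames(state$x)) {
      pr <- mir_stage_prior(i, s, state, order, hyper)
      total <- total + stats::dnorm(state$x[i, s], pr["mean"],
                                    1 / sqrt(pr["precision"]), log = TRUE)
    }
    for (g in rownames(state$y)) {
      pr <- mrna_stage_prior(g, s, state, order, predictions, hyper)
      total <- total + stats::dnorm(state$y[g, s], pr["mean"],
                                    1 / sqrt(pr["precision"]), log = TRUE)
    }
  }
  fm <- feature_matrix(predictions)
  for (p in seq_len(nrow(fm))) {
    total <- total + interaction_prior_logdensity(state$r[p], fm[p, ],
                                                  state$beta, state$phi_r)
  }
  p0 <- hyper$normal_prior_precision
  total <- total + sum(stats::dnorm(state$tau, 0, 1 / sqrt(p0), log = TRUE))
  total <- total + sum(stats::dnorm(state$beta, 0, 1 / sqrt(p0), log = TRUE))
  a0 <- hyper$gamma_shape
  b0 <- hyper$gamma_rate
  total <- total + sum(dgamma_log(c(state$lambda_mir, state$lambda_mrna,
                                    state$phi_r, state$phi_set_mir,
                                    state$phi_set_mrna, state$phi_rep_mir,
                                    state$phi_rep_mrna), a0, b0))
  total <- total + sum(dgamma_log(c(state$delta_mir, state$delta_mrna),
                                  hyper$development_shape,
                                  hyper$development_rate))
  unname(total)
}
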