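#' Configuration for the synthetic-data generator
#'
#' Two built-in profiles mirror the intended use: `"default"` matches the
#' scale of a filtered staged-disease microarray study (28 miRs, 367
#' genes, about 1750 candidate pairs, a 4-stage chain with one branch),
#' and `"tiny"` (4 miRs, 12 genes, a 3-stage chain) is sized for unit
#' tests.  Any field can be overridden through `...`.
#'
#' Fields and defaults (default profile):
#' * `n_mir = 28`, `n_gene = 367` - probe counts.
#' * `stage_labels = c("IA","IIA","IIIA","IIIB")`, `branches =
#'   list(PCL = "IA")` - the ordering design.
#' * `sets_per_stage = 4`, `reps_per_set = 2` - expression sets (arrays)
#'   per stage and within-array replicates.
#' * `pairs_per_gene = 4.8` - mean number of candidate miRs per gene.
#' * `active_fraction = 0.5` - fraction of predicted pairs with a truly
#'   nonzero interaction (the rest are prediction false positives).
#' * `n_trend = 5`, `trend_size = 1` - number of miRs with an injected
#'   trend and its magnitude (log-expression drift per unit development).
#' * `lambda_mir = 4`, `lambda_mrna = 4` - stage-propagation precisions
#'   (per-edge biological noise sd 0.5 at unit development).
#' * `phi_set = 4`, `phi_rep = 8` - technical precisions (between-array
#'   sd 0.5, within-array replicate sd about 0.35).
#' * `phi_r = 11.1` - spread of active interactions around their
#'   score-driven prior mean (sd 0.3).
#' * `beta_true = c(-0.2, 0.5, -0.2, 0.5)` - true prediction-feature
#'   coefficients (per-algorithm intercept and score slope); with
#'   negative scores these give predominantly negative interactions.
#' * `p_alg = 0.6` - probability that each algorithm predicts a candidate
#'   pair (at least one is forced).
#' * `delta_range = c(0.5, 1.5)` - true per-edge development distances
#'   (roughly equidistant stages).
#' * `algorithms = c("targetscan", "miranda")`.
#'
#' @param profile `"default"` or `"tiny"`.
#' @param ... Field overrides.
#' @return A list of class `synth_config`.
#' @export
synthetic_config <- function(profile = c("default", "tiny"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    n_mir = 28L, n_gene = 367L,
    stage_labels = c("IA", "IIA", "IIIA", "IIIB"),
    branches = list(PCL = "IA"),
    sets_per_stage = 4L, reps_per_set = 2L,
    pairs_per_gene = 4.8, active_fraction = 0.5,
    n_trend = 5L, trend_size = 1,
    lambda_mir = 4, lambda_mrna = 4,
    phi_set = 4, phi_rep = 8, phi_r = 1 / 0.3^2,
    beta_true = c(-0.2, 0.5, -0.2, 0.5),
    p_alg = 0.6, delta_range = c(0.5, 1.5),
    algorithms = c("targetscan", "miranda"))
  if (profile == "tiny") {
    cfg$n_mir <- 4L; cfg$n_gene <- 12L
    cfg$stage_labels <- c("A", "B", "C"); cfg$branches <- list()
    cfg$sets_per_stage <- 2L; cfg$reps_per_set <- 2L
    cfg$pairs_per_gene <- 2; cfg$n_trend <- 1L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (length(cfg$stage_labels) < 1L || cfg$n_mir < 1L || cfg$n_gene < 1L ||
      cfg$sets_per_stage < 1L || cfg$reps_per_set < 1L) {
    stop("inconsistent config: counts must be positive and at least one stage is required")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic paired expression study with known ground truth
#'
#' Runs the generative model forward: development distances and trends
#' are drawn, latent miR expression is propagated along the ordering DAG
#' through the stage priors, interaction coefficients for predicted pairs
#' are drawn from the score-informed prior (a configurable fraction is
#' truly active, the rest are prediction false positives with zero
#' effect), latent mRNA expression is propagated with the interaction
#' effects, and finally set-level and replicate-level technical noise is
#' added.  Everything is reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with elements `dataset` (`expression_dataset`),
#'   `predictions` (`prediction_set`), `order` (`partial_order`), `truth`
#'   (class `synthetic_truth`: `r`, `active`, `tau`, `trend_mirs`,
#'   `delta_mir`, `delta_mrna`, `x`, `y`, `state` (full `latent_state`),
#'   and the noise precisions used) and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  cfg <- config
  hyper <- default_hyperparameters()

  mir_ids <- sprintf("miR-%03d", seq_len(cfg$n_mir))
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_gene))
  labels <- c(cfg$stage_labels, names(cfg$branches))
  sample_tab <- data.frame(
    sample_id = unlist(lapply(labels, function(l) {
      sprintf("%s_s%d", l, seq_len(cfg$sets_per_stage))
    })),
    stage = rep(labels, each = cfg$sets_per_stage),
    stringsAsFactors = FALSE)
  order <- build_grouped_ordered(sample_tab, cfg$stage_labels, cfg$branches)
  stages <- topological_stages(order)
  edges <- order_edges(order)

  delta_mir <- stats::setNames(
    stats::runif(nrow(edges), cfg$delta_range[1], cfg$delta_range[2]),
    edges$key)
  delta_mrna <- stats::setNames(
    stats::runif(nrow(edges), cfg$delta_range[1], cfg$delta_range[2]),
    edges$key)

  tau <- stats::setNames(numeric(cfg$n_mir), mir_ids)
  trend_mirs <- sample(mir_ids, min(cfg$n_trend, cfg$n_mir))
  tau[trend_mirs] <- cfg$trend_size * sample(c(-1, 1), length(trend_mirs),
                                             replace = TRUE)

  # candidate pairs: 1 + Poisson(mean - 1) candidate miRs per gene
  n_cand <- pmin(cfg$n_mir,
                 1L + stats::rpois(cfg$n_gene, max(cfg$pairs_per_gene - 1, 0)))
  long <- do.call(rbind, lapply(seq_len(cfg$n_gene), function(gi) {
    mirs <- sample(mir_ids, n_cand[gi])
    data.frame(mir = mirs, gene = gene_ids[gi], stringsAsFactors = FALSE)
  }))
  # per-algorithm prediction indicators (at least one forced) and
  # mirSVR/context+-like negative scores
  n_pairs <- nrow(long)
  pred <- matrix(stats::runif(n_pairs * length(cfg$algorithms)) < cfg$p_alg,
                 n_pairs)
  none <- rowSums(pred) == 0L
  pred[cbind(which(none),
             sample(length(cfg$algorithms), sum(none), replace = TRUE))] <- TRUE
  draw_score <- function(n) {
    -pmin(pmax(abs(stats::rnorm(n, 0.6, 0.3)), 0.05), 1.5)
  }
  rows <- do.call(rbind, lapply(seq_along(cfg$algorithms), function(a) {
    keep <- pred[, a]
    data.frame(mir = long$mir[keep], gene = long$gene[keep],
               algorithm = cfg$algorithms[a], score = draw_score(sum(keep)),
               stringsAsFactors = FALSE)
  }))
  predictions <- prediction_set(rows, cfg$algorithms)
  pairs <- predictions$pairs

  # interactions from the score-informed prior; inactive pairs are
  # prediction false positives with zero true effect
  C <- feature_matrix(predictions)
  prior_mean <- as.numeric(C %*% cfg$beta_true)
  active <- stats::runif(nrow(pairs)) < cfg$active_fraction
  r <- ifelse(active,
              stats::rnorm(nrow(pairs), prior_mean, 1 / sqrt(cfg$phi_r)), 0)

  # latent expression propagated through the stage priors
  x <- matrix(0, cfg$n_mir, length(stages), dimnames = list(mir_ids, stages))
  y <- matrix(0, cfg$n_gene, length(stages), dimnames = list(gene_ids, stages))
  state <- latent_state(
    x = x, y = y, tau = tau,
    lambda_mir = stats::setNames(rep(cfg$lambda_mir, cfg$n_mir), mir_ids),
    lambda_mrna = stats::setNames(rep(cfg$lambda_mrna, cfg$n_gene), gene_ids),
    delta_mir = delta_mir, delta_mrna = delta_mrna,
    r = r, beta = cfg$beta_true, phi_r = cfg$phi_r,
    phi_set_mir = cfg$phi_set, phi_set_mrna = cfg$phi_set,
    phi_rep_mir = cfg$phi_rep, phi_rep_mrna = cfg$phi_rep)
  # initial stages start at N(0, 1) (z-scale world); later stages follow
  # the stage priors exactly
  for (s in stages) {
    init <- !length(order$parents[[s]])
    for (i in mir_ids) {
      if (init) {
        state$x[i, s] <- stats::rnorm(1)
      } else {
        pr <- mir_stage_prior(i, s, state, order, hyper)
        state$x[i, s] <- stats::rnorm(1, pr["mean"], 1 / sqrt(pr["precision"]))
      }
    }
  }
  for (s in stages) {
    init <- !length(order$parents[[s]])
    for (g in gene_ids) {
      if (init) {
        state$y[g, s] <- stats::rnorm(1)
      } else {
        pr <- mrna_stage_prior(g, s, state, order, predictions, hyper)
        state$y[g, s] <- stats::rnorm(1, pr["mean"], 1 / sqrt(pr["precision"]))
      }
    }
  }

  # technical noise: set-level latents, then replicate observations
  sos <- stage_of_sample(order)
  samples <- sample_tab$sample_id
  obs <- expand.grid(rep = seq_len(cfg$reps_per_set), sample = samples,
                     stringsAsFactors = FALSE)
  obs_ids <- sprintf("%s_r%d", obs$sample, obs$rep)
  annotation <- data.frame(observation_id = obs_ids, sample_id = obs$sample,
                           stage = sample_tab$stage[match(obs$sample, samples)],
                           replicate_id = as.character(obs$rep),
                           stringsAsFactors = FALSE)
  make_obs <- function(latent, phi_set, phi_rep) {
    n <- nrow(latent)
    u <- latent[, sos[samples], drop = FALSE] +
      matrix(stats::rnorm(n * length(samples), 0, 1 / sqrt(phi_set)),
             n, length(samples))
    colnames(u) <- samples
    z <- u[, obs$sample, drop = FALSE] +
      matrix(stats::rnorm(n * length(obs_ids), 0, 1 / sqrt(phi_rep)),
             n, length(obs_ids))
    colnames(z) <- obs_ids
    z
  }
  zm <- make_obs(state$x, cfg$phi_set, cfg$phi_rep)
  zr <- make_obs(state$y, cfg$phi_set, cfg$phi_rep)

  dataset <- expression_dataset(
    expression_matrix(zm, mir_ids, obs_ids, "miR"),
    expression_matrix(zr, gene_ids, obs_ids, "mRNA"),
    annotation)
  truth <- structure(list(
    r = r, active = active, pairs = pairs[, c("mir", "gene")],
    tau = tau, trend_mirs = trend_mirs,
    delta_mir = delta_mir, delta_mrna = delta_mrna,
    x = state$x, y = state$y, state = state,
    phi_set = cfg$phi_set, phi_rep = cfg$phi_rep, phi_r = cfg$phi_r),
    class = "synthetic_truth")
  list(dataset = dataset, predictions = predictions, order = order,
       truth = truth, config = cfg)
}

#' Compare a fitted posterior against synthetic ground truth
#'
#' @param truth A `synthetic_truth` from [generate_synthetic()].
#' @param state A `mirord_state` fitted on the generated data.
#' @param top_k Number of top-|z| pairs for the sign-agreement metric
#'   (default 50, capped at the number of pairs).
#' @param z_threshold Trend significance threshold (default 3).
#' @return List of metrics: `r_correlation` (Pearson, true vs estimated
#'   interaction coefficients over all candidate pairs); `sign_agreement`
#'   (sign correctness: among the top-|z| pairs whose true coefficient is
#'   nonzero, the fraction whose estimated sign matches - whether the
#'   top-|z| calls land on truly active pairs at all is measured
#'   separately); `active_top_quartile` (retrieval: fraction of truly
#'   active pairs ranked in the top quartile by |z|); and
#'   `trend_recovery` (fraction of injected-trend miRs with |z| above
#'   the threshold).
#' @export
recovery_report <- function(truth, state, top_k = 50L, z_threshold = 3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  post <- interaction_posterior(state)
  key_t <- paste(truth$pairs$mir, truth$pairs$gene, sep = "\r")
  key_p <- paste(post$mir, post$gene, sep = "\r")
  idx <- match(key_t, key_p)
  if (anyNA(idx) || length(key_t) != length(key_p)) {
    stop("candidate pair sets of truth and posterior do not match")
  }
  est <- post$mean[idx]
  z <- abs(post$z[idx])
  ord <- order(-z)
  k <- min(top_k, length(ord))
  top <- ord[seq_len(k)]
  top_active <- top[truth$r[top] != 0]
  sign_ok <- if (length(top_active)) {
    mean(sign(est[top_active]) == sign(truth$r[top_active]))
  } else {
    NA_real_
  }
  quartile <- ord[seq_len(ceiling(length(ord) / 4))]
  active_idx <- which(truth$r != 0)
  retrieval <- if (length(active_idx)) {
    mean(active_idx %in% quartile)
  } else {
    NA_real_
  }
  tr <- trend_posterior(state)
  tz <- abs(tr$z[match(truth$trend_mirs, tr$mir)])
  list(r_correlation = stats::cor(truth$r, est),
       sign_agreement = sign_ok,
       active_top_quartile = retrieval,
       trend_recovery = mean(tz > z_threshold))
}
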