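#' Control options for the variational fit
#'
#' @param fixed Named list of parameters to hold fixed (not updated)
#'   during the fit.  Supported entries: `phi_set_mir`, `phi_rep_mir`,
#'   `phi_set_mrna`, `phi_rep_mrna`, `phi_r` (positive values: the
#'   precision is treated as known), `delta` (`TRUE` freezes all
#'   development distances at their initial value 1), and `beta` (`TRUE`
#'   freezes the prediction coefficients at zero, i.e. an uninformed
#'   interaction prior).  Fixing parameters is mainly useful for reduced
#'   models and oracle checks.
#' @param elbo_tol Relative evidence-lower-bound change below which the
#'   fit may stop early (default 0: always run all iterations, matching
#'   the fixed-iteration fitting schedule).
#' @return A list of class `vb_control`.
#' @export
vb_control <- function(fixed = list(), elbo_tol = 0) {
  known <- c("phi_set_mir", "phi_rep_mir", "phi_set_mrna", "phi_rep_mrna",
             "phi_r", "delta", "beta")
  bad <- setdiff(names(fixed), known)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  structure(list(fixed = fixed, elbo_tol = elbo_tol), class = "vb_control")
}

# ---------------------------------------------------------------------------
# model frame: immutable index structures shared by all updates

build_frame <- function(data, order, predictions, hyper) {
  bad <- validate_partial_order(order)
  if (length(bad)) stop("invalid partial order: ", paste(bad, collapse = "; "))
  if (hyper$interaction_stage != "child") {
    stop("the VB engine fits the child-stage interaction variant; ",
         "the parent-stage variant is available for density evaluation only")
  }
  stages <- topological_stages(order)
  S <- length(stages)
  ann <- data$annotation
  sos <- stage_of_sample(order)
  obs_stage <- sos[ann$sample_id]
  if (anyNA(obs_stage)) {
    stop("observation(s) whose sample is not in the partial order: ",
         paste(utils::head(ann$observation_id[is.na(obs_stage)], 5L),
               collapse = ", "))
  }
  samples <- unique(ann$sample_id)
  K <- length(samples)
  set_of_obs <- match(ann$sample_id, samples)
  set_stage <- match(sos[samples], stages)
  n_rep <- as.integer(table(factor(set_of_obs, levels = seq_len(K))))

  mir_ids <- data$mir$probe_ids
  gene_ids <- data$mrna$probe_ids
  preds <- subset_predictions(predictions, mir_ids, gene_ids)
  if (!nrow(preds$pairs)) stop("empty candidate set: no predicted pair involves the data's probes")
  pair_mir <- match(preds$pairs$mir, mir_ids)
  pair_gene <- match(toupper(preds$pairs$gene), toupper(gene_ids))

  Zm <- data$mir$values[, ann$observation_id, drop = FALSE]
  Zr <- data$mrna$values[, ann$observation_id, drop = FALSE]
  grp <- factor(set_of_obs, levels = seq_len(K))
  Zm_sum <- t(rowsum(t(Zm), grp))
  Zr_sum <- t(rowsum(t(Zr), grp))
  Zm_sq <- t(rowsum(t(Zm^2), grp))
  Zr_sq <- t(rowsum(t(Zr^2), grp))

  parents_idx <- lapply(stages, function(s) match(order$parents[[s]], stages))
  children_idx <- lapply(seq_len(S), function(si) {
    which(vapply(parents_idx, function(p) si %in% p, logical(1)))
  })
  is_init <- lengths(parents_idx) == 0L
  stage_sets <- lapply(seq_len(S), function(si) which(set_stage == si))

  list(stages = stages, S = S, I = length(mir_ids), G = length(gene_ids),
       K = K, n_obs = nrow(ann), mir_ids = mir_ids, gene_ids = gene_ids,
       samples = samples, n_rep = n_rep, set_stage = set_stage,
       parents_idx = parents_idx, children_idx = children_idx,
       is_init = is_init, noninit = which(!is_init),
       stage_sets = stage_sets,
       Zm_sum = Zm_sum, Zr_sum = Zr_sum, Zm_sq = Zm_sq, Zr_sq = Zr_sq,
       predictions = preds, P = nrow(preds$pairs),
       pair_mir = pair_mir, pair_gene = pair_gene,
       pairs_of_mir = split(seq_along(pair_mir), factor(pair_mir, seq_along(mir_ids))),
       pairs_of_gene = split(seq_along(pair_gene), factor(pair_gene, seq_along(gene_ids))),
       C = feature_matrix(preds), hyper = hyper)
}

# per-stage geometry induced by the development distances of the edges
# into one stage: weights of the parents in the prior mean, the trend /
# interaction multiplier B, and the precision factor F
stage_geometry <- function(delta, form) {
  inv <- 1 / delta
  W <- sum(inv)
  list(delta = delta, inv = inv, W = W, a = inv / W,
       B = length(delta) / W,
       F = if (form == "sum") W else sum(inv^2) / W)
}

gamma_new <- function(shape, rate) list(shape = shape, rate = rate)

# expectations of a precision factor: fixed values behave as known
# constants (E = value, E log = log value)
prec_E <- function(st, name) {
  if (!is.null(st$fixed[[name]])) {
    rep(st$fixed[[name]], length.out = length(st$q[[name]]$shape))
  } else {
    st$q[[name]]$shape / st$q[[name]]$rate
  }
}
prec_Elog <- function(st, name) {
  if (!is.null(st$fixed[[name]])) {
    log(rep(st$fixed[[name]], length.out = length(st$q[[name]]$shape)))
  } else {
    digamma(st$q[[name]]$shape) - log(st$q[[name]]$rate)
  }
}

#' Initialize the variational posterior
#'
#' Latent-expression means start at the per-stage (and per-set)
#' observation means, falling back to the parent's mean (or zero at an
#' initial stage) when a stage carries no observations for a probe; all
#' normal factors start with precision 1; every gamma factor starts at its
#' prior; development distances start at 1.  Initialization is
#' deterministic given the seed.
#'
#' @param data An `expression_dataset` (typically preprocessed /
#'   z-scaled).
#' @param order A `partial_order`.
#' @param predictions A `prediction_set`; the candidate interaction set is
#'   its pairs restricted to the data's probes (must be non-empty).
#' @param hyper Hyperparameters from [default_hyperparameters()].
#' @param seed Integer seed (recorded; the initialization itself is
#'   deterministic).
#' @param control A [vb_control()].
#' @return A mutable state object of class `mirord_state` (an
#'   environment: updates modify it in place).
#' @export
vb_initialize <- function(data, order, predictions,
                          hyper = default_hyperparameters(), seed = 1L,
                          control = vb_control()) {
  fr <- build_frame(data, order, predictions, hyper)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$frame <- fr
  st$hyper <- hyper
  st$seed <- seed
  st$fixed <- control$fixed
  st$control <- control
  st$clamped <- 0L

  # set-level means as starting points
  Eu <- fr$Zm_sum / rep(fr$n_rep, each = fr$I)
  Ev <- fr$Zr_sum / rep(fr$n_rep, each = fr$G)
  st$Eu <- Eu; st$Vu <- Eu * 0 + 1
  st$Ev <- Ev; st$Vv <- Ev * 0 + 1

  stage_mean <- function(E_set) {
    out <- matrix(0, nrow(E_set), fr$S)
    for (si in seq_len(fr$S)) {
      ks <- fr$stage_sets[[si]]
      if (length(ks)) {
        out[, si] <- rowMeans(E_set[, ks, drop = FALSE])
      } else {
        ps <- fr$parents_idx[[si]]
        out[, si] <- if (length(ps)) rowMeans(out[, ps, drop = FALSE]) else 0
      }
    }
    out
  }
  # topological stage order guarantees parents are filled before children
  st$Ex <- stage_mean(Eu); st$Vx <- st$Ex * 0 + 1
  st$Ey <- stage_mean(Ev); st$Vy <- st$Ey * 0 + 1

  st$tau_m <- numeric(fr$I); st$tau_v <- rep(1, fr$I)
  st$r_m <- numeric(fr$P); st$r_v <- rep(1, fr$P)
  nF <- ncol(fr$C)
  if (isTRUE(st$fixed$beta)) {
    st$beta_m <- numeric(nF); st$beta_v <- numeric(nF)
  } else {
    st$beta_m <- numeric(nF); st$beta_v <- rep(1, nF)
  }

  a0 <- hyper$gamma_shape; b0 <- hyper$gamma_rate
  st$q <- list(
    lambda_mir = gamma_new(rep(a0, fr$I), rep(b0, fr$I)),
    lambda_mrna = gamma_new(rep(a0, fr$G), rep(b0, fr$G)),
    phi_set_mir = gamma_new(a0, b0), phi_rep_mir = gamma_new(a0, b0),
    phi_set_mrna = gamma_new(a0, b0), phi_rep_mrna = gamma_new(a0, b0),
    phi_r = gamma_new(a0, b0))

  st$delta_mir <- lapply(fr$parents_idx, function(p) rep(1, length(p)))
  st$delta_mrna <- lapply(fr$parents_idx, function(p) rep(1, length(p)))
  refresh_geometry(st)
  st$elbo_trace <- numeric(0)
  class(st) <- "mirord_state"
  st
}

refresh_geometry <- function(st) {
  fr <- st$frame
  form <- st$hyper$precision_form
  st$geo_mir <- lapply(seq_len(fr$S), function(si) {
    if (fr$is_init[si]) NULL else stage_geometry(st$delta_mir[[si]], form)
  })
  st$geo_mrna <- lapply(seq_len(fr$S), function(si) {
    if (fr$is_init[si]) NULL else stage_geometry(st$delta_mrna[[si]], form)
  })
  invisible(st)
}

#' @export
print.mirord_state <- function(x, ...) {
  fr <- x$frame
  cat(sprintf(paste0("variational state: %d miRs, %d genes, %d stages, ",
                     "%d candidate pairs\n"), fr$I, fr$G, fr$S, fr$P))
  if (length(x$elbo_trace)) {
    cat(sprintf("iterations: %d, ELBO: %.4f\n",
                length(x$elbo_trace), utils::tail(x$elbo_trace, 1L)))
  }
  invisible(x)
}

# sum a per-pair vector into a per-gene vector
pair_to_gene <- function(v, st) {
  fr <- st$frame
  out <- numeric(fr$G)
  if (length(v)) {
    rs <- rowsum(v, fr$pair_gene)
    out[as.integer(rownames(rs))] <- rs
  }
  out
}

# interaction totals T[g, s] = sum over g's candidate pairs of
# E[r_p] * E[x_{mir(p), s}]
interaction_totals <- function(st) {
  fr <- st$frame
  T <- matrix(0, fr$G, fr$S)
  for (si in seq_len(fr$S)) {
    T[, si] <- pair_to_gene(st$r_m * st$Ex[fr$pair_mir, si], st)
  }
  T
}

# parent-weighted means A[, s] = sum_p a_p E[, p] for one non-initial stage
parent_mix <- function(E, st, si, geo) {
  ps <- st$frame$parents_idx[[si]]
  as.numeric(E[, ps, drop = FALSE] %*% geo[[si]]$a)
}

clamp_pos <- function(st, x, floor = 1e-12) {
  low <- x < floor
  if (any(low)) {
    st$clamped <- st$clamped + sum(low)
    x[low] <- floor
  }
  x
}

# ---------------------------------------------------------------------------
# conjugate updates (each is an exact mean-field coordinate optimum)

update_set_latents <- function(st, platform) {
  fr <- st$frame
  if (platform == "mir") {
    ps <- prec_E(st, "phi_set_mir"); pr <- prec_E(st, "phi_rep_mir")
    prec <- matrix(ps + pr * fr$n_rep, fr$I, fr$K, byrow = TRUE)
    lin <- ps * st$Ex[, fr$set_stage, drop = FALSE] + pr * fr$Zm_sum
    st$Eu <- lin / prec; st$Vu <- 1 / prec
  } else {
    ps <- prec_E(st, "phi_set_mrna"); pr <- prec_E(st, "phi_rep_mrna")
    prec <- matrix(ps + pr * fr$n_rep, fr$G, fr$K, byrow = TRUE)
    lin <- ps * st$Ey[, fr$set_stage, drop = FALSE] + pr * fr$Zr_sum
    st$Ev <- lin / prec; st$Vv <- 1 / prec
  }
  invisible(st)
}

update_x <- function(st, only_i = NULL, only_si = NULL) {
  fr <- st$frame
  lam <- prec_E(st, "lambda_mir")
  lamr <- prec_E(st, "lambda_mrna")
  phi_sm <- prec_E(st, "phi_set_mir")
  p0 <- st$hyper$normal_prior_precision
  T <- interaction_totals(st)
  Ay <- matrix(0, fr$G, fr$S)
  for (si in fr$noninit) Ay[, si] <- parent_mix(st$Ey, st, si, st$geo_mrna)
  r2 <- st$r_m^2 + st$r_v

  stage_seq <- if (is.null(only_si)) seq_len(fr$S) else only_si
  for (si in stage_seq) {
    gm <- st$geo_mir[[si]]
    ks <- fr$stage_sets[[si]]
    gy <- st$geo_mrna[[si]]
    for (i in (if (is.null(only_i)) seq_len(fr$I) else only_i)) {
      lin <- 0; quad <- 0
      if (fr$is_init[si]) {
        quad <- quad + p0
      } else {
        target <- sum(gm$a * st$Ex[i, fr$parents_idx[[si]]]) +
          st$tau_m[i] * gm$B
        quad <- quad + lam[i] * gm$F
        lin <- lin + lam[i] * gm$F * target
      }
      for (ci in fr$children_idx[[si]]) {
        gc <- st$geo_mir[[ci]]
        ps <- fr$parents_idx[[ci]]
        w <- gc$a[ps == si]
        rest <- sum(gc$a * st$Ex[i, ps]) - w * st$Ex[i, si]
        resid <- st$Ex[i, ci] - rest - st$tau_m[i] * gc$B
        quad <- quad + lam[i] * gc$F * w^2
        lin <- lin + lam[i] * gc$F * w * resid
      }
      if (length(ks)) {
        quad <- quad + length(ks) * phi_sm
        lin <- lin + phi_sm * sum(st$Eu[i, ks])
      }
      if (!fr$is_init[si]) {
        for (p in fr$pairs_of_mir[[i]]) {
          g <- fr$pair_gene[p]
          resid <- st$Ey[g, si] - Ay[g, si] -
            gy$B * (T[g, si] - st$r_m[p] * st$Ex[i, si])
          quad <- quad + lamr[g] * gy$F * gy$B^2 * r2[p]
          lin <- lin + lamr[g] * gy$F * gy$B * st$r_m[p] * resid
        }
      }
      quad <- clamp_pos(st, quad)
      old <- st$Ex[i, si]
      st$Ex[i, si] <- lin / quad
      st$Vx[i, si] <- 1 / quad
      if (length(fr$pairs_of_mir[[i]])) {
        pp <- fr$pairs_of_mir[[i]]
        T[cbind(fr$pair_gene[pp], si)] <-
          T[cbind(fr$pair_gene[pp], si)] + st$r_m[pp] * (st$Ex[i, si] - old)
      }
    }
  }
  invisible(st)
}

update_y <- function(st, only_si = NULL) {
  fr <- st$frame
  lamr <- prec_E(st, "lambda_mrna")
  phi_sr <- prec_E(st, "phi_set_mrna")
  p0 <- st$hyper$normal_prior_precision
  T <- interaction_totals(st)
  stage_seq <- if (is.null(only_si)) seq_len(fr$S) else only_si
  for (si in stage_seq) {
    lin <- numeric(fr$G); quad <- numeric(fr$G)
    if (fr$is_init[si]) {
      quad <- quad + p0
    } else {
      g <- st$geo_mrna[[si]]
      target <- parent_mix(st$Ey, st, si, st$geo_mrna) + g$B * T[, si]
      quad <- quad + lamr * g$F
      lin <- lin + lamr * g$F * target
    }
    for (ci in fr$children_idx[[si]]) {
      gc <- st$geo_mrna[[ci]]
      ps <- fr$parents_idx[[ci]]
      w <- gc$a[ps == si]
      rest <- parent_mix(st$Ey, st, ci, st$geo_mrna) - w * st$Ey[, si]
      resid <- st$Ey[, ci] - rest - gc$B * T[, ci]
      quad <- quad + lamr * gc$F * w^2
      lin <- lin + lamr * gc$F * w * resid
    }
    ks <- fr$stage_sets[[si]]
    if (length(ks)) {
      quad <- quad + length(ks) * phi_sr
      lin <- lin + phi_sr * rowSums(st$Ev[, ks, drop = FALSE])
    }
    quad <- clamp_pos(st, quad)
    st$Ey[, si] <- lin / quad
    st$Vy[, si] <- 1 / quad
  }
  invisible(st)
}

update_tau <- function(st, only_i = NULL) {
  fr <- st$frame
  lam <- prec_E(st, "lambda_mir")
  p0 <- st$hyper$normal_prior_precision
  quad <- rep(p0, fr$I); lin <- numeric(fr$I)
  for (si in fr$noninit) {
    g <- st$geo_mir[[si]]
    Ax <- as.numeric(st$Ex[, fr$parents_idx[[si]], drop = FALSE] %*% g$a)
    quad <- quad + lam * g$F * g$B^2
    lin <- lin + lam * g$F * g$B * (st$Ex[, si] - Ax)
  }
  quad <- clamp_pos(st, quad)
  idx <- if (is.null(only_i)) seq_len(fr$I) else only_i
  st$tau_m[idx] <- (lin / quad)[idx]
  st$tau_v[idx] <- (1 / quad)[idx]
  invisible(st)
}

update_r <- function(st, only_gene = NULL) {
  fr <- st$frame
  if (!fr$P) return(invisible(st))
  lamr <- prec_E(st, "lambda_mrna")
  phir <- prec_E(st, "phi_r")
  T <- interaction_totals(st)
  Ay <- matrix(0, fr$G, fr$S)
  Ex2 <- st$Ex^2 + st$Vx
  for (si in fr$noninit) Ay[, si] <- parent_mix(st$Ey, st, si, st$geo_mrna)
  prior_mean <- as.numeric(fr$C %*% st$beta_m)
  genes <- if (is.null(only_gene)) seq_len(fr$G) else only_gene
  for (g in genes) {
    for (p in fr$pairs_of_gene[[g]]) {
      j <- fr$pair_mir[p]
      quad <- phir; lin <- phir * prior_mean[p]
      for (si in fr$noninit) {
        geo <- st$geo_mrna[[si]]
        resid <- st$Ey[g, si] - Ay[g, si] -
          geo$B * (T[g, si] - st$r_m[p] * st$Ex[j, si])
        quad <- quad + lamr[g] * geo$F * geo$B^2 * Ex2[j, si]
        lin <- lin + lamr[g] * geo$F * geo$B * st$Ex[j, si] * resid
      }
      quad <- clamp_pos(st, quad)
      old <- st$r_m[p]
      st$r_m[p] <- lin / quad
      st$r_v[p] <- 1 / quad
      T[g, ] <- T[g, ] + (st$r_m[p] - old) * st$Ex[j, ]
    }
  }
  invisible(st)
}

update_beta <- function(st) {
  fr <- st$frame
  if (isTRUE(st$fixed$beta) || !fr$P) return(invisible(st))
  phir <- prec_E(st, "phi_r")
  p0 <- st$hyper$normal_prior_precision
  M <- as.numeric(fr$C %*% st$beta_m)
  for (k in seq_len(ncol(fr$C))) {
    ck <- fr$C[, k]
    quad <- p0 + phir * sum(ck^2)
    lin <- phir * sum(ck * (st$r_m - (M - ck * st$beta_m[k])))
    quad <- clamp_pos(st, quad)
    old <- st$beta_m[k]
    st$beta_m[k] <- lin / quad
    st$beta_v[k] <- 1 / quad
    M <- M + ck * (st$beta_m[k] - old)
  }
  invisible(st)
}

# expected squared residual of the interaction prior, per pair
interaction_prior_ss <- function(st) {
  fr <- st$frame
  M <- as.numeric(fr$C %*% st$beta_m)
  (st$r_m - M)^2 + st$r_v + as.numeric(fr$C^2 %*% st$beta_v)
}

# expected squared stage-prior residuals, per probe, one stage
stage_residual_sq_mir <- function(st, si) {
  fr <- st$frame
  g <- st$geo_mir[[si]]
  ps <- fr$parents_idx[[si]]
  Ax <- as.numeric(st$Ex[, ps, drop = FALSE] %*% g$a)
  Vax <- as.numeric(st$Vx[, ps, drop = FALSE] %*% g$a^2)
  (st$Ex[, si] - Ax - st$tau_m * g$B)^2 + st$Vx[, si] + Vax +
    g$B^2 * st$tau_v
}

# per-gene variance of the interaction total at one stage:
# sum over pairs of Var(r_p x_{j s}) under the factorized posterior
interaction_var_gene <- function(st, si) {
  fr <- st$frame
  Ex2 <- st$Ex[fr$pair_mir, si]^2 + st$Vx[fr$pair_mir, si]
  v <- (st$r_m^2 + st$r_v) * Ex2 - st$r_m^2 * st$Ex[fr$pair_mir, si]^2
  pair_to_gene(v, st)
}

stage_residual_sq_mrna <- function(st, si, T = interaction_totals(st)) {
  fr <- st$frame
  g <- st$geo_mrna[[si]]
  ps <- fr$parents_idx[[si]]
  Ay <- as.numeric(st$Ey[, ps, drop = FALSE] %*% g$a)
  Vay <- as.numeric(st$Vy[, ps, drop = FALSE] %*% g$a^2)
  (st$Ey[, si] - Ay - g$B * T[, si])^2 + st$Vy[, si] + Vay +
    g$B^2 * interaction_var_gene(st, si)
}

update_gammas <- function(st, which = c("phi_r", "lambda_mir", "lambda_mrna",
                                        "phi_set_mir", "phi_rep_mir",
                                        "phi_set_mrna", "phi_rep_mrna")) {
  fr <- st$frame
  a0 <- st$hyper$gamma_shape; b0 <- st$hyper$gamma_rate
  upd <- function(name, shape, rate) {
    if (is.null(st$fixed[[name]])) {
      st$q[[name]] <- gamma_new(shape, clamp_pos(st, rate))
    }
  }
  if ("phi_r" %in% which && fr$P) {
    upd("phi_r", a0 + fr$P / 2, b0 + sum(interaction_prior_ss(st)) / 2)
  }
  if ("lambda_mir" %in% which && length(fr$noninit)) {
    rate <- rep(b0, fr$I)
    for (si in fr$noninit) {
      rate <- rate + st$geo_mir[[si]]$F * stage_residual_sq_mir(st, si) / 2
    }
    upd("lambda_mir", rep(a0 + length(fr$noninit) / 2, fr$I), rate)
  }
  if ("lambda_mrna" %in% which && length(fr$noninit)) {
    rate <- rep(b0, fr$G)
    T <- interaction_totals(st)
    for (si in fr$noninit) {
      rate <- rate + st$geo_mrna[[si]]$F * stage_residual_sq_mrna(st, si, T) / 2
    }
    upd("lambda_mrna", rep(a0 + length(fr$noninit) / 2, fr$G), rate)
  }
  if ("phi_set_mir" %in% which) {
    ss <- (st$Eu - st$Ex[, fr$set_stage, drop = FALSE])^2 + st$Vu +
      st$Vx[, fr$set_stage, drop = FALSE]
    upd("phi_set_mir", a0 + fr$I * fr$K / 2, b0 + sum(ss) / 2)
  }
  if ("phi_rep_mir" %in% which) {
    ss <- fr$Zm_sq - 2 * st$Eu * fr$Zm_sum +
      rep(fr$n_rep, each = fr$I) * (st$Eu^2 + st$Vu)
    upd("phi_rep_mir", a0 + fr$I * fr$n_obs / 2, b0 + sum(ss) / 2)
  }
  if ("phi_set_mrna" %in% which) {
    ss <- (st$Ev - st$Ey[, fr$set_stage, drop = FALSE])^2 + st$Vv +
      st$Vy[, fr$set_stage, drop = FALSE]
    upd("phi_set_mrna", a0 + fr$G * fr$K / 2, b0 + sum(ss) / 2)
  }
  if ("phi_rep_mrna" %in% which) {
    ss <- fr$Zr_sq - 2 * st$Ev * fr$Zr_sum +
      rep(fr$n_rep, each = fr$G) * (st$Ev^2 + st$Vv)
    upd("phi_rep_mrna", a0 + fr$G * fr$n_obs / 2, b0 + sum(ss) / 2)
  }
  invisible(st)
}

# ---------------------------------------------------------------------------
# development-distance optimization (ELBO-maximizing point updates)

# expected-log-joint contribution of one non-initial stage as a function
# of that stage's development vector (miR platform)
delta_objective_mir <- function(st, si, delta) {
  fr <- st$frame
  form <- st$hyper$precision_form
  g <- stage_geometry(delta, form)
  ps <- fr$parents_idx[[si]]
  lam <- prec_E(st, "lambda_mir")
  Ax <- as.numeric(st$Ex[, ps, drop = FALSE] %*% g$a)
  Vax <- as.numeric(st$Vx[, ps, drop = FALSE] %*% g$a^2)
  Q <- (st$Ex[, si] - Ax - st$tau_m * g$B)^2 + st$Vx[, si] + Vax +
    g$B^2 * st$tau_v
  hy <- st$hyper
  sum(0.5 * log(g$F) - lam * g$F * Q / 2) +
    sum((hy$development_shape - 1) * log(delta) - hy$development_rate * delta)
}

delta_objective_mrna <- function(st, si, delta, T, ivar) {
  fr <- st$frame
  form <- st$hyper$precision_form
  g <- stage_geometry(delta, form)
  ps <- fr$parents_idx[[si]]
  lamr <- prec_E(st, "lambda_mrna")
  Ay <- as.numeric(st$Ey[, ps, drop = FALSE] %*% g$a)
  Vay <- as.numeric(st$Vy[, ps, drop = FALSE] %*% g$a^2)
  Q <- (st$Ey[, si] - Ay - g$B * T[, si])^2 + st$Vy[, si] + Vay +
    g$B^2 * ivar
  hy <- st$hyper
  sum(0.5 * log(g$F) - lamr * g$F * Q / 2) +
    sum((hy$development_shape - 1) * log(delta) - hy$development_rate * delta)
}

#' Update the development distances by maximizing the lower bound
#'
#' Each per-edge development distance (miR and mRNA separately) is a point
#' value, updated by bounded one-dimensional search in log space over
#' (1e-6, 1e6) on the expected log joint terms that involve it (including
#' its gamma prior), holding all other factors fixed.  A candidate that
#' does not improve on the current value is rejected, so the evidence
#' lower bound cannot decrease.
#'
#' @param state A `mirord_state`.
#' @return The state, invisibly (modified in place).
#' @export
vb_update_developments <- function(state) {
  st <- state
  fr <- st$frame
  if (isTRUE(st$fixed$delta)) return(invisible(st))
  log_lo <- log(1e-6); log_hi <- log(1e6)
  for (si in fr$noninit) {
    # miR platform
    for (e in seq_along(st$delta_mir[[si]])) {
      cur <- st$delta_mir[[si]]
      obj <- function(l) {
        d <- cur; d[e] <- exp(l)
        delta_objective_mir(st, si, d)
      }
      opt <- try(stats::optimize(obj, c(log_lo, log_hi), maximum = TRUE,
                                 tol = 1e-8), silent = TRUE)
      if (inherits(opt, "try-error")) {
        warning("development optimizer failed; value retained")
        next
      }
      if (opt$objective > obj(log(cur[e]))) {
        st$delta_mir[[si]][e] <- exp(opt$maximum)
      }
    }
    # mRNA platform
    T <- interaction_totals(st)
    ivar <- interaction_var_gene(st, si)
    for (e in seq_along(st$delta_mrna[[si]])) {
      cur <- st$delta_mrna[[si]]
      obj <- function(l) {
        d <- cur; d[e] <- exp(l)
        delta_objective_mrna(st, si, d, T, ivar)
      }
      opt <- try(stats::optimize(obj, c(log_lo, log_hi), maximum = TRUE,
                                 tol = 1e-8), silent = TRUE)
      if (inherits(opt, "try-error")) {
        warning("development optimizer failed; value retained")
        next
      }
      if (opt$objective > obj(log(cur[e]))) {
        st$delta_mrna[[si]][e] <- exp(opt$maximum)
      }
    }
  }
  refresh_geometry(st)
  invisible(st)
}

# ---------------------------------------------------------------------------
# evidence lower bound

gamma_entropy <- function(shape, rate) {
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

#' Evidence lower bound of the current variational posterior
#'
#' Computes `E_q[log p(data, parameters)] - E_q[log q]` in closed form
#' (normal and gamma entropies; expected log precisions via digamma).
#' Parameters held fixed by [vb_control()] are treated as known constants:
#' they contribute neither prior nor entropy terms, so the bound is
#' conditional on their values.
#'
#' @param state A `mirord_state`.
#' @return A single number.
#' @export
vb_elbo <- function(state) {
  st <- state
  fr <- st$frame
  hy <- st$hyper
  p0 <- hy$normal_prior_precision
  a0 <- hy$gamma_shape; b0 <- hy$gamma_rate
  l2pi <- log(2 * pi)
  total <- 0

  # observation and set-level terms
  for (pl in c("mir", "mrna")) {
    if (pl == "mir") {
      Es <- st$Eu; Vs <- st$Vu; Ez <- st$Ex; Vz <- st$Vx
      Zs <- fr$Zm_sum; Zq <- fr$Zm_sq; n <- fr$I
      ps_n <- "phi_set_mir"; pr_n <- "phi_rep_mir"
    } else {
      Es <- st$Ev; Vs <- st$Vv; Ez <- st$Ey; Vz <- st$Vy
      Zs <- fr$Zr_sum; Zq <- fr$Zr_sq; n <- fr$G
      ps_n <- "phi_set_mrna"; pr_n <- "phi_rep_mrna"
    }
    ps <- prec_E(st, ps_n); psl <- prec_Elog(st, ps_n)
    pr <- prec_E(st, pr_n); prl <- prec_Elog(st, pr_n)
    ss_rep <- Zq - 2 * Es * Zs + rep(fr$n_rep, each = n) * (Es^2 + Vs)
    total <- total + (n * fr$n_obs / 2) * (prl - l2pi) - pr * sum(ss_rep) / 2
    ss_set <- (Es - Ez[, fr$set_stage, drop = FALSE])^2 + Vs +
      Vz[, fr$set_stage, drop = FALSE]
    total <- total + (n * fr$K / 2) * (psl - l2pi) - ps * sum(ss_set) / 2
  }

  # stage priors
  lam <- prec_E(st, "lambda_mir"); laml <- prec_Elog(st, "lambda_mir")
  lamr <- prec_E(st, "lambda_mrna"); lamrl <- prec_Elog(st, "lambda_mrna")
  T <- interaction_totals(st)
  for (si in seq_len(fr$S)) {
    if (fr$is_init[si]) {
      total <- total + sum(0.5 * (log(p0) - l2pi) -
                             p0 * (st$Ex[, si]^2 + st$Vx[, si]) / 2)
      total <- total + sum(0.5 * (log(p0) - l2pi) -
                             p0 * (st$Ey[, si]^2 + st$Vy[, si]) / 2)
    } else {
      gm <- st$geo_mir[[si]]
      Q <- stage_residual_sq_mir(st, si)
      total <- total + sum(0.5 * (laml + log(gm$F) - l2pi) - lam * gm$F * Q / 2)
      gy <- st$geo_mrna[[si]]
      Qy <- stage_residual_sq_mrna(st, si, T)
      total <- total + sum(0.5 * (lamrl + log(gy$F) - l2pi) -
                             lamr * gy$F * Qy / 2)
    }
  }

  # interaction priors
  if (fr$P) {
    phir <- prec_E(st, "phi_r"); phirl <- prec_Elog(st, "phi_r")
    total <- total + (fr$P / 2) * (phirl - l2pi) -
      phir * sum(interaction_prior_ss(st)) / 2
  }

  # vague normal priors on trends and coefficients
  total <- total + sum(0.5 * (log(p0) - l2pi) -
                         p0 * (st$tau_m^2 + st$tau_v) / 2)
  if (!isTRUE(st$fixed$beta)) {
    total <- total + sum(0.5 * (log(p0) - l2pi) -
                           p0 * (st$beta_m^2 + st$beta_v) / 2)
  }

  # gamma hyperpriors + entropies for free precisions
  for (name in names(st$q)) {
    if (!is.null(st$fixed[[name]])) next
    if (name == "phi_r" && !fr$P) next
    sh <- st$q[[name]]$shape; ra <- st$q[[name]]$rate
    el <- digamma(sh) - log(ra)
    total <- total + sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * el -
                           b0 * sh / ra)
    total <- total + sum(gamma_entropy(sh, ra))
  }

  # development priors
  if (!isTRUE(st$fixed$delta)) {
    dall <- c(unlist(st$delta_mir), unlist(st$delta_mrna))
    if (length(dall)) {
      total <- total + sum((hy$development_shape - 1) * log(dall) -
                             hy$development_rate * dall +
                             hy$development_shape * log(hy$development_rate) -
                             lgamma(hy$development_shape))
    }
  }

  # normal entropies
  ent <- function(v) sum(0.5 * log(2 * pi * exp(1) * v))
  total <- total + ent(st$Vx) + ent(st$Vy) + ent(st$Vu) + ent(st$Vv) +
    ent(st$tau_v)
  if (fr$P) total <- total + ent(st$r_v)
  if (!isTRUE(st$fixed$beta)) total <- total + ent(st$beta_v)
  total
}

# ---------------------------------------------------------------------------
# public single-parameter update and the full fitting loop

#' Apply one exact conjugate coordinate update
#'
#' Replaces the named variational factor (or family of factors) by its
#' exact mean-field optimum given all other factors; the evidence lower
#' bound cannot decrease.  Families are updated in a sequence of exact
#' single-coordinate updates wherever coordinates interact.
#'
#' Recognised ids: `"u"`, `"v"` (set-level latents), `"x"`, `"y"` (stage
#' latents; optionally `"x:<probe>:<stage>"` for a single coordinate),
#' `"tau"` (or `"tau:<probe>"`), `"r"` (or `"r:<gene>"`), `"beta"`,
#' `"phi_r"`, `"lambda_mir"`, `"lambda_mrna"`, `"phi_set_mir"`,
#' `"phi_rep_mir"`, `"phi_set_mrna"`, `"phi_rep_mrna"`.
#'
#' @param state A `mirord_state` (modified in place).
#' @param param_id Parameter identifier string (see Details).
#' @return The state, invisibly.
#' @export
vb_update <- function(state, param_id) {
  st <- state
  fr <- st$frame
  parts <- strsplit(param_id, ":", fixed = TRUE)[[1L]]
  head_id <- parts[1L]
  arg2 <- if (length(parts) > 1L) parts[2L] else NULL
  arg3 <- if (length(parts) > 2L) parts[3L] else NULL
  probe_idx <- function(id, ids) {
    k <- match(id, ids)
    if (is.na(k)) stop("unknown probe/stage id '", id, "'")
    k
  }
  switch(head_id,
    u = update_set_latents(st, "mir"),
    v = update_set_latents(st, "mrna"),
    x = update_x(st,
                 only_i = if (!is.null(arg2)) probe_idx(arg2, fr$mir_ids),
                 only_si = if (!is.null(arg3)) probe_idx(arg3, fr$stages)),
    y = update_y(st, only_si = if (!is.null(arg2)) probe_idx(arg2, fr$stages)),
    tau = update_tau(st, only_i = if (!is.null(arg2)) probe_idx(arg2, fr$mir_ids)),
    r = update_r(st, only_gene = if (!is.null(arg2)) probe_idx(arg2, fr$gene_ids)),
    beta = update_beta(st),
    phi_r = ,
    lambda_mir = ,
    lambda_mrna = ,
    phi_set_mir = ,
    phi_rep_mir = ,
    phi_set_mrna = ,
    phi_rep_mrna = update_gammas(st, which = head_id),
    stop("unknown parameter id '", param_id, "'")
  )
  invisible(st)
}

vb_sweep <- function(st) {
  update_set_latents(st, "mir")
  update_set_latents(st, "mrna")
  update_x(st)
  update_y(st)
  update_tau(st)
  update_r(st)
  update_beta(st)
  update_gammas(st, "phi_r")
  update_gammas(st, c("lambda_mir", "lambda_mrna"))
  update_gammas(st, c("phi_set_mir", "phi_rep_mir",
                      "phi_set_mrna", "phi_rep_mrna"))
  invisible(st)
}

#' Fit the model by variational Bayes coordinate ascent
#'
#' Runs [vb_initialize()] and then `n_iter` outer iterations, each a full
#' sweep of exact conjugate updates in a fixed order (set-level latents,
#' stage latents in topological order, trends, interactions, prediction
#' coefficients, then all precisions) followed by the ELBO-maximizing
#' point update of the development distances.  The evidence lower bound is
#' recorded after every outer iteration and is non-decreasing up to
#' numerical tolerance; 200 iterations are the default fitting schedule.
#'
#' @inheritParams vb_initialize
#' @param n_iter Number of outer iterations (default 200).
#' @param verbose Print the ELBO every 25 iterations?
#' @return The fitted `mirord_state`, with `elbo_trace` filled.
#' @export
vb_fit <- function(data, order, predictions,
                   hyper = default_hyperparameters(), n_iter = 200L,
                   seed = 1L, control = vb_control(), verbose = FALSE) {
  stopifnot(n_iter >= 1L)
  st <- vb_initialize(data, order, predictions, hyper, seed, control)
  last <- -Inf
  for (iter in seq_len(n_iter)) {
    vb_sweep(st)
    vb_update_developments(st)
    e <- vb_elbo(st)
    if (!is.finite(e)) {
      stop("non-finite ELBO at iteration ", iter,
           " (last update: developments); aborting")
    }
    st$elbo_trace <- c(st$elbo_trace, e)
    if (verbose && iter %% 25L == 0L) {
      message(sprintf("iteration %d: ELBO %.6f", iter, e))
    }
    if (st$control$elbo_tol > 0 && is.finite(last) &&
        abs(e - last) < st$control$elbo_tol * abs(e)) {
      break
    }
    last <- e
  }
  st
}

# ---------------------------------------------------------------------------
# posterior accessors

#' Posterior summaries of the interaction coefficients
#'
#' @param state A fitted `mirord_state`.
#' @return Data frame: `mir`, `gene`, `mean`, `sd`, `z` (posterior mean in
#'   posterior-sd units) and `predicted_by` (comma-separated algorithm
#'   names), one row per candidate pair.
#' @export
interaction_posterior <- function(state) {
  fr <- state$frame
  p <- fr$predictions$pairs
  algs <- fr$predictions$algorithms
  predicted_by <- apply(p[, paste0("predicted_", algs), drop = FALSE], 1L,
                        function(ind) paste(algs[ind == 1L], collapse = ","))
  sd <- sqrt(state$r_v)
  data.frame(mir = p$mir, gene = p$gene, mean = state$r_m, sd = sd,
             z = state$r_m / sd, predicted_by = predicted_by,
             stringsAsFactors = FALSE)
}

#' Posterior summaries of the per-miR trends
#'
#' @param state A fitted `mirord_state`.
#' @return Data frame: `mir`, `mean`, `sd`, `z`.
#' @export
trend_posterior <- function(state) {
  sd <- sqrt(state$tau_v)
  data.frame(mir = state$frame$mir_ids, mean = state$tau_m, sd = sd,
             z = state$tau_m / sd, stringsAsFactors = FALSE)
}

#' Development-distance point estimates
#' @param state A fitted `mirord_state`.
#' @return Data frame: `parent`, `child`, `platform`, `delta`.
#' @export
development_estimates <- function(state) {
  fr <- state$frame
  rows <- list()
  for (si in fr$noninit) {
    ps <- fr$stages[fr$parents_idx[[si]]]
    rows[[length(rows) + 1L]] <- data.frame(
      parent = rep(ps, 2L), child = fr$stages[si],
      platform = rep(c("miR", "mRNA"), each = length(ps)),
      delta = c(state$delta_mir[[si]], state$delta_mrna[[si]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
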