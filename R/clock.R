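# ---------------------------------------------------------------------------
# Fossil-calibrated relaxed molecular clock on a fixed rooted topology.
# Likelihood: LG amino-acid model with discrete-gamma rate heterogeneity
# (4 equal-probability categories, mean-of-category rates, normalized to
# mean 1), computed by Felsenstein pruning with branch length =
# branch rate x branch duration.  Priors: Yule on node ages, independent
# lognormal branch rates constrained to expected rate 1 (so calibrations
# supply the absolute time scale), lognormal fossil calibrations with a
# hard minimum offset.  Inference: Metropolis-Hastings MCMC; no topology
# moves (the topology is fixed by upstream inference and reconciliation).
# ---------------------------------------------------------------------------

.smtphylo_env <- new.env(parent = emptyenv())

# Build and cache the LG rate matrix (scaled to one expected substitution
# per site at equilibrium) and its eigendecomposition via the standard
# symmetrization D^(1/2) Q D^(-1/2).
lg_eigen <- function() {
  if (!is.null(.smtphylo_env$lg)) return(.smtphylo_env$lg)
  S <- 20L
  ex <- matrix(0, S, S)
  ex[lower.tri(ex)] <- .LG_EXCH
  ex <- ex + t(ex)
  pi <- .LG_FREQ / sum(.LG_FREQ)
  Q <- ex * rep(pi, each = S)
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  Q <- Q / beta
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / d) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(d)
  out <- list(Q = Q, pi = pi, U = U, Uinv = Uinv, lambda = eig$values,
              aa = .LG_AA)
  .smtphylo_env$lg <- out
  out
}

#' LG transition probability matrix
#'
#' @param t Expected substitutions per site (branch length).
#' @return 20x20 stochastic matrix P(t), rows/cols in ARNDCQEGHILKMFPSTWYV
#'   order.
#' @export
lg_transition <- function(t) {
  if (t < 0) stop("branch length must be non-negative")
  lg <- lg_eigen()
  P <- lg$U %*% diag(exp(lg$lambda * t)) %*% lg$Uinv
  P[P < 0] <- 0
  dimnames(P) <- list(lg$aa, lg$aa)
  P
}

#' LG equilibrium frequencies
#' @return Named numeric vector of the 20 stationary frequencies.
#' @export
lg_frequencies <- function() {
  lg <- lg_eigen()
  setNames(lg$pi, lg$aa)
}

#' Discrete-gamma category rates (mean-of-category convention)
#'
#' Equal-probability categories of a Gamma(shape, rate = shape)
#' distribution (mean 1); each category is represented by its conditional
#' mean, so the category rates average exactly 1.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param ncat Number of categories (default 4).
#' @return Numeric vector of `ncat` rates.
#' @export
gamma_category_rates <- function(shape, ncat = 4) {
  if (shape <= 0) stop("gamma shape must be positive")
  if (ncat < 1) stop("need at least one rate category")
  if (ncat == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = ncat + 1), shape, rate = shape)
  r <- ncat * diff(pgamma(b, shape + 1, rate = shape))
  r / mean(r) * 1  # guard against tail rounding; mean is 1 analytically
}

# alignment -> integer codes (0..19; -1 for gap/X/other), site patterns
.encode_alignment <- function(aln) {
  lg <- lg_eigen()
  codes <- matrix(match(aln, lg$aa) - 1L, nrow = nrow(aln))
  codes[is.na(codes)] <- -1L
  rownames(codes) <- rownames(aln)
  key <- apply(codes, 2, paste, collapse = ",")
  idx <- match(key, unique(key))
  patterns <- codes[, !duplicated(key), drop = FALSE]
  weights <- as.numeric(table(factor(idx, levels = seq_len(ncol(patterns)))))
  list(patterns = patterns, weights = weights)
}

#' Fossil calibration on a clade's age
#'
#' The clade age minus `offset` follows a lognormal(log_mean, log_sd)
#' distribution; ages at or below the hard minimum `offset` have density
#' zero.
#'
#' @param clade Character vector of tip labels identifying the calibrated
#'   node (their MRCA).
#' @param offset Hard minimum age (e.g. Ma).
#' @param log_mean,log_sd Lognormal parameters of (age - offset).
#' @return A `calibration` list.
#' @export
calibration <- function(clade, offset, log_mean, log_sd) {
  if (offset < 0) stop("offset must be >= 0")
  if (log_sd <= 0) stop("log_sd must be positive")
  structure(list(clade = clade, offset = offset, log_mean = log_mean,
                 log_sd = log_sd), class = "calibration")
}

#' Log-density of a calibration at a given age
#' @param age Node age.
#' @param cal A [calibration()].
#' @return Log-density; `-Inf` at or below the hard minimum.
#' @export
calibration_log_density <- function(age, cal) {
  if (age <= cal$offset) return(-Inf)
  dlnorm(age - cal$offset, cal$log_mean, cal$log_sd, log = TRUE)
}

#' Read calibrations from a TSV file
#'
#' Columns: `clade` (comma-separated tip labels), `offset`, `log_mean`,
#' `log_sd`.
#' @param path File path.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade", "offset", "log_mean", "log_sd")
  if (!all(need %in% names(tab))) {
    stop("calibration file needs columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    calibration(strsplit(tab$clade[i], ",")[[1]], tab$offset[i],
                tab$log_mean[i], tab$log_sd[i])
  })
}

#' Write calibrations to a TSV file
#' @param cals List of [calibration()] objects.
#' @param path Output path.
#' @export
write_calibrations <- function(cals, path) {
  tab <- data.frame(
    clade = vapply(cals, function(c) paste(c$clade, collapse = ","), ""),
    offset = vapply(cals, `[[`, 0, "offset"),
    log_mean = vapply(cals, `[[`, 0, "log_mean"),
    log_sd = vapply(cals, `[[`, 0, "log_sd")
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a relaxed-clock model
#'
#' @param topology Rooted binary `phylo`, fixed throughout the run.
#' @param alignment Character matrix ([as_alignment()]) or named character
#'   vector of aligned residue strings; names must match the tips.
#' @param calibrations List of [calibration()] objects.
#' @param n_gamma_categories Number of discrete-gamma categories
#'   (default 4).
#' @return A `clock_model` list used by [site_likelihood()] and [mcmc()].
#' @export
clock_model <- function(topology, alignment, calibrations = list(),
                        n_gamma_categories = 4) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    alignment <- as_alignment(alignment)
  }
  if (!setequal(rownames(alignment), topology$tip.label)) {
    stop("alignment names and topology leaves differ")
  }
  ntip <- length(topology$tip.label)
  kids <- .children_list(topology)
  if (any(lengths(kids)[(ntip + 1L):(ntip + topology$Nnode)] != 2)) {
    stop("topology must be rooted and binary")
  }
  alignment <- alignment[topology$tip.label, , drop = FALSE]
  enc <- .encode_alignment(alignment)
  post <- ape::reorder.phylo(topology, "postorder")
  cal_nodes <- vapply(calibrations, function(cal) {
    unknown <- setdiff(cal$clade, topology$tip.label)
    if (length(unknown)) {
      stop("calibration clade unresolvable; unknown tips: ",
           paste(unknown, collapse = ", "))
    }
    nd <- .mrca_of(topology, cal$clade)
    if (nd <= ntip) stop("calibration clade resolves to a single tip")
    nd
  }, integer(1))
  structure(list(
    topology = topology, edges = post$edge, ntip = ntip,
    nnode = topology$Nnode, patterns = enc$patterns,
    weights = enc$weights, n_sites = ncol(alignment),
    calibrations = calibrations, cal_nodes = cal_nodes,
    ncat = n_gamma_categories
  ), class = "clock_model")
}

#' LG+Gamma log-likelihood of a clock state
#'
#' @param model A [clock_model()].
#' @param ages Numeric vector of internal-node ages (names/order = ape
#'   internal node numbers `ntip+1 .. ntip+Nnode`); tips are age 0.
#' @param rates Per-edge substitution rates, aligned with `model$edges`
#'   rows.
#' @param gamma_shape Gamma shape for among-site rate heterogeneity.
#' @return Log-likelihood of the alignment.
#' @export
site_likelihood <- function(model, ages, rates, gamma_shape) {
  all_ages <- c(rep(0, model$ntip), ages)
  dur <- all_ages[model$edges[, 1]] - all_ages[model$edges[, 2]]
  if (any(dur < -1e-9)) stop("ages violate parent > child")
  blen <- pmax(dur, 0) * rates
  lg <- lg_eigen()
  prune_loglik_cpp(model$edges, model$ntip, model$nnode, blen,
                   model$patterns, model$weights, lg$U, lg$Uinv,
                   lg$lambda, lg$pi,
                   gamma_category_rates(gamma_shape, model$ncat))
}

#' Yule (pure-birth) log-prior on node ages
#'
#' Standard Yule density on the internal-node ages of a labeled topology:
#' each internal node contributes `log(birth_rate) - birth_rate * age`, and
#' the root contributes one extra `-birth_rate * age` term.  For a 2-taxon
#' tree this reduces to an exponential density on the root age.
#'
#' @param ages Internal-node ages (root = oldest).
#' @param birth_rate Speciation rate (> 0).
#' @return Log-density.
#' @export
yule_log_prior <- function(ages, birth_rate) {
  if (birth_rate <= 0) stop("birth rate must be positive")
  sum(log(birth_rate) - birth_rate * ages) - birth_rate * max(ages)
}

#' Log-prior of branch rates under the uncorrelated lognormal clock
#'
#' Rates are independent lognormal draws with log-mean `-rate_log_sd^2/2`,
#' so the expected rate is exactly 1: relative node ages are measured in
#' substitution time and the calibrations supply the absolute scale.
#'
#' @param rates Positive per-branch rates.
#' @param rate_log_sd Lognormal standard deviation (sigma) on the log
#'   scale.
#' @return Log-density (sum over branches).
#' @export
rates_log_prior <- function(rates, rate_log_sd) {
  if (rate_log_sd <= 0) return(-Inf)
  if (any(rates <= 0)) return(-Inf)
  sum(dlnorm(rates, -rate_log_sd^2 / 2, rate_log_sd, log = TRUE))
}

# total log-prior of a state (hyperpriors documented in mcmc())
.clock_log_prior <- function(model, state) {
  lp <- yule_log_prior(state$ages, state$birth_rate) +
    rates_log_prior(state$rates, state$rate_log_sd) +
    dexp(state$gamma_shape, 1, log = TRUE) +
    dexp(state$rate_log_sd, 3, log = TRUE) +
    dexp(state$birth_rate, 0.1, log = TRUE)
  for (i in seq_along(model$calibrations)) {
    nd <- model$cal_nodes[i]
    lp <- lp + calibration_log_density(
      state$ages[nd - model$ntip], model$calibrations[[i]]
    )
  }
  lp
}

# initial state: node-ranking ages rescaled toward the calibrations
.clock_init_state <- function(model, seed_ages = NULL) {
  ntip <- model$ntip
  kids <- .children_list(model$topology)
  ages <- rep(0, ntip + model$nnode)
  for (v in .postorder_nodes(model$topology)) {
    if (v <= ntip) next
    ages[v] <- max(ages[unlist(kids[[v]])]) + 1
  }
  ages <- ages[(ntip + 1L):(ntip + model$nnode)]
  if (!is.null(seed_ages)) ages <- seed_ages
  if (length(model$calibrations)) {
    # centre the scale on the calibration targets, then push up until all
    # hard minima are satisfied
    s <- mean(vapply(seq_along(model$calibrations), function(i) {
      cal <- model$calibrations[[i]]
      (cal$offset + exp(cal$log_mean)) / ages[model$cal_nodes[i] - ntip]
    }, numeric(1)))
    ages <- ages * s
    repeat {
      ok <- all(vapply(seq_along(model$calibrations), function(i) {
        ages[model$cal_nodes[i] - ntip] > model$calibrations[[i]]$offset
      }, logical(1)))
      if (ok) break
      ages <- ages * 1.1
    }
  }
  list(ages = ages, rates = rep(1, nrow(model$edges)),
       gamma_shape = 1, rate_log_sd = 0.3,
       birth_rate = (model$ntip - 1) / max(ages))
}

#' Metropolis-Hastings MCMC for the relaxed clock
#'
#' Moves: (i) uniform slide of a non-root internal-node age within
#' (oldest child age, parent age); (ii) scale of the root age above its
#' oldest child; (iii) scale of all node ages at once (mixes the overall
#' time scale against the calibrations); (iv) multiplier on a single
#' branch rate; (v) scale moves on `gamma_shape`, `rate_log_sd` and
#' `birth_rate` — each with the proper proposal-ratio term.  Scalar hyperpriors: `gamma_shape ~ Exp(1)`,
#' `rate_log_sd ~ Exp(3)` (mean 1/3), `birth_rate ~ Exp(0.1)` (diffuse).
#' The trace includes the generation-0 state, so its length is
#' `floor(n_gens / sample_every) + 1`.
#'
#' @param model A [clock_model()].
#' @param n_gens Number of generations (>= 1).
#' @param sample_every Sampling interval.
#' @param seed Integer seed; runs are deterministic given the seed.
#' @param move_weights Named weights for move classes `node_age`,
#'   `root_age`, `branch_rate`, `gamma_shape`, `rate_log_sd`,
#'   `birth_rate`.
#' @param use_likelihood `FALSE` samples from the prior alone (the standard
#'   sampler-correctness check).
#' @param init Optional initial state (as built by the internal
#'   initializer).
#' @return Trace data.frame (`gen`, `log_posterior`, `log_likelihood`,
#'   scalars, mean branch rate, and one `age_<node>` column per internal
#'   node), with acceptance rates and the seed in attributes.
#' @export
mcmc <- function(model, n_gens, sample_every = 100, seed = 1,
                 move_weights = c(node_age = 30, root_age = 5,
                                  tree_scale = 5, branch_rate = 30,
                                  gamma_shape = 2, rate_log_sd = 2,
                                  birth_rate = 2),
                 use_likelihood = TRUE, init = NULL) {
  if (n_gens < 1) stop("n_gens must be >= 1")
  set.seed(seed)
  ntip <- model$ntip
  root <- ntip + 1L
  idx <- .tree_index(model$topology)
  kids <- .children_list(model$topology)
  state <- if (is.null(init)) .clock_init_state(model) else init
  loglik <- function(s) {
    if (!use_likelihood) return(0)
    site_likelihood(model, s$ages, s$rates, s$gamma_shape)
  }
  ll <- loglik(state)
  lp <- .clock_log_prior(model, state)
  if (!is.finite(ll + lp)) stop("zero-probability starting state")
  internal <- (ntip + 1L):(ntip + model$nnode)
  non_root <- setdiff(internal, root)
  moves <- names(move_weights)
  probs <- move_weights / sum(move_weights)
  n_samples <- floor(n_gens / sample_every) + 1L
  age_cols <- paste0("age_", internal)
  trace <- matrix(NA_real_, n_samples, 7 + length(internal))
  colnames(trace) <- c("gen", "log_posterior", "log_likelihood",
                       "birth_rate", "gamma_shape", "rate_log_sd",
                       "mean_rate", age_cols)
  record <- function(row, gen) {
    trace[row, ] <<- c(gen, ll + lp, ll, state$birth_rate,
                       state$gamma_shape, state$rate_log_sd,
                       mean(state$rates), state$ages)
  }
  record(1L, 0L)
  acc <- prop <- setNames(numeric(length(moves)), moves)
  tune <- 1.0
  for (gen in seq_len(n_gens)) {
    mv <- sample(moves, 1, prob = probs)
    prop[mv] <- prop[mv] + 1
    cand <- state
    hastings <- 0
    lik_changed <- TRUE
    if (mv == "node_age" && length(non_root)) {
      v <- if (length(non_root) == 1L) non_root else sample(non_root, 1)
      all_ages <- c(rep(0, ntip), state$ages)
      lo <- max(all_ages[unlist(kids[[v]])])
      hi <- all_ages[idx$parent[v]]
      cand$ages[v - ntip] <- runif(1, lo, hi)
    } else if (mv == "root_age" || mv == "node_age") {
      all_ages <- c(rep(0, ntip), state$ages)
      lo <- max(all_ages[unlist(kids[[root]])])
      m <- exp(tune * (runif(1) - 0.5))
      cand$ages[root - ntip] <- lo + (state$ages[root - ntip] - lo) * m
      hastings <- log(m)
    } else if (mv == "tree_scale") {
      m <- exp(tune * (runif(1) - 0.5))
      cand$ages <- state$ages * m
      hastings <- length(state$ages) * log(m)
    } else if (mv == "branch_rate") {
      e <- sample.int(nrow(model$edges), 1)
      m <- exp(tune * (runif(1) - 0.5))
      cand$rates[e] <- state$rates[e] * m
      hastings <- log(m)
      lik_changed <- use_likelihood
    } else {
      m <- exp(tune * (runif(1) - 0.5))
      cand[[mv]] <- state[[mv]] * m
      hastings <- log(m)
      lik_changed <- mv == "gamma_shape" && use_likelihood
    }
    cand_lp <- .clock_log_prior(model, cand)
    if (is.finite(cand_lp)) {
      cand_ll <- if (lik_changed || mv %in% c("node_age", "root_age")) {
        loglik(cand)
      } else ll
      if (log(runif(1)) < cand_ll + cand_lp - ll - lp + hastings) {
        state <- cand; ll <- cand_ll; lp <- cand_lp
        acc[mv] <- acc[mv] + 1
      }
    }
    if (gen %% sample_every == 0) record(gen %/% sample_every + 1L, gen)
  }
  out <- as.data.frame(trace)
  attr(out, "acceptance") <- ifelse(prop > 0, acc / prop, NA)
  attr(out, "seed") <- seed
  attr(out, "node_ids") <- internal
  out
}

#' Highest-posterior-density interval of a sample
#' @param x Numeric sample.
#' @param prob Credibility level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1L)
  w <- x[starts + m - 1L] - x[starts]
  i <- which.min(w)
  c(x[i], x[i + m - 1L])
}

#' Summarize an MCMC trace: median node ages and 95% HPD intervals
#'
#' @param trace Trace from [mcmc()].
#' @param burnin_fraction Fraction of samples discarded from the start
#'   (default 0.25).
#' @return data.frame `node`, `median_age`, `hpd_lower`, `hpd_upper`.
#' @export
summarize_trace <- function(trace, burnin_fraction = 0.25) {
  n <- nrow(trace)
  burn <- floor(burnin_fraction * n)
  if (burn >= n) stop("burn-in consumes all samples")
  keep <- trace[(burn + 1L):n, , drop = FALSE]
  age_cols <- grep("^age_", colnames(trace), value = TRUE)
  out <- lapply(age_cols, function(cl) {
    h <- hpd_interval(keep[[cl]])
    data.frame(node = as.integer(sub("age_", "", cl)),
               median_age = median(keep[[cl]]),
               hpd_lower = h[1], hpd_upper = h[2])
  })
  do.call(rbind, out)
}

#' Dated tree from a trace summary
#'
#' Sets each internal node to its posterior median age; small violations of
#' parent > child (possible because medians are marginal) are clamped.
#'
#' @param model The [clock_model()] used for the run.
#' @param summary Output of [summarize_trace()].
#' @return Ultrametric `phylo` with branch lengths in age units.
#' @export
dated_tree_from_summary <- function(model, summary) {
  ntip <- model$ntip
  ages <- rep(0, ntip + model$nnode)
  ages[summary$node] <- summary$median_age
  kids <- .children_list(model$topology)
  for (v in rev(.postorder_nodes(model$topology))) {
    if (v <= ntip) next
    for (ch in unlist(kids[[v]])) {
      if (ch > ntip && ages[ch] >= ages[v]) {
        ages[ch] <- ages[v] * (1 - 1e-9)
      }
    }
  }
  set_node_ages(model$topology, ages)
}
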