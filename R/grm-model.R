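#' Construct a graded response model item
#'
#' An item under Samejima's graded response model (GRM) is described by a
#' positive discrimination `a` (logistic metric) and `V - 1` strictly
#' increasing thresholds `b`, where `V` is the number of ordered response
#' categories. A dichotomous item (`V = 2`, the two-parameter logistic model)
#' has a single threshold.
#'
#' @param a positive discrimination parameter (logistic metric).
#' @param b numeric vector of strictly increasing thresholds.
#' @return An object of class `grm_item` with elements `a` and `b`.
#' @examples
#' it <- grm_item(2, c(-1, 0, 1, 2))
#' n_categories(it)
#' @export
grm_item <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number")
  if (!is.numeric(b) || length(b) < 1L || anyNA(b))
    stop("`b` must be a numeric vector of thresholds")
  if (length(b) > 1L && any(diff(b) <= 0))
    stop("thresholds must be strictly increasing")
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "grm_item")
}

#' @rdname grm_item
#' @param item a `grm_item`.
#' @export
n_categories <- function(item) length(item$b) + 1L

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("GRM item: V = %d, a = %.3f, b = (%s)\n",
              n_categories(x), x$a, paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' Quadrature grid for latent-trait integration
#'
#' Equally spaced nodes with weights proportional to a normal density,
#' renormalized to sum to one. The default (61 nodes on \[-6, 6\], standard
#' normal weights) matches the estimation and scoring routines in this
#' package; a much denser grid serves as a brute-force integration oracle.
#'
#' @param n number of nodes.
#' @param lower,upper grid end points.
#' @param mean,sd moments of the normal prior supplying the weights.
#' @return A `latent_grid` object: list with `nodes` and `weights`.
#' @export
latent_grid <- function(n = 61L, lower = -6, upper = 6, mean = 0, sd = 1) {
  if (n < 2L || upper <= lower) stop("invalid grid specification")
  if (sd <= 0) stop("`sd` must be positive")
  nodes <- seq(lower, upper, length.out = n)
  w <- stats::dnorm(nodes, mean, sd)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "latent_grid")
}

#' Group structure for multigroup models
#'
#' The reference group fixes the latent metric (mean 0, variance 1); the
#' focal group's mean and variance are free model parameters.
#'
#' @param focal_mean focal group latent mean.
#' @param focal_variance positive focal group latent variance.
#' @return A `group_structure` object.
#' @export
group_structure <- function(focal_mean = 0, focal_variance = 1) {
  if (focal_variance <= 0) stop("`focal_variance` must be positive")
  structure(list(focal_mean = focal_mean, focal_variance = focal_variance),
            class = "group_structure")
}

#' Cumulative category response probability
#'
#' Probability of responding in category `v` or higher,
#' `P(u >= v) = logistic(a (theta - b_v))`, in the pure logistic metric
#' (no 1.7 scaling constant; see [a_to_loading()] for the normal-ogive
#' conversion).
#'
#' @param item a [grm_item()].
#' @param theta latent trait value(s).
#' @param v category index, `1 <= v <= V - 1`.
#' @return Probability (vectorized over `theta`).
#' @export
cumulative_prob <- function(item, theta, v) {
  stopifnot(inherits(item, "grm_item"))
  if (length(v) != 1L || v < 1L || v > length(item$b))
    stop("invalid category index `v`")
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  stats::plogis(item$a * (theta - item$b[v]))
}

#' Category response probabilities
#'
#' Probability of each of the `V` categories at trait value `theta`, as
#' differences of consecutive cumulative probabilities. Rows sum to one.
#'
#' @inheritParams cumulative_prob
#' @return For scalar `theta` a length-`V` vector; otherwise a
#'   `length(theta) x V` matrix.
#' @export
category_prob <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  cum <- stats::plogis(outer(theta, item$b, function(t, b) item$a * (t - b)))
  cum <- cbind(1, cum, 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
  if (length(theta) == 1L) drop(p) else p
}

# V x Q probability matrix for one item at the grid nodes (internal,
# vectorized building block shared by likelihoods, EAP, and simulation)
.item_prob_matrix <- function(item, nodes) {
  cum <- stats::plogis(item$a * outer(item$b, nodes, function(b, t) t - b))
  cum <- rbind(1, cum, 0)
  p <- cum[-nrow(cum), , drop = FALSE] - cum[-1L, , drop = FALSE]
  pmax(p, 1e-300)
}

# P x Q matrix of log pattern likelihoods: responses is a persons x items
# integer matrix with categories 0..V-1 and NA for missing.
.pattern_loglik_matrix <- function(responses, items, nodes) {
  P <- nrow(responses)
  Q <- length(nodes)
  out <- matrix(0, P, Q)
  for (j in seq_along(items)) {
    lp <- log(.item_prob_matrix(items[[j]], nodes))
    lp <- rbind(lp, 0)  # extra row: missing contributes nothing
    u <- responses[, j]
    idx <- ifelse(is.na(u), nrow(lp), u + 1L)
    out <- out + lp[idx, , drop = FALSE]
  }
  out
}

#' Log-likelihood of one response pattern at a fixed trait value
#'
#' Sum of log category probabilities over the observed entries of a pattern
#' (local independence); missing entries are skipped, so an all-missing
#' pattern has log-likelihood 0.
#'
#' @param pattern integer vector of responses in `0..V-1`, `NA` = missing.
#' @param items list of [grm_item()] objects, one per pattern entry.
#' @param theta scalar trait value.
#' @return Scalar log-likelihood.
#' @export
pattern_loglik <- function(pattern, items, theta) {
  if (length(pattern) != length(items))
    stop("pattern length must equal number of items")
  ll <- 0
  for (j in seq_along(items)) {
    u <- pattern[j]
    if (is.na(u)) next
    V <- n_categories(items[[j]])
    if (u < 0 || u >= V) stop("response category out of range for item ", j)
    p <- category_prob(items[[j]], theta)
    ll <- ll + log(p[u + 1L])
  }
  ll
}

#' Marginal log-likelihood of a two-group data set
#'
#' Quadrature approximation of the marginal likelihood: each person's
#' pattern likelihood is integrated against the group's normal prior
#' (reference N(0,1); focal N(focal_mean, focal_variance)) on the supplied
#' grid nodes, and log contributions are summed over persons.
#'
#' @param data list with response matrices `ref` and `foc` (categories
#'   `0..V-1`, `NA` = missing).
#' @param params list with item lists `ref` and `foc`.
#' @param groups a [group_structure()].
#' @param grid a [latent_grid()]; only its nodes are used, weights are
#'   recomputed from each group's prior.
#' @return Scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(data, params, groups, grid = latent_grid()) {
  stopifnot(inherits(groups, "group_structure"))
  nodes <- grid$nodes
  ll_group <- function(resp, items, mean, sd) {
    if (is.null(resp) || nrow(resp) == 0L) return(0)
    w <- stats::dnorm(nodes, mean, sd)
    w <- w / sum(w)
    L <- .pattern_loglik_matrix(resp, items, nodes)
    m <- apply(L, 1L, max)
    sum(m + log(exp(L - m) %*% w))
  }
  ll_group(data$ref, params$ref, 0, 1) +
    ll_group(data$foc, params$foc, groups$focal_mean,
             sqrt(groups$focal_variance))
}

#' Expected-a-posteriori trait score
#'
#' Posterior mean and standard deviation of the latent trait given a
#' response pattern, known item parameters, and a standard normal prior,
#' computed by quadrature. An all-missing (or empty) pattern returns the
#' prior moments of the grid.
#'
#' @inheritParams pattern_loglik
#' @param grid a [latent_grid()] carrying the prior (defaults to N(0,1)).
#' @return List with `mean` and `sd`.
#' @export
eap_score <- function(pattern, items, grid = latent_grid()) {
  if (length(items) == 0L) {
    warning("empty item list; returning prior moments")
    m <- sum(grid$weights * grid$nodes)
    return(list(mean = m,
                sd = sqrt(sum(grid$weights * grid$nodes^2) - m^2)))
  }
  res <- eap_scores(matrix(as.integer(pattern), nrow = 1L), items, grid)
  list(mean = res$mean[1L], sd = res$sd[1L])
}

#' @rdname eap_score
#' @param responses persons x items integer response matrix (`NA` missing).
#' @return For `eap_scores`, a data.frame with one row per person and
#'   columns `mean` and `sd`.
#' @export
eap_scores <- function(responses, items, grid = latent_grid()) {
  stopifnot(ncol(responses) == length(items))
  nodes <- grid$nodes
  L <- .pattern_loglik_matrix(responses, items, nodes)
  W <- exp(L) * rep(grid$weights, each = nrow(L))
  tot <- rowSums(W)
  m <- as.vector(W %*% nodes) / tot
  v <- as.vector(W %*% nodes^2) / tot - m^2
  data.frame(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Convert a logistic discrimination to a standardized factor loading
#'
#' The scaling constant `D = 1.7` applies only when converting a logistic
#' discrimination to the normal-ogive metric; with `a* = a / D`, the
#' standardized loading is `a* / sqrt(1 + a*^2)`. Used for reporting, never
#' in data generation or estimation.
#'
#' @param a logistic-metric discrimination(s).
#' @param D scaling constant (default 1.7).
#' @return Standardized factor loading(s).
#' @examples
#' a_to_loading(c(1.7, 3.5, 0.5, 1.0))
#' @export
a_to_loading <- function(a, D = 1.7) {
  astar <- a / D
  astar / sqrt(1 + astar^2)
}
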