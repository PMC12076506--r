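# Diffusion schedule. Reverse steps run t = T, T-1, ..., 1; "final" steps
# of the reverse process are the small-t end, where the anchoring weight
# gamma reaches 1 and masked atoms are clamped exactly onto their points.

#' Construct a diffusion schedule
#'
#' @param T_steps number of diffusion steps T.
#' @param beta noise schedule, vector of length T with values in [0, 1];
#'   default linear from 1e-4 to 0.1.
#' @param sigma_sq per-step sampling variance Sigma_t; defaults to beta.
#' @param gamma anchoring-weight vector, monotone non-increasing in t with
#'   gamma = 1 over the final hard-anchor window; defaults to
#'   `min(1, (1 - t/T)^2 / (1 - f))` clipped to 1 for
#'   `t <= ceiling(f * T)` with `f = hard_anchor_fraction`.
#' @param hard_anchor_fraction fraction f of final (small-t) steps with
#'   gamma = 1.
#' @return an object of class `ScheduleSpec`.
#' @export
make_schedule <- function(T_steps = 50L, beta = NULL, sigma_sq = NULL,
                          gamma = NULL, hard_anchor_fraction = 0.1) {
  T_steps <- as.integer(T_steps)
  if (T_steps < 1L) stop("T must be >= 1")
  if (is.null(beta)) beta <- seq(1e-4, 0.1, length.out = T_steps)
  if (length(beta) != T_steps) stop("beta must have length T")
  if (any(beta < 0 | beta > 1)) stop("all beta_t must lie in [0, 1]")
  if (is.null(sigma_sq)) sigma_sq <- beta
  if (length(sigma_sq) != T_steps) stop("sigma_sq must have length T")
  if (any(sigma_sq < 0)) stop("sigma_sq must be non-negative")
  f <- hard_anchor_fraction
  if (f < 0 || f >= 1) stop("hard_anchor_fraction must be in [0, 1)")
  n_hard <- ceiling(f * T_steps)
  if (is.null(gamma)) {
    t <- seq_len(T_steps)
    gamma <- pmin(1, (1 - t / T_steps)^2 / (1 - f))
    if (n_hard > 0L) gamma[seq_len(n_hard)] <- 1
  }
  if (length(gamma) != T_steps) stop("gamma must have length T")
  if (any(diff(gamma) > 1e-12))
    stop("gamma must be monotone non-increasing in t")
  if (n_hard > 0L && any(gamma[seq_len(n_hard)] != 1))
    stop("gamma must equal 1 over the hard-anchor window")
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  structure(list(T = T_steps, beta = beta, sigma_sq = sigma_sq,
                 gamma = gamma, hard_anchor_fraction = f,
                 n_hard = n_hard, alpha = alpha, alpha_bar = alpha_bar),
            class = "ScheduleSpec")
}

#' @export
print.ScheduleSpec <- function(x, ...) {
  cat(sprintf(
    "ScheduleSpec: T=%d, beta in [%.2g, %.2g], hard anchor over %d final steps\n",
    x$T, min(x$beta), max(x$beta), x$n_hard))
  invisible(x)
}
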