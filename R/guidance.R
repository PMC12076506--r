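# Clash guidance on a smoothed protein surface, masked position anchoring,
# and atom-type clamping -- the three conditioning primitives applied
# inside the reverse diffusion loop.

#' Smoothed distance to the protein surface
#'
#' The protein surface is described by the soft-minimum field
#' \deqn{S(r) = -\sigma \log \sum_j \exp(-\|r - a_j\| / \sigma)}
#' over protein heavy-atom positions a_j. S is a lower bound on the true
#' minimum atom distance and converges to it as sigma tends to 0.
#'
#' @param r numeric 3-vector or N x 3 matrix of query positions (Angstrom).
#' @param ctx a `ProteinContext` (supplies a_j and sigma).
#' @return numeric vector of surface distances, one per query row.
#' @export
protein_surface <- function(r, ctx) {
  if (is.null(dim(r))) r <- matrix(r, 1, 3)
  a <- ctx$atom_positions
  s <- ctx$sigma
  vapply(seq_len(nrow(r)), function(i) {
    d <- sqrt(colSums((t(a) - r[i, ])^2))
    m <- min(d)
    m - s * log(sum(exp(-(d - m) / s)))
  }, numeric(1))
}

#' Clash loss of a ligand configuration
#'
#' \deqn{L(R) = \sum_i \max(0, d_{clash} - S(r_i))^2}
#' Zero exactly when every atom's smoothed surface distance is at least the
#' clash threshold.
#'
#' @param R numeric N x 3 matrix of ligand atom positions.
#' @param ctx a `ProteinContext`.
#' @return non-negative scalar.
#' @export
clash_loss <- function(R, ctx) {
  s <- protein_surface(R, ctx)
  sum(pmax(0, ctx$clash_threshold - s)^2)
}

#' Analytic gradient of the clash loss
#'
#' Rows for non-clashing atoms are exactly zero. For a clashing atom the
#' gradient of L points toward the protein (L grows as the atom approaches
#' the surface); the sampler subtracts `lambda * Sigma_t * grad`, so the
#' applied guidance shift pushes the atom away.
#'
#' @param R numeric N x 3 matrix of ligand atom positions.
#' @param ctx a `ProteinContext`.
#' @return N x 3 matrix, `dL/dR`.
#' @export
clash_gradient <- function(R, ctx) {
  if (is.null(dim(R))) R <- matrix(R, 1, 3)
  a <- ctx$atom_positions
  s <- ctx$sigma
  g <- matrix(0, nrow(R), 3)
  for (i in seq_len(nrow(R))) {
    diff <- t(t(a) * -1 + R[i, ])          # a_j -> r_i vectors
    d <- sqrt(rowSums(diff^2))
    m <- min(d)
    w <- exp(-(d - m) / s)
    S <- m - s * log(sum(w))
    h <- ctx$clash_threshold - S
    if (h <= 0) next
    w <- w / sum(w)
    # dS/dr = sum_j w_j * (r - a_j)/||r - a_j||
    u <- diff / pmax(d, 1e-12)
    dS <- colSums(u * w)
    g[i, ] <- -2 * h * dS
  }
  g
}

#' Anchor masked atom positions toward their pharmacophore points
#'
#' Masked row k becomes the convex combination
#' `(1 - gamma_t) * r_pred_k + gamma_t * p_k`; unmasked rows are returned
#' bit-identical. In the default mode the reference points are used at
#' their original coordinates. In `noised_reference` mode the points are
#' forward-noised to level t
#' (`sqrt(abar_t) * p + sqrt(1 - abar_t) * eps`) before mixing.
#'
#' @param r_pred N x 3 matrix of sampled positions at step t.
#' @param spec a `ConstraintSpec`.
#' @param t current reverse step (T down to 1).
#' @param sched a `ScheduleSpec`.
#' @param noised_points optional m x 3 matrix replacing the original point
#'   coordinates (used by the noised-reference ablation mode).
#' @return N x 3 matrix.
#' @export
anchor_positions <- function(r_pred, spec, t, sched, noised_points = NULL) {
  m <- n_points(spec)
  if (m == 0L) return(r_pred)
  gam <- sched$gamma[t]
  pts <- if (is.null(noised_points)) point_matrix(spec) else noised_points
  idx <- seq_len(m)
  r_pred[idx, ] <- (1 - gam) * r_pred[idx, , drop = FALSE] + gam * pts
  r_pred
}

#' Clamp user-fixed atom types on masked slots
#'
#' @param type_sample character vector of sampled element symbols, length N.
#' @param spec a `ConstraintSpec` (uses `fixed_atom_types`).
#' @param vocabulary optional element vocabulary to validate the fixed
#'   types against.
#' @return character vector with masked slots overwritten where a fixed
#'   type is specified.
#' @export
clamp_types <- function(type_sample, spec, vocabulary = NULL) {
  ft <- spec$fixed_atom_types
  if (is.null(ft)) return(type_sample)
  if (!is.null(vocabulary)) {
    bad <- setdiff(ft[!is.na(ft)], vocabulary)
    if (length(bad) > 0L)
      stop("fixed atom type outside denoiser vocabulary: ",
           paste(bad, collapse = ", "))
  }
  for (k in seq_along(ft)) {
    if (!is.na(ft[k])) type_sample[k] <- ft[k]
  }
  type_sample
}

#' Guidance configuration
#'
#' @param lam guidance strength lambda (>= 0); 0 disables clash guidance.
#' @param max_attempts reverse-trajectory attempts per requested ligand
#'   before giving up (default 3).
#' @param init_mode initialization strategy: `"around_points"` (isotropic
#'   Gaussian around the pharmacophore points), `"pure_random"` (around the
#'   pocket origin) or `"noised_reference"` (around points, with the
#'   reference points forward-noised at every step).
#' @param init_spread standard deviation of the initialization Gaussian in
#'   Angstrom.
#' @param seed integer master seed; all randomness of a run derives from it
#'   through a counter-based splitting scheme.
#' @param grad_at where the clash gradient is evaluated: at the current
#'   state `"R_t"` (default) or at the predicted mean `"mu"`.
#' @return an object of class `GuidanceConfig`.
#' @export
guidance_config <- function(lam = 0.1, max_attempts = 3L,
                            init_mode = c("around_points", "pure_random",
                                          "noised_reference"),
                            init_spread = 1.0, seed = 1L,
                            grad_at = c("R_t", "mu")) {
  init_mode <- match.arg(init_mode)
  grad_at <- match.arg(grad_at)
  if (lam < 0) stop("config error: lambda must be >= 0")
  if (max_attempts < 1L) stop("max_attempts must be >= 1")
  if (!(init_spread > 0)) stop("init_spread must be > 0")
  structure(list(lam = lam, max_attempts = as.integer(max_attempts),
                 init_mode = init_mode, init_spread = init_spread,
                 seed = as.integer(seed), grad_at = grad_at),
            class = "GuidanceConfig")
}

# Counter-based seed splitting: one master seed, disjoint substreams per
# (ligand, attempt, step, purpose). Kept below 2^31.
derive_seed <- function(seed, ligand = 0L, attempt = 0L, step = 0L,
                        purpose = 0L) {
  x <- (as.double(seed) %% 2147483647)
  for (k in c(ligand, attempt, step, purpose)) {
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(x)
}

#' Initialize atom positions for a reverse trajectory
#'
#' @param spec a `ConstraintSpec`.
#' @param n_atoms number of atom slots.
#' @param mode `"around_points"`, `"pure_random"` or `"noised_reference"`
#'   (the latter initializes like `"around_points"`).
#' @param spread isotropic Gaussian standard deviation in Angstrom.
#' @param seed integer seed (draws are deterministic given it).
#' @param noise optional pre-drawn N x 3 standard-normal matrix overriding
#'   the internal draw (used for equivariance checks).
#' @return N x 3 matrix. Masked slots are centred on their bound points,
#'   free slots on the centroid of the points (or the origin when there are
#'   no points, with a warning for `around_points`).
#' @export
init_positions <- function(spec, n_atoms, mode = "around_points",
                           spread = 1.0, seed = 1L, noise = NULL) {
  m <- n_points(spec)
  if (mode %in% c("around_points", "noised_reference") && m == 0L) {
    warning("empty constraint spec: falling back to pure_random init")
    mode <- "pure_random"
  }
  centers <- matrix(0, n_atoms, 3)
  if (mode %in% c("around_points", "noised_reference")) {
    pm <- point_matrix(spec)
    centers[seq_len(m), ] <- pm
    if (n_atoms > m) {
      centers[(m + 1L):n_atoms, ] <- matrix(colMeans(pm), n_atoms - m, 3,
                                            byrow = TRUE)
    }
  }
  if (is.null(noise)) {
    set.seed(seed)
    noise <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
  }
  centers + spread * noise
}

#' One guided reverse-diffusion position update
#'
#' Samples `R_{t-1} ~ Normal(mu_theta - lambda * Sigma_t * grad L, Sigma_t I)`
#' where the clash gradient is evaluated at the current state `R_t` (or at
#' the predicted mean when configured).
#'
#' @param out a `DenoiserOutput` (list with `mu`, `sigma_sq_t`).
#' @param R_t N x 3 current positions.
#' @param ctx a `ProteinContext`, or NULL to disable guidance.
#' @param cfg a `GuidanceConfig` (uses `lam`, `grad_at`).
#' @param seed integer seed for the Gaussian draw.
#' @param noise optional pre-drawn N x 3 standard-normal matrix.
#' @return N x 3 matrix of updated positions.
#' @export
guided_step <- function(out, R_t, ctx, cfg, seed = 1L, noise = NULL) {
  if (cfg$lam < 0) stop("config error: lambda must be >= 0")
  mu <- out$mu
  if (cfg$lam > 0 && !is.null(ctx)) {
    at <- if (cfg$grad_at == "mu") mu else R_t
    mu <- mu - cfg$lam * out$sigma_sq_t * clash_gradient(at, ctx)
  }
  if (is.null(noise)) {
    set.seed(seed)
    noise <- matrix(rnorm(nrow(mu) * 3), nrow(mu), 3)
  }
  mu + sqrt(out$sigma_sq_t) * noise
}
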