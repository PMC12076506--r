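# Denoiser contract and the closed-form toy denoiser.
#
# A denoiser is a list with three functions:
#   denoise(positions, types, bonds, t) -> DenoiserOutput
#   vocabulary() -> character vector of element symbols
#   schedule()   -> ScheduleSpec
# Any model satisfying this contract can be conditioned by [sample_ligands()].

#' Construct a denoiser output
#'
#' @param mu N x 3 predicted position means.
#' @param type_logits N x K atom-type categorical logits.
#' @param bond_logits N x N x B bond categorical logits.
#' @param sigma_sq_t sampling variance at the current step.
#' @return an object of class `DenoiserOutput`.
#' @export
denoiser_output <- function(mu, type_logits, bond_logits, sigma_sq_t) {
  if (!all(is.finite(mu))) stop("mu must be finite")
  if (!all(is.finite(type_logits))) stop("type_logits must be finite")
  if (nrow(type_logits) != nrow(mu)) stop("type_logits shape mismatch")
  structure(list(mu = mu, type_logits = type_logits,
                 bond_logits = bond_logits, sigma_sq_t = sigma_sq_t),
            class = "DenoiserOutput")
}

#' Closed-form toy denoiser
#'
#' An analytic stand-in for a trained equivariant denoising network, used
#' to exercise the full conditioning loop without weights. The forward
#' process is `q(r_t | r_0) = Normal(sqrt(abar_t) r_0, (1 - abar_t) I)`
#' with `abar_t = prod(1 - beta_s)`; `denoise` returns the exact Gaussian
#' posterior mean of `r_{t-1}` given `r_t` and the ground-truth template
#' `r_0*`, written in the centred form
#' `mu = c1 r_0 + c2 r_t + (1 - c1 - c2) centroid(r_0)` so that the closed
#' form is exactly E(3)-equivariant (for an origin-centred template it
#' coincides with the plain posterior mean). Atom-type and bond logits are
#' one-hot encodings of the template.
#'
#' @param template a `Molecule3D`, the ground-truth ligand r_0*.
#' @param sched a `ScheduleSpec`.
#' @param vocabulary element vocabulary; default `c("C", "N", "O")`.
#' @return a denoiser object (list of `denoise`, `vocabulary`, `schedule`).
#' @export
toy_denoiser <- function(template, sched, vocabulary = c("C", "N", "O")) {
  r0 <- template$positions
  n <- nrow(r0)
  cen <- colMeans(r0)
  K <- length(vocabulary)
  tl <- matrix(0, n, K)
  tl[cbind(seq_len(n), match(template$atom_types, vocabulary))] <- 50
  B <- 2L  # bond states: none, single
  bl <- array(0, c(n, n, B))
  bl[, , 1] <- 50 * (template$bonds == 0L)
  bl[, , 2] <- 50 * (template$bonds == 1L)
  denoise <- function(positions, types, bonds, t) {
    if (t < 1L || t > sched$T) stop("step error: t out of [1, T]")
    if (nrow(positions) != n)
      stop("toy denoiser requires ", n, " atoms")
    abar_t <- sched$alpha_bar[t]
    abar_p <- if (t > 1L) sched$alpha_bar[t - 1L] else 1
    beta_t <- sched$beta[t]
    alpha_t <- sched$alpha[t]
    c1 <- sqrt(abar_p) * beta_t / (1 - abar_t)
    c2 <- sqrt(alpha_t) * (1 - abar_p) / (1 - abar_t)
    mu <- c1 * r0 + c2 * positions +
      matrix((1 - c1 - c2) * cen, n, 3, byrow = TRUE)
    denoiser_output(mu, tl, bl, sched$sigma_sq[t])
  }
  structure(list(denoise = denoise,
                 vocabulary = function() vocabulary,
                 schedule = function() sched,
                 n_atoms = n),
            class = c("toy_denoiser", "DenoiserInterface"))
}

#' MolDiff adapter stub
#'
#' Documents the checkpoint-loading contract for plugging a trained
#' bond-diffusing denoiser into the sampler. Loading trained weights is out
#' of scope for this package; calling this function always signals an
#' error describing the required interface.
#'
#' @param checkpoint path to a trained model checkpoint.
#' @return never returns.
#' @export
moldiff_denoiser <- function(checkpoint) {
  stop("moldiff adapter not implemented: supply an object with ",
       "denoise(positions, types, bonds, t) -> DenoiserOutput, ",
       "vocabulary() and schedule(), backed by the trained checkpoint ",
       "at ", checkpoint)
}
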