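# The conditioned reverse-diffusion sampling loop with the three-attempt
# retry policy. Per step: denoise -> guidance shift -> sample -> anchor ->
# clamp types; anchoring last guarantees the satisfaction geometry
# regardless of guidance.

.draw_noise <- function(seed, n) {
  set.seed(seed)
  matrix(rnorm(n * 3), n, 3)
}

.sample_categorical_rows <- function(logits, seed) {
  set.seed(seed)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  u <- runif(nrow(p))
  cp <- t(apply(p, 1, cumsum))
  vapply(seq_len(nrow(p)), function(i) {
    sum(u[i] > cp[i, ]) + 1L
  }, integer(1))
}

.argmax_bonds <- function(bond_logits) {
  n <- dim(bond_logits)[1]
  b <- matrix(0L, n, n)
  for (s in seq_len(dim(bond_logits)[3])) {
    sel <- bond_logits[, , s] >= apply(bond_logits, c(1, 2), max)
    if (s > 1L) b[sel] <- s - 1L
  }
  b <- pmax(b, t(b))
  diag(b) <- 0L
  b
}

run_trajectory <- function(denoiser, spec, ctx, cfg, sched, n_slots,
                           ligand, attempt, noise_transform = NULL,
                           mode = cfg$init_mode, keep_trace = FALSE) {
  vocab <- denoiser$vocabulary()
  tf <- if (is.null(noise_transform)) identity else noise_transform
  eps0 <- tf(.draw_noise(derive_seed(cfg$seed, ligand, attempt, 0L, 1L),
                         n_slots))
  R <- init_positions(spec, n_slots, mode = mode,
                      spread = cfg$init_spread, noise = eps0)
  set.seed(derive_seed(cfg$seed, ligand, attempt, 0L, 2L))
  types <- vocab[sample.int(length(vocab), n_slots, replace = TRUE)]
  types <- clamp_types(types, spec, vocab)
  bonds <- matrix(0L, n_slots, n_slots)
  pts <- point_matrix(spec)
  clash_trace <- numeric(0)
  trace <- if (keep_trace) list(R) else NULL
  for (t in seq(sched$T, 1L)) {
    out <- denoiser$denoise(R, types, bonds, t)
    eps <- tf(.draw_noise(derive_seed(cfg$seed, ligand, attempt, t, 3L),
                          n_slots))
    R <- guided_step(out, R, ctx, cfg, noise = eps)
    np <- NULL
    if (mode == "noised_reference" && n_points(spec) > 0L) {
      epsp <- tf(.draw_noise(derive_seed(cfg$seed, ligand, attempt, t, 4L),
                             n_points(spec)))
      np <- sqrt(sched$alpha_bar[t]) * pts +
        sqrt(1 - sched$alpha_bar[t]) * epsp
    }
    R <- anchor_positions(R, spec, t, sched, noised_points = np)
    ti <- .sample_categorical_rows(
      out$type_logits, derive_seed(cfg$seed, ligand, attempt, t, 5L))
    types <- clamp_types(vocab[ti], spec, vocab)
    bonds <- .argmax_bonds(out$bond_logits)
    if (keep_trace) trace[[length(trace) + 1L]] <- R
    if (!is.null(ctx)) clash_trace <- c(clash_trace, clash_loss(R, ctx))
  }
  mol <- molecule3d(types, R, bonds,
                    name = sprintf("gen_l%d_a%d", ligand, attempt))
  list(mol = mol, clash_trace = clash_trace, trace = trace)
}

#' Generate ligands by conditioned reverse diffusion
#'
#' For each requested ligand, up to `cfg$max_attempts` full reverse
#' trajectories are run (initialization, then per step: denoise, clash
#' guidance, Gaussian sample, masked-position anchoring, atom-type
#' clamping); the first attempt whose final molecule satisfies the
#' pharmacophore spec is accepted. Bond states are taken from the denoiser
#' unchanged.
#'
#' @param denoiser a denoiser object (see [toy_denoiser()]).
#' @param spec a `ConstraintSpec`.
#' @param ctx a `ProteinContext` or NULL (no clash guidance, no clash
#'   bookkeeping).
#' @param cfg a `GuidanceConfig`.
#' @param n_ligands number of ligands requested.
#' @param sched schedule; defaults to the denoiser's.
#' @param noise_transform optional function applied to every internal
#'   standard-normal draw (rotating the noise stream makes the whole
#'   sampler exactly equivariant under the same rotation of all inputs).
#' @param keep_trace store the per-step position matrices of each accepted
#'   ligand's trajectory in the report (`traces`).
#' @return a `GenerationReport`: list with `requested`, `accepted` (list of
#'   `Molecule3D`), `attempts` (per-ligand attempts used), `satisfied`
#'   (per-ligand verdicts), `reports` (per-ligand satisfaction report of
#'   the last attempt), `rejections` (data.frame log of every rejected
#'   attempt), `final_clash` (clash loss of each accepted ligand) and
#'   `clash_summary` (per-accepted-ligand mean/final clash loss over the
#'   trajectory).
#' @export
sample_ligands <- function(denoiser, spec, ctx, cfg, n_ligands,
                           sched = denoiser$schedule(),
                           noise_transform = NULL, keep_trace = FALSE) {
  ft <- spec$fixed_atom_types
  if (!is.null(ft)) {
    bad <- setdiff(ft[!is.na(ft)], denoiser$vocabulary())
    if (length(bad) > 0L)
      stop("fixed atom type outside denoiser vocabulary: ",
           paste(bad, collapse = ", "))
  }
  n_slots <- length(spec$mask)
  mode <- cfg$init_mode
  if (n_points(spec) == 0L && mode != "pure_random") mode <- "pure_random"
  accepted <- list()
  traces <- list()
  attempts <- integer(0)
  satisfied <- logical(0)
  reports <- list()
  rejections <- list()
  final_clash <- numeric(0)
  clash_summary <- list()
  if (n_ligands > 0L) {
    for (l in seq_len(n_ligands)) {
      got <- FALSE
      a <- 0L
      while (!got && a < cfg$max_attempts) {
        a <- a + 1L
        tr <- run_trajectory(denoiser, spec, ctx, cfg, sched, n_slots,
                             ligand = l, attempt = a,
                             noise_transform = noise_transform,
                             mode = mode, keep_trace = keep_trace)
        sat <- satisfaction(tr$mol, spec)
        if (sat$satisfied) {
          got <- TRUE
          accepted[[length(accepted) + 1L]] <- tr$mol
          if (keep_trace) traces[[length(traces) + 1L]] <- tr$trace
          reports[[l]] <- sat$report
          if (!is.null(ctx)) {
            fc <- clash_loss(tr$mol$positions, ctx)
            final_clash <- c(final_clash, fc)
            clash_summary[[length(clash_summary) + 1L]] <-
              c(mean = mean(tr$clash_trace), final = fc)
          }
        } else {
          rejections[[length(rejections) + 1L]] <- data.frame(
            ligand = l, attempt = a,
            unsatisfied_points = sum(!sat$report$satisfied))
          reports[[l]] <- sat$report
        }
      }
      attempts <- c(attempts, a)
      satisfied <- c(satisfied, got)
    }
  }
  structure(list(
    requested = as.integer(n_ligands),
    accepted = accepted,
    attempts = attempts,
    satisfied = satisfied,
    reports = reports,
    rejections = if (length(rejections)) do.call(rbind, rejections)
                 else data.frame(ligand = integer(0), attempt = integer(0),
                                 unsatisfied_points = integer(0)),
    final_clash = final_clash,
    clash_summary = clash_summary,
    traces = if (keep_trace) traces else NULL
  ), class = "GenerationReport")
}

#' @export
print.GenerationReport <- function(x, ...) {
  cat(sprintf("GenerationReport: %d/%d accepted (attempts: %s)\n",
              length(x$accepted), x$requested,
              paste(x$attempts, collapse = " ")))
  invisible(x)
}

#' Unconditional reverse diffusion with a denoiser
#'
#' The plain sampling chain (initialization around the origin, then per
#' step denoise and Gaussian sample) with the same counter-based seed
#' derivation as [sample_ligands()]. Conditioning with an empty constraint
#' spec and `lambda = 0` reproduces this chain bit-exactly under a shared
#' seed.
#'
#' @param denoiser a denoiser object.
#' @param n_atoms number of atoms.
#' @param cfg a `GuidanceConfig` (uses `seed`, `init_spread`,
#'   `max_attempts` is ignored; one trajectory per ligand).
#' @param n_ligands number of molecules to draw.
#' @param sched schedule; defaults to the denoiser's.
#' @return list of `Molecule3D`.
#' @export
sample_unconditional <- function(denoiser, n_atoms, cfg, n_ligands,
                                 sched = denoiser$schedule()) {
  vocab <- denoiser$vocabulary()
  empty <- build_constraints(list(), tau = 1.0, slots = n_atoms)
  out <- vector("list", n_ligands)
  for (l in seq_len(n_ligands)) {
    eps0 <- .draw_noise(derive_seed(cfg$seed, l, 1L, 0L, 1L), n_atoms)
    R <- cfg$init_spread * eps0
    set.seed(derive_seed(cfg$seed, l, 1L, 0L, 2L))
    types <- vocab[sample.int(length(vocab), n_atoms, replace = TRUE)]
    bonds <- matrix(0L, n_atoms, n_atoms)
    for (t in seq(sched$T, 1L)) {
      o <- denoiser$denoise(R, types, bonds, t)
      eps <- .draw_noise(derive_seed(cfg$seed, l, 1L, t, 3L), n_atoms)
      R <- o$mu + sqrt(o$sigma_sq_t) * eps
      ti <- .sample_categorical_rows(
        o$type_logits, derive_seed(cfg$seed, l, 1L, t, 5L))
      types <- vocab[ti]
      bonds <- .argmax_bonds(o$bond_logits)
    }
    out[[l]] <- molecule3d(types, R, bonds, name = sprintf("uncond_l%d", l))
  }
  out
}
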